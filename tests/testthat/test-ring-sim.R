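test_that("dipole model: on-axis and in-plane closed forms, zero strength, singularity", {
  kappa <- 40
  loop <- current_loop(radius = 1.39, strength = kappa)
  z <- 2.5
  sig <- tensor_matrix(loop_tensor_dipole(loop, c(0, 0, z)))
  expect_equal(sig[3, 3], 2 * kappa / z^3, tolerance = 1e-12)
  expect_equal(sig[1, 1], 0, tolerance = 1e-12)
  expect_equal(sig[2, 2], 0, tolerance = 1e-12)

  d <- 3.2
  sig_in <- tensor_matrix(loop_tensor_dipole(loop, c(d, 0, 0)))
  expect_equal(sig_in[3, 3], -kappa / d^3, tolerance = 1e-12)

  zero <- current_loop(strength = 0)
  expect_equal(tensor_matrix(loop_tensor_dipole(zero, c(1, 1, 1))), matrix(0, 3, 3))
  expect_error(loop_tensor_dipole(loop, c(0, 0, 0)), "coincides")
})

test_that("qualitative NICS sign pattern: shielded on-axis, deshielded in-plane, reversed for paratropic", {
  dia <- current_loop(strength = 40)
  para <- current_loop(strength = -40)
  n <- c(0, 0, 1)
  for (z in c(1, 2, 3)) {
    expect_lt(nics_component(loop_tensor_dipole(dia, c(0, 0, z)), n)$nics, 0)
    expect_gt(nics_component(loop_tensor_dipole(para, c(0, 0, z)), n)$nics, 0)
  }
  for (d in c(2.5, 4, 6)) {
    expect_gt(nics_component(loop_tensor_dipole(dia, c(d, 0, 0)), n)$nics, 0)
    expect_lt(nics_component(loop_tensor_dipole(para, c(d, 0, 0)), n)$nics, 0)
  }
})

test_that("Biot-Savart loop matches the on-axis closed form within 0.1% at 512 segments", {
  loop <- current_loop(radius = 1.39, strength = 40, normal = c(0, 0, 1))
  for (z in c(0.5, 1, 2, 4)) {
    got <- tensor_matrix(loop_tensor_biot_savart(loop, c(0, 0, z), 512))[3, 3]
    want <- loop_axial_shielding(z, 1.39, 40)
    expect_lt(abs(got - want) / abs(want), 0.001)
  }
  # tilted loop: component along its own normal
  tilt <- current_loop(radius = 1.0, strength = -25, normal = c(1, 1, 1))
  nh <- c(1, 1, 1) / sqrt(3)
  got <- nics_component(
    loop_tensor_biot_savart(tilt, 2 * nh, 512), nh
  )$nics
  expect_lt(abs(got - -loop_axial_shielding(2, 1, -25)) / abs(got), 0.001)
})

test_that("Biot-Savart converges to the point dipole in the far field (|d| = 20a, off-axis)", {
  loop <- current_loop(radius = 1, strength = 40)
  dirs <- list(c(0, 0, 1), c(1, 0, 1) / sqrt(2), c(0.3, -0.5, 0.81))
  for (u in dirs) {
    p <- 20 * (u / sqrt(sum(u^2)))
    bs <- tensor_matrix(loop_tensor_biot_savart(loop, p, 512))
    dp <- tensor_matrix(loop_tensor_dipole(loop, p))
    expect_lt(max(abs(bs - dp)) / max(abs(dp)), 0.01)
  }
})

test_that("Biot-Savart discretisation error: doubling segments changes the result < 0.01% at 3a", {
  loop <- current_loop(radius = 1.2, strength = 30)
  p <- c(2.1, 1.7, 1.9) # |p| ~ 3.3a, off-axis
  a <- tensor_matrix(loop_tensor_biot_savart(loop, p, 512))
  b <- tensor_matrix(loop_tensor_biot_savart(loop, p, 1024))
  expect_lt(max(abs(a - b)) / max(abs(b)), 1e-4)
  expect_error(loop_tensor_biot_savart(loop, c(1.2, 0, 0)), "wire")
  expect_error(loop_tensor_biot_savart(loop, c(0, 0, 1), 4), "n_segments")
})

test_that("field_scan superposes loops additively and reports singular pairs", {
  h <- 1.5
  loops <- dplyr::bind_rows(
    current_loop(centre = c(0, 0, -h), strength = 40, label = "lower"),
    current_loop(centre = c(0, 0, h), strength = 40, label = "upper")
  )
  mid <- as_probe_set(tibble::tibble(label = "mid", x = 0, y = 0, z = 0))
  sig <- tensor_matrix(field_scan(loops, mid))
  expect_equal(sig[3, 3], 2 * (2 * 40 / h^3), tolerance = 1e-12)

  # axial scan: magnitude decreases monotonically with distance
  probes <- ring_probes(c(0, 0, 0), c(0, 0, 1), offsets = seq(1, 4, by = 0.5))
  one <- field_scan(current_loop(strength = 40), probes)
  zz <- vapply(seq_len(nrow(one)), function(i) tensor_matrix(one, i)[3, 3], numeric(1))
  expect_true(all(diff(abs(zz)) < 0))

  empty <- field_scan(loops[0, ], mid)
  expect_equal(tensor_matrix(empty), matrix(0, 3, 3))

  bad <- as_probe_set(tibble::tibble(label = "centre", x = 0, y = 0, z = -h))
  expect_error(field_scan(loops, bad), "'lower' / probe 'centre'")
})

test_that("stacked paratropic rings reproduce the through-space mid-gap NICS structure", {
  # In the flat-ring model a loop responds only to the field along its
  # normal, so coplanar ring currents cannot shield in-plane directions:
  # at the mid-gap point of a coaxial paratropic stack the in-plane NICS
  # components vanish identically while the out-of-plane component stays
  # strongly antiaromatic. That is precisely the argument for interpreting
  # strong observed in-plane shielding between stacked rings as
  # through-space currents. Adding an explicit through-space loop (current
  # circulating in a plane containing the stacking axis) produces the
  # negative in-plane NICS component the flat rings cannot.
  h <- 1.7
  stacked <- dplyr::bind_rows(
    current_loop(centre = c(0, 0, -h), strength = -60, label = "a"),
    current_loop(centre = c(0, 0, h), strength = -60, label = "b")
  )
  mid <- as_probe_set(tibble::tibble(label = "mid", x = 0, y = 0, z = 0))
  sig <- field_scan(stacked, mid)
  ex <- c(1, 0, 0)
  ez <- c(0, 0, 1)
  expect_gt(nics_component(sig, ez)$nics, 0) # antiaromatic out-of-plane
  expect_equal(nics_component(sig, ex)$nics, 0, tolerance = 1e-12)
  expect_equal(nics_component(sig, c(0, 1, 0))$nics, 0, tolerance = 1e-12)

  through_space <- current_loop(
    centre = c(0, 0, 0), normal = c(1, 0, 0),
    radius = h, strength = 50, label = "through-space"
  )
  with_ts <- field_scan(dplyr::bind_rows(stacked, through_space), mid,
    method = "biot-savart"
  )
  expect_lt(nics_component(with_ts, ex)$nics, 0) # in-plane shielding appears
  expect_gt(nics_component(with_ts, ez)$nics, 0) # out-of-plane still deshielded
})

test_that("loop strength and radius are recovered within 5% from a noisy 21-point axial scan", {
  true_kappa <- 40
  true_a <- 1.39
  scan <- simulate_axial_scan(
    current_loop(radius = true_a, strength = true_kappa),
    offsets = seq(0.5, 4.5, length.out = 21), noise_sd = 0.1, seed = 1
  )
  expect_equal(nrow(scan), 21)
  fit <- fit_loop(scan)
  est <- tidy(fit)
  kappa_hat <- est$estimate[est$term == "strength"]
  a_hat <- est$estimate[est$term == "radius"]
  expect_lt(abs(kappa_hat - true_kappa) / true_kappa, 0.05)
  expect_lt(abs(a_hat - true_a) / true_a, 0.05)
  expect_true(glance(fit)$converged)
})

test_that("loop configs load from YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "loops:",
    "  - centre: [0, 0, -1.5]",
    "    normal: [0, 0, 1]",
    "    radius: 1.8",
    "    strength: -60",
    "    label: lower",
    "  - centre: [0, 0, 1.5]",
    "    radius: 1.8",
    "    strength: -60"
  ), f)
  loops <- read_loops(f)
  expect_equal(nrow(loops), 2)
  expect_equal(loops$cz, c(-1.5, 1.5))
  expect_equal(loops$strength, c(-60, -60))
  expect_equal(loops$label[1], "lower")
  writeLines("other: 1", f)
  expect_error(read_loops(f), "no `loops:`")
})
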