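test_that("symmetrize is idempotent, forced on off-diagonal pairs, and leaves an antisymmetric remainder", {
  sym <- shielding_tensor(rand_symmetric(), label = "s")
  expect_equal(symmetrize_tensors(sym), sym)

  m <- matrix(0, 3, 3)
  m[1, 2] <- 4
  tb <- symmetrize_tensors(shielding_tensor(m))
  expect_equal(tensor_matrix(tb)[1, 2], 2)
  expect_equal(tensor_matrix(tb)[2, 1], 2)

  set.seed(11)
  for (k in 1:20) {
    sig <- rand_tensor()
    out <- tensor_matrix(symmetrize_tensors(shielding_tensor(sig)))
    a <- out - sig
    expect_equal(a, -t(a), tolerance = 1e-12)
    expect_equal(symmetrize_tensors(symmetrize_tensors(shielding_tensor(sig))),
      symmetrize_tensors(shielding_tensor(sig)))
  }
})

test_that("decomposition of a diagonal tensor recovers eigenvalues and coordinate axes", {
  v <- vist(diag(c(20, -5, -5)))
  expect_equal(v$eigenvalues, c(20, -5, -5))
  # axes are coordinate axes; the degenerate -5 pair may appear in either
  # order (the tie-break prefers the axis closest to +z)
  expect_equal(v$axes[, 1], c(1, 0, 0), tolerance = 1e-12)
  expect_true(all(abs(v$axes) %in% c(0, 1)))
  expect_equal(crossprod(v$axes), diag(3), tolerance = 1e-12)
  expect_equal(v$axes[3, 2], 1) # tie-break: z-aligned axis first
  expect_false(v$complex_flag)
})

test_that("benzene ring-centre tensor gives dominant out-of-plane -13.3 ppm and isotropic -8.9 ppm", {
  res <- vist_decompose(benzene_nics0_tensor())
  expect_equal(res$nics[res$component == 1], -13.3)
  expect_equal(res$nics_iso[1], -8.9)
  # dominant axis is out-of-plane (x here, since 13.3 sits on s_xx)
  expect_equal(abs(res[res$component == 1, c("axis_x", "axis_y", "axis_z")]),
    tibble::tibble(axis_x = 1, axis_y = 0, axis_z = 0),
    tolerance = 1e-10
  )
})

test_that("eigenvalues match the characteristic-polynomial oracle for non-symmetric ring-sim tensors", {
  loop <- current_loop(radius = 1.39, strength = 40)
  pts <- list(c(1.1, 0.4, 0.9), c(-0.8, 1.3, 1.7), c(2.5, -0.3, 0.4))
  for (p in pts) {
    sig <- tensor_matrix(loop_tensor_dipole(loop, p))
    expect_gt(max(abs(sig - t(sig))), 1e-6) # genuinely non-symmetric off-axis
    got <- vist(sig, mode = "right-eigen")$eigenvalues
    expect_equal(got, Re(oracle_eigenvalues(sig)), tolerance = 1e-8)
  }
})

test_that("eigenvalue sum equals the trace in both modes (random tensors)", {
  set.seed(21)
  for (k in 1:200) {
    sig <- rand_tensor()
    for (mode in c("symmetrized", "right-eigen")) {
      v <- vist(sig, mode = mode)
      expect_equal(sum(v$eigenvalues), sum(diag(sig)),
        tolerance = 1e-8
      )
    }
  }
})

test_that("result invariants hold: unit axes, magnitude ordering, orthogonality in symmetrized mode", {
  set.seed(31)
  for (k in 1:100) {
    v <- vist(rand_tensor())
    norms <- sqrt(colSums(v$axes^2))
    expect_equal(norms, rep(1, 3), tolerance = 1e-10)
    expect_true(all(diff(abs(v$eigenvalues)) <= 1e-9))
    gram <- crossprod(v$axes)
    expect_equal(gram, diag(3), tolerance = 1e-8)
    expect_false(v$complex_flag)
  }
})

test_that("symmetrized and right-eigen modes agree exactly on symmetric tensors", {
  set.seed(41)
  for (k in 1:50) {
    sig <- rand_symmetric()
    a <- vist(sig, mode = "symmetrized")
    b <- vist(sig, mode = "right-eigen")
    expect_equal(a$eigenvalues, b$eigenvalues, tolerance = 1e-10)
    expect_false(b$complex_flag)
    expect_equal(abs(colSums(a$axes * b$axes)), rep(1, 3), tolerance = 1e-8)
  }
})

test_that("rotation equivariance: eigenvalues invariant, axes rotate (up to sign)", {
  set.seed(51)
  for (k in 1:50) {
    sig <- rand_tensor()
    r <- rand_rotation()
    v0 <- vist(sig)
    v1 <- vist(r %*% sig %*% t(r))
    expect_equal(v1$eigenvalues, v0$eigenvalues, tolerance = 1e-8)
    if (min(abs(diff(abs(v0$eigenvalues)))) > 1e-3) { # skip degenerate subspaces
      dots <- abs(colSums((r %*% v0$axes) * v1$axes))
      expect_equal(dots, rep(1, 3), tolerance = 1e-8)
    }
  }
})

test_that("complex conjugate pairs in right-eigen mode are flagged, not dropped", {
  # a rotation-like tensor with a complex pair
  sig <- matrix(c(
    0, -5, 0,
    5, 0, 0,
    0, 0, 3
  ), 3, 3, byrow = TRUE) + diag(c(1, 1, 0))
  v <- vist(sig, mode = "right-eigen")
  expect_true(v$complex_flag)
  expect_gt(v$imag_max, 1)
  expect_equal(sum(v$eigenvalues), sum(diag(sig)), tolerance = 1e-8)
  # symmetric inputs never flag
  set.seed(61)
  for (k in 1:20) {
    expect_false(vist(rand_symmetric(), mode = "right-eigen")$complex_flag)
  }
})

test_that("isotropic NICS equals -trace/3 and -mean eigenvalue in both modes", {
  expect_equal(nics_iso(shielding_tensor(matrix(0, 3, 3)))$nics_iso, 0)
  expect_equal(nics_iso(benzene_nics0_tensor())$nics_iso, -8.9)
  set.seed(71)
  for (k in 1:50) {
    sig <- rand_tensor()
    tb <- shielding_tensor(sig)
    ni <- nics_iso(tb)$nics_iso
    expect_equal(ni, -mean(Re(oracle_eigenvalues(sig))), tolerance = 1e-8)
    for (mode in c("symmetrized", "right-eigen")) {
      expect_equal(ni, -mean(vist(sig, mode = mode)$eigenvalues),
        tolerance = 1e-10
      )
    }
  }
})

test_that("directional NICS: out-of-plane projection, trace identity, rotation equivariance", {
  b <- benzene_nics0_tensor()
  expect_equal(nics_component(b, c(1, 0, 0))$nics, -13.3)
  expect_error(nics_component(b, c(1, 1, 0)), "unit")
  set.seed(81)
  for (k in 1:30) {
    sig <- rand_tensor()
    tb <- shielding_tensor(sig)
    avg <- mean(c(
      nics_component(tb, c(1, 0, 0))$nics,
      nics_component(tb, c(0, 1, 0))$nics,
      nics_component(tb, c(0, 0, 1))$nics
    ))
    expect_equal(avg, nics_iso(tb)$nics_iso, tolerance = 1e-10)
    r <- rand_rotation()
    u <- r %*% c(0, 0, 1)
    rot <- shielding_tensor(r %*% sig %*% t(r))
    expect_equal(nics_component(rot, as.numeric(u))$nics,
      nics_component(tb, c(0, 0, 1))$nics,
      tolerance = 1e-8
    )
  }
})

test_that("tensor tables round-trip through CSV and JSON and reject malformed input", {
  set.seed(91)
  tb <- dplyr::bind_rows(
    shielding_tensor(rand_tensor(), origin = c(0, 0, 1), label = "a"),
    shielding_tensor(rand_tensor(), origin = c(1, 2, 3), label = "b")
  )
  csv <- withr::local_tempfile(fileext = ".csv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_tensor_csv(tb, csv)
  write_tensor_json(tb, jsn)
  expect_equal(as.data.frame(read_tensor_csv(csv)), as.data.frame(tb))
  expect_equal(as.data.frame(read_tensor_json(jsn)), as.data.frame(tb))
  expect_error(as_tensor_table(tb[, -5]), "missing column")
  expect_error(
    as_tensor_table(dplyr::mutate(tb, label = "same")),
    "unique"
  )
  expect_error(shielding_tensor(matrix(c(1:8, NA), 3, 3)), "finite")
})

test_that("tidy and glance methods expose the decomposition as tibbles", {
  v <- vist(tensor_matrix(benzene_nics0_tensor()), label = "NICS(0)")
  td <- tidy(v)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  expect_equal(td$nics[1], -13.3)
  gl <- glance(v)
  expect_equal(gl$nics_iso, -8.9)
  expect_equal(gl$t_dominant, 13.3)
})
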