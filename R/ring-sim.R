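#' Classical ring-current loops
#'
#' A current loop is the desk-scale model of an (anti)aromatic ring: a
#' circle of radius `radius` (Angstrom) around `centre`, in the plane
#' orthogonal to the unit `normal`, whose circulating current responds
#' linearly to the component of the external field along the normal.
#' `strength` (kappa, ppm * Angstrom^3) carries every physical constant:
#' positive kappa is a diatropic (aromatic, shielding) ring, negative kappa
#' a paratropic (antiaromatic, deshielding) one. Loop sets are tibbles with
#' one loop per row, so arrangements such as tilted phenylenes or stacked
#' macrocycles are plain row-binds.
#'
#' @param centre loop centre, Angstrom.
#' @param normal plane normal (normalised internally).
#' @param radius loop radius, Angstrom (> 0).
#' @param strength response strength kappa, ppm * Angstrom^3.
#' @param label loop label.
#' @return a one-row loop-set tibble with columns `label`, `cx`, `cy`, `cz`,
#'   `nx`, `ny`, `nz`, `radius`, `strength`.
#' @examples
#' benzene_like <- current_loop(radius = 1.39, strength = 40)
#' paratropic <- current_loop(strength = -60, label = "antiaromatic")
#' @export
current_loop <- function(centre = c(0, 0, 0), normal = c(0, 0, 1),
                         radius = 1.39, strength = 40, label = "loop") {
  if (!is_number(radius) || radius <= 0) {
    stop("loop `radius` must be a positive number", call. = FALSE)
  }
  n <- unit_vec(as.numeric(normal))
  tibble::tibble(
    label = as.character(label),
    cx = centre[1], cy = centre[2], cz = centre[3],
    nx = n[1], ny = n[2], nz = n[3],
    radius = radius, strength = strength
  )
}

#' @rdname current_loop
#' @param data a data frame with loop-set columns.
#' @export
as_loop_set <- function(data) {
  need <- c("cx", "cy", "cz", "nx", "ny", "nz", "radius", "strength")
  if (!all(need %in% names(data))) {
    stop("not a loop set; need columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"label" %in% names(data)) {
    data$label <- sprintf("loop%d", seq_len(nrow(data)))
  }
  if (any(data$radius <= 0)) stop("loop radii must be > 0", call. = FALSE)
  nn <- sqrt(data$nx^2 + data$ny^2 + data$nz^2)
  if (any(abs(nn - 1) > 1e-8)) {
    stop("loop normals must be unit vectors", call. = FALSE)
  }
  tibble::as_tibble(data)
}

#' Read a loop configuration file
#'
#' YAML with a top-level `loops:` list; each entry has `centre`, `normal`,
#' `radius`, `strength` and optionally `label`.
#'
#' @param path YAML file path.
#' @return a loop-set tibble.
#' @export
read_loops <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$loops) || length(cfg$loops) == 0L) {
    stop("loop config has no `loops:` entries", call. = FALSE)
  }
  purrr::imap_dfr(cfg$loops, function(l, i) {
    current_loop(
      centre = as.numeric(l$centre %||% c(0, 0, 0)),
      normal = as.numeric(l$normal %||% c(0, 0, 1)),
      radius = as.numeric(l$radius %||% 1.39),
      strength = as.numeric(l$strength %||% 40),
      label = l$label %||% sprintf("loop%d", i)
    )
  })
}

loop_row <- function(loops, i) {
  list(
    centre = as.numeric(loops[i, c("cx", "cy", "cz")]),
    normal = as.numeric(loops[i, c("nx", "ny", "nz")]),
    radius = loops$radius[i],
    strength = loops$strength[i],
    label = loops$label[i]
  )
}

#' Shielding tensor of a current loop at a point
#'
#' `loop_tensor_dipole()` evaluates the point-dipole response model
#' \deqn{\sigma(p) = \kappa\,(3\hat d \hat d^T - I)\,\hat n \hat n^T / |d|^3}
#' with \eqn{d = p - centre}: the loop responds only to the normal component
#' of the field (the in-plane response of a flat ring is taken as zero), and
#' the induced field at the probe is that of the resulting point dipole. The
#' tensor is generally non-symmetric off-axis. On the axis the component
#' along the normal is \eqn{+2\kappa/z^3} (shielded for a diatropic loop);
#' in the ring plane it is \eqn{-\kappa/d^3} (deshielded outside a
#' diatropic ring), reproducing the qualitative NICS sign pattern of
#' aromatic rings.
#'
#' `loop_tensor_biot_savart()` replaces the point dipole by a discretised
#' circular wire: the induced field is the Biot-Savart sum over
#' `n_segments` straight segments, normalised so the far-field dipole
#' moment equals kappa. It converges to the dipole model for
#' `|d| >> radius` and to the textbook on-axis closed form
#' \eqn{\sigma_{nn}(z) = 2\kappa/(a^2+z^2)^{3/2}} (see
#' [loop_axial_shielding()]).
#'
#' @param loop a one-row loop set (or list from a loop-set row).
#' @param point evaluation point, Angstrom.
#' @param label probe label for the output row.
#' @return a one-row tensor table, ppm.
#' @export
loop_tensor_dipole <- function(loop, point, label = "probe") {
  l <- if (is.data.frame(loop)) loop_row(as_loop_set(loop), 1L) else loop
  d <- as.numeric(point) - l$centre
  dn <- vec_norm(d)
  if (dn < 1e-8) {
    stop(sprintf("probe coincides with centre of loop '%s'", l$label),
      call. = FALSE
    )
  }
  dh <- d / dn
  nh <- l$normal
  sigma <- l$strength * (3 * tcrossprod(dh) - diag(3)) %*% tcrossprod(nh) / dn^3
  shielding_tensor(sigma, origin = point, label = label)
}

#' @rdname loop_tensor_dipole
#' @param n_segments number of wire segments (>= 8).
#' @export
loop_tensor_biot_savart <- function(loop, point, n_segments = 256L,
                                    label = "probe") {
  l <- if (is.data.frame(loop)) loop_row(as_loop_set(loop), 1L) else loop
  if (n_segments < 8L) stop("need n_segments >= 8", call. = FALSE)
  p <- as.numeric(point)
  basis <- plane_basis(l$normal)
  phi <- (seq_len(n_segments) - 0.5) * 2 * pi / n_segments
  dphi <- 2 * pi / n_segments
  pos <- sweep(
    l$radius * (outer(cos(phi), basis$e1) + outer(sin(phi), basis$e2)),
    2, l$centre, `+`
  )
  dl <- l$radius * dphi * (outer(-sin(phi), basis$e1) + outer(cos(phi), basis$e2))
  # distance from the probe to the continuous wire circle
  rel <- p - l$centre
  z_loc <- sum(rel * l$normal)
  rho_loc <- vec_norm(rel - z_loc * l$normal)
  if (sqrt((rho_loc - l$radius)^2 + z_loc^2) < 1e-6) {
    stop(sprintf("probe lies on the wire of loop '%s'", l$label), call. = FALSE)
  }
  r <- sweep(-pos, 2, p, `+`) # p - wire position
  rn <- sqrt(rowSums(r * r))
  cr <- cbind(
    dl[, 2] * r[, 3] - dl[, 3] * r[, 2],
    dl[, 3] * r[, 1] - dl[, 1] * r[, 3],
    dl[, 1] * r[, 2] - dl[, 2] * r[, 1]
  )
  g <- colSums(cr / rn^3) # field per unit current (mu0/4pi = 1)
  # current per unit normal field component: far-field moment I * pi a^2 = kappa
  sigma <- tcrossprod(g * l$strength / (pi * l$radius^2), l$normal)
  shielding_tensor(sigma, origin = p, label = label)
}

#' On-axis closed form for the finite-loop shielding component
#'
#' The component of the loop response tensor along the loop normal, on the
#' loop axis at signed distance `z` from the centre:
#' \eqn{\sigma_{nn}(z) = 2\kappa\,/\,(a^2 + z^2)^{3/2}}. The corresponding
#' NICS component is its negative. This is the model function used by
#' [fit_loop()] and the analytic reference for the Biot-Savart oracle.
#'
#' @param z signed axial distance(s), Angstrom.
#' @param radius loop radius `a`, Angstrom.
#' @param strength kappa, ppm * Angstrom^3.
#' @return shielding component(s), ppm.
#' @export
loop_axial_shielding <- function(z, radius, strength) {
  2 * strength / (radius^2 + z^2)^1.5
}

#' Evaluate loop fields at a probe set
#'
#' Sums the response tensors of every loop at every probe (superposition is
#' exact for linear response). A probe hitting a singular point is reported
#' with the offending loop/probe pair.
#'
#' @param loops a loop-set tibble.
#' @param probes a probe-set tibble.
#' @param method `"dipole"` (default) or `"biot-savart"`.
#' @param n_segments wire discretisation for the Biot-Savart method.
#' @return a tensor table with one row per probe.
#' @examples
#' loops <- current_loop(radius = 1.39, strength = 40)
#' probes <- ring_probes(c(0, 0, 0), c(0, 0, 1), offsets = 1:2)
#' field_scan(loops, probes) |> nics_iso()
#' @export
field_scan <- function(loops, probes, method = c("dipole", "biot-savart"),
                       n_segments = 256L) {
  method <- match.arg(method)
  loops <- as_loop_set(loops)
  probes <- as_probe_set(probes)
  purrr::map_dfr(seq_len(nrow(probes)), function(k) {
    p <- as.numeric(probes[k, c("x", "y", "z")])
    sigma <- matrix(0, 3L, 3L)
    for (i in seq_len(nrow(loops))) {
      tb <- tryCatch(
        if (method == "dipole") {
          loop_tensor_dipole(loop_row(loops, i), p)
        } else {
          loop_tensor_biot_savart(loop_row(loops, i), p, n_segments)
        },
        error = function(e) {
          stop(sprintf(
            "loop '%s' / probe '%s': %s",
            loops$label[i], probes$label[k], conditionMessage(e)
          ), call. = FALSE)
        }
      )
      sigma <- sigma + tensor_matrix(tb)
    }
    shielding_tensor(sigma, origin = p, label = probes$label[k])
  })
}

#' Simulate a noisy axial NICS scan
#'
#' Generates the out-of-plane NICS component along the loop axis at the
#' given offsets, using the exact finite-loop on-axis form plus i.i.d.
#' Gaussian noise — the synthetic analogue of a NICS line scan through a
#' ring. The defaults emulate a benzene-like ring probed at 21 points.
#'
#' @param loop a one-row loop set.
#' @param offsets axial distances, Angstrom.
#' @param noise_sd noise standard deviation, ppm.
#' @param seed RNG seed (explicit so scans are reproducible).
#' @return a tibble with `z` and `nics` (ppm; NICS component along the
#'   normal, negative over a diatropic loop).
#' @export
simulate_axial_scan <- function(loop, offsets = seq(0.5, 4.5, length.out = 21),
                                noise_sd = 0.1, seed = 1L) {
  l <- loop_row(as_loop_set(loop), 1L)
  old <- .Random.seed_safe()
  set.seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  nics <- -loop_axial_shielding(offsets, l$radius, l$strength) +
    stats::rnorm(length(offsets), sd = noise_sd)
  tibble::tibble(z = offsets, nics = nics)
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fit a single current loop to an axial NICS scan
#'
#' Recovers the loop strength kappa and radius `a` from axial NICS values by
#' nonlinear least squares (Levenberg-Marquardt) on the closed-form model
#' `nics(z) = -2 kappa / (a^2 + z^2)^(3/2)`.
#'
#' @param data a tibble with columns `z` (Angstrom) and `nics` (ppm), e.g.
#'   from [simulate_axial_scan()].
#' @param start optional named list with starting values `strength`,
#'   `radius`; a data-driven heuristic is used when omitted.
#' @return an object of class `"loop_fit"` wrapping the nls fit; use
#'   [generics::tidy()] for parameter estimates and [generics::glance()]
#'   for fit statistics.
#' @examples
#' scan <- simulate_axial_scan(current_loop(radius = 1.39, strength = 40))
#' fit <- fit_loop(scan)
#' tidy(fit)
#' @export
fit_loop <- function(data, start = NULL) {
  stopifnot(all(c("z", "nics") %in% names(data)))
  if (nrow(data) < 3L) stop("need at least 3 scan points", call. = FALSE)
  if (is.null(start)) {
    z0 <- data$z[which.min(abs(data$z))]
    start <- list(
      strength = -data$nics[which.min(abs(data$z))] * (1 + z0^2)^1.5 / 2,
      radius = 1
    )
  }
  fit <- minpack.lm::nlsLM(
    nics ~ -2 * strength / (radius^2 + z^2)^1.5,
    data = data,
    start = start,
    lower = c(strength = -Inf, radius = 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  structure(list(fit = fit, data = tibble::as_tibble(data)),
    class = "loop_fit"
  )
}

#' @export
print.loop_fit <- function(x, ...) {
  est <- stats::coef(x$fit)
  cat(sprintf(
    "<loop_fit> kappa = %.4f ppm*A^3, radius = %.4f A (%d points)\n",
    est[["strength"]], est[["radius"]], nrow(x$data)
  ))
  invisible(x)
}

#' Tidy a loop fit
#'
#' @param x a `"loop_fit"` object.
#' @param ... unused.
#' @return `tidy()`: one row per parameter with estimate and standard error;
#'   `glance()`: one-row fit summary.
#' @method tidy loop_fit
#' @export
tidy.loop_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' @rdname tidy.loop_fit
#' @method glance loop_fit
#' @export
glance.loop_fit <- function(x, ...) {
  tibble::tibble(
    sigma = summary(x$fit)$sigma,
    n = nrow(x$data),
    converged = x$fit$convInfo$isConv,
    iterations = x$fit$convInfo$finIter
  )
}

#' Plot an axial NICS scan with its fitted loop model
#'
#' @param data a scan tibble (`z`, `nics`).
#' @param fit optional `"loop_fit"` to overlay.
#' @return a ggplot.
#' @export
plot_nics_scan <- function(data, fit = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$z, y = .data$nics)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "axial distance z (Å)",
      y = "NICS component along normal (ppm)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    est <- stats::coef(fit$fit)
    zz <- seq(min(data$z), max(data$z), length.out = 200)
    line <- tibble::tibble(
      z = zz,
      nics = -loop_axial_shielding(zz, est[["radius"]], est[["strength"]])
    )
    p <- p + ggplot2::geom_line(data = line, colour = "#2166ac")
  }
  p
}
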