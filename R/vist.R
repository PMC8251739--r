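#' Principal-axis decomposition of a shielding tensor
#'
#' Decomposes a 3x3 chemical shielding tensor into principal axes
#' (eigenvectors) and eigenvalues t(1), t(2), t(3), the representation behind
#' dumb-bell tensor glyphs. Because shielding tensors are in general
#' non-symmetric, two modes are offered:
#'
#' * `"symmetrized"` (default): eigendecomposition of the symmetric part
#'   `(sigma + t(sigma))/2`. Eigenvalues are guaranteed real and the axes
#'   mutually orthogonal; the antisymmetric part dropped here has zero trace
#'   and therefore no effect on the isotropic NICS.
#' * `"right-eigen"`: right eigenvectors of the raw matrix. Left and right
#'   eigenvectors of a non-symmetric matrix differ, axes need not be
#'   orthogonal, and a complex-conjugate eigenvalue pair can occur; in that
#'   case the real parts are kept, `complex_flag` is set and the largest
#'   imaginary magnitude is recorded in `imag_max` (never silently dropped).
#'
#' Components are sorted by descending `|t|` so the dominant component comes
#' first; ties are broken by descending signed value, then by the axis closest
#' to +z. Each axis is sign-fixed so that its largest-magnitude Cartesian
#' entry is positive, making output reproducible.
#'
#' The NICS value of the probe is minus a third of the eigenvalue sum,
#' identical to minus a third of the trace; per-component NICS contributions
#' are `-t(i)` (negative = shielded/aromatic, positive =
#' deshielded/antiaromatic).
#'
#' @param sigma a 3x3 numeric matrix (ppm).
#' @param mode `"symmetrized"` or `"right-eigen"`.
#' @param origin probe position (Angstrom), carried into the result.
#' @param label probe label.
#' @return an object of class `"vist"`: a list with `eigenvalues` (ppm,
#'   sorted), `axes` (3x3 matrix, unit columns), `nics_components` (`-t`),
#'   `nics_iso`, `mode`, `complex_flag`, `imag_max`, `origin`, `label`.
#' @seealso [vist_decompose()] for the data-frame interface,
#'   [generics::tidy()] / [generics::glance()] methods.
#' @examples
#' v <- vist(diag(c(13.3, 6.7, 6.7)))
#' v$nics_iso # -8.9
#' tidy(v)
#' @export
vist <- function(sigma, mode = c("symmetrized", "right-eigen"),
                 origin = c(0, 0, 0), label = "probe") {
  mode <- match.arg(mode)
  sigma <- as.matrix(sigma)
  if (!all(dim(sigma) == c(3L, 3L)) || !all(is.finite(sigma))) {
    stop("`sigma` must be a finite 3x3 numeric matrix", call. = FALSE)
  }

  if (mode == "symmetrized") {
    es <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
    tvals <- es$values
    axes <- es$vectors
    imag_max <- 0
  } else {
    es <- eigen(sigma)
    imag_max <- max(abs(Im(es$values)))
    tvals <- Re(es$values)
    axes <- matrix(0, 3L, 3L)
    for (i in 1:3) {
      v <- es$vectors[, i]
      re <- Re(v)
      # a complex pair's real part can vanish; fall back to the imaginary part
      axes[, i] <- if (vec_norm(re) > 1e-8) unit_vec(re) else unit_vec(Im(v))
    }
  }
  scale_ref <- max(1, max(abs(tvals)))
  complex_flag <- imag_max > 1e-10 * scale_ref

  # sign convention: largest-magnitude Cartesian entry positive
  for (i in 1:3) {
    k <- which.max(abs(axes[, i]))
    if (axes[k, i] < 0) axes[, i] <- -axes[, i]
  }

  ord <- order_components(tvals, axes)
  tvals <- tvals[ord]
  axes <- axes[, ord, drop = FALSE]

  structure(
    list(
      eigenvalues = tvals,
      axes = axes,
      nics_components = -tvals,
      nics_iso = -sum(tvals) / 3,
      mode = mode,
      complex_flag = complex_flag,
      imag_max = imag_max,
      origin = as.numeric(origin),
      label = as.character(label),
      sigma = sigma
    ),
    class = "vist"
  )
}

# descending |t|; ties by descending signed t; then axis closest to +z
order_components <- function(tvals, axes) {
  ord <- 1:3
  tol <- 1e-9 * max(1, max(abs(tvals)))
  before <- function(i, j) {
    if (abs(abs(tvals[i]) - abs(tvals[j])) > tol) {
      return(abs(tvals[i]) > abs(tvals[j]))
    }
    if (abs(tvals[i] - tvals[j]) > tol) {
      return(tvals[i] > tvals[j])
    }
    axes[3, i] >= axes[3, j]
  }
  for (a in 1:2) {
    for (b in 1:(3 - a)) {
      if (!before(ord[b], ord[b + 1])) {
        tmp <- ord[b]
        ord[b] <- ord[b + 1]
        ord[b + 1] <- tmp
      }
    }
  }
  ord
}

#' @export
print.vist <- function(x, ...) {
  cat(sprintf(
    "<vist> %s  mode=%s%s\n", x$label, x$mode,
    if (x$complex_flag) sprintf("  COMPLEX PAIR (|Im| max %.3g)", x$imag_max) else ""
  ))
  cat(sprintf("  isotropic NICS: %.4f ppm\n", x$nics_iso))
  for (i in 1:3) {
    cat(sprintf(
      "  t(%d) = %9.4f ppm  (NICS %9.4f)  axis [% .4f % .4f % .4f]\n",
      i, x$eigenvalues[i], -x$eigenvalues[i],
      x$axes[1, i], x$axes[2, i], x$axes[3, i]
    ))
  }
  invisible(x)
}

#' Tidy a VIST decomposition
#'
#' @param x a `"vist"` object.
#' @param ... unused.
#' @return `tidy()`: one row per principal component with the eigenvalue,
#'   NICS contribution and axis; `glance()`: a one-row summary with the
#'   isotropic NICS and decomposition flags.
#' @method tidy vist
#' @export
tidy.vist <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    component = 1:3,
    t = x$eigenvalues,
    nics = x$nics_components,
    axis_x = x$axes[1, ],
    axis_y = x$axes[2, ],
    axis_z = x$axes[3, ],
    mode = x$mode,
    complex_flag = x$complex_flag
  )
}

#' @rdname tidy.vist
#' @method glance vist
#' @export
glance.vist <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    nics_iso = x$nics_iso,
    t_dominant = x$eigenvalues[1],
    mode = x$mode,
    complex_flag = x$complex_flag,
    imag_max = x$imag_max
  )
}

#' Decompose every tensor in a tensor table
#'
#' Data-frame-first version of [vist()]: runs the principal-axis
#' decomposition for each row of a tensor table and returns a tidy tibble
#' with one row per probe and principal component.
#'
#' @param tensors a tensor table (see [shielding_tensor()]).
#' @param mode `"symmetrized"` (default) or `"right-eigen"`.
#' @return a tibble with columns `label`, `x`, `y`, `z`, `component`
#'   (1 = dominant), `t` (eigenvalue, ppm), `nics` (`-t`), `axis_x`,
#'   `axis_y`, `axis_z`, `nics_iso`, `mode`, `complex_flag`, `imag_max`.
#' @examples
#' shielding_tensor(diag(c(13.3, 6.7, 6.7)), label = "NICS(0)") |>
#'   vist_decompose()
#' @export
vist_decompose <- function(tensors, mode = c("symmetrized", "right-eigen")) {
  mode <- match.arg(mode)
  tensors <- as_tensor_table(tensors)
  purrr::map_dfr(seq_len(nrow(tensors)), function(i) {
    v <- vist(tensor_matrix(tensors, i),
      mode = mode,
      origin = as.numeric(tensors[i, c("x", "y", "z")]),
      label = tensors$label[i]
    )
    tibble::tibble(
      label = v$label,
      x = v$origin[1], y = v$origin[2], z = v$origin[3],
      component = 1:3,
      t = v$eigenvalues,
      nics = v$nics_components,
      axis_x = v$axes[1, ],
      axis_y = v$axes[2, ],
      axis_z = v$axes[3, ],
      nics_iso = v$nics_iso,
      mode = v$mode,
      complex_flag = v$complex_flag,
      imag_max = v$imag_max
    )
  })
}

#' Isotropic and directional NICS values
#'
#' `nics_iso()` returns the nucleus-independent chemical shift at each probe,
#' minus a third of the tensor trace (equivalently minus the mean eigenvalue;
#' negative = aromatic/shielded). `nics_component()` projects the tensor on a
#' fixed unit direction `u` and returns `-(u' sigma u)`; for `u` along the
#' ring normal this is the out-of-plane NICS_zz component.
#'
#' @param tensors a tensor table.
#' @param u unit 3-vector (checked to 1e-8).
#' @return the probe columns plus `nics_iso` (or `nics`) in ppm.
#' @examples
#' benzene <- shielding_tensor(diag(c(13.3, 6.7, 6.7)), label = "NICS(0)")
#' nics_iso(benzene)$nics_iso # -8.9
#' nics_component(benzene, c(0, 0, 1))$nics # -13.3
#' @export
nics_iso <- function(tensors) {
  tensors <- as_tensor_table(tensors)
  dplyr::transmute(
    tensors,
    label = .data$label, x = .data$x, y = .data$y, z = .data$z,
    nics_iso = -(.data$s_xx + .data$s_yy + .data$s_zz) / 3
  )
}

#' @rdname nics_iso
#' @export
nics_component <- function(tensors, u) {
  assert_unit(u, 1e-8, "`u`")
  tensors <- as_tensor_table(tensors)
  val <- vapply(seq_len(nrow(tensors)), function(i) {
    -as.numeric(t(u) %*% tensor_matrix(tensors, i) %*% u)
  }, numeric(1))
  dplyr::transmute(
    tensors,
    label = .data$label, x = .data$x, y = .data$y, z = .data$z,
    nics = val
  )
}
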