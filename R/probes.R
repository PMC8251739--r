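#' Molecules and probe sets
#'
#' A molecule is a tibble with columns `element`, `x`, `y`, `z` (Angstrom).
#' A probe set is a tibble with columns `label` (unique), `x`, `y`, `z`
#' (Angstrom) and an optional reference direction `nx`, `ny`, `nz` (unit
#' vector, `NA` when no natural normal exists). Probes mark the ghost-atom
#' ("Bq") positions at which shielding tensors are evaluated for NICS-style
#' analysis.
#'
#' @param element character vector of element symbols.
#' @param x,y,z Cartesian coordinates, Angstrom.
#' @return a molecule tibble.
#' @export
molecule <- function(element, x, y, z) {
  as_molecule(tibble::tibble(
    element = as.character(element),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)
  ))
}

#' @rdname molecule
#' @param data a data frame with molecule columns.
#' @export
as_molecule <- function(data) {
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(data))) {
    stop("a molecule needs columns element, x, y, z", call. = FALSE)
  }
  if (nrow(data) < 1L) stop("a molecule needs at least one atom", call. = FALSE)
  xyz <- as.matrix(data[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  if (nrow(xyz) > 1L) {
    dmin <- min(stats::dist(xyz))
    if (dmin < 0.1) {
      stop(sprintf(
        "atoms closer than 0.1 Angstrom (min distance %.3g)", dmin
      ), call. = FALSE)
    }
  }
  tibble::as_tibble(data)
}

#' @rdname molecule
#' @export
as_probe_set <- function(data) {
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(data))) {
    stop("a probe set needs columns label, x, y, z", call. = FALSE)
  }
  if (anyDuplicated(data$label)) {
    stop("probe labels must be unique", call. = FALSE)
  }
  for (nc in c("nx", "ny", "nz")) {
    if (!nc %in% names(data)) data[[nc]] <- NA_real_
  }
  tibble::as_tibble(data)
}

#' Read and write XYZ geometry files
#'
#' Standard two-header-line XYZ dialect: atom count, comment line, then one
#' `element x y z` record per atom, coordinates in Angstrom.
#'
#' @param path file path.
#' @param mol a molecule tibble.
#' @param comment comment line for the writer.
#' @return a molecule tibble (reader) or `path` invisibly (writer).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("XYZ file too short", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) {
    stop("first XYZ line must be the atom count", call. = FALSE)
  }
  if (length(lines) < n + 2L) {
    stop(sprintf("XYZ file truncated: expected %d atom lines", n), call. = FALSE)
  }
  rec <- strsplit(trimws(lines[3:(n + 2L)]), "\\s+")
  bad <- which(vapply(rec, length, integer(1)) < 4L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed XYZ record at line %d", bad[1] + 2L), call. = FALSE)
  }
  molecule(
    element = vapply(rec, `[[`, character(1), 1L),
    x = as.numeric(vapply(rec, `[[`, character(1), 2L)),
    y = as.numeric(vapply(rec, `[[`, character(1), 3L)),
    z = as.numeric(vapply(rec, `[[`, character(1), 4L))
  )
}

#' @rdname read_xyz
#' @export
write_xyz <- function(mol, path, comment = "generated by vistr") {
  mol <- as_molecule(mol)
  lines <- c(
    as.character(nrow(mol)),
    comment,
    sprintf("%-3s %12s %12s %12s", mol$element, num6(mol$x), num6(mol$y), num6(mol$z))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Ring centroid and best-fit plane normal
#'
#' Returns the centroid of the selected ring atoms and the unit normal of
#' their best-fit plane, computed as the direction of least coordinate
#' variance of the centred atoms. For puckered rings this least-variance
#' direction is the natural generalisation of the plane normal. The sign of
#' the normal follows the right-hand rule over the atom ordering, so listing
#' a planar ring counterclockwise (seen from +z) gives a +z normal.
#'
#' @param mol a molecule tibble.
#' @param indices atom indices of the ring (3 or more, non-collinear).
#' @return a list with `centre` (length-3) and `normal` (unit length-3).
#' @export
ring_centroid_normal <- function(mol, indices) {
  mol <- as_molecule(mol)
  if (length(indices) < 3L) {
    stop("need at least 3 ring atoms", call. = FALSE)
  }
  if (any(indices < 1L | indices > nrow(mol))) {
    stop("ring indices out of range", call. = FALSE)
  }
  pts <- as.matrix(mol[indices, c("x", "y", "z")])
  centre <- colMeans(pts)
  centred <- sweep(pts, 2, centre)
  es <- eigen(crossprod(centred) / nrow(centred), symmetric = TRUE)
  # eigenvalues descending; a ring spans 2 directions, collinear atoms only 1
  if (es$values[2] < 1e-10 * max(es$values[1], 1e-30)) {
    stop("ring atoms are collinear or degenerate; no plane defined",
      call. = FALSE
    )
  }
  normal <- es$vectors[, 3]
  # orient by right-hand rule over the atom ordering (polygon circulation)
  circ <- c(0, 0, 0)
  for (k in seq_len(nrow(centred))) {
    a <- centred[k, ]
    b <- centred[if (k == nrow(centred)) 1L else k + 1L, ]
    circ <- circ + c(
      a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1]
    )
  }
  if (sum(circ * normal) < 0) normal <- -normal
  list(centre = as.numeric(centre), normal = unit_vec(normal))
}

#' Probe points above ring centres, bonds, lines and planes
#'
#' `ring_probes()` places one probe per offset on the line through `centre`
#' along the unit `normal` (offset 0 is the classic ring-centre NICS(0)
#' position; 1 and 2 Angstrom give NICS(1)/NICS(2)). `bond_probes()` does
#' the same from the midpoint of two atoms, displaced along a supplied ring
#' normal. `line_scan()` returns `n` equally spaced probes between two
#' points, labelled by fractional position. `plane_grid()` returns a square
#' grid in the plane through `centre` orthogonal to `normal`, for 2D NICS
#' maps. "Above" the plane means the positive side of the right-hand-rule
#' normal; use `both_sides = TRUE` to emit mirror probes as well.
#'
#' @param centre ring centre (length-3, Angstrom).
#' @param normal unit plane normal.
#' @param offsets displacements along the normal, Angstrom.
#' @param both_sides also emit probes at minus each nonzero offset.
#' @param prefix label prefix.
#' @return a probe-set tibble.
#' @examples
#' ring_probes(c(0, 0, 0), c(0, 0, 1), offsets = c(0, 1, 2))
#' @export
ring_probes <- function(centre, normal, offsets, both_sides = FALSE,
                        prefix = "ring") {
  assert_unit(normal, 1e-8, "`normal`")
  offs <- as.numeric(offsets)
  if (both_sides) offs <- unique(c(offs, -offs[offs != 0]))
  pts <- t(vapply(offs, function(s) centre + s * normal, numeric(3)))
  as_probe_set(tibble::tibble(
    label = sprintf("%s_%+.2f", prefix, offs),
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    nx = normal[1], ny = normal[2], nz = normal[3]
  ))
}

#' @rdname ring_probes
#' @param mol a molecule tibble.
#' @param i,j atom indices of the bond.
#' @export
bond_probes <- function(mol, i, j, offsets, normal, both_sides = FALSE,
                        prefix = NULL) {
  mol <- as_molecule(mol)
  if (i == j) stop("bond needs two distinct atoms", call. = FALSE)
  if (any(c(i, j) < 1L | c(i, j) > nrow(mol))) {
    stop("bond atom index out of range", call. = FALSE)
  }
  mid <- as.numeric((mol[i, c("x", "y", "z")] + mol[j, c("x", "y", "z")]) / 2)
  if (is.null(prefix)) prefix <- sprintf("bond%d-%d", i, j)
  ring_probes(mid, normal, offsets, both_sides = both_sides, prefix = prefix)
}

#' @rdname ring_probes
#' @param p_start,p_end scan endpoints (length-3, Angstrom).
#' @param n number of probes (at least 2), endpoints included.
#' @export
line_scan <- function(p_start, p_end, n, prefix = "scan") {
  if (n < 2L) stop("a line scan needs n >= 2 points", call. = FALSE)
  d <- as.numeric(p_end) - as.numeric(p_start)
  if (vec_norm(d) < 1e-10) {
    stop("line scan endpoints coincide", call. = FALSE)
  }
  frac <- seq(0, 1, length.out = n)
  pts <- t(vapply(frac, function(f) p_start + f * d, numeric(3)))
  u <- unit_vec(d)
  as_probe_set(tibble::tibble(
    label = sprintf("%s_%.4f", prefix, frac),
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    nx = u[1], ny = u[2], nz = u[3]
  ))
}

#' @rdname ring_probes
#' @param half_extent half-width of the grid, Angstrom.
#' @param spacing grid spacing, Angstrom (> 0).
#' @export
plane_grid <- function(centre, normal, half_extent, spacing, prefix = "grid") {
  assert_unit(normal, 1e-8, "`normal`")
  if (!is_number(spacing) || spacing <= 0) {
    stop("`spacing` must be a positive number", call. = FALSE)
  }
  m <- floor(half_extent / spacing)
  basis <- plane_basis(normal)
  ij <- expand.grid(i = -m:m, j = -m:m)
  pts <- t(apply(ij, 1, function(k) {
    centre + k[1] * spacing * basis$e1 + k[2] * spacing * basis$e2
  }))
  as_probe_set(tibble::tibble(
    label = sprintf("%s_%+d_%+d", prefix, ij$i, ij$j),
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    nx = normal[1], ny = normal[2], nz = normal[3]
  ))
}

#' Read and write probe-set CSV files
#'
#' Columns `label, x, y, z, nx, ny, nz` (reference normal columns may be
#' `NA`), Angstrom.
#'
#' @param path file path.
#' @param probes a probe-set tibble.
#' @return the probe set (reader) or `path`, invisibly (writer).
#' @export
read_probe_csv <- function(path) {
  as_probe_set(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_probe_csv
#' @export
write_probe_csv <- function(probes, path) {
  readr::write_csv(as_probe_set(probes), path)
  invisible(path)
}
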