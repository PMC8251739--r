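#' Parse shielding tensors from a quantum-chemistry log
#'
#' Reads the `"Magnetic shielding tensor (ppm)"` block written by
#' Gaussian-style NMR jobs: one header line per centre
#' (`n  El  Isotropic = ...`) followed by three lines of labelled entries
#' (`XX= ... YX= ... ZX=` etc.). Each labelled entry `GB=` is mapped as
#' printed: first letter = matrix row (nuclear-moment component), second
#' letter = column (field component). Ghost centres (element `Bq`) are
#' flagged in the `ghost` column. Positions are taken from an orientation
#' geometry block when one is present (choose which with `coords`); when no
#' geometry block exists positions are set to zero and `position_known` is
#' `FALSE`.
#'
#' @param text a character vector of log lines, a single string, or a path
#'   to an existing file.
#' @param coords which geometry block to take ghost/atom coordinates from:
#'   `"input"` (default), `"standard"` (may be rotated relative to the input
#'   frame), or `"none"`.
#' @return a tensor table (see [shielding_tensor()]) with extra columns
#'   `element`, `ghost` and `position_known`.
#' @export
parse_shielding_log <- function(text, coords = c("input", "standard", "none")) {
  coords <- match.arg(coords)
  lines <- as_lines(text)
  marker <- "Magnetic shielding tensor (ppm)"
  start <- grep(marker, lines, fixed = TRUE)
  if (length(start) == 0L) {
    stop(sprintf("no shielding block found: expected marker \"%s\"", marker),
      call. = FALSE
    )
  }

  geom <- if (coords == "none") NULL else parse_orientation(lines, coords)

  i <- start[1] + 1L
  recs <- list()
  head_re <- "^\\s*(\\d+)\\s+(\\S+)\\s+Isotropic"
  while (i <= length(lines) && grepl(head_re, lines[i])) {
    m <- regmatches(lines[i], regexec(head_re, lines[i]))[[1]]
    centre <- as.integer(m[2])
    el <- m[3]
    sigma <- matrix(NA_real_, 3L, 3L)
    idx <- c(X = 1L, Y = 2L, Z = 3L)
    for (r in 1:3) {
      ln <- i + r
      if (ln > length(lines)) {
        stop(sprintf("shielding block truncated at line %d", length(lines)),
          call. = FALSE
        )
      }
      toks <- regmatches(
        lines[ln],
        gregexpr("([XYZ])([XYZ])=\\s*(-?[0-9.]+[0-9.eEdD+-]*)", lines[ln])
      )[[1]]
      if (length(toks) != 3L) {
        stop(sprintf("malformed tensor entries at line %d: \"%s\"", ln, lines[ln]),
          call. = FALSE
        )
      }
      for (tk in toks) {
        g <- idx[[substr(tk, 1, 1)]]
        b <- idx[[substr(tk, 2, 2)]]
        val <- suppressWarnings(as.numeric(
          gsub("[dD]", "e", sub("^..=\\s*", "", tk))
        ))
        if (is.na(val)) {
          stop(sprintf("malformed numeric field at line %d: \"%s\"", ln, tk),
            call. = FALSE
          )
        }
        sigma[g, b] <- val
      }
    }
    if (anyNA(sigma)) {
      stop(sprintf("incomplete tensor for centre %d", centre), call. = FALSE)
    }
    recs[[length(recs) + 1L]] <- list(centre = centre, element = el, sigma = sigma)
    i <- i + 4L
  }
  if (length(recs) == 0L) {
    stop("shielding block contains no centres", call. = FALSE)
  }

  purrr::map_dfr(recs, function(r) {
    pos <- c(0, 0, 0)
    known <- FALSE
    if (!is.null(geom) && r$centre <= nrow(geom)) {
      pos <- as.numeric(geom[r$centre, c("x", "y", "z")])
      known <- TRUE
    }
    ghost <- identical(toupper(r$element), "BQ")
    tb <- shielding_tensor(r$sigma,
      origin = pos,
      label = sprintf("%s%d", r$element, r$centre)
    )
    tb$element <- r$element
    tb$ghost <- ghost
    tb$position_known <- known
    tb
  })
}

#' @rdname parse_shielding_log
#' @param path log file path.
#' @export
read_shielding_log <- function(path, coords = c("input", "standard", "none")) {
  parse_shielding_log(readLines(path), coords = match.arg(coords))
}

as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    return(readLines(text))
  }
  if (length(text) == 1L) {
    return(strsplit(text, "\n", fixed = TRUE)[[1]])
  }
  as.character(text)
}

parse_orientation <- function(lines, which = "input") {
  tag <- if (which == "input") "Input orientation:" else "Standard orientation:"
  hit <- grep(tag, lines, fixed = TRUE)
  if (length(hit) == 0L) {
    return(NULL)
  }
  i <- hit[length(hit)] + 5L # skip the table rule lines
  rows <- list()
  re <- "^\\s*(\\d+)\\s+(-?\\d+)\\s+\\d+\\s+(-?[0-9.]+)\\s+(-?[0-9.]+)\\s+(-?[0-9.]+)"
  while (i <= length(lines) && grepl(re, lines[i])) {
    m <- regmatches(lines[i], regexec(re, lines[i]))[[1]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      centre = as.integer(m[2]),
      atomic_number = as.integer(m[3]),
      x = as.numeric(m[4]), y = as.numeric(m[5]), z = as.numeric(m[6])
    )
    i <- i + 1L
  }
  if (length(rows) == 0L) {
    return(NULL)
  }
  dplyr::bind_rows(rows)
}

#' Synthesise a shielding log (mock quantum-chemistry output)
#'
#' Writes a text block in the same dialect that [parse_shielding_log()]
#' reads: an `Input orientation:` geometry table followed by a
#' `Magnetic shielding tensor (ppm)` block, one centre per tensor-table row.
#' This is the test harness's stand-in for a real NMR job, used for
#' round-trip checks and for exercising the analysis pipeline without a
#' quantum-chemistry engine; the numbers it contains are whatever the
#' tensor table holds (e.g. ring-current simulator output), not ab initio
#' shieldings.
#'
#' @param tensors a tensor table; an `element` column is honoured, otherwise
#'   every centre is a ghost (`Bq`).
#' @return a single string (LF line endings).
#' @export
format_shielding_log <- function(tensors) {
  tensors <- as_tensor_table(tensors)
  el <- if ("element" %in% names(tensors)) tensors$element else rep("Bq", nrow(tensors))
  z <- ifelse(toupper(el) == "BQ", 0L, 6L) # mock: carbon unless ghost
  out <- c(
    " Entering synthetic shielding log (vistr)",
    "                         Input orientation:",
    " ---------------------------------------------------------------------",
    " Center     Atomic      Atomic             Coordinates (Angstroms)",
    " Number     Number       Type             X           Y           Z",
    " ---------------------------------------------------------------------",
    sprintf(
      "    %5d %10d %10d    %11s %11s %11s",
      seq_len(nrow(tensors)), z, 0L,
      num6(tensors$x), num6(tensors$y), num6(tensors$z)
    ),
    " ---------------------------------------------------------------------",
    " SCF GIAO Magnetic shielding tensor (ppm):"
  )
  for (i in seq_len(nrow(tensors))) {
    s <- tensor_matrix(tensors, i)
    iso <- mean(diag(s))
    out <- c(
      out,
      sprintf("  %5d  %-2s   Isotropic = %12.4f   Anisotropy = %12.4f",
        i, el[i], iso, 0
      ),
      sprintf("   XX= %12.4f   YX= %12.4f   ZX= %12.4f", s[1, 1], s[2, 1], s[3, 1]),
      sprintf("   XY= %12.4f   YY= %12.4f   ZY= %12.4f", s[1, 2], s[2, 2], s[3, 2]),
      sprintf("   XZ= %12.4f   YZ= %12.4f   ZZ= %12.4f", s[1, 3], s[2, 3], s[3, 3])
    )
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Write an NMR job input deck with ghost probes
#'
#' Emits a Gaussian-style input deck listing the real atoms followed by
#' ghost (`Bq`) centres at every probe position, the standard way of
#' requesting NICS values at arbitrary points. Output is deterministic,
#' byte-for-byte, for fixed inputs. A probe closer than 0.1 Angstrom to an
#' atom triggers a warning (the shielding there is dominated by the local
#' density, not by ring currents) but is still written.
#'
#' @param mol a molecule tibble.
#' @param probes a probe-set tibble (non-empty).
#' @param route route/method line.
#' @param charge,multiplicity molecular charge and spin multiplicity.
#' @param title job title line.
#' @return a single string (LF line endings).
#' @export
write_nmr_input <- function(mol, probes,
                            route = "# PBE1PBE/Def2SVP NMR=GIAO",
                            charge = 0L, multiplicity = 1L,
                            title = "vistr NICS job") {
  mol <- as_molecule(mol)
  probes <- as_probe_set(probes)
  if (nrow(probes) == 0L) {
    stop("probe set is empty: nothing to write", call. = FALSE)
  }
  axyz <- as.matrix(mol[, c("x", "y", "z")])
  for (k in seq_len(nrow(probes))) {
    p <- as.numeric(probes[k, c("x", "y", "z")])
    d <- sqrt(rowSums(sweep(axyz, 2, p)^2))
    if (min(d) < 0.1) {
      warning(sprintf(
        "probe '%s' lies within 0.1 Angstrom of atom %d", probes$label[k],
        which.min(d)
      ), call. = FALSE)
    }
  }
  lines <- c(
    route,
    "",
    title,
    "",
    sprintf("%d %d", as.integer(charge), as.integer(multiplicity)),
    sprintf("%-3s %12s %12s %12s", mol$element, num6(mol$x), num6(mol$y), num6(mol$z)),
    sprintf("%-3s %12s %12s %12s", "Bq", num6(probes$x), num6(probes$y), num6(probes$z)),
    ""
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Volumetric density grids (cube format)
#'
#' A density grid holds a scalar field on a regular 3D lattice in the layout
#' of the cube file format: an origin and three axis step vectors in bohr,
#' per-axis point counts, the scalar values (electrons/bohr^3 for electron
#' densities) and the atom list. Values are stored as a 3D array indexed
#' `[i1, i2, i3]`; in the file the third index runs fastest.
#'
#' `read_cube()`/`write_cube()` round-trip the standard dialect (two comment
#' lines; atom count + origin; three axis lines; atom records; values six
#' per line). Cube files with a negative atom count (the molecular-orbital
#' cube convention, which inserts an extra orbital-list record) are rejected
#' with a clear message rather than misread.
#'
#' @param origin grid origin, bohr.
#' @param axes 3x3 matrix, rows = step vectors along each axis, bohr.
#' @param values numeric 3D array of scalar values.
#' @param atoms tibble with `atomic_number`, `charge`, `x`, `y`, `z` (bohr);
#'   may be empty.
#' @param comments two comment lines.
#' @return a `density_grid` object.
#' @export
density_grid <- function(origin, axes, values,
                         atoms = NULL,
                         comments = c("vistr density grid", "")) {
  axes <- as.matrix(axes)
  stopifnot(all(dim(axes) == c(3L, 3L)), all(is.finite(axes)))
  counts <- dim(values)
  if (length(counts) != 3L || any(counts < 1L)) {
    stop("`values` must be a 3D array with counts >= 1 per axis", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("grid values must be finite", call. = FALSE)
  }
  if (is.null(atoms)) {
    atoms <- tibble::tibble(
      atomic_number = integer(), charge = numeric(),
      x = numeric(), y = numeric(), z = numeric()
    )
  }
  structure(
    list(
      origin = as.numeric(origin), axes = axes, counts = as.integer(counts),
      values = values, atoms = tibble::as_tibble(atoms),
      comments = rep_len(as.character(comments), 2L)
    ),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf(
    "<density_grid> %d x %d x %d points, %d atom(s)\n",
    x$counts[1], x$counts[2], x$counts[3], nrow(x$atoms)
  ))
  cat(sprintf(
    "  origin (bohr): %s\n  value range: [%g, %g]\n",
    paste(sprintf("%.4f", x$origin), collapse = " "),
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @rdname density_grid
#' @param text cube text: a character vector of lines, one string, or a path.
#' @export
read_cube <- function(text) {
  lines <- as_lines(text)
  if (length(lines) < 6L) stop("cube file too short", call. = FALSE)
  split_nums <- function(ln) as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
  hdr <- split_nums(lines[3])
  natoms <- as.integer(hdr[1])
  if (is.na(natoms)) stop("malformed cube header line 3", call. = FALSE)
  if (natoms < 0L) {
    stop(paste(
      "cube file uses the negative-atom-count molecular-orbital convention;",
      "only plain scalar-field cubes are supported"
    ), call. = FALSE)
  }
  origin <- hdr[2:4]
  counts <- integer(3)
  axes <- matrix(0, 3L, 3L)
  for (k in 1:3) {
    ax <- split_nums(lines[3 + k])
    counts[k] <- as.integer(ax[1])
    axes[k, ] <- ax[2:4]
  }
  if (any(counts < 1L)) {
    stop("cube axis counts must be >= 1", call. = FALSE)
  }
  atoms <- tibble::tibble(
    atomic_number = integer(), charge = numeric(),
    x = numeric(), y = numeric(), z = numeric()
  )
  if (natoms > 0L) {
    arec <- lapply(lines[7:(6 + natoms)], split_nums)
    atoms <- tibble::tibble(
      atomic_number = as.integer(vapply(arec, `[`, numeric(1), 1L)),
      charge = vapply(arec, `[`, numeric(1), 2L),
      x = vapply(arec, `[`, numeric(1), 3L),
      y = vapply(arec, `[`, numeric(1), 4L),
      z = vapply(arec, `[`, numeric(1), 5L)
    )
  }
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[(7L + natoms):length(lines)]), "\\s+")
  )))
  vals <- vals[!is.na(vals)]
  nexp <- prod(counts)
  if (length(vals) != nexp) {
    stop(sprintf(
      "truncated cube payload: expected %d values, found %d",
      nexp, length(vals)
    ), call. = FALSE)
  }
  # file order: third index fastest, first slowest
  arr <- aperm(array(vals, dim = rev(counts)), 3:1)
  density_grid(origin, axes, arr,
    atoms = atoms,
    comments = lines[1:2]
  )
}

#' @rdname density_grid
#' @param grid a `density_grid`.
#' @param path optional output file; when `NULL` the text is returned.
#' @export
write_cube <- function(grid, path = NULL) {
  stopifnot(inherits(grid, "density_grid"))
  out <- c(
    grid$comments[1], grid$comments[2],
    sprintf(
      "%5d %11.6f %11.6f %11.6f", nrow(grid$atoms),
      grid$origin[1], grid$origin[2], grid$origin[3]
    ),
    sprintf(
      "%5d %11.6f %11.6f %11.6f", grid$counts,
      grid$axes[, 1], grid$axes[, 2], grid$axes[, 3]
    )
  )
  if (nrow(grid$atoms) > 0L) {
    out <- c(out, sprintf(
      "%5d %11.6f %11.6f %11.6f %11.6f",
      grid$atoms$atomic_number, grid$atoms$charge,
      grid$atoms$x, grid$atoms$y, grid$atoms$z
    ))
  }
  flat <- as.vector(aperm(grid$values, 3:1)) # third index fastest
  rows <- split(flat, (seq_along(flat) - 1L) %/% 6L)
  out <- c(out, vapply(rows, function(r) {
    paste(sprintf("%13.6E", r), collapse = " ")
  }, character(1)))
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(path))
  }
  text
}

#' Voxel centre coordinates of a density grid
#'
#' @param grid a `density_grid`.
#' @return an `n x 3` matrix of grid point coordinates in bohr, in the same
#'   order as `as.vector(grid$values)` (first index fastest).
#' @keywords internal
#' @export
grid_points <- function(grid) {
  i1 <- seq_len(grid$counts[1]) - 1L
  i2 <- seq_len(grid$counts[2]) - 1L
  i3 <- seq_len(grid$counts[3]) - 1L
  idx <- as.matrix(expand.grid(i1 = i1, i2 = i2, i3 = i3))
  # expand.grid varies i1 fastest, matching as.vector() on the array
  sweep(idx %*% grid$axes, 2, grid$origin, `+`)
}
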