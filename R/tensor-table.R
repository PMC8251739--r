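#' Shielding tensor tables
#'
#' A shielding tensor set is stored as a tibble with one row per probe point
#' and thirteen columns: `label` (unique probe name), `x`, `y`, `z` (probe
#' position, Angstrom) and the nine tensor entries `s_xx`, `s_xy`, `s_xz`,
#' `s_yx`, ..., `s_zz` in ppm, row-major. The row index of the 3x3 matrix is
#' the nuclear-moment component (gamma) and the column index the external
#' field component (beta), the convention in which sigma is the mixed second
#' derivative of the energy with respect to moment and field. Shielding
#' tensors from a magnetic response calculation are in general non-symmetric,
#' so all nine entries are kept.
#'
#' `shielding_tensor()` builds a one-row tensor table from a 3x3 matrix;
#' `tensor_matrix()` recovers the matrix from row `i`; `as_tensor_table()`
#' validates a data frame (checks columns, finiteness and label uniqueness).
#'
#' @param sigma a 3x3 numeric matrix, ppm.
#' @param origin probe position, numeric length-3, Angstrom.
#' @param label probe label.
#' @param dia,para optional 3x3 matrices with the diamagnetic/paramagnetic
#'   split of `sigma`; stored as extra `d_*`/`p_*` columns, purely as
#'   metadata (the split is gauge-dependent and never used in analysis).
#' @return a tibble as described above.
#' @examples
#' benzene_nics0 <- shielding_tensor(diag(c(13.3, 6.7, 6.7)), label = "NICS(0)")
#' nics_iso(benzene_nics0)
#' @export
shielding_tensor <- function(sigma, origin = c(0, 0, 0), label = "probe",
                             dia = NULL, para = NULL) {
  sigma <- as.matrix(sigma)
  if (!all(dim(sigma) == c(3L, 3L)) || !all(is.finite(sigma))) {
    stop("`sigma` must be a finite 3x3 numeric matrix (ppm)", call. = FALSE)
  }
  if (length(origin) != 3L || !all(is.finite(origin))) {
    stop("`origin` must be a finite 3-vector (Angstrom)", call. = FALSE)
  }
  out <- tibble::tibble(
    label = as.character(label),
    x = origin[1], y = origin[2], z = origin[3]
  )
  ent <- as.vector(t(sigma)) # row-major
  for (k in seq_len(9L)) out[[TENSOR_COLS[k]]] <- ent[k]
  for (part in c("dia", "para")) {
    m <- if (part == "dia") dia else para
    if (!is.null(m)) {
      m <- as.matrix(m)
      stopifnot(all(dim(m) == c(3L, 3L)))
      e <- as.vector(t(m))
      pre <- if (part == "dia") "d_" else "p_"
      cols <- sub("^s_", pre, TENSOR_COLS)
      for (k in seq_len(9L)) out[[cols[k]]] <- e[k]
    }
  }
  out
}

#' @rdname shielding_tensor
#' @param tensors a tensor table.
#' @param i row index.
#' @export
tensor_matrix <- function(tensors, i = 1L) {
  tensors <- as_tensor_table(tensors)
  matrix(as.numeric(tensors[i, TENSOR_COLS]), 3L, 3L, byrow = TRUE)
}

#' @rdname shielding_tensor
#' @param data a data frame with the tensor-table columns.
#' @export
as_tensor_table <- function(data) {
  need <- c("label", "x", "y", "z", TENSOR_COLS)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0L) {
    stop(
      "not a tensor table; missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  num <- as.matrix(data[, c("x", "y", "z", TENSOR_COLS)])
  if (!all(is.finite(num))) {
    stop("tensor table contains non-finite entries", call. = FALSE)
  }
  if (anyDuplicated(data$label)) {
    stop("tensor table labels must be unique", call. = FALSE)
  }
  tibble::as_tibble(data)
}

#' Symmetrize shielding tensors
#'
#' Replaces each tensor by its symmetric part `(sigma + t(sigma)) / 2` at the
#' same probe position. The antisymmetric remainder never contributes to the
#' isotropic NICS (its trace is zero), so symmetrization changes principal
#' axes and eigenvalues only, not isotropic values. Idempotent.
#'
#' @param tensors a tensor table (see [shielding_tensor()]).
#' @return a tensor table of the same shape.
#' @export
symmetrize_tensors <- function(tensors) {
  tensors <- as_tensor_table(tensors)
  pairs <- list(
    c("s_xy", "s_yx"), c("s_xz", "s_zx"), c("s_yz", "s_zy")
  )
  for (p in pairs) {
    m <- (tensors[[p[1]]] + tensors[[p[2]]]) / 2
    tensors[[p[1]]] <- m
    tensors[[p[2]]] <- m
  }
  tensors
}

#' Read and write tensor tables
#'
#' CSV columns: `label, x, y, z, s_xx ... s_zz` (nine entries, row-major);
#' JSON is an array of records with the same fields. Positions in Angstrom,
#' tensor entries in ppm.
#'
#' @param path file path.
#' @param tensors a tensor table.
#' @return the tensor table (readers) or `path`, invisibly (writers).
#' @export
read_tensor_csv <- function(path) {
  as_tensor_table(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_tensor_csv
#' @export
write_tensor_csv <- function(tensors, path) {
  readr::write_csv(as_tensor_table(tensors), path)
  invisible(path)
}

#' @rdname read_tensor_csv
#' @export
read_tensor_json <- function(path) {
  as_tensor_table(tibble::as_tibble(jsonlite::fromJSON(path)))
}

#' @rdname read_tensor_csv
#' @export
write_tensor_json <- function(tensors, path) {
  jsonlite::write_json(as_tensor_table(tensors), path,
    dataframe = "rows", auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}
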