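# Internal helpers and physical constants.

# Bohr radius in Angstrom; cube files are in bohr by convention.
ANGSTROM_PER_BOHR <- 0.52917721

# alpha^2 expressed in ppm (fine-structure constant 1/137.035999).
ALPHA2_PPM <- (1 / 137.035999)^2 * 1e6

TENSOR_COLS <- c(
  "s_xx", "s_xy", "s_xz",
  "s_yx", "s_yy", "s_yz",
  "s_zx", "s_zy", "s_zz"
)

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) {
    stop("cannot normalise a (near-)zero vector", call. = FALSE)
  }
  v / n
}

assert_unit <- function(u, tol = 1e-8, what = "direction") {
  if (length(u) != 3L || !all(is.finite(u))) {
    stop(sprintf("%s must be a finite 3-vector", what), call. = FALSE)
  }
  if (abs(vec_norm(u) - 1) > tol) {
    stop(sprintf("%s must have unit norm (|u| = %g)", what, vec_norm(u)),
      call. = FALSE
    )
  }
  invisible(u)
}

# Two unit vectors spanning the plane orthogonal to a unit normal.
plane_basis <- function(normal) {
  seed <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit_vec(seed - sum(seed * normal) * normal)
  e2 <- c(
    normal[2] * e1[3] - normal[3] * e1[2],
    normal[3] * e1[1] - normal[1] * e1[3],
    normal[1] * e1[2] - normal[2] * e1[1]
  )
  list(e1 = e1, e2 = e2)
}

# Fixed-width numeric formatting used by all text writers (byte determinism).
num6 <- function(x) sprintf("%.6f", x + 0)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
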