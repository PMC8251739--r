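# Shared fixtures: random tensors/rotations and an independent eigenvalue
# oracle (characteristic-polynomial roots), kept separate from the
# eigen()-based implementation path.

rand_tensor <- function(sd = 10) {
  matrix(stats::rnorm(9, sd = sd), 3L, 3L)
}

rand_symmetric <- function(sd = 10) {
  m <- rand_tensor(sd)
  (m + t(m)) / 2
}

rand_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3L, 3L))
  r <- qr.Q(qr_d)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# roots of det(sigma - t I) via polyroot(), independent of eigen()
oracle_eigenvalues <- function(sigma) {
  tr <- sum(diag(sigma))
  c2 <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2] * sigma[2, 1] +
    sigma[1, 1] * sigma[3, 3] - sigma[1, 3] * sigma[3, 1] +
    sigma[2, 2] * sigma[3, 3] - sigma[2, 3] * sigma[3, 2]
  d <- det(sigma)
  # char poly: -t^3 + tr t^2 - c2 t + d = 0
  roots <- polyroot(c(d, -c2, tr, -1))
  roots[order(-abs(Re(roots)))]
}

benzene_nics0_tensor <- function() {
  shielding_tensor(diag(c(13.3, 6.7, 6.7)), label = "NICS(0)")
}

hexagon_ring <- function(r = 1.39) {
  ang <- (0:5) * pi / 3
  molecule(
    element = rep("C", 6),
    x = r * cos(ang), y = r * sin(ang), z = rep(0, 6)
  )
}
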