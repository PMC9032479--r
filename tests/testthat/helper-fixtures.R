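# shared fixtures: potential preset and small reference configurations
PAR <- salr_params()

dimer_at <- function(r) rbind(c(0, 0, 0), c(r, 0, 0))

equilateral_at <- function(s) {
  rbind(c(0, 0, 0), c(s, 0, 0), c(s / 2, s * sqrt(3) / 2, 0))
}

# 1-D oracle for the pair-minimum distance: dense scan bracketed, then
# bisection on the central-difference derivative; independent of the
# package's optimizers
pair_minimum_scan <- function(params = PAR) {
  r <- seq(0.8, 1.2, by = 1e-5)
  v <- pair_energy(r, params)
  i <- which.min(v)
  dv <- function(x, h = 1e-4) {
    # Richardson-extrapolated central difference (h^2 term cancelled)
    d1 <- (pair_energy(x + h, params) - pair_energy(x - h, params)) / (2 * h)
    d2 <- (pair_energy(x + 2 * h, params) - pair_energy(x - 2 * h, params)) / (4 * h)
    (4 * d1 - d2) / 3
  }
  lo <- r[i - 1]; hi <- r[i + 1]
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (dv(mid) < 0) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  list(r = mid, v = pair_energy(mid, params))
}

# central finite-difference gradient oracle
fd_gradient <- function(config, params = PAR, h = 1e-6) {
  g <- matrix(0, nrow(config), 3)
  for (i in seq_len(nrow(config))) {
    for (c in 1:3) {
      up <- config; up[i, c] <- up[i, c] + h
      dn <- config; dn[i, c] <- dn[i, c] - h
      g[i, c] <- (cluster_energy(up, params) - cluster_energy(dn, params)) / (2 * h)
    }
  }
  g
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  rbind(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c)),
        c(2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b)),
        c(2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2))
}

# straight chain along x with given spacing
chain_config <- function(n, spacing = 1) cbind((seq_len(n) - 1) * spacing, 0, 0)
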