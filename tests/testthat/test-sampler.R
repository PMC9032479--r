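test_that("move proposal displaces one uniformly chosen particle", {
  w <- new_walker(build_bernal_spiral(6), PAR, step_size = 0.2)
  set.seed(1)
  t1 <- propose_move(w)
  set.seed(1)
  t2 <- propose_move(w)
  expect_identical(t1, t2)
  moved <- attr(t1, "moved")
  expect_equal(sum(rowSums(t1 != w$config) > 0), 1)
  expect_true(all(abs(t1[moved, ] - w$config[moved, ]) <= 0.2))
  # zero step size proposes the current configuration
  w0 <- new_walker(build_bernal_spiral(6), PAR, step_size = 0)
  expect_equal(propose_move(w0), w0$config, ignore_attr = TRUE)
  # index choice is uniform: 4-sigma multinomial bound on each count
  set.seed(2)
  counts <- table(factor(replicate(1e4, attr(propose_move(w), "moved")),
                         levels = 1:6))
  expt <- 1e4 / 6
  bound <- 4 * sqrt(1e4 * (1 / 6) * (5 / 6))
  expect_true(all(abs(counts - expt) < bound))
})

test_that("metropolis rule accepts downhill and obeys the exact rate", {
  # downhill moves are always accepted: at T ~ 0 the stretched dimer can only
  # slide toward the pair minimum
  set.seed(3)
  w <- new_walker(dimer_at(1.10), PAR, step_size = 0.05)
  for (k in 1:100) w <- metropolis_step(w, T = 1e-8, PAR)
  expect_lt(w$energy, cluster_energy(dimer_at(1.10), PAR))
  expect_gt(w$accepts, 0)

  # empirical acceptance from a pinned state matches the analytic rule
  # (averaged over the proposal distribution, with rupture counted as reject)
  pm <- pair_minimum_scan()
  T <- 0.15
  n_tr <- 3000L
  e0 <- cluster_energy(dimer_at(pm$r), PAR)
  set.seed(4)
  w <- new_walker(dimer_at(pm$r), PAR, step_size = 0.12)
  p_bar <- 0
  for (k in seq_len(n_tr)) {
    trial <- propose_move(w)
    d_e <- cluster_energy(trial, PAR) - e0
    p_acc <- if (is_bound(trial, PAR)) min(1, exp(-d_e / T)) else 0
    p_bar <- p_bar + p_acc / n_tr
  }
  set.seed(5)
  w <- new_walker(dimer_at(pm$r), PAR, step_size = 0.12)
  got <- 0L
  for (k in seq_len(n_tr)) {
    prev <- w$accepts
    w <- metropolis_step(w, T, PAR)
    got <- got + (w$accepts - prev)
    w$config <- dimer_at(pm$r)   # pin so every trial is i.i.d.
    w$energy <- e0
  }
  se <- sqrt(p_bar * (1 - p_bar) / n_tr)
  expect_lt(abs(got / n_tr - p_bar), 4 * se + 0.01)
})

test_that("rupture is rejected even when energetically favourable", {
  # a dimer sitting on the barrier top goes downhill in both directions, but
  # the outward direction unbinds it and must always be refused
  r_top <- barrier_distance(PAR)
  set.seed(6)
  w <- new_walker(dimer_at(r_top - 1e-9), PAR, step_size = 0.15)
  for (k in 1:300) {
    w <- metropolis_step(w, T = 1e-6, PAR)
    r <- sqrt(sum((w$config[1, ] - w$config[2, ])^2))
    expect_true(r <= PAR$r_cut)
    w$config <- dimer_at(r_top - 1e-9)   # re-pin on the barrier top
    w$energy <- cluster_energy(w$config, PAR)
  }
  expect_gt(w$accepts, 0)   # inward downhill moves were accepted
  expect_lt(w$accepts, w$attempts)  # outward downhill moves were refused
  # starting from an unbound state violates the walker invariant
  expect_error(metropolis_step(new_walker(dimer_at(1), PAR), 0.1, PAR), NA)
  bad <- new_walker(dimer_at(1), PAR)
  bad$config <- dimer_at(3.5)
  expect_error(metropolis_step(bad, 0.1, PAR), "unbound")
})

test_that("walker never occupies an unbound configuration", {
  set.seed(11)
  w <- new_walker(build_bernal_spiral(5), PAR, step_size = 0.3)
  for (k in 1:300) {
    w <- metropolis_step(w, T = 0.25, PAR)
    expect_true(is_bound(w$config, PAR))
  }
  expect_equal(w$attempts, 300L)
})

test_that("step-size adaptation follows the multiplicative rule", {
  w <- new_walker(dimer_at(1), PAR, step_size = 0.1)
  # 50% acceptance leaves the step unchanged
  w$block_attempts <- 100L; w$block_accepts <- 50L
  expect_equal(adapt_step_size(w, block = 100)$step_size, 0.1)
  # 80% acceptance scales by 1.6
  w$block_attempts <- 100L; w$block_accepts <- 80L
  expect_equal(adapt_step_size(w, block = 100)$step_size, 0.16)
  # 0% acceptance halves (lower multiplicative clamp)
  w$block_attempts <- 100L; w$block_accepts <- 0L
  expect_equal(adapt_step_size(w, block = 100)$step_size, 0.05)
  # clamps on the step itself
  w$step_size <- 1.9; w$block_attempts <- 100L; w$block_accepts <- 100L
  expect_equal(adapt_step_size(w, block = 100)$step_size, 2)
  # below the block threshold nothing happens
  w$step_size <- 0.1; w$block_attempts <- 10L; w$block_accepts <- 10L
  expect_equal(adapt_step_size(w, block = 100)$step_size, 0.1)
})

test_that("chain sampling matches the dimer quadrature oracle", {
  # constrained Boltzmann average over the bound region r <= r_cut, with the
  # 3-D relative-coordinate Jacobian r^2
  T <- 0.1
  f <- function(r) pair_energy(r, PAR)
  w <- function(r) r^2 * exp(-(f(r) - f(1)) / T)
  Z <- integrate(w, 1e-3, PAR$r_cut)$value
  ev_oracle <- integrate(function(r) f(r) * w(r), 1e-3, PAR$r_cut)$value / Z
  ch <- run_chain(dimer_at(1), T = T, n_steps = 4e5, params = PAR,
                  n_therm = 2e4, record_stride = 20, seed = 7)
  e <- ch$energies
  m <- length(e)
  # crude autocorrelation-aware standard error (batch means)
  bm <- tapply(e, rep(seq_len(50), each = ceiling(m / 50))[seq_len(m)], mean)
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(e) - ev_oracle), 4 * se + 1e-4)
})

test_that("chains are deterministic given a seed and record correctly", {
  x <- build_bernal_spiral(6)
  a <- run_chain(x, T = 0.1, n_steps = 1e4, params = PAR, record_stride = 100,
                 seed = 42)
  b <- run_chain(x, T = 0.1, n_steps = 1e4, params = PAR, record_stride = 100,
                 seed = 42)
  expect_identical(a$energies, b$energies)
  expect_identical(a$samples, b$samples)
  expect_length(a$energies, 100)
  # record stride larger than the run yields empty recordings
  z <- run_chain(x, T = 0.1, n_steps = 50, params = PAR, record_stride = 100,
                 seed = 1)
  expect_length(z$energies, 0)
  # final state is bound and energy is consistent with the coordinates
  expect_true(is_bound(a$state$config, PAR))
  expect_equal(a$state$energy, cluster_energy(a$state$config, PAR),
               tolerance = 1e-9)
})

test_that("adaptation drives long-run acceptance to 50%", {
  x <- relax(build_bernal_spiral(9), PAR)$config
  for (T in c(0.05, 0.15, 0.25)) {
    ch <- run_chain(x, T = T, n_steps = 2e5, params = PAR, n_therm = 5e4,
                    record_stride = 1000, seed = 13)
    expect_gt(ch$acceptance, 0.45)
    expect_lt(ch$acceptance, 0.55)
  }
})

test_that("two-state toy chain reaches Boltzmann occupancies", {
  # discretized double-well check of detailed balance: dimer restricted near
  # two separations; occupancy ratio of r-bins must follow the constrained
  # Boltzmann weight. Use the quadrature oracle for the bin probabilities.
  T <- 0.12
  ch <- run_chain(dimer_at(1), T = T, n_steps = 6e5, params = PAR,
                  n_therm = 5e4, record_stride = 10, seed = 21)
  r <- apply(ch$samples, 1, function(v) {
    m <- matrix(v, ncol = 3, byrow = TRUE)
    sqrt(sum((m[1, ] - m[2, ])^2))
  })
  f <- function(x) pair_energy(x, PAR)
  w <- function(x) x^2 * exp(-(f(x) - f(1)) / T)
  edges <- c(0.95, 1.0, 1.05, 1.156)
  probs <- diff(vapply(edges, function(u) {
    integrate(w, 1e-3, u)$value
  }, 0))
  probs <- probs / integrate(w, 1e-3, PAR$r_cut)$value
  obs <- vapply(seq_len(3), function(i) mean(r > edges[i] & r <= edges[i + 1]), 0)
  n_eff <- length(r) / 20  # generous autocorrelation discount
  for (i in 1:3) {
    se <- sqrt(probs[i] * (1 - probs[i]) / n_eff)
    expect_lt(abs(obs[i] - probs[i]), 4 * se + 0.01)
  }
})
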