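test_that("temperature ladders reproduce the standard replica counts", {
  l26 <- build_ladder(0.05, 0.30, 0.01)
  expect_length(l26, 26)
  expect_equal(as.numeric(l26)[c(1, 26)], c(0.05, 0.30))
  l33 <- build_ladder(0.05, 0.30, 0.01,
                      refinements = list(list(interval = c(0.11, 0.18),
                                              step = 0.005)))
  expect_length(l33, 33)
  expect_true(all(diff(as.numeric(l33)) > 0))
  expect_equal(build_ladder(0.1, 0.2, 0.1), c(0.1, 0.2), ignore_attr = TRUE)
  expect_error(build_ladder(0.05, 0.30, 0.01,
                            refinements = list(list(interval = c(0.01, 0.1),
                                                    step = 0.005))),
               "outside")
})

test_that("DEO pairing alternates even and odd adjacent pairs", {
  expect_equal(deo_pairs(0, 4), cbind(c(1L, 3L), c(2L, 4L)))
  expect_equal(deo_pairs(1, 4), cbind(2L, 3L))
  expect_equal(nrow(deo_pairs(0, 1)), 0)
  expect_equal(deo_pairs(2, 5), cbind(c(1L, 3L), c(2L, 4L)))
  expect_equal(deo_pairs(3, 5), cbind(c(2L, 4L), c(3L, 5L)))
  # pairs are disjoint and adjacent
  for (r in 0:3) {
    pr <- deo_pairs(r, 7)
    expect_equal(pr[, 2] - pr[, 1], rep(1L, nrow(pr)))
    expect_equal(anyDuplicated(as.vector(pr)), 0)
  }
})

test_that("swap probability matches hand-evaluated values", {
  expect_equal(swap_probability(-5, -7, 0.1, 0.1), 1.0)
  expect_equal(swap_probability(-5, -5, 0.1, 0.2), 1.0)
  # (v_m - v_p)(1/t_m - 1/t_p) = (+2)(10 - 5) = +10 -> capped at 1
  expect_equal(swap_probability(-10, -12, 0.1, 0.2), 1.0)
  # reversed energies give exponent -10
  expect_equal(swap_probability(-12, -10, 0.1, 0.2), exp(-10))
  expect_error(swap_probability(-1, -2, 0, 0.1), "positive")
})

test_that("exchange rounds permute configurations and obey the rule", {
  x <- relax(build_bernal_spiral(5), PAR)$config
  ens <- replica_ensemble(x, build_ladder(0.1, 0.3, 0.05), PAR)
  # identical configurations: every proposed swap accepts, observables fixed
  set.seed(8)
  e2 <- exchange_round(ens)
  expect_equal(e2$round_index, 1L)
  expect_equal(sum(e2$swap_accepts), sum(e2$swap_attempts))
  expect_equal(e2$walkers[[1]]$energy, ens$walkers[[1]]$energy)
  # multiset of configurations is conserved by exchange
  ens3 <- ens
  for (k in seq_along(ens3$walkers)) {
    ens3$walkers[[k]]$config <- ens3$walkers[[k]]$config + k  # tag them
    ens3$walkers[[k]]$energy <- cluster_energy(ens3$walkers[[k]]$config, PAR)
  }
  before <- sort(vapply(ens3$walkers, function(w) w$energy, 0))
  set.seed(9)
  for (r in 1:6) ens3 <- exchange_round(ens3)
  after <- sort(vapply(ens3$walkers, function(w) w$energy, 0))
  expect_equal(after, before)
  # empirical per-pair acceptance on a frozen two-replica ensemble matches
  # the analytic swap probability (binomial check)
  ens2 <- replica_ensemble(x, build_ladder(0.1, 0.2, 0.1), PAR)
  ens2$walkers[[1]]$energy <- -10
  ens2$walkers[[2]]$energy <- -12.5
  p_true <- swap_probability(-10, -12.5, 0.1, 0.2)  # exp(-12.5)... exponent?
  # (v_m - v_p)(1/t_m - 1/t_p) = (2.5)(10 - 5) = 12.5 -> 1; reverse for < 1
  expect_equal(p_true, 1)
  ens2$walkers[[1]]$energy <- -12.5
  ens2$walkers[[2]]$energy <- -10
  p_true <- swap_probability(-12.5, -10, 0.1, 0.2)
  expect_equal(p_true, exp(-12.5))
  set.seed(10)
  n_acc <- 0L
  for (k in 1:2000) {
    ens2$round_index <- 0L
    tmp <- exchange_round(ens2)
    n_acc <- n_acc + tmp$swap_accepts[1]
    # freeze: restore energies regardless of swap outcome
    ens2$walkers[[1]]$energy <- -12.5
    ens2$walkers[[2]]$energy <- -10
    ens2$swap_attempts <- integer(1); ens2$swap_accepts <- integer(1)
  }
  se <- sqrt(2000 * p_true * (1 - p_true))
  expect_lt(abs(n_acc - 2000 * p_true), 3 * se + 3)
})

test_that("DEO round-trip time matches the schedule enumeration", {
  # independent oracle: simulate the index permutation the even-odd schedule
  # applies when every swap accepts, and count rounds until the configuration
  # that started at replica 1 reaches replica M
  oracle_rounds <- function(m) {
    pos <- 1L
    r <- 0L
    repeat {
      pr <- deo_pairs(r, m)
      hit <- which(pr[, 1] == pos | pr[, 2] == pos)
      if (length(hit) == 1) {
        pos <- if (pr[hit, 1] == pos) pr[hit, 2] else pr[hit, 1]
      }
      r <- r + 1L
      if (pos == m) return(r)
      if (r > 10 * m) stop("no arrival")
    }
  }
  for (m in c(2, 3, 5, 8)) {
    # frozen ensemble: all energies equal, so every swap accepts; track the
    # tagged configuration through real exchange_round calls
    x <- relax(build_bernal_spiral(4), PAR)$config
    ens <- replica_ensemble(x, build_ladder(0.1, 0.1 + 0.05 * (m - 1), 0.05), PAR)
    # tag the first replica's configuration by a rigid translation: energies
    # stay identical (all swaps accept) but the marker rides along
    ens$walkers[[1]]$config <- sweep(x, 2, c(1000, 0, 0), "+")
    set.seed(12)
    rounds <- 0L
    repeat {
      ens <- exchange_round(ens)
      rounds <- rounds + 1L
      if (ens$walkers[[m]]$config[1, 1] > 500) break
      if (rounds > 10 * m) stop("tag never arrived")
    }
    expect_equal(rounds, oracle_rounds(m))
  }
})

test_that("PTMC with one temperature degenerates to a plain chain", {
  x <- relax(build_bernal_spiral(6), PAR)$config
  one <- run_ptmc(x, build_ladder(0.1, 0.2, 0.1)[1], params = PAR,
                  n_therm = 1e3, n_prod = 2e4, record_stride = 100,
                  n_runs = 1, master_seed = 33)
  ch <- run_chain(x, T = 0.1, n_steps = 2e4, params = PAR, n_therm = 1e3,
                  record_stride = 100, seed = 33)
  expect_identical(one$runs[[1]]$traces[, 1], ch$energies)
})

test_that("PTMC runs are reproducible and conserve invariants", {
  x <- relax(build_bernal_spiral(6), PAR)$config
  lad <- build_ladder(0.08, 0.24, 0.04)
  a <- run_ptmc(x, lad, PAR, n_therm = 5e3, n_prod = 4e4, record_stride = 200,
                n_runs = 2, master_seed = 7)
  b <- run_ptmc(x, lad, PAR, n_therm = 5e3, n_prod = 4e4, record_stride = 200,
                n_runs = 2, master_seed = 7)
  expect_identical(a$runs[[1]]$traces, b$runs[[1]]$traces)
  expect_identical(a$runs[[2]]$traces, b$runs[[2]]$traces)
  # independent runs differ
  expect_false(identical(a$runs[[1]]$traces, a$runs[[2]]$traces))
  # all final states bound, energies consistent
  for (r in a$runs) {
    for (k in seq_along(lad)) {
      expect_true(is_bound(r$final_coords[[k]], PAR))
      expect_equal(r$final_energy[k],
                   cluster_energy(r$final_coords[[k]], PAR), tolerance = 1e-9)
    }
  }
  # swap stride beyond the run length means no exchanges at all
  z <- run_ptmc(x, lad, PAR, n_therm = 0, n_prod = 1e4, swap_stride = 1e6,
                record_stride = 100, n_runs = 1, master_seed = 7)
  expect_equal(sum(z$runs[[1]]$swap_attempts), 0)
  # unbound seeds are refused before sampling
  expect_error(run_ptmc(dimer_at(3), build_ladder(0.1, 0.2, 0.1), PAR,
                        n_prod = 10, n_runs = 1), "unbound")
})

test_that("mean replica energies increase along the ladder", {
  x <- relax(build_bernal_spiral(9), PAR)$config
  lad <- build_ladder(0.05, 0.25, 0.05)
  runs <- run_ptmc(x, lad, PAR, n_therm = 5e4, n_prod = 3e5,
                   record_stride = 100, n_runs = 1, master_seed = 19)
  me <- colMeans(runs$runs[[1]]$traces)
  expect_true(all(diff(me) > 0))
})

test_that("result objects print, summarise and plot without error", {
  x <- relax(build_bernal_spiral(5), PAR)$config
  runs <- run_ptmc(x, build_ladder(0.1, 0.25, 0.05), PAR, n_therm = 1e3,
                   n_prod = 2e4, record_stride = 100, n_runs = 2,
                   master_seed = 77)
  expect_output(print(runs), "ptmc_runs")
  expect_output(print(summary(runs)), "acceptance")
  expect_output(print(PAR), "Yukawa")
  expect_output(print(build_ladder(0.1, 0.2, 0.05)), "M = 3")
  expect_output(print(new_walker(x, PAR)), "walker_state")
  png_path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(png_path)
  plot(runs)
  grDevices::dev.off()
  expect_true(file.size(png_path) > 0)
})
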