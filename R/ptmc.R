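#' Build a temperature ladder
#'
#' Uniform grid from `t_min` to `t_max` (inclusive) in steps of `step`, plus
#' optional refined sub-intervals merged in and deduplicated.  The standard
#' ladders are 26 temperatures over 0.05-0.30 with step 0.01, and the
#' 33-temperature variant adding a 0.005 refinement on 0.11-0.18 around a
#' low-temperature structural-transition peak.
#'
#' @param t_min,t_max Range of reduced temperatures, `0 < t_min < t_max`.
#' @param step Base grid step (> 0); must divide `t_max - t_min`.
#' @param refinements Optional list of `list(interval = c(lo, hi), step = s)`
#'   entries; each interval must nest exactly into the base grid.
#' @return Object of class `temperature_ladder`: a numeric vector of strictly
#'   increasing temperatures with attributes `base_range`, `base_step`,
#'   `refinements`.
#' @examples
#' length(build_ladder(0.05, 0.30, 0.01))  # 26
#' length(build_ladder(0.05, 0.30, 0.01,
#'        refinements = list(list(interval = c(0.11, 0.18), step = 0.005))))  # 33
#' @export
build_ladder <- function(t_min, t_max, step, refinements = NULL) {
  stopifnot(t_min > 0, t_min < t_max, step > 0)
  k <- (t_max - t_min) / step
  if (abs(k - round(k)) > 1e-8) stop("step must divide t_max - t_min")
  temps <- t_min + step * (0:round(k))
  if (!is.null(refinements)) {
    for (rf in refinements) {
      lo <- rf$interval[1]; hi <- rf$interval[2]; s <- rf$step
      if (lo < t_min - 1e-12 || hi > t_max + 1e-12) {
        stop("refinement interval outside base range")
      }
      on_grid <- function(x) {
        m <- (x - t_min) / step
        abs(m - round(m)) < 1e-8
      }
      if (!on_grid(lo) || !on_grid(hi)) {
        stop("refinement endpoints must lie on the base grid")
      }
      kk <- (hi - lo) / s
      if (abs(kk - round(kk)) > 1e-8) stop("refinement step must divide its interval")
      temps <- c(temps, lo + s * (0:round(kk)))
    }
  }
  temps <- sort(temps)
  temps <- temps[c(TRUE, diff(temps) > 1e-9)]
  structure(temps, base_range = c(t_min, t_max), base_step = step,
            refinements = refinements, class = "temperature_ladder")
}

#' @export
print.temperature_ladder <- function(x, ...) {
  cat(sprintf("<temperature_ladder> M = %d temperatures in [%g, %g]\n",
              length(x), min(x), max(x)))
  print(as.numeric(x))
  invisible(x)
}

#' Deterministic even-odd exchange pairs
#'
#' Adjacent replica pairs attempted in a given exchange round: even rounds
#' pair replicas (1,2), (3,4), ...; odd rounds pair (2,3), (4,5), ...
#' (1-based indices; `round_index` counts from 0).  Pairs are disjoint, so a
#' round can be applied in any order.
#'
#' @param round_index Round counter starting at 0.
#' @param m Number of replicas (>= 1).
#' @return Two-column integer matrix of replica index pairs (possibly 0 rows).
#' @export
deo_pairs <- function(round_index, m) {
  stopifnot(m >= 1, round_index >= 0)
  first <- if (round_index %% 2 == 0) 1L else 2L
  a <- seq.int(first, length.out = max(0, floor((m - first) / 2) + 1), by = 2L)
  a <- a[a + 1L <= m]
  cbind(a, a + 1L, deparse.level = 0)
}

#' Replica-swap acceptance probability
#'
#' `min(1, exp((V_m - V_p) (1/T_m - 1/T_p)))` with `k = 1`: the canonical
#' parallel-tempering acceptance rule for exchanging the configurations held
#' at two temperatures.
#'
#' @param v_m,v_p Cluster energies of the two replicas.
#' @param t_m,t_p Their reduced temperatures (> 0).
#' @return Probability in `[0, 1]`.
#' @export
swap_probability <- function(v_m, v_p, t_m, t_p) {
  if (any(c(t_m, t_p) <= 0)) stop("temperatures must be positive")
  min(1, exp((v_m - v_p) * (1 / t_m - 1 / t_p)))
}

#' Create a replica ensemble
#'
#' One walker per ladder temperature, all starting from the same (bound)
#' seed configuration.
#'
#' @param config Seed configuration.
#' @param ladder A [build_ladder()] object (or numeric vector of increasing
#'   temperatures).
#' @param params A [salr_params()] object.
#' @param step_size Initial maximum step size for every walker.
#' @param swap_stride Attempts between exchange rounds.
#' @return Object of class `replica_ensemble`.
#' @export
replica_ensemble <- function(config, ladder, params = salr_params(),
                             step_size = 0.1, swap_stride = 50L) {
  temps <- as.numeric(ladder)
  stopifnot(all(diff(temps) > 0), all(temps > 0))
  walkers <- lapply(temps, function(t) new_walker(config, params, step_size))
  structure(list(ladder = ladder, temps = temps, walkers = walkers,
                 swap_stride = as.integer(swap_stride), round_index = 0L,
                 swap_attempts = integer(length(temps) - 1),
                 swap_accepts = integer(length(temps) - 1)),
            class = "replica_ensemble")
}

#' One deterministic even-odd exchange round
#'
#' For each DEO pair of the current round, the two walkers' configurations
#' (and energies) are swapped with probability [swap_probability()].  Step
#' sizes and acceptance counters stay attached to their temperature slots,
#' not to the configurations.  Uses R's RNG.
#'
#' @param ensemble A [replica_ensemble()].
#' @return The updated ensemble, with `round_index` incremented and swap
#'   statistics accumulated.
#' @export
exchange_round <- function(ensemble) {
  stopifnot(inherits(ensemble, "replica_ensemble"))
  pairs <- deo_pairs(ensemble$round_index, length(ensemble$temps))
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      pr <- swap_probability(ensemble$walkers[[a]]$energy,
                             ensemble$walkers[[b]]$energy,
                             ensemble$temps[a], ensemble$temps[b])
      ensemble$swap_attempts[a] <- ensemble$swap_attempts[a] + 1L
      if (runif(1) < pr || pr >= 1) {
        ensemble$swap_accepts[a] <- ensemble$swap_accepts[a] + 1L
        wa <- ensemble$walkers[[a]]; wb <- ensemble$walkers[[b]]
        tmp_c <- wa$config; tmp_e <- wa$energy
        wa$config <- wb$config; wa$energy <- wb$energy
        wb$config <- tmp_c; wb$energy <- tmp_e
        ensemble$walkers[[a]] <- wa; ensemble$walkers[[b]] <- wb
      }
    }
  }
  ensemble$round_index <- ensemble$round_index + 1L
  ensemble
}

#' Run parallel tempering Monte Carlo
#'
#' The main driver: `M` Metropolis walkers on a temperature ladder, all
#' seeded from the same structure (normally the putative global minimum, so
#' that no fragmented configurations contaminate early sampling), advancing
#' independently between deterministic even-odd exchange rounds every
#' `swap_stride` attempts.  Each independent run derives its own
#' reproducible per-replica RNG streams from `master_seed` and the run
#' index, so results are bit-identical for a fixed seed.
#'
#' @param seed_structure Bound configuration used to start every replica, or
#'   a `structure_record`.
#' @param ladder A [build_ladder()] ladder.
#' @param params A [salr_params()] object.
#' @param n_therm Thermalization attempts per replica (excluded from traces).
#' @param n_prod Production attempts per replica.
#' @param swap_stride Attempts between exchange rounds (default 50).
#' @param record_stride Attempts between recorded energies (default 1000).
#' @param sample_stride Attempts between stored configurations (default
#'   `record_stride`).
#' @param n_runs Number of independent runs (default 3); run `r` uses run
#'   index `r - 1` to derive its RNG streams.
#' @param master_seed Integer master seed.
#' @param step0 Initial maximum step size.
#' @param adapt_block Attempts per step-size adaptation block (0 disables).
#' @param target_acc Target acceptance rate (default 0.5).
#' @param mode Boundedness mode, see [is_bound()].
#' @param store_samples Store configurations for later quenching?
#' @return Object of class `ptmc_runs`: a list with `runs` (one `ptmc_run`
#'   per independent run, each holding `traces` -- a recorded-energy matrix
#'   with one column per temperature -- `samples`, swap statistics, final
#'   states), plus `ladder`, `params`, `n`, `spec`.
#' @seealso [cv_curve()], [quench_samples()]
#' @export
run_ptmc <- function(seed_structure, ladder, params = salr_params(),
                     n_therm = 5e5, n_prod = 2e6, swap_stride = 50L,
                     record_stride = 1000L, sample_stride = record_stride,
                     n_runs = 3L, master_seed = 1L, step0 = 0.1,
                     adapt_block = 1000L, target_acc = 0.5,
                     mode = c("connected", "per-particle"),
                     store_samples = TRUE) {
  mode <- match.arg(mode)
  if (inherits(seed_structure, "structure_record")) {
    seed_structure <- seed_structure$config
  }
  seed_structure <- as_configuration(seed_structure)
  if (!is_bound(seed_structure, params, mode)) {
    stop("seed structure is unbound; refusing to start sampling")
  }
  temps <- as.numeric(ladder)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    res <- cpp_run_ptmc(seed_structure, params_vector(params), temps,
                        n_therm, n_prod, as.integer(swap_stride),
                        as.integer(record_stride), as.integer(sample_stride),
                        as.integer(adapt_block), target_acc, step0,
                        identical(mode, "connected"),
                        as.numeric(master_seed), r - 1L, store_samples,
                        adapt_block > 0)
    runs[[r]] <- structure(
      list(temps = temps, traces = res$traces, samples = res$samples,
           final_coords = res$final_coords, final_energy = res$final_energy,
           step_sizes = res$step_sizes, acceptance = res$acceptance,
           swap_attempts = res$swap_attempts, swap_accepts = res$swap_accepts,
           rounds = res$rounds, run_index = r - 1L),
      class = "ptmc_run")
  }
  structure(list(runs = runs, ladder = ladder, temps = temps, params = params,
                 n = nrow(seed_structure), seed_structure = seed_structure,
                 spec = list(n_therm = n_therm, n_prod = n_prod,
                             swap_stride = swap_stride,
                             record_stride = record_stride,
                             sample_stride = sample_stride, n_runs = n_runs,
                             master_seed = master_seed, step0 = step0,
                             adapt_block = adapt_block,
                             target_acc = target_acc, mode = mode)),
            class = "ptmc_runs")
}

#' @export
print.ptmc_runs <- function(x, ...) {
  cat(sprintf(
    "<ptmc_runs> N = %d, M = %d temperatures in [%g, %g], %d run(s)\n",
    x$n, length(x$temps), min(x$temps), max(x$temps), length(x$runs)))
  cat(sprintf("  %g thermalization + %g production attempts per replica, swap every %d\n",
              x$spec$n_therm, x$spec$n_prod, x$spec$swap_stride))
  invisible(x)
}

#' @export
summary.ptmc_runs <- function(object, ...) {
  cv <- cv_curve(object)
  acc <- rowMeans(sapply(object$runs, function(r) r$acceptance))
  sw <- rowMeans(sapply(object$runs, function(r) {
    ifelse(r$swap_attempts > 0, r$swap_accepts / r$swap_attempts, NA_real_)
  }))
  out <- list(cv = cv, acceptance = acc, swap_rates = sw, n = object$n,
              n_runs = length(object$runs))
  class(out) <- "summary.ptmc_runs"
  out
}

#' @export
print.summary.ptmc_runs <- function(x, ...) {
  cat(sprintf("PTMC summary: N = %d, %d run(s)\n", x$n, x$n_runs))
  cat(sprintf("  move acceptance: %.3f-%.3f across temperatures\n",
              min(x$acceptance), max(x$acceptance)))
  if (length(x$swap_rates) && any(is.finite(x$swap_rates))) {
    cat(sprintf("  swap acceptance: %.3f-%.3f across adjacent pairs\n",
                min(x$swap_rates, na.rm = TRUE),
                max(x$swap_rates, na.rm = TRUE)))
  }
  cat("  heat-capacity curve:\n")
  print(utils::head(as.data.frame(x$cv), 8))
  invisible(x)
}

#' @export
plot.ptmc_runs <- function(x, ...) {
  plot(cv_curve(x), ...)
}
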