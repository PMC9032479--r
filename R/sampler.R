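#' Create a Metropolis walker state
#'
#' @param config Starting configuration (must be bound).
#' @param params A [salr_params()] object.
#' @param step_size Maximum per-axis displacement of a proposed move.
#' @param mode Boundedness mode, see [is_bound()].
#' @return Object of class `walker_state` with fields `config`, `energy`,
#'   `step_size`, `attempts`, `accepts`, `block_attempts`, `block_accepts`.
#' @export
new_walker <- function(config, params = salr_params(), step_size = 0.1,
                       mode = c("connected", "per-particle")) {
  mode <- match.arg(mode)
  config <- as_configuration(config)
  if (!is_bound(config, params, mode)) stop("starting configuration is unbound")
  structure(list(config = config, energy = cluster_energy(config, params),
                 step_size = step_size, attempts = 0L, accepts = 0L,
                 block_attempts = 0L, block_accepts = 0L, mode = mode),
            class = "walker_state")
}

#' @export
print.walker_state <- function(x, ...) {
  cat(sprintf(
    "<walker_state> N = %d, E = %.6f, step = %.4g, acceptance %s\n",
    nrow(x$config), x$energy, x$step_size,
    if (x$attempts > 0) sprintf("%.3f (%d/%d)", x$accepts / x$attempts,
                                x$accepts, x$attempts) else "-"))
  invisible(x)
}

#' Propose a single-particle move
#'
#' One particle chosen uniformly at random is displaced by a uniform random
#' vector in the cube `[-step_size, step_size]^3`; all others are unchanged.
#' Uses R's RNG (seed with [set.seed()] for reproducibility).
#'
#' @param state A `walker_state`.
#' @return The trial configuration matrix, with the moved particle's index in
#'   attribute `"moved"`.
#' @export
propose_move <- function(state) {
  stopifnot(inherits(state, "walker_state"))
  n <- nrow(state$config)
  i <- sample.int(n, 1)
  trial <- state$config
  trial[i, ] <- trial[i, ] + runif(3, -state$step_size, state$step_size)
  attr(trial, "moved") <- i
  trial
}

#' One Metropolis step with rupture rejection
#'
#' Proposes a single-particle move and accepts it with probability
#' `min(1, exp(-dV / T))` -- but only if the trial configuration is still
#' bound; a move that ruptures the cluster is rejected regardless of its
#' energy change, and counts as an attempt.
#'
#' @param state A `walker_state`.
#' @param T Reduced temperature (> 0).
#' @param params A [salr_params()] object.
#' @return The updated `walker_state`.
#' @export
metropolis_step <- function(state, T, params = salr_params()) {
  stopifnot(inherits(state, "walker_state"), T > 0)
  if (!is_bound(state$config, params, state$mode)) {
    stop("walker invariant violated: current state is unbound")
  }
  trial <- propose_move(state)
  e_new <- cluster_energy(trial, params)
  d_e <- e_new - state$energy
  accept <- if (d_e <= 0) TRUE else runif(1) < exp(-d_e / T)
  if (accept && !is_bound(trial, params, state$mode)) accept <- FALSE
  state$attempts <- state$attempts + 1L
  state$block_attempts <- state$block_attempts + 1L
  if (accept) {
    state$accepts <- state$accepts + 1L
    state$block_accepts <- state$block_accepts + 1L
    attr(trial, "moved") <- NULL
    state$config <- trial
    state$energy <- e_new
  }
  state
}

#' Adapt the maximum step size toward a target acceptance rate
#'
#' Once `block` attempts have accumulated, the step size is multiplied by
#' `acceptance_rate / target`, with the multiplicative change clamped to
#' `[0.5, 2]` per update and the step size itself clamped to
#' `[1e-4, 2 sigma]`; block counters are then reset.  The default target of
#' 50% keeps the Metropolis walk efficient at every temperature.
#'
#' @param state A `walker_state`.
#' @param target Target acceptance fraction (default 0.5).
#' @param block Attempts per adaptation block (>= 1).
#' @param sigma Particle diameter used for the upper clamp.
#' @return The (possibly) updated `walker_state`.
#' @export
adapt_step_size <- function(state, target = 0.5, block = 1000L, sigma = 1) {
  stopifnot(inherits(state, "walker_state"), block >= 1)
  if (state$block_attempts >= block) {
    rate <- state$block_accepts / state$block_attempts
    fac <- min(2, max(0.5, rate / target))
    state$step_size <- min(2 * sigma, max(1e-4, state$step_size * fac))
    state$block_attempts <- 0L
    state$block_accepts <- 0L
  }
  state
}

#' Run a single-temperature Metropolis chain
#'
#' Runs the compiled Metropolis engine (the same inner loop used by
#' [run_ptmc()]) at one temperature, with periodic step-size adaptation and
#' the rupture-rejection rule, recording every `record_stride`-th energy and
#' configuration of the production stage.
#'
#' @param state A `walker_state` (or a configuration matrix, from which one
#'   is built).
#' @param T Reduced temperature (> 0).
#' @param n_steps Production attempts (>= 1).
#' @param params A [salr_params()] object.
#' @param n_therm Thermalization attempts excluded from the records.
#' @param record_stride Attempts between recorded energies/configurations.
#' @param adapt_block Attempts per step-size adaptation block; `0` disables
#'   adaptation.
#' @param target Target acceptance rate for adaptation.
#' @param seed Integer master seed for the compiled RNG stream.
#' @return A list with `energies` (recorded trace), `samples` (matrix, one
#'   row per recorded configuration, coordinates flattened as
#'   `x1 y1 z1 x2 ...`), the final `state`, and `acceptance`.
#' @export
run_chain <- function(state, T, n_steps, params = salr_params(),
                      n_therm = 0, record_stride = 100L, adapt_block = 1000L,
                      target = 0.5, seed = 1L) {
  if (!inherits(state, "walker_state")) state <- new_walker(state, params)
  stopifnot(T > 0, n_steps >= 1)
  res <- cpp_run_ptmc(state$config, params_vector(params), as.numeric(T),
                      n_therm, n_steps, 2147483647L, as.integer(record_stride),
                      as.integer(record_stride), as.integer(adapt_block),
                      target, state$step_size,
                      identical(state$mode, "connected"), as.numeric(seed), 0L,
                      TRUE, adapt_block > 0)
  state$config <- res$final_coords[[1]]
  state$energy <- res$final_energy[[1]]
  state$step_size <- res$step_sizes[[1]]
  state$attempts <- state$attempts + as.integer(n_therm + n_steps)
  state$accepts <- state$accepts +
    as.integer(round(res$acceptance[[1]] * (n_therm + n_steps)))
  list(energies = res$traces[, 1], samples = res$samples[[1]], state = state,
       acceptance = res$acceptance[[1]])
}
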