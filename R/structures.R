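#' Ideal Bernal spiral (Boerdijk-Coxeter tetrahelix)
#'
#' Places `n` particles on the unit-edge tetrahelix: particle `k` (counting
#' from 0) at `(rho_h cos(k theta), rho_h sin(k theta), k h)` with
#' `rho_h = 3 sqrt(3) / 10`, `h = 1 / sqrt(10)` and `theta = acos(-2/3)`.
#' Consecutive tetrahedra share faces, so every particle sits at distance 1
#' from its (up to) three predecessors and three successors along the helix.
#' This is the idealized Bernal-spiral motif that SALR clusters adopt as
#' their low-energy structure at intermediate sizes.
#'
#' @param n Number of particles (>= 2).
#' @return An `n x 3` configuration matrix.
#' @examples
#' tet <- build_bernal_spiral(4)  # a regular unit tetrahedron
#' round(dist(tet), 9)
#' @export
build_bernal_spiral <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    stop("n must be an integer >= 2")
  }
  rho_h <- 3 * sqrt(3) / 10
  h <- 1 / sqrt(10)
  theta <- acos(-2 / 3)
  k <- seq_len(n) - 1
  cbind(rho_h * cos(k * theta), rho_h * sin(k * theta), k * h)
}

#' Random bound cluster
#'
#' Builds a connected configuration by sequential insertion: each new
#' particle is placed at a random distance in `(0.9 sigma, r_cut)` and random
#' direction from a uniformly chosen existing particle, retrying until the
#' new particle does not overlap (distance `> 0.9 sigma` from all others).
#' The result always passes [is_bound()] in connected mode.  Used as a
#' fixture generator for tests and as a random start for [basin_hopping()].
#'
#' @param n Number of particles (>= 2).
#' @param params A [salr_params()] object.
#' @param seed Optional integer seed for reproducibility.
#' @return An `n x 3` configuration matrix.
#' @export
random_bound_cluster <- function(n, params = salr_params(), seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    stop("n must be an integer >= 2")
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  rc <- params$r_cut
  # keep insertions off the steep Morse wall so the cluster is mechanically
  # reasonable (a 0.9 sigma contact already costs ~7e2 energy units)
  lo <- 0.95 * params$sigma
  x <- matrix(0, n, 3)
  for (i in 2:n) {
    repeat {
      anchor <- x[sample.int(i - 1, 1), ]
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      r <- runif(1, lo, rc)
      cand <- anchor + r * u
      d <- sqrt(colSums((t(x[seq_len(i - 1), , drop = FALSE]) - cand)^2))
      if (all(d > lo)) break
    }
    x[i, ] <- cand
  }
  x
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Structure record
#'
#' Lightweight container pairing a configuration with its energy.
#'
#' @param config Configuration matrix.
#' @param params A [salr_params()] object.
#' @param provenance One of `"built"`, `"basin-hopping"`, `"quench"`.
#' @param converged Logical, did the local optimization converge.
#' @return Object of class `structure_record` with fields `config`, `energy`,
#'   `energy_per_particle`, `n`, `provenance`, `converged`.
#' @export
structure_record <- function(config, params = salr_params(),
                             provenance = c("built", "basin-hopping", "quench"),
                             converged = NA) {
  provenance <- match.arg(provenance)
  config <- as_configuration(config)
  e <- cluster_energy(config, params)
  structure(list(config = config, energy = e,
                 energy_per_particle = e / nrow(config), n = nrow(config),
                 provenance = provenance, converged = converged),
            class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat(sprintf("<structure_record> N = %d, E = %.6f (%.4f per particle), %s%s\n",
              x$n, x$energy, x$energy_per_particle, x$provenance,
              if (isTRUE(x$converged)) ", converged"
              else if (identical(x$converged, FALSE)) ", NOT converged" else ""))
  invisible(x)
}

#' Basin-hopping global optimization
#'
#' Searches for the putative global minimum of an `n`-particle SALR cluster:
#' starting from a relaxed seed, each hop displaces one randomly chosen
#' particle by a uniform vector in `[-hop_size, hop_size]^3`, relaxes the
#' result to its local minimum, discards it if unbound, and accepts the new
#' minimum with the Metropolis probability `min(1, exp(-dE / temperature))`
#' on minima energies.  The best structure seen is tracked and returned; the
#' best-so-far energy is non-increasing in hop count by construction.
#'
#' @param n Cluster size (>= 2).
#' @param params A [salr_params()] object.
#' @param n_hops Number of hops (default 5000).
#' @param hop_size Maximum per-axis displacement of the perturbed particle,
#'   in units of sigma (default 0.3).
#' @param temperature Acceptance temperature on minima energies (default
#'   0.05, of the order of the lowest sampling temperatures).
#' @param seed Optional integer seed.
#' @param start `"spiral"` (relaxed tetrahelix, default), `"random"`, or a
#'   configuration matrix.
#' @param tol Gradient-norm convergence tolerance for each relaxation.
#' @return A `structure_record` (provenance `"basin-hopping"`) with an extra
#'   field `best_trace`, the best energy after each hop.
#' @export
basin_hopping <- function(n, params = salr_params(), n_hops = 5000,
                          hop_size = 0.3, temperature = 0.05, seed = NULL,
                          start = c("spiral", "random"), tol = 1e-8) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  if (is.character(start)) {
    start <- match.arg(start)
    x0 <- if (identical(start, "spiral")) build_bernal_spiral(n)
          else random_bound_cluster(n, params)
  } else {
    x0 <- as_configuration(start)
    stopifnot(nrow(x0) == n)
  }
  pv <- params_vector(params)
  cur <- cpp_relax(x0, pv, tol, 1000L)
  best <- cur
  best_trace <- numeric(n_hops)
  for (hop in seq_len(n_hops)) {
    trial <- cur$coords
    i <- sample.int(n, 1)
    trial[i, ] <- trial[i, ] + runif(3, -hop_size, hop_size)
    rx <- cpp_relax(trial, pv, tol, 1000L)
    ok <- rx$converged && cpp_is_bound(rx$coords, params$r_cut, TRUE)
    if (ok) {
      d_e <- rx$energy - cur$energy
      if (d_e <= 0 || runif(1) < exp(-d_e / temperature)) cur <- rx
      if (rx$energy < best$energy) best <- rx
    }
    best_trace[hop] <- best$energy
  }
  rec <- structure_record(best$coords, params, provenance = "basin-hopping",
                          converged = best$converged)
  rec$best_trace <- best_trace
  rec
}
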