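#' SALR pair-potential parameters
#'
#' Bundle the parameters of the Morse-plus-Yukawa pair potential in reduced
#' units.  The default preset `"M30+Y1.0"` is the type-II SALR model with
#' `rho = 30`, `eps_M = 2`, `sigma = 1`, `kappa_sigma = 0.5`, `eps_Y = 1`:
#' a narrow attractive well of depth 2 at contact plus a soft repulsive tail,
#' producing a barrier just beyond the well.  `r_cut`, the distance that
#' defines a "bound" interaction for the rupture-rejection test, defaults to
#' the barrier-top distance (the only distinguished length in the model); it
#' never truncates the energy, which always sums all pairs.
#'
#' @param preset Named preset, currently `"M30+Y1.0"`, or `NULL` to use the
#'   individual arguments.
#' @param rho Dimensionless Morse range parameter (> 0); larger values give a
#'   shorter-ranged attraction.
#' @param eps_M Morse well depth (reduced energy, > 0).
#' @param sigma Particle diameter, the unit of length (> 0).
#' @param eps_Y Yukawa repulsion strength (reduced energy, >= 0), proportional
#'   to the particle charge squared.
#' @param kappa_sigma Inverse Debye length times `sigma` (>= 0).
#' @param r_cut Bound-interaction cutoff.  `NULL` (default) uses the
#'   barrier-top distance when a barrier exists.
#' @return An object of class `salr_params`.
#' @examples
#' p <- salr_params()
#' pair_energy(1, p)  # -1: well depth -2 plus repulsion +1 at contact
#' @export
salr_params <- function(preset = "M30+Y1.0", rho = 30, eps_M = 2, sigma = 1,
                        eps_Y = 1, kappa_sigma = 0.5, r_cut = NULL) {
  if (!is.null(preset)) {
    if (!identical(preset, "M30+Y1.0")) {
      stop("unknown preset: ", preset)
    }
    rho <- 30; eps_M <- 2; sigma <- 1; eps_Y <- 1; kappa_sigma <- 0.5
  }
  stopifnot(rho > 0, eps_M > 0, sigma > 0, eps_Y >= 0, kappa_sigma >= 0)
  p <- structure(
    list(rho = rho, eps_M = eps_M, sigma = sigma, eps_Y = eps_Y,
         kappa_sigma = kappa_sigma, r_cut = NA_real_, preset = preset),
    class = "salr_params")
  if (is.null(r_cut)) {
    r_cut <- tryCatch(barrier_distance(p), error = function(e) NA_real_)
  }
  if (!is.na(r_cut) && r_cut <= sigma) stop("r_cut must exceed sigma")
  p$r_cut <- r_cut
  p
}

#' @export
print.salr_params <- function(x, ...) {
  cat("SALR pair potential (reduced units",
      if (!is.null(x$preset)) paste0(", preset ", x$preset), ")\n", sep = "")
  cat(sprintf("  Morse:  eps_M = %g, rho = %g, sigma = %g\n",
              x$eps_M, x$rho, x$sigma))
  cat(sprintf("  Yukawa: eps_Y = %g, kappa*sigma = %g\n", x$eps_Y, x$kappa_sigma))
  cat(sprintf("  bound cutoff r_cut = %.6g\n", x$r_cut))
  invisible(x)
}

params_vector <- function(params) {
  stopifnot(inherits(params, "salr_params"))
  c(params$rho, params$eps_M, params$sigma, params$eps_Y, params$kappa_sigma,
    params$r_cut)
}

check_r <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0)) {
    stop("pair distance must be positive and finite")
  }
}

#' Morse attraction
#'
#' Short-range attractive component
#' `eps_M * exp(rho (1 - r/sigma)) * (exp(rho (1 - r/sigma)) - 2)`:
#' a well of depth `eps_M` at `r = sigma`, decaying to zero at large `r`.
#'
#' @param r Pair distance(s), reduced length (> 0).
#' @param params A [salr_params()] object.
#' @return Reduced energy, vectorized over `r`.
#' @export
morse_attraction <- function(r, params = salr_params()) {
  check_r(r)
  e <- exp(params$rho * (1 - r / params$sigma))
  params$eps_M * e * (e - 2)
}

#' Yukawa repulsion
#'
#' Long-range repulsive component
#' `eps_Y * exp(-kappa_sigma (r/sigma - 1)) / (r/sigma)`, the screened
#' electrostatic tail; strictly positive and decreasing.
#'
#' @inheritParams morse_attraction
#' @return Reduced energy, vectorized over `r`.
#' @export
yukawa_repulsion <- function(r, params = salr_params()) {
  check_r(r)
  x <- r / params$sigma
  params$eps_Y * exp(-params$kappa_sigma * (x - 1)) / x
}

#' SALR pair energy
#'
#' Sum of [morse_attraction()] and [yukawa_repulsion()].
#'
#' @inheritParams morse_attraction
#' @return Reduced energy, vectorized over `r`.
#' @export
pair_energy <- function(r, params = salr_params()) {
  morse_attraction(r, params) + yukawa_repulsion(r, params)
}

#' Validate a configuration
#'
#' A configuration is an `N x 3` numeric matrix of reduced-length coordinates,
#' with `N >= 2` and no coincident particles.
#'
#' @param config Candidate configuration.
#' @return The configuration, invisibly, after validation.
#' @export
as_configuration <- function(config) {
  config <- as.matrix(config)
  if (!is.numeric(config) || ncol(config) != 3 || nrow(config) < 2) {
    stop("a configuration is an N x 3 numeric matrix with N >= 2")
  }
  if (any(!is.finite(config))) stop("non-finite coordinates")
  d <- stats::dist(config)
  if (any(d == 0)) stop("coincident particles in configuration")
  storage.mode(config) <- "double"
  config
}

#' Total cluster energy
#'
#' Sum of the SALR pair energy over all `N(N-1)/2` unordered pairs.  No
#' interaction truncation is applied: the Yukawa tail is summed in full and
#' `r_cut` is used only by the boundedness test.
#'
#' @param config `N x 3` coordinate matrix.
#' @param params A [salr_params()] object.
#' @return Reduced energy (scalar).
#' @export
cluster_energy <- function(config, params = salr_params()) {
  config <- as_configuration(config)
  cpp_cluster_energy(config, params_vector(params))
}

#' Analytic gradient of the cluster energy
#'
#' @inheritParams cluster_energy
#' @return `N x 3` matrix of partial derivatives of [cluster_energy()] with
#'   respect to the coordinates.  Columns sum to zero (translation
#'   invariance).
#' @export
cluster_gradient <- function(config, params = salr_params()) {
  config <- as_configuration(config)
  cpp_cluster_gradient(config, params_vector(params))
}

#' Distance of the repulsive barrier top
#'
#' Locates the interior maximum of the pair energy beyond the attractive well
#' by bracketed 1-D optimization.  For the `"M30+Y1.0"` preset the barrier
#' sits near `r = 1.15 sigma`; its top is the natural divide between bound
#' and unbound pair separations and is the default `r_cut`.
#'
#' @param params A [salr_params()] object (its `r_cut` is not used).
#' @return Barrier distance in reduced length.
#' @export
barrier_distance <- function(params = salr_params(r_cut = 2)) {
  if (params$eps_Y <= 0) stop("no barrier: pure Morse attraction has no maximum")
  # coarse grid to bracket the well and the barrier (the pair curve is not
  # unimodal, so a blind golden-section search can land on an endpoint)
  grid <- seq(0.5 * params$sigma, 5 * params$sigma, length.out = 4501)
  v <- pair_energy(grid, params)
  i_well <- which.min(v)
  after <- seq(i_well, length(grid))
  i_top <- after[which.max(v[after])]
  if (i_top <= i_well + 1 || i_top >= length(grid) - 1) {
    stop("no barrier: pair energy has no interior maximum")
  }
  top <- stats::optimize(function(r) pair_energy(r, params),
                         interval = grid[c(i_top - 1, i_top + 1)],
                         maximum = TRUE, tol = 1e-10)
  if (top$objective <= v[i_well] + 1e-12 ||
      top$objective <= pair_energy(5 * params$sigma, params) + 1e-12) {
    stop("no barrier: pair energy has no interior maximum")
  }
  top$maximum
}

#' Is a cluster bound?
#'
#' Tests the rupture criterion used to reject fragmenting Monte Carlo moves.
#' In `"per-particle"` mode every particle must have at least one neighbour
#' within `r_cut` (the literal criterion).  In `"connected"` mode (default)
#' the graph with edges `r_ij <= r_cut` must form a single connected
#' component, which also rejects detached sub-aggregates.
#'
#' @inheritParams cluster_energy
#' @param mode `"connected"` (default) or `"per-particle"`.
#' @return Logical scalar.
#' @export
is_bound <- function(config, params = salr_params(),
                     mode = c("connected", "per-particle")) {
  mode <- match.arg(mode)
  config <- as_configuration(config)
  if (is.na(params$r_cut)) stop("params has no r_cut set")
  cpp_is_bound(config, params$r_cut, identical(mode, "connected"))
}
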