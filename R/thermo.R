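#' Reduced heat capacity from energy fluctuations
#'
#' Canonical fluctuation estimator of the heat capacity per particle,
#' `cV = 3/2 + (<V^2> - <V>^2) / (N T^2)` with `k = 1`.  The kinetic term
#' contributes the constant 3/2, so `cV >= 1.5` always; moments are taken as
#' population (biased) averages over the recorded samples.
#'
#' @param energies Numeric vector of sampled cluster energies (>= 2 values).
#' @param t Reduced temperature (> 0).
#' @param n Number of particles (>= 2).
#' @return Reduced heat capacity per particle (scalar).
#' @export
heat_capacity <- function(energies, t, n) {
  if (length(energies) < 2) stop("need at least two energy samples")
  stopifnot(t > 0, n >= 2)
  v <- mean(energies^2) - mean(energies)^2
  1.5 + max(0, v) / (n * t^2)
}

#' Heat-capacity curve with run-to-run error bars
#'
#' Applies [heat_capacity()] to each temperature's recorded energy trace in
#' each independent run, then reports the per-temperature mean and the
#' standard deviation across runs (the error estimate used with three
#' independent runs).  With a single run the standard deviation is `NA`.
#'
#' @param runs A `ptmc_runs` object from [run_ptmc()], or a list of such
#'   objects/`ptmc_run`s sharing one ladder.
#' @return Object of class `cv_curve` (a data frame with columns `temp`,
#'   `cv_mean`, `cv_std` and attribute `n_runs`).
#' @export
cv_curve <- function(runs) {
  if (inherits(runs, "ptmc_runs")) {
    n <- runs$n
    temps <- runs$temps
    run_list <- runs$runs
  } else if (is.list(runs) && length(runs) > 0 &&
             all(vapply(runs, inherits, TRUE, "ptmc_run"))) {
    temps <- runs[[1]]$temps
    n <- ncol(runs[[1]]$samples[[1]]) / 3
    run_list <- runs
  } else {
    stop("runs must be a ptmc_runs object or a list of ptmc_run objects")
  }
  for (r in run_list) {
    if (length(r$temps) != length(temps) || any(abs(r$temps - temps) > 1e-12)) {
      stop("runs have mismatched temperature ladders")
    }
  }
  per_run <- sapply(run_list, function(r) {
    vapply(seq_along(temps),
           function(k) heat_capacity(r$traces[, k], temps[k], n), 0)
  })
  per_run <- matrix(per_run, nrow = length(temps))
  out <- data.frame(temp = temps, cv_mean = rowMeans(per_run),
                    cv_std = apply(per_run, 1, function(z) {
                      if (length(z) > 1) stats::sd(z) else NA_real_
                    }))
  structure(out, n_runs = length(run_list), n_particles = n,
            class = c("cv_curve", "data.frame"))
}

#' @export
plot.cv_curve <- function(x, ...) {
  graphics::plot(x$temp, x$cv_mean, type = "b", pch = 16,
                 xlab = "reduced temperature T",
                 ylab = expression(c[V]), ...)
  if (any(is.finite(x$cv_std))) {
    graphics::arrows(x$temp, x$cv_mean - x$cv_std, x$temp,
                     x$cv_mean + x$cv_std, angle = 90, code = 3,
                     length = 0.02)
  }
  invisible(x)
}

moving_average <- function(y, window) {
  if (window <= 1) return(y)
  half <- floor(window / 2)
  n <- length(y)
  vapply(seq_len(n), function(i) {
    j <- max(1, i - half):min(n, i + half)
    mean(y[j])
  }, 0)
}

#' Locate peaks and shoulders on a heat-capacity curve
#'
#' A peak is an interior local maximum of the (optionally smoothed) curve; a
#' shoulder is a flattening on the low-temperature flank of a peak -- a sign
#' change of the second difference without a local maximum.  Feature
#' temperatures are reported on the ladder grid, so localization is limited
#' to the ladder resolution.
#'
#' @param curve A [cv_curve()] object, or a data frame with columns `temp`
#'   and `cv_mean` (>= 5 grid points).
#' @param smoothing Moving-average window in grid points (default 3; 1
#'   disables smoothing).
#' @return Data frame with columns `type` (`"peak"` or `"shoulder"`),
#'   `temperature`, `height`, ordered by temperature.
#' @export
find_features <- function(curve, smoothing = 3) {
  stopifnot(nrow(curve) >= 5)
  t <- curve$temp
  y <- moving_average(curve$cv_mean, smoothing)
  n <- length(y)
  peaks <- integer(0)
  for (i in 2:(n - 1)) {
    if (y[i] > y[i - 1] && y[i] >= y[i + 1]) peaks <- c(peaks, i)
  }
  feats <- data.frame(type = character(0), temperature = numeric(0),
                      height = numeric(0))
  for (i in peaks) {
    feats <- rbind(feats, data.frame(type = "peak", temperature = t[i],
                                     height = curve$cv_mean[i]))
  }
  # shoulders: concavity flips (convex dip in an otherwise rising flank)
  if (n >= 5 && length(peaks) > 0) {
    d2 <- diff(y, differences = 2)  # d2[i] ~ curvature at i + 1
    first_peak <- min(peaks)
    i <- 3
    while (i + 1 < first_peak) {
      # concave -> convex -> concave on a rising stretch marks a shoulder
      if (d2[i - 1] < 0 && d2[i] >= 0 && y[i + 1] > y[i - 1]) {
        feats <- rbind(feats, data.frame(type = "shoulder",
                                         temperature = t[i + 1],
                                         height = curve$cv_mean[i + 1]))
        i <- i + 2
      }
      i <- i + 1
    }
  }
  feats[order(feats$temperature), , drop = FALSE]
}
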