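#' Read an XYZ file
#'
#' Standard XYZ: a count line, a comment line, then one `element x y z` line
#' per particle; multiple frames may be concatenated.  Comment lines written
#' by [write_xyz()] carry `key=value` metadata (e.g. `energy=... provenance=...`),
#' which is returned in the `"comment"` attribute of each frame.
#'
#' @param path File path.
#' @return A configuration matrix for a single-frame file, or a list of
#'   configuration matrices for a multi-frame file.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!grepl("\\S", lines[i])) {
      i <- i + 1
      next
    }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) stop("line ", i, ": expected a particle count")
    if (i + 1 + n > length(lines)) {
      stop("line ", i, ": count ", n, " exceeds remaining lines")
    }
    comment <- lines[i + 1]
    block <- lines[(i + 2):(i + 1 + n)]
    coords <- matrix(NA_real_, n, 3)
    elems <- character(n)
    for (k in seq_len(n)) {
      parts <- strsplit(trimws(block[k]), "\\s+")[[1]]
      if (length(parts) < 4) stop("line ", i + 1 + k, ": expected element + 3 coordinates")
      vals <- suppressWarnings(as.numeric(parts[2:4]))
      if (any(is.na(vals))) stop("line ", i + 1 + k, ": non-numeric coordinate")
      elems[k] <- parts[1]
      coords[k, ] <- vals
    }
    attr(coords, "comment") <- comment
    attr(coords, "element") <- elems[1]
    frames[[length(frames) + 1]] <- coords
    i <- i + 2 + n
  }
  if (length(frames) == 0) stop("no frames found in ", path)
  if (length(frames) == 1) frames[[1]] else frames
}

#' Write configurations to an XYZ file
#'
#' @param config A configuration matrix, a `structure_record`, or a list of
#'   either (written as a multi-frame file).
#' @param path Output path.
#' @param element Element symbol to write (default `"C"`).
#' @param comment Comment line; defaults to `key=value` metadata with the
#'   energy and provenance when available.
#' @param params Used to compute the energy for plain matrices.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(config, path, element = "C", comment = NULL,
                      params = NULL) {
  frames <- if (is.list(config) && !inherits(config, "structure_record")) {
    config
  } else {
    list(config)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    if (inherits(f, "structure_record")) {
      cmt <- sprintf("energy=%.10f provenance=%s", f$energy, f$provenance)
      m <- f$config
    } else {
      m <- as_configuration(f)
      cmt <- if (!is.null(comment)) {
        comment
      } else if (!is.null(params)) {
        sprintf("energy=%.10f provenance=built", cluster_energy(m, params))
      } else {
        ""
      }
    }
    if (!is.null(comment)) cmt <- comment
    writeLines(as.character(nrow(m)), con)
    writeLines(cmt, con)
    writeLines(sprintf("%s %.17g %.17g %.17g", element, m[, 1], m[, 2], m[, 3]),
               con)
  }
  invisible(path)
}

#' Run configuration
#'
#' Bundles everything needed to reproduce a PTMC run: potential preset and
#' overrides, cluster size, ladder, step counts, strides, number of runs and
#' master seed.  The `"desk"` profile holds the scaled-down defaults used
#' throughout this package (2e6 production attempts per replica); the
#' `"paper"` profile holds the full-scale settings (1.5e10 production,
#' 5e9 thermalization) that the desk runs approximate.
#'
#' @param n Cluster size.
#' @param profile `"desk"` (default) or `"paper"`.
#' @param preset Potential preset name.
#' @param t_min,t_max,step Ladder specification.
#' @param refinements Ladder refinements (see [build_ladder()]).
#' @param n_therm,n_prod,swap_stride,record_stride,n_runs,master_seed
#'   Overrides of the profile values.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(n, profile = c("desk", "paper"), preset = "M30+Y1.0",
                       t_min = 0.05, t_max = 0.30, step = 0.01,
                       refinements = NULL, n_therm = NULL, n_prod = NULL,
                       swap_stride = 50L, record_stride = 1000L,
                       n_runs = 3L, master_seed = 1L) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
                     desk = list(n_therm = 5e5, n_prod = 2e6),
                     paper = list(n_therm = 5e9, n_prod = 1.5e10))
  cfg <- list(n = as.integer(n), profile = profile, preset = preset,
              t_min = t_min, t_max = t_max, step = step,
              refinements = refinements,
              n_therm = if (is.null(n_therm)) defaults$n_therm else n_therm,
              n_prod = if (is.null(n_prod)) defaults$n_prod else n_prod,
              swap_stride = as.integer(swap_stride),
              record_stride = as.integer(record_stride),
              n_runs = as.integer(n_runs),
              master_seed = as.integer(master_seed))
  stopifnot(cfg$n >= 2, cfg$n_therm >= 0, cfg$n_prod > 0,
            cfg$swap_stride > 0, cfg$record_stride > 0, cfg$n_runs > 0)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @param path File path for the YAML serialization.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[setdiff(names(raw), "profile")] |>
            c(list(profile = raw$profile)))
}

#' Export a heat-capacity curve as CSV
#'
#' @param curve A [cv_curve()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
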