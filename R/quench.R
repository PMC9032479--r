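#' Relax a configuration to its local minimum
#'
#' Quenches a sampled configuration to the bottom of its energy-landscape
#' basin by limited-memory BFGS with a monotone (Armijo) line search: the
#' energy never increases along the way, so small perturbations of the input
#' cannot push the quench into a different basin.
#'
#' @param config Configuration matrix.
#' @param params A [salr_params()] object.
#' @param tol Gradient-norm convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap; non-convergence is flagged, not an error.
#' @return A `structure_record` (provenance `"quench"`) with fields
#'   `grad_norm` and `converged`.
#' @export
relax <- function(config, params = salr_params(), tol = 1e-8, max_iter = 1000L) {
  config <- as_configuration(config)
  res <- cpp_relax(config, params_vector(params), tol, as.integer(max_iter))
  rec <- structure_record(res$coords, params, provenance = "quench",
                          converged = res$converged)
  rec$grad_norm <- res$grad_norm
  rec$iterations <- res$iterations
  rec
}

#' Deduplicate relaxed minima by energy
#'
#' Greedy merge in ascending energy: a record joins the existing catalog
#' entry whose representative energy is within `tol`, otherwise it founds a
#' new entry.  The default tolerance of 1e-6 reduced energy units treats
#' relaxed structures this close as the same minimum.  Occurrence counts are
#' accumulated per source temperature.
#'
#' @param records List of `structure_record`s (all relaxed).
#' @param temp_index Integer vector, same length as `records`: the ladder
#'   index each record was sampled at.
#' @param n_temps Number of ladder temperatures (columns of the count
#'   matrix).
#' @param tol Energy tolerance for identity (default 1e-6).
#' @return Object of class `minima_catalog`: list with `energies`
#'   (ascending), `representatives` (configurations), `counts` (entries x
#'   temperatures matrix), `dedup_tol`.
#' @export
dedupe <- function(records, temp_index = rep(1L, length(records)),
                   n_temps = max(temp_index, 1L), tol = 1e-6) {
  stopifnot(length(temp_index) == length(records))
  if (length(records) == 0) {
    return(structure(list(energies = numeric(0),
                          representatives = list(),
                          counts = matrix(0, 0, n_temps), dedup_tol = tol),
                     class = "minima_catalog"))
  }
  e <- vapply(records, function(r) r$energy, 0)
  ord <- order(e)
  energies <- numeric(0)
  reps <- list()
  counts <- NULL
  for (i in ord) {
    k <- length(energies)
    if (k > 0 && abs(e[i] - energies[k]) < tol) {
      counts[k, temp_index[i]] <- counts[k, temp_index[i]] + 1
    } else {
      energies <- c(energies, e[i])
      reps[[k + 1]] <- records[[i]]$config
      row <- matrix(0, 1, n_temps)
      row[1, temp_index[i]] <- 1
      counts <- rbind(counts, row)
    }
  }
  structure(list(energies = energies, representatives = reps,
                 counts = counts, dedup_tol = tol),
            class = "minima_catalog")
}

#' @export
print.minima_catalog <- function(x, ...) {
  cat(sprintf("<minima_catalog> %d distinct minima (dedup tol %g), %d records\n",
              length(x$energies), x$dedup_tol, sum(x$counts)))
  if (length(x$energies) > 0) {
    cat("  lowest energies:",
        paste(sprintf("%.4f", utils::head(x$energies, 5)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Structural descriptors and motif label of a relaxed cluster
#'
#' Computes a bond graph (edge iff `r_ij <= r_cut`), the coordination
#' histogram, gyration-tensor eigenvalues (hence relative shape anisotropy),
#' graph diameter and terminal-chain statistics, then maps them to one of
#' the three motif families seen in SALR clusters:
#' \describe{
#'   \item{`"I"`}{compact/spiral, low-energy: near-spherical shapes
#'     (anisotropy below `aniso_compact`) or bond graphs matching a
#'     tetrahelix template (at least `3 N - 6 - template_slack` bonds).}
#'   \item{`"III"`}{linear/branched, essentially unrolled: maximum
#'     coordination `<= set3_max_coord`, or a path graph.}
#'   \item{`"II"`}{everything between -- "beaded-necklace" motifs that keep
#'     part of the 3-D shape.}
#' }
#' Thresholds are exposed because the taxonomy is a visual one
#' operationalized as descriptor cuts; a manual label override is accepted
#' downstream by [motif_frequencies()].
#'
#' @param record A `structure_record` (relaxed) or configuration matrix.
#' @param params A [salr_params()] object.
#' @param aniso_compact Relative-shape-anisotropy cut for compact shapes
#'   (default 0.25; 0 = sphere, 1 = rod).
#' @param template_slack Bonds a tetrahelix-like graph may be missing from
#'   the ideal `3N - 6` (default 2).
#' @param set3_max_coord Maximum coordination of linear/branched motifs
#'   (default 3).
#' @param check_bound Refuse unbound structures (default TRUE).  The quench
#'   pipeline disables the check so that rare fragmented minima still get a
#'   descriptor-based label instead of aborting the census.
#' @return List with `label` (`"I"`, `"II"` or `"III"`) and the descriptor
#'   fields `coordination`, `n_bonds`, `anisotropy`, `gyration_eigenvalues`,
#'   `diameter`, `is_path`, `terminal_chain`.
#' @export
classify_shape <- function(record, params = salr_params(),
                           aniso_compact = 0.25, template_slack = 2,
                           set3_max_coord = 3, check_bound = TRUE) {
  config <- if (inherits(record, "structure_record")) record$config
            else as_configuration(record)
  n <- nrow(config)
  if (check_bound && !is_bound(config, params, "connected")) {
    stop("cannot classify an unbound structure")
  }
  d <- as.matrix(stats::dist(config))
  adj <- d <= params$r_cut & upper.tri(d)
  n_bonds <- sum(adj)
  g <- igraph::graph_from_adjacency_matrix(d <= params$r_cut & d > 0,
                                           mode = "undirected")
  coord <- igraph::degree(g)
  diam <- igraph::diameter(g, unconnected = TRUE)
  is_path <- igraph::is_tree(g) && max(coord) <= 2
  # gyration tensor
  cc <- sweep(config, 2, colMeans(config))
  gt <- crossprod(cc) / n
  ev <- sort(eigen(gt, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  tr <- sum(ev)
  aniso <- if (tr > 0) {
    1.5 * sum(ev^2) / tr^2 - 0.5
  } else 0
  # terminal chains: peel coordination-1 vertices hanging off the body
  term <- 0L
  cg <- coord
  gg <- g
  repeat {
    leaves <- which(cg == 1)
    if (length(leaves) == 0 || igraph::vcount(gg) <= 2) break
    term <- term + length(leaves)
    gg <- igraph::delete_vertices(gg, leaves)
    cg <- igraph::degree(gg)
  }
  # compactness takes precedence: a small compact cluster (e.g. a
  # tetrahedron) has low coordination yet is not an unrolled motif
  label <- if (aniso <= aniso_compact || n_bonds >= 3 * n - 6 - template_slack) {
    "I"
  } else if (max(coord) <= set3_max_coord || is_path) {
    "III"
  } else {
    "II"
  }
  list(label = label, coordination = as.integer(coord), n_bonds = n_bonds,
       anisotropy = aniso, gyration_eigenvalues = ev, diameter = diam,
       is_path = is_path, terminal_chain = term)
}

#' Per-temperature motif-frequency table
#'
#' Entries whose frequency reaches `threshold` percent at some temperature
#' are "main motifs" and contribute to their set's frequency; entries always
#' below the threshold are pooled into `"miscellaneous"` regardless of their
#' shape label.  Frequencies are normalized per temperature, so the rows of
#' the table sum to 100% wherever any structure was recorded.
#'
#' @param catalog A [dedupe()] catalog.
#' @param labels Character vector of set labels (`"I"`, `"II"` -- or its
#'   sub-labels `"IIa"`/`"IIb"` -- and `"III"`), one per catalog entry;
#'   `NULL` labels of main entries are an error.  Defaults to classifying
#'   every representative with [classify_shape()].
#' @param params Parameters used when `labels` is `NULL`.
#' @param threshold Main-motif frequency threshold in percent (default 4).
#' @param temps Optional temperature vector for the table columns.
#' @param set2_terminal_split Optional integer: split necklaces into `"IIa"`
#'   (fewer terminal-chain particles than the split) and `"IIb"` (at least
#'   that many, i.e. more elongated with thinner terminations).  A heuristic
#'   sub-division; `NULL` (default) keeps a single Set II row.
#' @return Object of class `motif_table`: list with `frequencies` (matrix,
#'   rows `I`, `II` (or `IIa`/`IIb`), `III`, `misc`; columns temperatures,
#'   in percent), `labels`, `threshold`, `temps`.
#' @export
motif_frequencies <- function(catalog, labels = NULL, params = salr_params(),
                              threshold = 4, temps = NULL,
                              set2_terminal_split = NULL) {
  stopifnot(inherits(catalog, "minima_catalog"))
  counts <- catalog$counts
  n_entries <- nrow(counts)
  n_temps <- ncol(counts)
  if (is.null(labels) && n_entries > 0) {
    labels <- vapply(catalog$representatives,
                     function(cfg) classify_shape(cfg, params)$label, "")
  }
  totals <- colSums(counts)
  freq <- sweep(counts, 2, pmax(totals, 1), "/") * 100
  main <- if (n_entries > 0) {
    apply(freq, 1, function(z) any(z >= threshold))
  } else logical(0)
  if (!is.null(set2_terminal_split) && n_entries > 0) {
    labels <- vapply(seq_len(n_entries), function(k) {
      if (identical(labels[k], "II")) {
        cl <- classify_shape(catalog$representatives[[k]], params,
                             check_bound = FALSE)
        if (cl$terminal_chain >= set2_terminal_split) "IIb" else "IIa"
      } else labels[k]
    }, "")
  }
  set2_rows <- if (is.null(set2_terminal_split)) "II" else c("IIa", "IIb")
  ok_labels <- c("I", "II", "IIa", "IIb", "III")
  if (any(main & (is.na(labels) | !labels %in% ok_labels))) {
    stop("main motif entries must be labeled I, II or III")
  }
  out <- matrix(0, length(set2_rows) + 3, n_temps,
                dimnames = list(c("I", set2_rows, "III", "misc"), NULL))
  for (k in seq_len(n_entries)) {
    row <- if (main[k]) labels[k] else "misc"
    if (!row %in% rownames(out)) row <- "II"  # IIa/IIb fold back if unsplit
    out[row, ] <- out[row, ] + freq[k, ]
  }
  structure(list(frequencies = out, labels = labels, threshold = threshold,
                 temps = temps, totals = totals, main = main),
            class = "motif_table")
}

#' @export
print.motif_table <- function(x, ...) {
  cat(sprintf("<motif_table> %d entries (%d main, >= %g%% somewhere)\n",
              length(x$labels), sum(x$main), x$threshold))
  m <- round(x$frequencies, 1)
  if (!is.null(x$temps)) colnames(m) <- format(x$temps)
  print(m)
  invisible(x)
}

#' Quench stored PTMC samples into a minima catalog and motif table
#'
#' The inherent-structure pipeline: pools the stored configurations of all
#' runs (optionally subsampled to `max_per_temp` per temperature, evenly
#' across runs), relaxes each to its local minimum, deduplicates minima by
#' the energy rule, classifies each distinct minimum, and tabulates
#' per-temperature motif frequencies.
#'
#' @param runs A `ptmc_runs` object with stored samples.
#' @param params Parameters (defaults to the ones stored in `runs`).
#' @param max_per_temp Cap on quenched configurations per temperature
#'   (default 2000); evenly spaced subsample when more are available.
#' @param tol Relaxation gradient tolerance.
#' @param dedup_tol Energy-identity tolerance (default 1e-6).
#' @param threshold Main-motif percent threshold (default 4).
#' @param ... Passed to [classify_shape()].
#' @return List with `catalog` (a `minima_catalog`), `labels`, and `motifs`
#'   (a `motif_table`).
#' @export
quench_samples <- function(runs, params = runs$params, max_per_temp = 2000,
                           tol = 1e-8, dedup_tol = 1e-6, threshold = 4, ...) {
  stopifnot(inherits(runs, "ptmc_runs"))
  temps <- runs$temps
  n_temps <- length(temps)
  pv <- params_vector(params)
  all_energy <- vector("list", n_temps)
  all_coords <- vector("list", n_temps)
  for (k in seq_len(n_temps)) {
    stack <- do.call(rbind, lapply(runs$runs, function(r) r$samples[[k]]))
    if (nrow(stack) > max_per_temp) {
      idx <- round(seq(1, nrow(stack), length.out = max_per_temp))
      stack <- stack[idx, , drop = FALSE]
    }
    rx <- cpp_relax_many(stack, pv, tol, 1000L)
    all_energy[[k]] <- rx$energy
    all_coords[[k]] <- rx$coords
  }
  # assemble records without materializing one structure_record per sample
  energies <- unlist(all_energy)
  temp_index <- rep(seq_len(n_temps), vapply(all_energy, length, 0L))
  ord <- order(energies)
  ent_e <- numeric(0)
  reps <- list()
  counts <- matrix(0, 0, n_temps)
  row_of <- function(k) {
    m <- all_coords[[temp_index[k]]]
    local_i <- k - c(0, cumsum(vapply(all_energy, length, 0L)))[temp_index[k]]
    matrix(m[local_i, ], ncol = 3, byrow = TRUE)
  }
  for (i in ord) {
    k <- length(ent_e)
    if (k > 0 && abs(energies[i] - ent_e[k]) < dedup_tol) {
      counts[k, temp_index[i]] <- counts[k, temp_index[i]] + 1
    } else {
      ent_e <- c(ent_e, energies[i])
      reps[[k + 1]] <- row_of(i)
      counts <- rbind(counts, 0)
      counts[k + 1, temp_index[i]] <- 1
    }
  }
  catalog <- structure(list(energies = ent_e, representatives = reps,
                            counts = counts, dedup_tol = dedup_tol),
                       class = "minima_catalog")
  labels <- vapply(reps, function(cfg) {
    tryCatch(classify_shape(cfg, params, check_bound = FALSE, ...)$label,
             error = function(e) NA_character_)
  }, "")
  motifs <- motif_frequencies(catalog, labels, params, threshold = threshold,
                              temps = temps)
  list(catalog = catalog, labels = labels, motifs = motifs)
}
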