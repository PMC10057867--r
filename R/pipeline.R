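#' Default pipeline configuration
#'
#' The full study configuration: the 12-species pollen roster plus the four
#' non-pollen aerosol classes, laboratory-scale session lengths, the LOF
#' tuning grid, the oversampling parameters, automatic cluster-count
#' selection, the modal-bin F1 policy and the cross-validation protocol.
#'
#' @param n_frames Frames per session.
#' @param folds,repeats Cross-validation protocol.
#' @return Configuration list for [run_pipeline()].
#' @export
default_pipeline_config <- function(n_frames = 240L, folds = 10L,
                                    repeats = 5L) {
  profiles <- builtin_profiles()
  pollen <- names(profiles)[vapply(profiles, `[[`, "", "aerosol_class") ==
                              "pollen"]
  nonpollen <- setdiff(names(profiles), pollen)
  list(
    species = pollen,
    nonpollen = nonpollen,
    n_frames = n_frames,
    contamination = list(),
    sizing = list(lof_grid = c(5L, 10L, 20L, 35L), lof_p_grid = c(1, 2),
                  lof_threshold = 1.5, n_draws = 30L, min_per_bin = 20L,
                  k = "auto", k_range = 2:8),
    speciation = list(f1_policy = "modal"),
    classification = list(folds = folds, repeats = repeats,
                          exclude = list(carbonaceous = "largest")),
    instrument = list(a = 1, b = 2)
  )
}

#' Run the full discrimination pipeline
#'
#' Executes every stage in order: simulate one session per configured
#' species, LOF-filter the frames, oversample into cumulative
#' distributions, test clustering tendency, select the cluster count by
#' validity-index voting, cluster the pollen size distributions, compute
#' the optical signatures, and train/evaluate one one-vs-one classifier
#' per size cluster. Deterministic: one top-level seed is fanned out to
#' every stage.
#'
#' @param config Configuration list, see [default_pipeline_config()].
#' @param seed Top-level integer seed.
#' @param out_dir Optional output directory; when given, every stage table
#'   is written (CSV/JSON) together with a run manifest.
#' @return List with `sessions`, `cumulative`, `hopkins`, `k`, `k_votes`,
#'   `clusters` (a `cluster_model`), `pca`, `signatures`, `rosters`,
#'   `reports` (per-cluster `classifier_report`s) and `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = 1L,
                         out_dir = NULL) {
  cfg <- instrument_config(calibration = power_law_calibration(
    config$instrument$a %||% 1, config$instrument$b %||% 2))
  contamination <- do.call(contamination_model, config$contamination)
  profiles <- builtin_profiles()
  roster <- c(config$species, config$nonpollen)
  missing <- setdiff(roster, names(profiles))
  if (length(missing)) {
    stop("unknown species in roster: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  sessions <- lapply(roster, function(sp) {
    simulate_session(profiles[[sp]], contamination,
                     n_frames = config$n_frames, cfg = cfg,
                     seed = derive_seed(seed, paste0("session:", sp)))
  })
  names(sessions) <- roster

  sz <- config$sizing
  cum <- build_cumulative_dataset(sessions, n_draws = sz$n_draws,
                                  min_per_bin = sz$min_per_bin,
                                  lof_grid = sz$lof_grid,
                                  lof_p_grid = sz$lof_p_grid,
                                  lof_threshold = sz$lof_threshold,
                                  seed = derive_seed(seed, "cumulative"))

  pollen_rows <- cum$species %in% config$species
  Xp <- cum$size[pollen_rows, , drop = FALSE]
  sp_p <- cum$species[pollen_rows]

  hop <- hopkins_statistic(Xp, seed = derive_seed(seed, "hopkins"))
  if (identical(sz$k, "auto")) {
    kv <- optimal_k_vote(Xp, k_range = sz$k_range,
                         seed = derive_seed(seed, "kvote"))
    k <- kv$k; k_votes <- kv$votes
  } else {
    k <- as.integer(sz$k); k_votes <- NULL
  }
  k <- min(k, length(unique(sp_p)))
  clusters <- hierarchical_cluster(Xp, k, species = sp_p)
  pca <- pca_project(Xp)

  signatures <- signature_table(cum$counts, cfg$bin_edges, cum$species,
                                f1_policy = config$speciation$f1_policy)

  rosters <- assign_nonpollen_rosters(cum, config, clusters, cfg)
  reports <- per_cluster_classify(signatures, clusters$majority, rosters,
                                  folds = config$classification$folds,
                                  repeats = config$classification$repeats,
                                  seed = derive_seed(seed, "classify"))

  manifest <- list(seed = seed, config_hash = config_hash(config),
                   n_sessions = length(sessions),
                   frames_per_session = config$n_frames,
                   frames_kept = vapply(cum$inliers, sum, 0L),
                   k = k, hopkins = hop,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  result <- list(sessions = sessions, cumulative = cum, hopkins = hop,
                 k = k, k_votes = k_votes, clusters = clusters, pca = pca,
                 signatures = signatures, rosters = rosters,
                 reports = reports, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir, cfg)
  result
}

# cluster sizes in diameter order, to place each non-pollen class with the
# pollens of comparable size (configurable exclusions, e.g. no carbonaceous
# among the largest pollens)
assign_nonpollen_rosters <- function(cum, config, clusters, cfg) {
  if (length(config$nonpollen) == 0L) return(list())
  profiles <- builtin_profiles()
  centres <- bin_centres(cfg)
  cl_diam <- vapply(sort(unique(clusters$labels)), function(cl) {
    rows <- cum$size[cum$species %in% config$species, , drop = FALSE][
      clusters$labels == cl, , drop = FALSE]
    exp(mean(colSums(t(rows) * log(centres)) / rowSums(rows)))
  }, 0)
  largest <- sort(unique(clusters$labels))[which.max(cl_diam)]
  rosters <- stats::setNames(
    vector("list", length(cl_diam)), as.character(sort(unique(clusters$labels))))
  for (np in config$nonpollen) {
    d <- profiles[[np]]$median_diameter
    cl <- sort(unique(clusters$labels))[which.min(abs(log(cl_diam) - log(d)))]
    excl <- config$classification$exclude[[np]]
    if (!is.null(excl) &&
        (identical(excl, "largest") && cl == largest || identical(excl, cl))) {
      next
    }
    rosters[[as.character(cl)]] <- c(rosters[[as.character(cl)]], np)
  }
  rosters
}

write_pipeline_outputs <- function(result, out_dir, cfg) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cum <- result$cumulative
  df <- data.frame(species = cum$species, cum$size)
  names(df)[-1] <- paste0("bin", sprintf("%02d", seq_len(ncol(cum$size))))
  utils::write.csv(df, file.path(out_dir, "cumulative_size.csv"),
                   row.names = FALSE)
  utils::write.csv(result$signatures, file.path(out_dir, "signatures.csv"),
                   row.names = FALSE)
  cl <- data.frame(species = result$clusters$species,
                   cluster = result$clusters$labels)
  utils::write.csv(cl, file.path(out_dir, "clusters.csv"), row.names = FALSE)
  for (nm in names(result$reports)) {
    utils::write.csv(as.data.frame.matrix(result$reports[[nm]]$confusion),
                     file.path(out_dir, paste0("confusion_cluster", nm, ".csv")))
  }
  recall <- lapply(result$reports, function(r) as.list(r$recall))
  jsonlite::write_json(list(hopkins = result$hopkins, k = result$k,
                            recall = recall, manifest = result$manifest),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
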