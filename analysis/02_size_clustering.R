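#!/usr/bin/env Rscript
# Stage 2: particle sizing.
#
# Reads the simulated pollen sessions, tunes and applies the LOF outlier
# filter per session, oversamples the surviving frames into 30 cumulative
# size distributions per species (the 360 x 19 dataset), row-normalises,
# measures the clustering tendency (Hopkins), votes on the cluster count
# with ten internal validity indices, and cuts the complete-linkage tree --
# at the voted k and at the laboratory reference k = 3 -- before projecting
# the rows on their two principal axes.

suppressPackageStartupMessages(library(pollenoptics))

seed <- as.integer(Sys.getenv("POLLEN_SEED", "1"))
dir.create("results", showWarnings = FALSE)

cfg <- instrument_config()
profiles <- builtin_profiles()
pollen <- names(profiles)[vapply(profiles, `[[`, "", "aerosol_class") ==
                            "pollen"]

sessions <- lapply(pollen, function(sp) {
  slug <- gsub("[^a-z0-9]+", "_", tolower(sp))
  frames <- read_frames(file.path("results/sessions", paste0(slug, ".csv")))
  structure(list(species = sp, frames = frames,
                 outlier = rep(NA, length(frames)),
                 diameters = NULL, seed = NA), class = "session")
})
names(sessions) <- pollen

message("LOF filtering + cumulative oversampling")
cum <- build_cumulative_dataset(sessions, n_draws = 30L,
                                seed = derive_seed(seed, "cumulative"))
for (sp in pollen) {
  message(sprintf("  %-26s kept %3d/%3d frames (k=%d, p=%d, sil=%.2f)",
                  sp, sum(cum$inliers[[sp]]), length(cum$inliers[[sp]]),
                  cum$lof[[sp]]$n_neighbors, cum$lof[[sp]]$p,
                  cum$lof[[sp]]$silhouette))
}
df <- data.frame(species = cum$species, cum$size, check.names = FALSE)
names(df)[-1] <- paste0("bin", sprintf("%02d", 1:19))
write.csv(df, "results/cumulative_size.csv", row.names = FALSE)

hop <- mean(vapply(1:20, function(i) {
  hopkins_statistic(cum$size, seed = derive_seed(seed, paste0("hop:", i)))
}, 0))
message("Hopkins statistic (mean of 20 draws): ", round(hop, 4),
        "  -- strongly clustered")

kv <- optimal_k_vote(cum$size, k_range = 2:8,
                     seed = derive_seed(seed, "kvote"))
message("validity-index vote: k = ", kv$k, " (votes: ",
        paste(names(kv$votes), as.integer(kv$votes), sep = ":",
              collapse = " "), ")")
message("  note: the near-noise-free synthetic rows resolve individual ",
        "species; the laboratory reference is k = 3")

centres <- bin_centres(cfg)
for (k in unique(c(kv$k, 3L))) {
  cm <- hierarchical_cluster(cum$size, k, species = cum$species)
  write.csv(data.frame(species = cm$species, cluster = cm$labels),
            sprintf("results/clusters_k%d.csv", k), row.names = FALSE)
  message("k = ", k, " majority clusters:")
  for (cl in sort(unique(cm$majority))) {
    members <- names(cm$majority)[cm$majority == cl]
    d <- vapply(profiles[members], `[[`, 0, "median_diameter")
    message("  cluster ", cl, " (", round(min(d)), "-", round(max(d)),
            " um): ", paste(members, collapse = ", "))
  }
}

pca <- pca_project(cum$size, 2)
write.csv(data.frame(species = cum$species, pca$scores),
          "results/pca_scores.csv", row.names = FALSE)
jsonlite::write_json(
  list(hopkins = hop, k_vote = kv$k,
       votes = as.list(setNames(as.integer(kv$votes), names(kv$votes))),
       explained_variance = pca$explained_variance),
  "results/sizing_report.json", auto_unbox = TRUE, digits = NA)
message("explained variance (PC1, PC2): ",
        paste(round(pca$explained_variance, 3), collapse = ", "))
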