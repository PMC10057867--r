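#!/usr/bin/env Rscript
# Stage 4: per-size-cluster classification.
#
# Groups the optical signatures by the k = 3 size clusters (the laboratory
# reference cut), adds the non-pollen classes to the cluster of comparable
# size (carbonaceous particles are excluded from the largest-size cluster:
# they rarely occur at those sizes in ambient air), and evaluates one
# one-vs-one logistic model per cluster with F1-tuned decision thresholds
# under repeated stratified 10-fold cross-validation.

suppressPackageStartupMessages(library(pollenoptics))

seed <- as.integer(Sys.getenv("POLLEN_SEED", "1"))
dir.create("results", showWarnings = FALSE)

cfg <- instrument_config()
profiles <- builtin_profiles()
pollen <- names(profiles)[vapply(profiles, `[[`, "", "aerosol_class") ==
                            "pollen"]
nonpollen <- setdiff(names(profiles), pollen)

sig <- read.csv("results/signatures.csv")
clusters <- read.csv("results/clusters_k3.csv")
cluster_map <- vapply(split(clusters$cluster, clusters$species), function(l) {
  as.integer(names(which.max(table(l))))
}, 0L)
cluster_map <- cluster_map[pollen]

# order clusters by mean diameter; attach each non-pollen class to the
# cluster of nearest size
cl_diam <- vapply(sort(unique(cluster_map)), function(cl) {
  mean(vapply(profiles[names(cluster_map)[cluster_map == cl]],
              `[[`, 0, "median_diameter"))
}, 0)
largest <- sort(unique(cluster_map))[which.max(cl_diam)]
rosters <- list()
for (np in nonpollen) {
  d <- profiles[[np]]$median_diameter
  cl <- sort(unique(cluster_map))[which.min(abs(log(cl_diam) - log(d)))]
  if (np == "carbonaceous" && cl == largest) next
  rosters[[as.character(cl)]] <- c(rosters[[as.character(cl)]], np)
}

message("cluster rosters (pollen + attached non-pollen classes):")
for (cl in sort(unique(cluster_map))) {
  message("  cluster ", cl, ": ",
          paste(c(names(cluster_map)[cluster_map == cl],
                  rosters[[as.character(cl)]]), collapse = ", "))
}

reports <- per_cluster_classify(sig, cluster_map, rosters,
                                folds = 10L, repeats = 5L,
                                seed = derive_seed(seed, "classify"))

recall_out <- list()
for (nm in names(reports)) {
  r <- reports[[nm]]
  message("cluster ", nm, " recall (", r$protocol$repeats, "x",
          r$protocol$folds, "-fold CV):")
  for (sp in names(r$recall)) {
    message(sprintf("  %-26s %5.1f%%", sp, 100 * r$recall[[sp]]))
  }
  write.csv(as.data.frame.matrix(r$confusion),
            sprintf("results/confusion_cluster%s.csv", nm))
  recall_out[[nm]] <- as.list(r$recall)
}
jsonlite::write_json(list(seed = seed, recall = recall_out),
                     "results/classification_report.json",
                     auto_unbox = TRUE, digits = NA)
message("confusion matrices and recall report written under results/")
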