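#!/usr/bin/env Rscript
# Stage 5 - density-swept graph metrics and inter-subject NMI.
#
# Per subject x band: proportional thresholding from 50% down to 10%
# connection density in 2.5% steps (17 weighted graphs), weighted
# clustering, characteristic path length, global efficiency, Louvain
# modularity / participation-coefficient SD / modular span of the largest
# module averaged over 50 repetitions, all averaged across densities.
# Then the matched-repetition NMI matrix between every pair of subjects
# per band. Reads the dwPLI matrices from stage 4.

library(modspan)

seed <- as.integer(Sys.getenv("MODSPAN_SEED", "101"))
conn_dir <- file.path("results", "connectivity")
out_dir <- file.path("results", "graph")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

subjects <- validate_subject_table(file.path("results", "cohort",
                                             "subjects.csv"))
mont <- load_montage(file.path("results", "cohort", "montage.txt"))
bands <- analysis_bands()$name

rows <- list()
partitions <- setNames(lapply(bands, function(b) list()), bands)
sub_seeds <- derive_seeds(seed, nrow(subjects))
for (i in seq_len(nrow(subjects))) {
  sid <- subjects$subject_id[i]
  band_seeds <- derive_seeds(sub_seeds[i], length(bands))
  for (bi in seq_along(bands)) {
    b <- bands[bi]
    m <- as.matrix(read.csv(file.path(conn_dir, sprintf("%s_%s.csv", sid, b)),
                            row.names = 1, check.names = FALSE))
    res <- metrics_for_subject(m, mont, n_reps = 50, seed = band_seeds[bi])
    rows[[paste(sid, b)]] <- cbind(data.frame(subject_id = sid, band = b),
                                   res$summary)
    partitions[[b]][[sid]] <- res$partitions
  }
  cat(sid, "done\n")
}
gm <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
write.csv(gm, file.path(out_dir, "graph_metrics.csv"), row.names = FALSE)

for (b in bands) {
  M <- nmi_matrix(partitions[[b]])
  write.csv(M, file.path(out_dir, sprintf("nmi_%s.csv", b)))
}
cat("Wrote graph metrics and NMI matrices to", out_dir, "\n")
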