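#!/usr/bin/env Rscript
# Stage 6 - group statistics and the clinical report.
#
# Assembles the per-subject tables from stages 3-5 and runs the full
# battery: Welch unequal-variance t-tests on band power, mean dwPLI, graph
# metrics (Bonferroni-Holm corrected across the three analysed bands within
# each metric) and within-group NMI; robust regressions of alpha network
# metrics on CRS-R (all patients and MCS-only); imagery subgroup contrasts.
# Writes CSV stat tables and a Markdown report.

library(modspan)

out_dir <- file.path("results", "stats")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

subjects <- validate_subject_table(file.path("results", "cohort",
                                             "subjects.csv"))
gm <- read.csv(file.path("results", "graph", "graph_metrics.csv"))
mean_dwpli <- read.csv(file.path("results", "connectivity", "mean_dwpli.csv"))
gm <- merge(mean_dwpli, gm, by = c("subject_id", "band"))
nmi_mats <- lapply(analysis_bands()$name, function(b)
  as.matrix(read.csv(file.path("results", "graph", sprintf("nmi_%s.csv", b)),
                     row.names = 1, check.names = FALSE)))
names(nmi_mats) <- analysis_bands()$name
retained <- read.csv(file.path("results", "preprocessed",
                               "rejection_summary.csv"))

results <- structure(list(
  subjects = subjects,
  band_power = read.csv(file.path("results", "spectral", "band_power.csv")),
  band_variability = read.csv(file.path("results", "spectral",
                                        "band_variability.csv")),
  graph_metrics = gm,
  nmi = nmi_mats,
  retained_epochs = setNames(retained$retained_epochs, retained$subject_id),
  montage = load_montage(file.path("results", "cohort", "montage.txt")),
  seed = as.integer(Sys.getenv("MODSPAN_SEED", "101"))
), class = "cohort_results")

report <- cohort_report(results)
for (nm in c("contribution_tests", "band_variability_tests", "dwpli_tests",
             "graph_tests", "nmi_tests", "regressions", "imagery_tests",
             "patient_table")) {
  if (!is.null(report[[nm]]))
    write.csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")),
              row.names = FALSE)
}
write_report_markdown(report, file.path(out_dir, "report.md"))

cat("Graph-metric group tests (t > 0: controls > patients):\n")
print(report$graph_tests, digits = 3)
cat("\nRegressions of alpha metrics on CRS-R (all patients):\n")
print(report$regressions[report$regressions$subset == "all_patients", ],
      digits = 3)
cat("\nFull report:", file.path(out_dir, "report.md"), "\n")
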