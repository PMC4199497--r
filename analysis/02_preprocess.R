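#!/usr/bin/env Rscript
# Stage 2 - preprocess every recording.
#
# For each subject: 0.5-45 Hz zero-phase band-pass, segmentation into
# 60 x 10 s baseline-corrected epochs, variance-based channel/epoch
# rejection with inverse-distance channel fill, and average re-referencing.
# Writes the cleaned epoched recordings plus a rejection summary CSV.

library(modspan)

in_dir <- file.path("results", "cohort")
out_dir <- file.path("results", "preprocessed")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

subjects <- validate_subject_table(file.path(in_dir, "subjects.csv"))
mont <- load_montage(file.path(in_dir, "montage.txt"))

rows <- list()
for (sid in subjects$subject_id) {
  raw <- read_recording(file.path(in_dir, paste0(sid, ".rec.rds")))
  pp <- preprocess_recording(raw, mont)
  write_recording(pp$recording, file.path(out_dir, paste0(sid, ".rec.rds")))
  rows[[sid]] <- data.frame(
    subject_id = sid,
    retained_epochs = dim(pp$recording$data)[2],
    rejected_channels = length(pp$report$rejected_channels),
    rejected_epochs = length(pp$report$rejected_epochs))
  cat(sprintf("%s: %d epochs retained, %d channels filled\n", sid,
              dim(pp$recording$data)[2],
              length(pp$report$rejected_channels)))
}
summary_tab <- do.call(rbind, rows)
write.csv(summary_tab, file.path(out_dir, "rejection_summary.csv"),
          row.names = FALSE)
cat(sprintf("Mean retained epochs: %.1f of 60\n",
            mean(summary_tab$retained_epochs)))
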