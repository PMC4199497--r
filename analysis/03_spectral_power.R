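#!/usr/bin/env Rscript
# Stage 3 - Welch band power.
#
# Per subject: Welch spectra at 0.25 Hz resolution, percentage power
# contributions of the five canonical bands (delta, theta, alpha, beta,
# gamma; rows sum to 100%), and the temporal variability of those
# contributions across epochs. Writes long-format CSV tables.

library(modspan)

in_dir <- file.path("results", "preprocessed")
out_dir <- file.path("results", "spectral")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

subjects <- validate_subject_table(file.path("results", "cohort",
                                             "subjects.csv"))
bands <- canonical_bands()
bp <- list(); bv <- list()
for (sid in subjects$subject_id) {
  rec <- read_recording(file.path(in_dir, paste0(sid, ".rec.rds")))
  contrib <- colMeans(band_contributions(welch_spectrum(rec))$contributions)
  bp[[sid]] <- data.frame(subject_id = sid, band = bands$name,
                          contribution = unname(contrib))
  v <- band_variability(rec)
  bv[[sid]] <- data.frame(subject_id = sid, band = bands$name,
                          variability = unname(v))
  cat(sprintf("%s: delta %.1f%%  alpha %.1f%%\n", sid,
              contrib["delta"], contrib["alpha"]))
}
write.csv(do.call(rbind, bp), file.path(out_dir, "band_power.csv"),
          row.names = FALSE)
write.csv(do.call(rbind, bv), file.path(out_dir, "band_variability.csv"),
          row.names = FALSE)
cat("Wrote band power and variability tables to", out_dir, "\n")
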