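#!/usr/bin/env Rscript
# Step 4 — CASA kinematics per sample and motility-based freezability.
#
# For every donor x extender sample, 1000 two-dimensional tracks are
# simulated (fresh samples mostly progressive; frozen samples with a
# reduced motile fraction and slower swimmers), classified with the
# standard thresholds (immotile: VAP < 10 um/s; progressive: VAP > 30
# um/s and STR > 80%), and summarised into TM, PM, VCL, VSL and VAP.
# Post-thaw motility is then related to the fresh value per donor.

suppressPackageStartupMessages(library(spermHT))

out_dir <- "results"
design <- study_design(seed = 20240901)
frozen <- setdiff(design$extenders, design$fresh_label)

# Sample-level motile fractions: fresh high, frozen reduced according to
# how harsh the extender's volume effect is, good coolers less affected.
mid_mean <- vapply(design$extender_effects,
                   function(e) e$mean[["midpiece"]], 0)
rows <- list()
seed_k <- 0
for (d in seq_len(design$n_donors)) {
  for (ext in design$extenders) {
    seed_k <- seed_k + 1
    if (ext == design$fresh_label) {
      mix <- c(immotile = 0.10, motile = 0.20, progressive = 0.70)
    } else {
      drop <- design$susceptibility[d] * (1 - mid_mean[[ext]])
      immotile <- min(0.9, 0.10 + 1.5 * drop)
      prog <- max(0.05, 0.70 - 2 * drop)
      mix <- c(immotile = immotile, progressive = prog,
               motile = 1 - immotile - prog)[c("immotile", "motile",
                                               "progressive")]
    }
    tracks <- simulate_tracks(n = 1000, mixture = mix,
                              seed = 5000 + seed_k)
    s <- summarize_tracks(tracks)
    rows[[seed_k]] <- tibble::tibble(donor = d, extender = ext,
                                     TM = s$TM, PM = s$PM, VCL = s$VCL,
                                     VSL = s$VSL, VAP = s$VAP,
                                     n_tracks = s$n_tracks)
  }
}
kin <- dplyr::bind_rows(rows)
readr::write_csv(kin, file.path(out_dir, "kinematics.csv"))

fresh <- kin[kin$extender == design$fresh_label,
             c("donor", "TM", "PM")]
names(fresh)[2:3] <- c("TM_fresh", "PM_fresh")
fi_mot <- merge(kin[kin$extender != design$fresh_label, ], fresh,
                by = "donor")
fi_mot$fi_tm <- motility_freezability(fi_mot$TM, fi_mot$TM_fresh)
fi_mot$fi_pm <- motility_freezability(fi_mot$PM, fi_mot$PM_fresh)
fi_mot <- fi_mot[order(fi_mot$donor, fi_mot$extender),
                 c("donor", "extender", "TM", "PM", "fi_tm", "fi_pm")]
readr::write_csv(fi_mot, file.path(out_dir, "motility_freezability.csv"))

cat("post-thaw TM freezability (mean over donors) by extender:\n")
print(aggregate(fi_tm ~ extender, fi_mot, mean))
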