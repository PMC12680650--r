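#!/usr/bin/env Rscript
# Step 1 — simulate the synthetic cryotolerance cohort.
#
# Eleven donors, a fresh INRA96 reference arm plus four freezing
# extenders, forty cells per donor x extender sample. Each cell is a 3D
# refractive-index phantom (nucleus / midpiece / tail over medium);
# freezing shrinks compartment volumes by per-extender random factors,
# attenuated for the two "good cooler" donors. The full study is defined
# here and re-derived reproducibly from its seed in later steps; a small
# demo subset is written as TIFF + sidecar to show the on-disk format.

suppressPackageStartupMessages(library(spermHT))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

design <- study_design(seed = 20240901)
study <- simulate_study(design)

readr::write_csv(study$truth, file.path(out_dir, "ground_truth.csv"))

# Demo subset on disk: donor 1, one fresh and one frozen cell.
demo_dir <- file.path(out_dir, "demo_tomograms")
dir.create(demo_dir, showWarnings = FALSE)
idx <- which(study$cells$donor == 1 & study$cells$cell_id == 1 &
               study$cells$extender %in% c("INRA96", "HF20"))
for (i in idx) {
  tom <- render_study_cell(study, i)
  f <- sprintf("donor%02d_%s_cell%03d.tif", tom$metadata$donor,
               tom$metadata$extender, tom$metadata$cell_id)
  write_tomogram(tom, file.path(demo_dir, f))
}

cat(sprintf("simulated %d cells (%d donors x %d extenders x %d cells)\n",
            nrow(study$cells), design$n_donors, length(design$extenders),
            design$cells_per_sample))
cat("ground truth ->", file.path(out_dir, "ground_truth.csv"), "\n")
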