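#!/usr/bin/env Rscript
# Step 3 — holotomographic freezability index and cooler classification.
#
# For every donor x freezing extender x region, the sample-mean volume
# is related to the donor's fresh INRA96 sample mean:
# FI_HT = V_frozen / V_fresh x 100. Donors are then called good /
# intermediate / poor coolers from their pooled per-region indices
# (good: all regions >= 90%; poor: any region < 80%).

suppressPackageStartupMessages(library(spermHT))

out_dir <- "results"
morph <- readr::read_csv(file.path(out_dir, "morphometry_volumes.csv"),
                         show_col_types = FALSE)

records <- aggregate_freezability(morph, fresh_label = "INRA96")
readr::write_csv(records, file.path(out_dir, "freezability.csv"))

calls <- classify_cooler(records)
readr::write_csv(calls, file.path(out_dir, "cooler_calls.csv"))

cat("per-extender midpiece FI_HT (mean over donors):\n")
mid <- records[records$region == "midpiece", ]
print(aggregate(fi_ht ~ extender, mid, mean))
cat("\ncooler calls:\n")
print(as.data.frame(calls[, c("donor", "fi_midpiece", "call")]))
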