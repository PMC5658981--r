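#!/usr/bin/env Rscript
# Step 3 -- value for money on the cost-value plane.
#
# Divides each treatment's rounded total cost (drug + administration) by
# its overall weighted preference value, classifies pairwise dominance,
# and exports the cost-value plane coordinates.  Writes
# results/efficiency.csv.

suppressPackageStartupMessages(library(mavtkit))

cs <- mcrc_case_study()
res <- run_pipeline(cs$model, cs$performance, cs$costs, out_dir = NULL,
                    verbose = FALSE)

eff <- res$efficiency
dir.create("results", showWarnings = FALSE)
utils::write.csv(eff, file.path("results", "efficiency.csv"),
                 row.names = FALSE)

cat("Cost per MCDA value unit (GBP per value point):\n")
print(eff, row.names = FALSE)

for (p in list(c("cetuximab", "panitumumab"),
               c("panitumumab", "aflibercept_folfiri"))) {
  v <- icvr(cs$costs[[p[1]]], cs$costs[[p[2]]],
            res$evaluation$values[[p[1]]], res$evaluation$values[[p[2]]],
            p[1], p[2])
  cat(v$message, "\n")
}

cat("\nFinding: cetuximab sits alone on the efficiency frontier (~GBP 394\n")
cat("per value point); panitumumab (~638) and aflibercept + FOLFIRI\n")
cat("(~2056) are dominated.  Note this ordering reverses the external\n")
cat("cost-per-QALY ordering recorded with the fixture, driven by the\n")
cat("negative Grade 4 AE score of aflibercept + FOLFIRI.\n")
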