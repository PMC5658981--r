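#!/usr/bin/env Rscript
# Step 1 -- evaluate the mCRC appraisal model.
#
# Loads the packaged post-workshop model (9 attributes in 4 value
# clusters), the performance table for the three second-line biological
# treatments, and the cost profiles; scores every option on the
# reference-anchored value functions; aggregates with the baseline
# weights.  Writes the published-table-style report bundle under
# results/case_study/.

suppressPackageStartupMessages(library(mavtkit))

cs <- mcrc_case_study()
res <- run_pipeline(cs$model, cs$performance, cs$costs,
                    out_dir = file.path("results", "case_study"),
                    verbose = TRUE)

cat("\nOverall weighted preference values (0-100):\n")
print(res$evaluation)

cat("\nCluster weights (x100):\n")
print(round(100 * res$cluster_weights, 1))

cat("\nContribution decomposition, aflibercept + FOLFIRI:\n")
print(decompose(res$evaluation, "aflibercept_folfiri"), row.names = FALSE)

cat("\nFinding: cetuximab ranks first (45.7), panitumumab second (42.3);\n")
cat("aflibercept + FOLFIRI falls to 14.3 because its 21% Grade 4 AE rate\n")
cat("lies beyond the 10% lower reference, scoring -117.9 and contributing\n")
cat("-27.5 weighted points.  Full verification against the published\n")
cat("outputs:\n\n")
v <- verify_case_study(cs)
cat("verification:", if (attr(v, "passed")) "all checks pass"
    else "CHECKS FAILED", "\n")
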