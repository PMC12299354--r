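#!/usr/bin/env Rscript
# Step 2: load the simulated cohorts, harmonise device frames with the global
# gravity rotation, and build the three movement-data representations:
# SEMANTIC (PC1 projection + 25 biomechanical features), PCA_AUTO (automatic
# catalogue on the PC1 trace) and AUTO3D (automatic catalogue per raw axis).
# Feature tables are written under scratch/features/.

suppressPackageStartupMessages(library(dyskrep))

dir.create("scratch/features", showWarnings = FALSE, recursive = TRUE)

for (cohort in c("source", "shifted")) {
  manifest <- read_manifest(file.path("scratch", paste0("cohort_", cohort),
                                      "manifest.tsv"))
  sessions <- prepare_sessions(read_cohort(manifest))
  manifest <- manifest[manifest$session_id %in% names(sessions), ]
  report <- validate_cohort(manifest, sessions)
  cat(cohort, "cohort:", sum(report$per_session$pass), "of",
      nrow(report$per_session), "sessions retained\n")
  for (rep in c("SEMANTIC", "PCA_AUTO", "AUTO3D")) {
    X <- cohort_features(sessions[manifest$session_id], rep)
    out <- file.path("scratch/features",
                     sprintf("%s_%s.tsv", cohort, tolower(rep)))
    write_feature_matrix(X, manifest, out)
    cat("  ", rep, ": ", nrow(X), " x ", ncol(X), " -> ", out, "\n", sep = "")
  }
}
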