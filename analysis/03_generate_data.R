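#!/usr/bin/env Rscript
# Generates the synthetic lipidomics-style datasets used by the calibration
# analyses (two genotypes x two time points x four replicates, Gaussian
# noise per species) and writes them as PEtab-style problem directories.

suppressPackageStartupMessages(library(sphingorheostat))
dir.create("results", showWarnings = FALSE)

for (variant in c("feedback", "no_feedback")) {
  truth <- paper_like_truth(variant)
  m <- generate_measurements(truth, synthetic_design(), seed = 1)
  cat(sprintf("%s truth: %d measurements, ceramide cell means (pmol/mg):\n",
              variant, nrow(m)))
  cer <- aggregate(value ~ condition_id + time_dpf,
                   m[m$observable_id == "ceramide", ], mean)
  print(cer)
  for (fit_variant in c("no_feedback", "feedback")) {
    problem <- make_problem(m, fit_variant)
    d <- file.path("results", sprintf("petab_%s_truth_fit_%s", variant,
                                      fit_variant))
    write_problem(problem, d)
    cat("wrote", d, "\n")
  }
}
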