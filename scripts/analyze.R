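#!/usr/bin/env Rscript
# Full statistical treatment of a trial-table CSV: accuracies, equivalence
# margin and rank-based CI/TOST, Woolf homogeneity, Mantel-Haenszel pooled
# OR, per-participant A'/B''d with paired comparisons, and the split-half
# bias check. Prints a human-readable report and optionally writes JSON.
#
# Usage: Rscript scripts/analyze.R --trials trials.csv [--json report.json]
#        [--alpha 0.05] [--delta-fraction 0.2] [--confidence 0.90]

suppressPackageStartupMessages({
  library(optparse)
  library(stylemark)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--trials", type = "character"),
  make_option("--json", type = "character", default = NULL),
  make_option("--alpha", type = "double", default = 0.05),
  make_option("--delta-fraction", dest = "delta_fraction", type = "double",
              default = 0.2),
  make_option("--confidence", type = "double", default = 0.90)
)))

if (is.null(opts$trials)) stop("--trials <csv> is required")

report <- analyze_trials(opts$trials, delta_fraction = opts$delta_fraction,
                         confidence = opts$confidence, alpha = opts$alpha)
print(report)
if (!is.null(opts$json)) {
  write_report_json(report, opts$json)
  cat("report written to", opts$json, "\n")
}
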