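#!/usr/bin/env Rscript

# Step 3 — estimate per-division mini-chromosome loss rates:
#   * closed-form inversion of the retention model from the study's printed
#     clone medians (2.96% wild type, 86.1% DDX11-deficient; n = 21)
#   * median-based estimates with bootstrap CIs from the simulated clone
#     assays of step 1
#   * log-linear fit of the simulated 25-day bulk time course
#
# Writes results/loss_rates.tsv.

suppressPackageStartupMessages(library(minichrom))
rows <- list()
add <- function(label, r, lo = NA, hi = NA, n = NA) {
  rows[[label]] <<- data.frame(assay = label, rate_pct_per_division = 100 * r,
                               ci_lower = 100 * lo, ci_upper = 100 * hi, n = n)
  message(sprintf("%-28s %.3f %%/division", label, 100 * r))
}

# Closed form from the published medians
n21 <- num_divisions(7, 3)
r_wt <- invert_retention(1, 1 - 0.0296, n21)
r_ko <- invert_retention(1, 1 - 0.861, n21)
add("printed_median_wt", r_wt, n = n21)
add("printed_median_ddx11ko", r_ko, n = n21)
message(sprintf("fold increase on DDX11 loss: %.1fx", r_ko / r_wt))

# Simulated clone assays (clones with 100% GFP-negative cells excluded)
for (arm in c("wt", "ddx11ko")) {
  ca <- read_clone_assay_tsv(sprintf("results/clones_%s.tsv", arm))
  est <- estimate_from_clone_assay(ca, seed = 7)
  add(paste0("clone_assay_", arm), est$r_per_division, est$ci_lower,
      est$ci_upper, est$n_units)
}

# Bulk time course
tc <- read_timecourse_tsv("results/timecourse_mini.tsv")
est <- fit_timecourse(tc, seed = 7)
add("timecourse_mini", est$r_per_division, est$ci_lower, est$ci_upper,
    est$n_units)

write.table(do.call(rbind, rows), "results/loss_rates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
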