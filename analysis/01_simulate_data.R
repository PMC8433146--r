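#!/usr/bin/env Rscript

# Step 1 — generate the synthetic datasets for the whole analysis:
#   * binned whole-genome coverage (10-kb bins, Poisson, 10 reads/bin/copy)
#     for the trisomy control (CL18) and the four chromosome-2-edited strains
#   * a 25-day GFP flow time course for the mini-chromosome clone
#   * 7-day limiting-dilution clone assays for the wild-type and
#     DDX11-deficient backgrounds, at the loss rates the study inferred
#
# Outputs TSVs under results/.

suppressPackageStartupMessages(library(minichrom))
dir.create("results", showWarnings = FALSE)
seed <- 20260920

gen <- build_dt40_genome()
cfg <- coverage_sim_config()  # 10 reads/bin/copy, centromere masked

for (strain in strain_names()) {
  trk <- simulate_binned_coverage(make_strain_karyotype(strain, gen), gen,
                                  cfg, seed = seed + match(strain, strain_names()))
  path <- sprintf("results/coverage_%s.tsv", gsub("[^A-Za-z0-9_]", "_", strain))
  write_counts_tsv(trk, path)
  message(sprintf("%-14s mean chr2 count %.1f -> %s", strain,
                  mean(trk$counts$chr2[!trk$mask$chr2]), path))
}

# Bulk time course: r_eff = 0.002/division (p_lag_loss = 0.004), 3 divisions
# per day, sampled every 5 days, 1e5 founding cells after preselection.
tc <- simulate_flow_timecourse(segregation_params(p_lag_loss = 0.004),
                               days = 25, sample_days = seq(0, 25, by = 5),
                               initial_cells = 1e5, max_cells = 1e6,
                               seed = seed + 10)
write_timecourse_tsv(tc, "results/timecourse_mini.tsv")
message(sprintf("time course: GFP-negative %.1f%% at day 25",
                100 * tc$fraction_gfp_negative[tc$day == 25]))

# Clone assays: 1500 clones each, 7 days, at the per-division rates inverted
# from the study's medians (0.143% wild type, 8.97% DDX11-deficient).
for (arm in list(list(name = "wt", r = 0.00143, k = 20),
                 list(name = "ddx11ko", r = 0.0897, k = 21))) {
  ca <- simulate_clone_assay(segregation_params(p_lag_loss = 2 * arm$r),
                             n_clones = 1500, duration_days = 7,
                             seed = seed + arm$k)
  write_clone_assay_tsv(ca, sprintf("results/clones_%s.tsv", arm$name))
  message(sprintf("clone assay %s: median GFP-negative %.2f%%", arm$name,
                  100 * median(ca$gfp_negative_fraction)))
}
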