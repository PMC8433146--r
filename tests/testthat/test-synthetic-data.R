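test_that("coverage simulation hits the per-copy depth expectation", {
  gen <- two_chrom_genome()
  cfg <- coverage_sim_config()
  trk <- simulate_binned_coverage(make_strain_karyotype("CL18", gen), gen,
                                  cfg, seed = 31)
  counts <- trk$counts$chr2[!trk$mask$chr2]
  expect_gt(length(counts), 1000)
  expect_lt(abs(mean(counts) - 3 * cfg$depth_per_copy) / (3 * cfg$depth_per_copy),
            0.02)
})

test_that("expected coverage matches an independent per-bin calculator", {
  gen <- two_chrom_genome()
  cfg <- coverage_sim_config()
  kar <- make_strain_karyotype("Chr2_1_1_mini", gen)
  mus <- expected_bin_coverage(kar, gen, cfg)
  # independent oracle: copy number at the bin midpoint x depth, for bins not
  # straddling a truncation point or the mask edge
  nb <- length(mus$chr2)
  mids <- (seq_len(nb) - 0.5) * cfg$bin_size
  oracle <- copy_number_at(kar, "chr2", pmin(mids, gen$length[gen$name == "chr2"] - 1)) *
    cfg$depth_per_copy
  interior <- !attr(mus, "mask")$chr2 &
    !(mids > 51.9e6 & mids < 52.8e6)  # exclude edge bins
  expect_equal(mus$chr2[interior], oracle[interior])
  # truncation-point bins get fractional expectation
  bin_52 <- floor(52.0e6 / cfg$bin_size) + 1
  expect_equal(mus$chr2[bin_52], 3 * cfg$depth_per_copy)  # [52.0,52.01) fully in mini
})

test_that("zero-copy regions yield zero counts and empty read lists", {
  gen <- two_chrom_genome()
  cfg <- coverage_sim_config()
  kar <- holey_karyotype(gen)
  trk <- simulate_binned_coverage(kar, gen, cfg, seed = 17)
  hole_bins <- seq(10e6 / cfg$bin_size + 1, 12e6 / cfg$bin_size)
  expect_true(all(trk$counts$chr2[hole_bins] == 0))
  pos <- simulate_read_positions(kar, gen, "chr2", c(10e6, 12e6), cfg, seed = 17)
  expect_length(pos, 0)
})

test_that("simulators are reproducible under a fixed seed", {
  gen <- two_chrom_genome()
  cfg <- coverage_sim_config()
  kar <- make_strain_karyotype("CL18", gen)
  t1 <- simulate_binned_coverage(kar, gen, cfg, seed = 5)
  t2 <- simulate_binned_coverage(kar, gen, cfg, seed = 5)
  t3 <- simulate_binned_coverage(kar, gen, cfg, seed = 6)
  expect_identical(t1$counts, t2$counts)
  expect_false(identical(t1$counts, t3$counts))

  p1 <- simulate_read_positions(kar, gen, "chr2", c(0, 1e6), cfg, seed = 9)
  p2 <- simulate_read_positions(kar, gen, "chr2", c(0, 1e6), cfg, seed = 9)
  expect_identical(p1, p2)

  prm <- segregation_params(p_lag_loss = 0.01)
  a1 <- simulate_clone_assay(prm, 10, seed = 2)
  a2 <- simulate_clone_assay(prm, 10, seed = 2)
  expect_identical(a1$gfp_negative_fraction, a2$gfp_negative_fraction)
})

test_that("read positions bin to the same expectations as direct bin simulation", {
  gen <- two_chrom_genome()
  cfg <- coverage_sim_config()
  kar <- make_strain_karyotype("Chr2_1_1_q", gen)
  region <- c(50e6, 54e6)
  pos <- simulate_read_positions(kar, gen, "chr2", region, cfg, seed = 88)
  expect_true(all(pos >= region[1] & pos < region[2]))
  trk <- bin_reads(list(chr1 = numeric(0), chr2 = pos), gen, cfg$bin_size)
  mus <- expected_bin_coverage(kar, gen, cfg)
  bins <- seq(region[1] / cfg$bin_size + 1, region[2] / cfg$bin_size)
  obs <- trk$counts$chr2[bins]
  mu <- mus$chr2[bins]
  # aggregate Poisson check: total within 4 SD, masked bins empty
  expect_lt(abs(sum(obs) - sum(mu)), 4 * sqrt(sum(mu)))
  expect_true(all(obs[attr(mus, "mask")$chr2[bins]] == 0))
})

test_that("coverage ratios converge to aggregate copy over control ploidy", {
  gen <- two_chrom_genome()
  cfg <- coverage_sim_config()
  for (strain in c("CL18", "Chr2-2")) {
    trk <- simulate_binned_coverage(make_strain_karyotype(strain, gen), gen,
                                    cfg, seed = 300 + nchar(strain))
    rt <- normalize_to_reference_chrom(trk)
    r2 <- mean(rt$ratios$chr2[!rt$mask$chr2])
    expected <- if (strain == "CL18") 1.5 else 1.0
    expect_equal(r2, expected, tolerance = 0.01)
  }
})

test_that("flow time course obeys null and closed-form expectations", {
  p0 <- segregation_params()
  tc0 <- simulate_flow_timecourse(p0, days = 6, sample_days = c(0, 3, 6),
                                  initial_cells = 2000, seed = 3)
  expect_equal(tc0$fraction_gfp_negative, rep(0, 3))

  p <- segregation_params(p_lag_loss = 0.004)  # r_eff = 0.002
  tc <- simulate_flow_timecourse(p, days = 25, sample_days = c(0, 25),
                                 initial_cells = 1e5, max_cells = 5e5, seed = 21)
  expected <- 1 - 0.998^75
  obs <- tc$fraction_gfp_negative[tc$day == 25]
  # founder-level binomial SE understates branching variance; allow 3x margin
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_lt(abs(obs - expected), 9 * se)
  expect_true(all(tc$n_cells <= 5e5 | tc$day == 0))
})

test_that("nondisjunction produces double-GFP cells in the time course", {
  p <- segregation_params(p_nondisjunction = 0.01)
  tc <- simulate_flow_timecourse(p, days = 10, sample_days = c(0, 5, 10),
                                 initial_cells = 5e4, seed = 12)
  expect_equal(tc$fraction_gfp_double_or_more[1], 0)
  expect_gt(tc$fraction_gfp_double_or_more[3], 0)
})

test_that("clone assay matches the retention model in the mean, with right skew", {
  p0 <- segregation_params()
  ca0 <- simulate_clone_assay(p0, 10, seed = 1)
  expect_equal(ca0$gfp_negative_fraction, rep(0, 10))

  p <- segregation_params(p_lag_loss = 0.02)  # r_eff = 0.01
  ca <- simulate_clone_assay(p, 400, duration_days = 7, seed = 101)
  expected_mean <- 1 - (1 - 0.01)^21
  se <- stats::sd(ca$gfp_negative_fraction) / sqrt(nrow(ca))
  expect_lt(abs(mean(ca$gfp_negative_fraction) - expected_mean), 3 * se)
  # early stochastic losses give a heavy right tail: median below mean
  expect_lt(stats::median(ca$gfp_negative_fraction),
            mean(ca$gfp_negative_fraction))
  expect_gt(min(ca$gfp_negative_fraction), -1e-12)
})
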