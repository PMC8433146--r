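# Shared fixtures: a two-chromosome genome keeps coverage simulations cheap
# while preserving the chr2 geometry (centromere, truncation points) that the
# pipeline's breakpoint logic depends on.

two_chrom_genome <- function() {
  build_dt40_genome(include = c("chr1", "chr2"))
}

# A toy karyotype with a hand-built zero-copy hole on chr2 (both full copies
# dropped over [10, 12) Mb), for exercising zero-expectation paths.
holey_karyotype <- function(genome = two_chrom_genome()) {
  iv <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    dimnames(m) <- list(NULL, c("start", "end"))
    m
  }
  len1 <- genome$length[genome$name == "chr1"]
  len2 <- genome$length[genome$name == "chr2"]
  structure(list(
    strain = "holey",
    copies = list(
      chr1 = list(iv(0, len1), iv(0, len1)),
      chr2 = list(iv(0, 10e6, 12e6, len2), iv(0, 10e6, 12e6, len2))
    )
  ), class = "strain_karyotype")
}

# Score track built from noiseless expected coverage, so pipeline outputs can
# be compared against exact geometry.
noiseless_score_track <- function(strain, genome = two_chrom_genome(),
                                  config = coverage_sim_config()) {
  as_track <- function(kar) {
    mus <- expected_bin_coverage(kar, genome, config)
    counts <- lapply(mus, function(m) as.integer(round(m * 64)))  # scale up, keep integer
    coverage_track(kar$strain, config$bin_size, counts, attr(mus, "mask"))
  }
  smp <- as_track(make_strain_karyotype(strain, genome))
  ctl <- as_track(make_strain_karyotype("CL18", genome))
  normalize_to_control(normalize_to_reference_chrom(smp),
                       normalize_to_reference_chrom(ctl))
}

simulated_score_track <- function(strain, seed, genome = two_chrom_genome(),
                                  config = coverage_sim_config(),
                                  control_seed = seed + 5000) {
  smp <- simulate_binned_coverage(make_strain_karyotype(strain, genome),
                                  genome, config, seed = seed)
  ctl <- simulate_binned_coverage(make_strain_karyotype("CL18", genome),
                                  genome, config, seed = control_seed)
  normalize_to_control(normalize_to_reference_chrom(smp),
                       normalize_to_reference_chrom(ctl))
}
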