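## Synthetic whole-genome binned coverage.
##
## Sequencing a strain is emulated at the level of 10-kb bins: a bin's
## expected read count is depth_per_copy times the copy-weighted fraction of
## the bin retained by the karyotype, attenuated by a mappability weight
## (centromere repeats are unmappable, weight 0, by default). Counts are
## Poisson, or negative binomial when overdispersion is requested.

#' Coverage simulation configuration
#'
#' @param depth_per_copy Expected reads per bin per chromosome copy
#'   (default 10, i.e. ~30 reads/bin on a trisomic chromosome).
#' @param bin_size Bin width in base pairs (default 10 kb).
#' @param mask_centromeres If `TRUE` (default), centromere intervals of the
#'   genome model get mappability weight 0 — read pileups over centromeric
#'   repeats cannot be mapped uniquely, so those bins are dark in real data.
#' @param extra_mask Optional data frame `chrom, start, end, weight` of
#'   additional mappability intervals (weights in \[0, 1\]).
#' @param noise `"poisson"` (default) or `"nbinom"`.
#' @param dispersion Negative-binomial size parameter (only for
#'   `noise = "nbinom"`; smaller = more overdispersed).
#' @return An object of class `coverage_sim_config`.
#' @export
coverage_sim_config <- function(depth_per_copy = 10, bin_size = 10000L,
                                mask_centromeres = TRUE, extra_mask = NULL,
                                noise = c("poisson", "nbinom"),
                                dispersion = 20) {
  noise <- match.arg(noise)
  stopifnot(depth_per_copy > 0, bin_size > 0, dispersion > 0)
  if (!is.null(extra_mask)) {
    stopifnot(all(c("chrom", "start", "end", "weight") %in% names(extra_mask)),
              all(extra_mask$weight >= 0 & extra_mask$weight <= 1))
  }
  structure(list(depth_per_copy = depth_per_copy, bin_size = as.integer(bin_size),
                 mask_centromeres = mask_centromeres, extra_mask = extra_mask,
                 noise = noise, dispersion = dispersion),
            class = "coverage_sim_config")
}

n_bins <- function(len, bin_size) as.integer(ceiling(len / bin_size))

## Overlap (bp) of interval [s, e) with each bin of a chromosome.
bin_overlap_bp <- function(s, e, nb, bin_size) {
  starts <- (seq_len(nb) - 1) * bin_size
  ends <- starts + bin_size
  pmax(0, pmin(e, ends) - pmax(s, starts))
}

## Per-bin mappability weight for a chromosome under a config.
bin_mask_weights <- function(genome, chromosome, config) {
  gi <- genome_chrom(genome, chromosome)
  nb <- n_bins(gi$length, config$bin_size)
  w <- rep(1, nb)
  apply_mask <- function(s, e, weight) {
    frac <- bin_overlap_bp(s, e, nb, config$bin_size) / config$bin_size
    w <<- w * (1 - frac * (1 - weight))
  }
  if (config$mask_centromeres && !is.na(gi$cen_start))
    apply_mask(gi$cen_start, gi$cen_end, 0)
  em <- config$extra_mask
  if (!is.null(em)) {
    em <- em[em$chrom == chromosome, , drop = FALSE]
    for (i in seq_len(nrow(em))) apply_mask(em$start[i], em$end[i], em$weight[i])
  }
  w
}

#' Expected per-bin coverage for a karyotype
#'
#' Deterministic expectation of [simulate_binned_coverage()]: for each bin,
#' `depth_per_copy` x (summed fraction of the bin retained across copies) x
#' mappability weight. Exposed so noiseless tracks can drive the copy-number
#' pipeline exactly.
#'
#' @inheritParams simulate_binned_coverage
#' @return A list per chromosome of numeric expected counts, with a `mask`
#'   attribute (logical per chromosome: weight-zero bins).
#' @export
expected_bin_coverage <- function(karyotype, genome = build_dt40_genome(),
                                  config = coverage_sim_config()) {
  mus <- list(); masks <- list()
  for (chrom in genome$name) {
    gi <- genome_chrom(genome, chrom)
    nb <- n_bins(gi$length, config$bin_size)
    cov_bp <- rep(0, nb)
    for (cp in karyotype$copies[[chrom]]) {
      for (r in seq_len(nrow(cp))) {
        cov_bp <- cov_bp + bin_overlap_bp(cp[r, 1], cp[r, 2], nb, config$bin_size)
      }
    }
    w <- bin_mask_weights(genome, chrom, config)
    mus[[chrom]] <- config$depth_per_copy * (cov_bp / config$bin_size) * w
    masks[[chrom]] <- w == 0
  }
  attr(mus, "mask") <- masks
  mus
}

#' Simulate binned sequencing coverage for a strain
#'
#' Draws per-bin read counts for every chromosome of the genome model under
#' the strain's karyotype. Bins straddling a truncation point get counts
#' proportional to the retained fraction of the bin.
#'
#' @param karyotype A `strain_karyotype`.
#' @param genome A `genome_model`.
#' @param config A [coverage_sim_config()].
#' @param seed Optional RNG seed (same seed, identical track).
#' @return An object of class `coverage_track`: list with `strain`,
#'   `bin_size`, `counts` (named list of integer vectors per chromosome) and
#'   `mask` (named list of logicals marking weight-zero bins).
#' @export
simulate_binned_coverage <- function(karyotype, genome = build_dt40_genome(),
                                     config = coverage_sim_config(),
                                     seed = NULL) {
  mus <- expected_bin_coverage(karyotype, genome, config)
  masks <- attr(mus, "mask")
  counts <- with_seed(seed, {
    lapply(mus, function(mu) {
      if (config$noise == "poisson") {
        stats::rpois(length(mu), mu)
      } else {
        stats::rnbinom(length(mu), mu = mu, size = config$dispersion)
      }
    })
  })
  coverage_track(karyotype$strain, config$bin_size, counts, masks)
}

#' Construct a binned coverage track
#'
#' @param strain Strain label.
#' @param bin_size Bin width (bp).
#' @param counts Named list (per chromosome) of non-negative integer vectors.
#' @param mask Optional named list of logical vectors (TRUE = unmappable bin).
#' @return A `coverage_track`.
#' @export
coverage_track <- function(strain, bin_size, counts, mask = NULL) {
  stopifnot(is.list(counts), !is.null(names(counts)))
  for (v in counts) stopifnot(all(v >= 0), all(v == round(v)))
  if (is.null(mask)) mask <- lapply(counts, function(v) rep(FALSE, length(v)))
  stopifnot(identical(names(mask), names(counts)),
            all(mapply(function(m, v) length(m) == length(v), mask, counts)))
  structure(list(strain = strain, bin_size = as.integer(bin_size),
                 counts = counts, mask = mask),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> strain=%s bin_size=%d\n", x$strain, x$bin_size))
  for (chrom in names(x$counts))
    cat(sprintf("  %-6s %6d bins, mean count %.2f\n", chrom,
                length(x$counts[[chrom]]), mean(x$counts[[chrom]])))
  invisible(x)
}

#' Simulate read start positions in a region
#'
#' Uniformly scatters read starts over the retained copies of a genomic
#' region, with total count Poisson around the configured depth; mappability
#' weights thin reads by the weight of the bin they fall in. Intended for
#' small regions, to exercise the read-position ingestion path
#' ([bin_reads()]) against direct bin simulation.
#'
#' @param karyotype A `strain_karyotype`.
#' @param genome A `genome_model`.
#' @param chromosome Chromosome name.
#' @param region Numeric `c(start, end)` half-open, within the chromosome.
#' @param config A [coverage_sim_config()].
#' @param seed Optional RNG seed.
#' @return Sorted numeric vector of 0-based read start positions.
#' @export
simulate_read_positions <- function(karyotype, genome = build_dt40_genome(),
                                    chromosome, region,
                                    config = coverage_sim_config(),
                                    seed = NULL) {
  gi <- genome_chrom(genome, chromosome)
  if (region[1] < 0 || region[2] > gi$length || region[1] >= region[2])
    stop("region outside chromosome bounds")
  rate_per_bp <- config$depth_per_copy / config$bin_size  # per copy
  w <- bin_mask_weights(genome, chromosome, config)
  with_seed(seed, {
    pos <- numeric(0)
    for (cp in karyotype$copies[[chromosome]]) {
      for (r in seq_len(nrow(cp))) {
        s <- max(cp[r, 1], region[1]); e <- min(cp[r, 2], region[2])
        if (s >= e) next
        n <- stats::rpois(1, rate_per_bp * (e - s))
        p <- stats::runif(n, s, e)
        keep <- stats::runif(n) < w[floor(p / config$bin_size) + 1]
        pos <- c(pos, p[keep])
      }
    }
    sort(floor(pos))
  })
}
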