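## Control-normalized read-depth copy-number pipeline.
##
## Per-bin read counts are normalized twice: first each bin is divided by the
## mean bin count of a reference chromosome (chr1) within the same sample,
## removing total-depth differences; the resulting ratio track of the sample
## strain is then divided bin-by-bin by the control strain's ratio track,
## removing shared mappability structure. On the resulting score track a
## value of 1 means "same relative copy number as the control", and for a
## trisomic control chromosome the attainable levels are multiples of 1/3.

#' Bin read start positions into a coverage track
#'
#' @param read_positions Named list (per chromosome) of 0-based read start
#'   positions.
#' @param genome A `genome_model`.
#' @param bin_size Bin width in bp.
#' @param strain Strain label for the track.
#' @param strict If `TRUE`, out-of-bounds positions are an error; otherwise
#'   they are dropped with a message.
#' @return A `coverage_track` (no mask).
#' @examples
#' gen <- build_dt40_genome(include = "chr1")
#' bin_reads(list(chr1 = c(0, 9999, 10000)), gen, 10000)$counts$chr1[1:2]
#' @export
bin_reads <- function(read_positions, genome, bin_size = 10000L,
                      strain = "sample", strict = FALSE) {
  counts <- list()
  for (chrom in genome$name) {
    gi <- genome_chrom(genome, chrom)
    nb <- n_bins(gi$length, bin_size)
    pos <- read_positions[[chrom]]
    if (is.null(pos)) pos <- numeric(0)
    bad <- pos < 0 | pos >= gi$length
    if (any(bad)) {
      if (strict) stop(sum(bad), " read position(s) outside ", chrom)
      message("dropping ", sum(bad), " out-of-bounds position(s) on ", chrom)
      pos <- pos[!bad]
    }
    counts[[chrom]] <- as.integer(tabulate(floor(pos / bin_size) + 1, nbins = nb))
  }
  coverage_track(strain, bin_size, counts)
}

#' Normalize a coverage track by a reference chromosome
#'
#' Divides every bin count by the mean count over the (unmasked) bins of the
#' reference chromosome of the same track, removing sequencing-depth
#' differences between samples.
#'
#' @param track A `coverage_track`.
#' @param reference_chromosome Reference chromosome name (default `"chr1"`).
#' @return A `ratio_track`: list with `strain`, `bin_size`, `ratios` (named
#'   list of numeric vectors), `mask`, and `reference_chromosome`.
#' @export
normalize_to_reference_chrom <- function(track, reference_chromosome = "chr1") {
  if (!reference_chromosome %in% names(track$counts))
    stop("reference chromosome ", reference_chromosome, " not in track")
  ref <- track$counts[[reference_chromosome]]
  refmask <- track$mask[[reference_chromosome]]
  ref_mean <- mean(ref[!refmask])
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("reference chromosome has zero mean coverage; cannot normalize")
  ratios <- lapply(track$counts, function(v) v / ref_mean)
  structure(list(strain = track$strain, bin_size = track$bin_size,
                 ratios = ratios, mask = track$mask,
                 reference_chromosome = reference_chromosome,
                 ref_mean_count = ref_mean),
            class = "ratio_track")
}

#' Normalize a sample ratio track by a control strain
#'
#' Divides the sample's per-bin chr1-normalized ratios by the control's,
#' yielding a score proportional to the sample/control copy-number ratio.
#' Bins where the control ratio falls below `floor` (unmappable regions,
#' e.g. centromeric repeats) are masked (`NA`).
#'
#' @param sample_ratio_track,control_ratio_track `ratio_track`s on the same
#'   genome and binning.
#' @param floor Control-ratio floor below which bins are masked (default 0.1).
#' @return A `score_track`: list with `scores` (named list, `NA` = masked),
#'   `mask`, `bin_size` and provenance fields.
#' @export
normalize_to_control <- function(sample_ratio_track, control_ratio_track,
                                 floor = 0.1) {
  a <- sample_ratio_track; b <- control_ratio_track
  if (!identical(names(a$ratios), names(b$ratios)) ||
      a$bin_size != b$bin_size ||
      !all(mapply(function(x, y) length(x) == length(y), a$ratios, b$ratios)))
    stop("sample and control tracks have mismatched binning")
  scores <- list(); mask <- list(); chrom_score <- c()
  for (chrom in names(a$ratios)) {
    ctrl <- b$ratios[[chrom]]
    m <- ctrl < floor | a$mask[[chrom]] | b$mask[[chrom]]
    s <- a$ratios[[chrom]] / ctrl
    s[m] <- NA_real_
    scores[[chrom]] <- s
    mask[[chrom]] <- m
    ## chromosome-level score as a ratio of aggregate means: the per-bin
    ## ratio mean is biased upward by ~1/(control bin count) at low depth
    ## (Jensen), the ratio of means is not
    chrom_score[chrom] <- if (all(m)) NA_real_ else
      mean(a$ratios[[chrom]][!m]) / mean(ctrl[!m])
  }
  structure(list(scores = scores, mask = mask, bin_size = a$bin_size,
                 sample_strain = a$strain, control_strain = b$strain,
                 reference_chromosome = a$reference_chromosome,
                 chrom_score = chrom_score),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("<score_track> %s vs %s (ref %s), bin_size=%d\n",
              x$sample_strain, x$control_strain, x$reference_chromosome,
              x$bin_size))
  for (chrom in names(x$scores))
    cat(sprintf("  %-6s mean score %.3f (%d/%d bins masked)\n", chrom,
                mean(x$scores[[chrom]], na.rm = TRUE),
                sum(x$mask[[chrom]]), length(x$scores[[chrom]])))
  invisible(x)
}

#' Per-chromosome copy-number table
#'
#' Summarizes a score track into inferred chromosome copy numbers:
#' `control_copies * mean score`, reported raw and rounded to the nearest
#' whole copy. The chromosome-level mean score is the ratio of the
#' chromosome's aggregate sample and control ratios over unmasked bins
#' (unbiased at low depth, unlike the mean of per-bin ratios).
#'
#' @param score_track A `score_track`.
#' @param genome The `genome_model` the track was computed on.
#' @return Data frame with `chromosome`, `mean_score`, `copies_raw`,
#'   `copies` (rounded to nearest integer copy), `pct_change` (percent
#'   read-count change vs control); fully masked chromosomes get `NA`.
#' @export
chromosome_copy_table <- function(score_track, genome) {
  rows <- lapply(genome$name, function(chrom) {
    cc <- genome_chrom(genome, chrom)$control_copies
    mu <- if (!is.null(score_track$chrom_score)) {
      score_track$chrom_score[[chrom]]
    } else {
      s <- score_track$scores[[chrom]]
      if (all(is.na(s))) NA_real_ else mean(s, na.rm = TRUE)
    }
    data.frame(chromosome = chrom, control_copies = cc, mean_score = mu,
               copies_raw = cc * mu, copies = round(cc * mu),
               pct_change = 100 * (mu - 1), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## ---- segmentation ----------------------------------------------------------

## Running median over the unmasked bins only (masked bins stay NA); window
## is in unmasked-bin units so a masked gap does not shrink the window.
masked_runmed <- function(x, mask, window) {
  out <- x
  idx <- which(!mask)
  if (length(idx) == 0) return(out)
  v <- x[idx]
  if (length(v) >= window) {
    sm <- stats::runmed(v, window, endrule = "median")
  } else {
    sm <- rep(stats::median(v), length(v))
  }
  out[idx] <- sm
  out
}

## Exact 1-D Potts fit: assign each bin one of the attainable levels,
## minimizing sum (s_i - level_i)^2 + beta * (# level changes). Solved by
## dynamic programming over levels; ties broken toward staying at the
## current level, so the output is deterministic. Returns the level index
## per bin.
viterbi_quantize <- function(s, levels, beta) {
  n <- length(s)
  L <- length(levels)
  cost <- outer(s, levels, function(x, l) (x - l)^2)
  bp <- matrix(0L, n, L)
  C <- cost[1, ]
  bp[1, ] <- seq_len(L)
  for (i in 2:n) {
    jmin <- which.min(C)
    jumped <- C[jmin] + beta
    stay_ok <- C <= jumped  # <=: prefer staying on ties
    C_new <- ifelse(stay_ok, C, jumped) + cost[i, ]
    bp[i, ] <- ifelse(stay_ok, seq_len(L), jmin)
    C <- C_new
  }
  path <- integer(n)
  path[n] <- which.min(C)
  for (i in n:2) path[i - 1] <- bp[i, path[i]]
  path
}

## Robust per-bin score SD from lag-1 differences (true level steps are rare
## and the MAD ignores them).
robust_bin_sd <- function(scores) {
  s <- stats::mad(diff(scores), na.rm = TRUE) / sqrt(2)
  if (!is.finite(s) || s == 0) 1e-6 else s
}

#' Segment a score track into constant copy-number levels
#'
#' Deterministic segmentation designed for engineered karyotypes where the
#' attainable score levels are known rational multiples of
#' `1/control_copies`: the unmasked bins of each chromosome are assigned
#' levels from `{k/control_copies : k = 0..control_copies+1}` by exactly
#' minimizing the penalized least-squares (Potts) objective
#' `sum_i (s_i - level_i)^2 + beta * #{level changes}`, solved by dynamic
#' programming; runs shorter than `min_run` unmasked bins are then merged
#' into the neighboring run with the closer level. Optionally the scores are
#' median-smoothed first (off by default: pre-smoothing correlates the noise
#' and blurs step edges that the global fit localizes sharply). Masked bins
#' are bridged: a segment extends through them until the first unmasked bin
#' of a different level, and the boundary is placed at the start of that bin.
#'
#' The default changepoint penalty is BIC-like, `beta = 2 * sigma^2 *
#' log(n)`, with the per-bin score SD `sigma` estimated robustly from lag-1
#' differences of the chromosome's unmasked scores — large enough to
#' suppress noise-driven segments, small enough that a one-third-copy change
#' pays for itself within a handful of bins.
#'
#' @param score_track A `score_track`.
#' @param genome The `genome_model` (for control copy numbers and lengths).
#' @param penalty Changepoint penalty `beta`, or `NULL` (default) for the
#'   noise-adaptive BIC-like choice described above.
#' @param min_run Minimum run length in unmasked bins (default 3).
#' @param window Optional odd median pre-smoothing window in bins
#'   (default 1 = none).
#' @return Data frame of class `segment_calls`: `chromosome`, `start`, `end`
#'   (bp, bin-aligned, half-open), `mean_score`, `level`, `copies`, `n_bins`.
#' @export
segment_score_track <- function(score_track, genome, penalty = NULL,
                                min_run = 3, window = 1) {
  stopifnot(window %% 2 == 1, min_run >= 1, is.null(penalty) || penalty > 0)
  segs <- list()
  for (chrom in names(score_track$scores)) {
    gi <- genome_chrom(genome, chrom)
    s <- score_track$scores[[chrom]]
    m <- score_track$mask[[chrom]]
    bs <- score_track$bin_size
    idx <- which(!m)
    if (length(idx) == 0) next
    sm <- if (window > 1) masked_runmed(s, m, window) else s
    levels <- (0:(gi$control_copies + 1)) / gi$control_copies
    beta <- penalty %||% (2 * robust_bin_sd(sm[idx])^2 * log(length(idx)))
    ## bins separated by a sizeable masked gap are not neighbors: fit and
    ## merge per contiguous unmasked block, so that a breakpoint hidden in
    ## an unmappable region costs nothing and a stray bin at a gap edge
    ## cannot drag the boundary across the gap
    block <- cumsum(c(1, diff(idx) > min_run))
    lev <- numeric(length(idx))
    for (b in unique(block)) {
      bi <- block == b
      lv <- levels[viterbi_quantize(sm[idx[bi]], levels, beta)]
      lev[bi] <- merge_short_runs(lv, min_run)
    }
    ## runs over unmasked bins; boundaries at the first unmasked bin of the
    ## next run (masked gaps are absorbed into the preceding segment)
    brk <- c(0, which(diff(lev) != 0), length(lev))
    for (k in seq_len(length(brk) - 1)) {
      first <- idx[brk[k] + 1]
      start_bp <- if (k == 1) 0 else (first - 1) * bs
      end_bp <- if (k == length(brk) - 1) gi$length
                else (idx[brk[k + 1] + 1] - 1) * bs
      run_bins <- idx[(brk[k] + 1):brk[k + 1]]
      segs[[length(segs) + 1]] <- data.frame(
        chromosome = chrom, start = start_bp, end = end_bp,
        mean_score = mean(s[run_bins]),
        level = lev[brk[k] + 1],
        copies = round(lev[brk[k] + 1] * gi$control_copies * 1e9) / 1e9,
        n_bins = length(run_bins), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs)
  class(out) <- c("segment_calls", "data.frame")
  out
}

## Merge runs of identical levels shorter than min_run into the neighbor with
## the closer level (ties: the longer neighbor). Iterates until stable.
merge_short_runs <- function(lev, min_run) {
  repeat {
    r <- rle(lev)
    if (length(r$lengths) <= 1) return(lev)
    short <- which(r$lengths < min_run)
    if (length(short) == 0) return(lev)
    i <- short[which.min(r$lengths[short])]
    left <- if (i > 1) r$values[i - 1] else NA
    right <- if (i < length(r$values)) r$values[i + 1] else NA
    target <- if (is.na(left)) right
      else if (is.na(right)) left
      else {
        dl <- abs(r$values[i] - left); dr <- abs(r$values[i] - right)
        if (dl < dr) left
        else if (dr < dl) right
        else if (r$lengths[i - 1] >= r$lengths[i + 1]) left else right
      }
    r$values[i] <- target
    lev <- inverse.rle(r)
  }
}

#' Detect the mini-chromosome segment on a segmented chromosome
#'
#' Scans the segment calls of one chromosome for an elevated segment — a
#' level strictly above both flanking segments' levels — and returns the one
#' nearest the centromere (the mini-chromosome retains the centromere by
#' construction).
#'
#' @param segments `segment_calls` from [segment_score_track()].
#' @param genome A `genome_model` (for the centromere position).
#' @param chromosome Chromosome to scan (default `"chr2"`).
#' @return `NULL` if no elevated segment; otherwise a list with `start`,
#'   `end`, `length` (bp) and `level`.
#' @export
detect_mini_segment <- function(segments, genome = build_dt40_genome(),
                                chromosome = "chr2") {
  sg <- segments[segments$chromosome == chromosome, , drop = FALSE]
  if (nrow(sg) < 3) return(NULL)
  sg <- sg[order(sg$start), ]
  cand <- which(vapply(seq_len(nrow(sg)), function(i) {
    i > 1 && i < nrow(sg) &&
      sg$level[i] > sg$level[i - 1] && sg$level[i] > sg$level[i + 1]
  }, logical(1)))
  if (length(cand) == 0) return(NULL)
  gi <- genome_chrom(genome, chromosome)
  if (!is.na(gi$cen_start) && length(cand) > 1) {
    cen_mid <- (gi$cen_start + gi$cen_end) / 2
    mid <- (sg$start[cand] + sg$end[cand]) / 2
    cand <- cand[which.min(abs(mid - cen_mid))]
  } else {
    cand <- cand[1]
  }
  list(start = sg$start[cand], end = sg$end[cand],
       length = sg$end[cand] - sg$start[cand], level = sg$level[cand])
}

#' Differential regions between two strains' score tracks
#'
#' Segments both score tracks (each computed against the same control) and
#' returns the maximal intervals where the quantized copy levels differ,
#' with the direction of change in `B` relative to `A`.
#'
#' @param score_a,score_b `score_track`s on the same genome/binning (or
#'   precomputed `segment_calls`).
#' @param genome A `genome_model`.
#' @param ... Passed to [segment_score_track()].
#' @return Data frame with `chromosome`, `start`, `end`, `level_a`,
#'   `level_b`, `direction` (`"loss"` if B < A, `"gain"` if B > A).
#' @export
compare_strains <- function(score_a, score_b, genome = build_dt40_genome(),
                            ...) {
  seg_of <- function(x) {
    if (inherits(x, "segment_calls")) x else segment_score_track(x, genome, ...)
  }
  sa <- seg_of(score_a); sb <- seg_of(score_b)
  out <- list()
  for (chrom in unique(sa$chromosome)) {
    a <- sa[sa$chromosome == chrom, ]; b <- sb[sb$chromosome == chrom, ]
    if (nrow(b) == 0) next
    a <- a[order(a$start), ]; b <- b[order(b$start), ]
    edges <- sort(unique(c(a$start, a$end, b$start, b$end)))
    lv <- function(sg, p) {
      i <- findInterval(p, sg$start)
      ifelse(i >= 1 & p < sg$end[pmax(i, 1)], sg$level[pmax(i, 1)], NA)
    }
    mids <- (edges[-length(edges)] + edges[-1]) / 2
    la <- lv(a, mids); lb <- lv(b, mids)
    differ <- !is.na(la) & !is.na(lb) & abs(la - lb) > 1e-9
    if (!any(differ)) next
    key <- ifelse(differ, paste(la, lb), "same")
    r <- rle(key)
    pos <- cumsum(c(0, r$lengths))
    for (k in which(r$values != "same")) {
      i1 <- pos[k] + 1; i2 <- pos[k + 1]
      out[[length(out) + 1]] <- data.frame(
        chromosome = chrom, start = edges[i1], end = edges[i2 + 1],
        level_a = la[i1], level_b = lb[i1],
        direction = if (lb[i1] < la[i1]) "loss" else "gain",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0), level_a = numeric(0),
                      level_b = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
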