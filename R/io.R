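## Readers/writers for the pipeline's on-disk formats: binned counts TSV,
## score bedGraph, segment BED, read-position BED, and the two flow-assay
## TSVs. Genomic tracks go through rtracklayer (0-based half-open handled by
## the GRanges conversion); tabular files are plain TSV.

track_granges <- function(chroms, starts, ends, genome) {
  GenomicRanges::GRanges(
    seqnames = chroms,
    ranges = IRanges::IRanges(start = starts + 1, end = ends),
    seqlengths = stats::setNames(genome$length, genome$name)
  )
}

#' Write / read binned read counts as TSV
#'
#' Columns `chrom`, `start`, `end`, `count` (0-based half-open bins) plus a
#' header comment carrying the strain and bin size, so a written track
#' round-trips losslessly.
#'
#' @param track A `coverage_track`.
#' @param path File path.
#' @return `write_counts_tsv` returns `path` invisibly; `read_counts_tsv`
#'   returns a `coverage_track`.
#' @export
write_counts_tsv <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# strain=%s bin_size=%d", track$strain, track$bin_size), con)
  rows <- do.call(rbind, lapply(names(track$counts), function(chrom) {
    v <- track$counts[[chrom]]
    n <- length(v)
    data.frame(chrom = chrom, start = (seq_len(n) - 1) * track$bin_size,
               end = seq_len(n) * track$bin_size,
               count = v, masked = as.integer(track$mask[[chrom]]),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  header <- readLines(path, n = 1)
  strain <- sub(".*strain=(\\S+).*", "\\1", header)
  bin_size <- as.integer(sub(".*bin_size=(\\d+).*", "\\1", header))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "count")
  if (!all(need %in% names(df)))
    stop("malformed counts TSV ", path, ": need columns ",
         paste(need, collapse = ", "))
  chroms <- unique(df$chrom)
  counts <- lapply(chroms, function(ch) {
    d <- df[df$chrom == ch, ]
    d <- d[order(d$start), ]
    if (any(d$start != (seq_len(nrow(d)) - 1) * bin_size))
      stop("non-contiguous bins for ", ch, " in ", path)
    as.integer(d$count)
  })
  names(counts) <- chroms
  mask <- if ("masked" %in% names(df)) {
    ms <- lapply(chroms, function(ch) {
      d <- df[df$chrom == ch, ]
      as.logical(d$masked[order(d$start)])
    })
    names(ms) <- chroms
    ms
  } else NULL
  coverage_track(strain, bin_size, counts, mask)
}

#' Write a score track as bedGraph
#'
#' Masked bins are omitted from the output, as is conventional for missing
#' data in bedGraph tracks.
#'
#' @param score_track A `score_track`.
#' @param genome A `genome_model`.
#' @param path Output path (`.bedgraph`).
#' @return `path`, invisibly.
#' @export
write_score_bedgraph <- function(score_track, genome, path) {
  rows <- do.call(rbind, lapply(names(score_track$scores), function(chrom) {
    s <- score_track$scores[[chrom]]
    keep <- !score_track$mask[[chrom]]
    n <- length(s)
    gi <- genome_chrom(genome, chrom)
    starts <- (seq_len(n) - 1) * score_track$bin_size
    ends <- pmin(seq_len(n) * score_track$bin_size, gi$length)
    data.frame(chrom = chrom, start = starts, end = ends, score = s)[keep, ]
  }))
  gr <- track_granges(rows$chrom, rows$start, rows$end, genome)
  gr$score <- rows$score
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' Read a bedGraph score file
#'
#' @param path bedGraph path.
#' @return Data frame `chrom`, `start`, `end`, `score` (0-based half-open).
#' @export
read_score_bedgraph <- function(path) {
  gr <- rtracklayer::import.bedGraph(path)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             score = gr$score, stringsAsFactors = FALSE)
}

#' Write segment calls as BED
#'
#' The BED name field carries the quantized level as `level=<k>/<copies>`
#' alongside the inferred copy count.
#'
#' @param segments `segment_calls`.
#' @param genome A `genome_model`.
#' @param path Output path (`.bed`).
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, genome, path) {
  gr <- track_granges(segments$chromosome, segments$start, segments$end, genome)
  gr$name <- sprintf("level=%.6g;copies=%g", segments$level, segments$copies)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read segment calls from BED
#'
#' @param path BED path written by [write_segments_bed()].
#' @return Data frame `chromosome`, `start`, `end`, `level`, `copies`.
#' @export
read_segments_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  nm <- gr$name
  data.frame(chromosome = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             level = as.numeric(sub("level=([^;]+);.*", "\\1", nm)),
             copies = as.numeric(sub(".*copies=(.*)$", "\\1", nm)),
             stringsAsFactors = FALSE)
}

#' Write / read read start positions as BED
#'
#' Each read start becomes a 1-bp BED feature.
#'
#' @param positions Numeric vector of 0-based start positions.
#' @param chromosome Chromosome name.
#' @param genome A `genome_model`.
#' @param path Output path.
#' @return `write_read_positions_bed` returns `path` invisibly;
#'   `read_read_positions_bed` returns a named list of position vectors.
#' @export
write_read_positions_bed <- function(positions, chromosome, genome, path) {
  gr <- track_granges(rep(chromosome, length(positions)), positions,
                      positions + 1, genome)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' @rdname write_read_positions_bed
#' @export
read_read_positions_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  split(GenomicRanges::start(gr) - 1, as.character(GenomicRanges::seqnames(gr)))
}

#' Write / read a clone assay TSV
#'
#' Columns `clone_id`, `gfp_negative_fraction` and optionally
#' `gfp_double_fraction`; the assay duration travels in a header comment.
#'
#' @param assay A `clone_assay` data frame.
#' @param path File path.
#' @return `write_clone_assay_tsv` returns `path` invisibly;
#'   `read_clone_assay_tsv` a `clone_assay`.
#' @export
write_clone_assay_tsv <- function(assay, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_days=%g divisions_per_day=%d",
                     attr(assay, "duration_days"),
                     attr(assay, "divisions_per_day") %||% 3L), con)
  utils::write.table(assay, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clone_assay_tsv
#' @export
read_clone_assay_tsv <- function(path) {
  header <- readLines(path, n = 1)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("clone_id", "gfp_negative_fraction") %in% names(df)))
    stop("malformed clone assay TSV: ", path)
  if (any(df$gfp_negative_fraction < 0 | df$gfp_negative_fraction > 1))
    stop("fractions outside [0, 1] in ", path)
  attr(df, "duration_days") <- as.numeric(sub(".*duration_days=(\\S+).*", "\\1", header))
  attr(df, "divisions_per_day") <- as.integer(sub(".*divisions_per_day=(\\d+).*", "\\1", header))
  class(df) <- c("clone_assay", "data.frame")
  df
}

#' Write / read a flow time-course TSV
#'
#' Columns `day`, `fraction_gfp_negative`, `fraction_gfp_single`,
#' `fraction_gfp_double_or_more`.
#'
#' @param timecourse A `flow_timecourse` data frame.
#' @param path File path.
#' @return `write_timecourse_tsv` returns `path` invisibly;
#'   `read_timecourse_tsv` a `flow_timecourse`.
#' @export
write_timecourse_tsv <- function(timecourse, path) {
  utils::write.table(timecourse, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse_tsv
#' @export
read_timecourse_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("day", "fraction_gfp_negative") %in% names(df)))
    stop("malformed time-course TSV: ", path)
  class(df) <- c("flow_timecourse", "data.frame")
  df
}
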