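## Genome baseline and engineered-strain karyotypes.
##
## The DT40 CL18 karyotype is diploid except chromosome 2 (trisomic) and
## chromosome 24 (tetrasomic). Chromosome-editing strains differ from CL18
## only in the set of chromosome 2 copies they retain; each copy is described
## by the half-open base-pair intervals [start, end) it still carries, so a
## full copy is [0, length) and a truncated copy a sub-interval. All
## coordinates are 0-based, half-open, in base pairs.

#' Build the DT40 genome baseline
#'
#' Constructs the control-strain (CL18) genome model: chromosome lengths,
#' centromere intervals, and control copy numbers. By default four
#' chromosomes are modeled: chr1 (196 Mb, the normalization reference),
#' chr2 (153 Mb, trisomic, centromere at 52.2-52.7 Mb), chr3 (110 Mb) and
#' chr24 (6 Mb, tetrasomic).
#'
#' @param overrides Named list of per-chromosome overrides; each element is a
#'   list with any of `length`, `centromere` (length-2 numeric, `NA` or `NULL`
#'   to drop), `control_copies`.
#' @param include Optional character vector restricting the model to a subset
#'   of chromosomes (e.g. `c("chr1", "chr2")` for a fast two-chromosome model).
#' @return An object of class `genome_model`: a data frame with columns
#'   `name`, `length`, `cen_start`, `cen_end`, `control_copies`.
#' @examples
#' gen <- build_dt40_genome()
#' gen[gen$name == "chr2", ]
#' @export
build_dt40_genome <- function(overrides = NULL, include = NULL) {
  chroms <- data.frame(
    name = c("chr1", "chr2", "chr3", "chr24"),
    length = c(196e6, 153e6, 110e6, 6e6),
    cen_start = c(NA, 52.2e6, NA, NA),
    cen_end = c(NA, 52.7e6, NA, NA),
    control_copies = c(2L, 3L, 2L, 4L),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("`overrides` must be a named list keyed by chromosome name")
    for (nm in names(overrides)) {
      ov <- overrides[[nm]]
      i <- match(nm, chroms$name)
      if (is.na(i)) {  # new chromosome
        chroms <- rbind(chroms, data.frame(
          name = nm, length = NA_real_, cen_start = NA_real_,
          cen_end = NA_real_, control_copies = 2L, stringsAsFactors = FALSE))
        i <- nrow(chroms)
      }
      if (!is.null(ov$length)) chroms$length[i] <- ov$length
      if ("centromere" %in% names(ov)) {
        cen <- ov$centromere
        if (is.null(cen) || all(is.na(cen))) {
          chroms$cen_start[i] <- NA; chroms$cen_end[i] <- NA
        } else {
          chroms$cen_start[i] <- cen[1]; chroms$cen_end[i] <- cen[2]
        }
      }
      if (!is.null(ov$control_copies)) chroms$control_copies[i] <- as.integer(ov$control_copies)
    }
  }
  if (!is.null(include)) {
    missing <- setdiff(include, chroms$name)
    if (length(missing)) stop("unknown chromosome(s) in `include`: ", paste(missing, collapse = ", "))
    chroms <- chroms[match(include, chroms$name), , drop = FALSE]
    rownames(chroms) <- NULL
  }
  validate_genome(chroms)
  structure(chroms, class = c("genome_model", "data.frame"))
}

validate_genome <- function(chroms) {
  if (anyNA(chroms$length) || any(chroms$length <= 0))
    stop("chromosome lengths must be positive")
  if (anyDuplicated(chroms$name))
    stop("chromosome names must be unique")
  has_cen <- !is.na(chroms$cen_start)
  if (any(has_cen & (chroms$cen_start < 0 | chroms$cen_end > chroms$length |
                     chroms$cen_start >= chroms$cen_end)))
    stop("centromere interval must be a nonempty interval within [0, length)")
  if (any(chroms$control_copies < 1))
    stop("control copy numbers must be >= 1")
  invisible(chroms)
}

genome_chrom <- function(genome, chromosome) {
  i <- match(chromosome, genome$name)
  if (is.na(i)) stop("unknown chromosome: ", chromosome)
  genome[i, , drop = FALSE]
}

#' Built-in engineered strain names
#' @export
strain_names <- function() c("CL18", "Chr2-2", "Chr2_1_1_q", "Chr2_1_1_mini", "Chr2_1_p_q")

## Truncation coordinates on chr2 shared by the engineered strains: the p-arm
## telomere-seeding site sits 0.2 Mb left of the centromere (52.0 Mb) and the
## q-arm site at the distal centromere edge (52.7 Mb), so the double-truncated
## mini-chromosome spans [52.0, 52.7) Mb = 0.7 Mb.
P_TRUNC <- 52.0e6
Q_TRUNC <- 52.7e6

#' Construct a built-in strain karyotype
#'
#' Encodes the chromosome 2 copy structure of the five strains of the editing
#' series: `CL18` (trisomic control), `Chr2-2` (trisomy corrected to disomy),
#' `Chr2_1_1_q` (two full copies plus a p-arm-truncated copy retaining
#' q-arm and centromere), `Chr2_1_1_mini` (two full copies plus the 0.7-Mb
#' mini-chromosome), and `Chr2_1_p_q` (one full copy plus complementary p- and
#' q-retaining truncated copies). Non-chr2 chromosomes follow the genome
#' baseline.
#'
#' @param strain_name One of [strain_names()].
#' @param genome A `genome_model`, by default [build_dt40_genome()].
#' @return An object of class `strain_karyotype`: a list with `strain` and
#'   `copies`, the latter a named list (per chromosome) of copies, each copy a
#'   two-column matrix of retained `[start, end)` intervals.
#' @examples
#' kar <- make_strain_karyotype("Chr2_1_1_mini")
#' copy_number_at(kar, "chr2", 52.1e6)  # 3: inside the mini interval
#' @export
make_strain_karyotype <- function(strain_name, genome = build_dt40_genome()) {
  if (!strain_name %in% strain_names())
    stop("unknown strain: ", strain_name, " (known: ", paste(strain_names(), collapse = ", "), ")")
  full <- function(len) matrix(c(0, len), nrow = 1,
                               dimnames = list(NULL, c("start", "end")))
  iv <- function(s, e) matrix(c(s, e), nrow = 1,
                              dimnames = list(NULL, c("start", "end")))
  copies <- lapply(seq_len(nrow(genome)), function(i) {
    replicate(genome$control_copies[i], full(genome$length[i]), simplify = FALSE)
  })
  names(copies) <- genome$name
  if ("chr2" %in% genome$name) {
    len2 <- genome_chrom(genome, "chr2")$length
    copies[["chr2"]] <- switch(strain_name,
      "CL18" = list(full(len2), full(len2), full(len2)),
      "Chr2-2" = list(full(len2), full(len2)),
      "Chr2_1_1_q" = list(full(len2), full(len2), iv(P_TRUNC, len2)),
      "Chr2_1_1_mini" = list(full(len2), full(len2), iv(P_TRUNC, Q_TRUNC)),
      "Chr2_1_p_q" = list(full(len2), iv(0, Q_TRUNC), iv(P_TRUNC, len2))
    )
  }
  kar <- structure(list(strain = strain_name, copies = copies),
                   class = "strain_karyotype")
  viol <- validate_karyotype(kar, genome)
  if (length(viol)) stop("invalid karyotype: ", paste(viol, collapse = "; "))
  kar
}

#' Aggregate copy number at a position
#'
#' Counts how many copies of `chromosome` in the karyotype retain the base
#' position `position_bp`.
#'
#' @param karyotype A `strain_karyotype`.
#' @param chromosome Chromosome name.
#' @param position_bp 0-based position in base pairs (may be a vector).
#' @return Integer vector of copy counts.
#' @export
copy_number_at <- function(karyotype, chromosome, position_bp) {
  cps <- karyotype$copies[[chromosome]]
  if (is.null(cps)) stop("unknown chromosome: ", chromosome)
  if (any(position_bp < 0)) stop("position must be >= 0")
  # positions beyond every retained interval are valid if within the
  # chromosome; the genome is not in scope here, so only reject negative
  # input and let validate_karyotype own the length check
  vapply(position_bp, function(p) {
    sum(vapply(cps, function(m) {
      any(m[, "start"] <= p & p < m[, "end"])
    }, logical(1)))
  }, integer(1))
}

#' Validate a strain karyotype against a genome model
#'
#' Checks interval sanity (sorted, non-overlapping, within chromosome bounds)
#' for every copy of every chromosome. Reports violations rather than
#' throwing.
#'
#' @inheritParams copy_number_at
#' @param genome A `genome_model`.
#' @return Character vector of violation messages; empty if valid.
#' @export
validate_karyotype <- function(karyotype, genome) {
  viol <- character(0)
  for (chrom in names(karyotype$copies)) {
    i <- match(chrom, genome$name)
    if (is.na(i)) {
      viol <- c(viol, sprintf("%s: not in genome model", chrom))
      next
    }
    len <- genome$length[i]
    for (k in seq_along(karyotype$copies[[chrom]])) {
      m <- karyotype$copies[[chrom]][[k]]
      tag <- sprintf("%s copy %d", chrom, k)
      if (!is.matrix(m) || ncol(m) != 2) {
        viol <- c(viol, sprintf("%s: intervals must be a 2-column matrix", tag))
        next
      }
      if (nrow(m) == 0) next  # an empty copy carries nothing; allowed
      if (any(m[, 1] >= m[, 2]))
        viol <- c(viol, sprintf("%s: empty or reversed interval", tag))
      if (any(m[, 1] < 0) || any(m[, 2] > len))
        viol <- c(viol, sprintf("%s: interval outside [0, %g)", tag, len))
      if (nrow(m) > 1) {
        if (is.unsorted(m[, 1], strictly = FALSE))
          viol <- c(viol, sprintf("%s: intervals not sorted", tag))
        else if (any(m[-1, 1] < m[-nrow(m), 2]))
          viol <- c(viol, sprintf("%s: overlapping intervals", tag))
      }
    }
  }
  viol
}

#' @export
print.strain_karyotype <- function(x, ...) {
  cat("<strain_karyotype>", x$strain, "\n")
  for (chrom in names(x$copies)) {
    cps <- x$copies[[chrom]]
    desc <- vapply(cps, function(m) {
      paste(sprintf("[%.1f,%.1f)Mb", m[, 1] / 1e6, m[, 2] / 1e6), collapse = "+")
    }, character(1))
    cat(sprintf("  %-6s %d copies: %s\n", chrom, length(cps), paste(desc, collapse = " | ")))
  }
  invisible(x)
}

#' Write / read a genome + karyotype configuration as YAML
#'
#' Round-trips the genome model and (optionally) a strain karyotype through a
#' structured YAML document, so edited geometries can be versioned alongside
#' an analysis.
#'
#' @param genome A `genome_model`.
#' @param path Output file path.
#' @param karyotype Optional `strain_karyotype` to embed.
#' @return `write_karyotype_yaml` returns `path` invisibly;
#'   `read_karyotype_yaml` returns a list with `genome` and (if present)
#'   `karyotype`.
#' @export
write_karyotype_yaml <- function(genome, path, karyotype = NULL) {
  doc <- list(chromosomes = lapply(seq_len(nrow(genome)), function(i) {
    ch <- list(name = genome$name[i], length = genome$length[i],
               control_copies = as.integer(genome$control_copies[i]))
    if (!is.na(genome$cen_start[i]))
      ch$centromere <- c(genome$cen_start[i], genome$cen_end[i])
    ch
  }))
  if (!is.null(karyotype)) {
    doc$strain <- karyotype$strain
    doc$copies <- lapply(karyotype$copies, function(cps) {
      lapply(cps, function(m) lapply(seq_len(nrow(m)), function(r) c(m[r, 1], m[r, 2])))
    })
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_karyotype_yaml
#' @export
read_karyotype_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  chroms <- do.call(rbind, lapply(doc$chromosomes, function(ch) {
    data.frame(name = ch$name, length = as.numeric(ch$length),
               cen_start = if (!is.null(ch$centromere)) as.numeric(ch$centromere[[1]]) else NA_real_,
               cen_end = if (!is.null(ch$centromere)) as.numeric(ch$centromere[[2]]) else NA_real_,
               control_copies = as.integer(ch$control_copies),
               stringsAsFactors = FALSE)
  }))
  validate_genome(chroms)
  genome <- structure(chroms, class = c("genome_model", "data.frame"))
  out <- list(genome = genome)
  if (!is.null(doc$copies)) {
    copies <- lapply(doc$copies, function(cps) {
      lapply(cps, function(ivs) {
        m <- do.call(rbind, lapply(ivs, function(v) as.numeric(unlist(v))))
        dimnames(m) <- list(NULL, c("start", "end"))
        m
      })
    })
    out$karyotype <- structure(list(strain = doc$strain %||% "custom", copies = copies),
                               class = "strain_karyotype")
  }
  out
}
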