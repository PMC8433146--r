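#!/usr/bin/env Rscript

# Step 2 — copy-number genotyping of the edited strains from the binned
# coverage written by 01_simulate_data.R: chr1-then-control double
# normalization, per-chromosome copy table, segmentation of chromosome 2,
# mini-chromosome detection, and pairwise strain comparisons.
#
# Writes results/copy_table.tsv, per-strain bedGraph/BED tracks, and
# results/breakpoints.tsv.

suppressPackageStartupMessages(library(minichrom))
gen <- build_dt40_genome()

read_track <- function(strain) {
  read_counts_tsv(sprintf("results/coverage_%s.tsv",
                          gsub("[^A-Za-z0-9_]", "_", strain)))
}
ctl <- normalize_to_reference_chrom(read_track("CL18"))

copy_rows <- list(); segs <- list()
for (strain in setdiff(strain_names(), "CL18")) {
  st <- normalize_to_control(normalize_to_reference_chrom(read_track(strain)), ctl)
  tab <- chromosome_copy_table(st, gen)
  tab$strain <- strain
  copy_rows[[strain]] <- tab
  seg <- segment_score_track(st, gen)
  segs[[strain]] <- seg
  slug <- gsub("[^A-Za-z0-9_]", "_", strain)
  write_score_bedgraph(st, gen, sprintf("results/score_%s.bedgraph", slug))
  write_segments_bed(seg, gen, sprintf("results/segments_%s.bed", slug))
  message(sprintf("%-14s chr2 copies %.2f (%+.1f%% reads)", strain,
                  tab$copies_raw[tab$chromosome == "chr2"],
                  tab$pct_change[tab$chromosome == "chr2"]))
}
copy_table <- do.call(rbind, copy_rows)
write.table(copy_table, "results/copy_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# Mini-chromosome geometry in the two strains that carry it
bps <- list()
for (strain in c("Chr2_1_1_mini", "Chr2_1_p_q")) {
  mini <- detect_mini_segment(segs[[strain]], gen)
  message(sprintf("%s: mini-chromosome [%.2f, %.2f) Mb, %.2f Mb", strain,
                  mini$start / 1e6, mini$end / 1e6, mini$length / 1e6))
  bps[[strain]] <- data.frame(comparison = paste0(strain, "_mini"),
                              chromosome = "chr2", start = mini$start,
                              end = mini$end)
}

# Incremental losses between strains along the editing series
pairs <- list(c("Chr2_1_1_q", "Chr2_1_1_mini"), c("Chr2_1_1_q", "Chr2_1_p_q"))
for (pr in pairs) {
  d <- compare_strains(segs[[pr[1]]], segs[[pr[2]]], gen)
  d <- d[d$chromosome == "chr2", , drop = FALSE]
  for (i in seq_len(nrow(d))) {
    message(sprintf("%s -> %s: %s of [%.2f, %.2f) Mb", pr[1], pr[2],
                    d$direction[i], d$start[i] / 1e6, d$end[i] / 1e6))
  }
  d$comparison <- paste(pr, collapse = "_vs_")
  bps[[paste(pr, collapse = "|")]] <- d[, c("comparison", "chromosome", "start", "end")]
}
write.table(do.call(rbind, bps), "results/breakpoints.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
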