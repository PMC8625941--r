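#!/usr/bin/env Rscript

# Stage 2 — call differential RNA 5'/3' ends.
#
# Loads the bedGraph end-count tracks written by 01_simulate.R, and for each
# ribonuclease compares wild type against the cognate mutant at the published
# operating point (|log2FC| >= 1, BH-adjusted p <= 0.05). Positions enriched
# in the wild type are candidate enzyme-generated ends; positions enriched in
# the mutant reflect precursor accumulation.

suppressPackageStartupMessages({
  library(srnaends)
  library(dplyr)
})

out_tab <- "results/analysis"
trk_dir <- "scratch/analysis/tracks"
libs <- read.delim(file.path(out_tab, "library_sizes.tsv"))

load_strain <- function(strain) {
  rows <- libs[libs$strain == strain, ]
  sets <- lapply(seq_len(nrow(rows)), function(i) {
    s <- rows$sample_id[i]
    comps <- expand.grid(strand = c("+", "-"),
                         end_type = c("five_prime", "three_prime"),
                         stringsAsFactors = FALSE)
    parts <- lapply(seq_len(nrow(comps)), function(j) {
      f <- file.path(trk_dir, sprintf(
        "%s.%s.%s.bedgraph", s,
        if (comps$strand[j] == "+") "plus" else "minus",
        if (comps$end_type[j] == "five_prime") "5p" else "3p"))
      read_bedgraph(f, s, comps$strand[j], comps$end_type[j],
                    library_size = rows$library_size[i])
    })
    end_tracks(bind_rows(lapply(parts, track_counts)),
               setNames(rows$library_size[i], s))
  })
  do.call(bind_tracks, sets)
}

wt <- load_strain("WT")
all_calls <- bind_rows(lapply(c("RNaseE", "RNaseIII", "PNPase"), function(enz) {
  mut <- load_strain(paste0(enz, "_mut"))
  de <- call_differential_ends(wt, mut, enz)
  cat(sprintf("%-9s %3d differential ends (%d wild-type enriched)\n",
              enz, nrow(de), sum(de$direction == "wt_enriched")))
  de
}))

write.table(all_calls, file.path(out_tab, "differential_ends.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_diff_ends_bed(all_calls, file.path(out_tab, "differential_ends.bed"))

truth <- read.delim(file.path(out_tab, "truth_diff_ends.tsv"))
key <- function(d, pos) paste(d[[pos]], d$strand, d$end_type, d$enzyme)
wt_enr <- all_calls[all_calls$direction == "wt_enriched", ]
sens <- mean(key(truth, "position") %in% key(wt_enr, "position"))
fdp <- mean(!(key(wt_enr, "position") %in% key(truth, "position")))
cat(sprintf("Recovery against implanted truth: sensitivity %.3f, FDP %.3f\n",
            sens, fdp))
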