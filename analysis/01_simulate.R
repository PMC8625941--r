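#!/usr/bin/env Rscript

# Stage 1 — generate the synthetic study inputs.
#
# Simulates a master set of 79 sRNAs on a 50 kb replicon in the origin
# proportions of the real master set (38 orphan : 14 5'UTR : 16 3'UTR among
# assignable classes), places TSS, terminator and ribonuclease-dependent end
# features at the true end positions, and draws triplicate strand-specific
# 5'/3' end-count tracks for the wild type and the RNase E, RNase III and
# PNPase mutant strains. Annotation goes to results/analysis as GFF3; the
# bulky per-sample bedGraph tracks go to scratch/analysis/tracks.

suppressPackageStartupMessages({
  library(srnaends)
  library(dplyr)
})

out_tab <- "results/analysis"
out_trk <- "scratch/analysis/tracks"
dir.create(out_tab, recursive = TRUE, showWarnings = FALSE)
dir.create(out_trk, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1L)   # study-condition defaults
ann <- simulate_annotation(cfg)

# annotation as one GFF3 (UTR ids carry their gene in the ID)
gff <- bind_rows(
  tibble(type = "sRNA", id = ann$srnas$srna_id, replicon = ann$srnas$replicon,
         start = ann$srnas$start, end = ann$srnas$end,
         strand = ann$srnas$strand),
  tibble(type = ifelse(ann$utrs$kind == "five_prime", "five_prime_UTR",
                       "three_prime_UTR"),
         id = paste0(ann$utrs$gene_id, ":", ann$utrs$kind, "_UTR"),
         replicon = ann$utrs$replicon, start = ann$utrs$start,
         end = ann$utrs$end, strand = ann$utrs$strand),
  tibble(type = "gene", id = ann$genes$gene_id, replicon = ann$genes$replicon,
         start = ann$genes$start, end = ann$genes$end,
         strand = ann$genes$strand),
  tibble(type = "TSS", id = ann$tss$feature_id, replicon = ann$tss$replicon,
         start = ann$tss$position, end = ann$tss$position + 1L,
         strand = ann$tss$strand),
  tibble(type = "terminator", id = ann$terminators$feature_id,
         replicon = ann$terminators$replicon,
         start = ann$terminators$position,
         end = ann$terminators$position + 1L,
         strand = ann$terminators$strand))
write_gff3(gff, file.path(out_tab, "annotation.gff3"))

# ground truth for later stages
truth <- ann$truth
truth_flat <- mutate(truth,
                     mech5 = vapply(mech5, paste, "", collapse = ","),
                     mech3 = vapply(mech3, paste, "", collapse = ","))
write.table(truth_flat, file.path(out_tab, "truth_srnas.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(truth_diff_ends(truth), file.path(out_tab, "truth_diff_ends.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# strain tracks
lib_rows <- list()
for (strain in c("WT", "RNaseE_mut", "RNaseIII_mut", "PNPase_mut")) {
  tr <- simulate_end_tracks(ann, strain, cfg)
  for (s in names(track_library_sizes(tr))) {
    write_bedgraph_set(tr, out_trk, s)
    lib_rows[[s]] <- tibble(sample_id = s, strain = strain,
                            library_size = track_library_sizes(tr)[[s]])
  }
}
libs <- bind_rows(lib_rows)
write.table(libs, file.path(out_tab, "library_sizes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Simulated", nrow(ann$srnas), "sRNAs on a",
    cfg$replicon_length, "nt replicon\n")
cat("Origin truth:", paste(names(table(truth$origin)),
                           table(truth$origin), collapse = ", "), "\n")
cat("Implanted differential ends:", nrow(truth_diff_ends(truth)),
    "across", length(unique(truth_diff_ends(truth)$enzyme)), "enzymes\n")
cat("Tracks for", nrow(libs), "samples written to", out_trk, "\n")
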