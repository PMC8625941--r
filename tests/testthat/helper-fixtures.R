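# Shared fixtures and independent brute-force oracles. The oracles
# deliberately use plain loops and arithmetic, no package internals.

random_features <- function(n, span = 2000, seed = NULL, replicon = "chr1") {
  if (!is.null(seed)) set.seed(seed)
  feature_records(
    feature_id = paste0("f", seq_len(n)),
    kind = sample(c("tss", "terminator"), n, replace = TRUE),
    replicon = replicon,
    position = sample.int(span, n, replace = TRUE) - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE))
}

# brute-force window scan: loop over every feature row
brute_window <- function(query_position, strand, flank, features) {
  keep <- logical(nrow(features))
  for (i in seq_len(nrow(features))) {
    keep[i] <- features$strand[i] == strand &&
      abs(features$position[i] - query_position) <= flank
  }
  out <- features[keep, , drop = FALSE]
  out$distance <- out$position - as.integer(query_position)
  out[order(abs(out$distance), out$position), , drop = FALSE]
}

# brute-force origin classification of a single sRNA against row-wise scans
brute_classify_one <- function(s, utrs, genes) {
  ov <- function(a1, a2, b1, b2) max(a1, b1) < min(a2, b2)
  has <- c(five_prime = FALSE, three_prime = FALSE, gene = FALSE)
  for (i in seq_len(nrow(utrs))) {
    if (utrs$strand[i] == s$strand && utrs$replicon[i] == s$replicon &&
        ov(s$start, s$end, utrs$start[i], utrs$end[i])) {
      has[utrs$kind[i]] <- TRUE
    }
  }
  for (i in seq_len(nrow(genes))) {
    if (genes$strand[i] == s$strand && genes$replicon[i] == s$replicon &&
        ov(s$start, s$end, genes$start[i], genes$end[i])) {
      has["gene"] <- TRUE
    }
  }
  if (has[["five_prime"]] && !has[["three_prime"]]) return("five_prime_utr")
  if (has[["three_prime"]] && !has[["five_prime"]]) return("three_prime_utr")
  if (has[["five_prime"]] && has[["three_prime"]]) return("unclassified")
  if (has[["gene"]]) return("unclassified")
  "orphan"
}

# brute-force mechanism assignment by an all-pairs distance scan
brute_assign <- function(srnas, features, window_default = 5,
                         window_terminator = 10, gate_ends = TRUE) {
  rows <- list()
  for (i in seq_len(nrow(srnas))) {
    s <- srnas[i, ]
    for (we in c("five_prime", "three_prime")) {
      pos <- if (we == "five_prime") s$end5 else s$end3
      found <- list()
      for (j in seq_len(nrow(features))) {
        f <- features[j, ]
        if (f$strand != s$strand || f$replicon != s$replicon) next
        if (f$kind == "tss" && (gate_ends && we != "five_prime")) next
        if (f$kind == "terminator" && (gate_ends && we != "three_prime")) next
        if (f$kind == "diff_end" && f$end_type != we) next
        if (f$kind == "diff_end" && !is.na(f$direction) &&
            f$direction != "wt_enriched") next
        w <- if (f$kind == "terminator") window_terminator else window_default
        if (abs(f$position - pos) <= w) {
          mech <- switch(f$kind, tss = "TSS", terminator = "terminator",
                         diff_end = f$enzyme)
          found[[length(found) + 1]] <-
            data.frame(srna_id = s$srna_id, which_end = we, mechanism = mech,
                       stringsAsFactors = FALSE)
        }
      }
      if (!length(found)) {
        found[[1]] <- data.frame(srna_id = s$srna_id, which_end = we,
                                 mechanism = "unknown", stringsAsFactors = FALSE)
      }
      rows <- c(rows, found)
    }
  }
  out <- unique(do.call(rbind, rows))
  out[order(out$srna_id, out$which_end, out$mechanism), , drop = FALSE]
}

sort_calls <- function(calls) {
  out <- unique(as.data.frame(calls[, c("srna_id", "which_end", "mechanism")]))
  out[order(out$srna_id, out$which_end, out$mechanism), , drop = FALSE]
}

# minimal single-end SAM with one 60 nt reference
write_test_sam <- function(reads, path = tempfile(fileext = ".sam"),
                           rname = "chr1", rlen = 400L) {
  # reads: data.frame(pos1 (1-based), len, strand, flag_extra)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", rname, rlen))
  body <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    flag <- if (r$strand == "-") 16L else 0L
    flag <- flag + (r$flag_extra %||% 0L)
    sprintf("r%03d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s", i, flag, rname,
            r$pos1, r$len, strrep("A", r$len), strrep("I", r$len))
  }, "")
  writeLines(c(hdr, body[order(reads$pos1)]), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_tracks <- function(counts_list, libs) {
  # counts_list: named list sample -> data.frame(pos, count[, strand, end_type, replicon])
  rows <- lapply(names(counts_list), function(s) {
    d <- as.data.frame(counts_list[[s]])
    d$sample_id <- s
    d$replicon <- d$replicon %||% "chr1"
    d$strand <- d$strand %||% "+"
    d$end_type <- d$end_type %||% "five_prime"
    d
  })
  end_tracks(dplyr::bind_rows(rows), libs)
}
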