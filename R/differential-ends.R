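#' Parameters for differential end calling
#'
#' The log2 fold-change cutoff (emit only `|log2FC| >= 1`) and the
#' Benjamini-Hochberg adjusted p-value threshold (`p_adj <= 0.05`) are the
#' published operating point of the analysis; `min_count` (candidate
#' selection) and `pseudocount` (fold-change stabilization) are exposed knobs.
#'
#' @param lfc_cutoff Positive log2 fold-change cutoff (default 1).
#' @param alpha BH-adjusted p-value threshold in (0, 1) (default 0.05).
#' @param min_count Candidate positions must reach this summed raw count in at
#'   least one group (default 10).
#' @param pseudocount Added to group mean CPM before the log ratio (default 0.5).
#' @param stat Test statistic used by [call_differential_ends()]:
#'   `"exact_poisson"` (default) is an exact binomial test of the pooled raw
#'   counts against the library-size proportion, conditioned on the candidate
#'   selection rule so that its null distribution stays valid for selected
#'   positions; `"welch"` is a Welch t-test on log2(CPM + pseudocount) across
#'   replicates (more robust when counts are overdispersed, less powerful at
#'   n = 3).
#' @return A `diff_end_params` list.
#' @export
diff_end_params <- function(lfc_cutoff = 1, alpha = 0.05, min_count = 10,
                            pseudocount = 0.5,
                            stat = c("exact_poisson", "welch")) {
  stat <- match.arg(stat)
  if (!(lfc_cutoff > 0)) abort("lfc_cutoff must be > 0")
  if (!(alpha > 0 && alpha < 1)) abort("alpha must be in (0, 1)")
  if (!is_count(min_count) || min_count < 1) abort("min_count must be >= 1")
  if (!(pseudocount > 0)) abort("pseudocount must be > 0")
  structure(list(lfc_cutoff = lfc_cutoff, alpha = alpha,
                 min_count = as.integer(min_count),
                 pseudocount = pseudocount, stat = stat),
            class = "diff_end_params")
}

track_combos <- function(tracks) {
  distinct(track_counts(tracks), .data$replicon, .data$strand, .data$end_type)
}

group_sums <- function(tracks, name) {
  track_counts(tracks) |>
    group_by(.data$replicon, .data$strand, .data$end_type, .data$pos) |>
    summarise("{name}" := sum(.data$count), .groups = "drop")
}

#' Candidate positions for differential end testing
#'
#' A position is a candidate when the summed raw count of at least one group
#' reaches `min_count`.
#'
#' @param wt_tracks,mut_tracks [end_tracks()] sets (replicates pooled per set).
#' @param min_count Threshold on the per-group summed raw count.
#' @return Tibble `replicon`, `strand`, `end_type`, `pos`, `wt_sum`, `mut_sum`.
#' @export
candidate_positions <- function(wt_tracks, mut_tracks, min_count = 10) {
  cw <- track_combos(wt_tracks); cm <- track_combos(mut_tracks)
  if (nrow(dplyr::symdiff(cw, cm))) {
    abort("wild-type and mutant tracks cover different replicon/strand/end_type combinations")
  }
  dplyr::full_join(group_sums(wt_tracks, "wt_sum"),
                   group_sums(mut_tracks, "mut_sum"),
                   by = c("replicon", "strand", "end_type", "pos")) |>
    mutate(wt_sum = dplyr::coalesce(.data$wt_sum, 0L),
           mut_sum = dplyr::coalesce(.data$mut_sum, 0L)) |>
    filter(pmax(.data$wt_sum, .data$mut_sum) >= min_count) |>
    arrange(.data$replicon, .data$pos, .data$strand, .data$end_type)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; output order matches
#' the input order and values are capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  n <- length(p_values)
  o <- order(p_values)
  q <- p_values[o] * n / seq_len(n)
  adj <- pmin(1, rev(cummin(rev(q))))
  adj[order(o)]
}

# Welch t-test on log2(value + pseudocount); returns two-sided p.
# Vectorized over rows of the two matrices.
welch_log_p <- function(A, B, pseudocount) {
  LA <- log2(A + pseudocount); LB <- log2(B + pseudocount)
  nA <- ncol(LA); nB <- ncol(LB)
  mA <- rowMeans(LA); mB <- rowMeans(LB)
  vA <- apply(LA, 1, var); vB <- apply(LB, 1, var)
  se2 <- vA / nA + vB / nB
  p <- rep(NA_real_, nrow(LA))
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(mA[degenerate] == mB[degenerate], 1, 0)
  i <- !degenerate
  tstat <- (mA[i] - mB[i]) / sqrt(se2[i])
  df <- se2[i]^2 / (vA[i]^2 / (nA^2 * (nA - 1)) + vB[i]^2 / (nB^2 * (nB - 1)))
  p[i] <- 2 * pt(-abs(tstat), df)
  p
}

# Exact two-sided binomial test of the pooled wild-type count against the
# library-size proportion, optionally truncated to the candidate-selection
# region {x >= min_count or total - x >= min_count}. Minimum-likelihood
# two-sided tail, as in binom.test.
exact_poisson_p <- function(wt_sum, mut_sum, wt_lib, mut_lib, min_count = NULL) {
  prob <- wt_lib / (wt_lib + mut_lib)
  mapply(function(a, b) {
    tot <- a + b
    if (tot == 0) return(1)
    x <- 0:tot
    f <- dbinom(x, tot, prob)
    sel <- if (is.null(min_count)) rep(TRUE, tot + 1) else
      (x >= min_count) | ((tot - x) >= min_count)
    if (!any(sel)) return(1)
    tail <- sel & f <= f[a + 1] * (1 + 1e-7)
    min(1, sum(f[tail]) / sum(f[sel]))
  }, wt_sum, mut_sum)
}

#' Test one position for a differential end
#'
#' Log2 fold change is `log2((mean(wt) + pc) / (mean(mut) + pc))` on
#' CPM-normalized replicate values (wild type over mutant, so enzyme-generated
#' ends come out positive). With at least two replicates per group the p-value
#' is a two-sided Welch t-test on `log2(value + pc)`; with a single replicate
#' in either group it falls back to an exact two-sided binomial test of the
#' pooled wild-type raw count against the proportion expected from the library
#' sizes (raw counts and library sizes must then be supplied).
#'
#' @param wt_norm,mut_norm CPM-normalized replicate values.
#' @param pseudocount Stabilizing constant, see [diff_end_params()].
#' @param wt_raw,mut_raw,wt_lib,mut_lib Pooled raw counts and library sizes,
#'   needed only for the single-replicate fallback.
#' @return List with `log2fc` and `p_value`.
#' @export
test_position <- function(wt_norm, mut_norm, pseudocount = 0.5,
                          wt_raw = NULL, mut_raw = NULL,
                          wt_lib = NULL, mut_lib = NULL) {
  if (!length(wt_norm) || !length(mut_norm)) abort("both groups must be non-empty")
  log2fc <- log2((mean(wt_norm) + pseudocount) / (mean(mut_norm) + pseudocount))
  if (length(wt_norm) >= 2 && length(mut_norm) >= 2) {
    p <- welch_log_p(matrix(wt_norm, 1), matrix(mut_norm, 1), pseudocount)
  } else {
    if (is.null(wt_raw) || is.null(mut_raw) || is.null(wt_lib) || is.null(mut_lib)) {
      abort("single-replicate groups need raw counts and library sizes for the exact binomial fallback")
    }
    p <- exact_poisson_p(sum(wt_raw), sum(mut_raw), sum(wt_lib), sum(mut_lib))
  }
  list(log2fc = log2fc, p_value = unname(p))
}

#' Call differential RNA 5'/3' ends between wild type and an enzyme mutant
#'
#' Candidate positions (summed raw count >= `min_count` in either group) are
#' tested per position, adjusted genome-wide with Benjamini-Hochberg across
#' all replicons, strands and end types of the comparison jointly, and
#' reported when `|log2FC| >= lfc_cutoff` and `p_adj <= alpha`. Output rows
#' are ordered by replicon, position, strand, end type.
#'
#' @param wt_tracks,mut_tracks Replicate [end_tracks()] sets.
#' @param enzyme Label for the mutated enzyme (e.g. `"RNaseE"`).
#' @param params A [diff_end_params()] object.
#' @return Tibble with columns `replicon`, `position`, `strand`, `end_type`,
#'   `enzyme`, `mean_wt`, `mean_mut` (CPM), `log2fc`, `p_value`, `p_adj`,
#'   `direction` (`wt_enriched` / `mutant_enriched`).
#' @export
call_differential_ends <- function(wt_tracks, mut_tracks, enzyme,
                                   params = diff_end_params()) {
  cand <- candidate_positions(wt_tracks, mut_tracks, params$min_count)
  empty <- tibble(replicon = character(), position = integer(),
                  strand = character(), end_type = character(),
                  enzyme = character(), mean_wt = numeric(),
                  mean_mut = numeric(), log2fc = numeric(),
                  p_value = numeric(), p_adj = numeric(),
                  direction = character())
  if (!nrow(cand)) return(empty)

  wt_mat <- replicate_matrix(wt_tracks, cand)
  mut_mat <- replicate_matrix(mut_tracks, cand)
  mean_wt <- rowMeans(wt_mat); mean_mut <- rowMeans(mut_mat)
  pc <- params$pseudocount
  log2fc <- log2((mean_wt + pc) / (mean_mut + pc))

  wt_libs <- track_library_sizes(wt_tracks); mut_libs <- track_library_sizes(mut_tracks)
  if (params$stat == "exact_poisson" || ncol(wt_mat) < 2 || ncol(mut_mat) < 2) {
    p <- exact_poisson_p(cand$wt_sum, cand$mut_sum,
                         sum(wt_libs), sum(mut_libs),
                         min_count = params$min_count)
  } else {
    p <- welch_log_p(wt_mat, mut_mat, pc)
  }
  p_adj <- benjamini_hochberg(p)

  out <- tibble(replicon = cand$replicon, position = cand$pos,
                strand = cand$strand, end_type = cand$end_type,
                enzyme = enzyme, mean_wt = mean_wt, mean_mut = mean_mut,
                log2fc = log2fc, p_value = p, p_adj = p_adj,
                direction = if_else(log2fc > 0, "wt_enriched", "mutant_enriched"))
  out |>
    filter(abs(.data$log2fc) >= params$lfc_cutoff, .data$p_adj <= params$alpha) |>
    arrange(.data$replicon, .data$position, .data$strand, .data$end_type)
}

# candidate x replicate matrix of CPM values (zeros where a sample has no count)
replicate_matrix <- function(tracks, cand) {
  norm <- normalize_cpm(tracks)
  samples <- names(track_library_sizes(tracks))
  key <- function(d, pos_col) {
    paste(d$replicon, d$strand, d$end_type, d[[pos_col]], sep = "\r")
  }
  ck <- key(cand, "pos")
  m <- matrix(0, nrow(cand), length(samples), dimnames = list(NULL, samples))
  norm <- norm[key(norm, "pos") %in% ck, , drop = FALSE]
  idx <- match(key(norm, "pos"), ck)
  m[cbind(idx, match(norm$sample_id, samples))] <- norm$cpm
  m
}

#' Convert called differential ends to point-feature records
#'
#' @param diff_ends Output of [call_differential_ends()].
#' @return A [feature_records()] tibble of kind `diff_end` (carrying enzyme,
#'   end type and direction), usable in mechanism assignment.
#' @export
diff_ends_to_features <- function(diff_ends) {
  if (!nrow(diff_ends)) {
    return(feature_records(character(), character(), character(), integer(),
                           character()))
  }
  feature_records(
    feature_id = sprintf("%s_%s_%s_%d", diff_ends$enzyme, diff_ends$end_type,
                         diff_ends$strand, diff_ends$position),
    kind = "diff_end", replicon = diff_ends$replicon,
    position = diff_ends$position, strand = diff_ends$strand,
    enzyme = diff_ends$enzyme, end_type = diff_ends$end_type,
    direction = diff_ends$direction)
}

#' Export differential ends as BED6
#'
#' Name column is `enzyme:end_type`, score is `round(10 * |log2FC|)`.
#'
#' @param diff_ends Output of [call_differential_ends()].
#' @param path Output file.
#' @export
write_diff_ends_bed <- function(diff_ends, path) {
  df <- data.frame(diff_ends$replicon, diff_ends$position,
                   diff_ends$position + 1L,
                   paste0(diff_ends$enzyme, ":", diff_ends$end_type),
                   round(10 * abs(diff_ends$log2fc)), diff_ends$strand)
  con <- file(path, "wt"); on.exit(close(con))
  if (nrow(df)) {
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
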