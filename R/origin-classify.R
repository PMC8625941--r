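#' Classify sRNAs by genomic origin
#'
#' Same-strand overlap of at least 1 nt decides membership (the BEDtools
#' `window -s` convention): overlap with 5' UTRs only gives `five_prime_utr`,
#' with 3' UTRs only `three_prime_utr`, with both kinds `unclassified`; an
#' sRNA touching no UTR is `orphan` when it also touches no gene body and
#' `unclassified` otherwise.
#'
#' @param srnas [srna_records()] tibble.
#' @param utrs [utr_records()] tibble.
#' @param genes Gene-body intervals ([genomic_intervals()] tibble; extra
#'   columns are ignored).
#' @return Character vector of classes, one per sRNA, in input order.
#' @export
classify_origin <- function(srnas, utrs, genes) {
  lv <- unique(c(srnas$replicon, utrs$replicon, genes$replicon))
  as_gr <- function(d) {
    GenomicRanges::GRanges(
      factor(d$replicon, levels = lv),
      IRanges::IRanges(d$start + 1L, d$end), strand = d$strand)
  }
  gs <- as_gr(srnas)
  overlaps_any <- function(d) {
    if (!nrow(d)) return(logical(length(gs)))
    GenomicRanges::countOverlaps(gs, as_gr(d), minoverlap = 1L) > 0
  }
  has5 <- overlaps_any(utrs[utrs$kind == "five_prime", , drop = FALSE])
  has3 <- overlaps_any(utrs[utrs$kind == "three_prime", , drop = FALSE])
  hasg <- overlaps_any(genes)
  dplyr::case_when(
    has5 & !has3 ~ "five_prime_utr",
    has3 & !has5 ~ "three_prime_utr",
    has5 & has3 ~ "unclassified",
    hasg ~ "unclassified",
    .default = "orphan")
}

#' Summarize an origin classification
#'
#' @param classes Character vector as returned by [classify_origin()].
#' @return Tibble with one row per class (`five_prime_utr`,
#'   `three_prime_utr`, `orphan`, `unclassified`), columns `origin`, `n`,
#'   `fraction`, plus a `total` attribute. Fractions sum to 1.
#' @export
summarize_origins <- function(classes) {
  if (!length(classes)) abort("cannot summarize an empty classification")
  lev <- c("five_prime_utr", "three_prime_utr", "orphan", "unclassified")
  if (!all(classes %in% lev)) abort("unknown origin class label")
  n <- as.integer(table(factor(classes, levels = lev)))
  out <- tibble(origin = lev, n = n, fraction = n / length(classes))
  attr(out, "total") <- length(classes)
  out
}
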