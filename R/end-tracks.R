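#' End-count track sets
#'
#' An end-count track records, per replicon, strand and end type (5' or 3'),
#' how many reads start or stop at each genomic position. A track *set* holds
#' the sparse counts of one or more samples in a single tidy table together
#' with per-sample library sizes (counted reads), the denominator for CPM
#' normalization.
#'
#' @param counts Tibble with columns `sample_id`, `replicon`, `strand`,
#'   `end_type`, `pos` (0-based), `count` (non-negative integer). Zero counts
#'   may be omitted.
#' @param library_sizes Named numeric vector, one entry per `sample_id`.
#' @return An object of class `end_tracks`.
#' @export
end_tracks <- function(counts, library_sizes) {
  counts <- as_tibble(counts)
  need <- c("sample_id", "replicon", "strand", "end_type", "pos", "count")
  if (!all(need %in% names(counts))) {
    abort(paste("track counts need columns:", paste(need, collapse = ", ")))
  }
  if (any(counts$count < 0) || any(counts$count != floor(counts$count))) {
    abort("end counts must be non-negative integers")
  }
  if (!all(counts$strand %in% .STRANDS)) abort("strand must be '+' or '-'")
  if (!all(counts$end_type %in% .END_TYPES)) {
    abort("end_type must be five_prime or three_prime")
  }
  samples <- unique(counts$sample_id)
  if (is.null(names(library_sizes)) ||
      !all(samples %in% names(library_sizes))) {
    abort("library_sizes must be named and cover every sample_id")
  }
  structure(list(counts = counts,
                 library_sizes = library_sizes[unique(names(library_sizes))]),
            class = "end_tracks")
}

#' @export
print.end_tracks <- function(x, ...) {
  cat("<end_tracks> ", length(x$library_sizes), " sample(s), ",
      nrow(x$counts), " nonzero positions\n", sep = "")
  invisible(x)
}

#' @rdname end_tracks
#' @param x An `end_tracks` object.
#' @export
track_counts <- function(x) x$counts

#' @rdname end_tracks
#' @export
track_library_sizes <- function(x) x$library_sizes

#' Combine track sets from several samples
#'
#' @param ... `end_tracks` objects with distinct sample ids.
#' @export
bind_tracks <- function(...) {
  xs <- list(...)
  counts <- bind_rows(lapply(xs, track_counts))
  libs <- do.call(c, lapply(xs, track_library_sizes))
  if (anyDuplicated(names(libs))) abort("duplicate sample ids in bind_tracks()")
  end_tracks(counts, libs)
}

#' Count read 5' and 3' ends from an alignment file
#'
#' For a forward-strand read aligned to `[s, e)` (0-based half-open span of
#' the aligned bases, soft clips excluded) the 5'-end track gains a count at
#' `s` and the 3'-end track at `e - 1`; reverse-strand reads are mirrored.
#' Unmapped, secondary and supplementary records are skipped. With
#' `paired = "mates"`, only the first mate defines the fragment 5' end and
#' only the second mate the fragment 3' end (on the first mate's strand);
#' unpaired reads are counted as single-end either way.
#'
#' @param path BAM file (SAM files are converted on the fly).
#' @param sample_id Sample label for the resulting tracks.
#' @param paired `"ignore"` (treat every record as single-end) or `"mates"`.
#' @return An [end_tracks()] set; `library_size` is the number of counted
#'   units (reads, or fragments for the paired mode).
#' @export
count_read_ends <- function(path, sample_id, paired = c("ignore", "mates")) {
  paired <- match.arg(paired)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = TRUE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = "flag")
  aln <- GenomicAlignments::readGAlignments(path, param = param)
  if (!length(aln)) {
    return(end_tracks(tibble(sample_id = character(), replicon = character(),
                             strand = character(), end_type = character(),
                             pos = integer(), count = integer()),
                      setNames(0, sample_id)))
  }
  flag <- S4Vectors::mcols(aln)$flag
  s0 <- BiocGenerics::start(aln) - 1L
  e0 <- BiocGenerics::end(aln)          # half-open end of aligned span
  str <- as.character(BiocGenerics::strand(aln))
  repl <- as.character(GenomeInfoDb::seqnames(aln))
  own5 <- ifelse(str == "+", s0, e0 - 1L)
  own3 <- ifelse(str == "+", e0 - 1L, s0)

  is_paired <- bitwAnd(flag, 1L) > 0L
  if (paired == "mates" && any(is_paired)) {
    first <- bitwAnd(flag, 64L) > 0L
    second <- bitwAnd(flag, 128L) > 0L
    single <- !is_paired
    rows <- bind_rows(
      tibble(replicon = repl[single | first],
             strand = str[single | first],
             end_type = "five_prime", pos = own5[single | first]),
      tibble(replicon = repl[single], strand = str[single],
             end_type = "three_prime", pos = own3[single]),
      # mate 2 marks the fragment 3' end; fragment strand is the opposite of
      # its own alignment strand
      tibble(replicon = repl[second],
             strand = ifelse(str[second] == "+", "-", "+"),
             end_type = "three_prime", pos = own5[second]))
    n_units <- sum(single) + sum(first)
  } else {
    rows <- bind_rows(
      tibble(replicon = repl, strand = str, end_type = "five_prime", pos = own5),
      tibble(replicon = repl, strand = str, end_type = "three_prime", pos = own3))
    n_units <- length(aln)
  }
  counts <- rows |>
    count(.data$replicon, .data$strand, .data$end_type, .data$pos,
          name = "count") |>
    mutate(sample_id = sample_id, .before = 1)
  end_tracks(counts, setNames(n_units, sample_id))
}

#' CPM-normalize end-count tracks
#'
#' Multiplies every count by `1e6 / library_size` of its sample.
#'
#' @param tracks An [end_tracks()] set with positive library sizes.
#' @return The counts tibble with an extra `cpm` column.
#' @export
normalize_cpm <- function(tracks) {
  libs <- track_library_sizes(tracks)
  used <- unique(track_counts(tracks)$sample_id)
  if (any(libs[used] < 1)) abort("library_size must be >= 1 for CPM normalization")
  mutate(track_counts(tracks),
         cpm = .data$count * 1e6 / unname(libs[.data$sample_id]))
}

#' Read one bedGraph file into an end-count track
#'
#' bedGraph intervals (0-based half-open) are expanded to per-position counts.
#' Overlapping intervals are rejected: per-position counts would be ambiguous.
#'
#' @param path bedGraph file.
#' @param sample_id,strand,end_type Track labels (bedGraph itself is unstranded).
#' @param library_size Library size to attach; default, the sum of counts.
#' @return An [end_tracks()] set with one component track.
#' @export
read_bedgraph <- function(path, sample_id, strand, end_type, library_size = NULL) {
  stopifnot(strand %in% .STRANDS, end_type %in% .END_TYPES)
  empty <- tibble(sample_id = character(), replicon = character(),
                  strand = character(), end_type = character(),
                  pos = integer(), count = integer())
  if (!length(readLines(path, warn = FALSE))) {
    return(end_tracks(empty, setNames(library_size %||% 0, sample_id)))
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!IRanges::isDisjoint(GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                                  IRanges::ranges(gr)))) {
    abort("overlapping bedGraph intervals: per-position counts are ambiguous")
  }
  w <- BiocGenerics::width(gr)
  counts <- tibble(
    sample_id = sample_id,
    replicon = rep(as.character(GenomeInfoDb::seqnames(gr)), w),
    strand = strand, end_type = end_type,
    pos = unlist(lapply(seq_along(gr), function(i) {
      seq.int(BiocGenerics::start(gr)[i] - 1L, length.out = w[i])
    })),
    count = rep(S4Vectors::mcols(gr)$score, w))
  counts <- filter(counts, .data$count != 0)
  end_tracks(counts, setNames(library_size %||% sum(counts$count), sample_id))
}

#' Write one component track as bedGraph
#'
#' Adjacent positions with equal counts are merged into one interval.
#'
#' @param tracks An [end_tracks()] set.
#' @param path Output file.
#' @param sample_id,strand,end_type Which component to write.
#' @export
write_bedgraph <- function(tracks, path, sample_id, strand, end_type) {
  cc <- filter(track_counts(tracks), .data$sample_id == !!sample_id,
               .data$strand == !!strand, .data$end_type == !!end_type) |>
    arrange(.data$replicon, .data$pos)
  if (!nrow(cc)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  runs <- cc |>
    mutate(new_run = .data$replicon != lag(.data$replicon, default = "") |
             .data$pos != lag(.data$pos, default = -2L) + 1L |
             .data$count != lag(.data$count, default = -1L)) |>
    mutate(run = cumsum(.data$new_run)) |>
    group_by(.data$run) |>
    summarise(replicon = .data$replicon[1], start = min(.data$pos),
              end = max(.data$pos) + 1L, count = .data$count[1],
              .groups = "drop")
  write.table(runs[, c("replicon", "start", "end", "count")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write all four component tracks of one sample
#'
#' Files follow the `<sample>.<plus|minus>.<5p|3p>.bedgraph` naming scheme.
#'
#' @param tracks An [end_tracks()] set.
#' @param dir Output directory (created if missing).
#' @param sample_id Sample to export.
#' @return Character vector of the four file paths.
#' @export
write_bedgraph_set <- function(tracks, dir, sample_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- expand.grid(strand = .STRANDS, end_type = .END_TYPES,
                      stringsAsFactors = FALSE)
  vapply(seq_len(nrow(grid)), function(i) {
    f <- file.path(dir, sprintf("%s.%s.%s.bedgraph", sample_id,
                                if (grid$strand[i] == "+") "plus" else "minus",
                                if (grid$end_type[i] == "five_prime") "5p" else "3p"))
    write_bedgraph(tracks, f, sample_id, grid$strand[i], grid$end_type[i])
    f
  }, "")
}
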