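#' Stranded genomic interval records
#'
#' All coordinates inside the package are 0-based, half-open (`start` inclusive,
#' `end` exclusive). File readers and writers convert at the boundary: GFF3 is
#' 1-based inclusive, BED and bedGraph are 0-based half-open.
#'
#' @param replicon Character vector of replicon (chromosome/plasmid) names.
#' @param start,end Integer vectors, 0-based half-open; `0 <= start < end`.
#' @param strand Character vector, each element `"+"` or `"-"`.
#' @return A tibble with columns `replicon`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(replicon, start, end, strand) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(!nzchar(replicon)) || anyNA(replicon)) {
    abort("replicon ids must be non-empty")
  }
  if (anyNA(start) || anyNA(end) || any(start < 0L) || any(start >= end)) {
    abort("intervals require 0 <= start < end")
  }
  if (!all(strand %in% .STRANDS)) {
    abort("strand must be '+' or '-'")
  }
  tibble(replicon = as.character(replicon), start = start, end = end,
         strand = as.character(strand))
}

#' sRNA records with derived single-nucleotide end positions
#'
#' An sRNA's 5' and 3' ends are treated as single nucleotides (the first and
#' last transcribed base). On the `+` strand `end5 = start` and
#' `end3 = end - 1`; on the `-` strand the two are swapped.
#'
#' @param srna_id Unique sRNA identifiers.
#' @inheritParams genomic_intervals
#' @return Tibble with `srna_id`, interval columns, `end5`, `end3`.
#' @export
srna_records <- function(srna_id, replicon, start, end, strand) {
  if (anyDuplicated(srna_id)) abort("srna_id values must be unique")
  iv <- genomic_intervals(replicon, start, end, strand)
  mutate(tibble(srna_id = as.character(srna_id), iv),
         end5 = if_else(.data$strand == "+", .data$start, .data$end - 1L),
         end3 = if_else(.data$strand == "+", .data$end - 1L, .data$start))
}

#' UTR records
#'
#' @param gene_id Identifier of the gene the UTR belongs to.
#' @param kind `"five_prime"` or `"three_prime"`.
#' @inheritParams genomic_intervals
#' @return Tibble with `gene_id`, `kind` and interval columns.
#' @export
utr_records <- function(gene_id, kind, replicon, start, end, strand) {
  if (!all(kind %in% .END_TYPES)) abort("UTR kind must be five_prime or three_prime")
  tibble(gene_id = as.character(gene_id), kind = as.character(kind),
         genomic_intervals(replicon, start, end, strand))
}

#' Point-anchored feature records
#'
#' Features carry a single anchor coordinate: TSS are the initiating
#' nucleotide, terminators are anchored at the 3'-most base of the annotated
#' terminator interval on their strand, and differential ends are the tested
#' position. Differential-end features additionally carry the enzyme label,
#' the end type they explain, and the enrichment direction.
#'
#' @param feature_id Identifiers.
#' @param kind One of `"tss"`, `"terminator"`, `"diff_end"` per feature.
#' @param replicon,position,strand Anchor coordinates (0-based position).
#' @param enzyme,end_type,direction Optional payload columns for `diff_end`
#'   features (`NA` otherwise).
#' @return Tibble of features.
#' @export
feature_records <- function(feature_id, kind, replicon, position, strand,
                            enzyme = NA_character_, end_type = NA_character_,
                            direction = NA_character_) {
  if (!all(kind %in% c("tss", "terminator", "diff_end"))) {
    abort("feature kind must be one of tss, terminator, diff_end")
  }
  position <- as.integer(position)
  if (anyNA(position) || any(position < 0L)) abort("feature position must be >= 0")
  if (!all(strand %in% .STRANDS)) abort("strand must be '+' or '-'")
  if (any(kind == "diff_end" & (is.na(enzyme) | is.na(end_type)))) {
    abort("diff_end features require enzyme and end_type payload")
  }
  tibble(feature_id = as.character(feature_id), kind = as.character(kind),
         replicon = as.character(replicon), position = position,
         strand = as.character(strand), enzyme = as.character(enzyme),
         end_type = as.character(end_type), direction = as.character(direction))
}

#' Default mapping from GFF3 feature types to internal record kinds
#'
#' @return Named character vector; names are GFF3 `type` values, values are
#'   internal kinds (`srna`, `gene`, `five_prime_utr`, `three_prime_utr`,
#'   `tss`, `terminator`).
#' @export
gff3_type_map <- function() {
  c(sRNA = "srna", ncRNA = "srna", small_regulatory_ncRNA = "srna",
    gene = "gene", CDS = "gene",
    five_prime_UTR = "five_prime_utr", three_prime_UTR = "three_prime_utr",
    TSS = "tss", transcription_start_site = "tss",
    terminator = "terminator", Rho_independent_terminator = "terminator")
}

#' Parse a GFF3 annotation file
#'
#' Reads GFF3 (1-based inclusive) and converts to the internal 0-based
#' half-open convention. Records are typed through `type_map`; GFF3 types
#' absent from the map are kept with kind `"other"`. Lines whose strand column
#' is neither `+` nor `-` are dropped with a warning; lines without nine
#' tab-separated columns raise an error naming the line.
#'
#' @param path GFF3 file.
#' @param type_map Named character vector, see [gff3_type_map()].
#' @param shift Integer offset added to both coordinates after conversion
#'   (for imported predictions whose coordinate convention is in doubt).
#' @return Tibble with columns `record_kind`, `type`, `id`, `gene_id`,
#'   `replicon`, `start`, `end`, `strand`.
#' @export
parse_gff3 <- function(path, type_map = gff3_type_map(), shift = 0L) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^#", lines) & nzchar(trimws(lines))
  empty_out <- tibble(record_kind = character(), type = character(),
                      id = character(), gene_id = character(),
                      replicon = character(), start = integer(),
                      end = integer(), strand = character())
  if (!any(body)) return(empty_out)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1]]
    abort(sprintf("malformed GFF3 line %d: expected 9 tab-separated columns", bad))
  }
  strand_col <- vapply(fields, `[[`, "", 7L)
  bad_strand <- !(strand_col %in% .STRANDS)
  if (any(bad_strand)) {
    warn(sprintf("dropping %d GFF3 record(s) with unknown strand symbol", sum(bad_strand)))
    fields <- fields[!bad_strand]
    if (!length(fields)) return(empty_out)
  }
  # validated above; rtracklayer does the attribute/coordinate parsing
  tmp <- tempfile(fileext = ".gff3")
  on.exit(unlink(tmp))
  writeLines(c("##gff-version 3",
               vapply(fields, paste, "", collapse = "\t")), tmp)
  gr <- rtracklayer::import(tmp, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  id <- if (!is.null(mc$ID)) as.character(mc$ID) else rep(NA_character_, length(gr))
  nm <- if (!is.null(mc$Name)) as.character(mc$Name) else rep(NA_character_, length(gr))
  id <- ifelse(is.na(id), nm, id)
  id <- ifelse(is.na(id), paste0(type, "_", seq_along(gr)), id)
  parent <- if (!is.null(mc$Parent)) {
    vapply(mc$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_, "")
  } else rep(NA_character_, length(gr))
  tibble(
    record_kind = unname(ifelse(type %in% names(type_map), type_map[type], "other")),
    type = type, id = id,
    gene_id = ifelse(is.na(parent), id, parent),
    replicon = as.character(GenomeInfoDb::seqnames(gr)),
    start = as.integer(BiocGenerics::start(gr)) - 1L + as.integer(shift),
    end = as.integer(BiocGenerics::end(gr)) + as.integer(shift),
    strand = as.character(BiocGenerics::strand(gr)))
}

#' Write records to GFF3
#'
#' Inverse of [parse_gff3()]: internal 0-based half-open coordinates are
#' converted back to 1-based inclusive.
#'
#' @param records Tibble with `type`, `id`, `replicon`, `start`, `end`, `strand`.
#' @param path Output file.
#' @export
write_gff3 <- function(records, path) {
  gr <- GenomicRanges::GRanges(
    records$replicon,
    IRanges::IRanges(records$start + 1L, records$end),
    strand = records$strand)
  S4Vectors::mcols(gr)$type <- records$type
  S4Vectors::mcols(gr)$ID <- records$id
  S4Vectors::mcols(gr)$source <- "srnaends"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# pick the identifier column of a record tibble
record_ids <- function(records) {
  for (col in c("srna_id", "feature_id", "gene_id", "id")) {
    if (col %in% names(records)) return(as.character(records[[col]]))
  }
  as.character(seq_len(nrow(records)))
}

#' Write interval- or point-anchored records as BED6
#'
#' BED is 0-based half-open, matching the internal convention, so coordinates
#' pass through unchanged; point features become 1-nt intervals. The score
#' column is 0 and strand is preserved.
#'
#' @param records Tibble with `replicon`, `strand` and either `start`/`end` or
#'   `position` columns.
#' @param path Output file.
#' @export
write_bed <- function(records, path) {
  if (!"start" %in% names(records) && "position" %in% names(records)) {
    records <- mutate(records, start = .data$position, end = .data$position + 1L)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(records)) {
    df <- data.frame(records$replicon, records$start, records$end,
                     record_ids(records), 0L, records$strand)
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a BED file into interval records
#'
#' @param path BED file.
#' @return Tibble with `id`, `replicon`, `start`, `end`, `strand`, `score`.
#' @export
read_bed <- function(path) {
  if (!length(readLines(path, warn = FALSE))) {
    return(tibble(id = character(), replicon = character(), start = integer(),
                  end = integer(), strand = character(), score = numeric()))
  }
  gr <- rtracklayer::import(path, format = "bed")
  tibble(id = S4Vectors::mcols(gr)$name %||% as.character(seq_along(gr)),
         replicon = as.character(GenomeInfoDb::seqnames(gr)),
         start = as.integer(BiocGenerics::start(gr)) - 1L,
         end = as.integer(BiocGenerics::end(gr)),
         strand = as.character(BiocGenerics::strand(gr)),
         score = S4Vectors::mcols(gr)$score %||% rep(0, length(gr)))
}

#' Strand-aware window query around a position
#'
#' Returns every feature on the same strand (and replicon, when given) whose
#' anchor lies within `flank` nucleotides of `query_position`, boundaries
#' included — the "-5 nt to +5 nt" window rule with `flank = 5`. Results are
#' ordered by absolute distance, then position.
#'
#' @param query_position Integer genomic position (0-based).
#' @param strand `"+"` or `"-"`.
#' @param flank Non-negative window half-width in nt.
#' @param features Feature tibble (see [feature_records()]).
#' @param replicon Optional replicon filter.
#' @return The matching feature rows with an extra `distance` column
#'   (`position - query_position`, genomic orientation).
#' @export
window_query <- function(query_position, strand, flank, features, replicon = NULL) {
  if (!is.numeric(flank) || length(flank) != 1 || is.na(flank) || flank < 0) {
    abort("flank must be a non-negative number")
  }
  sub <- features[features$strand == strand, , drop = FALSE]
  if (!is.null(replicon)) sub <- sub[sub$replicon == replicon, , drop = FALSE]
  if (!nrow(sub)) return(mutate(sub, distance = integer()))
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(query_position - flank, query_position + flank),
    IRanges::IRanges(sub$position, width = 1L))
  out <- sub[S4Vectors::subjectHits(hits), , drop = FALSE]
  out$distance <- out$position - as.integer(query_position)
  out[order(abs(out$distance), out$position), , drop = FALSE]
}
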