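#' Assign generation mechanisms to sRNA 5' and 3' ends
#'
#' Every feature whose anchor falls within the kind-specific window of an sRNA
#' end is considered a potential generation mechanism for that end; when
#' several features qualify, all are kept. The windows are inclusive on both
#' boundaries: ±`window_default` nt (default ±5) for TSS and differential
#' ends, ±`window_terminator` nt (default ±10) for Rho-independent
#' terminators. By default TSS are eligible only for 5' ends and terminators
#' only for 3' ends (`gate_ends = FALSE` mimics a naive windowed overlap);
#' differential ends are always matched to the sRNA end of the same end type,
#' and only those in the configured enrichment direction count (wild-type
#' enriched ends mark enzyme-generated ends; mutant-enriched ends reflect
#' precursor accumulation). Ends with no qualifying feature are `unknown`.
#'
#' @param srnas [srna_records()] tibble.
#' @param features [feature_records()] tibble (TSS, terminators and
#'   differential ends together; see [diff_ends_to_features()]).
#' @param window_default,window_terminator Window half-widths in nt.
#' @param gate_ends Restrict TSS to 5' ends and terminators to 3' ends.
#' @param diff_direction Direction filter for differential-end features
#'   (`"wt_enriched"`, `"mutant_enriched"` or `"both"`).
#' @return Long tibble with one row per (sRNA end, mechanism):
#'   `srna_id`, `which_end`, `mechanism` (`"TSS"`, `"terminator"`, an enzyme
#'   label, or `"unknown"`), `distance` (signed offset in transcription
#'   direction: positive = downstream of the end; `NA` for unknown) and
#'   `feature_id`.
#' @export
assign_end_mechanisms <- function(srnas, features,
                                  window_default = 5, window_terminator = 10,
                                  gate_ends = TRUE,
                                  diff_direction = c("wt_enriched",
                                                     "mutant_enriched", "both")) {
  diff_direction <- match.arg(diff_direction)
  if (nrow(features) &&
      (anyNA(features$kind) ||
       !all(features$kind %in% c("tss", "terminator", "diff_end")))) {
    abort("every feature must be labeled tss, terminator or diff_end")
  }
  if (diff_direction != "both" && "direction" %in% names(features)) {
    features <- features[features$kind != "diff_end" |
                           is.na(features$direction) |
                           features$direction == diff_direction, , drop = FALSE]
  }
  rows <- vector("list", 2L * nrow(srnas))
  k <- 0L
  for (i in seq_len(nrow(srnas))) {
    s <- srnas[i, ]
    for (which_end in .END_TYPES) {
      end_pos <- if (which_end == "five_prime") s$end5 else s$end3
      elig <- features$kind == "diff_end" & features$end_type == which_end
      if (gate_ends) {
        if (which_end == "five_prime") elig <- elig | features$kind == "tss"
        else elig <- elig | features$kind == "terminator"
      } else {
        elig <- elig | features$kind %in% c("tss", "terminator")
      }
      fe <- features[elig, , drop = FALSE]
      hit <- bind_rows(
        window_query(end_pos, s$strand, window_default,
                     fe[fe$kind != "terminator", , drop = FALSE], s$replicon),
        window_query(end_pos, s$strand, window_terminator,
                     fe[fe$kind == "terminator", , drop = FALSE], s$replicon))
      k <- k + 1L
      if (nrow(hit)) {
        mech <- ifelse(hit$kind == "tss", "TSS",
                       ifelse(hit$kind == "terminator", "terminator", hit$enzyme))
        rows[[k]] <- tibble(
          srna_id = s$srna_id, which_end = which_end, mechanism = mech,
          distance = if (s$strand == "+") hit$distance else -hit$distance,
          feature_id = hit$feature_id)
      } else {
        rows[[k]] <- tibble(srna_id = s$srna_id, which_end = which_end,
                            mechanism = "unknown", distance = NA_integer_,
                            feature_id = NA_character_)
      }
    }
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(srna_id = character(), which_end = character(),
                  mechanism = character(), distance = integer(),
                  feature_id = character())
  }
  distinct(out, .data$srna_id, .data$which_end, .data$mechanism,
           .data$feature_id, .keep_all = TRUE)
}

#' Summarize mechanism calls by origin class and end
#'
#' Incidence counts per (origin class, end, mechanism); an end carrying
#' several mechanisms increments several cells, and `unknown` is counted like
#' any other mechanism.
#'
#' @param calls Output of [assign_end_mechanisms()].
#' @param origins Tibble with `srna_id` and `origin` for every sRNA in `calls`.
#' @return Tibble `origin`, `which_end`, `mechanism`, `n`.
#' @export
summarize_mechanisms <- function(calls, origins) {
  missing <- setdiff(unique(calls$srna_id), origins$srna_id)
  if (length(missing)) {
    abort(paste0("no origin class for sRNA(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  calls |>
    inner_join(origins[, c("srna_id", "origin")], by = "srna_id") |>
    count(.data$origin, .data$which_end, .data$mechanism, name = "n") |>
    arrange(.data$origin, .data$which_end, .data$mechanism)
}
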