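#' Loading-control normalization of a blot signal
#'
#' Divides the probe signal by the loading-control (5S rRNA) signal of the
#' same lane.
#'
#' @param raw_intensity Non-negative probe intensity.
#' @param loading_intensity Positive loading-control intensity (same lane).
#' @return `raw_intensity / loading_intensity`, vectorized.
#' @export
normalize_signal <- function(raw_intensity, loading_intensity) {
  if (any(loading_intensity <= 0)) abort("loading_intensity must be > 0")
  if (any(raw_intensity < 0)) abort("raw_intensity must be >= 0")
  raw_intensity / loading_intensity
}

#' Log2 fold change between two replicate groups
#'
#' Default is the log2 ratio of group means (treated over reference); the
#' paired mode averages per-pair log2 ratios instead, for lanes compared on
#' the same membrane.
#'
#' @param treated,reference Positive replicate values (normalized signals).
#' @param paired Use replicate-wise pairing (requires equal lengths).
#' @return A single log2 fold change.
#' @export
log2_fold_change <- function(treated, reference, paired = FALSE) {
  if (!length(treated) || !length(reference)) abort("both groups must be non-empty")
  if (paired) {
    if (length(treated) != length(reference)) {
      abort("paired mode needs matched replicates")
    }
    if (any(treated <= 0) || any(reference <= 0)) {
      abort("paired log ratios need positive values")
    }
    return(mean(log2(treated / reference)))
  }
  mt <- mean(treated); mr <- mean(reference)
  if (mt <= 0 || mr <= 0) abort("group means must be positive")
  log2(mt / mr)
}

#' Trend classification of a log2 fold change
#'
#' Strictly greater than `threshold` is `"increased"`, strictly less than
#' `-threshold` is `"decreased"`, everything else (boundaries included) is
#' `"no_change"`.
#'
#' @param lfc Finite log2 fold change(s).
#' @param threshold Positive classification threshold (default 0.65).
#' @return Character vector of trend classes.
#' @export
classify_trend <- function(lfc, threshold = 0.65) {
  if (!(threshold > 0)) abort("threshold must be > 0")
  if (any(!is.finite(lfc))) abort("lfc must be finite")
  dplyr::case_when(lfc > threshold ~ "increased",
                   lfc < -threshold ~ "decreased",
                   .default = "no_change")
}

#' Mature/precursor signal ratio per replicate
#'
#' Element-wise ratio of matched replicates. Because both species are read
#' from the same lane, the loading control cancels: raw and normalized
#' intensities give the same ratio. Replicates with non-positive precursor
#' signal are unquantifiable and returned as `NA` with a warning.
#'
#' @param mature,precursor Matched replicate values (raw or normalized).
#' @return Numeric vector of ratios.
#' @export
mature_precursor_ratio <- function(mature, precursor) {
  if (length(mature) != length(precursor)) abort("replicates must be matched")
  out <- ifelse(precursor > 0, mature / precursor, NA_real_)
  if (anyNA(out)) warn("precursor signal too low for quantification in some replicates")
  out
}

#' Two-sided Student's t-test (pooled variance)
#'
#' Classical equal-variance t-test with `df = n_a + n_b - 2`. When the pooled
#' variance is zero the convention is `t = 0, p = 1` for equal means and
#' `p = 0` otherwise.
#'
#' @param group_a,group_b Numeric vectors with at least 2 values each.
#' @return List with `t`, `df`, `p`.
#' @export
students_t_two_sided <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 values")
  }
  df <- length(group_a) + length(group_b) - 2
  # same degeneracy criterion as stats::t.test ("data are essentially constant")
  stderr_ab <- sqrt(var(group_a) / length(group_a) + var(group_b) / length(group_b))
  if (stderr_ab < 10 * .Machine$double.eps * max(abs(mean(group_a)),
                                                 abs(mean(group_b)))) {
    if (isTRUE(all.equal(mean(group_a), mean(group_b)))) {
      return(list(t = 0, df = df, p = 1))
    }
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf, df = df, p = 0))
  }
  fit <- t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(fit$statistic), df = unname(fit$parameter), p = fit$p.value)
}

#' Trend agreement between sRNA levels and promoter activities
#'
#' Compares per-condition trend classes: both sides in the same non-neutral
#' class (or both `no_change`) agree, opposite directions disagree, and a
#' `no_change` on exactly one side is a partial call.
#'
#' @param srna_trends,promoter_trends Named character vectors
#'   (condition -> trend class); only shared conditions are compared.
#' @return Tibble `condition`, `srna`, `promoter`, `agreement`
#'   (`agree`/`partial`/`disagree`) with attribute `n_agree`.
#' @export
trend_agreement <- function(srna_trends, promoter_trends) {
  keys <- intersect(names(srna_trends), names(promoter_trends))
  if (!length(keys)) abort("no shared conditions between the two trend maps")
  a <- srna_trends[keys]; b <- promoter_trends[keys]
  out <- tibble(
    condition = keys, srna = unname(a), promoter = unname(b),
    agreement = dplyr::case_when(
      a == b ~ "agree",
      xor(a == "no_change", b == "no_change") ~ "partial",
      .default = "disagree"))
  attr(out, "n_agree") <- sum(out$agreement == "agree")
  out
}

#' Read a densitometry signal table
#'
#' Expected CSV schema: `sample_id, condition, replicate, probe, species,
#' raw_intensity, loading_intensity` with `species` in
#' `{mature, precursor}`.
#'
#' @param path CSV file.
#' @return Validated tibble with a `normalized` column added.
#' @export
read_signal_table <- function(path) {
  d <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("sample_id", "condition", "replicate", "probe", "species",
            "raw_intensity", "loading_intensity")
  if (!all(need %in% names(d))) {
    abort(paste("signal table needs columns:", paste(need, collapse = ", ")))
  }
  if (!all(d$species %in% c("mature", "precursor"))) {
    abort("species must be mature or precursor")
  }
  mutate(d, normalized = normalize_signal(.data$raw_intensity,
                                          .data$loading_intensity))
}

#' Read a promoter-fluorescence table
#'
#' Expected CSV schema: `sample_id, construct, condition, replicate,
#' fluorescence, od660`. Adds the per-cell activity proxy
#' `f_over_od = fluorescence / od660`, after optional blank subtraction.
#'
#' @param path CSV file.
#' @param blank Background fluorescence subtracted before the ratio.
#' @return Validated tibble with `f_over_od`.
#' @export
read_fluor_table <- function(path, blank = 0) {
  d <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("sample_id", "construct", "condition", "replicate",
            "fluorescence", "od660")
  if (!all(need %in% names(d))) {
    abort(paste("fluorescence table needs columns:", paste(need, collapse = ", ")))
  }
  if (any(d$od660 <= 0)) abort("od660 must be > 0")
  mutate(d, f_over_od = (.data$fluorescence - blank) / .data$od660)
}

#' Per-probe fold changes and trends against a reference condition
#'
#' For the chosen species, normalized replicate signals are averaged per
#' probe and condition; every non-reference condition is compared to the
#' reference by [log2_fold_change()] and classified by [classify_trend()].
#'
#' @param signals Tibble from [read_signal_table()] (or of the same shape
#'   with a `normalized` column).
#' @param reference_condition Condition used as the denominator.
#' @param species `"mature"` (default) or `"precursor"`.
#' @param threshold Trend threshold, see [classify_trend()].
#' @param paired Replicate-wise pairing for the fold change.
#' @return Tibble `probe`, `condition`, `log2fc`, `trend`.
#' @export
probe_fold_changes <- function(signals, reference_condition,
                               species = "mature", threshold = 0.65,
                               paired = FALSE) {
  d <- filter(signals, .data$species == !!species)
  if (!reference_condition %in% d$condition) {
    abort(paste0("reference condition '", reference_condition, "' not in table"))
  }
  conds <- setdiff(unique(d$condition), reference_condition)
  grid <- expand.grid(probe = unique(d$probe), condition = conds,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    ref <- d$normalized[d$probe == grid$probe[i] &
                          d$condition == reference_condition]
    trt <- d$normalized[d$probe == grid$probe[i] &
                          d$condition == grid$condition[i]]
    lfc <- log2_fold_change(trt, ref, paired = paired)
    tibble(probe = grid$probe[i], condition = grid$condition[i],
           log2fc = lfc, trend = classify_trend(lfc, threshold))
  })
  arrange(bind_rows(out), .data$probe, .data$condition)
}

#' Per-replicate mature/precursor ratios from a signal table
#'
#' Mature and precursor rows are matched by probe, condition and replicate.
#'
#' @param signals Tibble from [read_signal_table()].
#' @return Tibble `probe`, `condition`, `replicate`, `ratio`.
#' @export
ratio_table <- function(signals) {
  wide <- tidyr::pivot_wider(
    select(signals, "probe", "condition", "replicate", "species", "normalized"),
    names_from = "species", values_from = "normalized")
  if (!all(c("mature", "precursor") %in% names(wide))) {
    abort("ratio_table needs both mature and precursor rows")
  }
  mutate(wide, ratio = mature_precursor_ratio(.data$mature, .data$precursor)) |>
    select("probe", "condition", "replicate", "ratio") |>
    arrange(.data$probe, .data$condition, .data$replicate)
}

#' Student's t comparison of mature/precursor ratios between two conditions
#'
#' @param signals Tibble from [read_signal_table()].
#' @param probe Probe (sRNA) name.
#' @param cond_a,cond_b Conditions to compare.
#' @param log_ratios Test log-transformed ratios instead of raw ratios.
#' @return Tibble `probe`, `cond_a`, `cond_b`, `t`, `df`, `p`.
#' @export
compare_ratio_conditions <- function(signals, probe, cond_a, cond_b,
                                     log_ratios = FALSE) {
  rt <- ratio_table(signals)
  a <- rt$ratio[rt$probe == probe & rt$condition == cond_a]
  b <- rt$ratio[rt$probe == probe & rt$condition == cond_b]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (log_ratios) { a <- log2(a); b <- log2(b) }
  tt <- students_t_two_sided(a, b)
  tibble(probe = probe, cond_a = cond_a, cond_b = cond_b,
         t = tt$t, df = tt$df, p = tt$p)
}
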