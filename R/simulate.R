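#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study design the pipeline is built for: a master set
#' of 79 sRNAs in origin proportions echoing the published classification
#' (38 orphan : 14 from 5' UTRs : 16 from 3' UTRs among the assignable
#' classes), biological triplicates, sharp enzyme-dependent end positions
#' with mean depth `signal_depth` that retain only `mutant_residual` of their
#' signal in the cognate ribonuclease mutant, and Poisson background noise at
#' rate `background_rate` per position. Mechanism probabilities are drawn
#' separately for 5' ends (TSS, RNase E, RNase III, PNPase, unknown) and 3'
#' ends (terminator, RNase E, RNase III, PNPase, unknown).
#'
#' @param seed Master seed; per-(strain, replicate) streams are derived from
#'   it by fixed offsets (keep it below 2^31 - 1e6).
#' @param replicon_id,replicon_length Replicon name and length (nt).
#' @param n_srnas Number of sRNA loci to place.
#' @param origin_props Named proportions over `orphan`, `five_prime_utr`,
#'   `three_prime_utr` (sum 1).
#' @param mech_probs_5p,mech_probs_3p Named probability vectors for the true
#'   generation mechanism of each end (sum 1 each).
#' @param multi_prob Probability that an end with an assigned (non-unknown)
#'   mechanism receives a second, distinct mechanism — both features are then
#'   placed at the end, mirroring co-occurring generation signals.
#' @param signal_depth Mean end count at a true end (lambda_signal).
#' @param background_rate Mean end count at background positions (lambda_bg).
#' @param mutant_residual Fraction of signal retained at enzyme-dependent
#'   ends in the cognate mutant, in \[0, 1\].
#' @param n_replicates Biological replicates per strain.
#' @param terminator_jitter Maximum |offset| (nt) applied to terminator
#'   anchors (default 0, anchors sit exactly on the 3' end).
#' @param overdispersion Optional gamma-mixing coefficient; `NULL` keeps pure
#'   Poisson counts.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       replicon_id = "chr1",
                       replicon_length = 50000L,
                       n_srnas = 79L,
                       origin_props = c(orphan = 38, five_prime_utr = 14,
                                        three_prime_utr = 16) / 68,
                       mech_probs_5p = c(TSS = 0.45, RNaseE = 0.25,
                                         RNaseIII = 0.10, PNPase = 0.05,
                                         unknown = 0.15),
                       mech_probs_3p = c(terminator = 0.30, RNaseE = 0.15,
                                         RNaseIII = 0.10, PNPase = 0.20,
                                         unknown = 0.25),
                       multi_prob = 0.1,
                       signal_depth = 100,
                       background_rate = 1,
                       mutant_residual = 0.05,
                       n_replicates = 3L,
                       terminator_jitter = 0L,
                       overdispersion = NULL) {
  cfg <- list(seed = as.integer(seed), replicon_id = replicon_id,
              replicon_length = as.integer(replicon_length),
              n_srnas = as.integer(n_srnas), origin_props = origin_props,
              mech_probs_5p = mech_probs_5p, mech_probs_3p = mech_probs_3p,
              multi_prob = multi_prob, signal_depth = signal_depth,
              background_rate = background_rate,
              mutant_residual = mutant_residual,
              n_replicates = as.integer(n_replicates),
              terminator_jitter = as.integer(terminator_jitter),
              overdispersion = overdispersion)
  chk_probs <- function(p, nm) {
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      abort(paste(nm, "must be non-negative and sum to 1"))
    }
  }
  chk_probs(cfg$origin_props, "origin_props")
  chk_probs(cfg$mech_probs_5p, "mech_probs_5p")
  chk_probs(cfg$mech_probs_3p, "mech_probs_3p")
  if (!setequal(names(cfg$origin_props),
                c("orphan", "five_prime_utr", "three_prime_utr"))) {
    abort("origin_props must name orphan, five_prime_utr, three_prime_utr")
  }
  if (!(cfg$signal_depth > cfg$background_rate) || cfg$background_rate < 0) {
    abort("need signal_depth > background_rate >= 0")
  }
  if (cfg$mutant_residual < 0 || cfg$mutant_residual > 1) {
    abort("mutant_residual must be in [0, 1]")
  }
  if (cfg$n_replicates < 1) abort("n_replicates must be >= 1")
  structure(cfg, class = "sim_config")
}

.SIM_STRAINS <- c("WT", "RNaseE_mut", "RNaseIII_mut", "PNPase_mut")
strain_enzyme <- c(WT = NA_character_, RNaseE_mut = "RNaseE",
                   RNaseIII_mut = "RNaseIII", PNPase_mut = "PNPase")

draw_mechs <- function(probs, multi_prob) {
  m <- sample(names(probs), 1, prob = probs)
  if (m != "unknown" && runif(1) < multi_prob) {
    others <- setdiff(names(probs), c(m, "unknown"))
    if (length(others)) {
      po <- probs[others]
      m <- c(m, if (sum(po) > 0) sample(others, 1, prob = po) else sample(others, 1))
    }
  }
  m
}

#' Simulate a genome annotation with known ground truth
#'
#' Lays out non-overlapping loci along the replicon: orphan sRNAs sit in
#' intergenic space; UTR-derived sRNAs sit strictly inside the 5' or 3' UTR
#' of a generated gene model (UTR orientation follows the strand). Each sRNA
#' end receives a true generation mechanism drawn from the configured
#' probabilities; TSS features are placed at TSS-generated 5' ends,
#' terminator anchors at terminator-generated 3' ends, and enzyme-dependent
#' ends are recorded as implanted differential ends.
#'
#' @param config A [sim_config()].
#' @return List with `srnas`, `utrs`, `genes`, `tss`, `terminators`
#'   (record tibbles), `truth` (per-sRNA origin, ends and mechanism sets,
#'   plus `diff_ends`), and `config`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  slot <- 550L
  need <- config$n_srnas * slot + 100L
  if (config$replicon_length < need) {
    abort(sprintf("replicon too short: %d sRNA loci need >= %d nt",
                  config$n_srnas, need))
  }
  set.seed(config$seed)
  repl <- config$replicon_id
  origins <- sample(names(config$origin_props), config$n_srnas,
                    replace = TRUE, prob = config$origin_props)
  strands <- sample(.STRANDS, config$n_srnas, replace = TRUE)

  srna <- utr <- gene <- vector("list", config$n_srnas)
  mech5 <- mech3 <- vector("list", config$n_srnas)
  for (i in seq_len(config$n_srnas)) {
    base <- 50L + (i - 1L) * slot
    st <- strands[i]
    L <- sample(60:160, 1)
    id <- sprintf("sRNA_%03d", i)
    if (origins[i] == "orphan") {
      srna[[i]] <- tibble(srna_id = id, replicon = repl, start = base + 50L,
                          end = base + 50L + L, strand = st)
    } else {
      utr_at_left <- (origins[i] == "five_prime_utr") == (st == "+")
      if (utr_at_left) {
        u <- c(base + 20L, base + 220L); g <- c(base + 220L, base + 470L)
      } else {
        g <- c(base + 20L, base + 270L); u <- c(base + 270L, base + 470L)
      }
      s_start <- u[1] + 20L
      srna[[i]] <- tibble(srna_id = id, replicon = repl, start = s_start,
                          end = s_start + min(L, u[2] - s_start - 10L),
                          strand = st)
      kind <- if (origins[i] == "five_prime_utr") "five_prime" else "three_prime"
      utr[[i]] <- tibble(gene_id = sprintf("gene_%03d", i), kind = kind,
                         replicon = repl, start = u[1], end = u[2], strand = st)
      gene[[i]] <- tibble(gene_id = sprintf("gene_%03d", i), replicon = repl,
                          start = g[1], end = g[2], strand = st)
    }
    mech5[[i]] <- draw_mechs(config$mech_probs_5p, config$multi_prob)
    mech3[[i]] <- draw_mechs(config$mech_probs_3p, config$multi_prob)
  }
  srnas <- bind_rows(srna)
  srnas <- srna_records(srnas$srna_id, srnas$replicon, srnas$start,
                        srnas$end, srnas$strand)
  utrs <- bind_rows(utr)
  if (!nrow(utrs)) {
    utrs <- utr_records(character(), character(), character(), integer(),
                        integer(), character())
  }
  genes <- bind_rows(gene)
  if (!nrow(genes)) {
    genes <- tibble(gene_id = character(),
                    genomic_intervals(character(), integer(), integer(),
                                      character()))
  }

  truth <- tibble(srna_id = srnas$srna_id, origin = origins,
                  replicon = repl, strand = srnas$strand,
                  end5 = srnas$end5, end3 = srnas$end3,
                  mech5 = mech5, mech3 = mech3)

  has_tss <- vapply(mech5, function(m) "TSS" %in% m, TRUE)
  tss <- feature_records(
    feature_id = paste0("TSS_", srnas$srna_id[has_tss]), kind = "tss",
    replicon = repl, position = srnas$end5[has_tss],
    strand = srnas$strand[has_tss])
  has_term <- vapply(mech3, function(m) "terminator" %in% m, TRUE)
  jit <- if (config$terminator_jitter > 0) {
    sample(-config$terminator_jitter:config$terminator_jitter,
           sum(has_term), replace = TRUE)
  } else 0L
  terminators <- feature_records(
    feature_id = paste0("term_", srnas$srna_id[has_term]), kind = "terminator",
    replicon = repl, position = srnas$end3[has_term] + jit,
    strand = srnas$strand[has_term])

  de <- bind_rows(lapply(seq_len(config$n_srnas), function(i) {
    bind_rows(
      tibble(enzyme = intersect(mech5[[i]], .ENZYMES), end_type = "five_prime",
             position = srnas$end5[i]),
      tibble(enzyme = intersect(mech3[[i]], .ENZYMES), end_type = "three_prime",
             position = srnas$end3[i])) |>
      mutate(replicon = repl, strand = srnas$strand[i],
             srna_id = srnas$srna_id[i])
  }))
  if (!nrow(de)) {
    de <- tibble(enzyme = character(), end_type = character(),
                 position = integer(), replicon = character(),
                 strand = character(), srna_id = character())
  }
  truth <- structure(truth, diff_ends = de)
  list(srnas = srnas, utrs = utrs, genes = genes, tss = tss,
       terminators = terminators, truth = truth, config = config)
}

#' Implanted differential ends of a simulated annotation
#'
#' @param truth The `truth` component of [simulate_annotation()].
#' @return Tibble `enzyme`, `end_type`, `position`, `replicon`, `strand`,
#'   `srna_id`.
#' @export
truth_diff_ends <- function(truth) attr(truth, "diff_ends")

#' Ground-truth features for mechanism assignment
#'
#' Builds the TSS/terminator/differential-end feature set exactly at the
#' truth positions (differential ends as wild-type enriched), for
#' truth-consistency checks of the assignment stage.
#'
#' @param annotation Result of [simulate_annotation()].
#' @return A [feature_records()] tibble.
#' @export
truth_to_features <- function(annotation) {
  de <- truth_diff_ends(annotation$truth)
  bind_rows(
    annotation$tss, annotation$terminators,
    if (nrow(de)) feature_records(
      feature_id = sprintf("%s_%s_%s", de$enzyme, de$end_type, de$srna_id),
      kind = "diff_end", replicon = de$replicon, position = de$position,
      strand = de$strand, enzyme = de$enzyme, end_type = de$end_type,
      direction = "wt_enriched"))
}

#' Expected mechanism calls from the ground truth
#'
#' @param truth The `truth` component of [simulate_annotation()].
#' @return Long tibble `srna_id`, `which_end`, `mechanism` — one row per true
#'   mechanism, with `"unknown"` for ends that have none.
#' @export
truth_mechanism_calls <- function(truth) {
  expand_end <- function(which_end, col) {
    bind_rows(lapply(seq_len(nrow(truth)), function(i) {
      tibble(srna_id = truth$srna_id[i], which_end = which_end,
             mechanism = truth[[col]][[i]])
    }))
  }
  bind_rows(expand_end("five_prime", "mech5"),
            expand_end("three_prime", "mech3")) |>
    arrange(.data$srna_id, .data$which_end, .data$mechanism)
}

# counts drawn for one (strand, end_type) component of one replicate
component_counts <- function(config, ann, strain, strand, end_type) {
  L <- config$replicon_length
  lam <- rep(config$background_rate, L)
  idx <- ann$srnas$strand == strand
  pos <- if (end_type == "five_prime") ann$srnas$end5[idx] else ann$srnas$end3[idx]
  mech <- if (end_type == "five_prime") ann$truth$mech5[idx] else ann$truth$mech3[idx]
  enz <- strain_enzyme[[strain]]
  scale <- vapply(mech, function(m) {
    if (!is.na(enz) && enz %in% m) config$mutant_residual else 1
  }, 1)
  lam[pos + 1L] <- lam[pos + 1L] + config$signal_depth * scale
  if (!is.null(config$overdispersion) && config$overdispersion > 0) {
    phi <- config$overdispersion
    lam <- lam * rgamma(L, shape = 1 / phi, scale = phi)
  }
  counts <- rpois(L, lam)
  nz <- counts > 0L
  tibble(pos = which(nz) - 1L, count = counts[nz])
}

#' Simulate replicate end-count tracks for one strain
#'
#' Every true sRNA end receives Poisson(`signal_depth`) counts, scaled by
#' `mutant_residual` in the cognate enzyme mutant only; every position of the
#' replicon additionally receives Poisson(`background_rate`) background on
#' each strand and end-type track. Each (strain, replicate) pair uses its own
#' RNG stream derived from the master seed, so partial re-runs reproduce
#' byte-identical tracks. The per-sample library size is the average of total
#' 5'- and 3'-end counts (each sequenced read contributes one end of each
#' type).
#'
#' @param annotation Result of [simulate_annotation()].
#' @param strain One of `"WT"`, `"RNaseE_mut"`, `"RNaseIII_mut"`,
#'   `"PNPase_mut"`.
#' @param config The [sim_config()] used for the annotation.
#' @return An [end_tracks()] set with `n_replicates` samples named
#'   `<strain>_rep<i>`.
#' @export
simulate_end_tracks <- function(annotation, strain, config = annotation$config) {
  strain <- match.arg(strain, .SIM_STRAINS)
  strain_idx <- match(strain, .SIM_STRAINS)
  counts <- vector("list", config$n_replicates)
  libs <- numeric(config$n_replicates)
  ids <- sprintf("%s_rep%d", strain, seq_len(config$n_replicates))
  for (r in seq_len(config$n_replicates)) {
    set.seed(config$seed + 100000L * strain_idx + r)
    comp <- lapply(.STRANDS, function(st) {
      lapply(.END_TYPES, function(et) {
        mutate(component_counts(config, annotation, strain, st, et),
               strand = st, end_type = et)
      })
    })
    cc <- bind_rows(unlist(comp, recursive = FALSE)) |>
      mutate(sample_id = ids[r], replicon = config$replicon_id, .before = 1)
    counts[[r]] <- cc
    tot <- tapply(cc$count, cc$end_type, sum)
    libs[r] <- max(1, round(mean(tot)))
  }
  end_tracks(bind_rows(counts), setNames(libs, ids))
}

#' Simulate a densitometry signal table with known truth
#'
#' Two conditions (reference and treated) are generated per probe with
#' `n_replicates` lanes each; mature intensities differ by the configured
#' true log2 fold change and precursor intensities follow the configured
#' mature/precursor ratio. Lane loading-control intensities vary log-normally
#' and multiplicative log-normal noise with coefficient of variation
#' `noise_cv` is applied to every band; `noise_cv = 0` reproduces the truth
#' exactly.
#'
#' @param true_lfcs Named numeric: probe -> true log2 fold change
#'   (treated vs reference) of the mature species.
#' @param true_ratios Named numeric: probe -> true mature/precursor ratio
#'   (same in both conditions).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param n_replicates Lanes per condition.
#' @param reference_condition,treated_condition Condition labels.
#' @param seed RNG seed.
#' @return List with `signals` (tibble in the [read_signal_table()] schema
#'   plus `normalized`) and `truth`.
#' @export
simulate_signal_table <- function(true_lfcs, true_ratios, noise_cv = 0.1,
                                  n_replicates = 3,
                                  reference_condition = "exp",
                                  treated_condition = "treated",
                                  seed = 1L) {
  stopifnot(noise_cv >= 0, setequal(names(true_lfcs), names(true_ratios)))
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- function(n) if (sdlog == 0) rep(1, n) else exp(rnorm(n, 0, sdlog))
  rows <- list()
  for (probe in names(true_lfcs)) {
    for (cond in c(reference_condition, treated_condition)) {
      mat_true <- if (cond == treated_condition) 2^true_lfcs[[probe]] else 1
      pre_true <- mat_true / true_ratios[[probe]]
      loading <- exp(rnorm(n_replicates, 0, 0.2))
      rows[[length(rows) + 1]] <- tibble(
        sample_id = sprintf("%s_%s_%d", probe, cond, seq_len(n_replicates)),
        condition = cond, replicate = seq_len(n_replicates), probe = probe,
        species = rep("mature", n_replicates),
        raw_intensity = mat_true * loading * noise(n_replicates),
        loading_intensity = loading)
      rows[[length(rows) + 1]] <- tibble(
        sample_id = sprintf("%s_%s_%d", probe, cond, seq_len(n_replicates)),
        condition = cond, replicate = seq_len(n_replicates), probe = probe,
        species = rep("precursor", n_replicates),
        raw_intensity = pre_true * loading * noise(n_replicates),
        loading_intensity = loading)
    }
  }
  signals <- mutate(bind_rows(rows),
                    normalized = normalize_signal(.data$raw_intensity,
                                                  .data$loading_intensity))
  list(signals = signals,
       truth = list(lfcs = true_lfcs, ratios = true_ratios,
                    reference_condition = reference_condition,
                    treated_condition = treated_condition))
}
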