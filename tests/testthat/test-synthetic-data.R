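small_cfg <- function(...) {
  args <- modifyList(list(seed = 5L, n_srnas = 12L, replicon_length = 8000L),
                     list(...))
  do.call(sim_config, args)
}

test_that("the generator is deterministic given the seed", {
  a <- simulate_annotation(small_cfg())
  b <- simulate_annotation(small_cfg())
  expect_identical(a$srnas, b$srnas)
  expect_identical(a$truth, b$truth)
  ta <- simulate_end_tracks(a, "RNaseE_mut")
  tb <- simulate_end_tracks(b, "RNaseE_mut")
  expect_identical(track_counts(ta), track_counts(tb))
  expect_identical(track_library_sizes(ta), track_library_sizes(tb))
  # byte-identical files
  f1 <- tempfile(); f2 <- tempfile()
  write_bedgraph(ta, f1, "RNaseE_mut_rep1", "+", "five_prime")
  write_bedgraph(tb, f2, "RNaseE_mut_rep1", "+", "five_prime")
  expect_identical(readLines(f1), readLines(f2))
  c_ <- simulate_annotation(small_cfg(seed = 6L))
  expect_false(identical(a$truth$end5, c_$truth$end5))
})

test_that("an all-orphan configuration is recovered in full by the classifier", {
  cfg <- small_cfg(origin_props = c(orphan = 1, five_prime_utr = 0,
                                    three_prime_utr = 0))
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$srnas), 12)
  expect_true(all(ann$truth$origin == "orphan"))
  expect_true(all(classify_origin(ann$srnas, ann$utrs, ann$genes) == "orphan"))
})

test_that("realized origin proportions stay inside binomial 99% bounds", {
  cfg <- sim_config(seed = 10L, n_srnas = 100L, replicon_length = 60000L,
                    origin_props = c(orphan = 0.5, five_prime_utr = 0.25,
                                     three_prime_utr = 0.25))
  ann <- simulate_annotation(cfg)
  n_orphan <- sum(ann$truth$origin == "orphan")
  bounds <- qbinom(c(0.005, 0.995), 100, 0.5)
  expect_gte(n_orphan, bounds[1])
  expect_lte(n_orphan, bounds[2])
})

test_that("a too-short replicon is rejected", {
  expect_error(simulate_annotation(small_cfg(replicon_length = 1000L)),
               "too short")
})

test_that("without background noise counts appear only at implanted ends", {
  cfg <- small_cfg(background_rate = 0, signal_depth = 50)
  ann <- simulate_annotation(cfg)
  tr <- simulate_end_tracks(ann, "WT")
  cc <- track_counts(tr)
  ends5 <- paste(ann$srnas$strand, "five_prime", ann$srnas$end5)
  ends3 <- paste(ann$srnas$strand, "three_prime", ann$srnas$end3)
  expect_true(all(paste(cc$strand, cc$end_type, cc$pos) %in% c(ends5, ends3)))
})

test_that("the cognate mutant loses signal at enzyme-dependent ends only", {
  cfg <- small_cfg(seed = 12L, n_srnas = 30L, replicon_length = 17000L,
                   background_rate = 0, signal_depth = 100,
                   mutant_residual = 0.05, multi_prob = 0)
  ann <- simulate_annotation(cfg)
  de <- truth_diff_ends(ann$truth)
  de_E <- de[de$enzyme == "RNaseE", ]
  expect_gte(nrow(de_E), 3)
  wt <- simulate_end_tracks(ann, "WT")
  mut <- simulate_end_tracks(ann, "RNaseE_mut")
  mean_at <- function(tr, pos, strand, end_type) {
    cc <- track_counts(tr)
    sum(cc$count[cc$pos %in% pos & cc$strand == strand &
                   cc$end_type == end_type]) / length(track_library_sizes(tr))
  }
  ratios <- vapply(seq_len(nrow(de_E)), function(i) {
    w <- mean_at(wt, de_E$position[i], de_E$strand[i], de_E$end_type[i])
    m <- mean_at(mut, de_E$position[i], de_E$strand[i], de_E$end_type[i])
    w / max(m, 0.5)
  }, 0)
  # expectation 100/5 = 20 (log2 ~ 4.3); Poisson noise at n = 3 is wide
  expect_gt(mean(ratios), 10)
  # ends dependent on other enzymes keep full signal in this mutant
  de_other <- de[de$enzyme != "RNaseE", ]
  if (nrow(de_other)) {
    r2 <- vapply(seq_len(nrow(de_other)), function(i) {
      w <- mean_at(wt, de_other$position[i], de_other$strand[i],
                   de_other$end_type[i])
      m <- mean_at(mut, de_other$position[i], de_other$strand[i],
                   de_other$end_type[i])
      w / max(m, 0.5)
    }, 0)
    expect_lt(max(r2), 3)
  }
})

test_that("truth helpers expose implanted features and expected calls", {
  ann <- simulate_annotation(small_cfg())
  feats <- truth_to_features(ann)
  expect_true(all(feats$kind %in% c("tss", "terminator", "diff_end")))
  de <- truth_diff_ends(ann$truth)
  expect_equal(sum(feats$kind == "diff_end"), nrow(de))
  tmc <- truth_mechanism_calls(ann$truth)
  expect_equal(nrow(tmc) >= 2 * nrow(ann$srnas), TRUE)
  expect_true(all(tmc$mechanism %in% c("TSS", "terminator", "RNaseE",
                                       "RNaseIII", "PNPase", "unknown")))
})

test_that("noiseless signal tables recover the configured truth exactly", {
  tab <- simulate_signal_table(true_lfcs = c(a = 2, b = -0.5),
                               true_ratios = c(a = 3, b = 1),
                               noise_cv = 0, seed = 3)
  fc <- probe_fold_changes(tab$signals, "exp")
  expect_equal(setNames(fc$log2fc, fc$probe), c(a = 2, b = -0.5),
               tolerance = 1e-12)
  rt <- ratio_table(tab$signals)
  expect_equal(unique(rt$ratio[rt$probe == "a"]), 3, tolerance = 1e-12)
})

test_that("noisy signal tables recover fold changes within simulation tolerance", {
  tab <- simulate_signal_table(true_lfcs = c(a = 2), true_ratios = c(a = 2),
                               noise_cv = 0.1, seed = 21)
  fc <- probe_fold_changes(tab$signals, "exp")
  expect_lt(abs(fc$log2fc - 2), 0.3)
})

test_that("null signal tables reject at about the nominal t-test rate", {
  set.seed(77)
  rej <- vapply(1:1000, function(i) {
    tab <- simulate_signal_table(true_lfcs = c(a = 0), true_ratios = c(a = 1),
                                 noise_cv = 0.2, seed = sample.int(1e6, 1))
    compare_ratio_conditions(tab$signals, "a", "exp", "treated")$p <= 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})
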