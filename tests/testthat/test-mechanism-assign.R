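one_srna <- function(strand = "+", start = 1000L, end = 1100L) {
  srna_records("s1", "chr1", start, end, strand)
}

test_that("windowed features become mechanisms with signed distances", {
  s <- one_srna() # 5' end at 1000, 3' end at 1099 on +
  feats <- feature_records("e1", "diff_end", "chr1", 1003L, "+",
                           enzyme = "RNaseE", end_type = "five_prime",
                           direction = "wt_enriched")
  calls <- assign_end_mechanisms(s, feats)
  five <- calls[calls$which_end == "five_prime", ]
  expect_equal(five$mechanism, "RNaseE")
  expect_equal(five$distance, 3L)
  expect_equal(calls$mechanism[calls$which_end == "three_prime"], "unknown")

  # on the minus strand the same genomic offset points the other way
  sm <- srna_records("s1", "chr1", 900L, 1001L, "-") # 5' end at 1000
  feats_m <- feature_records("e1", "diff_end", "chr1", 1003L, "-",
                             enzyme = "RNaseE", end_type = "five_prime",
                             direction = "wt_enriched")
  calls_m <- assign_end_mechanisms(sm, feats_m)
  expect_equal(calls_m$distance[calls_m$which_end == "five_prime"], -3L)
})

test_that("co-occurring features are all kept as generation mechanisms", {
  s <- one_srna()
  feats <- dplyr::bind_rows(
    feature_records("t1", "tss", "chr1", 999L, "+"),
    feature_records("e1", "diff_end", "chr1", 1002L, "+",
                    enzyme = "RNaseE", end_type = "five_prime",
                    direction = "wt_enriched"))
  five <- assign_end_mechanisms(s, feats)
  five <- five[five$which_end == "five_prime", ]
  expect_setequal(five$mechanism, c("TSS", "RNaseE"))
  expect_false(any(five$mechanism == "unknown"))
})

test_that("window sizes separate terminators from other features", {
  s <- one_srna() # 3' end at 1099
  near7 <- feature_records("e1", "diff_end", "chr1", 1106L, "+",
                           enzyme = "PNPase", end_type = "three_prime",
                           direction = "wt_enriched")
  calls <- assign_end_mechanisms(s, near7)
  expect_equal(calls$mechanism[calls$which_end == "three_prime"], "unknown")

  term8 <- feature_records("T1", "terminator", "chr1", 1107L, "+")
  calls2 <- assign_end_mechanisms(s, term8)
  three <- calls2[calls2$which_end == "three_prime", ]
  expect_equal(three$mechanism, "terminator")
  expect_equal(three$distance, 8L)
})

test_that("end-type gating keeps TSS off 3' ends and terminators off 5' ends", {
  s <- one_srna()
  feats <- dplyr::bind_rows(
    feature_records("t1", "tss", "chr1", 1098L, "+"),       # near the 3' end
    feature_records("T1", "terminator", "chr1", 1001L, "+")) # near the 5' end
  gated <- assign_end_mechanisms(s, feats)
  expect_true(all(gated$mechanism == "unknown"))
  naive <- assign_end_mechanisms(s, feats, gate_ends = FALSE)
  expect_true("TSS" %in% naive$mechanism[naive$which_end == "three_prime"])
  expect_true("terminator" %in% naive$mechanism[naive$which_end == "five_prime"])
})

test_that("only wild-type-enriched differential ends count by default", {
  s <- one_srna()
  feats <- feature_records("e1", "diff_end", "chr1", 1001L, "+",
                           enzyme = "RNaseE", end_type = "five_prime",
                           direction = "mutant_enriched")
  calls <- assign_end_mechanisms(s, feats)
  expect_true(all(calls$mechanism == "unknown"))
  both <- assign_end_mechanisms(s, feats, diff_direction = "both")
  expect_true("RNaseE" %in% both$mechanism)
})

test_that("assignment equals a brute-force all-pairs scan and widening is monotone", {
  set.seed(23)
  for (rep in 1:30) {
    n_s <- sample(2:6, 1)
    st <- sample.int(4000, n_s)
    srnas <- srna_records(sprintf("s%02d", seq_len(n_s)), "chr1", st,
                          st + sample(40:120, n_s, TRUE),
                          sample(c("+", "-"), n_s, TRUE))
    feats <- dplyr::bind_rows(
      random_features(20, span = 4200),
      feature_records(paste0("d", 1:15), "diff_end", "chr1",
                      sample.int(4200, 15) - 1L, sample(c("+", "-"), 15, TRUE),
                      enzyme = sample(c("RNaseE", "RNaseIII", "PNPase"), 15, TRUE),
                      end_type = sample(c("five_prime", "three_prime"), 15, TRUE),
                      direction = sample(c("wt_enriched", "mutant_enriched"),
                                         15, TRUE)))
    # anchor some features near ends so matches actually occur
    feats$position[1:4] <- srnas$end5[1] + c(-5L, 0L, 5L, 6L)
    got <- sort_calls(assign_end_mechanisms(srnas, feats))
    ref <- brute_assign(srnas, feats)
    expect_equal(got, ref, ignore_attr = TRUE)

    wide <- assign_end_mechanisms(srnas, feats, window_default = 8,
                                  window_terminator = 14)
    got_mech <- got[got$mechanism != "unknown", ]
    wide_key <- paste(wide$srna_id, wide$which_end, wide$mechanism)
    expect_true(all(paste(got_mech$srna_id, got_mech$which_end,
                          got_mech$mechanism) %in% wide_key))
  }
})

test_that("mechanism summaries count incidences per origin class and end", {
  calls <- tibble::tibble(
    srna_id = c("a", "a", "b", "b", "b"),
    which_end = c("five_prime", "three_prime", "five_prime", "five_prime",
                  "three_prime"),
    mechanism = c("TSS", "unknown", "TSS", "RNaseE", "terminator"),
    distance = c(0L, NA, 1L, -2L, 0L), feature_id = NA_character_)
  origins <- tibble::tibble(srna_id = c("a", "b"),
                            origin = c("five_prime_utr", "five_prime_utr"))
  s <- summarize_mechanisms(calls, origins)
  expect_equal(s$n[s$which_end == "five_prime" & s$mechanism == "TSS"], 2L)
  expect_equal(s$n[s$which_end == "five_prime" & s$mechanism == "RNaseE"], 1L)
  expect_equal(s$n[s$mechanism == "unknown"], 1L)
  expect_error(summarize_mechanisms(calls, origins[1, ]), "no origin")

  empty <- assign_end_mechanisms(srna_records(character(), character(),
                                              integer(), integer(), character()),
                                 feature_records(character(), character(),
                                                 character(), integer(),
                                                 character()))
  expect_equal(nrow(empty), 0)
})
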