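make_groups <- function(wt_counts, mut_counts, lib = 1e6) {
  # each element of *_counts: data.frame(pos, count) for one replicate
  wt <- tiny_tracks(setNames(wt_counts, paste0("wt", seq_along(wt_counts))),
                    setNames(rep(lib, length(wt_counts)),
                             paste0("wt", seq_along(wt_counts))))
  mut <- tiny_tracks(setNames(mut_counts, paste0("mut", seq_along(mut_counts))),
                     setNames(rep(lib, length(mut_counts)),
                              paste0("mut", seq_along(mut_counts))))
  list(wt = wt, mut = mut)
}

test_that("candidate selection applies the per-group min_count rule", {
  g <- make_groups(list(data.frame(pos = c(5, 9), count = c(12L, 3L))),
                   list(data.frame(pos = c(5, 9), count = c(0L, 3L))))
  cand <- candidate_positions(g$wt, g$mut, min_count = 10)
  expect_equal(cand$pos, 5L)
  expect_equal(cand$wt_sum, 12L)
  expect_equal(cand$mut_sum, 0L)
})

test_that("candidate selection equals a brute-force scan over nonzero positions", {
  set.seed(21)
  reps <- function() lapply(1:3, function(i) {
    data.frame(pos = sample.int(200, 80), count = rpois(80, 3) + 1L)
  })
  g <- make_groups(reps(), reps())
  cand <- candidate_positions(g$wt, g$mut, min_count = 10)
  wt_sum <- rowsum(track_counts(g$wt)$count, track_counts(g$wt)$pos)
  mut_sum <- rowsum(track_counts(g$mut)$count, track_counts(g$mut)$pos)
  all_pos <- sort(unique(c(as.integer(rownames(wt_sum)),
                           as.integer(rownames(mut_sum)))))
  brute <- all_pos[sapply(all_pos, function(p) {
    a <- if (as.character(p) %in% rownames(wt_sum)) wt_sum[as.character(p), ] else 0
    b <- if (as.character(p) %in% rownames(mut_sum)) mut_sum[as.character(p), ] else 0
    max(a, b) >= 10
  })]
  expect_equal(cand$pos, brute)
})

test_that("mismatched track combinations between groups are rejected", {
  wt <- tiny_tracks(list(w = data.frame(pos = 1, count = 20L)), c(w = 100))
  mut <- tiny_tracks(list(m = data.frame(pos = 1, count = 20L,
                                         strand = "-")), c(m = 100))
  expect_error(candidate_positions(wt, mut), "combinations")
})

test_that("per-position test matches hand-computed fold change and reference tests", {
  # identical groups: no fold change, p = 1
  r0 <- test_position(c(100, 100, 100), c(100, 100, 100))
  expect_equal(r0$log2fc, 0)
  expect_equal(r0$p_value, 1)

  wt <- c(100, 120, 110); mut <- c(10, 12, 9)
  r <- test_position(wt, mut, pseudocount = 0.5)
  expect_equal(r$log2fc, log2(110.5 / (31 / 3 + 0.5)), tolerance = 1e-12)
  expect_equal(r$log2fc, 3.35, tolerance = 0.01)
  # reference: Welch t on the log scale via stats::t.test
  ref <- t.test(log2(wt + 0.5), log2(mut + 0.5))$p.value
  expect_equal(r$p_value, ref, tolerance = 1e-12)
  expect_lt(r$p_value, 0.01)

  # single replicate per group falls back to the exact binomial test
  r1 <- test_position(30, 0, wt_raw = 30, mut_raw = 0,
                      wt_lib = 1e6, mut_lib = 1e6)
  expect_equal(r1$p_value, binom.test(30, 30, 0.5)$p.value, tolerance = 1e-12)
  expect_error(test_position(30, 0), "library sizes")
  expect_error(test_position(numeric(), 1), "non-empty")
})

test_that("Benjamini-Hochberg matches the step-up formula and a reference", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(33)
  for (i in 1:5) {
    p <- runif(1000)^sample(c(0.5, 1, 3), 1)
    expect_equal(benjamini_hochberg(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # adjusted values are non-decreasing in the sorted order
  p <- sort(runif(200))
  expect_true(all(diff(benjamini_hochberg(p)) >= 0))
})

test_that("identical groups produce no differential ends", {
  reps <- lapply(1:3, function(i) data.frame(pos = 1:20, count = 50L))
  g <- make_groups(reps, reps)
  expect_equal(nrow(call_differential_ends(g$wt, g$mut, "RNaseE")), 0)
})

test_that("an implanted wild-type-only end is recovered with the right direction", {
  set.seed(41)
  mk <- function(signal) lapply(1:3, function(i) {
    bg <- data.frame(pos = 0:499, count = rpois(500, 0.5))
    bg$count[bg$pos == 250] <- bg$count[bg$pos == 250] + signal
    bg[bg$count > 0, ]
  })
  g <- make_groups(mk(100L), mk(0L), lib = 1000)
  de <- call_differential_ends(g$wt, g$mut, "RNaseE")
  expect_equal(de$position, 250L)
  expect_equal(de$direction, "wt_enriched")
  expect_gt(de$log2fc, 1)
  expect_true(all(de$p_adj >= de$p_value))

  # swapping the groups negates the fold change and flips the direction
  de2 <- call_differential_ends(g$mut, g$wt, "RNaseE")
  expect_equal(de2$position, 250L)
  expect_equal(de2$log2fc, -de$log2fc, tolerance = 1e-9)
  expect_equal(de2$p_value, de$p_value, tolerance = 1e-9)
  expect_equal(de2$direction, "mutant_enriched")
})

test_that("every emitted record satisfies both thresholds and the cutoff is monotone", {
  set.seed(51)
  mk <- function(lam) lapply(1:3, function(i) {
    d <- data.frame(pos = 0:299, count = rpois(300, lam))
    d[d$count > 0, ]
  })
  g <- make_groups(mk(4), mk(1), lib = 500)
  loose <- diff_end_params(lfc_cutoff = 0.5)
  strict <- diff_end_params(lfc_cutoff = 1.5)
  de_loose <- call_differential_ends(g$wt, g$mut, "PNPase", loose)
  de_strict <- call_differential_ends(g$wt, g$mut, "PNPase", strict)
  expect_true(all(abs(de_loose$log2fc) >= 0.5 & de_loose$p_adj <= 0.05))
  expect_true(all(de_strict$position %in% de_loose$position))
})

test_that("welch statistic option is available and test surface stays consistent", {
  set.seed(61)
  mk <- function(lam) lapply(1:3, function(i) {
    d <- data.frame(pos = 0:99, count = rpois(100, lam))
    d[d$count > 0, ]
  })
  g <- make_groups(mk(30), mk(2), lib = 1000)
  de <- call_differential_ends(g$wt, g$mut, "RNaseE",
                               diff_end_params(stat = "welch"))
  expect_gt(nrow(de), 0)
  # caller's welch p at one position agrees with test_position()
  cand <- candidate_positions(g$wt, g$mut, 10)
  p <- cand$pos[1]
  val <- function(tr) sapply(paste0(names(track_library_sizes(tr))), function(s) {
    cc <- track_counts(tr)
    r <- cc[cc$sample_id == s & cc$pos == p, ]
    cnt <- if (nrow(r)) r$count else 0
    cnt * 1e6 / track_library_sizes(tr)[[s]]
  })
  ref <- test_position(val(g$wt), val(g$mut))
  full <- call_differential_ends(g$wt, g$mut, "RNaseE",
                                 diff_end_params(stat = "welch", alpha = 0.999999,
                                                 lfc_cutoff = 1e-9))
  row <- full[full$position == p, ]
  expect_equal(row$p_value, ref$p_value, tolerance = 1e-9)
  expect_equal(row$log2fc, ref$log2fc, tolerance = 1e-9)
})

test_that("differential ends convert to features and BED export", {
  de <- tibble::tibble(replicon = "chr1", position = 10L, strand = "+",
                       end_type = "five_prime", enzyme = "RNaseE",
                       mean_wt = 100, mean_mut = 1, log2fc = 4.2,
                       p_value = 1e-5, p_adj = 1e-4, direction = "wt_enriched")
  fe <- diff_ends_to_features(de)
  expect_equal(fe$kind, "diff_end")
  expect_equal(fe$position, 10L)
  expect_equal(fe$direction, "wt_enriched")
  f <- tempfile(fileext = ".bed")
  write_diff_ends_bed(de, f)
  expect_equal(readLines(f), "chr1\t10\t11\tRNaseE:five_prime\t42\t+")
})
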