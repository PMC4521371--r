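# Hit classification, pairing, error-adjusted coverage, total FPR.

mk_dissected <- function(variant, e_orig, e_fc, e_rem = 1e-10) {
  structure(list(full_score = 0, fc_sum = 0, rem_sum = 0,
                 evalue_original = e_orig, evalue_fc = e_fc,
                 evalue_rem = e_rem,
                 log10_ratio = if (is.na(e_rem)) NA_real_
                               else log10(e_fc) - log10(e_rem),
                 variant = variant),
            class = "dissected_score")
}

test_that("classification implements the four-way criteria exhaustively", {
  t <- classification_thresholds()
  for (variant in c("H2", "H3")) {
    oc <- t[[variant]]$original_e_cutoff
    fcc <- t[[variant]]$fc_e_cutoff
    for (orig_sig in c(TRUE, FALSE)) for (fc_sig in c(TRUE, FALSE))
      for (rem_sig in c(TRUE, FALSE)) {
        d <- mk_dissected(variant,
                          if (orig_sig) oc * 0.5 else oc * 2,
                          if (fc_sig) fcc * 0.5 else fcc * 2,
                          if (rem_sig) fcc * 0.5 else fcc * 2)
        cl <- classify(d, t)
        expected <- if (orig_sig && fc_sig) "TP"
          else if (!orig_sig && fc_sig) "FN"
          else if (!orig_sig && !fc_sig) "TN"
          else "FP"
        expect_identical(cl$label, expected,
                         label = sprintf("%s orig=%s fc=%s rem=%s", variant,
                                         orig_sig, fc_sig, rem_sig))
        expect_identical(cl$retained, expected %in% c("TP", "FN"))
      }
  }
  # cutoff boundaries are inclusive
  d <- mk_dissected("H2", 0.1, 10^-3.45)
  expect_identical(classify(d, t)$label, "TP")
  # the rescued class: insignificant original, significant fold-critical
  expect_identical(classify(mk_dissected("H2", 0.5, 1e-4), t)$label, "FN")
  expect_identical(classify(mk_dissected("H2", 0.05, 1e-2, 1e-4), t)$label,
                   "FP")
  # deciding the FP branch without a remnant E-value is an error
  expect_error(classify(mk_dissected("H2", 0.05, 1e-2, NA), t), "remnant")
})

test_that("overlap ratio follows the generalized intersection formula", {
  expect_equal(overlap_ratio(c(10, 100), c(10, 100)), 1.0)
  expect_equal(overlap_ratio(c(1, 100), c(91, 190)), 9 / 99)
  expect_equal(overlap_ratio(c(91, 190), c(1, 100)), 9 / 99)  # sorts internally
  expect_equal(overlap_ratio(c(1, 50), c(60, 100)), 0)
  # nesting: generalized intersection length, still min over both segments
  expect_equal(overlap_ratio(c(1, 100), c(40, 60)), min(20 / 99, 20 / 20))
  expect_error(overlap_ratio(c(5, 5), c(1, 10)), "zero-length")
})

test_that("pairing is threshold-gated, injective and never crosses models", {
  h2 <- fake_hit("q", "mA", "H2", c(1, 100), c(1, 50), 50)
  h3 <- fake_hit("q", "mA", "H3", c(3, 98), c(5, 40), 50)
  m <- pair_hits(list(h2), list(h3))
  expect_length(m, 1L)
  expect_false(is.null(m[[1]]$h2)); expect_false(is.null(m[[1]]$h3))
  expect_equal(m[[1]]$coverage_h2, 1)
  expect_equal(m[[1]]$coverage_h3, 36 / 50)

  # overlap 0.5 -> two orphans
  h3b <- fake_hit("q", "mA", "H3", c(51, 150), c(5, 40), 50)
  m2 <- pair_hits(list(h2), list(h3b))
  expect_length(m2, 2L)
  expect_true(any(vapply(m2, function(x) is.null(x$h3), TRUE)))
  expect_true(any(vapply(m2, function(x) is.null(x$h2), TRUE)))

  # orphan H2 with no H3 counterpart at all
  m3 <- pair_hits(list(h2), list())
  expect_length(m3, 1L)
  expect_null(m3[[1]]$h3)
  expect_equal(m3[[1]]$coverage_h2, 1)

  # same spans but different models never pair
  h3c <- fake_hit("q", "mB", "H3", c(1, 100), c(5, 40), 50)
  m4 <- pair_hits(list(h2), list(h3c))
  expect_length(m4, 2L)
  expect_true(all(vapply(m4, function(x) is.null(x$h2) || is.null(x$h3),
                         TRUE)))

  # injectivity: two H2 candidates, one H3 -> one pair + one orphan
  h2b <- fake_hit("q", "mA", "H2", c(2, 99), c(1, 50), 50)
  m5 <- pair_hits(list(h2, h2b), list(h3))
  expect_length(m5, 2L)
  expect_equal(sum(vapply(m5, function(x)
    !is.null(x$h2) && !is.null(x$h3), TRUE)), 1L)
})

test_that("error-adjusted coverage follows the paired formula and the orphan rule", {
  h2 <- fake_hit("q", "mA", "H2", c(1, 100), c(1, 50), 50,
                 e_fc = 1e-8, e_rem = 1)
  h3 <- fake_hit("q", "mA", "H3", c(3, 98), c(1, 25), 50,
                 e_fc = 1e-8, e_rem = 1)
  m <- pair_hits(list(h2), list(h3))[[1]]
  expect_equal(m$coverage_h3, 0.5)

  # both fprs 0, both coverages at their maxima -> 1/2 (1 + 0.5) = 0.75;
  # with full H3 coverage the endpoint is exactly 1
  m0 <- error_adjusted_coverage(m, flat_tables(0, 0))
  expect_equal(m0$coverage_fce, (1 * 1 + 1 * 0.5) / 2)
  h3full <- fake_hit("q", "mA", "H3", c(3, 98), c(1, 50), 50,
                     e_fc = 1e-8, e_rem = 1)
  mfull <- error_adjusted_coverage(pair_hits(list(h2), list(h3full))[[1]],
                                   flat_tables(0, 0))
  expect_equal(mfull$coverage_fce, 1)

  # fpr_h2 0.1 cov 1, fpr_h3 0.2 cov 0.5 -> 0.5 (0.9 + 0.4) = 0.65
  m1 <- error_adjusted_coverage(m, flat_tables(0.1, 0.2))
  expect_equal(m1$coverage_fce, 0.5 * (0.9 * 1 + 0.8 * 0.5))
  expect_equal(m1$coverage_fce, 0.65)

  # orphan rule drops the half factor: 0.49 * 0.42
  orphan <- fake_hit("q", "mB", "H3", c(10, 90), c(1, 21), 50,
                     e_fc = 1e-8, e_rem = 1)
  mo <- pair_hits(list(), list(orphan))[[1]]
  expect_equal(mo$coverage_h3, 0.42)
  mo <- error_adjusted_coverage(mo, flat_tables(0, 0.51))
  expect_equal(mo$coverage_fce, 0.49 * 0.42)
  mo2 <- error_adjusted_coverage(pair_hits(list(), list(orphan))[[1]],
                                 flat_tables(0, 0.51), halve_orphans = TRUE)
  expect_equal(mo2$coverage_fce, 0.49 * 0.42 / 2)
})

test_that("coverage is monotone in the component FPRs and coverages", {
  h2 <- fake_hit("q", "mA", "H2", c(1, 100), c(1, 50), 50)
  covs <- vapply(c(0, 0.2, 0.5, 0.9), function(f) {
    h3 <- fake_hit("q", "mA", "H3", c(1, 100), c(1, 40), 50)
    m <- error_adjusted_coverage(pair_hits(list(h2), list(h3))[[1]],
                                 flat_tables(0.1, f))
    m$coverage_fce
  }, 0)
  expect_true(all(diff(covs) < 0))
  covs2 <- vapply(c(10, 25, 40, 50), function(ncol_) {
    h3 <- fake_hit("q", "mA", "H3", c(1, 100), c(1, ncol_), 50)
    m <- error_adjusted_coverage(pair_hits(list(h2), list(h3))[[1]],
                                 flat_tables(0.1, 0.1))
    m$coverage_fce
  }, 0)
  expect_true(all(diff(covs2) > 0))
})

test_that("total FPR is the plain sum and sorting is stable", {
  expect_equal(total_fpr(0.53, 0.54), 1.07)
  expect_equal(total_fpr(0, 0), 0)
  expect_equal(total_fpr(0.28, 0.01), 0.29)
  expect_error(total_fpr(-0.1, 0.5), "is not TRUE")

  # stable ascending sort with ties preserving input order
  h2a <- fake_hit("q", "mA", "H2", c(1, 100), c(1, 50), 50)
  h2b <- fake_hit("q", "mB", "H2", c(1, 100), c(1, 50), 50)
  h2c <- fake_hit("q", "mC", "H2", c(1, 100), c(1, 50), 50)
  merged <- lapply(pair_hits(list(h2a, h2b, h2c), list()),
                   error_adjusted_coverage, tables = flat_tables(0, 0))
  roc <- roc_from_scores(c(1, 1, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  rep_ <- rank_hits(merged, roc, roc)
  expect_true(!is.unsorted(rep_$total_fpr))
  expect_equal(rep_$model_id, c("mA", "mB", "mC"))  # tie keeps input order
})

test_that("domain scores average the per-sequence best coverages", {
  mk_merged <- function(q, m, cov) {
    h <- fake_hit(q, m, "H2", c(1, 100), c(1, 50), 50)
    x <- pair_hits(list(h), list())[[1]]
    x$coverage_ratio <- cov; x$coverage_fce <- cov
    x
  }
  merged <- list(mk_merged("s1", "mA", 1.0), mk_merged("s2", "mA", 0.5),
                 mk_merged("s3", "mA", 0.75))
  ds <- domain_scores(merged)
  expect_equal(ds$value[ds$measure_kind == "fce"], 0.75)
  expect_equal(ds$n_contributing_sequences[ds$measure_kind == "fce"], 3L)

  single <- domain_scores(list(mk_merged("s1", "mA", 0.6)))
  expect_equal(single$value[single$measure_kind == "ratio"], 0.6)

  # two hits of one sequence to the same model contribute their maximum
  two <- domain_scores(list(mk_merged("s1", "mA", 0.4),
                            mk_merged("s1", "mA", 0.9)))
  expect_equal(two$value[two$measure_kind == "fce"], 0.9)

  expect_equal(nrow(domain_scores(list())), 0L)
})

test_that("the plain-coverage baseline filters by original E-value", {
  mk_h3 <- function(q, m, ev, span) {
    h <- fake_hit(q, m, "H3", c(1, 100), span, 50, e_orig = ev)
    h
  }
  hits <- list(mk_h3("s1", "mA", 0.05, c(1, 50)),
               mk_h3("s2", "mA", 5, c(1, 25)),
               mk_h3("s3", "mA", 0.08, c(1, 25)))
  b <- hmmer3_baseline_scores(hits, evalue_cutoff = 0.1)
  # kept: s1 (cov 1) and s3 (cov 0.5); dropped: s2
  expect_equal(b$value, mean(c(1, 0.5)))
  expect_equal(b$n_contributing_sequences, 2L)
  b2 <- hmmer3_baseline_scores(hits, evalue_cutoff = 10)
  expect_equal(b2$value, mean(c(1, 0.5, 0.5)))
  expect_equal(nrow(hmmer3_baseline_scores(hits, evalue_cutoff = 1e-6)), 0L)
})
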