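# Column masks, predictors, weighted combination, normalisation, ROC.

test_that("DSSP masks follow the fold-code sets and the short-run merge", {
  m <- mask_from_dssp("HHHHH")
  expect_true(all(m$labels == "FOLD_CRITICAL"))

  # an internal remnant run of 4 (< 10) is folded into the globular segment
  m2 <- mask_from_dssp("HHH----HHH")
  expect_true(all(m2$labels == "FOLD_CRITICAL"))

  # a run of 12 survives
  m3 <- mask_from_dssp(paste0(strrep("H", 5), strrep("-", 12), strrep("H", 5)))
  expect_equal(m3$labels,
               c(rep("FOLD_CRITICAL", 5), rep("REMNANT", 12),
                 rep("FOLD_CRITICAL", 5)))
  expect_identical(m3$provenance, "dssp_derived")
})

test_that("unknown DSSP codes follow the configured policy and warn once", {
  expect_warning(m <- mask_from_dssp(paste0("G", strrep("-", 11), "HHH")),
                 "outside the fold set")
  expect_equal(m$labels[1], "REMNANT")  # by-elimination default
  m2 <- suppressWarnings(
    mask_from_dssp(paste0("B", strrep("H", 12)),
                   unknown_policy = "fold_critical"))
  expect_equal(m2$labels[1], "FOLD_CRITICAL")
  expect_error(mask_from_dssp("HZH", unknown_policy = "error"),
               "unknown DSSP code")
})

test_that("short-run merging is idempotent", {
  for (seed in 1:10) {
    set.seed(seed)
    lab <- sample(c("FOLD_CRITICAL", "REMNANT"), 60, replace = TRUE)
    once <- merge_short_remnant_runs(lab)
    expect_identical(merge_short_remnant_runs(once), once)
    runs <- rle(once)
    expect_true(all(runs$lengths[runs$values == "REMNANT"] >= 10))
  }
})

test_that("per-sequence labels aggregate to the structured fraction per column", {
  msa <- c("ACD-", "ACD-", "AC-E", "ACDE")
  labs <- list(c(1, 1, 1), c(1, 1, 1), c(1, 0, 0), c(0, 1, 1, 1))
  ps <- predictor_column_scores(msa, labs)
  # col1: 3/4 structured; col2: 3/4; col3: 3/3; col4: 1/2
  expect_equal(ps$scores, c(3 / 4, 3 / 4, 1, 1 / 2))
  expect_equal(ps$n_sequences, 4L)

  # all-gap column scores 0
  ps2 <- predictor_column_scores(c("A-", "A-"), list(1, 1))
  expect_equal(ps2$scores, c(1, 0))

  expect_error(predictor_column_scores(msa, list(c(1, 1), labs[[2]],
                                                 labs[[3]], labs[[4]])),
               "length mismatch")
})

test_that("windowed-entropy segmentation flags low complexity at the stated thresholds", {
  # homopolymer: zero entropy everywhere
  expect_true(all(seg_labels(strrep("A", 50)) == 0L))
  # cycling through all 20 residues: window entropy > hicut, no low complexity
  cyc <- paste(rep(aa_alphabet(), length.out = 50), collapse = "")
  expect_true(all(seg_labels(cyc) == 1L))
  # verify against a direct entropy computation for the cycling window
  w <- strsplit(cyc, "")[[1]][1:25]
  f <- table(w) / 25
  expect_gt(-sum(f * log2(f)), 3.4)
  # shorter than the window: one whole-sequence window decides
  expect_true(all(seg_labels(strrep("A", 8)) == 0L))
  expect_true(all(seg_labels(paste(aa_alphabet()[1:12], collapse = "")) == 1L))
})

test_that("globularity labels follow the run-length rules on the propensity curve", {
  ordered_res <- names(sort(disorder_propensity()))  # most order-promoting first
  glob <- strrep(ordered_res[1], 60)
  expect_true(all(globplot_labels(glob) == 1L))
  # a 60-residue disorder-promoting block inside a globular context
  dis60 <- strrep("P", 60)
  seqmix <- paste0(strrep("W", 60), dis60, strrep("W", 60))
  lab <- globplot_labels(seqmix)
  mid <- 61:120
  expect_gt(mean(lab[mid] == 0L), 0.7)
  expect_true(all(lab[1:50] == 1L))
  # shorter than dompeakframe falls back to the structured default
  expect_true(all(globplot_labels(strrep("P", 12)) == 1L))
})

test_that("conservation quality score matches a brute-force sum-of-pairs oracle", {
  msa <- c("AWAD", "AWVD", "AWID", "AW-D")
  qs <- quality_score(msa)
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- e$BLOSUM62[aa_alphabet(), aa_alphabet()]
  smin <- min(S)
  oracle <- function(col, nrows) {
    col <- col[col != "-"]
    if (!length(col)) return(0)
    if (length(col) == 1L) return(1 / nrows)
    pr <- utils::combn(length(col), 2)
    v <- numeric(ncol(pr))
    for (j in seq_len(ncol(pr))) {
      a <- col[pr[1, j]]; b <- col[pr[2, j]]
      v[j] <- min(max((S[a, b] - smin) /
                        (min(S[a, a], S[b, b]) - smin), 0), 1)
    }
    mean(v) * length(col) / nrows
  }
  mat <- do.call(rbind, strsplit(msa, ""))
  for (k in 1:4)
    expect_equal(qs$scores[k], oracle(mat[, k], 4), tolerance = 1e-12)
  # identical gap-free column scores exactly 1
  expect_equal(qs$scores[1], 1)
  expect_equal(qs$scores[2], 1)
  # a column of minimally similar residues scores at the normalisation floor
  worst <- which(S == min(S), arr.ind = TRUE)[1, ]
  msa2 <- c(strrep(rownames(S)[worst[1]], 2), strrep(rownames(S)[worst[2]], 2))
  qs2 <- quality_score(c(msa2[1], msa2[2]))
  expect_equal(qs2$scores[1], 0)
  expect_error(quality_score("ACDE"), "single-sequence")
})

test_that("weighted combination applies the stated weights and the sequence floor", {
  mk <- function(pred, sc, n) predictor_scores(pred, sc, n)
  all1 <- list(mk("qualityscore", 1, 6), mk("psipred", 1, 6),
               mk("seg", 1, 6), mk("globplot", 1, 6))
  expect_equal(combine_weighted(all1), 0.61 + 0.50 + 0.41 + 0.39)
  all0 <- list(mk("qualityscore", 0, 6), mk("psipred", 0, 6),
               mk("seg", 0, 6), mk("globplot", 0, 6))
  expect_equal(combine_weighted(all0), 0)
  # below the 5-sequence floor only the conservation vector survives
  few <- list(mk("qualityscore", 0.8, 3), mk("psipred", 1, 3),
              mk("seg", 1, 3), mk("globplot", 1, 3))
  expect_equal(combine_weighted(few), 0.8 * 0.61)
  expect_error(combine_weighted(list(mk("psipred", 1, 6))), "qualityscore")
  expect_error(combine_weighted(list(mk("qualityscore", c(1, 1), 6),
                                     mk("psipred", 1, 6))),
               "length")
})

test_that("combination is linear in each predictor vector", {
  set.seed(42)
  for (i in 1:5) {
    a <- runif(8); b <- runif(8); q <- runif(8)
    v1 <- combine_weighted(list(predictor_scores("qualityscore", q, 9),
                                predictor_scores("seg", a, 9)))
    v2 <- combine_weighted(list(predictor_scores("qualityscore", q, 9),
                                predictor_scores("seg", b, 9)))
    v12 <- combine_weighted(list(predictor_scores("qualityscore", q, 9),
                                 predictor_scores("seg", (a + b) / 2, 9)))
    expect_equal(v12, (v1 + v2) / 2, tolerance = 1e-12)
  }
})

test_that("min-max normalisation hits its endpoints and is affine-invariant", {
  expect_equal(normalize_scores(c(0, 0.955, 1.91)), c(0, 0.5, 1.0))
  expect_warning(out <- normalize_scores(rep(0.3, 5)), "degenerate")
  expect_equal(out, rep(0.5, 5))
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(12)
    n1 <- normalize_scores(x)
    n2 <- normalize_scores(3.7 * x + 11)
    expect_equal(n1, n2, tolerance = 1e-12)
    expect_true(all(n1 >= 0 & n1 <= 1))
    expect_equal(range(n1), c(0, 1))
  }
})

test_that("score thresholding declares fold-critical at >= 0.5 and merges runs", {
  m <- mask_from_scores(rep(0.9, 12))
  expect_true(all(m$labels == "FOLD_CRITICAL"))
  m2 <- mask_from_scores(c(rep(0.9, 5), rep(0.1, 12), rep(0.9, 5)))
  expect_equal(sum(m2$labels == "REMNANT"), 12L)
  m3 <- mask_from_scores(c(rep(0.9, 5), rep(0.1, 4), rep(0.9, 5)))
  expect_true(all(m3$labels == "FOLD_CRITICAL"))  # run of 4 merged
  # tie at the threshold is fold-critical
  m4 <- mask_from_scores(rep(0.5, 11))
  expect_true(all(m4$labels == "FOLD_CRITICAL"))
  expect_identical(m2$provenance, "predictor_derived")
  expect_equal(m2$raw_scores, c(rep(0.9, 5), rep(0.1, 12), rep(0.9, 5)))
})

test_that("mask statistics report remnant ratios and surviving segment lengths", {
  m1 <- column_mask("a", c(rep("FOLD_CRITICAL", 5), rep("REMNANT", 15)),
                    "dssp_derived")
  m2 <- column_mask("b", rep("FOLD_CRITICAL", 10), "dssp_derived")
  m3 <- column_mask("c", rep("REMNANT", 12), "dssp_derived")
  st <- mask_stats(list(m1, m2, m3))
  expect_equal(st$per_model$ratio, c(15 / 20, 0, 1))
  expect_equal(sort(st$segment_lengths), c(12L, 15L))
  expect_equal(st$n_ratio_gt_half, 2L)
  expect_equal(st$n_ratio_one, 1L)
  expect_error(mask_stats(list()), "empty")
})

test_that("predictor ROC behaves at the endpoints and for random/inverted scores", {
  set.seed(11)
  truth <- column_mask("m", sample(c("FOLD_CRITICAL", "REMNANT"), 400,
                                   replace = TRUE), "dssp_derived",
                       merge_runs = FALSE)
  perfect <- ifelse(truth$labels == "FOLD_CRITICAL", 1, 0)
  r <- predictor_roc(list(m = perfect), list(m = truth))
  expect_true(all(r$tpr == 1 & r$fpr == 0))

  rnd <- runif(400)
  r2 <- predictor_roc(list(m = rnd), list(m = truth))
  # random scores: TPR ~ FPR within binomial error at every threshold
  expect_lt(max(abs(r2$tpr - r2$fpr)), 4 * sqrt(0.25 / 200))

  r3 <- predictor_roc(list(m = 1 - perfect), list(m = truth))
  expect_true(all(r3$margin <= 0))
  expect_error(predictor_roc(list(x = rnd), list(m = truth)), "share no")
})

test_that("the weighted scheme is at least as good as single predictors under independent errors", {
  set.seed(99)
  K <- 600
  truth_lab <- sample(c("FOLD_CRITICAL", "REMNANT"), K, replace = TRUE)
  truth <- column_mask("m", truth_lab, "dssp_derived", merge_runs = FALSE)
  t01 <- as.numeric(truth_lab == "FOLD_CRITICAL")
  noisy <- function(noise) pmin(pmax(t01 + rnorm(K, 0, noise), 0), 1)
  vecs <- list(predictor_scores("qualityscore", noisy(0.45), 9),
               predictor_scores("psipred", noisy(0.5), 9),
               predictor_scores("seg", noisy(0.55), 9),
               predictor_scores("globplot", noisy(0.6), 9))
  weighted <- normalize_scores(combine_weighted(vecs))
  best_single <- max(vapply(vecs, function(v)
    max(predictor_roc(list(m = v$scores), list(m = truth))$margin,
        na.rm = TRUE), 0))
  best_weighted <- max(predictor_roc(list(m = weighted),
                                     list(m = truth))$margin, na.rm = TRUE)
  expect_gte(best_weighted, best_single - 0.05)
})
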