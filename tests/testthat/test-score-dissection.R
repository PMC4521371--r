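# Score reconstruction, dissection, EVD evaluation, Viterbi alignment.

test_that("a one-column alignment reconstructs to entry + emission + exit by hand", {
  me <- matrix(-1, 1, 20, dimnames = list(NULL, aa_alphabet()))
  me[1, "A"] <- 2.5
  ie <- matrix(0, 1, 20, dimnames = list(NULL, aa_alphabet()))
  tr <- cbind(MM = 0, MI = -2, MD = -3, IM = -1, II = -1, DM = -1, DD = -1,
              BM = -0.25, ME = -0.75)
  p <- profile_hmm("one", "H2", me, ie, tr, invariant = 0.5)
  a <- seq_dom_alignment("q", "one", "H2",
                         data.frame(state = "M", k = 1L, qpos = 1L,
                                    residue = "A", stringsAsFactors = FALSE))
  # entry (-0.25) + emission (2.5) + exit (-0.75) + invariant (0.5)
  expect_equal(reconstruct_score(a, p), -0.25 + 2.5 - 0.75 + 0.5)
})

test_that("viterbi and reconstruction agree with exhaustive path enumeration on small models", {
  set.seed(31)
  for (trial in 1:6) {
    K <- sample(2:4, 1)
    L <- sample(3:6, 1)
    dialect <- if (trial %% 2) "H2" else "H3"
    p <- random_profile(K, seed = 300 + trial, dialect = dialect, n_calib = 0)
    s <- random_aa_seq(L)
    mode <- if (dialect == "H2") "glocal" else "local"
    a <- viterbi_align(p, s, mode)
    oracle <- brute_force_best_score(p, s, mode)
    expect_equal(a$reported_score, oracle, tolerance = 1e-9,
                 label = sprintf("viterbi %s K=%d L=%d", mode, K, L))
    expect_equal(reconstruct_score(a, p), oracle, tolerance = 1e-9)
  }
})

test_that("glocal paths span the full model and local scores dominate glocal", {
  for (seed in 1:5) {
    p2 <- random_profile(6, seed = 400 + seed, dialect = "H2", n_calib = 0)
    p3 <- random_profile(6, seed = 400 + seed, dialect = "H3", n_calib = 0)
    set.seed(seed)
    s <- random_aa_seq(9)
    g <- viterbi_align(p2, s, "glocal")
    expect_equal(g$model_span, c(1L, 6L))
    # on the same emissions, the local path space contains competitive
    # cropped paths: local best >= glocal best minus the entry-term gap
    l <- viterbi_align(p3, s, "local")
    g3 <- viterbi_align(p3, s, "glocal")
    expect_gte(l$reported_score, g3$reported_score - 1e-9)
  }
})

test_that("dissection conserves the full score and credits invariant terms to the fold-critical sum", {
  for (seed in 1:8) {
    dialect <- if (seed %% 2) "H2" else "H3"
    p <- random_profile(8, seed = 500 + seed, dialect = dialect, n_calib = 0)
    set.seed(seed)
    s <- random_aa_seq(12)
    a <- viterbi_align(p, s, if (dialect == "H2") "glocal" else "local")
    full <- reconstruct_score(a, p)

    all_fc <- make_mask(p, rep("FOLD_CRITICAL", 8))
    sums <- dissect(a, p, all_fc)
    expect_equal(unname(sums["fc_sum"]), full, tolerance = 1e-9)
    expect_equal(unname(sums["rem_sum"]), 0)

    all_rem <- make_mask(p, rep("REMNANT", 8))
    sums2 <- dissect(a, p, all_rem)
    ct_inv <- sums2[["fc_sum"]]  # entry + exit + invariant only
    expect_equal(sums2[["rem_sum"]], full - ct_inv, tolerance = 1e-9)

    set.seed(seed * 13)
    lab <- sample(c("FOLD_CRITICAL", "REMNANT"), 8, replace = TRUE)
    sums3 <- dissect(a, p, make_mask(p, lab))
    expect_equal(sums3[["fc_sum"]] + sums3[["rem_sum"]], full,
                 tolerance = 1e-6)
  }
})

test_that("checkerboard dissection equals an independent per-column re-summation", {
  p <- tiny_profile(4, "H2", calibrated = FALSE)
  a <- viterbi_align(p, "ACDF", "glocal")
  lab <- c("FOLD_CRITICAL", "REMNANT", "FOLD_CRITICAL", "REMNANT")
  sums <- dissect(a, p, make_mask(p, lab))
  # oracle: walk the path, credit each record's emission + entering
  # transition to its column class, entry/exit to fold-critical
  tr <- p$transitions
  fc <- unname(tr[a$path$k[1], "BM"])
  last_md <- max(which(a$path$state != "I"))
  fc <- fc + unname(tr[a$path$k[last_md], "ME"])
  rem <- 0
  prev <- NULL
  for (i in seq_len(nrow(a$path))) {
    st <- a$path$state[i]; k <- a$path$k[i]
    contrib <- 0
    if (st == "M") contrib <- contrib + p$match_emissions[k, a$path$residue[i]]
    if (st == "I") contrib <- contrib + p$insert_emissions[k, a$path$residue[i]]
    if (!is.null(prev))
      contrib <- contrib + unname(tr[prev$k, paste0(prev$st, st)])
    if (lab[k] == "FOLD_CRITICAL") fc <- fc + contrib else rem <- rem + contrib
    prev <- list(st = st, k = k)
  }
  expect_equal(unname(sums["fc_sum"]), unname(fc), tolerance = 1e-9)
  expect_equal(unname(sums["rem_sum"]), unname(rem), tolerance = 1e-9)
})

test_that("moving one column between classes shifts exactly its credited contribution", {
  p <- random_profile(6, seed = 77, dialect = "H2", n_calib = 0)
  set.seed(77)
  a <- viterbi_align(p, random_aa_seq(9), "glocal")
  lab <- rep("REMNANT", 6)
  base <- dissect(a, p, make_mask(p, lab))
  for (k in 1:6) {
    lab2 <- lab; lab2[k] <- "FOLD_CRITICAL"
    moved <- dissect(a, p, make_mask(p, lab2))
    delta_fc <- moved[["fc_sum"]] - base[["fc_sum"]]
    delta_rem <- base[["rem_sum"]] - moved[["rem_sum"]]
    expect_equal(delta_fc, delta_rem, tolerance = 1e-9)
    # total conserved
    expect_equal(moved[["fc_sum"]] + moved[["rem_sum"]],
                 base[["fc_sum"]] + base[["rem_sum"]], tolerance = 1e-9)
  }
})

test_that("E-values match the closed forms and their limits", {
  ev <- evd_params(mu = 5, lam = 0.7, tail_kind = "gumbel", db_size = 1)
  expect_equal(evalue(5, ev), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(evalue(1e6, ev), 0)
  expect_equal(evalue(-1e6, ev), 1, tolerance = 1e-12)  # -> z
  ev2 <- evd_params(5, 0.7, "gumbel", db_size = 1000)
  expect_equal(evalue(-1e6, ev2), 1000, tolerance = 1e-9)
  # doubling z doubles E where P << 1
  x <- 30
  expect_equal(evalue(x, ev2, db_size = 2000), 2 * evalue(x, ev2),
               tolerance = 1e-9)
  # exponential tail: E = z * min(1, exp(-lam (x - tau)))
  et <- evd_params(mu = 3, lam = 0.6, tail_kind = "exponential_tail",
                   db_size = 10)
  expect_equal(evalue(8, et), 10 * exp(-0.6 * 5), tolerance = 1e-12)
  expect_equal(evalue(-100, et), 10)
})

test_that("E is strictly decreasing in the score for both tail kinds", {
  # below mu the Gumbel survival saturates at z within double precision, so
  # strictness is asserted over the representable range
  xs <- seq(-2, 900, by = 7)
  for (tk in c("gumbel", "exponential_tail")) {
    ev <- evd_params(2, 0.55, tk, db_size = 540261)
    lg <- vapply(xs, function(x) evalue(x, ev, log10 = TRUE), 0)
    if (tk == "exponential_tail") lg <- lg[xs >= 2]  # min(1, .) plateau
    expect_true(all(diff(lg) < 0))
  }
})

test_that("dissected E-values compose correctly and flag underflowing ratios", {
  p <- random_profile(8, seed = 88, dialect = "H2", n_calib = 200)
  set.seed(88)
  a <- viterbi_align(p, random_aa_seq(10), "glocal")
  all_fc <- make_mask(p, rep("FOLD_CRITICAL", 8))
  d <- dissect_evalues(a, p, all_fc)
  expect_equal(d$evalue_fc, d$evalue_original, tolerance = 1e-12)
  expect_s3_class(d, "dissected_score")

  # monotonicity: whenever both partial sums are below the full score the
  # partial E-values sit above the original
  set.seed(3)
  lab <- sample(c("FOLD_CRITICAL", "REMNANT"), 8, replace = TRUE)
  d2 <- dissect_evalues(a, p, make_mask(p, lab))
  if (d2$fc_sum <= d2$full_score && d2$rem_sum <= d2$full_score) {
    expect_gte(d2$evalue_fc, d2$evalue_original)
    expect_gte(d2$evalue_rem, d2$evalue_original)
  }
  if (d2$rem_sum > d2$fc_sum) expect_gt(d2$log10_ratio, 0)

  # remnant underflow to exact zero leaves the ratio undefined
  g <- generate_synthetic_profile(8, seed = 89, dialect = "H2", n_calib = 0)
  p4 <- g$profile
  p4$evd <- evd_params(-50, 10, "gumbel", db_size = 1)
  a4 <- viterbi_align(p4, g$consensus, "glocal")
  d3 <- dissect_evalues(a4, p4, make_mask(p4, rep("REMNANT", 8)))
  expect_identical(d3$evalue_rem, 0)
  expect_true(is.na(d3$log10_ratio))

  expect_error(dissect_evalues(a, tiny_profile(8, "H2", calibrated = FALSE),
                               all_fc), "uncalibrated|model_id")
})

test_that("uncalibrated profiles are refused by E-value operations only", {
  p <- tiny_profile(3, "H2", calibrated = FALSE)
  a <- viterbi_align(p, "ACD", "glocal")
  expect_true(is.finite(reconstruct_score(a, p)))
  expect_error(dissect_evalues(a, p, make_mask(p, rep("FOLD_CRITICAL", 3))),
               "uncalibrated")
})
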