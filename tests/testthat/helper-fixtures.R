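# Shared fixture builders and independent oracles.

# A tiny hand-specified profile: emissions/transitions chosen so scores can
# be summed by hand. Consensus "ACD" (first K letters of ACDEF...).
tiny_profile <- function(K = 3L, dialect = "H2", calibrated = TRUE) {
  cons <- aa_alphabet()[seq_len(K)]
  me <- matrix(-1, K, 20, dimnames = list(NULL, aa_alphabet()))
  me[cbind(seq_len(K), match(cons, aa_alphabet()))] <- 2
  ie <- matrix(0, K, 20, dimnames = list(NULL, aa_alphabet()))
  tp <- c(MM = -0.1, MI = -4, MD = -5, IM = -0.5, II = -2, DM = -0.5,
          DD = -2)
  tr <- matrix(rep(tp, each = K), K, 7, dimnames = list(NULL, names(tp)))
  if (dialect == "H2") {
    bm <- c(0, rep(-Inf, K - 1L)); mex <- c(rep(-Inf, K - 1L), 0)
  } else {
    bm <- rep(-log2(K), K); mex <- rep(0, K)
  }
  profile_hmm("tiny", dialect, me, ie, cbind(tr, BM = bm, ME = mex),
              evd = if (calibrated) evd_params(0, 0.7,
                if (dialect == "H2") "gumbel" else "exponential_tail",
                db_size = 1000) else NULL)
}

# random calibrated profile via the generator (finite transitions)
random_profile <- function(K, seed, dialect = "H2", n_calib = 300L) {
  generate_synthetic_profile(K, seed = seed, dialect = dialect,
                             n_calib = n_calib)$profile
}

random_aa_seq <- function(L) {
  paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
}

# Independent brute-force path enumeration oracle: explores every legal
# path of the state machine with its own score accumulation (no shared code
# with viterbi_align / reconstruct_score).
brute_force_best_score <- function(p, seq, mode) {
  res <- strsplit(seq, "")[[1]]
  L <- length(res); K <- p$K
  tr <- p$transitions
  em <- p$match_emissions; ei <- p$insert_emissions
  best <- -Inf
  rec <- function(state, k, q, sc, emitted) {
    if (mode == "local") {
      if (state == "M") best <<- max(best, sc + tr[k, "ME"])
    } else if (k == K && state != "I" && emitted) {
      best <<- max(best, sc + tr[K, "ME"])
    }
    if (state == "M") {
      if (k < K && q < L)
        rec("M", k + 1L, q + 1L, sc + tr[k, "MM"] + em[k + 1L, res[q + 1L]],
            TRUE)
      if (q < L)
        rec("I", k, q + 1L, sc + tr[k, "MI"] + ei[k, res[q + 1L]], TRUE)
      if (k < K) rec("D", k + 1L, q, sc + tr[k, "MD"], emitted)
    } else if (state == "I") {
      if (k < K && q < L)
        rec("M", k + 1L, q + 1L, sc + tr[k, "IM"] + em[k + 1L, res[q + 1L]],
            TRUE)
      if (q < L)
        rec("I", k, q + 1L, sc + tr[k, "II"] + ei[k, res[q + 1L]], TRUE)
    } else {
      if (k < K && q < L)
        rec("M", k + 1L, q + 1L, sc + tr[k, "DM"] + em[k + 1L, res[q + 1L]],
            TRUE)
      if (k < K) rec("D", k + 1L, q, sc + tr[k, "DD"], emitted)
    }
  }
  for (s in seq_len(L)) {
    if (mode == "local") {
      for (k0 in seq_len(K))
        if (is.finite(tr[k0, "BM"]))
          rec("M", k0, s, tr[k0, "BM"] + em[k0, res[s]], TRUE)
    } else {
      rec("M", 1L, s, tr[1L, "BM"] + em[1L, res[s]], TRUE)
      rec("D", 1L, s - 1L, tr[1L, "BM"], FALSE)
    }
  }
  best + p$invariant
}

# build a legal glocal all-match path by hand
manual_match_path <- function(res, k_start = 1L, q_start = 1L) {
  K <- length(res)
  data.frame(state = rep("M", K), k = seq.int(k_start, k_start + K - 1L),
             qpos = seq.int(q_start, q_start + K - 1L), residue = res,
             stringsAsFactors = FALSE)
}

make_mask <- function(p, labels) {
  column_mask(p$model_id, labels, "dssp_derived", merge_runs = FALSE)
}

# minimal classified-hit record for pair_hits tests
fake_hit <- function(query_id, model_id, variant, seq_span, model_span, K,
                     e_orig = 1e-5, e_fc = 1e-8, e_rem = 1, full = 50) {
  d <- structure(list(full_score = full, fc_sum = full, rem_sum = 0,
                      evalue_original = e_orig, evalue_fc = e_fc,
                      evalue_rem = e_rem,
                      log10_ratio = log10(e_fc) - log10(e_rem),
                      variant = variant),
                 class = "dissected_score")
  list(query_id = query_id, model_id = model_id, variant = variant,
       seq_span = seq_span, model_span = model_span, K = K,
       classified = classify(d))
}

flat_tables <- function(fpr2 = 0, fpr3 = 0) {
  # degenerate tables producing a constant FPR for any measure: all mass in
  # the top bin scaled is impossible, so build two-bin tables by hand
  mk <- function(v, mk_, f) {
    edges <- default_bin_edges()
    nb <- length(edges) - 1L
    freq <- c(f, rep(0, nb - 2L), 1 - f)
    calibration_table(freq, edges, v, mk_, provenance = "empirical")
  }
  list(H2_fc_evalue = mk("H2", "fc_evalue", fpr2),
       H2_ratio = mk("H2", "ratio", fpr2),
       H3_fc_evalue = mk("H3", "fc_evalue", fpr3),
       H3_ratio = mk("H3", "ratio", fpr3))
}
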