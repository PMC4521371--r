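# Synthetic fixture generation: profiles with planted consensus, calibrated
# EVD statistics from score simulations, and a small remote-homology
# benchmark with known truth labels. All randomness flows through the seed
# argument; the caller's RNG state is left untouched.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

random_sequence <- function(L, p = aa_background()) {
  paste(sample(aa_alphabet(), L, replace = TRUE, prob = p), collapse = "")
}

# emission probability rows: `focus` residue gets prob p0, rest share 1 - p0
peaked_emissions <- function(consensus, p0) {
  K <- length(consensus)
  m <- matrix((1 - p0) / 19, K, 20, dimnames = list(NULL, aa_alphabet()))
  m[cbind(seq_len(K), match(consensus, aa_alphabet()))] <- p0
  m
}

default_transition_probs <- function() {
  c(MM = 0.94, MI = 0.03, MD = 0.03, IM = 0.70, II = 0.30,
    DM = 0.70, DD = 0.30)
}

#' Fit Gumbel location/scale to a score sample by the method of moments
#'
#' `lambda = pi / (sd * sqrt(6))`, `mu = mean - gamma / lambda` (gamma the
#' Euler-Mascheroni constant). Used to calibrate synthetic profiles from
#' random-sequence score simulations.
#'
#' @param scores Numeric sample.
#' @return List with `mu` and `lam`.
#' @export
fit_gumbel_moments <- function(scores) {
  lam <- pi / (stats::sd(scores) * sqrt(6))
  list(mu = mean(scores) - 0.5772156649 / lam, lam = lam)
}

#' Generate a calibrated synthetic profile
#'
#' Builds a profile whose match emissions are elevated along a planted
#' consensus sequence (probability `p0` for the consensus residue at each
#' column, the rest uniform), with standard core transitions. Designated
#' remnant columns get a sharper low-complexity-like consensus (residue
#' `remnant_residue` at probability `remnant_p0`), emulating the conserved
#' non-globular stretches that attract spurious alignments. EVD statistics
#' are calibrated by aligning `n_calib` random background sequences and
#' fitting a Gumbel by moments (bound as the forward exponential tail for
#' the H3 dialect).
#'
#' @param K Number of match columns.
#' @param seed Integer seed; the same seed yields byte-identical profiles.
#' @param dialect `"H2"` (glocal entry/exit) or `"H3"` (uniform local
#'   entry).
#' @param planted_consensus Optional residue vector/string of length K;
#'   sampled uniformly when NULL.
#' @param remnant_cols Integer indices of remnant columns (may be empty).
#' @param p0,remnant_p0 Consensus emission probabilities (defaults 0.7 and
#'   0.95).
#' @param remnant_residue Residue planted in remnant columns (default "Q").
#' @param n_calib Random sequences for the EVD fit (default 1000); 0 skips
#'   calibration (uncalibrated profile).
#' @param db_size Effective database size bound into the EVD.
#' @param model_id Model name.
#' @return List with `profile` (a `profile_hmm`), `consensus` (string) and
#'   `remnant_cols`.
#' @export
generate_synthetic_profile <- function(K, seed, dialect = c("H2", "H3"),
                                       planted_consensus = NULL,
                                       remnant_cols = integer(0),
                                       p0 = 0.7, remnant_p0 = 0.95,
                                       remnant_residue = "Q",
                                       n_calib = 1000L, db_size = 540261L,
                                       model_id = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(K >= 1L)
  with_seed(seed, {
    cons <- if (is.null(planted_consensus)) {
      sample(aa_alphabet(), K, replace = TRUE)
    } else if (length(planted_consensus) == 1L) {
      strsplit(planted_consensus, "")[[1]]
    } else planted_consensus
    stopifnot(length(cons) == K)
    cons[remnant_cols] <- remnant_residue
    probs <- peaked_emissions(cons, p0)
    if (length(remnant_cols))
      probs[remnant_cols, ] <- peaked_emissions(cons[remnant_cols],
                                                remnant_p0)
    bg <- aa_background()
    me <- log2(sweep(probs, 2L, bg, `/`))
    ie <- matrix(0, K, 20, dimnames = list(NULL, aa_alphabet()))
    tp <- default_transition_probs()
    tr <- matrix(rep(log2(tp), each = K), K, 7,
                 dimnames = list(NULL, names(tp)))
    if (dialect == "H2") {
      bm <- c(0, rep(-Inf, K - 1L))
      mexit <- c(rep(-Inf, K - 1L), 0)
    } else {
      bm <- rep(-log2(K), K)
      mexit <- rep(0, K)
    }
    p <- profile_hmm(model_id %||% sprintf("synth_%s_K%d_s%d", dialect, K, seed),
                     dialect = dialect,
                     match_emissions = me, insert_emissions = ie,
                     transitions = cbind(tr, BM = bm, ME = mexit),
                     null_model = list(p = bg, ext = 0))
    if (n_calib > 0L) {
      Lc <- max(K + 6L, ceiling(1.2 * K))
      mode <- if (dialect == "H2") "glocal" else "local"
      calseqs <- vapply(seq_len(n_calib), function(i) random_sequence(Lc), "")
      sc <- viterbi_score_batch(p, calseqs, mode)
      fit <- fit_gumbel_moments(sc)
      p$evd <- evd_params(fit$mu, fit$lam,
                          if (dialect == "H2") "gumbel" else "exponential_tail",
                          db_size = db_size)
    }
    list(profile = p, consensus = paste(cons, collapse = ""),
         remnant_cols = remnant_cols)
  })
}

mutate_fc <- function(res, fc_cols, rate) {
  if (rate <= 0 || !length(fc_cols)) return(res)
  hit <- fc_cols[stats::runif(length(fc_cols)) < rate]
  res[hit] <- sample(aa_alphabet(), length(hit), replace = TRUE)
  res
}

#' Generate a synthetic remote-homology benchmark
#'
#' Emulates, at toy scale, a benchmark of structure-defined superfamilies
#' mapped to sequence-profile domain models. Each model consists of two
#' fold-critical blocks flanking a conserved low-complexity remnant block
#' (so the true column mask is known by construction) and is generated in
#' both dialects over the same emissions. Superfamily member sequences are
#' the model consensus with substitution noise in the fold-critical blocks;
#' a fraction of members (`fn_fraction`) additionally has its remnant
#' stretch replaced by a different low-complexity run, which wrecks the
#' remnant score sum while preserving the fold-critical one -- the planted
#' false negatives that dissection should rescue. Decoy sequences
#' (`contamination` fraction, superfamily label `"decoy"`, never mapped)
#' are background-random with the remnant consensus run planted, baiting
#' remnant-driven false positives that dissection should suppress.
#'
#' @param n_superfamilies,n_sequences,n_models Benchmark sizes: models are
#'   assigned to superfamilies round-robin; `n_sequences` member sequences
#'   per superfamily.
#' @param contamination Decoy sequences as a fraction of the total member
#'   count (default 0.3).
#' @param seed Integer seed.
#' @param fc_block,remnant_block Column counts of each fold-critical block
#'   and of the remnant block (defaults 12 and 30; K = 2 * fc_block +
#'   remnant_block).
#' @param mutation_rate Substitution rate in fold-critical columns of member
#'   sequences (default 0.15).
#' @param fn_fraction Fraction of member sequences with the remnant stretch
#'   scrambled (default 0.5).
#' @param n_calib EVD calibration sample per profile (default 1000).
#' @param db_size Effective database size.
#' @return List with `profiles` (per model: list of `H2`/`H3`
#'   `profile_hmm`s), `masks` (per model `column_mask`), `mapping`
#'   (data.frame superfamily_id/model_id), `sequences` (data.frame seq_id,
#'   superfamily, sequence, is_decoy, planted_fn) and `truth` (data.frame
#'   seq_id x model_id with logical `positive`).
#' @export
generate_benchmark <- function(n_superfamilies = 3L, n_sequences = 6L,
                               n_models = 6L, contamination = 0.3,
                               seed = 1L, fc_block = 12L, remnant_block = 30L,
                               mutation_rate = 0.15, fn_fraction = 0.5,
                               n_calib = 1000L, db_size = 540261L) {
  stopifnot(n_superfamilies >= 1L, n_sequences >= 1L, n_models >= 1L)
  K <- 2L * fc_block + remnant_block
  rem_cols <- seq.int(fc_block + 1L, fc_block + remnant_block)
  fc_cols <- setdiff(seq_len(K), rem_cols)
  sf_of_model <- ((seq_len(n_models) - 1L) %% n_superfamilies) + 1L
  model_ids <- sprintf("model%02d", seq_len(n_models))
  sf_ids <- sprintf("sf%d", seq_len(n_superfamilies))

  profiles <- list(); masks <- list(); consensi <- list()
  for (mi in seq_len(n_models)) {
    g2 <- generate_synthetic_profile(K, seed = seed * 1000L + mi,
                                     dialect = "H2",
                                     remnant_cols = rem_cols,
                                     n_calib = n_calib, db_size = db_size,
                                     model_id = model_ids[mi])
    g3 <- generate_synthetic_profile(K, seed = seed * 1000L + mi,
                                     dialect = "H3",
                                     remnant_cols = rem_cols,
                                     n_calib = n_calib, db_size = db_size,
                                     model_id = model_ids[mi])
    profiles[[model_ids[mi]]] <- list(H2 = g2$profile, H3 = g3$profile)
    consensi[[model_ids[mi]]] <- g2$consensus
    lab <- rep("FOLD_CRITICAL", K)
    lab[rem_cols] <- "REMNANT"
    masks[[model_ids[mi]]] <- column_mask(model_ids[mi], lab, "dssp_derived")
  }
  mapping <- data.frame(superfamily_id = sf_ids[sf_of_model],
                        model_id = model_ids, stringsAsFactors = FALSE)

  with_seed(seed * 7919L + 1L, {
    seqs <- list()
    for (si in seq_len(n_superfamilies)) {
      own <- model_ids[sf_of_model == si]
      for (j in seq_len(n_sequences)) {
        src <- own[((j - 1L) %% length(own)) + 1L]
        res <- strsplit(consensi[[src]], "")[[1]]
        res <- mutate_fc(res, fc_cols, mutation_rate)
        planted <- stats::runif(1) < fn_fraction
        if (planted) {
          # replace the remnant stretch by a different low-complexity run
          res[rem_cols] <- "A"
        }
        seqs[[length(seqs) + 1L]] <- data.frame(
          seq_id = sprintf("%s_seq%02d", sf_ids[si], j),
          superfamily = sf_ids[si],
          sequence = paste(res, collapse = ""),
          is_decoy = FALSE, planted_fn = planted, stringsAsFactors = FALSE)
      }
    }
    n_decoys <- round(contamination * n_superfamilies * n_sequences)
    for (j in seq_len(n_decoys)) {
      res <- strsplit(random_sequence(K), "")[[1]]
      bait <- model_ids[((j - 1L) %% n_models) + 1L]
      res[rem_cols] <- strsplit(consensi[[bait]], "")[[1]][rem_cols]
      seqs[[length(seqs) + 1L]] <- data.frame(
        seq_id = sprintf("decoy_seq%02d", j), superfamily = "decoy",
        sequence = paste(res, collapse = ""),
        is_decoy = TRUE, planted_fn = FALSE, stringsAsFactors = FALSE)
    }
    sequences <- do.call(rbind, seqs)
    truth <- expand.grid(seq_id = sequences$seq_id, model_id = model_ids,
                         stringsAsFactors = FALSE)
    truth$positive <- mapply(function(s, m) {
      sf <- sequences$superfamily[sequences$seq_id == s]
      !sequences$is_decoy[sequences$seq_id == s] &&
        mapping$superfamily_id[mapping$model_id == m] == sf
    }, truth$seq_id, truth$model_id)
    list(profiles = profiles, masks = masks, mapping = mapping,
         sequences = sequences, truth = truth, K = K)
  })
}
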