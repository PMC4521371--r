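#' Construct a profile hidden Markov model object
#'
#' The in-memory representation of a protein profile HMM shared by both
#' supported on-disk dialects (the HMMER2 save format and the HMMER3 text
#' format). All scores are held in bits (log2 odds against the null model)
#' regardless of the on-disk encoding: HMMER2 files store integers scaled by
#' 1000, HMMER3 files store negative natural-log probabilities; parsers
#' convert on read, writers convert back on write.
#'
#' @param model_id Model name/accession.
#' @param dialect `"H2"` (glocal-capable HMMER2 save format) or `"H3"`
#'   (local-only HMMER3 text format).
#' @param match_emissions K x 20 numeric matrix of match-state emission
#'   log-odds (bits), columns in `aa_alphabet()` order.
#' @param insert_emissions K x 20 matrix of insert-state emission log-odds
#'   (bits).
#' @param transitions K x 9 matrix with columns `MM, MI, MD, IM, II, DM, DD,
#'   BM, ME` of state-transition log-odds (bits). Row k holds transitions out
#'   of column k; `BM[k]` is the entry term B -> M_k and `ME[k]` the exit term
#'   M_k -> E.
#' @param null_model List with `p` (length-20 background emission
#'   probabilities summing to 1 within 1e-6) and `ext` (null length-extension
#'   log-odds term per emitted residue, bits; 0 in the packaged fixtures).
#' @param evd `evd_params()` object, or `NULL` for an uncalibrated profile.
#'   Uncalibrated profiles parse and score fine but any E-value computation
#'   on them fails loudly.
#' @param invariant Model-level position-independent score term (bits),
#'   e.g. entry/exit normalisation. Credited to the fold-critical sum during
#'   dissection.
#' @return Object of class `profile_hmm`.
#' @seealso [parse_profile()], [write_profile()], [viterbi_align()]
#' @export
profile_hmm <- function(model_id, dialect = c("H2", "H3"),
                        match_emissions, insert_emissions, transitions,
                        null_model = list(p = aa_background(), ext = 0),
                        evd = NULL, invariant = 0) {
  dialect <- match.arg(dialect)
  match_emissions <- as.matrix(match_emissions)
  insert_emissions <- as.matrix(insert_emissions)
  transitions <- as.matrix(transitions)
  K <- nrow(match_emissions)
  if (K < 1L) stop("profile must have at least one match column")
  if (ncol(match_emissions) != 20L || ncol(insert_emissions) != 20L)
    stop("emission tables must have 20 columns")
  if (nrow(insert_emissions) != K)
    stop("insert_emissions must have K = ", K, " rows")
  tcols <- c("MM", "MI", "MD", "IM", "II", "DM", "DD", "BM", "ME")
  if (nrow(transitions) != K || ncol(transitions) != 9L)
    stop("transitions must be a K x 9 matrix (MM MI MD IM II DM DD BM ME)")
  colnames(transitions) <- tcols
  colnames(match_emissions) <- colnames(insert_emissions) <- aa_alphabet()
  psum <- sum(null_model$p)
  if (abs(psum - 1) > 1e-6)
    stop("null-model emission probabilities must sum to 1 (got ",
         format(psum), ")")
  if (!is.null(evd) && !inherits(evd, "evd_params"))
    stop("evd must be an evd_params object or NULL")
  structure(
    list(model_id = as.character(model_id), dialect = dialect, K = K,
         alphabet = aa_alphabet(),
         match_emissions = match_emissions,
         insert_emissions = insert_emissions,
         transitions = transitions,
         null_model = null_model, evd = evd,
         invariant = as.numeric(invariant)),
    class = "profile_hmm")
}

#' Extreme-value statistics of a profile
#'
#' Location/scale parameters of the score null distribution used to turn a
#' bit score into an E-value. HMMER2 models carry a fitted Gumbel
#' (`tail_kind = "gumbel"`); HMMER3 models are evaluated against the
#' forward-score exponential tail (`tail_kind = "exponential_tail"`, with the
#' tail offset tau stored in `mu`).
#'
#' @param mu Location (Gumbel mu, or exponential tail offset tau), bits.
#' @param lam Scale lambda (> 0), per bit.
#' @param tail_kind `"gumbel"` or `"exponential_tail"`.
#' @param db_size Effective number of database comparisons z (>= 1). The
#'   default 540261 is the corrected search-database size used throughout the
#'   packaged thresholds.
#' @return Object of class `evd_params`.
#' @export
evd_params <- function(mu, lam, tail_kind = c("gumbel", "exponential_tail"),
                       db_size = 540261L) {
  tail_kind <- match.arg(tail_kind)
  if (!is.finite(lam) || lam <= 0) stop("lam must be > 0")
  if (db_size < 1) stop("db_size must be >= 1")
  structure(list(mu = as.numeric(mu), lam = as.numeric(lam),
                 tail_kind = tail_kind, db_size = as.numeric(db_size)),
            class = "evd_params")
}

is_calibrated <- function(p) !is.null(p$evd)

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm '%s' [%s], K = %d match columns\n",
              x$model_id, x$dialect, x$K))
  if (is_calibrated(x)) {
    cat(sprintf("  EVD: %s mu = %.3f lambda = %.4f (z = %g)\n",
                x$evd$tail_kind, x$evd$mu, x$evd$lam, x$evd$db_size))
  } else {
    cat("  uncalibrated (no EVD statistics; E-value operations will refuse it)\n")
  }
  invisible(x)
}

#' Construct a sequence-to-domain alignment
#'
#' One alignment path of a query sequence against a domain model, the object
#' over which score reconstruction and dissection sums are taken. The path is
#' a table of state records: match (M) records consume a model column and a
#' query residue, insert (I) records consume a query residue and sit after
#' model column `k`, delete (D) records consume a model column only.
#'
#' @param query_id,model_id Identifiers.
#' @param variant `"H2"` (glocal: model span must be the full model) or
#'   `"H3"` (local).
#' @param path `data.frame` with columns `state` ("M"/"I"/"D"), `k` (model
#'   column; for I records the preceding match column), `qpos` (1-based query
#'   position, NA for D), `residue` (NA for D).
#' @param reported_score,reported_evalue Optional bit score / E-value as
#'   reported by the search program.
#' @return Object of class `seq_dom_alignment` with `seq_span` and
#'   `model_span` derived from the first/last emitting records (1-based,
#'   inclusive).
#' @export
seq_dom_alignment <- function(query_id, model_id, variant = c("H2", "H3"),
                              path, reported_score = NA_real_,
                              reported_evalue = NA_real_) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(path),
            all(c("state", "k", "qpos", "residue") %in% names(path)))
  if (nrow(path) == 0L) stop("alignment path must contain at least one record")
  emit <- path$state %in% c("M", "I")
  if (!any(emit)) stop("alignment path must emit at least one residue")
  mcols <- path$k[path$state %in% c("M", "D")]
  structure(
    list(query_id = as.character(query_id), model_id = as.character(model_id),
         variant = variant, path = path,
         seq_span = range(path$qpos[emit]),
         model_span = if (length(mcols)) range(mcols) else c(NA_integer_, NA_integer_),
         reported_score = reported_score,
         reported_evalue = reported_evalue),
    class = "seq_dom_alignment")
}

#' @export
print.seq_dom_alignment <- function(x, ...) {
  cat(sprintf("seq_dom_alignment: %s vs %s [%s]\n", x$query_id, x$model_id,
              x$variant))
  cat(sprintf("  query %d-%d, model columns %d-%d, %d path records\n",
              x$seq_span[1], x$seq_span[2], x$model_span[1], x$model_span[2],
              nrow(x$path)))
  if (!is.na(x$reported_score))
    cat(sprintf("  reported score %.2f bits", x$reported_score),
        if (!is.na(x$reported_evalue)) sprintf(", E = %.3g", x$reported_evalue),
        "\n", sep = "")
  invisible(x)
}

#' Validate an alignment against its profile
#'
#' Structural diagnostics, not exceptions: checks that the path is a legal
#' state sequence (M may be followed by M/I/D, I by M/I, D by M/D; model
#' columns strictly increase over M/D records; query positions strictly
#' increase over M/I records), that columns fit the model, residues belong to
#' the alphabet, that a glocal (H2) alignment spans the full model, and that
#' the recorded spans agree with the first/last emitting records.
#'
#' @param a `seq_dom_alignment`.
#' @param p `profile_hmm` with matching `model_id`.
#' @return Character vector of diagnostics; empty when the alignment is legal.
#' @export
validate_alignment <- function(a, p) {
  stopifnot(inherits(a, "seq_dom_alignment"), inherits(p, "profile_hmm"))
  diag <- character(0)
  if (a$model_id != p$model_id)
    diag <- c(diag, sprintf("model_id mismatch: alignment '%s' vs profile '%s'",
                            a$model_id, p$model_id))
  path <- a$path
  st <- path$state
  if (!all(st %in% c("M", "I", "D")))
    diag <- c(diag, "path contains states outside {M, I, D}")
  allowed <- list(M = c("M", "I", "D"), I = c("M", "I"), D = c("M", "D"))
  if (nrow(path) > 1L) {
    for (i in seq_len(nrow(path) - 1L)) {
      if (!st[i + 1L] %in% allowed[[st[i]]]) {
        diag <- c(diag, sprintf("illegal transition %s->%s at record %d",
                                st[i], st[i + 1L], i))
        break
      }
    }
  }
  if (any(path$k < 1L | path$k > p$K, na.rm = TRUE))
    diag <- c(diag, sprintf("model column out of range 1..%d", p$K))
  md <- path$k[st %in% c("M", "D")]
  if (length(md) > 1L && any(diff(md) != 1L))
    diag <- c(diag, "model columns must increase by exactly 1 over M/D records")
  qp <- path$qpos[st %in% c("M", "I")]
  if (length(qp) > 1L && any(diff(qp) != 1L))
    diag <- c(diag, "query positions must increase by exactly 1 over M/I records")
  res <- path$residue[st %in% c("M", "I")]
  if (any(!res %in% p$alphabet))
    diag <- c(diag, "residues outside the model alphabet")
  if (a$variant == "H2" && length(md) &&
      !(min(md) == 1L && max(md) == p$K))
    diag <- c(diag, sprintf(
      "glocal (H2) alignment must span model columns (1, %d), got (%d, %d)",
      p$K, min(md), max(md)))
  emit <- st %in% c("M", "I")
  if (any(emit)) {
    sp <- range(path$qpos[emit])
    if (!isTRUE(all.equal(sp, a$seq_span)))
      diag <- c(diag, "seq_span disagrees with first/last emitting records")
  }
  if (length(md)) {
    ms <- range(md)
    if (!isTRUE(all.equal(as.numeric(ms), as.numeric(a$model_span))))
      diag <- c(diag, "model_span disagrees with first/last M/D records")
  }
  diag
}
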