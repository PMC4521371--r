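# Per-record score contributions along an alignment path.
#
# Record i contributes its emission (M/I states; deletes emit nothing) plus
# the transition entering its state from record i-1. The entry term
# (B -> first state), the exit term (last M/D -> E) and the model-level
# invariant term are position-independent and returned separately; during
# dissection they are credited to the fold-critical sum.
path_contributions <- function(a, p) {
  path <- a$path
  n <- nrow(path)
  tr <- p$transitions
  emit <- numeric(n)
  for (i in seq_len(n)) {
    st <- path$state[i]
    if (st == "M") emit[i] <- p$match_emissions[path$k[i], path$residue[i]]
    if (st == "I") emit[i] <- p$insert_emissions[path$k[i], path$residue[i]]
  }
  trans <- numeric(n)
  if (n > 1L) {
    for (i in 2L:n) {
      from <- path$state[i - 1L]; to <- path$state[i]
      kf <- path$k[i - 1L]
      trans[i] <- switch(paste0(from, to),
        MM = tr[kf, "MM"], MI = tr[kf, "MI"], MD = tr[kf, "MD"],
        IM = tr[kf, "IM"], II = tr[kf, "II"],
        DM = tr[kf, "DM"], DD = tr[kf, "DD"],
        stop("illegal state pair ", from, "->", to))
    }
  }
  first <- path$state[1L]
  # glocal paths may begin in D_1; entry is charged as B -> column 1
  entry <- unname(tr[path$k[1L], "BM"])
  if (first == "D") entry <- unname(tr[1L, "BM"])
  last_md <- which(path$state %in% c("M", "D"))
  exit <- if (length(last_md)) unname(tr[path$k[max(last_md)], "ME"]) else 0
  list(emit = emit, trans = trans, entry = entry, exit = exit,
       invariant = p$invariant)
}

#' Reconstruct the full alignment bit score from the model
#'
#' Sums emission log-odds over match/insert records, transition log-odds
#' along consecutive state pairs, and the entry/exit plus model-level
#' invariant terms. On alignments produced by [viterbi_align()] this equals
#' the reported score exactly; on parsed search output it reproduces the
#' program's per-domain bit score to within formatting precision.
#'
#' @param a `seq_dom_alignment` that passes [validate_alignment()].
#' @param p The alignment's `profile_hmm`.
#' @return Bit score (numeric scalar).
#' @export
reconstruct_score <- function(a, p) {
  d <- validate_alignment(a, p)
  if (length(d)) stop("invalid alignment: ", d[[1]])
  ct <- path_contributions(a, p)
  sum(ct$emit) + sum(ct$trans) + ct$entry + ct$exit + ct$invariant
}

#' Split an alignment score into fold-critical and remnant sums
#'
#' Credits each path record's contribution (its emission plus the transition
#' entering its state) to the class of its model column: match and delete
#' records to their own column's class, insert records to the class of the
#' match column they follow. The position-independent entry/exit/invariant
#' terms are credited to the fold-critical sum, keeping
#' `fc_sum + rem_sum == full_score` exact.
#'
#' @param a `seq_dom_alignment`.
#' @param p `profile_hmm`.
#' @param m [column_mask()] for the same model (`m$K == p$K`).
#' @return Named numeric vector `c(fc_sum =, rem_sum =)` in bits.
#' @export
dissect <- function(a, p, m) {
  stopifnot(inherits(m, "column_mask"))
  if (m$model_id != p$model_id)
    stop("mask model_id '", m$model_id, "' does not match profile '",
         p$model_id, "'")
  if (m$K != p$K) stop("mask length ", m$K, " does not match model length ", p$K)
  ct <- path_contributions(a, p)
  contrib <- ct$emit + ct$trans
  cls <- m$labels[a$path$k]
  fc <- sum(contrib[cls == "FOLD_CRITICAL"]) + ct$entry + ct$exit + ct$invariant
  rem <- sum(contrib[cls == "REMNANT"])
  c(fc_sum = fc, rem_sum = rem)
}

#' E-value of a bit score under the model's extreme-value statistics
#'
#' For a Gumbel tail, `E = z * (1 - exp(-exp(-lambda (x - mu))))`; for the
#' forward-score exponential tail, `E = z * min(1, exp(-lambda (x - tau)))`
#' with tau stored in `mu`. Both are strictly decreasing in the score.
#' Computation is done in log space; E-values below 1e-300 are reported as
#' exact zero (which downstream triggers the ratio-exclusion rule).
#'
#' @param score Bit score.
#' @param evd `evd_params`; an uncalibrated profile (NULL) is refused.
#' @param db_size Optional override of the EVD's effective database size.
#' @param log10 Return log10(E) instead (never underflows; `-Inf` only for a
#'   `+Inf` score).
#' @return E-value (or its log10).
#' @export
evalue <- function(score, evd, db_size = NULL, log10 = FALSE) {
  if (is.null(evd))
    stop("profile is uncalibrated: no EVD statistics available")
  stopifnot(inherits(evd, "evd_params"))
  z <- if (is.null(db_size)) evd$db_size else as.numeric(db_size)
  y <- evd$lam * (score - evd$mu)
  if (evd$tail_kind == "gumbel") {
    if (y > 30) {
      lg <- log10(z) - y / log(10)  # P ~ exp(-y) to double precision here
    } else {
      lg <- log10(z) + log10(-expm1(-exp(-y)))
    }
  } else {
    lg <- log10(z) + min(0, -y / log(10))
  }
  if (log10) return(lg)
  if (lg < -300) 0 else 10^lg
}

#' Dissect an alignment and re-evaluate all three sums as E-values
#'
#' Composes [reconstruct_score()], [dissect()] and [evalue()]: the full,
#' fold-critical and remnant score sums are each pushed through the model's
#' EVD, yielding the original, fold-critical and remnant E-values plus the
#' ratio measure `log10(evalue_fc / evalue_rem)`. The ratio is undefined
#' (`NA`) when the remnant E-value underflows to exact zero; such hits are
#' excluded from ratio-based calibration downstream.
#'
#' @inheritParams dissect
#' @param db_size Optional override of the effective database size.
#' @return Object of class `dissected_score` with fields `full_score`,
#'   `fc_sum`, `rem_sum`, `evalue_original`, `evalue_fc`, `evalue_rem`,
#'   `log10_ratio`, `variant`.
#' @export
dissect_evalues <- function(a, p, m, db_size = NULL) {
  if (!is_calibrated(p))
    stop("profile is uncalibrated: no EVD statistics available")
  full <- reconstruct_score(a, p)
  sums <- dissect(a, p, m)
  e_orig <- evalue(full, p$evd, db_size)
  e_fc <- evalue(sums[["fc_sum"]], p$evd, db_size)
  e_rem <- evalue(sums[["rem_sum"]], p$evd, db_size)
  ratio <- if (e_rem == 0) NA_real_ else {
    evalue(sums[["fc_sum"]], p$evd, db_size, log10 = TRUE) -
      evalue(sums[["rem_sum"]], p$evd, db_size, log10 = TRUE)
  }
  structure(list(full_score = full, fc_sum = unname(sums[["fc_sum"]]),
                 rem_sum = unname(sums[["rem_sum"]]),
                 evalue_original = e_orig, evalue_fc = e_fc,
                 evalue_rem = e_rem, log10_ratio = ratio,
                 variant = a$variant),
            class = "dissected_score")
}

#' @export
print.dissected_score <- function(x, ...) {
  cat(sprintf("dissected_score [%s]: full %.2f = fc %.2f + rem %.2f bits\n",
              x$variant, x$full_score, x$fc_sum, x$rem_sum))
  cat(sprintf("  E original %.3g | fold-critical %.3g | remnant %.3g | log10 ratio %s\n",
              x$evalue_original, x$evalue_fc, x$evalue_rem,
              if (is.na(x$log10_ratio)) "undefined (remnant E = 0)"
              else sprintf("%.2f", x$log10_ratio)))
  invisible(x)
}
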