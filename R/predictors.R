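#' Predictor weighting configuration
#'
#' Weights, decision threshold and post-processing parameters of the
#' weighted-scoring scheme that combines the four sequence-property
#' predictors into one per-column fold-criticality score. The default
#' weights are each predictor's best benchmark margin (TPR - FPR):
#' conservation quality score 0.61, secondary-structure prediction 0.50,
#' low-complexity (SEG) 0.41, globularity (GlobPlot) 0.39. A column whose
#' normalised weighted score is >= 0.5 is declared fold-critical. Models
#' whose alignment has fewer than `min_sequences_for_predictors` sequences
#' fall back to the conservation score alone.
#'
#' @param w_qualityscore,w_psipred,w_seg,w_globplot Predictor weights (> 0).
#' @param threshold Fold-critical decision threshold in (0, 1).
#' @param min_remnant_run Shortest remnant run kept after masking.
#' @param min_sequences_for_predictors Minimum MSA depth for the
#'   structure/complexity/globularity predictors to be used.
#' @return Object of class `weight_config`.
#' @export
weight_config <- function(w_qualityscore = 0.61, w_psipred = 0.50,
                          w_seg = 0.41, w_globplot = 0.39,
                          threshold = 0.5, min_remnant_run = 10L,
                          min_sequences_for_predictors = 5L) {
  w <- c(qualityscore = w_qualityscore, psipred = w_psipred,
         seg = w_seg, globplot = w_globplot)
  if (any(w <= 0)) stop("all weights must be > 0")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(list(weights = w, threshold = threshold,
                 min_remnant_run = as.integer(min_remnant_run),
                 min_sequences_for_predictors =
                   as.integer(min_sequences_for_predictors)),
            class = "weight_config")
}

#' Per-column predictor score vector
#'
#' @param predictor One of `"qualityscore"`, `"psipred"`, `"seg"`,
#'   `"globplot"`, `"external"`.
#' @param scores Length-K vector, each value in `[0, 1]`.
#' @param n_sequences Number of MSA sequences the scores summarise.
#' @return Object of class `predictor_scores`.
#' @export
predictor_scores <- function(predictor, scores, n_sequences) {
  predictor <- match.arg(predictor, c("qualityscore", "psipred", "seg",
                                      "globplot", "external"))
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  structure(list(predictor = predictor, scores = as.numeric(scores),
                 n_sequences = as.integer(n_sequences)),
            class = "predictor_scores")
}

as_msa_matrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  if (is.character(msa)) {
    m <- do.call(rbind, strsplit(msa, ""))
    rownames(m) <- names(msa)
    return(m)
  }
  as.matrix(msa)  # Biostrings MultipleAlignment and friends
}

#' Aggregate per-sequence structured/unstructured labels to columns
#'
#' Given an alignment and, for every sequence, a binary label per (ungapped)
#' residue with 1 = structured, computes the per-column score as the fraction
#' of non-gap residues labelled structured. All-gap columns score 0.
#'
#' @param msa Alignment: character matrix, vector of aligned strings, or a
#'   Biostrings MultipleAlignment.
#' @param per_residue_labels List (one element per sequence) of 0/1 vectors,
#'   each as long as the sequence's ungapped length.
#' @param predictor Predictor tag recorded on the result.
#' @return `predictor_scores` of length K = alignment width.
#' @export
predictor_column_scores <- function(msa, per_residue_labels,
                                    predictor = "external") {
  m <- as_msa_matrix(msa)
  n <- nrow(m); K <- ncol(m)
  if (length(per_residue_labels) != n)
    stop("need one label vector per sequence (", n, " sequences)")
  num <- den <- numeric(K)
  for (i in seq_len(n)) {
    nongap <- which(!m[i, ] %in% c("-", ".", " "))
    lab <- per_residue_labels[[i]]
    if (length(lab) != length(nongap))
      stop("label/sequence length mismatch for sequence ",
           rownames(m)[i] %||% i, ": ", length(lab), " labels vs ",
           length(nongap), " residues")
    num[nongap] <- num[nongap] + lab
    den[nongap] <- den[nongap] + 1
  }
  sc <- ifelse(den > 0, num / den, 0)
  predictor_scores(predictor, sc, n)
}

window_entropy <- function(counts, n) {
  f <- counts[counts > 0] / n
  -sum(f * log2(f))
}

#' Low-complexity labels by two-threshold windowed entropy segmentation
#'
#' Wootton-Federhen style segmentation: the Shannon entropy (bits) of the
#' residue composition in a sliding window is assigned to the window centre;
#' residues whose entropy falls at or below `locut` seed low-complexity
#' segments, which are extended in both directions while the entropy stays at
#' or below `hicut`. Sequences shorter than the window use a single
#' whole-sequence window. Ambiguous residues are excluded from the window
#' composition. Orientation: structured = 1, low-complexity = 0.
#'
#' @param sequence Protein sequence (string or residue vector).
#' @param window Window size (default 25).
#' @param locut,hicut Trigger and extension entropy thresholds in bits
#'   (defaults 3.1 and 3.4).
#' @return Integer vector of per-residue labels (1 structured,
#'   0 low-complexity).
#' @export
seg_labels <- function(sequence, window = 25L, locut = 3.1, hicut = 3.4) {
  res <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  L <- length(res)
  if (L < 1L) stop("sequence must have length >= 1")
  unk <- setdiff(unique(res), aa_alphabet())
  for (u in unk)
    warn_once(paste0("seg_", u),
              sprintf("residue '%s' excluded from complexity windows", u))
  idx <- match(res, aa_alphabet())
  w <- min(window, L)
  nwin <- L - w + 1L
  went <- numeric(nwin)
  for (s in seq_len(nwin)) {
    ii <- idx[s:(s + w - 1L)]
    ii <- ii[!is.na(ii)]
    went[s] <- if (length(ii)) window_entropy(tabulate(ii, 20L), length(ii))
               else Inf
  }
  # per-residue entropy = entropy of the window centred closest to it
  centre <- pmin(pmax(seq_len(L) - (w %/% 2L), 1L), nwin)
  h <- went[centre]
  low <- h <= locut
  ext <- h <= hicut
  lab <- rep(1L, L)
  if (any(low)) {
    r <- rle(ext)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      if (any(low[starts[j]:ends[j]])) lab[starts[j]:ends[j]] <- 0L
    }
  }
  lab
}

#' Globularity labels from a smoothed propensity running sum
#'
#' A running sum of per-residue globularity propensity (the negated disorder
#' propensity) is smoothed by a moving average over `smoothframe` residues;
#' the sign of its slope classifies each residue as being on an upward
#' (globularity-gaining) or downward stretch. Upward runs of at least
#' `dompeakframe` residues, after joining runs separated by at most
#' `domjoinframe`, become globular (structured = 1); downward runs of at
#' least `dispeakframe`, joined across gaps of at most `disjoinframe`,
#' become disordered (0); everything unassigned defaults to structured.
#' Sequences shorter than `dompeakframe` fall back entirely to the
#' structured default.
#'
#' @param sequence Protein sequence.
#' @param smoothframe,domjoinframe,dompeakframe,disjoinframe,dispeakframe
#'   Run-length parameters (defaults 10, 10, 40, 4, 5).
#' @param propensity Named per-residue disorder propensity vector; defaults
#'   to the packaged [disorder_propensity()] table.
#' @return Integer vector of per-residue labels (1 structured/globular,
#'   0 disordered).
#' @export
globplot_labels <- function(sequence, smoothframe = 10L, domjoinframe = 10L,
                            dompeakframe = 40L, disjoinframe = 4L,
                            dispeakframe = 5L,
                            propensity = disorder_propensity()) {
  res <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  L <- length(res)
  if (L < 1L) stop("sequence must have length >= 1")
  if (L < dompeakframe) return(rep(1L, L))  # documented boundary rule
  glob <- -propensity[res]
  unk <- is.na(glob)
  if (any(unk)) {
    for (u in unique(res[unk]))
      warn_once(paste0("glob_", u),
                sprintf("residue '%s' given neutral globularity propensity", u))
    glob[unk] <- 0
  }
  run <- cumsum(glob)
  sm <- stats::filter(run, rep(1 / smoothframe, smoothframe), sides = 2)
  sm[is.na(sm)] <- run[is.na(sm)]
  slope <- c(diff(as.numeric(sm)), 0)
  up <- slope > 0
  lab <- rep(1L, L)
  mark_runs <- function(flag, peak, join) {
    r <- rle(flag)
    # join qualifying runs separated by short gaps
    if (length(r$lengths) > 2L) {
      for (j in seq(2L, length(r$lengths) - 1L)) {
        if (!r$values[j] && r$lengths[j] <= join &&
            r$values[j - 1L] && r$values[j + 1L])
          r$values[j] <- TRUE
      }
      flag <- inverse.rle(r)
      r <- rle(flag)
    }
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= peak
    out <- rep(FALSE, length(flag))
    for (j in which(keep)) out[starts[j]:ends[j]] <- TRUE
    out
  }
  dom <- mark_runs(up, dompeakframe, domjoinframe)
  dis <- mark_runs(!up, dispeakframe, disjoinframe)
  lab[dis & !dom] <- 0L
  lab
}

#' Column conservation (quality) score of an alignment
#'
#' Per-column conservation in `[0, 1]`: for every pair of non-gap residues
#' the substitution-matrix similarity is normalised between the matrix
#' minimum and the smaller of the two diagonal (self) scores, the pair
#' values are averaged, and the column score is multiplied by the non-gap
#' fraction. A gap-free column of identical residues scores exactly 1; a
#' column drawn to minimise matrix similarity scores 0. Ambiguous residues
#' get the matrix-average similarity. Requires at least two sequences.
#'
#' @param msa Alignment (as in [predictor_column_scores()]).
#' @param substitution_matrix Square scoring matrix (default BLOSUM62 from
#'   Biostrings).
#' @return `predictor_scores` with predictor `"qualityscore"`.
#' @export
quality_score <- function(msa, substitution_matrix = NULL) {
  m <- as_msa_matrix(msa)
  if (nrow(m) < 2L)
    stop("conservation is undefined for a single-sequence alignment")
  S <- if (is.null(substitution_matrix)) blosum62_core() else substitution_matrix
  smin <- min(S)
  smean <- mean(S)
  aa <- rownames(S)
  sc <- numeric(ncol(m))
  for (k in seq_len(ncol(m))) {
    col <- m[, k]
    nongap <- col[!col %in% c("-", ".", " ")]
    nr <- length(nongap)
    if (nr == 0L) { sc[k] <- 0; next }
    if (nr == 1L) { sc[k] <- nr / nrow(m); next }
    known <- nongap %in% aa
    if (any(!known)) {
      for (u in unique(nongap[!known]))
        warn_once(paste0("qs_", u),
                  sprintf("residue '%s' scored at the matrix average", u))
    }
    pairs <- utils::combn(nr, 2L)
    pairval <- apply(pairs, 2L, function(ij) {
      a <- nongap[ij[1]]; b <- nongap[ij[2]]
      if (!(a %in% aa) || !(b %in% aa)) {
        v <- (smean - smin) / (max(S) - smin)
      } else {
        v <- (S[a, b] - smin) / (min(S[a, a], S[b, b]) - smin)
      }
      min(max(v, 0), 1)
    })
    sc[k] <- mean(pairval) * (nr / nrow(m))
  }
  predictor_scores("qualityscore", sc, nrow(m))
}

#' Weighted combination of predictor score vectors
#'
#' Position-wise weighted sum `sum_i score_i * w_i` over the supplied
#' predictor vectors. When the alignment has fewer sequences than the
#' configured floor, only the conservation (qualityscore) vector enters the
#' sum -- the other predictors are dropped before summing. The qualityscore
#' vector must always be present.
#'
#' @param vectors List of `predictor_scores`, all of the same length.
#' @param cfg [weight_config()].
#' @return Numeric length-K vector of weighted scores (not yet normalised).
#' @export
combine_weighted <- function(vectors, cfg = weight_config()) {
  stopifnot(all(vapply(vectors, inherits, TRUE, "predictor_scores")))
  preds <- vapply(vectors, `[[`, "", "predictor")
  if (!"qualityscore" %in% preds)
    stop("the qualityscore vector must be present")
  K <- length(vectors[[1]]$scores)
  if (!all(vapply(vectors, function(v) length(v$scores), 0L) == K))
    stop("predictor vectors differ in length")
  n_seq <- vectors[[match("qualityscore", preds)]]$n_sequences
  if (n_seq < cfg$min_sequences_for_predictors)
    vectors <- vectors[preds == "qualityscore"]
  out <- numeric(K)
  for (v in vectors) {
    w <- cfg$weights[[if (v$predictor == "external") "psipred" else v$predictor]]
    out <- out + v$scores * w
  }
  out
}

#' Min-max normalisation of the weighted score over a model's columns
#'
#' Rescales the weighted score to `[0, 1]` using the model's own minimum and
#' maximum. A constant vector is degenerate (no information): every column is
#' set to 0.5 -- exactly at the decision threshold -- with a warning, so the
#' downstream tie rule decides.
#'
#' @param weighted Numeric length-K vector.
#' @return Numeric vector in `[0, 1]` with min 0 and max 1 when the input is
#'   non-constant.
#' @export
normalize_scores <- function(weighted) {
  if (!length(weighted)) stop("empty score vector")
  lo <- min(weighted); hi <- max(weighted)
  if (hi - lo <= .Machine$double.eps * max(1, abs(hi))) {
    warning("degenerate normalisation: constant weighted scores; ",
            "returning 0.5 everywhere", call. = FALSE)
    return(rep(0.5, length(weighted)))
  }
  (weighted - lo) / (hi - lo)
}

#' ROC of predictor scores against reference masks
#'
#' Pools all score-residue pairs over the shared models, treats reference
#' `FOLD_CRITICAL` as the positive class, and sweeps the declaration
#' threshold (score >= t is a predicted fold-critical residue) over a grid.
#'
#' @param predicted Named list of numeric score vectors (one per model).
#' @param reference Named list of `column_mask` (same models, same K).
#' @param thresholds Threshold grid (default 0.05 to 0.95 by 0.05).
#' @return data.frame with threshold, tp, fp, fn, tn, tpr, fpr and margin
#'   (tpr - fpr).
#' @export
predictor_roc <- function(predicted, reference,
                          thresholds = seq(0.05, 0.95, by = 0.05)) {
  common <- intersect(names(predicted), names(reference))
  if (!length(common)) stop("predicted and reference share no models")
  scores <- unlist(predicted[common], use.names = FALSE)
  truth <- unlist(lapply(reference[common], function(m)
    m$labels == "FOLD_CRITICAL"), use.names = FALSE)
  if (length(scores) != length(truth))
    stop("score/mask length mismatch over the shared models")
  out <- lapply(thresholds, function(t) {
    pred <- scores >= t
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
    data.frame(threshold = t, tp = tp, fp = fp, fn = fn, tn = tn,
               tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_)
  })
  out <- do.call(rbind, out)
  out$margin <- out$tpr - out$fpr
  out
}
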