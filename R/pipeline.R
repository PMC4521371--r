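#' Hit classification thresholds
#'
#' Original and fold-critical E-value cutoffs per search variant. Defaults:
#' original E 0.1 (H2, the manual's trusted-hit cutoff) and 1e-3 (H3, the
#' cutoff matching the same benchmark false-positive rate), fold-critical E
#' 10^-3.45 (H2) and 10^-6 (H3), both preset at a fold-critical FPR of 0.1.
#'
#' @param h2_e,h3_e Original E-value cutoffs.
#' @param h2_fce,h3_fce Fold-critical E-value cutoffs.
#' @return Object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(h2_e = 0.1, h3_e = 1e-3,
                                      h2_fce = 10^-3.45, h3_fce = 1e-6) {
  v <- c(h2_e, h3_e, h2_fce, h3_fce)
  if (any(v <= 0)) stop("all cutoffs must be > 0")
  structure(list(H2 = list(original_e_cutoff = h2_e, fc_e_cutoff = h2_fce),
                 H3 = list(original_e_cutoff = h3_e, fc_e_cutoff = h3_fce)),
            class = "classification_thresholds")
}

#' Classify a dissected hit
#'
#' Implements the four-way criteria over the original and fold-critical
#' E-values (remnant E is consulted only to confirm the false-positive
#' class):
#'
#' * `TP`: original E <= cutoff and fold-critical E <= fc cutoff;
#' * `FN`: original E > cutoff but fold-critical E <= fc cutoff -- the
#'   rescued fold-related class;
#' * `TN`: original E > cutoff and fold-critical E > fc cutoff;
#' * `FP`: original E <= cutoff with fold-critical E > fc cutoff (a hit
#'   whose significance is not fold-supported; typically the remnant
#'   E-value <= fc cutoff carries it).
#'
#' Only TP and FN hits are retained for downstream merging.
#'
#' @param d `dissected_score`.
#' @param t [classification_thresholds()].
#' @return List (class `classified_hit`) with `label` and `retained`.
#' @export
classify <- function(d, t = classification_thresholds()) {
  stopifnot(inherits(d, "dissected_score"))
  cut <- t[[d$variant]]
  orig_sig <- d$evalue_original <= cut$original_e_cutoff
  fc_sig <- d$evalue_fc <= cut$fc_e_cutoff
  label <- if (orig_sig && fc_sig) "TP"
    else if (!orig_sig && fc_sig) "FN"
    else if (!orig_sig && !fc_sig) "TN"
    else {
      # original significant, fold-critical not: false positive; the remnant
      # E-value is what typically carried the hit
      if (is.na(d$evalue_rem))
        stop("remnant E-value required to decide the FP branch")
      "FP"
    }
  structure(list(dissected = d, label = label,
                 retained = label %in% c("TP", "FN")),
            class = "classified_hit")
}

#' Overlap ratio of two sequence segments
#'
#' The generalized overlap: `L = min(b_i, b_j) - max(a_i, a_j)` clamped at 0,
#' divided by each segment's own length `b - a`, taking the minimum. For a
#' segment i preceding a non-nested segment j this reduces to
#' `min((b_i - a_j)/(b_i - a_i), (b_i - a_j)/(b_j - a_j))`; the generalized
#' intersection also handles nesting, where the shorter form would miscount.
#'
#' @param span_i,span_j Length-2 vectors `(a, b)` with `a < b` (1-based
#'   positions; the operation sorts the two segments internally).
#' @return Overlap ratio in `[0, 1]`.
#' @export
overlap_ratio <- function(span_i, span_j) {
  if (diff(span_i) <= 0 || diff(span_j) <= 0)
    stop("zero-length span")
  L <- min(span_i[2], span_j[2]) - max(span_i[1], span_j[1])
  if (L <= 0) return(0)
  min(L / diff(span_i), L / diff(span_j))
}

#' Pair overlapping H2/H3 hits into merged records
#'
#' For each (query, model), retained H2 (glocal) and H3 (local) hits whose
#' query spans overlap at ratio >= `min_overlap` are paired greedily by
#' descending overlap (ties broken by lower H3 start, then lower H2 start);
#' each hit is used at most once and pairing never crosses model ids.
#' Unpaired hits become orphan merged records.
#'
#' Each element of `h2_hits` / `h3_hits` is a list with `query_id`,
#' `model_id`, `seq_span`, `model_span`, `K`, `classified` (a
#' `classified_hit`); only retained (TP/FN) hits should be supplied.
#'
#' @param h2_hits,h3_hits Lists as above (possibly empty).
#' @param min_overlap Pairing threshold (default 0.9).
#' @return List of `merged_hit` objects: fields `query_id`, `model_id`,
#'   `h2`, `h3` (hit or NULL), `coverage_h2` (1 when present), `coverage_h3`
#'   (aligned model columns / K).
#' @export
pair_hits <- function(h2_hits, h3_hits, min_overlap = 0.9) {
  keys <- unique(c(vapply(h2_hits, hit_key, ""), vapply(h3_hits, hit_key, "")))
  merged <- list()
  for (key in keys) {
    g2 <- Filter(function(h) hit_key(h) == key, h2_hits)
    g3 <- Filter(function(h) hit_key(h) == key, h3_hits)
    cand <- list()
    if (length(g2) && length(g3)) {
      for (i in seq_along(g2)) for (j in seq_along(g3)) {
        ov <- overlap_ratio(g2[[i]]$seq_span, g3[[j]]$seq_span)
        if (ov >= min_overlap)
          cand[[length(cand) + 1L]] <- c(i = i, j = j, ov = ov,
                                         s3 = g3[[j]]$seq_span[1],
                                         s2 = g2[[i]]$seq_span[1])
      }
    }
    used2 <- logical(length(g2)); used3 <- logical(length(g3))
    if (length(cand)) {
      cm <- do.call(rbind, cand)
      cm <- cm[order(-cm[, "ov"], cm[, "s3"], cm[, "s2"]), , drop = FALSE]
      for (r in seq_len(nrow(cm))) {
        i <- cm[r, "i"]; j <- cm[r, "j"]
        if (used2[i] || used3[j]) next
        used2[i] <- used3[j] <- TRUE
        merged[[length(merged) + 1L]] <- merged_hit(g2[[i]], g3[[j]])
      }
    }
    for (i in which(!used2))
      merged[[length(merged) + 1L]] <- merged_hit(g2[[i]], NULL)
    for (j in which(!used3))
      merged[[length(merged) + 1L]] <- merged_hit(NULL, g3[[j]])
  }
  merged
}

hit_key <- function(h) paste(h$query_id, h$model_id, sep = "\r")

merged_hit <- function(h2, h3) {
  src <- if (!is.null(h2)) h2 else h3
  cov3 <- if (!is.null(h3)) (h3$model_span[2] - h3$model_span[1] + 1) / h3$K
          else NA_real_
  structure(list(query_id = src$query_id, model_id = src$model_id,
                 h2 = h2, h3 = h3,
                 coverage_h2 = if (!is.null(h2)) 1 else NA_real_,
                 coverage_h3 = cov3),
            class = "merged_hit")
}

measure_fprs <- function(hit, tables) {
  # hit: one side of a merged hit (or NULL); tables: named list keyed
  # "H2_fc_evalue", "H2_ratio", "H3_fc_evalue", "H3_ratio"
  if (is.null(hit)) return(c(ratio = NA_real_, fce = NA_real_))
  d <- hit$classified$dissected
  v <- d$variant
  fce_tab <- tables[[paste0(v, "_fc_evalue")]]
  ratio_tab <- tables[[paste0(v, "_ratio")]]
  if (is.null(fce_tab) || is.null(ratio_tab))
    stop("missing calibration table for variant ", v)
  lfc <- if (d$evalue_fc == 0) -Inf else log10(d$evalue_fc)
  c(ratio = if (is.na(d$log10_ratio)) NA_real_
            else fpr_lookup(ratio_tab, d$log10_ratio),
    fce = fpr_lookup(fce_tab, lfc))
}

#' Error-adjusted domain coverage of a merged hit
#'
#' For a paired hit, `coverage = 1/2 [(1 - fpr_H2) cov_H2 +
#' (1 - fpr_H3) cov_H3]` per measure (ratio and fold-critical E-value), with
#' each variant's measure-level FPR looked up in its calibration table. For
#' an orphan hit the half factor is dropped: `coverage = (1 - fpr) cov` of
#' the present variant (set `halve_orphans = TRUE` for the strict halved
#' reading). A side whose ratio measure is undefined (remnant E underflowed
#' to 0) is treated as absent for the ratio-based coverage, which then falls
#' back to the defined side; when no side has a defined measure the coverage
#' is `NA`. The fold-critical-E-based coverage is always computed.
#'
#' @param m `merged_hit`.
#' @param tables Named list of calibration tables keyed
#'   `"H2_fc_evalue"`, `"H2_ratio"`, `"H3_fc_evalue"`, `"H3_ratio"`.
#' @param halve_orphans Apply the 1/2 factor to orphan hits too.
#' @return The `merged_hit` with fields `fpr_ratio_h2`, `fpr_fce_h2`,
#'   `fpr_ratio_h3`, `fpr_fce_h3`, `coverage_ratio`, `coverage_fce` filled.
#' @export
error_adjusted_coverage <- function(m, tables, halve_orphans = FALSE) {
  stopifnot(inherits(m, "merged_hit"))
  f2 <- measure_fprs(m$h2, tables)
  f3 <- measure_fprs(m$h3, tables)
  m$fpr_ratio_h2 <- f2[["ratio"]]; m$fpr_fce_h2 <- f2[["fce"]]
  m$fpr_ratio_h3 <- f3[["ratio"]]; m$fpr_fce_h3 <- f3[["fce"]]
  # a side whose measure is undefined (remnant E underflow for the ratio)
  # is treated as absent for that measure; both sides undefined -> NA
  comb <- function(fpr2, fpr3) {
    t2 <- if (!is.null(m$h2) && !is.na(fpr2)) (1 - fpr2) * m$coverage_h2
          else NA_real_
    t3 <- if (!is.null(m$h3) && !is.na(fpr3)) (1 - fpr3) * m$coverage_h3
          else NA_real_
    if (!is.na(t2) && !is.na(t3)) {
      (t2 + t3) / 2
    } else if (is.na(t2) && is.na(t3)) {
      NA_real_
    } else {
      v <- if (!is.na(t2)) t2 else t3
      if (halve_orphans) v / 2 else v
    }
  }
  m$coverage_ratio <- comb(m$fpr_ratio_h2, m$fpr_ratio_h3)
  m$coverage_fce <- comb(m$fpr_fce_h2, m$fpr_fce_h3)
  m
}

#' Total false-positive rate of a hit
#'
#' The sum of the two independent ROC-derived FPRs of the hit's ratio-based
#' and fold-critical-E-based coverage scores. It ranges over `[0, 2]` -- a
#' sum of two error rates, not a probability -- and is the ascending sort key
#' for reported hits.
#'
#' @param roc_fpr_ratio,roc_fpr_fce Component FPRs in `[0, 1]`.
#' @return Their sum.
#' @export
total_fpr <- function(roc_fpr_ratio, roc_fpr_fce) {
  stopifnot(all(roc_fpr_ratio >= 0 & roc_fpr_ratio <= 1, na.rm = TRUE),
            all(roc_fpr_fce >= 0 & roc_fpr_fce <= 1, na.rm = TRUE))
  roc_fpr_ratio + roc_fpr_fce
}

#' Finalise merged hits with ROC FPRs and total FPR
#'
#' Looks up each coverage score in the corresponding benchmark ROC table,
#' sums the two FPRs into the total FPR, and returns a report table sorted
#' ascending by total FPR (stable: ties preserve input order).
#'
#' @param merged List of `merged_hit` with coverages filled (see
#'   [error_adjusted_coverage()]).
#' @param roc_ratio,roc_fce `roc_table`s for the two measures.
#' @return data.frame, one row per merged hit, with coverage scores, ROC
#'   FPRs and `total_fpr`, sorted ascending by `total_fpr`.
#' @export
rank_hits <- function(merged, roc_ratio, roc_fce) {
  rows <- lapply(merged, function(m) {
    rr <- if (is.na(m$coverage_ratio)) NA_real_
          else roc_fpr_lookup(roc_ratio, m$coverage_ratio)
    rf <- if (is.na(m$coverage_fce)) NA_real_
          else roc_fpr_lookup(roc_fce, m$coverage_fce)
    data.frame(
      query_id = m$query_id, model_id = m$model_id,
      seq_from = min(c(if (!is.null(m$h2)) m$h2$seq_span[1],
                       if (!is.null(m$h3)) m$h3$seq_span[1])),
      seq_to = max(c(if (!is.null(m$h2)) m$h2$seq_span[2],
                     if (!is.null(m$h3)) m$h3$seq_span[2])),
      coverage_h2 = m$coverage_h2, coverage_h3 = m$coverage_h3,
      evalue_h2 = if (!is.null(m$h2))
        m$h2$classified$dissected$evalue_original else NA_real_,
      evalue_h3 = if (!is.null(m$h3))
        m$h3$classified$dissected$evalue_original else NA_real_,
      coverage_ratio = m$coverage_ratio, roc_fpr_ratio = rr,
      coverage_fce = m$coverage_fce, roc_fpr_fce = rf,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$total_fpr <- ifelse(is.na(df$roc_fpr_ratio) | is.na(df$roc_fpr_fce),
                         NA_real_,
                         total_fpr(df$roc_fpr_ratio, df$roc_fpr_fce))
  df[order(df$total_fpr, method = "radix", na.last = TRUE), , drop = FALSE]
}

#' Domain-wise scores over the sequences of one alignment
#'
#' Gathers the merged hits of all sequences of a multiple alignment by
#' domain model and measure, and averages the coverage scores across the
#' hitting sequences: each sequence contributes the maximum coverage of its
#' hits to the model (a domain is detected by its best-supported hit).
#'
#' @param merged List of `merged_hit` with coverages filled; each must carry
#'   `query_id` identifying its sequence.
#' @return data.frame with `model_id`, `measure_kind`, `value`,
#'   `n_contributing_sequences`.
#' @export
domain_scores <- function(merged) {
  if (!length(merged)) {
    return(data.frame(model_id = character(), measure_kind = character(),
                      value = numeric(),
                      n_contributing_sequences = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(merged, function(m)
    data.frame(model_id = m$model_id, query_id = m$query_id,
               ratio = m$coverage_ratio, fce = m$coverage_fce,
               stringsAsFactors = FALSE)))
  out <- list()
  for (mk in c("ratio", "fce")) {
    vals <- df[[mk]]
    sub <- df[!is.na(vals), , drop = FALSE]
    if (!nrow(sub)) next
    per_seq <- stats::aggregate(sub[[mk]],
                                by = list(model_id = sub$model_id,
                                          query_id = sub$query_id), FUN = max)
    agg <- stats::aggregate(per_seq$x, by = list(model_id = per_seq$model_id),
                            FUN = mean)
    n <- stats::aggregate(per_seq$x, by = list(model_id = per_seq$model_id),
                          FUN = length)
    out[[mk]] <- data.frame(model_id = agg$model_id, measure_kind = mk,
                            value = agg$x,
                            n_contributing_sequences = n$x,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Plain-coverage baseline scores from local hits only
#'
#' The un-dissected reference: local (H3) hits are filtered by their reported
#' original E-value at the given cutoff and the domain-wise score is simply
#' the domain coverage of the kept hits (no error adjustment, no glocal
#' term), aggregated like [domain_scores()].
#'
#' @param h3_hits List of hit records (as in [pair_hits()]), each with
#'   `evalue_original` reachable via `classified$dissected` or a `evalue`
#'   field.
#' @param evalue_cutoff Original E-value cutoff (0.1, 1 or 10 in the
#'   benchmark protocol).
#' @return data.frame with `model_id`, `measure_kind = "coverage"`, `value`,
#'   `n_contributing_sequences`.
#' @export
hmmer3_baseline_scores <- function(h3_hits, evalue_cutoff = 0.1) {
  if (!length(h3_hits)) {
    return(data.frame(model_id = character(), measure_kind = character(),
                      value = numeric(),
                      n_contributing_sequences = integer(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(h3_hits, function(h) {
    ev <- if (!is.null(h$classified)) h$classified$dissected$evalue_original
          else h$evalue
    data.frame(model_id = h$model_id, query_id = h$query_id, evalue = ev,
               coverage = (h$model_span[2] - h$model_span[1] + 1) / h$K,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[df$evalue <= evalue_cutoff, , drop = FALSE]
  if (!nrow(df)) {
    return(data.frame(model_id = character(), measure_kind = character(),
                      value = numeric(),
                      n_contributing_sequences = integer(),
                      stringsAsFactors = FALSE))
  }
  per_seq <- stats::aggregate(df$coverage,
                              by = list(model_id = df$model_id,
                                        query_id = df$query_id), FUN = max)
  agg <- stats::aggregate(per_seq$x, by = list(model_id = per_seq$model_id),
                          FUN = mean)
  n <- stats::aggregate(per_seq$x, by = list(model_id = per_seq$model_id),
                        FUN = length)
  data.frame(model_id = agg$model_id, measure_kind = "coverage",
             value = agg$x, n_contributing_sequences = n$x,
             stringsAsFactors = FALSE)
}
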