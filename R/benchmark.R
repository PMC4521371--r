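#' Run the full dissection pipeline over a synthetic benchmark
#'
#' Aligns every sequence against every model in both modes (glocal for the
#' H2 profile, local for the H3 one), dissects and re-evaluates each
#' alignment, builds empirical FPR calibration tables from the negative
#' hits (E-value candidate listing at `evalue_list_cutoff`), classifies hits
#' and retains the TP/FN classes, pairs overlapping H2/H3 hits, computes
#' error-adjusted coverages and domain-wise scores per (superfamily, model),
#' plus the plain local-hit coverage baseline at an original-E cutoff.
#'
#' @param bench A [generate_benchmark()] result.
#' @param thresholds [classification_thresholds()].
#' @param evalue_list_cutoff Candidate listing cutoff (default 20).
#' @param min_overlap Pairing overlap threshold (default 0.9).
#' @param baseline_cutoff Original-E cutoff of the baseline (default 0.1).
#' @return List with `hits` (per-alignment data.frame), `tables`
#'   (calibration tables), `merged` (merged hits with coverages),
#'   `domain_points` (per superfamily x model: dissected scores for both
#'   measures, baseline score, truth label), and `report` (ranked hit table
#'   once ROC tables exist).
#' @export
run_dissection_benchmark <- function(bench,
                                     thresholds = classification_thresholds(),
                                     evalue_list_cutoff = 20,
                                     min_overlap = 0.9,
                                     baseline_cutoff = 0.1) {
  seqs <- bench$sequences
  model_ids <- names(bench$profiles)
  hit_rows <- list()
  hit_objs <- list()
  for (i in seq_len(nrow(seqs))) {
    for (m in model_ids) {
      for (v in c("H2", "H3")) {
        p <- bench$profiles[[m]][[v]]
        a <- viterbi_align(p, seqs$sequence[i],
                           if (v == "H2") "glocal" else "local")
        a$query_id <- seqs$seq_id[i]
        d <- dissect_evalues(a, p, bench$masks[[m]])
        key <- paste(seqs$seq_id[i], m, v)
        hit_objs[[key]] <- list(query_id = seqs$seq_id[i], model_id = m,
                                variant = v, seq_span = a$seq_span,
                                model_span = a$model_span, K = p$K,
                                alignment = a, dissected = d)
        hit_rows[[key]] <- data.frame(
          query_id = seqs$seq_id[i], model_id = m, variant = v,
          query_superfamily = seqs$superfamily[i],
          evalue_original = d$evalue_original,
          log10_fc = if (d$evalue_fc == 0) -Inf else log10(d$evalue_fc),
          log10_ratio = d$log10_ratio,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- do.call(rbind, hit_rows)

  neg <- collect_negative_measures(hits, bench$mapping, evalue_list_cutoff)
  tables <- list()
  for (v in c("H2", "H3")) {
    fc <- neg[[v]]$fc %||% numeric(0)
    ra <- neg[[v]]$ratio %||% numeric(0)
    tables[[paste0(v, "_fc_evalue")]] <-
      if (length(fc)) build_fpr_table(fc, v, "fc_evalue")
      else packaged_anchor_table(v, "fc_evalue")
    tables[[paste0(v, "_ratio")]] <-
      if (length(ra)) build_fpr_table(ra, v, "ratio")
      else packaged_anchor_table(v, "ratio")
  }

  # classify, keep TP/FN, candidate-filter at the listing cutoff
  retained2 <- list(); retained3 <- list()
  for (h in hit_objs) {
    if (h$dissected$evalue_original > evalue_list_cutoff &&
        h$dissected$evalue_fc > thresholds[[h$variant]]$fc_e_cutoff) next
    cl <- classify(h$dissected, thresholds)
    if (!cl$retained) next
    h$classified <- cl
    if (h$variant == "H2") retained2[[length(retained2) + 1L]] <- h
    else retained3[[length(retained3) + 1L]] <- h
  }
  merged <- pair_hits(retained2, retained3, min_overlap)
  merged <- lapply(merged, error_adjusted_coverage, tables = tables)

  # domain-wise score points per (superfamily, model); unhit pairs score 0
  members <- seqs[!seqs$is_decoy, , drop = FALSE]
  sf_ids <- unique(members$superfamily)
  ds <- domain_scores(merged)
  sf_of_query <- stats::setNames(seqs$superfamily, seqs$seq_id)
  dp <- expand.grid(superfamily = sf_ids, model_id = model_ids,
                    stringsAsFactors = FALSE)
  score_of <- function(sf, m, kind) {
    vals <- vapply(merged, function(x) {
      if (x$model_id == m && sf_of_query[[x$query_id]] == sf) {
        v <- if (kind == "ratio") x$coverage_ratio else x$coverage_fce
        if (is.na(v)) 0 else v
      } else NA_real_
    }, 0)
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(0)
    # per-sequence max, then mean over hitting sequences
    qs <- vapply(merged, function(x)
      if (x$model_id == m && sf_of_query[[x$query_id]] == sf) x$query_id
      else NA_character_, "")
    mean(tapply(vals, qs[!is.na(qs)], max))
  }
  dp$score_ratio <- mapply(score_of, dp$superfamily, dp$model_id, "ratio")
  dp$score_fce <- mapply(score_of, dp$superfamily, dp$model_id, "fce")
  dp$score_baseline <- 0
  for (r in seq_len(nrow(dp))) {
    sf <- dp$superfamily[r]; m <- dp$model_id[r]
    h3 <- Filter(function(h) h$variant == "H3" && h$model_id == m &&
                   sf_of_query[[h$query_id]] == sf &&
                   h$dissected$evalue_original <= baseline_cutoff, hit_objs)
    if (length(h3)) {
      cov <- vapply(h3, function(h)
        (h$model_span[2] - h$model_span[1] + 1) / h$K, 0)
      qs <- vapply(h3, `[[`, "", "query_id")
      dp$score_baseline[r] <- mean(tapply(cov, qs, max))
    }
  }
  dp$positive <- mapply(function(sf, m)
    any(bench$mapping$superfamily_id == sf & bench$mapping$model_id == m),
    dp$superfamily, dp$model_id)

  report <- NULL
  if (any(dp$positive) && !all(dp$positive)) {
    roc_ratio <- roc_from_scores(dp$score_ratio, dp$positive, "ratio")
    roc_fce <- roc_from_scores(dp$score_fce, dp$positive, "fc_evalue")
    report <- rank_hits(merged, roc_ratio, roc_fce)
  }

  list(hits = hits, tables = tables, merged = merged, domain_points = dp,
       report = report, domain_scores = ds)
}

#' Partial area under a ROC curve up to an FPR bound
#'
#' Trapezoidal area of TPR over FPR restricted to `fpr <= fpr_max`,
#' normalised by `fpr_max` so a perfect classifier scores 1.
#'
#' @param scores,labels As in [roc_from_scores()].
#' @param fpr_max Upper FPR bound (default 0.15).
#' @return Normalised partial AUC in `[0, 1]`.
#' @export
partial_auc <- function(scores, labels, fpr_max = 0.15) {
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  stopifnot(npos > 0, nneg > 0)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord]); fp <- cumsum(!labels[ord])
  tpr <- c(0, tp / npos); fpr <- c(0, fp / nneg)
  keep <- fpr <= fpr_max
  fx <- fpr[keep]; ty <- tpr[keep]
  if (max(fx) < fpr_max) {
    # extend horizontally/linearly to the bound
    nxt <- which(!keep)[1]
    ty_end <- if (is.na(nxt)) ty[length(ty)] else {
      w <- (fpr_max - fx[length(fx)]) / (fpr[nxt] - fx[length(fx)])
      ty[length(ty)] + w * (tpr[nxt] - ty[length(ty)])
    }
    fx <- c(fx, fpr_max); ty <- c(ty, ty_end)
  }
  sum(diff(fx) * (utils::head(ty, -1) + utils::tail(ty, -1)) / 2) / fpr_max
}
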