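#' Per-model-column fold-critical/remnant mask
#'
#' Labels every match column of a domain model as `FOLD_CRITICAL` (belonging
#' to the secondary-structural elements of the fold, whose alignment
#' similarity carries the homology signal) or `REMNANT` (non-globular: loops,
#' linkers, low-complexity, disorder). Masks come either from the DSSP string
#' of a representative structure or from the weighted predictor combination.
#'
#' @param model_id Model identifier.
#' @param labels Character vector over `{"FOLD_CRITICAL", "REMNANT"}`.
#' @param provenance `"dssp_derived"` or `"predictor_derived"`.
#' @param raw_scores Optional normalised per-column scores in `[0, 1]`
#'   (kept for predictor-derived masks).
#' @param merge_runs Apply [merge_short_remnant_runs()] (default TRUE).
#' @param min_remnant_run Minimal surviving remnant-run length (default 10
#'   columns; shorter runs are folded into the globular segments).
#' @return Object of class `column_mask`.
#' @export
column_mask <- function(model_id, labels,
                        provenance = c("dssp_derived", "predictor_derived"),
                        raw_scores = NULL, merge_runs = TRUE,
                        min_remnant_run = 10L) {
  provenance <- match.arg(provenance)
  if (!all(labels %in% c("FOLD_CRITICAL", "REMNANT")))
    stop("labels must be FOLD_CRITICAL or REMNANT")
  if (merge_runs) labels <- merge_short_remnant_runs(labels, min_remnant_run)
  if (!is.null(raw_scores)) {
    stopifnot(length(raw_scores) == length(labels),
              all(raw_scores >= 0 & raw_scores <= 1))
  }
  structure(list(model_id = as.character(model_id), K = length(labels),
                 labels = labels, provenance = provenance,
                 raw_scores = raw_scores),
            class = "column_mask")
}

#' @export
print.column_mask <- function(x, ...) {
  cat(sprintf("column_mask '%s' (%s): K = %d, %d remnant columns\n",
              x$model_id, x$provenance, x$K, sum(x$labels == "REMNANT")))
  cat(" ", paste(ifelse(x$labels == "REMNANT", "-", "F"), collapse = ""), "\n")
  invisible(x)
}

#' Fold short remnant runs into the surrounding globular segments
#'
#' Maximal runs of `REMNANT` shorter than `min_run` columns are relabelled
#' `FOLD_CRITICAL`: short non-globular stretches are treated as part of the
#' globular segment. Idempotent.
#'
#' @param labels Label vector.
#' @param min_run Minimal surviving run length (default 10).
#' @return Label vector with no remnant run shorter than `min_run`.
#' @export
merge_short_remnant_runs <- function(labels, min_run = 10L) {
  r <- rle(labels)
  short <- r$values == "REMNANT" & r$lengths < min_run
  r$values[short] <- "FOLD_CRITICAL"
  inverse.rle(r)
}

#' Build a mask from a DSSP per-column string
#'
#' Columns whose DSSP code belongs to the fold set (default `H`, `E`, `I`,
#' `T`, `S`) are fold-critical; gap codes `-` and `?` are remnant. Codes
#' outside both sets (e.g. `G`, `B`, `C`) are handled per `unknown_policy`:
#' by default they are labelled remnant (everything outside the enumerated
#' fold set is non-fold by elimination) with a one-time warning per code,
#' since the omission of `G`/`B` from the fold set may be an upstream
#' artifact. Short remnant runs are then merged.
#'
#' @param dssp_column_string Length-K string of per-column DSSP codes.
#' @param model_id Model identifier.
#' @param fold_codes Codes counted as fold-critical.
#' @param unknown_policy `"remnant"` (default), `"fold_critical"`, or
#'   `"error"` for codes outside `fold_codes` and the gap set.
#' @param min_remnant_run Run-merging threshold (default 10).
#' @return `column_mask` with provenance `dssp_derived`.
#' @export
mask_from_dssp <- function(dssp_column_string, model_id = "model",
                           fold_codes = c("H", "E", "I", "T", "S"),
                           unknown_policy = c("remnant", "fold_critical",
                                              "error"),
                           min_remnant_run = 10L) {
  unknown_policy <- match.arg(unknown_policy)
  ch <- strsplit(dssp_column_string, "")[[1]]
  if (!length(ch)) stop("empty DSSP string")
  known_rem <- c("-", "?")
  unknown <- setdiff(unique(ch), c(fold_codes, known_rem))
  if (length(unknown)) {
    if (unknown_policy == "error")
      stop("unknown DSSP code(s): ", paste(unknown, collapse = ", "))
    for (u in unknown)
      warn_once(paste0("dssp_", u),
                sprintf("DSSP code '%s' outside the fold set; treated as %s",
                        u, unknown_policy))
  }
  lab <- ifelse(ch %in% fold_codes, "FOLD_CRITICAL",
          ifelse(ch %in% known_rem, "REMNANT",
                 if (unknown_policy == "fold_critical") "FOLD_CRITICAL"
                 else "REMNANT"))
  column_mask(model_id, lab, "dssp_derived", min_remnant_run = min_remnant_run)
}

#' Threshold normalised predictor scores into a mask
#'
#' Columns scoring at or above the threshold are fold-critical (a score of
#' exactly 0.5 is fold-critical, matching the `>= 0.5` decision rule); the
#' rest are remnant, then short remnant runs are merged.
#'
#' @param normscores Length-K vector in `[0, 1]` (see [normalize_scores()]).
#' @param model_id Model identifier.
#' @param cfg [weight_config()] supplying `threshold` and `min_remnant_run`.
#' @return `column_mask` with provenance `predictor_derived` and
#'   `raw_scores` retained.
#' @export
mask_from_scores <- function(normscores, model_id = "model",
                             cfg = weight_config()) {
  stopifnot(all(normscores >= 0 & normscores <= 1))
  lab <- ifelse(normscores >= cfg$threshold, "FOLD_CRITICAL", "REMNANT")
  column_mask(model_id, lab, "predictor_derived", raw_scores = normscores,
              min_remnant_run = cfg$min_remnant_run)
}

#' Summary statistics over a collection of masks
#'
#' Computes, per model, the remnant/total column ratio, pools the lengths of
#' surviving remnant segments (only runs that pass the short-run merge are
#' present in a mask), and counts the red-flag models: those with more
#' remnant than fold-critical columns (ratio > 0.5) and those without any
#' fold-critical column (ratio = 1).
#'
#' @param masks List of `column_mask`.
#' @return List with `per_model` (data.frame model_id, K, n_remnant, ratio),
#'   `segment_lengths` (integer vector pooled over models),
#'   `n_ratio_gt_half`, `n_ratio_one`.
#' @export
mask_stats <- function(masks) {
  if (!length(masks)) stop("empty mask collection")
  stopifnot(all(vapply(masks, inherits, TRUE, "column_mask")))
  per <- do.call(rbind, lapply(masks, function(m) {
    data.frame(model_id = m$model_id, K = m$K,
               n_remnant = sum(m$labels == "REMNANT"),
               stringsAsFactors = FALSE)
  }))
  per$ratio <- per$n_remnant / per$K
  seglen <- unlist(lapply(masks, function(m) {
    r <- rle(m$labels)
    r$lengths[r$values == "REMNANT"]
  }))
  list(per_model = per,
       segment_lengths = as.integer(seglen),
       n_ratio_gt_half = sum(per$ratio > 0.5),
       n_ratio_one = sum(per$ratio == 1))
}

#' Read/write the mask exchange TSV
#'
#' The package's canonical annotation format: tab-separated with header
#' `model_id  K  labels  provenance`, where `labels` is a length-K string of
#' `F` (fold-critical) / `-` (remnant).
#'
#' @param masks List of `column_mask` (for writing).
#' @param path File path.
#' @return `write_mask_tsv` returns the path invisibly; `read_mask_tsv`
#'   returns a list of `column_mask`.
#' @export
write_mask_tsv <- function(masks, path) {
  df <- data.frame(
    model_id = vapply(masks, `[[`, "", "model_id"),
    K = vapply(masks, `[[`, 0L, "K"),
    labels = vapply(masks, function(m)
      paste(ifelse(m$labels == "REMNANT", "-", "F"), collapse = ""), ""),
    provenance = vapply(masks, `[[`, "", "provenance"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask_tsv
#' @export
read_mask_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character",
                                         "character"))
  lapply(seq_len(nrow(df)), function(i) {
    ch <- strsplit(df$labels[i], "")[[1]]
    column_mask(df$model_id[i],
                ifelse(ch == "-", "REMNANT", "FOLD_CRITICAL"),
                provenance = df$provenance[i],
                merge_runs = FALSE)
  })
}
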