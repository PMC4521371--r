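#' Empirical false-positive-rate calibration table
#'
#' A histogram of a negative-hit measure (log10 fold-critical E-value or
#' log10 fold-critical/remnant E-value ratio) whose cumulative sum gives the
#' empirical false-positive rate `fpr(x) = P(measure <= x)`. The default bin
#' grid covers log10 values -205 to 3 at unit step; values at a bin edge
#' belong to the lower bin (the `<= x` semantics of the cumulative lookup).
#'
#' @param frequencies Per-bin fractions summing to 1.
#' @param bin_edges Increasing edge vector (length = bins + 1).
#' @param variant `"H2"` or `"H3"`.
#' @param measure_kind `"fc_evalue"` or `"ratio"`.
#' @param n_samples Number of measures behind the frequencies.
#' @param provenance `"empirical"` or `"packaged_anchor"`.
#' @return Object of class `calibration_table`.
#' @export
calibration_table <- function(frequencies, bin_edges = default_bin_edges(),
                              variant = c("H2", "H3"),
                              measure_kind = c("fc_evalue", "ratio"),
                              n_samples = NA_integer_,
                              provenance = c("empirical", "packaged_anchor")) {
  variant <- match.arg(variant)
  measure_kind <- match.arg(measure_kind)
  provenance <- match.arg(provenance)
  if (length(frequencies) != length(bin_edges) - 1L)
    stop("need one frequency per bin")
  if (any(frequencies < 0)) stop("frequencies must be nonnegative")
  if (abs(sum(frequencies) - 1) > 1e-9)
    stop("frequencies must sum to 1 (got ", format(sum(frequencies)), ")")
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  structure(list(variant = variant, measure_kind = measure_kind,
                 bin_edges = as.numeric(bin_edges),
                 frequencies = as.numeric(frequencies),
                 cumulative = cumsum(as.numeric(frequencies)),
                 n_samples = n_samples, provenance = provenance),
            class = "calibration_table")
}

#' @rdname calibration_table
#' @export
default_bin_edges <- function() seq(-205, 3, by = 1)

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("calibration_table [%s/%s, %s]: %d bins over [%g, %g], n = %s\n",
              x$variant, x$measure_kind, x$provenance,
              length(x$frequencies), min(x$bin_edges), max(x$bin_edges),
              format(x$n_samples)))
  invisible(x)
}

#' Build an empirical FPR table from negative-hit measures
#'
#' Histograms the log10 measures of a negative population on the configured
#' bins, normalising by the sample count. Values outside the bin range are
#' clamped into the end bins with a warning.
#'
#' @param measures Numeric vector of log10 measure values (finite).
#' @param variant,measure_kind,bin_edges See [calibration_table()].
#' @return `calibration_table` with provenance `"empirical"`.
#' @export
build_fpr_table <- function(measures, variant = "H2",
                            measure_kind = "fc_evalue",
                            bin_edges = default_bin_edges()) {
  if (!length(measures)) stop("empty measure set")
  if (any(!is.finite(measures))) stop("measures must be finite")
  lo <- min(bin_edges); hi <- max(bin_edges)
  if (any(measures <= lo | measures > hi)) {
    warning("measures outside the bin range were clamped to the end bins",
            call. = FALSE)
    measures <- pmin(pmax(measures, lo + 1e-12), hi)
  }
  # (lower, upper] bins: edge values belong to the lower bin
  idx <- findInterval(measures, bin_edges, left.open = TRUE,
                      rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(bin_edges) - 1L)
  calibration_table(counts / length(measures), bin_edges,
                    variant, measure_kind, n_samples = length(measures),
                    provenance = "empirical")
}

#' Cumulative FPR lookup
#'
#' The empirical false-positive rate at cutoff `x`: the summed frequencies of
#' all bins up to and including the bin containing `x` (values sitting on an
#' edge belong to the lower bin). Below the lowest edge the lookup is 0; at
#' or above the top edge it is 1.
#'
#' @param t `calibration_table`.
#' @param x log10 measure value(s).
#' @return FPR in `[0, 1]`, vectorised over `x`.
#' @export
fpr_lookup <- function(t, x) {
  stopifnot(inherits(t, "calibration_table"))
  idx <- findInterval(x, t$bin_edges, left.open = TRUE,
                      rightmost.closed = FALSE)
  n <- length(t$frequencies)
  out <- numeric(length(x))
  out[idx >= n + 1L | x >= max(t$bin_edges)] <- 1
  inside <- idx >= 1L & idx <= n & x < max(t$bin_edges)
  out[inside] <- t$cumulative[idx[inside]]
  out
}

# printed anchor points (log10 cutoff -> FPR) per variant and measure
anchor_points <- function(variant, measure_kind) {
  key <- paste(variant, measure_kind, sep = "_")
  switch(key,
    H2_fc_evalue = cbind(x = c(-6, -3.45), fpr = c(0.01, 0.10)),
    H3_fc_evalue = cbind(x = c(-9, -6), fpr = c(0.01, 0.10)),
    H2_ratio = cbind(x = -2.25, fpr = 0.10),
    H3_ratio = cbind(x = -9.1, fpr = 0.10),
    stop("no packaged anchors for ", key))
}

#' Packaged anchor calibration tables
#'
#' A documented reconstruction of the negative-set FPR curves from their
#' printed anchor points: for the fold-critical E-value measure, FPR 0.10 at
#' cutoff 10^-3.45 and 0.01 at 10^-6 (H2), 0.10 at 10^-6 and 0.01 at 10^-9
#' (H3); for the ratio measure, FPR 0.10 at 10^-2.25 (H2) and at 10^-9.1
#' (H3). The curve is log-linearly interpolated between anchors, pinned to 0
#' at the low end of the bin range and 1 at the top, and laid on the default
#' unit-step bin grid augmented with the anchor cutoffs themselves so each
#' printed (cutoff, FPR) pair is reproduced exactly by [fpr_lookup()]. Users
#' with a benchmark should regenerate these tables empirically with
#' [build_fpr_table()].
#'
#' @param variant `"H2"` or `"H3"`.
#' @param measure_kind `"fc_evalue"` or `"ratio"`.
#' @return `calibration_table` with provenance `"packaged_anchor"`.
#' @export
packaged_anchor_table <- function(variant = c("H2", "H3"),
                                  measure_kind = c("fc_evalue", "ratio")) {
  variant <- match.arg(variant)
  measure_kind <- match.arg(measure_kind)
  anch <- anchor_points(variant, measure_kind)
  base <- default_bin_edges()
  edges <- sort(unique(c(base, anch[, "x"])))
  # interpolate log10(fpr) linearly in x through the anchors, pinning the
  # endpoints of the bin range to (effectively) 0 and to 1
  xk <- c(min(base), anch[, "x"], max(base))
  lk <- c(-12, log10(anch[, "fpr"]), 0)
  cum <- 10^stats::approx(xk, lk, xout = edges[-1L], rule = 2)$y
  cum[edges[-1L] <= min(base)] <- 0
  cum <- cummax(pmin(cum, 1))
  cum[length(cum)] <- 1
  freq <- diff(c(0, cum))
  calibration_table(freq, edges, variant, measure_kind,
                    n_samples = NA_integer_, provenance = "packaged_anchor")
}

#' Collect negative-hit measures for calibration
#'
#' Given classified, dissected hits labelled with their query's superfamily
#' and a superfamily-to-model mapping, returns the log10 fold-critical
#' E-values and log10 ratio measures of the negative hits: those whose
#' domain model is not in the query superfamily's mapped set, after the
#' candidate-listing E-value filter (original E <= 20 by default). Ratio
#' entries drop hits whose remnant E-value underflowed to zero. Zero
#' fold-critical E-values are represented by their exact log10 value when
#' supplied (see `log10_fc` below), otherwise excluded with a warning.
#'
#' @param hits data.frame with columns `query_superfamily`, `model_id`,
#'   `variant`, `evalue_original`, `log10_fc` (log10 fold-critical E-value)
#'   and `log10_ratio` (NA where undefined).
#' @param mapping data.frame with columns `superfamily_id`, `model_id`.
#' @param evalue_list_cutoff Candidate listing cutoff on the original
#'   E-value (default 20).
#' @return List with one element per variant present, each a list of
#'   `fc` and `ratio` numeric vectors of log10 measures.
#' @export
collect_negative_measures <- function(hits, mapping, evalue_list_cutoff = 20) {
  need <- c("query_superfamily", "model_id", "variant", "evalue_original",
            "log10_fc", "log10_ratio")
  if (!all(need %in% names(hits)))
    stop("hits must have columns: ", paste(need, collapse = ", "))
  if (any(is.na(hits$query_superfamily)))
    stop("every hit needs its query's superfamily label")
  hits <- hits[hits$evalue_original <= evalue_list_cutoff, , drop = FALSE]
  mapped <- paste(mapping$superfamily_id, mapping$model_id)
  neg <- hits[!paste(hits$query_superfamily, hits$model_id) %in% mapped, ,
              drop = FALSE]
  out <- list()
  for (v in unique(neg$variant)) {
    nv <- neg[neg$variant == v, , drop = FALSE]
    out[[v]] <- list(fc = nv$log10_fc[is.finite(nv$log10_fc)],
                     ratio = nv$log10_ratio[is.finite(nv$log10_ratio)])
  }
  out
}

#' Serialize calibration tables as TSV
#'
#' Columns: variant, measure_kind, bin_lo, bin_hi, frequency.
#'
#' @param tables List of `calibration_table` (writing) / path (reading).
#' @param path File path.
#' @return Path invisibly / list of tables keyed `variant_measure`.
#' @export
write_calibration_tsv <- function(tables, path) {
  rows <- lapply(tables, function(t) {
    data.frame(variant = t$variant, measure_kind = t$measure_kind,
               bin_lo = t$bin_edges[-length(t$bin_edges)],
               bin_hi = t$bin_edges[-1L],
               frequency = t$frequencies, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_tsv
#' @export
read_calibration_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  out <- list()
  for (key in unique(paste(df$variant, df$measure_kind, sep = "_"))) {
    sub <- df[paste(df$variant, df$measure_kind, sep = "_") == key, ]
    f <- sub$frequency
    out[[key]] <- calibration_table(f / sum(f),
                                    c(sub$bin_lo, sub$bin_hi[nrow(sub)]),
                                    variant = sub$variant[1],
                                    measure_kind = sub$measure_kind[1],
                                    provenance = "empirical")
  }
  out
}

#' Read/write a superfamily-to-model mapping TSV
#'
#' Two tab-separated columns: `superfamily_id` (e.g. "cl.cf.sf") and
#' `model_id`.
#'
#' @param mapping data.frame (writing) / `path` File path.
#' @return Path invisibly / data.frame.
#' @export
write_mapping_tsv <- function(mapping, path) {
  stopifnot(all(c("superfamily_id", "model_id") %in% names(mapping)))
  utils::write.table(mapping[, c("superfamily_id", "model_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mapping_tsv
#' @export
read_mapping_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' ROC table of domain-wise scores against truth labels
#'
#' Sweeps a threshold over the `[0, 1]` score range at 0.01 steps; a domain
#' is predicted positive at threshold t when its score is >= t. TPR is
#' computed over the mapped (positive) domains and FPR over the negatives.
#'
#' @param scores Numeric vector in `[0, 1]`.
#' @param labels Logical (TRUE = positive) of the same length; both classes
#'   must be present.
#' @param measure_kind Tag recorded on the table.
#' @param thresholds Threshold grid (default 0 to 1 by 0.01).
#' @return Object of class `roc_table` (data.frame threshold/tpr/fpr plus
#'   attributes).
#' @export
roc_from_scores <- function(scores, labels, measure_kind = "ratio",
                            thresholds = seq(0, 1, by = 0.01)) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both positive and negative labels are required")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  npos <- sum(labels); nneg <- sum(!labels)
  tpr <- vapply(thresholds, function(t) sum(scores >= t & labels) / npos, 0)
  fpr <- vapply(thresholds, function(t) sum(scores >= t & !labels) / nneg, 0)
  structure(data.frame(threshold = thresholds, tpr = tpr, fpr = fpr),
            measure_kind = measure_kind, provenance = "empirical",
            class = c("roc_table", "data.frame"))
}

#' Expected FPR of admitting hits at a coverage score
#'
#' Looks up the ROC row at the largest tabulated threshold that does not
#' exceed the score (rounding the score down to the threshold grid, the
#' conservative direction), and returns its FPR: the expected false-positive
#' rate of admitting every hit scoring at least that well.
#'
#' @param r `roc_table`.
#' @param score Coverage score(s) in `[0, 1]`.
#' @return FPR value(s).
#' @export
roc_fpr_lookup <- function(r, score) {
  stopifnot(inherits(r, "roc_table"))
  if (any(score < 0 | score > 1, na.rm = TRUE))
    stop("score must lie in [0, 1]")
  idx <- findInterval(score, r$threshold)
  out <- rep(NA_real_, length(score))
  ok <- !is.na(score)
  out[ok] <- r$fpr[pmax(idx[ok], 1L)]
  out
}
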