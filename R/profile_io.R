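#' Parse a profile-HMM model file
#'
#' Reads a profile in either supported text dialect and returns a fully
#' populated [profile_hmm()]. The dialect is recognised from the first line:
#' `HMMER2.0` (save format, scores stored as integers scaled by 1000) or
#' `HMMER3/*` (text format, emissions/transitions stored as negative natural
#' logs of probabilities). All scores are converted to bits on read.
#'
#' HMMER2 statistics come from the `EVD mu lambda` line (Gumbel tail);
#' HMMER3 files carry three `STATS LOCAL` lines of which the forward-score
#' tail parameters (`STATS LOCAL FORWARD tau lambda`) are bound into the
#' profile's `evd`, since dissected partial-score sums are evaluated against
#' the forward exponential tail. A file without its statistics line(s) parses
#' into an uncalibrated profile: scoring works, E-value operations refuse it.
#'
#' HMMER3 files store no explicit null model or entry/exit terms; the
#' `COMPO` line is taken as the background and the uniform local entry
#' `B -> M_k = -log2(K)` bits with zero exit terms is reconstituted, matching
#' what [write_profile()] assumes.
#'
#' @param text Model-file content: a single string or a character vector of
#'   lines; alternatively a file path to read (when `is_path = TRUE`).
#' @param is_path Treat `text` as a path.
#' @return A `profile_hmm`.
#' @export
parse_profile <- function(text, is_path = FALSE) {
  if (is_path) text <- readLines(text, warn = FALSE)
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- text[nzchar(trimws(text)) | seq_along(text) == length(text)]
  if (!length(text)) stop("empty model text")
  hdr <- text[[1]]
  if (startsWith(hdr, "HMMER2.0")) {
    parse_profile_h2(text)
  } else if (startsWith(hdr, "HMMER3/")) {
    parse_profile_h3(text)
  } else {
    stop("unsupported dialect: unrecognized header '",
         substr(hdr, 1, 30), "'")
  }
}

H2_SCALE <- 1000

fields_of <- function(line) strsplit(trimws(line), "[[:space:]]+")[[1]]

h2_num <- function(tok) {
  v <- rep(-Inf, length(tok))
  num <- tok != "*"
  v[num] <- as.numeric(tok[num]) / H2_SCALE
  v
}
h2_tok <- function(x) {
  ifelse(is.finite(x), as.character(round(x * H2_SCALE)), "*")
}

parse_profile_h2 <- function(lines) {
  kv <- list()
  i <- 2L
  evd <- NULL
  nule <- NULL
  nult <- 0
  while (i <= length(lines) && !startsWith(lines[[i]], "HMM")) {
    f <- fields_of(lines[[i]])
    key <- f[[1]]
    if (key == "NAME") kv$name <- f[[2]]
    if (key == "LENG") kv$K <- as.integer(f[[2]])
    if (key == "ALPH") kv$alph <- f[[2]]
    if (key == "NULE") nule <- h2_num(f[-1])
    if (key == "NULT") nult <- h2_num(f[[2]])
    if (key == "EVD") evd <- evd_params(as.numeric(f[[2]]), as.numeric(f[[3]]),
                                        "gumbel")
    i <- i + 1L
  }
  if (i > length(lines)) stop("parse error: no HMM section found")
  if (is.null(kv$K)) stop("parse error: missing LENG line")
  K <- kv$K
  if (is.null(nule)) stop("parse error: missing NULE line")
  null_p <- 2^nule / 20
  null_p <- null_p / sum(null_p)
  i <- i + 2L  # skip HMM alphabet header and transition header
  me <- matrix(NA_real_, K, 20)
  ie <- matrix(NA_real_, K, 20)
  tr <- matrix(NA_real_, K, 9)
  for (k in seq_len(K)) {
    base <- i + (k - 1L) * 3L
    if (base + 2L > length(lines))
      stop("parse error: truncated column block at column ", k)
    fm <- fields_of(lines[[base]])
    if (length(fm) < 21L || suppressWarnings(as.integer(fm[[1]])) != k)
      stop("parse error: malformed match line at column ", k)
    me[k, ] <- h2_num(fm[2:21])
    fi <- fields_of(lines[[base + 1L]])
    if (length(fi) < 21L)
      stop("parse error: malformed insert line at column ", k)
    ie[k, ] <- h2_num(fi[2:21])
    ft <- fields_of(lines[[base + 2L]])
    if (length(ft) < 10L)
      stop("parse error: malformed transition line at column ", k)
    tr[k, ] <- h2_num(ft[2:10])
  }
  profile_hmm(model_id = kv$name %||% "unnamed", dialect = "H2",
              match_emissions = me, insert_emissions = ie, transitions = tr,
              null_model = list(p = stats::setNames(null_p, aa_alphabet()),
                                ext = nult),
              evd = evd, invariant = 0)
}

h3_num_to_bits_emit <- function(tok, bg) {
  # file stores -ln(p); bits = log2(p / bg)
  v <- ifelse(tok == "*", Inf, suppressWarnings(as.numeric(tok)))
  (-v - log(bg)) / log(2)
}

h3_num_to_bits_trans <- function(tok) {
  v <- ifelse(tok == "*", Inf, suppressWarnings(as.numeric(tok)))
  -v / log(2)
}

parse_profile_h3 <- function(lines) {
  kv <- list()
  i <- 2L
  fwd <- NULL
  while (i <= length(lines) && !grepl("^HMM[[:space:]]", lines[[i]])) {
    f <- fields_of(lines[[i]])
    if (f[[1]] == "NAME") kv$name <- f[[2]]
    if (f[[1]] == "LENG") kv$K <- as.integer(f[[2]])
    if (f[[1]] == "STATS" && length(f) >= 5L && f[[3]] == "FORWARD")
      fwd <- evd_params(as.numeric(f[[4]]), as.numeric(f[[5]]),
                        "exponential_tail")
    i <- i + 1L
  }
  if (i > length(lines)) stop("parse error: no HMM section found")
  if (is.null(kv$K)) stop("parse error: missing LENG line")
  K <- kv$K
  i <- i + 2L  # skip HMM header + transition header
  # COMPO block: background emissions + node-0 insert + node-0 transitions
  fc <- fields_of(lines[[i]])
  if (fc[[1]] != "COMPO") stop("parse error: missing COMPO line")
  bg <- exp(-as.numeric(fc[2:21]))
  bg <- bg / sum(bg)
  i <- i + 3L
  me <- matrix(NA_real_, K, 20)
  ie <- matrix(NA_real_, K, 20)
  tr7 <- matrix(NA_real_, K, 7)
  for (k in seq_len(K)) {
    base <- i + (k - 1L) * 3L
    if (base + 2L > length(lines))
      stop("parse error: truncated column block at column ", k)
    fm <- fields_of(lines[[base]])
    if (length(fm) < 21L || suppressWarnings(as.integer(fm[[1]])) != k)
      stop("parse error: malformed match line at column ", k)
    me[k, ] <- h3_num_to_bits_emit(fm[2:21], bg)
    fi <- fields_of(lines[[base + 1L]])
    if (length(fi) < 20L)
      stop("parse error: malformed insert line at column ", k)
    ie[k, ] <- h3_num_to_bits_emit(fi[1:20], bg)
    ft <- fields_of(lines[[base + 2L]])
    if (length(ft) < 7L)
      stop("parse error: malformed transition line at column ", k)
    tr7[k, ] <- h3_num_to_bits_trans(ft[1:7])
  }
  tr <- cbind(tr7,
              BM = rep(-log2(K), K),
              ME = rep(0, K))
  profile_hmm(model_id = kv$name %||% "unnamed", dialect = "H3",
              match_emissions = me, insert_emissions = ie, transitions = tr,
              null_model = list(p = stats::setNames(bg, aa_alphabet()), ext = 0),
              evd = fwd, invariant = 0)
}

#' Write a profile-HMM model file
#'
#' Emits text that [parse_profile()] accepts, with numeric round-trip to the
#' format's printed precision (0.001 bits for the integer-scaled HMMER2
#' format, about 1e-5 bits for the five-decimal HMMER3 format).
#'
#' Writing a profile into the other dialect is only possible when the fields
#' that exist in one dialect only are compatible: an H2 profile with
#' non-uniform entry/exit terms (B->M_k, M_k->E) cannot be represented in the
#' HMMER3 text format and raises a conversion error, as does a Gumbel-tail
#' profile requested as H3 (whose statistics line is a forward exponential
#' tail) and vice versa.
#'
#' @param p `profile_hmm`.
#' @param dialect Target dialect; defaults to the profile's own.
#' @param path Optional file path; when given the text is also written there.
#' @return Character vector of lines, invisibly when `path` is given.
#' @export
write_profile <- function(p, dialect = p$dialect, path = NULL) {
  stopifnot(inherits(p, "profile_hmm"))
  dialect <- match.arg(dialect, c("H2", "H3"))
  if (dialect != p$dialect) {
    if (dialect == "H3") {
      std_bm <- rep(-log2(p$K), p$K)
      if (!isTRUE(all.equal(unname(p$transitions[, "BM"]), std_bm,
                            tolerance = 1e-9)) ||
          any(p$transitions[, "ME"] != 0))
        stop("conversion error: glocal entry/exit terms (B->M_k, M_k->E) ",
             "have no HMMER3 text representation")
      if (!is.null(p$evd) && p$evd$tail_kind != "exponential_tail")
        stop("conversion error: Gumbel statistics cannot be written as an ",
             "HMMER3 forward-tail STATS line")
    } else {
      if (!is.null(p$evd) && p$evd$tail_kind != "gumbel")
        stop("conversion error: forward-tail statistics cannot be written ",
             "as an HMMER2 EVD line")
    }
  }
  out <- if (dialect == "H2") write_profile_h2(p) else write_profile_h3(p)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

write_profile_h2 <- function(p) {
  nule <- log2(p$null_model$p * 20)
  out <- c(
    "HMMER2.0  [hmmdissect profile save format]",
    paste("NAME ", p$model_id),
    paste("LENG ", p$K),
    "ALPH  Amino",
    paste("NULE ", paste(h2_tok(nule), collapse = " ")),
    paste("NULT ", h2_tok(p$null_model$ext)))
  if (!is.null(p$evd))
    out <- c(out, sprintf("EVD   %.6f %.6f", p$evd$mu, p$evd$lam))
  out <- c(out,
           paste("HMM  ", paste(aa_alphabet(), collapse = "  ")),
           "       m->m  m->i  m->d  i->m  i->i  d->m  d->d  b->m  m->e")
  for (k in seq_len(p$K)) {
    out <- c(out,
      paste(format(k, width = 6),
            paste(h2_tok(p$match_emissions[k, ]), collapse = " ")),
      paste("     -", paste(h2_tok(p$insert_emissions[k, ]), collapse = " ")),
      paste("     -", paste(h2_tok(p$transitions[k, ]), collapse = " ")))
  }
  c(out, "//")
}

h3_tok_emit <- function(bits, bg) {
  # bits = log2(p/bg) -> -ln p
  v <- -(bits * log(2) + log(bg))
  ifelse(is.finite(bits), sprintf("%.5f", v), "*")
}

h3_tok_trans <- function(bits) {
  ifelse(is.finite(bits), sprintf("%.5f", -bits * log(2)), "*")
}

write_profile_h3 <- function(p) {
  bg <- p$null_model$p
  out <- c(
    "HMMER3/f [hmmdissect profile text format]",
    paste("NAME ", p$model_id),
    paste("LENG ", p$K),
    "ALPH  amino")
  if (!is.null(p$evd)) {
    out <- c(out,
      sprintf("STATS LOCAL MSV      %.5f  %.5f", p$evd$mu, p$evd$lam),
      sprintf("STATS LOCAL VITERBI  %.5f  %.5f", p$evd$mu, p$evd$lam),
      sprintf("STATS LOCAL FORWARD  %.5f  %.5f", p$evd$mu, p$evd$lam))
  }
  out <- c(out,
    paste("HMM  ", paste(aa_alphabet(), collapse = "        ")),
    "            m->m   m->i   m->d   i->m   i->i   d->m   d->d",
    paste("  COMPO  ", paste(sprintf("%.5f", -log(bg)), collapse = " ")),
    paste("         ", paste(sprintf("%.5f", -log(bg)), collapse = " ")),
    paste("         ", paste(rep("0.00000", 7), collapse = " ")))
  for (k in seq_len(p$K)) {
    out <- c(out,
      paste(format(k, width = 7),
            paste(h3_tok_emit(p$match_emissions[k, ], bg), collapse = " ")),
      paste("         ",
            paste(h3_tok_emit(p$insert_emissions[k, ], bg), collapse = " ")),
      paste("         ",
            paste(h3_tok_trans(p$transitions[k, 1:7]), collapse = " ")))
  }
  c(out, "//")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
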