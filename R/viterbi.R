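#' Align a sequence to a profile by Viterbi dynamic programming
#'
#' Finds the highest-scoring legal path of a query sequence through the
#' profile's match/insert/delete state machine, in one of two modes:
#'
#' * `glocal` -- local to the sequence, global to the domain: the path must
#'   cover model columns 1..K (through match or delete states) while any
#'   query prefix/suffix may be skipped at no cost. This is the HMMER2-style
#'   mode used for full-domain hits.
#' * `local` -- local to both: the path may cover any contiguous model-column
#'   range, beginning and ending at match states, with entry/exit terms
#'   `BM[k]`/`ME[k]`. This is the HMMER3-style mode.
#'
#' Scores are in bits throughout; the returned alignment's `reported_score`
#' is set from [reconstruct_score()] so that reconstruction and search agree
#' by construction. Ties between continuation candidates are broken
#' deterministically (match continuation, then insert, then delete, then a
#' fresh entry). A pure-delete path emits nothing and is not a legal
#' alignment; delete-terminated candidates are only accepted when their
#' traceback passes through a match state.
#'
#' @param p `profile_hmm` (calibration not required).
#' @param seq Query protein sequence: a single string or character vector of
#'   residues.
#' @param mode `"glocal"` or `"local"`.
#' @return A `seq_dom_alignment` (variant `"H2"` for glocal, `"H3"` for
#'   local).
#' @export
viterbi_align <- function(p, seq, mode = c("glocal", "local")) {
  stopifnot(inherits(p, "profile_hmm"))
  mode <- match.arg(mode)
  res <- if (length(seq) == 1L) strsplit(seq, "")[[1]] else seq
  L <- length(res)
  if (L < 1L) stop("sequence must have length >= 1")
  ridx <- match(res, p$alphabet)
  if (anyNA(ridx)) stop("sequence contains residues outside the alphabet: ",
                        paste(unique(res[is.na(ridx)]), collapse = ","))
  K <- p$K
  tr <- p$transitions
  emt <- t(p$match_emissions)   # 20 x K: emt[r, ] is the per-column vector
  eit <- t(p$insert_emissions)
  NEG <- -Inf
  glocal <- mode == "glocal"

  tMM <- unname(tr[, "MM"]); tMI <- unname(tr[, "MI"]); tMD <- unname(tr[, "MD"])
  tIM <- unname(tr[, "IM"]); tII <- unname(tr[, "II"])
  tDM <- unname(tr[, "DM"]); tDD <- unname(tr[, "DD"])
  start_m <- if (glocal) c(unname(tr[1L, "BM"]), rep(NEG, K - 1L))
             else unname(tr[, "BM"])
  d_start <- if (glocal) unname(tr[1L, "BM"]) else NEG

  # row l+1 = l residues consumed
  Mv <- matrix(NEG, L + 1L, K)
  Iv <- matrix(NEG, L + 1L, K)
  Dv <- matrix(NEG, L + 1L, K)
  # pointers: 1 = from M, 2 = from I, 3 = from D, 4 = fresh start
  Mp <- matrix(0L, L + 1L, K)
  Ip <- matrix(0L, L + 1L, K)
  Dp <- matrix(0L, L + 1L, K)

  d_chain <- function(mrow) {
    # delete chain at fixed residue count (sequential along k)
    dv <- rep(NEG, K); dp <- integer(K)
    dv[1L] <- d_start; if (glocal) dp[1L] <- 4L
    if (K > 1L) {
      fmv <- mrow + tMD
      for (k in 2L:K) {
        fm <- fmv[k - 1L]
        fd <- dv[k - 1L] + tDD[k - 1L]
        if (fm >= fd) { dv[k] <- fm; dp[k] <- 1L }
        else { dv[k] <- fd; dp[k] <- 3L }
      }
    }
    list(v = dv, p = dp)
  }

  du <- d_chain(Mv[1L, ])
  Dv[1L, ] <- du$v; Dp[1L, ] <- du$p

  for (l in seq_len(L)) {
    l1 <- l + 1L
    r <- ridx[l]
    mprev <- Mv[l, ]; iprev <- Iv[l, ]; dprev <- Dv[l, ]
    pm <- c(NEG, mprev[-K] + tMM[-K])
    pi_ <- c(NEG, iprev[-K] + tIM[-K])
    pd <- c(NEG, dprev[-K] + tDM[-K])
    best <- pmax(pm, pi_, pd, start_m)
    ptr <- rep(4L, K)
    ptr[pd == best] <- 3L
    ptr[pi_ == best] <- 2L
    ptr[pm == best] <- 1L
    mrow <- best + emt[r, ]
    Mv[l1, ] <- mrow
    Mp[l1, ] <- ptr
    fm <- mprev + tMI
    fi <- iprev + tII
    Iv[l1, ] <- pmax(fm, fi) + eit[r, ]
    Ip[l1, ] <- ifelse(fm >= fi, 1L, 2L)
    du <- d_chain(mrow)
    Dv[l1, ] <- du$v; Dp[l1, ] <- du$p
  }

  tME <- unname(tr[, "ME"])
  delete_chain_emits <- function(l1) {
    k <- K
    repeat {
      ptr <- Dp[l1, k]
      if (ptr == 4L || ptr == 0L) return(FALSE)
      if (ptr == 1L) return(TRUE)
      k <- k - 1L
    }
  }
  if (glocal) {
    endM <- Mv[, K] + tME[K]
    endD <- Dv[, K] + tME[K]
    sc <- c(endM, endD)
    ord <- order(sc, decreasing = TRUE)
    pick <- NA_integer_
    for (o in ord) {
      if (!is.finite(sc[o])) break
      if (o <= L + 1L) { pick <- o; end_state <- "M"; break }
      if (delete_chain_emits(o - L - 1L)) {
        pick <- o - L - 1L; end_state <- "D"; break
      }
    }
    if (is.na(pick)) stop("no legal emitting glocal path exists")
    bl <- pick
    end_k <- K
  } else {
    endmat <- sweep(Mv, 2L, tME, `+`)
    idx <- arrayInd(which.max(endmat), dim(endmat))
    bl <- idx[1L]; end_k <- idx[2L]; end_state <- "M"
  }

  # traceback; the I state between match columns k and k+1 carries column k
  n_alloc <- 2L * (L + K) + 4L
  stv <- character(n_alloc); kv <- integer(n_alloc); qv <- integer(n_alloc)
  n <- 0L
  st <- end_state; k <- end_k; l1 <- bl
  repeat {
    n <- n + 1L
    if (st == "M") {
      stv[n] <- "M"; kv[n] <- k; qv[n] <- l1 - 1L
      ptr <- Mp[l1, k]
      if (ptr == 4L) break
      st <- c("M", "I", "D")[ptr]
      k <- k - 1L
      l1 <- l1 - 1L
    } else if (st == "I") {
      stv[n] <- "I"; kv[n] <- k; qv[n] <- l1 - 1L
      st <- c("M", "I")[Ip[l1, k]]
      l1 <- l1 - 1L
    } else {
      stv[n] <- "D"; kv[n] <- k; qv[n] <- NA_integer_
      ptr <- Dp[l1, k]
      if (ptr == 4L) break
      if (ptr != 1L && ptr != 3L) stop("internal traceback error")
      st <- c("M", NA, "D")[ptr]
      k <- k - 1L
    }
  }
  ix <- n:1L
  path <- data.frame(state = stv[ix], k = kv[ix], qpos = qv[ix],
                     residue = ifelse(is.na(qv[ix]), NA_character_,
                                      res[qv[ix]]),
                     stringsAsFactors = FALSE)
  a <- seq_dom_alignment(query_id = "query", model_id = p$model_id,
                         variant = if (glocal) "H2" else "H3", path = path)
  a$reported_score <- reconstruct_score(a, p)
  if (is_calibrated(p))
    a$reported_evalue <- evalue(a$reported_score, p$evd)
  a
}

#' Best match-terminated Viterbi score (score only)
#'
#' The score-only companion of [viterbi_align()] used for EVD calibration
#' simulations: identical recurrences but no traceback, and termination is
#' restricted to match states (a path ending in a match always emits, so no
#' legality fallback is needed). Considerably faster.
#'
#' @inheritParams viterbi_align
#' @return Bit score of the best match-terminated path.
#' @export
viterbi_score <- function(p, seq, mode = c("glocal", "local")) {
  mode <- match.arg(mode)
  res <- if (length(seq) == 1L) strsplit(seq, "")[[1]] else seq
  L <- length(res)
  ridx <- match(res, p$alphabet)
  if (anyNA(ridx)) stop("sequence contains residues outside the alphabet")
  K <- p$K
  tr <- p$transitions
  emt <- t(p$match_emissions)
  eit <- t(p$insert_emissions)
  NEG <- -Inf
  glocal <- mode == "glocal"
  tMM <- unname(tr[, "MM"]); tMI <- unname(tr[, "MI"]); tMD <- unname(tr[, "MD"])
  tIM <- unname(tr[, "IM"]); tII <- unname(tr[, "II"])
  tDM <- unname(tr[, "DM"]); tDD <- unname(tr[, "DD"])
  tME <- unname(tr[, "ME"])
  start_m <- if (glocal) c(unname(tr[1L, "BM"]), rep(NEG, K - 1L))
             else unname(tr[, "BM"])
  d_start <- if (glocal) unname(tr[1L, "BM"]) else NEG

  # dv[k] = C[k-1] + max(d_start, max_{j<k}(fmv[j] - C[j])) where C is the
  # cumulative DD cost: the delete-chain recurrence unrolled into a prefix
  # cummax (valid when the transition costs are finite; falls back to the
  # sequential form otherwise)
  finite_dd <- all(is.finite(tDD)) && all(is.finite(tMD))
  Cdd <- cumsum(tDD)
  d_chain <- if (finite_dd) {
    function(mrow) {
      pref <- cummax(c(d_start, mrow + tMD - Cdd))[seq_len(K)]
      c(0, Cdd[-K]) + pref
    }
  } else {
    function(mrow) {
      dv <- rep(NEG, K)
      dv[1L] <- d_start
      if (K > 1L) {
        fmv <- mrow + tMD
        for (k in 2L:K) dv[k] <- max(fmv[k - 1L], dv[k - 1L] + tDD[k - 1L])
      }
      dv
    }
  }

  mprev <- rep(NEG, K); iprev <- rep(NEG, K)
  dprev <- d_chain(mprev)
  best_end <- NEG
  for (l in seq_len(L)) {
    r <- ridx[l]
    pm <- c(NEG, mprev[-K] + tMM[-K])
    pi_ <- c(NEG, iprev[-K] + tIM[-K])
    pd <- c(NEG, dprev[-K] + tDM[-K])
    mrow <- pmax(pm, pi_, pd, start_m) + emt[r, ]
    iprev <- pmax(mprev + tMI, iprev + tII) + eit[r, ]
    dprev <- d_chain(mrow)
    mprev <- mrow
    e <- if (glocal) mrow[K] + tME[K] else max(mrow + tME)
    if (e > best_end) best_end <- e
  }
  best_end + p$invariant
}

#' Batch match-terminated Viterbi scores
#'
#' [viterbi_score()] for many equal-length sequences at once, vectorising
#' the dynamic programme across sequences. Used by the EVD calibration
#' simulations where thousands of random sequences are scored against one
#' profile.
#'
#' @param p `profile_hmm`.
#' @param seqs Character vector of sequences, all the same length.
#' @param mode `"glocal"` or `"local"`.
#' @return Numeric vector of bit scores, one per sequence.
#' @export
viterbi_score_batch <- function(p, seqs, mode = c("glocal", "local")) {
  mode <- match.arg(mode)
  n <- length(seqs)
  if (!n) return(numeric(0))
  rmat <- do.call(rbind, lapply(strsplit(seqs, ""), match, p$alphabet))
  if (anyNA(rmat)) stop("sequences contain residues outside the alphabet")
  L <- ncol(rmat)
  K <- p$K
  tr <- p$transitions
  emt <- t(p$match_emissions)  # 20 x K
  eit <- t(p$insert_emissions)
  NEG <- -Inf
  glocal <- mode == "glocal"
  tMM <- unname(tr[, "MM"]); tMI <- unname(tr[, "MI"]); tMD <- unname(tr[, "MD"])
  tIM <- unname(tr[, "IM"]); tII <- unname(tr[, "II"])
  tDD <- unname(tr[, "DD"]); tDM <- unname(tr[, "DM"]); tME <- unname(tr[, "ME"])
  if (!all(is.finite(tDD)) || !all(is.finite(tMD)))
    return(vapply(seqs, function(s) viterbi_score(p, s, mode), 0,
                  USE.NAMES = FALSE))
  start_m <- if (glocal) c(unname(tr[1L, "BM"]), rep(NEG, K - 1L))
             else unname(tr[, "BM"])
  d_start <- if (glocal) unname(tr[1L, "BM"]) else NEG
  Cdd <- cumsum(tDD)
  Cprev <- c(0, Cdd[-K])
  rowm <- function(v) matrix(v, n, length(v), byrow = TRUE)
  TMM <- rowm(tMM[-K]); TIM <- rowm(tIM[-K]); TDM <- rowm(tDM[-K])
  TMI <- rowm(tMI); TII <- rowm(tII); TMD_C <- rowm(tMD - Cdd)
  SM <- rowm(start_m); CP <- rowm(Cprev); MEm <- rowm(tME)
  negcol <- rep(NEG, n)

  d_chain <- function(mrow) {
    pref <- matrix(NEG, n, K)
    pref[, 1L] <- d_start
    if (K > 1L) {
      w <- mrow + TMD_C
      for (k in 2L:K) pref[, k] <- pmax(pref[, k - 1L], w[, k - 1L])
    }
    CP + pref
  }

  Mv <- matrix(NEG, n, K); Iv <- matrix(NEG, n, K)
  Dv <- d_chain(Mv)
  best <- negcol
  for (l in seq_len(L)) {
    r <- rmat[, l]
    pm <- cbind(negcol, Mv[, -K, drop = FALSE] + TMM)
    pi_ <- cbind(negcol, Iv[, -K, drop = FALSE] + TIM)
    pd <- cbind(negcol, Dv[, -K, drop = FALSE] + TDM)
    Mnew <- pmax(pm, pi_, pd, SM) + emt[r, , drop = FALSE]
    Iv <- pmax(Mv + TMI, Iv + TII) + eit[r, , drop = FALSE]
    Mv <- Mnew
    Dv <- d_chain(Mv)
    e <- if (glocal) Mv[, K] + tME[K]
         else {
           rm_ <- Mv + MEm
           rm_[cbind(seq_len(n), max.col(rm_, ties.method = "first"))]
         }
    best <- pmax(best, e)
  }
  best + p$invariant
}
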