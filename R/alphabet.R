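#' Amino-acid alphabet and background model
#'
#' The package works on the standard 20-letter amino-acid alphabet in the
#' fixed order used by HMMER profile files. Background (null-model) emission
#' frequencies default to the uniform 1/20 distribution; real profiles carry
#' their own null model which takes precedence once parsed.
#'
#' @return `aa_alphabet()` returns the 20 one-letter residue codes in file
#'   order; `aa_background()` returns a named numeric vector of background
#'   emission probabilities summing to 1.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_alphabet
#' @export
aa_background <- function() {
  p <- rep(1 / 20, 20)
  names(p) <- aa_alphabet()
  p
}

# Residues outside the core alphabet that may show up in real sequences.
# They get a neutral treatment (documented per operation) with a one-time
# warning per code.
AMBIGUOUS_RESIDUES <- c("X", "B", "Z", "U", "O")

# warn once per (context, code) within a session
.warn_env <- new.env(parent = emptyenv())

warn_once <- function(key, msg) {
  if (!isTRUE(.warn_env[[key]])) {
    .warn_env[[key]] <- TRUE
    warning(msg, call. = FALSE)
  }
  invisible(NULL)
}

#' Disorder propensity table used by the globularity predictor
#'
#' Per-residue disorder propensities in the style of the Russell/Linding
#' scale used by running-sum globularity prediction: positive values mark
#' disorder-promoting residues (P, E, S, Q, K, R, G), negative values mark
#' order-promoting ones (W, C, F, I, Y, V, L, M). The packaged numbers are a
#' documented approximation bundled for self-contained operation; every
#' function that consumes the table accepts a replacement vector, so users
#' with the published scale can supply it directly.
#'
#' @return Named numeric vector over the 20 residues; higher means more
#'   disorder-prone.
#' @export
disorder_propensity <- function() {
  c(A =  0.06, C = -0.02, D =  0.19, E =  0.26, F = -0.70,
    G =  0.43, H = -0.10, I = -0.49, K =  0.22, L = -0.33,
    M = -0.23, N =  0.01, P =  0.55, Q =  0.32, R =  0.18,
    S =  0.14, T =  0.05, V = -0.38, W = -0.88, Y = -0.51)
}

# BLOSUM62 over the 20 core residues, taken from Biostrings.
blosum62_core <- function() {
  mat <- get_blosum62()
  mat[aa_alphabet(), aa_alphabet()]
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})
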