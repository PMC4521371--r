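#' Read multiple sequence alignments and FASTA sequences
#'
#' Thin wrappers over Biostrings for the standard formats: aligned FASTA and
#' Stockholm alignments are returned as character matrices (rows =
#' sequences); FASTA sequence sets as named character vectors.
#'
#' @param path File path.
#' @param format `"fasta"` or `"stockholm"` (alignments).
#' @return Character matrix (`read_msa`) or named character vector
#'   (`read_fasta_sequences`).
#' @export
read_msa <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  m <- Biostrings::readAAMultipleAlignment(path, format = format)
  as.matrix(m)
}

#' @rdname read_msa
#' @export
read_fasta_sequences <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' @rdname read_msa
#' @param sequences Named character vector of sequences.
#' @export
write_fasta_sequences <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' One parsed search-report record
#'
#' Carrier for a per-domain alignment reported by a search program: the
#' reported score/E-value plus the parsed [seq_dom_alignment()].
#'
#' @param query_id,model_id,variant Identifiers.
#' @param score,evalue Reported bit score and E-value.
#' @param alignment `seq_dom_alignment`.
#' @param unmatched Set when the named model was not found in the supplied
#'   profile library.
#' @return Object of class `search_output_record`.
#' @export
search_output_record <- function(query_id, model_id, variant, score, evalue,
                                 alignment, unmatched = FALSE) {
  structure(list(query_id = query_id, model_id = model_id, variant = variant,
                 score = score, evalue = evalue, alignment = alignment,
                 unmatched = unmatched),
            class = "search_output_record")
}

path_to_tokens <- function(path) {
  vapply(seq_len(nrow(path)), function(i) {
    if (path$state[i] == "D") paste0("D:", path$k[i])
    else paste(path$state[i], path$k[i], path$qpos[i], path$residue[i],
               sep = ":")
  }, "")
}

tokens_to_path <- function(tokens, line_no) {
  recs <- lapply(tokens, function(tok) {
    f <- strsplit(tok, ":", fixed = TRUE)[[1]]
    if (f[1] == "D") {
      if (length(f) != 2L)
        stop("malformed alignment block at line ", line_no,
             ": bad token '", tok, "'")
      data.frame(state = "D", k = as.integer(f[2]), qpos = NA_integer_,
                 residue = NA_character_, stringsAsFactors = FALSE)
    } else {
      if (length(f) != 4L || !f[1] %in% c("M", "I"))
        stop("malformed alignment block at line ", line_no,
             ": bad token '", tok, "'")
      data.frame(state = f[1], k = as.integer(f[2]), qpos = as.integer(f[3]),
                 residue = f[4], stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, recs)
}

#' Write a per-domain search report
#'
#' The package's search-report exchange format, modelled on the per-domain
#' reports of the standard search programs: a header naming the variant,
#' then one block per query with one `>>` line per domain hit (model, bit
#' score, E-value, query and model spans) followed by an explicit alignment
#' path line, `//` terminated.
#'
#' @param records List of `search_output_record`.
#' @param path Optional output file.
#' @return Character vector of lines (invisibly when `path` given).
#' @export
write_search_output <- function(records, path = NULL) {
  out <- "# hmmdissect search report 1.0"
  for (q in unique(vapply(records, `[[`, "", "query_id"))) {
    out <- c(out, paste("Query:", q))
    for (r in Filter(function(x) x$query_id == q, records)) {
      a <- r$alignment
      out <- c(out,
        sprintf(">> %s variant: %s score: %.4f evalue: %.6g qspan: %d-%d mspan: %d-%d",
                r$model_id, r$variant, r$score, r$evalue,
                a$seq_span[1], a$seq_span[2], a$model_span[1], a$model_span[2]),
        paste("PATH", paste(path_to_tokens(a$path), collapse = " ")))
    }
    out <- c(out, "//")
  }
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}

#' Parse a per-domain search report
#'
#' Inverse of [write_search_output()]. When a profile library is supplied,
#' each parsed alignment is validated against its named model; records naming
#' an unknown model are kept but flagged `unmatched`.
#'
#' @param text Report content (string, lines, or path via `is_path`).
#' @param profiles Optional named list of `profile_hmm` to validate against.
#' @param is_path Treat `text` as a file path.
#' @return List of `search_output_record` (possibly empty).
#' @export
parse_search_output <- function(text, profiles = NULL, is_path = FALSE) {
  if (is_path) text <- readLines(text, warn = FALSE)
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  records <- list()
  query <- NULL
  i <- 1L
  while (i <= length(text)) {
    line <- text[[i]]
    if (startsWith(line, "Query:")) {
      query <- trimws(sub("^Query:", "", line))
    } else if (startsWith(line, ">>")) {
      f <- fields_of(line)
      if (length(f) < 11L)
        stop("malformed domain line at line ", i)
      model <- f[2]
      variant <- f[4]
      score <- as.numeric(f[6])
      ev <- as.numeric(f[8])
      if (i + 1L > length(text) || !startsWith(text[[i + 1L]], "PATH"))
        stop("malformed alignment block at line ", i + 1L,
             ": missing PATH line")
      toks <- fields_of(text[[i + 1L]])[-1]
      pth <- tokens_to_path(toks, i + 1L)
      a <- seq_dom_alignment(query, model, variant, pth,
                             reported_score = score, reported_evalue = ev)
      unmatched <- FALSE
      if (!is.null(profiles)) {
        if (is.null(profiles[[model]])) {
          unmatched <- TRUE
        } else {
          d <- validate_alignment(a, profiles[[model]])
          if (length(d))
            stop("malformed alignment block at line ", i + 1L, ": ", d[[1]])
        }
      }
      records[[length(records) + 1L]] <-
        search_output_record(query, model, variant, score, ev, a, unmatched)
      i <- i + 1L
    }
    i <- i + 1L
  }
  records
}
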