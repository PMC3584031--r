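#' Token streams
#'
#' A token stream is an ordered sequence of word tokens, optionally divided
#' into documents.  Co-occurrence windows never cross document boundaries.
#'
#' @param docs A list of character vectors (one per document), or a single
#'   character vector which is treated as one document.
#' @return An object of class `token_stream`: a list of character vectors.
#' @export
token_stream <- function(docs) {
  if (is.character(docs)) docs <- list(docs)
  if (!is.list(docs) || !all(vapply(docs, is.character, logical(1))))
    stop("`docs` must be a character vector or a list of character vectors")
  docs <- lapply(docs, function(d) d[nzchar(d)])
  if (any(vapply(docs, function(d) any(grepl("[[:space:]]", d)), logical(1))))
    stop("tokens must not contain embedded whitespace")
  structure(docs, class = "token_stream")
}

#' @export
print.token_stream <- function(x, ...) {
  n <- sum(lengths(x))
  cat(sprintf("<token_stream: %d tokens in %d document(s)>\n", n, length(x)))
  invisible(x)
}

#' Normalise raw text into a token stream
#'
#' Lower-cases, strips punctuation (keeping intra-word hyphens and
#' apostrophes), optionally removes parenthesised material such as unclear
#' utterances, and tokenises on whitespace.  One document per input line.
#' Morphological standardisation (e.g. mapping plural to singular forms) is a
#' pluggable hook applied token-wise; the default is the identity, which is
#' appropriate for synthetic corpora that are generated pre-normalised.
#'
#' @param raw_text A character vector; each element may contain newlines,
#'   and each resulting line becomes one document.
#' @param drop_parentheticals Remove `(...)` groups before tokenising.
#' @param standardize A function mapping a character vector of tokens to a
#'   character vector of the same length (default `identity`).
#' @return A [token_stream()].
#' @examples
#' normalize_tokens("The cat, sat.")
#' @export
normalize_tokens <- function(raw_text, drop_parentheticals = TRUE,
                             standardize = identity) {
  lines <- unlist(strsplit(raw_text, "\n", fixed = TRUE), use.names = FALSE)
  if (length(lines) == 0) return(token_stream(list()))
  x <- tolower(lines)
  if (drop_parentheticals) x <- gsub("\\([^)]*\\)", " ", x)
  # punctuation to spaces, except hyphen and apostrophe which can be
  # word-internal ("jack-in-the-box"); then strip any left dangling
  x <- gsub("[^[:alnum:]'-]", " ", x)
  docs <- lapply(strsplit(x, "[[:space:]]+"), function(tok) {
    tok <- gsub("^['-]+|['-]+$", "", tok)
    tok[nzchar(tok)]
  })
  docs <- docs[lengths(docs) > 0]
  docs <- lapply(docs, function(tok) {
    out <- standardize(tok)
    stopifnot(length(out) == length(tok))
    out
  })
  token_stream(docs)
}

#' Token frequency table of a stream
#' @param stream A [token_stream()].
#' @return Named integer vector of counts, unordered.
#' @keywords internal
token_counts <- function(stream) {
  tab <- table(unlist(stream, use.names = FALSE))
  stats::setNames(as.integer(tab), names(tab))
}

#' Select the context vocabulary
#'
#' The context vocabulary is the `size` most frequent tokens of the stream
#' after removing stop words, mirroring the usual practice of building
#' distributional vectors over the most common content words.  Frequency ties
#' are broken lexicographically (C locale).
#'
#' @param stream A [token_stream()].
#' @param size Number of context words to keep.
#' @param stoplist Character vector of tokens to exclude (default none).
#' @return Character vector of context words, most frequent first.
#' @export
select_context_vocab <- function(stream, size, stoplist = character()) {
  stopifnot(is.numeric(size), length(size) == 1, size >= 1)
  cnt <- token_counts(stream)
  cnt <- cnt[!(names(cnt) %in% stoplist)]
  ord <- order(-cnt, names(cnt), method = "radix")
  vocab <- names(cnt)[ord]
  if (length(vocab) < size) {
    warning(sprintf("only %d eligible tokens available (requested %d)",
                    length(vocab), size))
    return(vocab)
  }
  vocab[seq_len(size)]
}

#' Write/read a corpus as plain text (one document per line)
#' @param stream A [token_stream()].
#' @param path File path.
#' @export
write_corpus <- function(stream, path) {
  writeLines(vapply(stream, paste, character(1), collapse = " "), path)
  invisible(path)
}

#' @rdname write_corpus
#' @param ... Passed on to [normalize_tokens()].
#' @export
read_corpus <- function(path, ...) {
  normalize_tokens(readLines(path), ...)
}
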