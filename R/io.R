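#' Write a data frame as TSV
#'
#' The package's canonical tabular output: tab-separated, no quoting, no
#' row names, Unix line endings, full double precision.  Identical inputs
#' give byte-identical files.  List columns are collapsed with `";"`.
#'
#' @param df A data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  is_list <- vapply(df, is.list, logical(1))
  for (j in which(is_list))
    df[[j]] <- vapply(df[[j]], paste, character(1), collapse = ";")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
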