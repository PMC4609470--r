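# Internal helpers shared across modules.

#' Reverse-complement nucleotide strings
#'
#' Vectorised over `x`. `N` is self-complementary.
#'
#' @param x Character vector of sequences over `A`, `C`, `G`, `T`, `N`.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  flipped <- chartr("ACGTN", "TGCAN", x)
  vapply(flipped, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Validate a sequence table: tibble with at least id and seq columns.
check_seq_tbl <- function(x, arg = "records") {
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns `id` and `seq`.", arg))
  }
  if (anyDuplicated(x$id)) {
    dup <- x$id[duplicated(x$id)][1]
    abort(sprintf("duplicate sequence id in `%s`: '%s'", arg, dup))
  }
  invisible(x)
}

# Normalise one sequence: uppercase; IUPAC ambiguity codes other than N -> N;
# anything outside the IUPAC alphabet is an error.
normalize_seq <- function(seq, id = "?") {
  s <- toupper(seq)
  bad <- gsub("[ACGTRYSWKMBDHVNU]", "", s)
  if (nzchar(bad)) {
    abort(sprintf("record '%s': illegal character '%s' in sequence",
                  id, substr(bad, 1, 1)))
  }
  s <- gsub("U", "T", s, fixed = TRUE)
  gsub("[RYSWKMBDHV]", "N", s)
}

gc_of_string <- function(s) {
  n_gc <- nchar(gsub("[^GC]", "", s))
  n_acgt <- nchar(gsub("[^ACGT]", "", s))
  c(n_gc = n_gc, n_acgt = n_acgt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
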