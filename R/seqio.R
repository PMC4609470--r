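# seqio: FASTA input/output, sequence cleaning, base composition.

#' Read a FASTA file into a sequence table
#'
#' Sequences are normalised on input: lowercase is uppercased, `U` becomes `T`,
#' and IUPAC ambiguity codes other than `N` are mapped to `N`. Any other
#' character (including alignment gaps) is an error, as are duplicate
#' identifiers and empty sequences.
#'
#' @param path Path to a FASTA file.
#' @param source Optional library label recorded in the `source` column;
#'   defaults to the file name without extension.
#' @return A tibble with columns `id`, `seq`, `source`, one row per entry in
#'   file order.
#' @export
read_fasta <- function(path, source = NULL) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: '%s'", path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (length(seqs) == 0) abort(sprintf("'%s' contains no FASTA records", path))
  empty <- which(!nzchar(seqs))
  if (length(empty)) {
    abort(sprintf("record '%s' has an empty sequence", ids[empty[1]]))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) abort(sprintf("duplicate FASTA id: '%s'", dup[1]))
  seqs <- vapply(seq_along(seqs), function(i) normalize_seq(seqs[i], ids[i]),
                 character(1))
  tibble(id = ids, seq = unname(seqs),
         source = source %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a sequence table to FASTA
#'
#' @param records Sequence table (columns `id`, `seq`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  check_seq_tbl(records)
  set <- Biostrings::DNAStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Clean EST sequences
#'
#' Applies the standard single-pass EST hygiene rules: optional end-adapter
#' stripping, truncation to a fixed-length prefix from the reading start, and
#' removal of short sequences. Records of length exactly `min_len` are kept
#' (the drop rule is strictly "shorter than").
#'
#' @param records Sequence table (columns `id`, `seq`; extra columns carried
#'   through).
#' @param max_prefix_len Keep at most this many leading nucleotides
#'   (default 800).
#' @param min_len Drop sequences shorter than this after trimming
#'   (default 100).
#' @param adapters Character vector of adapter sequences stripped from either
#'   end before truncation (default none).
#' @return A list with `kept` (cleaned sequence tibble, input order preserved)
#'   and `report` (one row per input record: `id`, `input_len`, `kept_len`,
#'   `disposition`, `reason`).
#' @export
clean_sequences <- function(records, max_prefix_len = 800L, min_len = 100L,
                            adapters = character()) {
  check_seq_tbl(records)
  if (!(max_prefix_len > min_len && min_len > 0)) {
    abort("require max_prefix_len > min_len > 0")
  }
  strip_adapters <- function(s) {
    for (a in adapters) {
      a <- toupper(a)
      if (startsWith(s, a)) s <- substring(s, nchar(a) + 1L)
      if (endsWith(s, a)) s <- substring(s, 1L, nchar(s) - nchar(a))
    }
    s
  }
  input_len <- nchar(records$seq)
  trimmed <- vapply(records$seq, strip_adapters, character(1),
                    USE.NAMES = FALSE)
  trimmed <- substring(trimmed, 1L, max_prefix_len)
  kept_len <- nchar(trimmed)
  keep <- kept_len >= min_len
  report <- tibble(
    id = records$id,
    input_len = input_len,
    kept_len = ifelse(keep, kept_len, 0L),
    disposition = ifelse(keep, "kept", "dropped"),
    reason = dplyr::case_when(
      !keep ~ "below min_len",
      kept_len < input_len ~ "truncated to max_prefix_len",
      TRUE ~ ""
    )
  )
  kept <- records[keep, , drop = FALSE]
  kept$seq <- trimmed[keep]
  list(kept = as_tibble(kept), report = report)
}

#' GC content of a sequence library
#'
#' GC fraction is (G + C) / (A + C + G + T); `N` is excluded from both
#' numerator and denominator, so an all-`N` record contributes nothing to the
#' pooled value. Two library-level figures are reported because they answer
#' different questions: the pooled fraction weights every base equally, the
#' per-record mean weights every sequence equally.
#'
#' @param records Sequence table.
#' @return One-row tibble: `gc_pooled`, `gc_mean_per_record`, `n_records`,
#'   `n_bases`.
#' @seealso [gc_per_record()]
#' @export
gc_content <- function(records) {
  per <- gc_per_record(records)
  n_gc <- sum(per$n_gc)
  n_acgt <- sum(per$n_acgt)
  if (n_acgt == 0) abort("no unambiguous bases: GC content undefined")
  tibble(
    gc_pooled = n_gc / n_acgt,
    gc_mean_per_record = mean(per$gc, na.rm = TRUE),
    n_records = nrow(per),
    n_bases = n_acgt
  )
}

#' Per-record GC content
#'
#' @param records Sequence table.
#' @return Tibble with `id`, `gc` (NA for all-`N` records), `n_gc`, `n_acgt`.
#' @export
gc_per_record <- function(records) {
  check_seq_tbl(records)
  if (nrow(records) == 0) abort("empty input")
  counts <- t(vapply(records$seq, gc_of_string, c(n_gc = 0, n_acgt = 0),
                     USE.NAMES = FALSE))
  n_gc <- counts[, 1]; n_acgt <- counts[, 2]
  tibble(
    id = records$id,
    gc = ifelse(n_acgt > 0, n_gc / n_acgt, NA_real_),
    n_gc = as.integer(n_gc),
    n_acgt = as.integer(n_acgt)
  )
}

#' Write a cleaning report as TSV
#'
#' @param report The `report` tibble from [clean_sequences()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(path)
}
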