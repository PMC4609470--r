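# match: all-vs-all matching of two unigene sets with identity/E-value/length
# filtering and best-hit-per-query selection.

#' Construct a match object from an HSP table
#'
#' Bundles a table of qualifying HSPs with the query and subject sequence
#' tables and recomputes the per-pair and coverage summaries. Normally
#' produced by [match_sets()]; exposed so HSP tables can be round-tripped
#' through TSV or constructed directly.
#'
#' @param hsps HSP tibble as returned by [local_align()], plus `query_id` and
#'   `subject_id` columns (and optionally `bit_score`, `evalue`).
#' @param query_seqs,subject_seqs Sequence tables covering every id in `hsps`.
#' @return An object of class `est_match`: list with `hsps`, `pairs`,
#'   `summary`, `query_seqs`, `subject_seqs`.
#' @export
est_match <- function(hsps, query_seqs, subject_seqs) {
  check_seq_tbl(query_seqs, "query_seqs")
  check_seq_tbl(subject_seqs, "subject_seqs")
  needed <- c("query_id", "subject_id", "q_start", "q_end", "s_start",
              "s_end", "strand", "q_row", "s_row", "n_columns", "n_matches",
              "identity", "raw_score")
  missing <- setdiff(needed, names(hsps))
  if (length(missing)) {
    abort(paste0("hsps table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"bit_score" %in% names(hsps)) hsps$bit_score <- NA_real_
  if (!"evalue" %in% names(hsps)) hsps$evalue <- NA_real_
  # enforce storage types so tables round-trip through TSV unchanged
  for (col in c("q_start", "q_end", "s_start", "s_end", "n_columns",
                "n_matches", "raw_score")) {
    hsps[[col]] <- as.integer(hsps[[col]])
  }
  hsps <- arrange(hsps, .data$query_id, .data$q_start)
  pairs <- hsps %>%
    group_by(.data$query_id, .data$subject_id) %>%
    summarise(n_hsps = n(),
              matched_columns = sum(.data$n_columns),
              n_matches = sum(.data$n_matches),
              total_bit = sum(.data$bit_score),
              .groups = "drop") %>%
    mutate(identity = .data$n_matches / .data$matched_columns)
  qlen <- tibble(query_id = query_seqs$id, q_len = nchar(query_seqs$seq))
  matched_q <- qlen %>% filter(.data$query_id %in% pairs$query_id)
  summary <- tibble(
    n_query = nrow(query_seqs),
    n_subject = nrow(subject_seqs),
    matched_unigene_count = dplyr::n_distinct(pairs$query_id),
    matched_columns = sum(pairs$matched_columns),
    matched_query_length = sum(matched_q$q_len),
    coverage_pct = if (nrow(matched_q) > 0)
      100 * sum(pairs$matched_columns) / sum(matched_q$q_len) else NA_real_
  )
  structure(list(hsps = as_tibble(hsps), pairs = pairs, summary = summary,
                 query_seqs = as_tibble(query_seqs),
                 subject_seqs = as_tibble(subject_seqs)),
            class = "est_match")
}

#' Match two unigene sets
#'
#' Aligns every query unigene in `A` against the subject set `B` (a shared
#' k-mer prefilter skips pairs that cannot qualify), keeps HSPs passing the
#' identity / E-value / HSP-length filter, and selects one best subject per
#' query by total bit score over qualifying HSPs (ties broken by higher
#' identity, then lexicographically smaller subject id). The coverage summary
#' reports the matched-unigene count and the matched coverage: total aligned
#' columns over all retained pairs divided by the total length of the matched
#' query unigenes, as a percentage.
#'
#' @param A,B Sequence tables (e.g. `tidy()` of a [cluster_unigenes()]
#'   result): queries and subjects.
#' @param min_identity Minimum HSP identity, gap columns included in the
#'   denominator (default 0.96).
#' @param max_evalue Maximum HSP E-value (default 1e-10).
#' @param min_hsp_len Minimum HSP length in alignment columns (default 33).
#' @param scoring Scoring scheme from [alignment_scoring()].
#' @param max_gap_run Passed to [local_align()] (default 23).
#' @param prefilter Use the k-mer candidate prefilter (default TRUE). With
#'   `FALSE` every query/subject pair is aligned.
#' @param k,min_shared_kmers Prefilter parameters: candidate pairs must share
#'   at least `min_shared_kmers` `k`-mers on one strand (defaults 12 and 5).
#' @return An `est_match` object; see [est_match()]. `tidy()` returns the HSP
#'   table, `glance()` the one-row coverage summary.
#' @export
match_sets <- function(A, B, min_identity = 0.96, max_evalue = 1e-10,
                       min_hsp_len = 33L, scoring = alignment_scoring(),
                       max_gap_run = 23L, prefilter = TRUE, k = 12L,
                       min_shared_kmers = 5L) {
  check_seq_tbl(A, "A"); check_seq_tbl(B, "B")
  if (nrow(A) == 0 || nrow(B) == 0) abort("both sets must be nonempty")
  n_db <- sum(nchar(B$seq))
  if (prefilter) {
    cand <- kmer_pairs_cpp(A$seq, B$seq, as.integer(k),
                           as.integer(min_shared_kmers), FALSE)
  } else {
    cand <- expand.grid(i = seq_len(nrow(A)), j = seq_len(nrow(B)))
  }
  rows <- vector("list", nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    m <- nchar(A$seq[i])
    ms <- min_raw_score(max_evalue, m, n_db, scoring)
    h <- local_align(A$seq[i], B$seq[j], scoring = scoring,
                     min_score = ms, max_gap_run = max_gap_run)
    if (nrow(h) == 0) next
    h$bit_score <- bit_score(h$raw_score, scoring)
    h$evalue <- evalue(h$bit_score, m, n_db)
    h <- h %>% filter(.data$n_columns >= min_hsp_len,
                      .data$identity >= min_identity,
                      .data$evalue <= max_evalue)
    if (nrow(h) == 0) next
    h$query_id <- A$id[i]
    h$subject_id <- B$id[j]
    rows[[r]] <- h
  }
  hsps <- bind_rows(compact(rows))
  if (nrow(hsps) == 0) {
    return(est_match(cbind(empty_hsp_tbl(),
                           tibble(query_id = character(),
                                  subject_id = character(),
                                  bit_score = double(), evalue = double())),
                     A, B))
  }
  # best subject per query: total bit score, then identity, then subject id
  best <- hsps %>%
    group_by(.data$query_id, .data$subject_id) %>%
    summarise(total_bit = sum(.data$bit_score),
              identity = sum(.data$n_matches) / sum(.data$n_columns),
              .groups = "drop") %>%
    arrange(.data$query_id, desc(.data$total_bit), desc(.data$identity),
            .data$subject_id) %>%
    group_by(.data$query_id) %>%
    slice(1) %>%
    ungroup() %>%
    select("query_id", "subject_id")
  hsps <- inner_join(hsps, best, by = c("query_id", "subject_id"))
  est_match(hsps, A, B)
}

#' @export
tidy.est_match <- function(x, ...) x$hsps

#' @export
glance.est_match <- function(x, ...) x$summary

#' @export
print.est_match <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<est_match> %d/%d queries matched (%d HSPs); coverage %.2f%%\n",
    s$matched_unigene_count, s$n_query, nrow(x$hsps),
    ifelse(is.na(s$coverage_pct), 0, s$coverage_pct)))
  invisible(x)
}

#' Write the match table as TSV
#'
#' One row per qualifying HSP of each best-hit pair, 1-based inclusive
#' coordinates, including the aligned rows so the table can be read back with
#' [read_match_tsv()].
#'
#' @param match An `est_match` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_match_tsv <- function(match, path) {
  readr::write_tsv(match$hsps, path)
  invisible(path)
}

#' Read a match table written by [write_match_tsv()]
#'
#' @param path TSV path.
#' @param query_seqs,subject_seqs The sequence tables the table was computed
#'   from.
#' @return An `est_match` object.
#' @export
read_match_tsv <- function(path, query_seqs, subject_seqs) {
  hsps <- readr::read_tsv(path, show_col_types = FALSE)
  est_match(hsps, query_seqs, subject_seqs)
}
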