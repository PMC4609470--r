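# align: Smith-Waterman local alignment with affine gaps, HSP post-processing,
# and Karlin-Altschul E-value arithmetic.

#' Default alignment scoring scheme
#'
#' Match +1, mismatch -2, gap open 5, gap extend 2 (a gap of length L costs
#' `gap_open + L * gap_extend`). `lambda` and `K` are the published ungapped
#' Karlin-Altschul constants for the +1/-2 scheme, used for bit scores and
#' E-values; they parameterise the significance filter, not the alignment
#' itself.
#'
#' @param match,mismatch,gap_open,gap_extend Integer scores/costs.
#' @param lambda,K Karlin-Altschul constants.
#' @return A named list.
#' @export
alignment_scoring <- function(match = 1L, mismatch = -2L, gap_open = 5L,
                              gap_extend = 2L, lambda = 1.28, K = 0.46) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend > 0,
            lambda > 0, K > 0)
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
       lambda = lambda, K = K)
}

#' Bit score from a raw alignment score
#'
#' `bit = (lambda * raw - ln K) / ln 2`.
#'
#' @param raw_score Raw alignment score(s).
#' @param scoring Scoring scheme from [alignment_scoring()].
#' @return Numeric vector of bit scores.
#' @export
bit_score <- function(raw_score, scoring = alignment_scoring()) {
  (scoring$lambda * raw_score - log(scoring$K)) / log(2)
}

#' Karlin-Altschul expectation value
#'
#' `E = m * n * 2^(-bit_score)`: the expected number of chance alignments of
#' at least this bit score between a query of length `m` and a database of
#' effective length `n`.
#'
#' @param bit Bit score(s).
#' @param m Query length.
#' @param n Effective database length.
#' @return Numeric vector of E-values.
#' @export
evalue <- function(bit, m, n) {
  stopifnot(m > 0, n > 0)
  m * n * 2^(-bit)
}

# Smallest raw score whose E-value is <= max_evalue.
min_raw_score <- function(max_evalue, m, n, scoring) {
  bit_min <- log2(m * n / max_evalue)
  max(1L, as.integer(ceiling((bit_min * log(2) + log(scoring$K)) /
                               scoring$lambda)))
}

#' Local alignment of two sequences
#'
#' Smith-Waterman local alignment with affine gap costs. Returns the optimal
#' HSP plus non-overlapping (on the query) suboptimal HSPs found by greedy
#' masking re-alignment, down to `min_score`. Both subject orientations are
#' tried; HSPs overlapping a higher-scoring HSP on the query across strands
#' are dropped. In-alignment gap runs of length `max_gap_run` or more split
#' the HSP at the run (heuristic aligners terminate extension across such
#' gaps, and the large-indel caller relies on that split topology).
#'
#' @param query,subject Sequence strings, or single-row sequence tables.
#' @param scoring Scoring scheme from [alignment_scoring()].
#' @param min_score Minimum raw score for reported HSPs (default 20).
#' @param max_gap_run Split HSPs at gap runs of at least this length
#'   (default 23); `Inf` disables splitting.
#' @param max_hsps Cap on HSPs per orientation (default 25).
#' @return A tibble of HSPs with 1-based inclusive coordinates on the stored
#'   (forward) strands: `q_start`, `q_end`, `s_start`, `s_end`, `strand`
#'   (subject orientation), aligned rows `q_row`/`s_row` (subject row in
#'   alignment orientation), `n_columns`, `n_matches`, `identity` (gap
#'   columns in the denominator), `raw_score`.
#' @export
local_align <- function(query, subject, scoring = alignment_scoring(),
                        min_score = 20L, max_gap_run = 23L, max_hsps = 25L) {
  if (is.data.frame(query)) query <- query$seq[1]
  if (is.data.frame(subject)) subject <- subject$seq[1]
  if (!nzchar(query) || !nzchar(subject)) abort("empty sequence")
  slen <- nchar(subject)
  run_one <- function(subj, strand) {
    h <- sw_hsps_cpp(query, subj, scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend,
                     as.integer(min_score), as.integer(max_hsps))
    if (length(h$q_start) == 0) return(NULL)
    tb <- tibble(
      q_start = h$q_start + 1L, q_end = h$q_end,
      s_start_or = h$s_start + 1L, s_end_or = h$s_end,
      strand = strand, q_row = h$q_row, s_row = h$s_row,
      n_columns = h$n_columns, n_matches = h$n_matches,
      raw_score = h$score
    )
    tb
  }
  res <- bind_rows(run_one(subject, "+"), run_one(revcomp(subject), "-"))
  if (is.null(res) || nrow(res) == 0) return(empty_hsp_tbl())
  if (is.finite(max_gap_run)) {
    res <- bind_rows(lapply(seq_len(nrow(res)), function(i) {
      split_hsp_row(res[i, ], scoring, max_gap_run, min_score)
    }))
  }
  if (nrow(res) == 0) return(empty_hsp_tbl())
  # resolve query overlaps across strands: keep higher score
  res <- res[order(-res$raw_score, res$q_start), , drop = FALSE]
  keep <- logical(nrow(res))
  taken <- integer(0)
  for (i in seq_len(nrow(res))) {
    span <- res$q_start[i]:res$q_end[i]
    if (!any(span %in% taken)) {
      keep[i] <- TRUE
      taken <- c(taken, span)
    }
  }
  res <- res[keep, , drop = FALSE]
  # forward-strand subject coordinates
  res$s_start <- ifelse(res$strand == "+", res$s_start_or,
                        slen - res$s_end_or + 1L)
  res$s_end <- ifelse(res$strand == "+", res$s_end_or,
                      slen - res$s_start_or + 1L)
  res$identity <- res$n_matches / res$n_columns
  res <- res[order(res$q_start), , drop = FALSE]
  as_tibble(res[, c("q_start", "q_end", "s_start", "s_end", "strand",
                    "q_row", "s_row", "n_columns", "n_matches", "identity",
                    "raw_score")])
}

empty_hsp_tbl <- function() {
  tibble(q_start = integer(), q_end = integer(), s_start = integer(),
         s_end = integer(), strand = character(), q_row = character(),
         s_row = character(), n_columns = integer(), n_matches = integer(),
         identity = double(), raw_score = integer())
}

# Recompute the raw score of an aligned row pair under `scoring`.
score_rows <- function(q_row, s_row, scoring) {
  qc <- strsplit(q_row, "", fixed = TRUE)[[1]]
  sc <- strsplit(s_row, "", fixed = TRUE)[[1]]
  gap <- qc == "-" | sc == "-"
  nmatch <- sum(!gap & qc == sc & qc != "N")
  nmis <- sum(!gap & (qc != sc | qc == "N"))
  score <- nmatch * scoring$match + nmis * scoring$mismatch
  for (run in rle(gap)$lengths[rle(gap)$values]) {
    score <- score - scoring$gap_open - run * scoring$gap_extend
  }
  score
}

# Split one HSP row (oriented coordinates) at gap runs >= max_gap_run, trim
# terminal gap columns of the fragments and recompute per-fragment stats.
split_hsp_row <- function(row, scoring, max_gap_run, min_score) {
  qc <- strsplit(row$q_row, "", fixed = TRUE)[[1]]
  sc <- strsplit(row$s_row, "", fixed = TRUE)[[1]]
  gap <- qc == "-" | sc == "-"
  r <- rle(gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  big <- which(r$values & r$lengths >= max_gap_run)
  if (!length(big)) return(row)
  cutpoints <- cbind(starts[big], ends[big])
  seg_start <- c(1L, cutpoints[, 2] + 1L)
  seg_end <- c(cutpoints[, 1] - 1L, length(qc))
  out <- list()
  for (s in seq_along(seg_start)) {
    a <- seg_start[s]; b <- seg_end[s]
    if (a > b) next
    # trim terminal gap columns
    while (a <= b && (qc[a] == "-" || sc[a] == "-")) a <- a + 1L
    while (b >= a && (qc[b] == "-" || sc[b] == "-")) b <- b - 1L
    if (a > b) next
    qseg <- qc[a:b]; sseg <- sc[a:b]
    q_adv_before <- sum(qc[seq_len(a - 1L)] != "-")
    s_adv_before <- sum(sc[seq_len(a - 1L)] != "-")
    nr <- row
    nr$q_start <- row$q_start + q_adv_before
    nr$q_end <- nr$q_start + sum(qseg != "-") - 1L
    nr$s_start_or <- row$s_start_or + s_adv_before
    nr$s_end_or <- nr$s_start_or + sum(sseg != "-") - 1L
    nr$q_row <- paste(qseg, collapse = "")
    nr$s_row <- paste(sseg, collapse = "")
    nr$n_columns <- length(qseg)
    nr$n_matches <- sum(qseg == sseg & qseg != "-" & qseg != "N")
    nr$raw_score <- score_rows(nr$q_row, nr$s_row, scoring)
    if (nr$raw_score >= min_score) out[[length(out) + 1L]] <- nr
  }
  if (!length(out)) return(row[0, , drop = FALSE])
  bind_rows(out)
}
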