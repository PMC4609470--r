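# mechanism: boundary-repeat motif detection and mechanistic classification
# of large indels (identical flanks / boundary repeat / modified flanks).

#' Find a boundary repeat motif at an indel
#'
#' Tests whether the gained or lost segment duplicates a motif abutting the
#' breakpoint (the replication-slippage signature): the longest `m` with
#' `1 <= |m| <= max_motif` such that the indel sequence starts with `m` while
#' the 5' flank ends with `m`, or ends with `m` while the 3' flank starts
#' with `m`. For a 1-nt motif this reduces to the indel base extending a
#' homopolymer run. A homopolymer motif is reported at its unit length.
#'
#' @param seq The inserted or deleted sequence.
#' @param flank5,flank3 Flanking sequence on each side of the event.
#' @param max_motif Longest motif considered (default 51 nt).
#' @return A list `(motif, motif_len)`, or `NULL` when no boundary repeat
#'   exists.
#' @export
find_boundary_repeat <- function(seq, flank5 = "", flank3 = "",
                                 max_motif = 51L) {
  flank5 <- flank5 %||% ""; flank3 <- flank3 %||% ""
  if (is.na(flank5)) flank5 <- ""
  if (is.na(flank3)) flank3 <- ""
  top <- min(max_motif, nchar(seq))
  for (L in rev(seq_len(top))) {
    m5 <- substr(seq, 1L, L)
    if (nchar(flank5) >= L &&
        substr(flank5, nchar(flank5) - L + 1L, nchar(flank5)) == m5) {
      motif <- unit_motif(m5)
      return(list(motif = motif, motif_len = nchar(motif)))
    }
    m3 <- substr(seq, nchar(seq) - L + 1L, nchar(seq))
    if (nchar(flank3) >= L && substr(flank3, 1L, L) == m3) {
      motif <- unit_motif(m3)
      return(list(motif = motif, motif_len = nchar(motif)))
    }
  }
  NULL
}

# Report a homopolymer (or perfect tandem) motif at its repeat unit length.
unit_motif <- function(m) {
  L <- nchar(m)
  for (u in seq_len(L - 1)) {
    if (L %% u != 0) next
    unit <- substr(m, 1L, u)
    if (strrep(unit, L / u) == m) return(unit)
  }
  m
}

#' Classify large indels by flanking-sequence mechanism
#'
#' Assigns each large indel to exactly one of three groups, in precedence
#' order: `boundary_repeat` when [find_boundary_repeat()] finds a motif of at
#' least `min_motif` nt (long flanks are re-extracted from the carrier
#' sequences, since motifs may exceed the stored 10-nt flanks);
#' `modified_flanks` when at least one substitution lies within
#' `flank_window` alignment columns of the breakpoint on either side;
#' `identical_flanks` when those flank columns are mismatch- and gap-free;
#' `unclassified` otherwise (gap-containing but substitution-free flanks).
#' The number of flank substitutions is always reported.
#'
#' @param large_indels Large-indel tibble from [detect_large_indels()] (or
#'   the `size_class == "large"` rows of [call_variants()]).
#' @param match The `est_match` object the indels came from.
#' @param flank_window Alignment columns inspected on each side of the
#'   breakpoint (default 10).
#' @param max_motif Longest boundary motif considered (default 51).
#' @param min_motif Shortest motif accepted as a boundary repeat (default 1,
#'   as 1-nt homopolymer-extending motifs are counted; raise to 3 to exclude
#'   motifs short enough to arise by chance).
#' @return The input tibble plus `group`, `motif`, `motif_len`,
#'   `n_flank_snps`.
#' @export
classify_indels <- function(large_indels, match, flank_window = 10L,
                            max_motif = 51L, min_motif = 1L) {
  n <- nrow(large_indels)
  group <- character(n); motif <- character(n)
  motif_len <- integer(n); n_snps <- integer(n)
  for (i in seq_len(n)) {
    ind <- large_indels[i, ]
    fl <- long_flanks(ind, match, 2L * max_motif + 10L)
    rep <- best_repeat_over_placements(ind$seq, fl$flank5, fl$flank3,
                                       max_motif)
    fs <- flank_mismatches(ind, match, flank_window)
    n_snps[i] <- fs$n_mismatch
    if (!is.null(rep) && rep$motif_len >= min_motif) {
      group[i] <- "boundary_repeat"
      motif[i] <- rep$motif; motif_len[i] <- rep$motif_len
    } else if (fs$n_mismatch >= 1L) {
      group[i] <- "modified_flanks"
    } else if (!fs$has_gap) {
      group[i] <- "identical_flanks"
    } else {
      group[i] <- "unclassified"
    }
  }
  large_indels %>%
    mutate(group = group, motif = motif, motif_len = motif_len,
           n_flank_snps = n_snps)
}

# An indel's placement against its carrier is ambiguous when the event
# boundary repeats flanking sequence (exactly the situation boundary-repeat
# detection targets), and the aligner commits to one equivalent placement
# arbitrarily. Enumerate all alignment-equivalent placements by sliding the
# event left/right one base at a time and keep the longest motif any
# placement yields.
best_repeat_over_placements <- function(seq, flank5, flank3, max_motif,
                                        max_slide = 60L) {
  best <- find_boundary_repeat(seq, flank5, flank3, max_motif)
  take <- function(cand) {
    if (!is.null(cand) &&
        (is.null(best) || cand$motif_len > best$motif_len)) best <<- cand
    invisible(NULL)
  }
  s <- seq; f5 <- flank5; f3 <- flank3
  for (k in seq_len(max_slide)) {  # slide right
    if (!nzchar(f3) || substr(s, 1, 1) != substr(f3, 1, 1)) break
    f5 <- paste0(f5, substr(s, 1, 1))
    s <- paste0(substring(s, 2), substr(f3, 1, 1))
    f3 <- substring(f3, 2)
    take(find_boundary_repeat(s, f5, f3, max_motif))
  }
  s <- seq; f5 <- flank5; f3 <- flank3
  for (k in seq_len(max_slide)) {  # slide left
    n5 <- nchar(f5); ns <- nchar(s)
    if (n5 == 0 || substr(f5, n5, n5) != substr(s, ns, ns)) break
    f3 <- paste0(substr(s, ns, ns), f3)
    s <- paste0(substr(f5, n5, n5), substr(s, 1, ns - 1))
    f5 <- substr(f5, 1, n5 - 1)
    take(find_boundary_repeat(s, f5, f3, max_motif))
  }
  best
}

# Re-extract flanks of up to max_motif nt from the carrier of the indel
# sequence (query for insertions, subject for deletions), using the abutting
# HSP coordinates stored by detect_large_indels().
long_flanks <- function(ind, match, width) {
  strand <- ind$strand
  if (ind$kind == "insertion") {
    carrier <- match$query_seqs$seq[match(ind$query_id,
                                          match$query_seqs$id)]
  } else {
    carrier <- match$subject_seqs$seq[match(ind$subject_id,
                                            match$subject_seqs$id)]
    if (!is.na(strand) && strand == "-") carrier <- revcomp(carrier)
  }
  # carrier_pos is the last carrier base before the event, in the same
  # (oriented) coordinates the event sequence was extracted in
  a <- ind$carrier_pos
  if (is.null(a) || is.na(a)) {
    return(list(flank5 = ind$flank5, flank3 = ind$flank3))
  }
  b <- a + ind$length + 1L
  list(flank5 = substr(carrier, max(1L, a - width + 1L), a),
       flank3 = substr(carrier, b, b + width - 1L))
}

# Count mismatch columns (and detect gap columns) in the flank_window
# alignment columns abutting the event on both sides.
flank_mismatches <- function(ind, match, flank_window) {
  hh <- match$hsps %>%
    filter(.data$query_id == ind$query_id,
           .data$subject_id == ind$subject_id,
           .data$strand == ind$strand)
  left <- hh %>% filter(.data$q_end == ind$left_q_end)
  right <- hh %>% filter(.data$q_start == ind$right_q_start)
  n_mm <- 0L; has_gap <- FALSE
  count_cols <- function(q_row, s_row, from_end) {
    qc <- strsplit(q_row, "", fixed = TRUE)[[1]]
    sc <- strsplit(s_row, "", fixed = TRUE)[[1]]
    idx <- if (from_end) tail(seq_along(qc), flank_window)
           else head(seq_along(qc), flank_window)
    qc <- qc[idx]; sc <- sc[idx]
    list(mm = sum(qc != "-" & sc != "-" & qc != sc & qc != "N" & sc != "N"),
         gap = any(qc == "-" | sc == "-"))
  }
  if (nrow(left) == 1) {
    z <- count_cols(left$q_row, left$s_row, TRUE)
    n_mm <- n_mm + z$mm; has_gap <- has_gap || z$gap
  }
  if (nrow(right) == 1) {
    z <- count_cols(right$q_row, right$s_row, FALSE)
    n_mm <- n_mm + z$mm; has_gap <- has_gap || z$gap
  }
  list(n_mismatch = n_mm, has_gap = has_gap)
}

#' Summarise indel mechanism groups
#'
#' @param classes Output of [classify_indels()].
#' @return Tibble of counts per `kind` and `group`.
#' @export
mechanism_summary <- function(classes) {
  if (nrow(classes) == 0) {
    return(tibble(kind = character(), group = character(), n = integer()))
  }
  classes %>% count(.data$kind, .data$group)
}
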