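# variants: directional SNPs, small indels (inside HSPs) and large indels
# (between split HSPs) from matched pairs.

# Per-HSP column bookkeeping shared by the callers.
hsp_columns <- function(hsp, slen) {
  qc <- strsplit(hsp$q_row, "", fixed = TRUE)[[1]]
  sc <- strsplit(hsp$s_row, "", fixed = TRUE)[[1]]
  s_or_start <- if (hsp$strand == "+") hsp$s_start else slen - hsp$s_end + 1L
  list(
    qc = qc, sc = sc,
    q_pos = hsp$q_start - 1L + cumsum(qc != "-"),
    s_pos_or = s_or_start - 1L + cumsum(sc != "-")
  )
}

s_fwd <- function(pos_or, strand, slen) {
  if (strand == "+") pos_or else slen - pos_or + 1L
}

subject_len <- function(match, subject_id) {
  nchar(match$subject_seqs$seq[match(subject_id, match$subject_seqs$id)])
}

#' Call directional SNPs from a match
#'
#' One record per aligned column where both rows carry a non-gap, non-`N`
#' base and the bases differ. The pattern is written subject to query
#' (`"G->A"` means the subject carries G and the query A); the class is
#' `transition` for A/G and C/T pairs, `transversion` otherwise.
#'
#' @param match An `est_match` object.
#' @return Tibble: `query_id`, `subject_id`, `s_pos` (1-based forward subject
#'   coordinate), `q_pos`, `subject_base`, `query_base` (alignment frame),
#'   `pattern`, `cls`.
#' @export
call_snps <- function(match) {
  hsps <- match$hsps
  if (nrow(hsps) == 0) return(empty_snp_tbl())
  out <- vector("list", nrow(hsps))
  for (i in seq_len(nrow(hsps))) {
    h <- hsps[i, ]
    slen <- subject_len(match, h$subject_id)
    cc <- hsp_columns(h, slen)
    hit <- which(cc$qc != "-" & cc$sc != "-" & cc$qc != cc$sc &
                   cc$qc != "N" & cc$sc != "N")
    if (!length(hit)) next
    sb <- cc$sc[hit]; qb <- cc$qc[hit]
    out[[i]] <- tibble(
      query_id = h$query_id, subject_id = h$subject_id,
      s_pos = vapply(cc$s_pos_or[hit], s_fwd, integer(1),
                     strand = h$strand, slen = slen),
      q_pos = cc$q_pos[hit],
      subject_base = sb, query_base = qb,
      pattern = paste0(sb, "->", qb),
      cls = ifelse(paste0(pmin(sb, qb), pmax(sb, qb)) %in% c("AG", "CT"),
                   "transition", "transversion")
    )
  }
  bind_rows(compact(out))
}

empty_snp_tbl <- function() {
  tibble(query_id = character(), subject_id = character(), s_pos = integer(),
         q_pos = integer(), subject_base = character(),
         query_base = character(), pattern = character(), cls = character())
}

empty_indel_tbl <- function() {
  tibble(query_id = character(), subject_id = character(), kind = character(),
         size_class = character(), length = integer(), s_pos = integer(),
         seq = character(), flank5 = character(), flank3 = character(),
         strand = character(), carrier_pos = integer(),
         left_q_end = integer(), right_q_start = integer())
}

#' Call small indels from a match
#'
#' Each maximal run of consecutive gap columns inside an HSP is one indel of
#' length equal to the run length. Gaps in the subject row are insertions
#' (present in the query, absent in the subject); gaps in the query row are
#' deletions. Flanks of up to `flank_width` nt are taken from the gap-free
#' sequence that carries the event (the query for insertions, the subject for
#' deletions), truncated at sequence ends.
#'
#' @param match An `est_match` object.
#' @param flank_width Maximum flank length recorded (default 10).
#' @return Tibble of indel records: `query_id`, `subject_id`, `kind`,
#'   `size_class` (`"small"`), `length`, `s_pos` (forward subject coordinate
#'   of the last aligned base 5' of the event), `seq`, `flank5`, `flank3`,
#'   `strand`.
#' @export
call_small_indels <- function(match, flank_width = 10L) {
  hsps <- match$hsps
  if (nrow(hsps) == 0) return(empty_indel_tbl())
  out <- list()
  for (i in seq_len(nrow(hsps))) {
    h <- hsps[i, ]
    slen <- subject_len(match, h$subject_id)
    cc <- hsp_columns(h, slen)
    qseq <- match$query_seqs$seq[match(h$query_id, match$query_seqs$id)]
    sseq_or <- match$subject_seqs$seq[match(h$subject_id,
                                            match$subject_seqs$id)]
    if (h$strand == "-") sseq_or <- revcomp(sseq_or)
    for (row in c("s", "q")) {
      gap <- if (row == "s") cc$sc == "-" else cc$qc == "-"
      r <- rle(gap)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      for (k in runs) {
        a <- starts[k]; b <- ends[k]
        L <- b - a + 1L
        if (row == "s") {  # insertion: carrier is the query
          qa <- cc$q_pos[a]; qb <- cc$q_pos[b]
          rec <- tibble(
            query_id = h$query_id, subject_id = h$subject_id,
            kind = "insertion", size_class = "small", length = L,
            s_pos = s_fwd(cc$s_pos_or[a], h$strand, slen),
            seq = paste(cc$qc[a:b], collapse = ""),
            flank5 = substr(qseq, max(1L, qa - flank_width), qa - 1L),
            flank3 = substr(qseq, qb + 1L, qb + flank_width),
            strand = h$strand, carrier_pos = qa - 1L,
            left_q_end = NA_integer_, right_q_start = NA_integer_
          )
        } else {           # deletion: carrier is the subject
          sa <- cc$s_pos_or[a]; sb <- cc$s_pos_or[b]
          rec <- tibble(
            query_id = h$query_id, subject_id = h$subject_id,
            kind = "deletion", size_class = "small", length = L,
            s_pos = s_fwd(sa - 1L, h$strand, slen),
            seq = paste(cc$sc[a:b], collapse = ""),
            flank5 = substr(sseq_or, max(1L, sa - flank_width), sa - 1L),
            flank3 = substr(sseq_or, sb + 1L, sb + flank_width),
            strand = h$strand, carrier_pos = sa - 1L,
            left_q_end = NA_integer_, right_q_start = NA_integer_
          )
        }
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  if (!length(out)) return(empty_indel_tbl())
  bind_rows(out)
}

#' Detect large indels between split alignments
#'
#' For each pair of consecutive collinear HSPs of a matched pair (same
#' strand, query and subject both non-overlapping and advancing), let `gq`
#' and `gs` be the unaligned gaps on the query and subject side. If the
#' smaller gap is at most `slop` (absorbing alignment-end raggedness) and the
#' larger at least `min_large`, one large indel of length `max - min` is
#' emitted: an insertion when the query gap is larger, otherwise a deletion.
#' The event sequence is taken 5'-anchored from the carrier side; flanks come
#' from the sequence that retains continuity across the junction (the subject
#' for insertions, the query for deletions).
#'
#' @param match An `est_match` object.
#' @param slop Maximum gap on the shorter side (default 5 nt).
#' @param min_large Minimum gap on the longer side (default 23 nt).
#' @param flank_width Flank length recorded (default 10).
#' @return Tibble of large-indel records in the same shape as
#'   [call_small_indels()], plus `left_q_end`/`right_q_start` marking the
#'   abutting HSP ends on the query.
#' @export
detect_large_indels <- function(match, slop = 5L, min_large = 23L,
                                flank_width = 10L) {
  hsps <- match$hsps
  if (nrow(hsps) == 0) return(empty_indel_tbl())
  out <- list()
  keys <- hsps %>% distinct(.data$query_id, .data$subject_id, .data$strand)
  for (r in seq_len(nrow(keys))) {
    hh <- hsps %>%
      filter(.data$query_id == keys$query_id[r],
             .data$subject_id == keys$subject_id[r],
             .data$strand == keys$strand[r]) %>%
      arrange(.data$q_start)
    if (nrow(hh) < 2) next
    slen <- subject_len(match, keys$subject_id[r])
    strand <- keys$strand[r]
    s_or_start <- if (strand == "+") hh$s_start else slen - hh$s_end + 1L
    s_or_end <- if (strand == "+") hh$s_end else slen - hh$s_start + 1L
    qseq <- match$query_seqs$seq[match(keys$query_id[r],
                                       match$query_seqs$id)]
    sseq_or <- match$subject_seqs$seq[match(keys$subject_id[r],
                                            match$subject_seqs$id)]
    if (strand == "-") sseq_or <- revcomp(sseq_or)
    for (i in seq_len(nrow(hh) - 1L)) {
      q_end_i <- hh$q_end[i]; s_end_i <- s_or_end[i]
      gq <- hh$q_start[i + 1L] - q_end_i - 1L
      gs <- s_or_start[i + 1L] - s_end_i - 1L
      # a local alignment can extend a few columns past the true breakpoint
      # into the event (when the event boundary resembles the continuation);
      # such extension shows as an HSP overlap on one side. Trim the left
      # HSP back until the overlap disappears, tracking both coordinates
      # through its alignment columns.
      if (gs < 0 || gq < 0) {
        tr <- trim_hsp_end(hh$q_row[i], hh$s_row[i],
                           trim_q = max(0L, -gq), trim_s = max(0L, -gs))
        q_end_i <- q_end_i - tr["dq"]
        s_end_i <- s_end_i - tr["ds"]
        gq <- hh$q_start[i + 1L] - q_end_i - 1L
        gs <- s_or_start[i + 1L] - s_end_i - 1L
      }
      if (gq < 0 || gs < 0) next              # not collinear
      if (min(gq, gs) > slop || max(gq, gs) < min_large) next
      kind <- if (gq > gs) "insertion" else "deletion"
      len <- max(gq, gs) - min(gq, gs)
      if (kind == "insertion") {
        seq <- substr(qseq, q_end_i + 1L, q_end_i + len)
        flank5 <- substr(sseq_or, max(1L, s_end_i - flank_width + 1L),
                         s_end_i)
        flank3 <- substr(sseq_or, s_or_start[i + 1L],
                         s_or_start[i + 1L] + flank_width - 1L)
      } else {
        seq <- substr(sseq_or, s_end_i + 1L, s_end_i + len)
        flank5 <- substr(qseq, max(1L, q_end_i - flank_width + 1L),
                         q_end_i)
        flank3 <- substr(qseq, hh$q_start[i + 1L],
                         hh$q_start[i + 1L] + flank_width - 1L)
      }
      out[[length(out) + 1L]] <- tibble(
        query_id = keys$query_id[r], subject_id = keys$subject_id[r],
        kind = kind, size_class = "large", length = len,
        s_pos = s_fwd(s_end_i, strand, slen),
        seq = seq, flank5 = flank5, flank3 = flank3, strand = strand,
        carrier_pos = if (kind == "insertion") q_end_i else s_end_i,
        left_q_end = hh$q_end[i], right_q_start = hh$q_start[i + 1L]
      )
    }
  }
  if (!length(out)) return(empty_indel_tbl())
  bind_rows(out)
}

# Walk an HSP's alignment columns backwards until at least `trim_q` query
# bases and `trim_s` subject bases have been removed; return the number of
# query/subject bases removed.
trim_hsp_end <- function(q_row, s_row, trim_q = 0L, trim_s = 0L) {
  qc <- strsplit(q_row, "", fixed = TRUE)[[1]]
  sc <- strsplit(s_row, "", fixed = TRUE)[[1]]
  dq <- 0L; ds <- 0L
  j <- length(qc)
  while (j >= 1L && (dq < trim_q || ds < trim_s)) {
    if (qc[j] != "-") dq <- dq + 1L
    if (sc[j] != "-") ds <- ds + 1L
    j <- j - 1L
  }
  c(dq = dq, ds = ds)
}

#' Call all variants from a match
#'
#' Runs [call_snps()], [call_small_indels()] and [detect_large_indels()] and
#' binds the results into one variant table: `type` is `SNP`, `INS` or `DEL`;
#' `ref`/`alt` carry the subject/query alleles (the event sequence sits in
#' `alt` for insertions and `ref` for deletions); `pattern` and `cls` are
#' SNP-only; `size_class`, `flank5`, `flank3` are indel-only.
#'
#' @param match An `est_match` object.
#' @param slop,min_large Large-indel topology thresholds (defaults 5, 23).
#' @param flank_width Indel flank length (default 10).
#' @return A variant tibble.
#' @export
call_variants <- function(match, slop = 5L, min_large = 23L,
                          flank_width = 10L) {
  snps <- call_snps(match)
  small <- call_small_indels(match, flank_width)
  large <- detect_large_indels(match, slop, min_large, flank_width)
  snp_rows <- if (nrow(snps)) snps %>%
    mutate(type = "SNP", size_class = NA_character_, length = 1L,
           ref = .data$subject_base, alt = .data$query_base,
           flank5 = NA_character_, flank3 = NA_character_) %>%
    select("query_id", "subject_id", "s_pos", "type", "size_class",
           "length", "ref", "alt", "pattern", "cls", "flank5", "flank3")
  indel_rows <- bind_rows(small, large)
  indel_rows <- if (nrow(indel_rows)) indel_rows %>%
    mutate(type = ifelse(.data$kind == "insertion", "INS", "DEL"),
           ref = ifelse(.data$kind == "deletion", .data$seq, ""),
           alt = ifelse(.data$kind == "insertion", .data$seq, ""),
           pattern = NA_character_, cls = NA_character_) %>%
    select("query_id", "subject_id", "s_pos", "type", "size_class",
           "length", "ref", "alt", "pattern", "cls", "flank5", "flank3",
           "kind", "seq", "strand", "carrier_pos", "left_q_end",
           "right_q_start")
  out <- bind_rows(snp_rows, indel_rows)
  if (nrow(out) == 0) return(empty_variant_tbl())
  arrange(out, .data$query_id, .data$s_pos)
}

empty_variant_tbl <- function() {
  tibble(query_id = character(), subject_id = character(), s_pos = integer(),
         type = character(), size_class = character(), length = integer(),
         ref = character(), alt = character(), pattern = character(),
         cls = character(), flank5 = character(), flank3 = character(),
         kind = character(), seq = character(), strand = character(),
         left_q_end = integer(), right_q_start = integer())
}

#' Write a variant table as TSV
#'
#' @param variants Variant tibble from [call_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(path)
}
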