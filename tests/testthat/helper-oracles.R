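# Independent oracles and fixture builders used across the suite.
# These deliberately reimplement the checked quantities with plain,
# unoptimised R so they share no code with the package internals.

# Exhaustive affine-gap Smith-Waterman score (no traceback): the oracle for
# the alignment engine's optimal raw score.
oracle_sw_score <- function(q, s, match = 1, mismatch = -2, gap_open = 5,
                            gap_extend = 2) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (qc[i] == sc[j] && qc[i] != "N") match else mismatch
      E[i + 1, j + 1] <- max(H[i, j + 1] - gap_open - gap_extend,
                             E[i, j + 1] - gap_extend)
      F[i + 1, j + 1] <- max(H[i + 1, j] - gap_open - gap_extend,
                             F[i + 1, j] - gap_extend)
      H[i + 1, j + 1] <- max(0, H[i, j] + sub, E[i + 1, j + 1],
                             F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# Exhaustive ungapped offset scan: the oracle for find_overlap(). Returns
# the best qualifying (identity, length) or NULL.
oracle_overlap <- function(a, b, min_overlap, min_identity) {
  ac <- strsplit(a, "")[[1]]
  best <- NULL
  for (bb in c(b, estpoly::revcomp(b))) {
    bc <- strsplit(bb, "")[[1]]
    la <- length(ac); lb <- length(bc)
    for (d in (-(lb - min_overlap)):(la - min_overlap)) {
      a0 <- max(1, d + 1); a1 <- min(la, d + lb)
      L <- a1 - a0 + 1
      if (L < min_overlap) next
      am <- ac[a0:a1]; bm <- bc[(a0 - d):(a1 - d)]
      id <- mean(am == bm & am != "N")
      if (id >= min_identity &&
          (is.null(best) || id > best$identity ||
           (id == best$identity && L > best$length))) {
        best <- list(identity = id, length = L)
      }
    }
  }
  best
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

seq_tbl <- function(ids, seqs, source = "test") {
  tibble::tibble(id = ids, seq = seqs, source = source)
}

# Build an est_match from hand-written aligned rows. Coordinates are derived
# from the rows; the query/subject sequences must contain the aligned
# segments at the stated starts.
match_from_rows <- function(query_seq, subject_seq, rows,
                            query_id = "q", subject_id = "s") {
  hsps <- dplyr::bind_rows(lapply(rows, function(r) {
    qc <- strsplit(r$q_row, "")[[1]]
    sc <- strsplit(r$s_row, "")[[1]]
    q_start <- r$q_start
    s_start <- r$s_start
    tibble::tibble(
      query_id = query_id, subject_id = subject_id,
      q_start = q_start, q_end = q_start + sum(qc != "-") - 1L,
      s_start = s_start, s_end = s_start + sum(sc != "-") - 1L,
      strand = "+", q_row = r$q_row, s_row = r$s_row,
      n_columns = length(qc),
      n_matches = sum(qc == sc & qc != "-" & qc != "N"),
      identity = sum(qc == sc & qc != "-" & qc != "N") / length(qc),
      raw_score = 0L
    )
  }))
  estpoly::est_match(hsps, seq_tbl(query_id, query_seq),
                     seq_tbl(subject_id, subject_seq))
}

# One constructed matched pair holding a large deletion whose mechanistic
# group is forced by construction: optionally n substitutions in the 10
# flank columns left of the breakpoint, optionally a boundary motif shared
# between the deleted block's end and the 3' flank.
build_large_indel_case <- function(n_flank_snps = 0, motif = NULL) {
  set.seed(50)
  L <- random_seq(200); R <- random_seq(200)
  del <- random_seq(80)
  if (!is.null(motif)) del <- paste0(substr(del, 1, 80 - nchar(motif)), motif)
  Rr <- if (!is.null(motif)) paste0(motif, substr(R, nchar(motif) + 1, 200))
        else R
  Lq <- L
  if (n_flank_snps > 0) {
    lc <- strsplit(L, "")[[1]]
    for (i in seq(196, by = -2, length.out = n_flank_snps)) {
      lc[i] <- chartr("ACGT", "GTAC", lc[i])
    }
    Lq <- paste(lc, collapse = "")
  }
  qseq <- paste0(Lq, Rr)                  # query lacks the deleted block
  sseq <- paste0(L, del, Rr)
  m <- match_from_rows(qseq, sseq,
                       list(list(q_row = Lq, s_row = L,
                                 q_start = 1L, s_start = 1L),
                            list(q_row = Rr, s_row = Rr,
                                 q_start = 201L, s_start = 281L)))
  list(match = m, indel = estpoly::detect_large_indels(m), del = del)
}

write_temp_fasta <- function(entries, dir = tempdir()) {
  path <- tempfile("fx", tmpdir = dir, fileext = ".fasta")
  writeLines(unlist(lapply(names(entries), function(id) {
    c(paste0(">", id), entries[[id]])
  })), path)
  path
}
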