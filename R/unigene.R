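# unigene: greedy overlap clustering of cleaned ESTs into contigs/singletons.

#' Find the best end-to-end overlap between two sequences
#'
#' Scans every relative offset of `b` (and of its reverse complement) against
#' `a` and returns the best ungapped dovetail or containment overlap of length
#' at least `min_overlap` and identity at least `min_identity`. Best means
#' highest identity, ties broken by longer overlap. `N` never counts as a
#' match.
#'
#' @param a,b Sequence strings, or single-row sequence tables.
#' @param min_overlap Minimum overlap length in nt (default 50).
#' @param min_identity Minimum overlap identity (default 0.95).
#' @return A one-row tibble (`length`, `identity`, `offset`, `orientation`)
#'   where `offset` is the start of (oriented) `b` relative to the start of
#'   `a` (0-based, may be negative) and `orientation` is `"+"` or `"-"`;
#'   `NULL` if no qualifying overlap exists.
#' @export
find_overlap <- function(a, b, min_overlap = 50L, min_identity = 0.95) {
  if (is.data.frame(a)) a <- a$seq[1]
  if (is.data.frame(b)) b <- b$seq[1]
  stopifnot(min_overlap >= 1, min_identity > 0, min_identity <= 1)
  fwd <- scan_overlap_cpp(a, b, as.integer(min_overlap), min_identity)
  rev <- scan_overlap_cpp(a, revcomp(b), as.integer(min_overlap), min_identity)
  pick <- NULL
  if (fwd$found) pick <- c(fwd, orientation = "+")
  if (rev$found && (is.null(pick) || rev$identity > pick$identity ||
                    (rev$identity == pick$identity && rev$length > pick$length))) {
    pick <- c(rev, orientation = "-")
  }
  if (is.null(pick)) return(NULL)
  tibble(length = pick$length, identity = pick$identity,
         offset = pick$offset, orientation = pick$orientation)
}

# Union-find with path compression.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Cluster sequences into unigenes
#'
#' Single-linkage clustering under the qualifying-overlap relation of
#' [find_overlap()], followed by majority-vote consensus construction.
#' Candidate pairs are pre-screened with a shared k-mer index so unrelated
#' sequences are never scanned. For each cluster of two or more members a
#' consensus is built by anchoring on the longest member, laying out the
#' remaining members at their overlap offsets (re-oriented to the anchor's
#' strand), and taking a per-column majority vote; vote ties take the base of
#' the longest covering member, then the lexicographically smallest base.
#' Singletons pass through unchanged.
#'
#' Unigene ids are `"<library>_u<counter>"` in order of first member
#' appearance, with the library label taken from the first member's `source`.
#'
#' @param records Cleaned sequence table.
#' @param min_overlap,min_identity Overlap thresholds (defaults 50 nt, 0.95).
#' @param k K-mer size for the candidate prefilter (default 12).
#' @return An object of class `unigene_set`: a list with `unigenes` (tibble
#'   `id`, `seq`, `kind`, `n_members`, `length`, `source`) and `members`
#'   (tibble `unigene_id`, `member_id`, `offset` (1-based start in the
#'   unigene), `strand`).
#' @export
cluster_unigenes <- function(records, min_overlap = 50L, min_identity = 0.95,
                             k = 12L) {
  check_seq_tbl(records)
  n <- nrow(records)
  src <- records$source %||% rep("lib", n)
  if (is.null(records$source)) records$source <- src
  cand <- kmer_pairs_cpp(records$seq, records$seq, as.integer(k), 1L, TRUE)
  edges <- list()
  parent <- uf_new(n)
  if (nrow(cand) > 0) {
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      ov <- find_overlap(records$seq[i], records$seq[j], min_overlap,
                         min_identity)
      if (!is.null(ov)) {
        edges[[length(edges) + 1L]] <- list(i = i, j = j)
        ri <- uf_find(parent, i); rj <- uf_find(parent, j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  # order clusters by first member appearance
  first_idx <- tapply(seq_len(n), comp, min)
  comp_order <- names(sort(first_idx))
  adj <- vector("list", n)
  for (e in edges) {
    adj[[e$i]] <- c(adj[[e$i]], e$j)
    adj[[e$j]] <- c(adj[[e$j]], e$i)
  }

  uni_rows <- list(); mem_rows <- list()
  counter <- 0L
  for (cid in comp_order) {
    members <- which(comp == as.integer(cid))
    counter <- counter + 1L
    lib <- src[min(members)]
    uid <- sprintf("%s_u%d", lib, counter)
    if (length(members) == 1L) {
      i <- members
      uni_rows[[counter]] <- tibble(id = uid, seq = records$seq[i],
                                    kind = "singleton", n_members = 1L,
                                    source = lib)
      mem_rows[[counter]] <- tibble(unigene_id = uid,
                                    member_id = records$id[i],
                                    offset = 1L, strand = "+")
      next
    }
    layout <- layout_cluster(records, members, adj, min_overlap, min_identity)
    cons <- consensus_from_layout(layout)
    uni_rows[[counter]] <- tibble(id = uid, seq = cons, kind = "contig",
                                  n_members = length(members), source = lib)
    mem_rows[[counter]] <- tibble(unigene_id = uid,
                                  member_id = records$id[layout$idx],
                                  offset = layout$offset + 1L,
                                  strand = layout$strand)
  }
  unigenes <- bind_rows(uni_rows)
  unigenes$length <- nchar(unigenes$seq)
  unigenes <- unigenes[, c("id", "seq", "kind", "n_members", "length", "source")]
  out <- list(unigenes = unigenes, members = bind_rows(mem_rows))
  class(out) <- "unigene_set"
  out
}

# BFS layout of one cluster: offsets/orientations relative to the anchor
# (longest member, ties by lexicographically smallest id). Returns a tibble
# idx / oriented seq / offset (0-based, shifted so min is 0) / strand.
layout_cluster <- function(records, members, adj, min_overlap, min_identity) {
  lens <- nchar(records$seq[members])
  anchor_pos <- order(-lens, records$id[members])[1]
  anchor <- members[anchor_pos]
  placed_seq <- setNames(vector("list", length(members)),
                         as.character(members))
  offset <- setNames(rep(NA_real_, length(members)), as.character(members))
  strand <- setNames(rep(NA_character_, length(members)),
                     as.character(members))
  placed_seq[[as.character(anchor)]] <- records$seq[anchor]
  offset[as.character(anchor)] <- 0
  strand[as.character(anchor)] <- "+"
  queue <- anchor
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    nb <- sort(intersect(adj[[u]], members))
    for (v in nb) {
      key <- as.character(v)
      if (!is.na(offset[key])) next
      ov <- find_overlap(placed_seq[[as.character(u)]], records$seq[v],
                         min_overlap, min_identity)
      if (is.null(ov)) next  # placed orientation may not overlap; rare
      sv <- if (ov$orientation == "+") records$seq[v] else revcomp(records$seq[v])
      placed_seq[[key]] <- sv
      offset[key] <- offset[as.character(u)] + ov$offset
      # placed_seq[[u]] is already in the anchor frame, so the overlap
      # orientation IS the member's strand in that frame
      strand[key] <- ov$orientation
      queue <- c(queue, v)
    }
  }
  ok <- !is.na(offset)
  idx <- members[match(names(offset)[ok], as.character(members))]
  off <- offset[ok] - min(offset[ok])
  tibble(idx = idx,
         seq = unlist(placed_seq[ok], use.names = FALSE),
         offset = as.integer(off),
         strand = unname(strand[ok]),
         len = nchar(unlist(placed_seq[ok], use.names = FALSE)))
}

consensus_from_layout <- function(layout) {
  width <- max(layout$offset + layout$len)
  m <- nrow(layout)
  chars <- matrix("", nrow = m, ncol = width)
  for (r in seq_len(m)) {
    cols <- (layout$offset[r] + 1L):(layout$offset[r] + layout$len[r])
    chars[r, cols] <- strsplit(layout$seq[r], "", fixed = TRUE)[[1]]
  }
  out <- character(width)
  for (j in seq_len(width)) {
    col <- chars[, j]
    cover <- which(col %in% c("A", "C", "G", "T"))
    if (!length(cover)) {
      nn <- which(col == "N")
      out[j] <- if (length(nn)) "N" else ""
      next
    }
    tab <- table(col[cover])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) { out[j] <- top; next }
    # tie: base of the longest member covering this column with a tied base
    cand <- cover[col[cover] %in% top]
    cand <- cand[order(-layout$len[cand], col[cand])]
    out[j] <- col[cand[1]]
  }
  paste(out[nzchar(out)], collapse = "")
}

#' @export
glance.unigene_set <- function(x, ...) {
  tibble(
    n_unigenes = nrow(x$unigenes),
    n_contigs = sum(x$unigenes$kind == "contig"),
    n_singletons = sum(x$unigenes$kind == "singleton"),
    n_members = sum(x$unigenes$n_members),
    mean_length = mean(x$unigenes$length)
  )
}

#' @export
tidy.unigene_set <- function(x, ...) x$unigenes

#' @export
print.unigene_set <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<unigene_set> %d unigenes (%d contigs, %d singletons) from %d sequences\n",
              g$n_unigenes, g$n_contigs, g$n_singletons, g$n_members))
  invisible(x)
}
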