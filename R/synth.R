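# synth: seeded divergence simulator with exact ground-truth bookkeeping.

#' Simulation parameters
#'
#' Defaults emulate the polymorphism structure of a somatic-hybrid vs
#' parental wheat EST comparison: unigenes of 700-1000 nt at 54 % GC, a
#' pairwise SNP rate of 11.33 per 1000 nt split into transitions and
#' transversions at 6.70:4.63, small indels at 1.58 per 1000 nt with a
#' strongly 1-nt-dominated length distribution, insertions 63 % of indel
#' events, rarer large indels of 23-574 nt, and 44 % of indels generated by
#' boundary-motif duplication with motifs of 1-51 nt.
#'
#' `sub_rate` is per site per branch (each descendant diverges independently
#' from the ancestor, so the pairwise rate is close to twice it). The indel
#' rates are pairwise event rates: each event is assigned a pairwise polarity
#' (insertion = extra sequence in library A, the query; deletion = extra
#' sequence in library B, the subject) and realised as an insertion into the
#' corresponding branch, which keeps pairwise statistics exactly controlled
#' and truth bookkeeping closed under liftover.
#'
#' @param n_unigenes Number of ancestral unigenes (default 500).
#' @param len_range Ancestor length range in nt (default c(700, 1000)).
#' @param gc_target Ancestral GC fraction (default 0.54).
#' @param sub_rate Per-site, per-branch substitution probability
#'   (default 11.328/2000).
#' @param tstv_ratio Expected transition:transversion ratio
#'   (default 6.701/4.627).
#' @param small_indel_rate Per-site pairwise small-indel event probability
#'   (default 1.577/1000).
#' @param small_len_dist Length distribution over 1-10 nt (default the
#'   observed per-length small-indel frequencies, heavily 1-nt-weighted).
#' @param large_indel_rate Expected pairwise large-indel events per sequence
#'   (default 0.067).
#' @param large_len_range Large-indel length range (default c(23, 574)).
#' @param ins_del_odds Probability an indel event is an insertion
#'   (default 1331/2120).
#' @param repeat_fraction Fraction of indels generated by boundary-motif
#'   duplication (default 0.44).
#' @param motif_len_range Repeat motif length range (default c(1, 51)),
#'   capped by the indel length.
#' @param reads_per_unigene Fragment each descendant into this many
#'   overlapping reads for assembly testing (default 1 = no fragmentation).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A validated list of class `synth_params`.
#' @export
synth_params <- function(n_unigenes = 500L,
                         len_range = c(700L, 1000L),
                         gc_target = 0.54,
                         sub_rate = 11.328 / 2000,
                         tstv_ratio = 6.701 / 4.627,
                         small_indel_rate = 1.577 / 1000,
                         small_len_dist = c(1.319, 0.109, 0.076, 0.031,
                                            0.010, 0.019, 0.004, 0.003,
                                            0.005, 0.001),
                         large_indel_rate = 0.067,
                         large_len_range = c(23L, 574L),
                         ins_del_odds = 1331 / 2120,
                         repeat_fraction = 0.44,
                         motif_len_range = c(1L, 51L),
                         reads_per_unigene = 1L,
                         seed = NULL) {
  p <- list(n_unigenes = as.integer(n_unigenes),
            len_range = as.integer(len_range), gc_target = gc_target,
            sub_rate = sub_rate, tstv_ratio = tstv_ratio,
            small_indel_rate = small_indel_rate,
            small_len_dist = small_len_dist / sum(small_len_dist),
            large_indel_rate = large_indel_rate,
            large_len_range = as.integer(large_len_range),
            ins_del_odds = ins_del_odds, repeat_fraction = repeat_fraction,
            motif_len_range = as.integer(motif_len_range),
            reads_per_unigene = as.integer(reads_per_unigene), seed = seed)
  probs <- c(p$gc_target, p$sub_rate, p$small_indel_rate, p$ins_del_odds,
             p$repeat_fraction)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (p$len_range[1] > p$len_range[2] ||
      p$large_len_range[1] > p$large_len_range[2] ||
      p$motif_len_range[1] > p$motif_len_range[2]) {
    abort("ranges must be ordered (lo, hi)")
  }
  if (p$n_unigenes < 1) abort("n_unigenes must be positive")
  if (p$tstv_ratio <= 0) abort("tstv_ratio must be positive")
  if (length(p$small_len_dist) != 10) {
    abort("small_len_dist must have 10 entries (lengths 1-10)")
  }
  if (p$large_indel_rate > 0 && p$len_range[1] < 2 * large_margin()) {
    abort(sprintf(
      "len_range minimum %d leaves no alignable flanks around large indels (need >= %d)",
      p$len_range[1], 2 * large_margin()))
  }
  if (p$len_range[1] < 100) abort("sequences shorter than 100 nt are not alignable")
  structure(p, class = "synth_params")
}

large_margin <- function() 100L

empty_truth_tbl <- function() {
  tibble(seq_id = character(), type = character(), kind = character(),
         size_class = character(), anc_pos = integer(), pos_a = integer(),
         pos_b = integer(), length = integer(), seq = character(),
         pattern = character(), cls = character(), mechanism = character(),
         motif = character(), motif_len = integer())
}

empty_edits_tbl <- function() {
  tibble(seq_id = character(), branch = character(), type = character(),
         pos = integer(), base = character(), seq = character())
}

random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

transition_of <- c(A = "G", G = "A", C = "T", T = "C")
transversions_of <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

# Substitute bases at `sites`; transition with probability r/(1+r).
mutate_bases <- function(bases, sites, tstv_ratio) {
  if (!length(sites)) return(bases)
  is_ti <- runif(length(sites)) < tstv_ratio / (1 + tstv_ratio)
  new <- character(length(sites))
  for (k in seq_along(sites)) {
    b <- bases[sites[k]]
    new[k] <- if (is_ti[k]) transition_of[[b]] else
      sample(transversions_of[[b]], 1)
  }
  bases[sites] <- new
  bases
}

#' Simulate a diverged library pair with ground truth
#'
#' Draws ancestral unigenes with i.i.d. bases at the target GC, applies
#' substitutions independently to each branch (transitions vs transversions
#' at the configured odds), then plants small and large indel events
#' (boundary-motif duplications for the repeat-mediated fraction), recording
#' every edit exactly. Optionally fragments each descendant into overlapping
#' reads. The random stream is consumed in a fixed documented order
#' (ancestors; then per sequence: branch-A substitutions, branch-B
#' substitutions, small indels, large indels; then reads), so a fixed seed
#' reproduces the output byte for byte.
#'
#' @param params A [synth_params()] object.
#' @return A list of class `synth_pair`: `lib_a`/`lib_b` (sequence tibbles,
#'   `source` `"A"`/`"B"`), `ancestors`, `truth` (pairwise variant truth:
#'   ancestral and both descendant coordinates, kind, size class, mechanism,
#'   motif), `edits` (per-branch edit list for liftover), `params`.
#' @export
simulate_pair <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  lens <- sample(p$len_range[1]:p$len_range[2], p$n_unigenes, replace = TRUE)
  anc <- lapply(lens, function(L) random_bases(L, p$gc_target))
  ids <- sprintf("u%04d", seq_len(p$n_unigenes))

  lib_a <- character(p$n_unigenes); lib_b <- character(p$n_unigenes)
  truth_rows <- vector("list", p$n_unigenes)
  edit_rows <- vector("list", p$n_unigenes)

  for (u in seq_len(p$n_unigenes)) {
    L <- lens[u]
    a0 <- anc[[u]]
    sitesA <- which(runif(L) < p$sub_rate)
    basesA <- mutate_bases(a0, sitesA, p$tstv_ratio)
    sitesB <- which(runif(L) < p$sub_rate)
    basesB <- mutate_bases(a0, sitesB, p$tstv_ratio)

    events <- draw_indel_events(p, L)
    events <- realize_insertions(events, basesA, basesB, p)

    insA <- events[events$branch == "A", , drop = FALSE]
    insB <- events[events$branch == "B", , drop = FALSE]
    lib_a[u] <- apply_insertions(basesA, insA)
    lib_b[u] <- apply_insertions(basesB, insB)

    shiftA <- make_shift(insA)
    shiftB <- make_shift(insB)

    snp_sites <- sort(union(sitesA, sitesB))
    snp_sites <- snp_sites[basesA[snp_sites] != basesB[snp_sites]]
    snp_truth <- if (length(snp_sites)) {
      qb <- basesA[snp_sites]; sb <- basesB[snp_sites]
      tibble(
        seq_id = ids[u], type = "SNP", kind = NA_character_,
        size_class = NA_character_, anc_pos = snp_sites,
        pos_a = snp_sites + shiftA(snp_sites),
        pos_b = snp_sites + shiftB(snp_sites),
        length = 1L, seq = NA_character_,
        pattern = paste0(sb, "->", qb),
        cls = ifelse(paste0(pmin(sb, qb), pmax(sb, qb)) %in% c("AG", "CT"),
                     "transition", "transversion"),
        mechanism = "substitution", motif = NA_character_,
        motif_len = NA_integer_
      )
    }
    indel_truth <- if (nrow(events)) {
      tibble(
        seq_id = ids[u], type = ifelse(events$pair_kind == "insertion",
                                       "INS", "DEL"),
        kind = events$pair_kind, size_class = events$size_class,
        anc_pos = events$anchor,
        pos_a = events$anchor + shiftA(events$anchor),
        pos_b = events$anchor + shiftB(events$anchor),
        length = events$length, seq = events$seq,
        pattern = NA_character_, cls = NA_character_,
        mechanism = events$mechanism, motif = events$motif,
        motif_len = events$motif_len
      )
    }
    truth_rows[[u]] <- bind_rows(snp_truth, indel_truth)

    edit_rows[[u]] <- bind_rows(
      if (length(sitesA)) tibble(seq_id = ids[u], branch = "A", type = "sub",
                                 pos = sitesA, base = basesA[sitesA],
                                 seq = NA_character_),
      if (length(sitesB)) tibble(seq_id = ids[u], branch = "B", type = "sub",
                                 pos = sitesB, base = basesB[sitesB],
                                 seq = NA_character_),
      if (nrow(insA)) tibble(seq_id = ids[u], branch = "A", type = "ins",
                             pos = insA$anchor, base = NA_character_,
                             seq = insA$seq),
      if (nrow(insB)) tibble(seq_id = ids[u], branch = "B", type = "ins",
                             pos = insB$anchor, base = NA_character_,
                             seq = insB$seq)
    )
  }

  ancestors <- tibble(id = ids,
                      seq = vapply(anc, paste, character(1), collapse = ""),
                      source = "ancestor")
  truth <- bind_rows(truth_rows)
  if (nrow(truth) == 0) truth <- empty_truth_tbl()
  edits <- bind_rows(edit_rows)
  if (nrow(edits) == 0) edits <- empty_edits_tbl()
  out <- list(
    lib_a = tibble(id = paste0("A_", ids), anc_id = ids, seq = lib_a,
                   source = "A"),
    lib_b = tibble(id = paste0("B_", ids), anc_id = ids, seq = lib_b,
                   source = "B"),
    ancestors = ancestors,
    truth = truth,
    edits = edits,
    params = p
  )
  if (p$reads_per_unigene > 1L) {
    out$reads_a <- fragment_reads(out$lib_a, p$reads_per_unigene)
    out$reads_b <- fragment_reads(out$lib_b, p$reads_per_unigene)
  }
  class(out) <- "synth_pair"
  out
}

# Draw pairwise indel events for one sequence: anchor (insertion after this
# ancestral position), size class, length, polarity, mechanism.
draw_indel_events <- function(p, L) {
  small_anchor <- which(runif(L) < p$small_indel_rate)
  n_large <- rpois(1, p$large_indel_rate)
  m <- large_margin()
  large_anchor <- if (n_large > 0 && L > 2 * m)
    sample(m:(L - m), n_large) else integer(0)
  ev <- tibble(
    anchor = c(small_anchor, large_anchor),
    size_class = rep(c("small", "large"),
                     c(length(small_anchor), length(large_anchor)))
  )
  if (nrow(ev) == 0) {
    return(tibble(anchor = integer(), size_class = character(),
                  length = integer(), pair_kind = character(),
                  branch = character(), mechanism = character(),
                  motif = NA_character_, motif_len = integer(),
                  side = character()))
  }
  ev <- ev[!duplicated(ev$anchor), , drop = FALSE]
  ev$length <- NA_integer_
  small <- ev$size_class == "small"
  ev$length[small] <- sample(1:10, sum(small), replace = TRUE,
                             prob = p$small_len_dist)
  ev$length[!small] <- sample(p$large_len_range[1]:p$large_len_range[2],
                              sum(!small), replace = TRUE)
  ev$pair_kind <- ifelse(runif(nrow(ev)) < p$ins_del_odds,
                         "insertion", "deletion")
  ev$branch <- ifelse(ev$pair_kind == "insertion", "A", "B")
  ev$mechanism <- ifelse(runif(nrow(ev)) < p$repeat_fraction,
                         "repeat", "plain")
  ev$motif <- NA_character_
  ev$motif_len <- NA_integer_
  ev$side <- sample(c("5", "3"), nrow(ev), replace = TRUE)
  ev
}

# Construct the inserted sequence for each event on its branch background.
realize_insertions <- function(events, basesA, basesB, p) {
  if (nrow(events) == 0) { events$seq <- character(0); return(events) }
  L_anc <- length(basesA)
  seqs <- character(nrow(events))
  for (k in seq_len(nrow(events))) {
    e <- events[k, ]
    bg <- if (e$branch == "A") basesA else basesB
    L <- e$length
    if (e$mechanism == "repeat") {
      lo <- min(p$motif_len_range[1], L)
      hi <- min(p$motif_len_range[2], L)
      mlen <- if (lo >= hi) lo else sample(lo:hi, 1)
      side <- e$side
      if (side == "5" && e$anchor < mlen) side <- "3"
      if (side == "3" && e$anchor + mlen > L_anc) side <- "5"
      if (side == "5" && e$anchor >= mlen) {
        motif <- paste(bg[(e$anchor - mlen + 1):e$anchor], collapse = "")
        rest <- if (L > mlen)
          paste(random_bases(L - mlen, p$gc_target), collapse = "") else ""
        seqs[k] <- paste0(motif, rest)
      } else if (side == "3" && e$anchor + mlen <= L_anc) {
        motif <- paste(bg[(e$anchor + 1):(e$anchor + mlen)], collapse = "")
        rest <- if (L > mlen)
          paste(random_bases(L - mlen, p$gc_target), collapse = "") else ""
        seqs[k] <- paste0(rest, motif)
      } else {  # no room on either side: fall back to a plain event
        events$mechanism[k] <- "plain"
        seqs[k] <- paste(random_bases(L, p$gc_target), collapse = "")
        next
      }
      events$motif[k] <- motif
      events$motif_len[k] <- mlen
      events$side[k] <- side
    } else {
      seqs[k] <- paste(random_bases(L, p$gc_target), collapse = "")
    }
  }
  events$seq <- seqs
  events
}

# Insert event sequences into a base vector (anchors are ancestral
# coordinates; insertion goes after `anchor`).
apply_insertions <- function(bases, ins) {
  s <- paste(bases, collapse = "")
  if (nrow(ins) == 0) return(s)
  ins <- ins[order(-ins$anchor), , drop = FALSE]
  for (k in seq_len(nrow(ins))) {
    i <- ins$anchor[k]
    s <- paste0(substr(s, 1, i), ins$seq[k],
                substr(s, i + 1, nchar(s)))
  }
  s
}

# Cumulative coordinate shift: descendant position of ancestral position x
# is x + shift(x), counting insertions strictly before x.
make_shift <- function(ins) {
  if (nrow(ins) == 0) return(function(x) rep(0L, length(x)))
  anchors <- ins$anchor; lens <- ins$length
  function(x) {
    vapply(x, function(xx) sum(lens[anchors < xx]), integer(1))
  }
}

#' Reapply a recorded edit list to ancestral sequences
#'
#' Reconstructs one branch's descendant sequences from the ancestors and the
#' `edits` table of [simulate_pair()] — the liftover-closure check.
#'
#' @param ancestors Ancestor sequence table.
#' @param edits The `edits` tibble.
#' @param branch `"A"` or `"B"`.
#' @return Named character vector of descendant sequences (names are
#'   ancestor ids).
#' @export
apply_edits <- function(ancestors, edits, branch) {
  out <- setNames(character(nrow(ancestors)), ancestors$id)
  for (i in seq_len(nrow(ancestors))) {
    id <- ancestors$id[i]
    bases <- strsplit(ancestors$seq[i], "", fixed = TRUE)[[1]]
    e <- edits %>% filter(.data$seq_id == id, .data$branch == !!branch)
    subs <- e %>% filter(.data$type == "sub")
    if (nrow(subs)) bases[subs$pos] <- subs$base
    ins <- e %>% filter(.data$type == "ins") %>%
      mutate(anchor = .data$pos, length = nchar(.data$seq))
    out[i] <- apply_insertions(bases, ins)
  }
  out
}

# Fragment descendants into overlapping reads (>= 50 nt overlaps).
fragment_reads <- function(lib, n_reads, overlap = 100L) {
  rows <- lapply(seq_len(nrow(lib)), function(i) {
    len <- nchar(lib$seq[i])
    rl <- ceiling((len + (n_reads - 1) * overlap) / n_reads)
    rl <- min(max(rl, overlap + 50L), len)
    starts <- unique(round(seq(1, len - rl + 1, length.out = n_reads)))
    tibble(id = sprintf("%s_r%d", lib$id[i], seq_along(starts)),
           anc_id = lib$anc_id[i],
           seq = substring(lib$seq[i], starts, starts + rl - 1L),
           source = lib$source[i])
  })
  bind_rows(rows)
}

#' @export
print.synth_pair <- function(x, ...) {
  cat(sprintf(
    "<synth_pair> %d unigenes; truth: %d SNPs, %d small indels, %d large indels\n",
    nrow(x$ancestors), sum(x$truth$type == "SNP"),
    sum(x$truth$size_class == "small", na.rm = TRUE),
    sum(x$truth$size_class == "large", na.rm = TRUE)))
  invisible(x)
}
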