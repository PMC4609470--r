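test_that("SNP patterns are written subject -> query and classified", {
  m <- match_from_rows("CCCCACCCC", "CCCCGCCCC",
                       list(list(q_row = "CCCCACCCC", s_row = "CCCCGCCCC",
                                 q_start = 1L, s_start = 1L)))
  snps <- call_snps(m)
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$pattern, "G->A")      # subject G, query A
  expect_equal(snps$cls, "transition")
  expect_equal(snps$s_pos, 5L)
})

test_that("identical sequences produce no variants", {
  set.seed(20)
  s <- random_seq(120)
  m <- match_sets(seq_tbl("q", s), seq_tbl("s", s))
  expect_equal(nrow(call_variants(m)), 0L)
})

test_that("planted mismatches are recovered with their classes", {
  set.seed(21)
  sc <- strsplit(random_seq(100), "")[[1]]
  qc <- sc
  sc[20] <- "C"; qc[20] <- "T"   # transition
  sc[50] <- "A"; qc[50] <- "T"   # transversion
  sc[80] <- "G"; qc[80] <- "C"   # transversion
  m <- match_from_rows(paste(qc, collapse = ""), paste(sc, collapse = ""),
                       list(list(q_row = paste(qc, collapse = ""),
                                 s_row = paste(sc, collapse = ""),
                                 q_start = 1L, s_start = 1L)))
  snps <- call_snps(m)
  expect_equal(nrow(snps), 3L)
  expect_equal(sum(snps$cls == "transition"), 1L)
  expect_equal(sum(snps$cls == "transversion"), 2L)
  expect_setequal(snps$pattern, c("C->T", "A->T", "G->C"))
})

test_that("a gap run is one indel; separated gaps are separate indels", {
  m <- match_from_rows("ACTTAGT", "ACGT",
                       list(list(q_row = "ACTTAGT", s_row = "AC---GT",
                                 q_start = 1L, s_start = 1L)))
  ind <- call_small_indels(m)
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$kind, "insertion")
  expect_equal(ind$length, 3L)
  expect_equal(ind$seq, "TTA")

  # two 1-nt gaps separated by a match column: two indels of length 1
  m2 <- match_from_rows("ACGTCGA", "ACTGTACGA",
                        list(list(q_row = "AC-GT-CGA", s_row = "ACTGTACGA",
                                  q_start = 1L, s_start = 1L)))
  ind2 <- call_small_indels(m2)
  expect_equal(nrow(ind2), 2L)
  expect_equal(ind2$length, c(1L, 1L))
  expect_equal(ind2$kind, c("deletion", "deletion"))
})

test_that("indel flanks come from the carrier sequence", {
  set.seed(22)
  L <- random_seq(60); R <- random_seq(60)
  ins <- "TTAGG"
  qseq <- paste0(L, ins, R)
  m <- match_from_rows(qseq, paste0(L, R),
                       list(list(q_row = qseq,
                                 s_row = paste0(L, strrep("-", 5), R),
                                 q_start = 1L, s_start = 1L)))
  ind <- call_small_indels(m)
  expect_equal(ind$seq, ins)
  expect_equal(ind$flank5, substr(L, 51, 60))
  expect_equal(ind$flank3, substr(R, 1, 10))
})

test_that("large-indel topology rule is enforced", {
  set.seed(23)
  A <- random_seq(200); B <- random_seq(200)
  gap <- random_seq(100)
  # two HSPs, query gap 100, subject gap 0 -> large insertion of 100
  m <- match_from_rows(paste0(A, gap, B), paste0(A, B),
                       list(list(q_row = A, s_row = A,
                                 q_start = 1L, s_start = 1L),
                            list(q_row = B, s_row = B,
                                 q_start = 301L, s_start = 201L)))
  li <- detect_large_indels(m)
  expect_equal(nrow(li), 1L)
  expect_equal(li$kind, "insertion")
  expect_equal(li$length, 100L)
  expect_equal(li$seq, gap)

  # gq = 15, gs = 12: max below min_large, nothing emitted
  m2 <- match_from_rows(paste0(A, random_seq(15), B),
                        paste0(A, random_seq(12), B),
                        list(list(q_row = A, s_row = A,
                                  q_start = 1L, s_start = 1L),
                             list(q_row = B, s_row = B,
                                  q_start = 216L, s_start = 213L)))
  expect_equal(nrow(detect_large_indels(m2)), 0L)

  # gq = 30, gs = 10: neither side within slop, not a clean split
  m3 <- match_from_rows(paste0(A, random_seq(30), B),
                        paste0(A, random_seq(10), B),
                        list(list(q_row = A, s_row = A,
                                  q_start = 1L, s_start = 1L),
                             list(q_row = B, s_row = B,
                                  q_start = 231L, s_start = 211L)))
  expect_equal(nrow(detect_large_indels(m3)), 0L)
})

test_that("a planted 474-nt insertion is recovered exactly", {
  set.seed(24)
  L <- random_seq(300); R <- random_seq(300)
  ins <- random_seq(474)
  m <- match_sets(seq_tbl("q", paste0(L, ins, R)),
                  seq_tbl("s", paste0(L, R)))
  li <- detect_large_indels(m)
  expect_equal(nrow(li), 1L)
  expect_equal(li$kind, "insertion")
  expect_equal(li$length, 474L)
})

test_that("swapping query and subject mirrors every variant", {
  sim <- simulate_pair(synth_params(n_unigenes = 8, seed = 31))
  ab <- call_variants(match_sets(sim$lib_a, sim$lib_b))
  ba <- call_variants(match_sets(sim$lib_b, sim$lib_a))
  flip <- function(p) paste0(substr(p, 4, 4), "->", substr(p, 1, 1))
  ab_snp <- sort(ab$pattern[ab$type == "SNP"])
  ba_snp <- sort(flip(ba$pattern[ba$type == "SNP"]))
  expect_equal(ab_snp, ba_snp)
  expect_equal(sum(ab$type == "INS"), sum(ba$type == "DEL"))
  expect_equal(sum(ab$type == "DEL"), sum(ba$type == "INS"))
  expect_equal(sort(ab$length[ab$type != "SNP"]),
               sort(ba$length[ba$type != "SNP"]))
})

test_that("gap columns reconcile with coordinate spans per HSP", {
  sim <- simulate_pair(synth_params(n_unigenes = 6, seed = 32))
  m <- match_sets(sim$lib_a, sim$lib_b)
  for (i in seq_len(nrow(m$hsps))) {
    h <- m$hsps[i, ]
    qc <- strsplit(h$q_row, "")[[1]]
    sc <- strsplit(h$s_row, "")[[1]]
    expect_equal(length(qc), h$n_columns)
    expect_equal(sum(qc != "-"), h$q_end - h$q_start + 1L)
    expect_equal(sum(sc != "-"), h$s_end - h$s_start + 1L)
    # total columns = aligned pairs + summed indel lengths
    expect_equal(h$n_columns,
                 sum(qc != "-" & sc != "-") + sum(qc == "-") + sum(sc == "-"))
  }
})

test_that("planted small-indel size spectrum is recovered", {
  sim <- simulate_pair(synth_params(
    n_unigenes = 30, sub_rate = 0, small_indel_rate = 0.004,
    large_indel_rate = 0, seed = 33))
  vars <- call_variants(match_sets(sim$lib_a, sim$lib_b))
  called <- table(factor(vars$length[vars$type != "SNP"], levels = 1:10))
  planted <- table(factor(sim$truth$length[sim$truth$type != "SNP"],
                          levels = 1:10))
  # two classes of planted events are unrecoverable in principle: events
  # within ~10 nt of a sequence end fall outside the local alignment, and
  # opposite-polarity events a few bases apart are rendered as mismatch
  # columns by any optimal aligner. Isolated interior events must all be
  # recovered at their exact lengths.
  tr <- sim$truth
  lens <- nchar(sim$ancestors$seq)[match(tr$seq_id, sim$ancestors$id)]
  nearest <- vapply(seq_len(nrow(tr)), function(i) {
    d <- abs(tr$anc_pos[tr$seq_id == tr$seq_id[i]] - tr$anc_pos[i])
    min(d[d > 0], Inf)
  }, numeric(1))
  isolated <- tr$type != "SNP" & tr$anc_pos > 12 & tr$anc_pos < lens - 12 &
    nearest > 20
  planted_isolated <- table(factor(tr$length[isolated], levels = 1:10))
  expect_true(all(as.integer(called) >= as.integer(planted_isolated)))
  expect_lte(sum(called), sum(planted))
  expect_gte(sum(called), 0.9 * sum(planted))
})
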