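test_that("a duplicated boundary word is found as the motif", {
  # deletion ending in CATCCC whose 3' flank begins with CATCCC
  rep <- find_boundary_repeat(paste0("GATTTGGCAA", "CATCCC"),
                              flank5 = "TTGACCTGAA",
                              flank3 = paste0("CATCCC", "GTAA"))
  expect_equal(rep$motif, "CATCCC")
  expect_equal(rep$motif_len, 6L)
})

test_that("a 1-nt motif is an extension of a homopolymer run", {
  rep <- find_boundary_repeat("G", flank5 = "ACTGAC", flank3 = "GGGGAT")
  expect_equal(rep$motif, "G")
  expect_equal(rep$motif_len, 1L)
  expect_null(find_boundary_repeat("TTA", flank5 = "ACGTACGGAC",
                                   flank3 = "CCGGCCGGCC"))
})

test_that("tandem motifs are reported at their unit length", {
  rep <- find_boundary_repeat("GGGG", flank5 = "ATCGGGG", flank3 = "TTACA")
  expect_equal(rep$motif, "G")
  expect_equal(rep$motif_len, 1L)
})

test_that("the longest boundary motif wins", {
  rep <- find_boundary_repeat(paste0("ACGTGA", "TTTTTTTTTT"),
                              flank5 = "GGCCAACGTGA",
                              flank3 = "TTTTTTTTTTAGC")
  # 10-nt T-run at the 3' side beats any shorter 5' word, but is reported
  # at unit length 1
  expect_equal(rep$motif, "T")
})

test_that("classification precedence is repeat > modified > identical", {
  clean <- build_large_indel_case()
  expect_equal(clean$indel$kind, "deletion")
  cl <- classify_indels(clean$indel, clean$match)
  expect_equal(cl$group, "identical_flanks")
  expect_equal(cl$n_flank_snps, 0L)

  mod <- build_large_indel_case(n_flank_snps = 3)
  cl2 <- classify_indels(mod$indel, mod$match)
  expect_equal(cl2$group, "modified_flanks")
  expect_equal(cl2$n_flank_snps, 3L)

  rep <- build_large_indel_case(motif = "CATCCC")
  cl3 <- classify_indels(rep$indel, rep$match)
  expect_equal(cl3$group, "boundary_repeat")
  expect_equal(cl3$motif, "CATCCC")

  # repeat wins even when flank SNPs are present
  both <- build_large_indel_case(n_flank_snps = 2, motif = "CATCCC")
  cl4 <- classify_indels(both$indel, both$match)
  expect_equal(cl4$group, "boundary_repeat")
  expect_equal(cl4$n_flank_snps, 2L)
})

test_that("every large indel receives exactly one group", {
  sim <- simulate_pair(synth_params(n_unigenes = 30, large_indel_rate = 0.5,
                                    seed = 51))
  res <- run_pipeline(sim$lib_a, sim$lib_b,
                      pipeline_config(max_prefix_len = 2000))
  expect_true(all(res$classes$group %in%
                    c("boundary_repeat", "modified_flanks",
                      "identical_flanks", "unclassified")))
  expect_equal(nrow(res$classes),
               sum(res$variants$size_class == "large", na.rm = TRUE))
})

test_that("boundary-repeat detection has precision and recall >= 0.9", {
  # mutation-free flanks, planted motifs of >= 3 nt, classification at the
  # matching motif floor
  sim <- simulate_pair(synth_params(
    n_unigenes = 80, sub_rate = 0, small_indel_rate = 0,
    large_indel_rate = 0.7, repeat_fraction = 0.5,
    motif_len_range = c(3, 51), seed = 52))
  res <- run_pipeline(sim$lib_a, sim$lib_b,
                      pipeline_config(max_prefix_len = 2000, min_motif = 3))
  mem <- res$unigenes_a$members
  called <- res$classes
  called$anc_id <- sub("^A_", "",
                       mem$member_id[match(called$query_id, mem$unigene_id)])
  truth <- dplyr::filter(sim$truth, size_class == "large")
  # match called events to planted by sequence, polarity and length
  called$key <- paste(called$anc_id, called$kind, called$length)
  truth$key <- paste(truth$seq_id, truth$kind, truth$length)
  matched <- dplyr::inner_join(called, truth, by = "key",
                               suffix = c("", ".t"))
  pred_rep <- matched$group == "boundary_repeat"
  true_rep <- matched$mechanism == "repeat"
  precision <- sum(pred_rep & true_rep) / sum(pred_rep)
  recall <- sum(pred_rep & true_rep) / sum(true_rep)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
})

test_that("classification is invariant under polarity reversal", {
  rep <- build_large_indel_case(motif = "CATCCC")
  # realign the pair the other way round: the deletion becomes an insertion
  q <- rep$match$query_seqs$seq
  s <- rep$match$subject_seqs$seq
  m_rev <- match_sets(seq_tbl("s", s), seq_tbl("q", q))
  ind_rev <- detect_large_indels(m_rev)
  expect_equal(ind_rev$kind, "insertion")
  cl <- classify_indels(ind_rev, m_rev)
  expect_equal(cl$group, "boundary_repeat")
  expect_equal(cl$motif, "CATCCC")
})
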