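# A hand-built variant table: counts are exact by construction.
toy_variants <- function(n_ti = 6, n_tv = 4, n_ins = 3, n_del = 1) {
  dplyr::bind_rows(
    tibble::tibble(type = "SNP", cls = "transition", pattern = "G->A",
                   size_class = NA_character_, length = 1L, query_id = "q",
                   s_pos = seq_len(n_ti)),
    tibble::tibble(type = "SNP", cls = "transversion", pattern = "G->C",
                   size_class = NA_character_, length = 1L, query_id = "q",
                   s_pos = 100L + seq_len(n_tv)),
    tibble::tibble(type = "INS", cls = NA_character_,
                   pattern = NA_character_, size_class = "small",
                   length = 1L, query_id = "q", s_pos = 200L + seq_len(n_ins)),
    tibble::tibble(type = "DEL", cls = NA_character_,
                   pattern = NA_character_, size_class = "small",
                   length = 1L, query_id = "q", s_pos = 300L + seq_len(n_del))
  )
}

test_that("per-kb frequencies are forced arithmetic", {
  s <- summarize_polymorphism(toy_variants(), matched_length = 2000)
  g <- glance(s)
  expect_equal(g$snp_per_kb, 5.0)
  expect_equal(g$transition_per_kb, 3.0)
  expect_equal(g$transversion_per_kb, 2.0)
  expect_equal(g$indel_per_kb, 2.0)
  expect_equal(g$insertion_per_kb, 1.5)
  expect_equal(g$deletion_per_kb, 0.5)
})

test_that("frequency conservation holds exactly", {
  g <- glance(summarize_polymorphism(toy_variants(7, 5, 2, 2),
                                     matched_length = 3137))
  expect_identical(g$transition_per_kb + g$transversion_per_kb, g$snp_per_kb)
  expect_identical(g$insertion_per_kb + g$deletion_per_kb, g$indel_per_kb)
  expect_equal(sum(tidy(summarize_polymorphism(
    toy_variants(7, 5, 2, 2), matched_length = 3137))$n[1:12]), 12)
})

test_that("zero variants give zero frequencies, and zero length errors", {
  g <- glance(summarize_polymorphism(toy_variants(0, 0, 0, 0),
                                     matched_length = 1000))
  expect_equal(g$snp_per_kb, 0)
  expect_equal(g$indel_per_kb, 0)
  expect_error(summarize_polymorphism(toy_variants(), matched_length = 0),
               "matched_length")
})

test_that("summaries are invariant to row order", {
  v <- toy_variants(8, 3, 4, 2)
  g1 <- glance(summarize_polymorphism(v, matched_length = 5000))
  g2 <- glance(summarize_polymorphism(v[sample(nrow(v)), ],
                                      matched_length = 5000))
  expect_equal(g1, g2)
})

spectrum_variants <- function(ins_by_len, del_by_len, size_class = "small") {
  dplyr::bind_rows(lapply(seq_along(ins_by_len), function(L) {
    dplyr::bind_rows(
      if (ins_by_len[L] > 0)
        tibble::tibble(type = "INS", size_class = size_class, length = L,
                       n = seq_len(ins_by_len[L])),
      if (del_by_len[L] > 0)
        tibble::tibble(type = "DEL", size_class = size_class, length = L,
                       n = seq_len(del_by_len[L]))
    )
  }))
}

test_that("a perfectly linear decreasing ratio gives r2 = 1, negative", {
  v <- spectrum_variants(ins_by_len = c(4, 3, 2, 1),
                         del_by_len = c(1, 1, 1, 1))
  rs <- ratio_spectrum(v, "small", bins = 1:4)
  expect_equal(rs$r_squared, 1.0)
  expect_equal(rs$direction, -1)
  expect_equal(tidy(rs)$ratio, c(4, 3, 2, 1))
})

test_that("flat ratios are flagged as zero variance with r2 = 0", {
  v <- spectrum_variants(c(2, 2, 2), c(2, 2, 2))
  rs <- ratio_spectrum(v, "small", bins = 1:3)
  expect_equal(rs$r_squared, 0)
  expect_true(rs$zero_variance)
})

test_that("fewer than three defined bins leaves the correlation undefined", {
  v <- spectrum_variants(c(3, 1, 2), c(1, 0, 1))   # middle bin has no dels
  rs <- ratio_spectrum(v, "small", bins = 1:3)
  expect_equal(rs$n_defined, 2L)
  expect_true(is.na(rs$r_squared))
})

test_that("undefined-ratio bins are excluded from the correlation", {
  v <- spectrum_variants(c(4, 3, 2, 1, 5), c(1, 1, 1, 1, 0))
  rs <- ratio_spectrum(v, "small", bins = 1:5)
  expect_equal(rs$n_defined, 4L)
  expect_equal(rs$r_squared, 1.0)   # the defined bins are perfectly linear
})

test_that("a planted length-dependent polarity trend is detected", {
  set.seed(40)
  lengths <- rep(1:5, each = 80)
  # insertion odds decay with length: planted negative trend
  v <- tibble::tibble(type = ifelse(runif(length(lengths)) <
                                      0.9 - 0.12 * lengths, "INS", "DEL"),
                      size_class = "small", length = lengths)
  rs <- ratio_spectrum(v, "small", bins = 1:5)
  expect_equal(rs$direction, -1)
  expect_gt(rs$r_squared, 0.5)
})

test_that("flank GC profile reads off positions correctly", {
  v <- tibble::tibble(type = "INS", size_class = "small", length = 1L,
                      flank5 = strrep("G", 10), flank3 = strrep("G", 10))
  fp <- flank_profile(v)
  expect_true(all(tidy(fp)$gc == 1.0))

  v2 <- tibble::tibble(type = "DEL", size_class = "small", length = 1L,
                       flank5 = "ACGTACGTAC", flank3 = "GATTACAGAT")
  t2 <- tidy(flank_profile(v2))
  expect_equal(t2$gc[t2$position == 1 & t2$category == "all"], 1.0)   # G
  expect_equal(t2$gc[t2$position == 2 & t2$category == "all"], 0.0)   # A
  expect_equal(t2$gc[t2$position == -1 & t2$category == "all"], 1.0)  # C
})

test_that("truncated flanks contribute only covered positions", {
  v <- tibble::tibble(type = "INS", size_class = "small", length = 1L,
                      flank5 = "GG", flank3 = "AT")
  t <- tidy(flank_profile(v))
  expect_setequal(t$position[t$category == "insertion"], c(-2, -1, 1, 2))
})

test_that("GC enrichment adjacent to insertions is visible in the profile", {
  set.seed(42)
  n <- 400
  mk_flank <- function(n, pos1_gc) {
    inner <- ifelse(runif(n) < pos1_gc, "G", "A")
    paste0(vapply(seq_len(n), function(i) random_seq(9), character(1)),
           inner)
  }
  v <- tibble::tibble(type = "INS", size_class = "small", length = 1L,
                      flank5 = mk_flank(n, 0.9),
                      flank3 = vapply(seq_len(n), function(i) random_seq(10),
                                      character(1)))
  t <- tidy(flank_profile(v))
  ins <- t[t$category == "insertion", ]
  expect_gt(ins$gc[ins$position == -1],
            mean(ins$gc[ins$position %in% -(10:2)]))
})

test_that("functional bins restrict and recombine consistently", {
  sim <- simulate_pair(synth_params(n_unigenes = 10, seed = 43))
  m <- match_sets(sim$lib_a, sim$lib_b)
  v <- call_variants(m)
  ids <- m$pairs$query_id
  # one category holding everything equals the global summary
  all_map <- tibble::tibble(unigene_id = ids, category = "all")
  fb <- functional_bins(v, m, all_map)
  g <- glance(summarize_polymorphism(v, m))
  expect_equal(fb$snp_per_kb, g$snp_per_kb)
  expect_equal(fb$matched_length, g$matched_length)
  # a category with no members is flagged, not an error
  none <- functional_bins(v, m, tibble::tibble(unigene_id = "nope",
                                               category = "empty"))
  expect_true(none$zero_matched_length)
  expect_equal(none$snp_total, 0)
  # two disjoint categories recombine to the global frequencies
  half <- split(ids, rep(1:2, length.out = length(ids)))
  map2 <- dplyr::bind_rows(
    tibble::tibble(unigene_id = half[[1]], category = "one"),
    tibble::tibble(unigene_id = half[[2]], category = "two"))
  fb2 <- functional_bins(v, m, map2)
  expect_equal(sum(fb2$snp_total), g$snp_total)
  expect_equal(sum(fb2$matched_length), g$matched_length)
  pooled <- 1000 * sum(fb2$snp_total) / sum(fb2$matched_length)
  expect_equal(pooled, g$snp_per_kb)
})
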