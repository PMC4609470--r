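test_that("zero rates reproduce the ancestors with empty truth", {
  sim <- simulate_pair(synth_params(n_unigenes = 5, sub_rate = 0,
                                    small_indel_rate = 0,
                                    large_indel_rate = 0, seed = 60))
  expect_equal(sim$lib_a$seq, sim$ancestors$seq)
  expect_equal(sim$lib_b$seq, sim$ancestors$seq)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("a fixed seed reproduces output exactly; seeds differ", {
  p <- synth_params(n_unigenes = 6, seed = 61)
  s1 <- simulate_pair(p)
  s2 <- simulate_pair(p)
  expect_identical(s1$lib_a$seq, s2$lib_a$seq)
  expect_identical(s1$lib_b$seq, s2$lib_b$seq)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_pair(synth_params(n_unigenes = 6, seed = 62))
  expect_false(identical(s1$lib_a$seq, s3$lib_a$seq))
})

test_that("liftover closure: recorded edits rebuild both descendants", {
  sim <- simulate_pair(synth_params(n_unigenes = 15, seed = 63))
  rebuilt_a <- apply_edits(sim$ancestors, sim$edits, "A")
  rebuilt_b <- apply_edits(sim$ancestors, sim$edits, "B")
  expect_identical(unname(rebuilt_a), sim$lib_a$seq)
  expect_identical(unname(rebuilt_b), sim$lib_b$seq)
})

test_that("planted SNP counts are binomially consistent with the rate", {
  p <- synth_params(n_unigenes = 200, len_range = c(700, 1000),
                    sub_rate = 0.005, small_indel_rate = 0,
                    large_indel_rate = 0, seed = 64)
  sim <- simulate_pair(p)
  L <- sum(nchar(sim$ancestors$seq))
  r <- p$sub_rate
  t <- p$tstv_ratio / (1 + p$tstv_ratio)
  # both branches hitting one site can coincide on the same base
  q_same <- t^2 + (1 - t)^2 / 2
  p_diff <- 2 * r * (1 - r) + r^2 * (1 - q_same)
  expected <- L * p_diff
  se <- sqrt(L * p_diff * (1 - p_diff))
  expect_lt(abs(sum(sim$truth$type == "SNP") - expected), 3 * se)
})

test_that("realised transition:transversion ratio tracks the parameter", {
  ratios <- vapply(1:20, function(s) {
    sim <- simulate_pair(synth_params(n_unigenes = 30, small_indel_rate = 0,
                                      large_indel_rate = 0, seed = 400 + s))
    sum(sim$truth$cls == "transition") / sum(sim$truth$cls == "transversion")
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 6.701 / 4.627) / (6.701 / 4.627), 0.05)
})

test_that("ancestral GC composition hits the target", {
  sim <- simulate_pair(synth_params(n_unigenes = 120, seed = 65))
  expect_gt(sum(nchar(sim$ancestors$seq)), 1e5)
  gc <- gc_content(sim$ancestors)$gc_pooled
  expect_lt(abs(gc - 0.54), 0.01)
})

test_that("unigene lengths honour the configured range", {
  sim <- simulate_pair(synth_params(n_unigenes = 50, seed = 66))
  lens <- nchar(sim$ancestors$seq)
  expect_true(all(lens >= 700 & lens <= 1000))
})

test_that("planted insertion polarity matches the configured odds", {
  sim <- simulate_pair(synth_params(n_unigenes = 150, sub_rate = 0,
                                    small_indel_rate = 0.004,
                                    large_indel_rate = 0, seed = 67))
  ind <- dplyr::filter(sim$truth, type != "SNP")
  n <- nrow(ind)
  p <- 1331 / 2120
  se <- sqrt(n * p * (1 - p))
  expect_lt(abs(sum(ind$type == "INS") - n * p), 3 * se)
})

test_that("read fragmentation covers the descendant with long overlaps", {
  sim <- simulate_pair(synth_params(n_unigenes = 4, reads_per_unigene = 3,
                                    seed = 68))
  expect_true(all(vapply(seq_len(nrow(sim$reads_a)), function(i) {
    grepl(sim$reads_a$seq[i],
          sim$lib_a$seq[sim$lib_a$anc_id == sim$reads_a$anc_id[i]],
          fixed = TRUE)
  }, logical(1))))
  # reads reassemble to the descendant
  one <- dplyr::filter(sim$reads_a, anc_id == "u0001")
  cl <- cluster_unigenes(one)
  expect_equal(cl$unigenes$seq,
               sim$lib_a$seq[sim$lib_a$anc_id == "u0001"])
})

test_that("invalid parameter combinations are rejected", {
  expect_error(synth_params(gc_target = 1.2), "probabilities")
  expect_error(synth_params(len_range = c(1000, 700)), "ordered")
  expect_error(synth_params(len_range = c(150, 300)), "alignable")
  expect_error(synth_params(small_len_dist = c(1, 1)), "10 entries")
})

test_that("recovery on a zero-rate run reports exact zeros", {
  sim <- simulate_pair(synth_params(n_unigenes = 5, sub_rate = 0,
                                    small_indel_rate = 0,
                                    large_indel_rate = 0, seed = 69))
  res <- run_pipeline(sim$lib_a, sim$lib_b,
                      pipeline_config(max_prefix_len = 2000))
  rr <- recovery_report(sim, res)
  counts <- rr[rr$parameter %in% c("snp", "small_indel", "large_indel"), ]
  expect_true(all(counts$planted == 0))
  expect_true(all(counts$estimated == 0))
  expect_true(all(counts$relative_error == 0))
})

test_that("zero tolerance fails whenever any recovery error exists", {
  sim <- simulate_pair(synth_params(n_unigenes = 40, seed = 70))
  res <- run_pipeline(sim$lib_a, sim$lib_b,
                      pipeline_config(max_prefix_len = 2000))
  rr0 <- recovery_report(sim, res, tolerance = 0)
  rr10 <- recovery_report(sim, res, tolerance = 0.1)
  imperfect <- !is.na(rr0$relative_error) & rr0$relative_error > 0
  expect_true(all(!rr0$pass[imperfect]))
  expect_true(sum(rr10$pass) >= sum(rr0$pass))
})
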