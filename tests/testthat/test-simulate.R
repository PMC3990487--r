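test_that("generator is deterministic per seed and honours group counts", {
  p <- sim_params(seed = 7, n_dna = 30, n_r1 = 20, n_r2 = 10,
                  library_size = 1e4, sirna_library_size = 1e4)
  w1 <- simulate_exemplar_db(p)
  w2 <- simulate_exemplar_db(p)
  expect_identical(w1, w2)
  expect_equal(nrow(w1$db), 60)
  expect_equal(sum(w1$db$te_class == "DNA"), 30)
  expect_equal(table(w1$truth$true_group)[["R2"]], 10)

  g1 <- simulate_genomic_hits(w1$db, w1$truth, p, "x")
  g2 <- simulate_genomic_hits(w1$db, w1$truth, p, "x")
  expect_identical(g1, g2)
  # different accession label -> different stream
  g3 <- simulate_genomic_hits(w1$db, w1$truth, p, "y")
  expect_false(identical(g1$counts$hits, g3$counts$hits))

  fc1 <- simulate_expression_fc(w1$db, w1$truth, p)
  expect_identical(fc1, simulate_expression_fc(w1$db, w1$truth, p))

  # no DNA exemplars requested -> none generated
  p0 <- sim_params(seed = 7, n_dna = 0, n_r1 = 10, n_r2 = 10)
  w0 <- simulate_exemplar_db(p0)
  expect_false(any(w0$db$te_class == "DNA"))
})

test_that("invalid configs name the offending field", {
  expect_error(sim_params(fgs_fraction = 0.7, knob_fraction = 0.5),
               "fgs_fraction")
  expect_error(sim_params(n_dna = -1), "n_dna")
  expect_error(sim_params(sirna_rate_22 = c(dna = 1, r1 = 1)), "sirna_rate_22")
})

test_that("group length ordering R2 > R1 > D is recovered at n = 500", {
  p <- sim_params(seed = 5, n_dna = 500, n_r1 = 500, n_r2 = 500)
  w <- simulate_exemplar_db(p)
  mean_len <- tapply(w$db$length_bp, w$truth$true_group, mean)
  expect_gt(mean_len[["R2"]], mean_len[["R1"]])
  expect_gt(mean_len[["R1"]], mean_len[["D"]])
})

test_that("genomic reads are conserved and follow multinomial moments", {
  p <- sim_params(seed = 21, n_dna = 50, n_r1 = 40, n_r2 = 30,
                  library_size = 1e6)
  w <- simulate_exemplar_db(p)
  g <- simulate_genomic_hits(w$db, w$truth, p, "acc1")
  expect_equal(total_ute_hits(g) + g$fgs_hits + g$knob_hits, 1e6)

  # expected hits within 3 binomial SDs of the configured probabilities
  wgt <- w$truth$true_copy_number * w$db$length_bp
  prob <- (1 - p$fgs_fraction - p$knob_fraction) * wgt / sum(wgt)
  expected <- 1e6 * prob
  sds <- sqrt(1e6 * prob * (1 - prob))
  expect_true(mean(abs(g$counts$hits - expected) <= 3 * sds) > 0.98)

  # one exemplar with all copy weight receives every non-FGS/Knob read
  truth1 <- w$truth
  truth1$true_copy_number <- c(1, rep(0, nrow(truth1) - 1))
  g1 <- simulate_genomic_hits(w$db, truth1, p, "acc1")
  expect_equal(g1$counts$hits[1], total_ute_hits(g1))

  truth0 <- w$truth
  truth0$true_copy_number <- 0
  expect_error(simulate_genomic_hits(w$db, truth0, p, "acc1"), "degenerate")
})

test_that("empirical hit frequencies match configured probabilities (KS)", {
  p <- sim_params(seed = 9, n_dna = 100, n_r1 = 60, n_r2 = 40,
                  library_size = 1e6)
  w <- simulate_exemplar_db(p)
  g <- simulate_genomic_hits(w$db, w$truth, p, "ks")
  wgt <- w$truth$true_copy_number * w$db$length_bp
  prob <- wgt / sum(wgt)
  freq <- g$counts$hits / total_ute_hits(g)
  # chi-square goodness of fit of the multinomial allocation
  expected <- total_ute_hits(g) * prob
  stat <- sum((g$counts$hits - expected)^2 / expected)
  pval <- pchisq(stat, df = length(prob) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
  expect_equal(sum(freq), 1)
})

test_that("siRNA counts follow copy-proportional expectations", {
  p <- sim_params(seed = 13, n_dna = 40, n_r1 = 30, n_r2 = 20,
                  sirna_library_size = 2e5)
  w <- simulate_exemplar_db(p)
  s24 <- simulate_sirna_hits(w$db, w$truth, p, "a", 24)
  expect_equal(s24$total_hits, 2e5)
  expect_error(simulate_sirna_hits(w$db, w$truth, p, "a", 23), "size_class")

  # zero rate for a group -> zero counts in that group
  p0 <- sim_params(seed = 13, n_dna = 40, n_r1 = 30, n_r2 = 20,
                   sirna_rate_24 = c(dna = 0, r1 = 1, r2 = 1))
  s0 <- simulate_sirna_hits(w$db, w$truth, p0, "a", 24)
  expect_true(all(s0$counts$hits[w$truth$true_group == "D"] == 0))

  # doubling prop_deviation for one exemplar doubles its expected count:
  # verified against the analytic multinomial mean over 1000 replicates
  idx <- which.max(w$truth$true_copy_number)
  truth2 <- w$truth
  truth2$prop_deviation[idx] <- 2
  rates <- p$sirna_rate_24[c(D = "dna", R1 = "r1", R2 = "r2")[w$truth$true_group]]
  wgt <- w$truth$true_copy_number * unname(rates)
  wgt2 <- wgt * truth2$prop_deviation
  n_rep <- 1000
  tot <- 0
  for (r in seq_len(n_rep)) {
    pr <- sim_params(seed = 1000 + r, n_dna = 40, n_r1 = 30, n_r2 = 20,
                     sirna_library_size = 1e4)
    tot <- tot + simulate_sirna_hits(w$db, truth2, pr, "a", 24)$counts$hits[idx]
  }
  mean_obs <- tot / n_rep
  expect_mu <- 1e4 * wgt2[idx] / sum(wgt2)
  sd_one <- sqrt(1e4 * (wgt2[idx] / sum(wgt2)) * (1 - wgt2[idx] / sum(wgt2)))
  expect_lt(abs(mean_obs - expect_mu), 3 * sd_one / sqrt(n_rep))
})

test_that("expression fold changes recover configured group means", {
  p <- sim_params(seed = 31, n_dna = 300, n_r1 = 300, n_r2 = 300)
  w <- simulate_exemplar_db(p)
  fc <- simulate_expression_fc(w$db, w$truth, p)
  means <- tapply(fc$log2_fc, fc$true_group, mean)
  # configured: D = +1.2-fold, R1 = -1.6-fold, R2 = 1.03-fold, sd = 1 log2
  se3 <- 3 / sqrt(300)
  expect_lt(abs(means[["D"]] - log2(1.2)), se3)
  expect_lt(abs(means[["R1"]] - (-log2(1.6))), se3)
  expect_lt(abs(means[["R2"]] - log2(1.03)), se3)

  # sd = 0 degenerates to the group means exactly
  p0 <- sim_params(seed = 31, n_dna = 5, n_r1 = 5, n_r2 = 5,
                   fc_mop_sd_log2 = c(dna = 0, r1 = 0, r2 = 0))
  w0 <- simulate_exemplar_db(p0)
  fc0 <- simulate_expression_fc(w0$db, w0$truth, p0)
  expect_true(all(fc0$log2_fc[fc0$true_group == "R1"] == -log2(1.6)))
})

test_that("FASTA round-trip preserves the exemplar database", {
  w <- simulate_exemplar_db(sim_params(seed = 2, n_dna = 5, n_r1 = 4,
                                       n_r2 = 3))
  path <- withr::local_tempfile(fileext = ".fa")
  write_exemplar_db(w$db, path)
  back <- read_exemplar_db(path)
  expect_equal(as.data.frame(back), as.data.frame(w$db))
})
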