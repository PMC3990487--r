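test_that("standard chi-square matches hand oracles and the Z-test identity", {
  # hand oracle: Pearson statistic on (10, 990; 20, 980), via chisq.test
  res <- chi2_std(10, 990, 20, 980)
  expect_equal(res$statistic, 3.384095, tolerance = 1e-6)
  # exactly proportional table -> 0
  expect_equal(chi2_std(10, 990, 20, 1980)$statistic, 0)
  # untestable when the subfamily margin is zero
  expect_true(is.na(chi2_std(0, 100, 0, 100)$statistic))
  expect_false(chi2_std(0, 100, 0, 100)$testable)

  # identity with the squared two-proportion Z statistic, 1e3 random tables
  set.seed(77)
  for (i in 1:1000) {
    n_a <- rpois(1, 30); n_b <- rpois(1, 30)
    r_a <- rpois(1, 500) + 1; r_b <- rpois(1, 500) + 1
    if (n_a + n_b == 0) next
    stat <- chi2_std(n_a, r_a, n_b, r_b)$statistic
    p1 <- n_a / (n_a + r_a); p2 <- n_b / (n_b + r_b)
    pp <- (n_a + n_b) / (n_a + r_a + n_b + r_b)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / (n_a + r_a) + 1 / (n_b + r_b)))
    expect_equal(stat, z^2, tolerance = 1e-9)
  }

  # independent implementation oracle on random tables
  set.seed(78)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 200) + 1, 2)
    expect_equal(chi2_std(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])$statistic,
                 unname(chisq.test(tab, correct = FALSE)$statistic),
                 tolerance = 1e-9)
  }
})

test_that("coverage-corrected chi-square matches its binomial construction", {
  # hand oracle: equal coverage, (30, 10): (30-20)^2 / (40 * 0.25) = 10
  expect_equal(chi2_corr(30, 10, 1, 1)$statistic, 10)
  # counts exactly proportional to coverage -> 0
  expect_equal(chi2_corr(20, 10, 2, 1)$statistic, 0)
  # equal coverage equals the p = 1/2 binomial z^2 exactly
  set.seed(5)
  for (i in 1:20) {
    n_a <- rpois(1, 50); n_b <- rpois(1, 50)
    t_i <- n_a + n_b
    if (t_i == 0) next
    expect_equal(chi2_corr(n_a, n_b, 3, 3)$statistic,
                 (n_a - t_i / 2)^2 / (t_i / 4))
  }
  expect_false(chi2_corr(0, 0, 1, 1)$testable)
  expect_error(chi2_corr(1, 1, 0, 1), "coverage")

  # p-values agree with the exact binomial test once expected counts are
  # large (several hundred); at smaller margins the exact two-sided test's
  # discreteness dominates the gap
  set.seed(6)
  worst <- 0
  for (i in 1:200) {
    p <- runif(1, 0.3, 0.7)
    t_i <- 1000
    n_a <- rbinom(1, t_i, p)
    approx_p <- chi2_corr(n_a, t_i - n_a, p, 1 - p)$p_value
    exact_p <- binom.test(n_a, t_i, p)$p.value
    # agreement asserted where the test decides anything; near p = 1 the
    # exact two-sided p is dominated by discreteness
    if (min(approx_p, exact_p) <= 0.1) {
      worst <- max(worst, abs(approx_p - exact_p))
    }
  }
  expect_lt(worst, 0.01)
})

test_that("proportionality chi-square matches the worked example", {
  # identical counts and coverages -> 0
  expect_equal(chi2_prop(50, 50, 80, 80, 1, 1, 1, 1)$statistic, 0)
  # hand oracle: equal coverages, n = (100, 100), s = (400, 100):
  # (ln 4)^2 / (1/400 + 1/100 + 1/100 + 1/100) = 59.13268
  expect_equal(chi2_prop(100, 100, 400, 100, 1, 1, 1, 1)$statistic,
               59.13268, tolerance = 1e-5)
  # any zero count -> untestable, not an error
  r0 <- chi2_prop(0, 100, 400, 100, 1, 1, 1, 1)
  expect_false(r0$testable)
  expect_true(is.na(r0$statistic))
  # coverage shifts move the null, not the data: doubling the genomic
  # coverage of A is offset by doubled observed n_a
  expect_equal(chi2_prop(200, 100, 400, 400, 2, 1, 1, 1)$statistic, 0)

  # binomial variant agrees with its own construction
  rb <- chi2_prop(100, 100, 400, 100, 1, 1, 1, 1, variant = "binomial")
  q <- 0.5
  expect_equal(rb$statistic, (400 - 500 * q)^2 / (500 * q * (1 - q)))
})

test_that("BH correction matches the step-up construction", {
  res <- bh_fdr(c(0.001, 0.02, 0.9), q_threshold = 0.05)
  expect_equal(res$q_value, c(0.003, 0.03, 0.9))
  expect_equal(res$significant, c(TRUE, TRUE, FALSE))
  # all p = 1 -> all q = 1, none significant
  r1 <- bh_fdr(rep(1, 5))
  expect_true(all(r1$q_value == 1) && !any(r1$significant))
  # NA (untestable) entries stay NA and do not enter the family size
  r2 <- bh_fdr(c(0.001, NA, 0.02, 0.9))
  expect_true(is.na(r2$q_value[2]))
  expect_equal(r2$q_value[-2], c(0.003, 0.03, 0.9))
  # step-up monotonicity on random input
  set.seed(8)
  p <- runif(50)
  q <- bh_fdr(p)$q_value
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_equal(nrow(bh_fdr(numeric())), 0)
})

test_that("both novel tests are calibrated under their simulated nulls", {
  # chi2_corr: multinomial libraries with 2x coverage imbalance, 1e4
  # exemplars, expected counts >= 50 on the smaller side
  n_ex <- 1e4
  set.seed(91)
  probs <- c(0.15, 0.061, rep((1 - 0.15 - 0.061) / n_ex, n_ex))
  lib_a <- rmultinom(1, 2e6, probs)[, 1]
  lib_b <- rmultinom(1, 1e6, probs)[, 1]
  res <- chi2_corr(lib_a[-(1:2)], lib_b[-(1:2)],
                   cov_a = lib_a[1], cov_b = lib_b[1])
  rate <- mean(res$p_value < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)

  # chi2_prop under the proportional null (prop_deviation = 1, equal
  # coverages), expected counts >= 50 everywhere
  set.seed(92)
  sprob <- rep(1 / n_ex, n_ex)
  n_a <- rmultinom(1, 1e6, sprob)[, 1]
  n_b <- rmultinom(1, 1e6, sprob)[, 1]
  s_a <- rmultinom(1, 1e6, sprob)[, 1]
  s_b <- rmultinom(1, 1e6, sprob)[, 1]
  resp <- chi2_prop(n_a, n_b, s_a, s_b, 1, 1, 1, 1)
  rate_p <- mean(resp$p_value < 0.05, na.rm = TRUE)
  expect_gt(rate_p, 0.035)
  expect_lt(rate_p, 0.065)
})

test_that("proportionality power rises with the deviation factor", {
  set.seed(93)
  n_ex <- 2000
  rates <- sapply(c(1, 1.5, 2), function(dev) {
    n_a <- rpois(n_ex, 100) + 1
    n_b <- rpois(n_ex, 100) + 1
    s_a <- rpois(n_ex, 100 * dev) + 1
    s_b <- rpois(n_ex, 100) + 1
    mean(chi2_prop(n_a, n_b, s_a, s_b, 1, 1, 1, 1)$p_value < 0.05,
         na.rm = TRUE)
  })
  expect_true(all(diff(rates) > 0))
  expect_gt(rates[3], 0.9)
})

test_that("accession-level test wrappers join counts and correct the family", {
  st <- shared_study()
  res <- test_abundance(st$genomic$A, st$genomic$B, method = "corr",
                        q_threshold = 0.001)
  expect_equal(nrow(res), nrow(st$db))
  expect_true(all(res$q_value >= res$p_value - 1e-12, na.rm = TRUE))
  # identical truth in A and B: essentially no significant calls at q<0.001
  expect_lt(mean(res$significant), 0.01)

  prop <- test_proportionality(st$genomic$A, st$genomic$B,
                               st$sirna24$A, st$sirna24$B)
  expect_equal(nrow(prop), nrow(st$db))
  expect_true(all(!prop$testable | prop$statistic >= 0))
  expect_lt(mean(prop$significant), 0.01)
})

test_that("group comparison produces letters consistent with separation", {
  # trivially separable groups -> three distinct letters
  set.seed(12)
  df <- data.frame(
    value = c(rnorm(50, 0, 0.1), rnorm(50, 5, 0.1), rnorm(50, 10, 0.1)),
    group = rep(c("D", "R1", "R2"), each = 50)
  )
  gc <- group_compare(df, "value", "group")
  expect_lt(gc$kw_p, 1e-10)
  expect_equal(length(unique(gc$summary$letters)), 3)

  # one common distribution -> all share a letter most of the time
  share_all <- replicate(40, {
    d0 <- data.frame(value = rnorm(120), group = rep(c("D", "R1", "R2"), 40))
    g0 <- group_compare(d0, "value", "group")
    length(unique(strsplit(paste(g0$summary$letters, collapse = ""),
                           "")[[1]])) == 1
  })
  expect_gt(mean(share_all), 0.85)

  # constant variable -> KW statistic 0
  dc <- data.frame(value = rep(1, 30), group = rep(c("D", "R1", "R2"), 10))
  expect_equal(group_compare(dc, "value", "group")$kw_statistic, 0)

  expect_error(group_compare(data.frame(value = 1:4, group = "D"),
                             "value", "group"),
               "two groups")
})

test_that("log-scale correlation matches exact relationships", {
  h <- c(10, 100, 1000, 55, 7)
  r1 <- correlation_log(h, h)
  expect_equal(r1$r_squared, 1)
  expect_equal(r1$slope, 1)
  expect_equal(r1$intercept, 0)
  r2 <- correlation_log(h, 2 * h)
  expect_equal(r2$slope, 1)
  expect_equal(r2$intercept, log(2))
  # zero-hit exemplars are excluded
  r3 <- correlation_log(c(h, 0), c(h, 5))
  expect_equal(r3$n, 5)
  expect_error(correlation_log(c(1, 0), c(1, 1)), "at least 3")

  # replicate libraries from one truth correlate strongly
  st <- shared_study()
  j <- dplyr::full_join(
    dplyr::rename(st$genomic$A$counts, a = hits),
    dplyr::rename(st$genomic$B$counts, b = hits), by = "exemplar_id")
  expect_gt(correlation_log(j$a, j$b)$r_squared, 0.9)
})
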