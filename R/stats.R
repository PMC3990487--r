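# Hypothesis tests for comparing TE abundance and siRNA targeting between
# accessions. All three chi-square statistics have 1 df and no continuity
# correction (each is a normal approximation squared, so a correction would
# break the Z-test identities).

#' Standard chi-square test of differential hit proportion
#'
#' Pearson chi-square on the 2x2 table (hits to the subfamily vs hits to all
#' other subfamilies, in each of two accessions), 1 df, no continuity
#' correction — analytically identical to the squared two-proportion Z
#' statistic. Vectorised over exemplars.
#'
#' @param n_a,n_b Hits to the subfamily in accessions A and B.
#' @param rest_a,rest_b Hits to all other subfamilies in A and B.
#' @return Tibble: `statistic`, `p_value`, `testable`. Rows where the
#'   subfamily has zero hits in both accessions (or a zero row total) are
#'   flagged untestable with `NA` statistic.
#' @export
chi2_std <- function(n_a, rest_a, n_b, rest_b) {
  if (any(c(n_a, rest_a, n_b, rest_b) < 0)) abort("cell counts must be >= 0")
  row_a <- n_a + rest_a
  row_b <- n_b + rest_b
  if (any(row_a <= 0) || any(row_b <= 0)) abort("both row totals must be > 0")
  t_i <- n_a + n_b
  rest <- rest_a + rest_b
  total <- row_a + row_b
  testable <- t_i > 0 & rest > 0
  e_a <- row_a * t_i / total
  e_b <- row_b * t_i / total
  e_ra <- row_a * rest / total
  e_rb <- row_b * rest / total
  stat <- (n_a - e_a)^2 / e_a + (n_b - e_b)^2 / e_b +
    (rest_a - e_ra)^2 / e_ra + (rest_b - e_rb)^2 / e_rb
  stat[!testable] <- NA_real_
  tibble(statistic = stat,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE),
         testable = testable)
}

#' Coverage-corrected chi-square test of differential abundance
#'
#' The null proportion of a subfamily's hits falling in accession A is set
#' by relative gene-set coverage, p = F_A / (F_A + F_B), instead of by the
#' overall TE hit totals — correcting for genuinely different genome-wide
#' TE contents. With T = n_a + n_b, the statistic is the squared normal
#' approximation to Binomial(T, p):
#' (n_a - T p)^2 / (T p (1 - p)), 1 df.
#'
#' @param n_a,n_b Subfamily hits in accessions A and B.
#' @param cov_a,cov_b Gene-set (FGS) coverage proxies for A and B (e.g. FGS
#'   hit totals, or per-base depths); only their ratio matters.
#' @return Tibble: `statistic`, `p_value`, `testable` (`FALSE` when
#'   `n_a + n_b == 0`).
#' @export
chi2_corr <- function(n_a, n_b, cov_a, cov_b) {
  if (any(c(n_a, n_b) < 0)) abort("counts must be >= 0")
  if (any(c(cov_a, cov_b) <= 0)) abort("coverages must be > 0")
  p <- cov_a / (cov_a + cov_b)
  if (any(p <= 0 | p >= 1)) abort("null proportion must lie strictly in (0,1)")
  t_i <- n_a + n_b
  testable <- t_i > 0
  stat <- (n_a - t_i * p)^2 / (t_i * p * (1 - p))
  stat[!testable] <- NA_real_
  tibble(statistic = stat,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE),
         testable = testable)
}

#' Chi-square test of copy-number / siRNA proportionality
#'
#' Tests, per subfamily, the null that siRNA targeting per TE copy is equal
#' between two accessions, correcting for the genomic and siRNA library
#' coverages. The default (`"delta"`) construction works on the log ratio
#' of siRNA counts: under the null its expectation is
#' r = ln(n_a/n_b) - ln(F_A/F_B) + ln(S_A/S_B)
#' (copy-number ratio from genomic hits corrected by gene-set coverage,
#' rescaled by the siRNA library coverages), and the delta-method variance
#' of the observed log ratio propagates the sampling noise of all four
#' counts, giving
#' statistic = (ln(s_a/s_b) - r)^2 / (1/s_a + 1/s_b + 1/n_a + 1/n_b),
#' referred to chi-square with 1 df. The `"binomial"` variant instead
#' conditions on the siRNA total s_a + s_b (ignoring genomic sampling
#' noise): s_a is Binomial(s_a + s_b, q) with q = e^r / (1 + e^r), and the
#' statistic is its squared normal approximation.
#'
#' @param n_a,n_b Genomic hits to the subfamily in accessions A and B.
#' @param s_a,s_b siRNA hits to the subfamily (one size class).
#' @param fgs_cov_a,fgs_cov_b Genomic gene-set coverage proxies.
#' @param sirna_cov_a,sirna_cov_b siRNA library coverage proxies (total
#'   siRNA hits mapped to the exemplar set per library).
#' @param variant `"delta"` (both noise sources) or `"binomial"`
#'   (conditional on siRNA totals).
#' @return Tibble: `statistic`, `p_value`, `testable` (`FALSE` where any of
#'   the four counts is zero).
#' @export
chi2_prop <- function(n_a, n_b, s_a, s_b, fgs_cov_a, fgs_cov_b,
                      sirna_cov_a, sirna_cov_b,
                      variant = c("delta", "binomial")) {
  variant <- match.arg(variant)
  if (any(c(fgs_cov_a, fgs_cov_b, sirna_cov_a, sirna_cov_b) <= 0)) {
    abort("coverages must be > 0")
  }
  if (any(c(n_a, n_b, s_a, s_b) < 0)) abort("counts must be >= 0")
  testable <- n_a > 0 & n_b > 0 & s_a > 0 & s_b > 0
  r <- log(n_a / n_b) - log(fgs_cov_a / fgs_cov_b) +
    log(sirna_cov_a / sirna_cov_b)
  if (variant == "delta") {
    stat <- (log(s_a / s_b) - r)^2 / (1 / s_a + 1 / s_b + 1 / n_a + 1 / n_b)
  } else {
    s <- s_a + s_b
    q <- exp(r) / (1 + exp(r))
    stat <- (s_a - s * q)^2 / (s * q * (1 - q))
  }
  stat[!testable] <- NA_real_
  tibble(statistic = stat,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE),
         testable = testable)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment over the testable entries only (untestable `NA`
#' p-values carry no hypothesis and do not enter the family size m).
#'
#' @param p_values Vector of p-values; `NA` marks untestable entries.
#' @param q_threshold Significance threshold on the q-value scale
#'   (default 0.001).
#' @return Tibble: `p_value`, `q_value`, `significant`.
#' @export
bh_fdr <- function(p_values, q_threshold = 0.001) {
  if (length(p_values) == 0) {
    return(tibble(p_value = numeric(), q_value = numeric(),
                  significant = logical()))
  }
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p_values))
  q[ok] <- p.adjust(p_values[ok], method = "BH")
  tibble(p_value = p_values, q_value = q,
         significant = !is.na(q) & q < q_threshold)
}

#' Test differential TE abundance between two accessions
#'
#' Applies [chi2_std()] or [chi2_corr()] to every exemplar and corrects the
#' family with [bh_fdr()]. For `"std"` the comparison cell is hits to all
#' other exemplars; for `"corr"` the null proportion comes from the two
#' libraries' FGS hit totals.
#'
#' @param counts_a,counts_b [te_counts()] objects.
#' @param method `"corr"` (coverage-corrected; default) or `"std"`.
#' @param q_threshold BH significance threshold (default 0.001).
#' @return Tibble: `exemplar_id`, `n_a`, `n_b`, `statistic`, `p_value`,
#'   `q_value`, `significant`, `testable`, plus a `test_name` column.
#' @export
test_abundance <- function(counts_a, counts_b, method = c("corr", "std"),
                           q_threshold = 0.001) {
  method <- match.arg(method)
  stopifnot(inherits(counts_a, "te_counts"), inherits(counts_b, "te_counts"))
  joined <- full_join(
    rename(counts_a$counts, n_a = "hits"),
    rename(counts_b$counts, n_b = "hits"),
    by = "exemplar_id"
  ) %>%
    mutate(n_a = dplyr::coalesce(.data$n_a, 0),
           n_b = dplyr::coalesce(.data$n_b, 0))
  res <- if (method == "std") {
    chi2_std(joined$n_a, sum(joined$n_a) - joined$n_a,
             joined$n_b, sum(joined$n_b) - joined$n_b)
  } else {
    chi2_corr(joined$n_a, joined$n_b, counts_a$fgs_hits, counts_b$fgs_hits)
  }
  adj <- bh_fdr(res$p_value, q_threshold)
  tibble(
    exemplar_id = joined$exemplar_id,
    n_a = joined$n_a, n_b = joined$n_b,
    statistic = res$statistic,
    p_value = res$p_value,
    q_value = adj$q_value,
    significant = adj$significant,
    testable = res$testable,
    test_name = if (method == "std") "chi2_std" else "chi2_corr"
  )
}

#' Test copy-number / siRNA proportionality between two accessions
#'
#' Runs [chi2_prop()] for every exemplar with the genomic FGS totals and
#' the siRNA library totals as the coverage proxies, then BH-corrects.
#'
#' @param counts_a,counts_b [te_counts()] objects (genomic).
#' @param sirna_a,sirna_b [sirna_counts()] objects for one size class.
#' @param variant See [chi2_prop()].
#' @param q_threshold BH significance threshold.
#' @return Tibble like [test_abundance()]'s, with siRNA counts `s_a`, `s_b`.
#' @export
test_proportionality <- function(counts_a, counts_b, sirna_a, sirna_b,
                                 variant = c("delta", "binomial"),
                                 q_threshold = 0.001) {
  variant <- match.arg(variant)
  stopifnot(inherits(sirna_a, "sirna_counts"),
            inherits(sirna_b, "sirna_counts"))
  if (sirna_a$size_class != sirna_b$size_class) {
    abort("siRNA libraries must share one size class")
  }
  joined <- full_join(
    rename(counts_a$counts, n_a = "hits"),
    rename(counts_b$counts, n_b = "hits"),
    by = "exemplar_id"
  ) %>%
    left_join(rename(sirna_a$counts, s_a = "hits"), by = "exemplar_id") %>%
    left_join(rename(sirna_b$counts, s_b = "hits"), by = "exemplar_id") %>%
    mutate(across(c("n_a", "n_b", "s_a", "s_b"),
                  ~ dplyr::coalesce(.x, 0)))
  res <- chi2_prop(joined$n_a, joined$n_b, joined$s_a, joined$s_b,
                   counts_a$fgs_hits, counts_b$fgs_hits,
                   sirna_a$total_hits, sirna_b$total_hits,
                   variant = variant)
  adj <- bh_fdr(res$p_value, q_threshold)
  tibble(
    exemplar_id = joined$exemplar_id,
    n_a = joined$n_a, n_b = joined$n_b,
    s_a = joined$s_a, s_b = joined$s_b,
    statistic = res$statistic,
    p_value = res$p_value,
    q_value = adj$q_value,
    significant = adj$significant,
    testable = res$testable,
    test_name = paste0("chi2_prop_", variant)
  )
}

#' Kruskal-Wallis group comparison with compact letters
#'
#' Compares a per-exemplar variable across the D/R1/R2 groups with a
#' Kruskal-Wallis rank test, followed by Dunn-type pairwise z-tests on the
#' pooled ranks (BH-corrected) summarised as a compact letter display:
#' groups sharing a letter are not significantly different at `alpha`.
#'
#' @param data Data frame with the value and the group columns.
#' @param value,group Column names (strings) of the variable and the group
#'   label. Missing values are dropped.
#' @param alpha Pairwise significance level (default 0.05).
#' @return An object of class `group_comparison`: `summary` (per-group
#'   median/quartiles/n and letters), `kw_statistic`, `kw_p`, `pairwise`
#'   (tibble of Dunn z, p, p_adj), `variable`.
#' @export
group_compare <- function(data, value, group, alpha = 0.05) {
  df <- tibble(value = data[[value]], group = as.character(data[[group]])) %>%
    filter(!is.na(.data$value), !is.na(.data$group))
  counts <- dplyr::count(df, .data$group)
  counts <- counts[counts$n >= 2, ]
  df <- filter(df, .data$group %in% counts$group)
  if (dplyr::n_distinct(df$group) < 2) {
    abort("need at least two groups with at least two observations")
  }
  kw <- if (length(unique(df$value)) == 1L) {
    # all observations tied: no rank variation, statistic is 0 by convention
    list(statistic = c(chi2 = 0), p.value = 1)
  } else {
    kruskal.test(df$value, factor(df$group))
  }
  pw <- dunn_pairwise(df$value, df$group)
  pw$p_adj <- p.adjust(pw$p_value, method = "BH")
  groups <- sort(unique(df$group))
  letters_map <- compact_letters(groups, pw, alpha)
  summary <- df %>%
    group_by(.data$group) %>%
    summarise(
      n = n(),
      q1 = quantile(.data$value, 0.25),
      median = stats::median(.data$value),
      q3 = quantile(.data$value, 0.75),
      mean = mean(.data$value),
      .groups = "drop"
    ) %>%
    mutate(letters = unname(letters_map[.data$group]))
  structure(list(summary = summary,
                 kw_statistic = unname(kw$statistic), kw_p = kw$p.value,
                 pairwise = pw, variable = value, alpha = alpha,
                 data = df),
            class = "group_comparison")
}

# Dunn-type pairwise z statistics on pooled ranks, with tie correction.
dunn_pairwise <- function(x, g) {
  rk <- rank(x)
  n <- length(x)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rk <- tapply(rk, g, mean)
  n_g <- tapply(rk, g, length)
  groups <- sort(unique(g))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z <- (mean_rk[[a]] - mean_rk[[b]]) / se
    tibble(group_a = a, group_b = b, z = z,
           p_value = 2 * stats::pnorm(-abs(z)))
  })
}

# Insert-and-absorb compact letter display from pairwise adjusted p-values.
compact_letters <- function(groups, pairwise, alpha) {
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairwise))) {
    if (!is.na(pairwise$p_adj[i]) && pairwise$p_adj[i] < alpha) {
      sig[pairwise$group_a[i], pairwise$group_b[i]] <- TRUE
      sig[pairwise$group_b[i], pairwise$group_a[i]] <- TRUE
    }
  }
  # each letter = a maximal set of mutually non-different groups
  sets <- list()
  for (g in groups) {
    placed <- FALSE
    for (j in seq_along(sets)) {
      if (!any(sig[g, sets[[j]]])) {
        sets[[j]] <- c(sets[[j]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- g
  }
  # absorb sets contained in others
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && keep[j] && all(sets[[i]] %in% sets[[j]]) &&
          length(sets[[i]]) < length(sets[[j]])) {
        keep[i] <- FALSE
      }
    }
  }
  sets <- sets[keep]
  out <- setNames(rep("", k), groups)
  for (j in seq_along(sets)) {
    for (g in sets[[j]]) out[g] <- paste0(out[g], letters[j])
  }
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: Kruskal-Wallis chi2=%.3f, p=%.3g\n",
              x$variable, x$kw_statistic, x$kw_p))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.group_comparison <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.group_comparison <- function(x, ...) {
  tibble(variable = x$variable, kw_statistic = x$kw_statistic,
         kw_p = x$kw_p, n_groups = nrow(x$summary), alpha = x$alpha)
}

#' Log-scale correlation of hit counts between accessions
#'
#' Ordinary least squares of log(hits_B) on log(hits_A) over exemplars with
#' nonzero hits in both accessions (natural log), as used for pairwise
#' accession comparisons of TE abundance.
#'
#' @param hits_a,hits_b Per-exemplar hit counts, aligned.
#' @return One-row tibble: `r_squared`, `slope`, `intercept`, `n`.
#' @export
correlation_log <- function(hits_a, hits_b) {
  if (length(hits_a) != length(hits_b)) abort("inputs must have equal length")
  keep <- !is.na(hits_a) & !is.na(hits_b) & hits_a > 0 & hits_b > 0
  if (sum(keep) < 3) abort("need at least 3 exemplars with nonzero hits in both")
  x <- log(hits_a[keep]); y <- log(hits_b[keep])
  fit <- lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 1 else stats::cor(x, y)^2
  tibble(r_squared = r2,
         slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         n = sum(keep))
}
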