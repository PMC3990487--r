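#' Genomic abundance log2 fold change between accessions
#'
#' FC_TE = log2 of the ratio of coverage-normalized hits: each accession's
#' per-exemplar hits are divided by its gene-set (FGS) hit total and
#' multiplied by its mean read length (the read-length factor matters only
#' when libraries differ in read length). Exemplars with zero hits in
#' either accession are excluded, and the number excluded is recorded as
#' attribute `n_excluded`.
#'
#' @param counts_a,counts_b [te_counts()] objects.
#' @return Tibble: `exemplar_id`, `fc_te`.
#' @export
fc_te <- function(counts_a, counts_b) {
  stopifnot(inherits(counts_a, "te_counts"), inherits(counts_b, "te_counts"))
  if (counts_a$fgs_hits <= 0 || counts_b$fgs_hits <= 0) {
    abort("both libraries need positive FGS hit totals")
  }
  joined <- full_join(
    rename(counts_a$counts, n_a = "hits"),
    rename(counts_b$counts, n_b = "hits"),
    by = "exemplar_id"
  ) %>%
    mutate(n_a = dplyr::coalesce(.data$n_a, 0),
           n_b = dplyr::coalesce(.data$n_b, 0))
  n_excl <- sum(joined$n_a == 0 | joined$n_b == 0)
  out <- joined %>%
    filter(.data$n_a > 0, .data$n_b > 0) %>%
    mutate(fc_te = log2(
      (.data$n_a * counts_a$mean_read_length / counts_a$fgs_hits) /
        (.data$n_b * counts_b$mean_read_length / counts_b$fgs_hits)
    )) %>%
    select("exemplar_id", "fc_te")
  attr(out, "n_excluded") <- n_excl
  out
}

#' Upper-quartile normalization factor of an siRNA library
#'
#' The 75th percentile of the per-exemplar *nonzero* counts, nearest-rank
#' convention (the ceiling(0.75 n)-th order statistic), so the factor is
#' deterministic and invariant to appending zero-count exemplars.
#'
#' @param sirna A [sirna_counts()] object.
#' @return Scalar upper quartile.
#' @export
upper_quartile <- function(sirna) {
  stopifnot(inherits(sirna, "sirna_counts"))
  nz <- sirna$counts$hits[sirna$counts$hits > 0]
  if (length(nz) == 0) abort("all-zero siRNA library: upper quartile undefined")
  if (length(nz) < 4) abort("need at least 4 exemplars with nonzero counts")
  quantile_nearest_rank(nz, 0.75)
}

#' siRNA log2 fold change between accessions
#'
#' FC = log2 of the ratio of upper-quartile-normalized siRNA counts.
#' Exemplars with zero siRNA hits in either library are excluded (count in
#' attribute `n_excluded`).
#'
#' @param sirna_a,sirna_b [sirna_counts()] objects of the same size class.
#' @return Tibble: `exemplar_id`, `fc` (named `fc_22` or `fc_24` after the
#'   size class).
#' @export
fc_sirna <- function(sirna_a, sirna_b) {
  stopifnot(inherits(sirna_a, "sirna_counts"), inherits(sirna_b, "sirna_counts"))
  if (sirna_a$size_class != sirna_b$size_class) {
    abort("siRNA libraries must share one size class")
  }
  uq_a <- upper_quartile(sirna_a)
  uq_b <- upper_quartile(sirna_b)
  joined <- full_join(
    rename(sirna_a$counts, s_a = "hits"),
    rename(sirna_b$counts, s_b = "hits"),
    by = "exemplar_id"
  ) %>%
    mutate(s_a = dplyr::coalesce(.data$s_a, 0),
           s_b = dplyr::coalesce(.data$s_b, 0))
  n_excl <- sum(joined$s_a == 0 | joined$s_b == 0)
  col <- paste0("fc_", sirna_a$size_class)
  out <- joined %>%
    filter(.data$s_a > 0, .data$s_b > 0) %>%
    mutate(!!col := log2((.data$s_a / uq_a) / (.data$s_b / uq_b))) %>%
    select("exemplar_id", dplyr::all_of(col))
  attr(out, "n_excluded") <- n_excl
  out
}

#' Per-group fold-change summaries with pairwise t-tests
#'
#' Joins per-exemplar fold changes with group labels and reports, per
#' group, the mean signed FC, mean |FC| and median, plus two-tailed Welch
#' t-tests between groups on the chosen scale (|FC| for abundance shifts,
#' signed FC for siRNA shifts).
#'
#' @param fc Tibble with `exemplar_id` and one fold-change column.
#' @param groups A [assign_groups()] tibble (or any tibble with
#'   `exemplar_id` and `group`).
#' @param fc_col Name of the fold-change column; defaults to the first
#'   non-id column.
#' @param compare_on `"abs"` (Welch t-tests on |FC|) or `"signed"`.
#' @return List: `summary` (per-group tibble), `pairwise` (tibble of Welch
#'   t-test results), `fc_col`, `compare_on`.
#' @export
group_fc_summary <- function(fc, groups, fc_col = NULL,
                             compare_on = c("abs", "signed")) {
  compare_on <- match.arg(compare_on)
  fc_col <- fc_col %||% setdiff(names(fc), "exemplar_id")[1]
  df <- fc %>%
    inner_join(select(as_tibble(groups), "exemplar_id", "group"),
               by = "exemplar_id") %>%
    filter(.data$group %in% c("D", "R1", "R2"),
           !is.na(.data[[fc_col]]))
  summary <- df %>%
    group_by(.data$group) %>%
    summarise(
      n = n(),
      mean_fc = mean(.data[[fc_col]]),
      mean_abs_fc = mean(abs(.data[[fc_col]])),
      median_fc = stats::median(.data[[fc_col]]),
      frac_decreasing = mean(.data[[fc_col]] < 0),
      .groups = "drop"
    )
  usable <- summary$group[summary$n >= 2]
  skipped <- setdiff(summary$group, usable)
  if (length(skipped)) {
    warn(paste("groups skipped in pairwise tests (n < 2):",
               paste(skipped, collapse = ", ")))
  }
  pairs <- if (length(usable) >= 2) {
    utils::combn(sort(usable), 2, simplify = FALSE)
  } else list()
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    xa <- df[[fc_col]][df$group == pr[1]]
    xb <- df[[fc_col]][df$group == pr[2]]
    if (compare_on == "abs") { xa <- abs(xa); xb <- abs(xb) }
    tt <- t.test(xa, xb)
    tibble(group_a = pr[1], group_b = pr[2],
           t = unname(tt$statistic), p_value = tt$p.value)
  })
  list(summary = summary, pairwise = pairwise, fc_col = fc_col,
       compare_on = compare_on)
}

#' Join an external expression fold-change table to the groups
#'
#' Name-matched join of a per-exemplar log2 expression fold-change table
#' (e.g. a wild-type vs siRNA-pathway-mutant contrast computed elsewhere)
#' onto the group assignment; reports per-group means and the fraction of
#' exemplars with decreased expression, plus a per-exemplar table paired
#' with the 24:22 siRNA targeting ratio for scatter plots.
#'
#' @param expr_fc Tibble with `exemplar_id` and `log2_fc`.
#' @param groups A [assign_groups()] tibble.
#' @param ratio Optional [ratio_24_22()] tibble to pair with.
#' @return List: `summary` (per-group n, mean log2 FC, fraction
#'   decreasing), `matched` (per-exemplar joined tibble), `n_unmatched`.
#' @export
join_expression_fc <- function(expr_fc, groups, ratio = NULL) {
  if (!all(c("exemplar_id", "log2_fc") %in% names(expr_fc))) {
    abort("`expr_fc` needs columns exemplar_id and log2_fc")
  }
  g <- select(as_tibble(groups), "exemplar_id", "group")
  matched <- inner_join(as_tibble(expr_fc), g, by = "exemplar_id")
  if (nrow(matched) == 0) abort("no exemplar names match the group assignment")
  n_unmatched <- nrow(expr_fc) - nrow(matched)
  if (!is.null(ratio)) {
    matched <- left_join(matched,
                         select(ratio, "exemplar_id", "ratio_24_22"),
                         by = "exemplar_id")
  }
  summary <- matched %>%
    filter(.data$group %in% c("D", "R1", "R2")) %>%
    group_by(.data$group) %>%
    summarise(
      n = n(),
      mean_log2_fc = mean(.data$log2_fc),
      frac_decreasing = mean(.data$log2_fc < 0),
      .groups = "drop"
    )
  list(summary = summary, matched = matched, n_unmatched = n_unmatched)
}
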