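#' Run the full comparative TE / siRNA analysis
#'
#' Orchestrates every stage over a set of accessions: per-accession
#' abundance tables (RPKM, copy number, low-copy filter); group assignment
#' with the R1/R2 split frozen on a reference accession plus the
#' cross-accession agreement report; pairwise differential-abundance tests
#' (standard and coverage-corrected chi-square) and proportionality tests
#' per siRNA size class, BH-corrected; pairwise log2 fold changes with
#' per-group summaries; per-group trait comparisons (Kruskal-Wallis with
#' compact letters); pairwise log-scale correlations; and a machine-readable
#' run manifest. All outputs are returned as a list and, when `out_dir` is
#' given, written as TSV files whose bytes depend only on the inputs.
#'
#' @param db Exemplar tibble.
#' @param genomic Named list of [te_counts()] objects, one per accession
#'   (two or more; names are the accession ids).
#' @param sirna22,sirna24 Named lists of [sirna_counts()] objects over the
#'   same accession names (optional; `NULL` skips siRNA stages).
#' @param expr_fc Optional external expression fold-change tibble
#'   (`exemplar_id`, `log2_fc`).
#' @param reference_accession Accession whose fitted split defines the
#'   R1/R2 boundary reused everywhere (default: first of `genomic`).
#' @param low_copy_rpkm,fdr_q,alpha Analysis thresholds: low-copy RPKM
#'   cutoff (default 1.2), BH significance level (default 0.001), pairwise
#'   comparison level (default 0.05).
#' @param prop_variant Proportionality-test construction, see [chi2_prop()].
#' @param out_dir Optional directory for TSV reports.
#' @return A list of class `te_pipeline`: `abundance`, `groups`,
#'   `split`, `agreement`, `tests`, `proportionality`, `fold_changes`,
#'   `fc_summaries`, `group_comparisons`, `correlations`, `expression`,
#'   `manifest`.
#' @export
run_te_pipeline <- function(db, genomic, sirna22 = NULL, sirna24 = NULL,
                            expr_fc = NULL, reference_accession = NULL,
                            low_copy_rpkm = 1.2, fdr_q = 0.001, alpha = 0.05,
                            prop_variant = c("delta", "binomial"),
                            out_dir = NULL) {
  prop_variant <- match.arg(prop_variant)
  assert_db(db)
  if (length(genomic) < 2 || is.null(names(genomic))) {
    abort("`genomic` must be a named list of two or more te_counts objects")
  }
  if (anyDuplicated(names(genomic))) abort("accession names must be unique")
  accs <- names(genomic)
  reference_accession <- reference_accession %||% accs[1]
  if (!reference_accession %in% accs) {
    abort(sprintf("stage groups: reference accession '%s' not among libraries",
                  reference_accession))
  }

  # --- abundance ---
  abundance <- purrr::map(genomic, te_abundance, db = db,
                          low_copy_rpkm = low_copy_rpkm)

  # --- classification ---
  assignments <- purrr::map(abundance, assign_groups)
  split_ref <- attr(assignments[[reference_accession]], "split")
  groups <- assign_groups(abundance[[reference_accession]], split = split_ref)
  agreement <- group_agreement(assignments)

  # --- pairwise tests ---
  pair_names <- utils::combn(accs, 2, simplify = FALSE)
  tests <- purrr::map_dfr(pair_names, function(pr) {
    bind_rows(
      test_abundance(genomic[[pr[1]]], genomic[[pr[2]]], method = "std",
                     q_threshold = fdr_q),
      test_abundance(genomic[[pr[1]]], genomic[[pr[2]]], method = "corr",
                     q_threshold = fdr_q)
    ) %>%
      mutate(accession_a = pr[1], accession_b = pr[2], .before = 1)
  })

  proportionality <- NULL
  for (sc in c(22, 24)) {
    lib <- if (sc == 22) sirna22 else sirna24
    if (is.null(lib)) next
    res <- purrr::map_dfr(pair_names, function(pr) {
      test_proportionality(genomic[[pr[1]]], genomic[[pr[2]]],
                           lib[[pr[1]]], lib[[pr[2]]],
                           variant = prop_variant, q_threshold = fdr_q) %>%
        mutate(accession_a = pr[1], accession_b = pr[2],
               size_class = sc, .before = 1)
    })
    proportionality <- bind_rows(proportionality, res)
  }

  # --- fold changes ---
  fold_changes <- purrr::map_dfr(pair_names, function(pr) {
    fc <- fc_te(genomic[[pr[1]]], genomic[[pr[2]]])
    for (sc in c(22, 24)) {
      lib <- if (sc == 22) sirna22 else sirna24
      if (!is.null(lib)) {
        fc <- full_join(fc, fc_sirna(lib[[pr[1]]], lib[[pr[2]]]),
                        by = "exemplar_id")
      }
    }
    mutate(fc, accession_a = pr[1], accession_b = pr[2], .before = 1)
  })
  fc_summaries <- purrr::map_dfr(pair_names, function(pr) {
    fc_pair <- filter(fold_changes, .data$accession_a == pr[1],
                      .data$accession_b == pr[2])
    purrr::map_dfr(intersect(c("fc_te", "fc_22", "fc_24"), names(fc_pair)),
                   function(col) {
      s <- group_fc_summary(select(fc_pair, "exemplar_id",
                                   dplyr::all_of(col)),
                            groups, fc_col = col,
                            compare_on = if (col == "fc_te") "abs" else "signed")
      mutate(s$summary, accession_a = pr[1], accession_b = pr[2],
             variable = col, .before = 1)
    })
  })

  # --- per-group traits on the reference accession ---
  ref_tbl <- abundance[[reference_accession]] %>%
    as_tibble() %>%
    left_join(select(as_tibble(groups), "exemplar_id", "group"),
              by = "exemplar_id") %>%
    filter(.data$group %in% c("D", "R1", "R2"))
  trait_cols <- c("length_kb", "rpkm_te")
  if (!is.null(sirna22) && !is.null(sirna24)) {
    ref_tbl <- ref_tbl %>%
      left_join(ratio_24_22(sirna24[[reference_accession]],
                            sirna22[[reference_accession]], db),
                by = "exemplar_id") %>%
      left_join(select(sirna_per_copy(sirna24[[reference_accession]],
                                      abundance[[reference_accession]], db),
                       "exemplar_id", "sirna_per_copy"),
                by = "exemplar_id")
    trait_cols <- c(trait_cols, "ratio_24_22", "sirna_per_copy")
  }
  group_comparisons <- purrr::map(
    setNames(trait_cols, trait_cols),
    function(v) group_compare(ref_tbl, v, "group", alpha = alpha)
  )

  # --- correlations ---
  correlations <- purrr::map_dfr(pair_names, function(pr) {
    j <- full_join(rename(genomic[[pr[1]]]$counts, a = "hits"),
                   rename(genomic[[pr[2]]]$counts, b = "hits"),
                   by = "exemplar_id")
    correlation_log(j$a, j$b) %>%
      mutate(accession_a = pr[1], accession_b = pr[2], .before = 1)
  })

  # --- external expression fold changes ---
  expression <- if (!is.null(expr_fc)) {
    ratio <- if (!is.null(sirna22) && !is.null(sirna24)) {
      ratio_24_22(sirna24[[reference_accession]],
                  sirna22[[reference_accession]], db)
    } else NULL
    join_expression_fc(expr_fc, groups, ratio = ratio)
  }

  manifest <- bind_rows(
    tibble(key = "package_version",
           value = as.character(utils::packageVersion("tedyn"))),
    tibble(key = "reference_accession", value = reference_accession),
    tibble(key = "accessions", value = paste(accs, collapse = ",")),
    tibble(key = "low_copy_rpkm", value = format(low_copy_rpkm)),
    tibble(key = "fdr_q", value = format(fdr_q)),
    tibble(key = "alpha", value = format(alpha)),
    tibble(key = "prop_variant", value = prop_variant),
    tibble(key = "n_exemplars", value = as.character(nrow(db))),
    purrr::map_dfr(accs, function(a) tibble(
      key = paste0("n_low_copy_filtered_", a),
      value = as.character(sum(!abundance[[a]]$passes_filter))
    )),
    tibble(key = "split_threshold_rpkm",
           value = format(split_ref$split_threshold, digits = 10))
  )

  out <- structure(
    list(abundance = abundance, groups = groups, split = split_ref,
         agreement = agreement, tests = tests,
         proportionality = proportionality, fold_changes = fold_changes,
         fc_summaries = fc_summaries, group_comparisons = group_comparisons,
         correlations = correlations, expression = expression,
         manifest = manifest),
    class = "te_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_reports(out, out_dir)
  out
}

write_pipeline_reports <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tbl, name) {
    readr::write_tsv(tbl, file.path(out_dir, paste0(name, ".tsv")))
  }
  purrr::iwalk(x$abundance, function(tab, acc) {
    w(as_tibble(tab), paste0("abundance_", acc))
  })
  w(as_tibble(x$groups), "group_assignment")
  w(x$agreement$pairwise, "agreement_pairwise")
  w(x$tests, "tests_abundance")
  if (!is.null(x$proportionality)) w(x$proportionality, "tests_proportionality")
  w(x$fold_changes, "fold_changes")
  w(x$fc_summaries, "fc_group_summaries")
  w(purrr::imap_dfr(x$group_comparisons,
                    ~ mutate(tidy(.x), variable = .y, .before = 1)),
    "group_comparisons")
  w(x$correlations, "correlations")
  if (!is.null(x$expression)) w(x$expression$summary, "expression_fc_summary")
  w(x$manifest, "manifest")
  invisible(x)
}

#' @export
print.te_pipeline <- function(x, ...) {
  cat("<te_pipeline>\n")
  cat(sprintf("  accessions: %s\n",
              paste(names(x$abundance), collapse = ", ")))
  cat(sprintf("  R1/R2 split threshold: %.4g RPKM\n", x$split$split_threshold))
  cat(sprintf("  overall R1/R2 agreement: %.1f%% (n=%d)\n",
              100 * x$agreement$overall, x$agreement$n_shared))
  cat(sprintf("  abundance tests: %d rows; significant at q: %d\n",
              nrow(x$tests), sum(x$tests$significant, na.rm = TRUE)))
  invisible(x)
}

#' Convenience: simulate a full synthetic study
#'
#' Generates the exemplar database plus genomic and siRNA libraries for a
#' set of accessions from one [sim_params()] world — the quickest way to a
#' complete, analysable dataset.
#'
#' @param params A [sim_params()] object.
#' @param accessions Character vector of accession names.
#' @param copy_multipliers Optional named list: per-accession multiplicative
#'   perturbations of the true copy numbers (scalar or per-exemplar
#'   vector), to plant real abundance differences.
#' @return List: `db`, `truth`, `genomic`, `sirna22`, `sirna24`,
#'   `expr_fc` — ready for [run_te_pipeline()].
#' @export
simulate_study <- function(params, accessions = c("simA", "simB"),
                           copy_multipliers = NULL) {
  world <- simulate_exemplar_db(params)
  libs <- purrr::map(setNames(accessions, accessions), function(acc) {
    truth <- world$truth
    m <- copy_multipliers[[acc]]
    if (!is.null(m)) truth$true_copy_number <- truth$true_copy_number * m
    list(
      genomic = simulate_genomic_hits(world$db, truth, params, acc),
      s22 = simulate_sirna_hits(world$db, truth, params, acc, 22),
      s24 = simulate_sirna_hits(world$db, truth, params, acc, 24)
    )
  })
  list(
    db = world$db, truth = world$truth,
    genomic = purrr::map(libs, "genomic"),
    sirna22 = purrr::map(libs, "s22"),
    sirna24 = purrr::map(libs, "s24"),
    expr_fc = simulate_expression_fc(world$db, world$truth, params)
  )
}
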