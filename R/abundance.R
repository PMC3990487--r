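#' Per-exemplar TE abundance: RPKM and approximate copy number
#'
#' `te_rpkm()` computes, for every exemplar in the database,
#' RPKM_i = N_i / (L_i\[kb\] * R / 1e6), where N_i is the exemplar's hit
#' count and R the total reads mapped to the exemplar set — the study's
#' proxy for subfamily copy number. Exemplars absent from the counts get 0.
#' `te_copy_number()` adds an absolute copy-number estimate
#' C_i = N_i * l / (L_i\[bp\] * depth), where l is the mean read length and
#' depth the per-base genomic depth estimated from the gene set
#' (`depth = fgs_hits * l / fgs_length_bp`). `filter_low_copy()` marks
#' exemplars whose RPKM falls below the low-copy cutoff (default 1.2,
#' approximately two copies in a maize-scale library); the boundary value is
#' retained. `te_abundance()` runs all three.
#'
#' @param counts A [te_counts()] object.
#' @param db Exemplar tibble (see [read_exemplar_db()]).
#' @param low_copy_rpkm RPKM cutoff below which an exemplar is flagged as
#'   too low-copy for classification.
#' @param fgs_length_bp Total gene-set length in bp; defaults to the value
#'   recorded on `counts`. `NA` leaves `copy_number` as `NA`.
#' @return A tibble (class `te_abundance`) with one row per exemplar:
#'   `exemplar_id`, `te_class`, `family_code`, `length_kb`, `hits`,
#'   `rpkm_te`, `copy_number`, `passes_filter`.
#' @export
te_abundance <- function(counts, db, low_copy_rpkm = 1.2,
                         fgs_length_bp = NULL) {
  tab <- te_rpkm(counts, db)
  tab <- te_copy_number_impl(tab, counts, fgs_length_bp)
  filter_low_copy(tab, low_copy_rpkm)
}

#' @rdname te_abundance
#' @export
te_rpkm <- function(counts, db) {
  stopifnot(inherits(counts, "te_counts"))
  assert_db(db)
  r_total <- total_ute_hits(counts)
  if (r_total <= 0) abort("degenerate library: no reads mapped to the exemplar set")
  unknown <- setdiff(counts$counts$exemplar_id, db$exemplar_id)
  if (length(unknown)) {
    abort(paste0("counts reference exemplars absent from db: ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  tab <- db %>%
    left_join(counts$counts, by = "exemplar_id") %>%
    mutate(
      hits = dplyr::coalesce(.data$hits, 0),
      length_kb = .data$length_bp / 1000,
      rpkm_te = .data$hits / (.data$length_kb * r_total / 1e6)
    ) %>%
    select("exemplar_id", "te_class", "family_code", "length_kb", "hits",
           "rpkm_te")
  attr(tab, "accession_id") <- counts$accession_id
  attr(tab, "total_ute_hits") <- r_total
  class(tab) <- c("te_abundance", class(tab))
  tab
}

#' @rdname te_abundance
#' @export
te_copy_number <- function(counts, db, fgs_length_bp = NULL) {
  te_copy_number_impl(te_rpkm(counts, db), counts, fgs_length_bp)
}

te_copy_number_impl <- function(tab, counts, fgs_length_bp = NULL) {
  lambda <- fgs_length_bp %||% counts$fgs_length_bp
  if (is.null(lambda) || is.na(lambda)) {
    tab$copy_number <- NA_real_
    return(tab)
  }
  assert_positive_scalar(lambda, "fgs_length_bp")
  if (counts$fgs_hits <= 0) {
    abort("cannot estimate depth: no hits to the gene set")
  }
  depth <- counts$fgs_hits * counts$mean_read_length / lambda
  if (depth <= 0) abort("zero estimated genomic depth")
  tab$copy_number <-
    tab$hits * counts$mean_read_length / (tab$length_kb * 1000 * depth)
  tab
}

#' @rdname te_abundance
#' @param abundance A `te_abundance` tibble (output of `te_rpkm()` or
#'   `te_abundance()`).
#' @export
filter_low_copy <- function(abundance, low_copy_rpkm = 1.2) {
  assert_positive_scalar(low_copy_rpkm, "low_copy_rpkm")
  if (!"rpkm_te" %in% names(abundance)) abort("rpkm_te not computed")
  abundance$passes_filter <- abundance$rpkm_te >= low_copy_rpkm
  attr(abundance, "low_copy_rpkm") <- low_copy_rpkm
  abundance
}

# RPKM over an siRNA library, same formula with the library's own totals.
sirna_rpkm_tbl <- function(sirna, db) {
  stopifnot(inherits(sirna, "sirna_counts"))
  assert_db(db)
  if (sirna$total_hits <= 0) abort("degenerate siRNA library: zero total hits")
  db %>%
    left_join(sirna$counts, by = "exemplar_id") %>%
    mutate(
      hits = dplyr::coalesce(.data$hits, 0),
      sirna_rpkm = .data$hits /
        ((.data$length_bp / 1000) * sirna$total_hits / 1e6)
    ) %>%
    select("exemplar_id", sirna_hits = "hits", "sirna_rpkm")
}

#' siRNA targeting per TE copy
#'
#' The per-copy targeting proxy of a subfamily: siRNA RPKM divided by
#' genomic RPKM (both RPKM computed over their own library totals, so the
#' ratio is free of library size). Undefined (NA) where the genomic RPKM
#' is zero.
#'
#' @param sirna A [sirna_counts()] object.
#' @param abundance A `te_abundance` tibble for the same accession.
#' @param db Exemplar tibble.
#' @return Tibble: `exemplar_id`, `sirna_rpkm`, `rpkm_te`, `sirna_per_copy`.
#' @export
sirna_per_copy <- function(sirna, abundance, db) {
  srp <- sirna_rpkm_tbl(sirna, db)
  abundance %>%
    as_tibble() %>%
    select("exemplar_id", "rpkm_te") %>%
    inner_join(srp, by = "exemplar_id") %>%
    mutate(sirna_per_copy = if_else(.data$rpkm_te > 0,
                                    .data$sirna_rpkm / .data$rpkm_te,
                                    NA_real_)) %>%
    select("exemplar_id", "sirna_rpkm", "rpkm_te", "sirna_per_copy")
}

#' Expression per TE copy
#'
#' Same contract as [sirna_per_copy()] with an expression RPKM table in the
#' numerator: expression per copy = RPKM_RNAseq / RPKM_TE, NA where the
#' genomic RPKM is zero.
#'
#' @param expr_rpkm Tibble with columns `exemplar_id`, `expr_rpkm`.
#' @param abundance A `te_abundance` tibble.
#' @return Tibble: `exemplar_id`, `expr_rpkm`, `rpkm_te`, `expr_per_copy`.
#' @export
expression_per_copy <- function(expr_rpkm, abundance) {
  if (!all(c("exemplar_id", "expr_rpkm") %in% names(expr_rpkm))) {
    abort("`expr_rpkm` needs columns exemplar_id and expr_rpkm")
  }
  abundance %>%
    as_tibble() %>%
    select("exemplar_id", "rpkm_te") %>%
    inner_join(as_tibble(expr_rpkm), by = "exemplar_id") %>%
    mutate(expr_per_copy = if_else(.data$rpkm_te > 0,
                                   .data$expr_rpkm / .data$rpkm_te,
                                   NA_real_)) %>%
    select("exemplar_id", "expr_rpkm", "rpkm_te", "expr_per_copy")
}

#' 24:22 nt siRNA targeting ratio
#'
#' Per-exemplar ratio of 24 nt to 22 nt siRNA abundance (RPKM scale). To
#' handle zero counts, the 22 nt counts are first rescaled to the 24 nt
#' library total (putting both libraries on one count scale; exemplar
#' length cancels in the ratio) and the pseudocount is then added to both.
#' As the pseudocount tends to 0 the ratio equals RPKM24/RPKM22 exactly,
#' and an exemplar with zero counts in both classes gets exactly 1.
#'
#' @param sirna24,sirna22 [sirna_counts()] objects for the two size classes.
#' @param db Exemplar tibble.
#' @param pseudocount Count-scale pseudocount added to both size classes
#'   (default 0.5).
#' @return Tibble: `exemplar_id`, `rpkm_24`, `rpkm_22`, `ratio_24_22`.
#' @export
ratio_24_22 <- function(sirna24, sirna22, db, pseudocount = 0.5) {
  stopifnot(inherits(sirna24, "sirna_counts"), inherits(sirna22, "sirna_counts"))
  if (sirna24$size_class != 24L || sirna22$size_class != 22L) {
    abort("pass the 24 nt library first, the 22 nt library second")
  }
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  assert_db(db)
  tot24 <- max(sirna24$total_hits, 1)
  tot22 <- max(sirna22$total_hits, 1)
  base <- db %>%
    left_join(rename(sirna24$counts, hits24 = "hits"), by = "exemplar_id") %>%
    left_join(rename(sirna22$counts, hits22 = "hits"), by = "exemplar_id") %>%
    mutate(
      hits24 = dplyr::coalesce(.data$hits24, 0),
      hits22 = dplyr::coalesce(.data$hits22, 0),
      rpkm_24 = .data$hits24 / ((.data$length_bp / 1000) * tot24 / 1e6),
      rpkm_22 = .data$hits22 / ((.data$length_bp / 1000) * tot22 / 1e6),
      ratio_24_22 = (.data$hits24 + pseudocount) /
        (.data$hits22 * tot24 / tot22 + pseudocount)
    )
  select(base, "exemplar_id", "rpkm_24", "rpkm_22", "ratio_24_22")
}
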