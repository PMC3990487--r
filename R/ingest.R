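# Turning alignment records into validated count structures under the
# study's counting rules: >30 bp alignments only, best-hit with ties across
# exemplars discarded, database priority KnobC > UTE > FGS, identity filters
# 0.80 (UTE/KnobC) and 0.90 (FGS), and fractional multi-target counting for
# small RNAs.

#' Count genomic hits from alignment records
#'
#' Applies the genomic counting rules to a table of alignment records and
#' returns per-exemplar hit counts plus the FGS/Knob totals. Per read:
#' alignments of 30 bp or shorter are dropped (strictly greater than 30
#' required); identity filters are applied where an `identity` column is
#' present (>= 0.80 against the TE and knob sets, >= 0.90 against the gene
#' set); a read with any surviving knob alignment counts to the knob total
#' (KnobC has priority over the TE set, which has priority over the gene
#' set); a read whose best TE score is tied across two or more distinct
#' exemplars is discarded entirely; multiple best alignments within one
#' exemplar collapse to a single hit. Classification is invariant to record
#' order.
#'
#' @param alignments Tibble of alignment records with columns `read_id`,
#'   `target_set` (`"UTE"`, `"FGS"` or `"KnobC"`), `target_id`,
#'   `alignment_length` (bp on the read), `score`; optional `identity`
#'   (fraction) and `read_length`.
#' @param db Exemplar tibble; UTE targets must appear in it.
#' @param accession_id Label for the resulting library.
#' @return A [te_counts()] object (zero rows for unhit exemplars included).
#'   Filter bookkeeping (records dropped by the length, identity and tie
#'   rules) is attached as attribute `filter_log`.
#' @export
count_genomic_hits <- function(alignments, db, accession_id = "library") {
  assert_db(db)
  aln <- as_tibble(alignments)
  req <- c("read_id", "target_set", "target_id", "alignment_length", "score")
  missing <- setdiff(req, names(aln))
  if (length(missing)) {
    abort(paste0("alignments missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(aln$alignment_length < 0)) abort("negative alignment lengths")
  if (!all(aln$target_set %in% c("UTE", "FGS", "KnobC"))) {
    abort("target_set must be UTE, FGS or KnobC")
  }
  unknown <- setdiff(aln$target_id[aln$target_set == "UTE"], db$exemplar_id)
  if (length(unknown)) {
    abort(paste0("alignments reference unknown exemplar(s): ",
                 paste(head(unknown, 3), collapse = ", ")))
  }

  n0 <- nrow(aln)
  aln <- filter(aln, .data$alignment_length > 30)
  n_short <- n0 - nrow(aln)
  n_identity <- 0L
  if ("identity" %in% names(aln)) {
    if (any(!is.na(aln$identity) & (aln$identity < 0 | aln$identity > 1))) {
      abort("identity must lie in [0, 1]")
    }
    thr <- if_else(aln$target_set == "FGS", 0.90, 0.80)
    keep <- is.na(aln$identity) | aln$identity >= thr
    n_identity <- sum(!keep)
    aln <- aln[keep, ]
  }

  # Per read: resolve the database priority, then best-score tie handling
  # within the TE set.
  per_read <- if (nrow(aln) == 0) {
    tibble(read_id = character(), set = character(), target = character())
  } else {
    aln %>%
      group_by(.data$read_id) %>%
      summarise(assignment = list(resolve_read(.data$target_set,
                                               .data$target_id, .data$score)),
                .groups = "drop") %>%
      tidyr::unnest_wider("assignment")
  }

  n_ties <- sum(per_read$set == "tie")
  hits <- per_read %>%
    filter(.data$set == "UTE") %>%
    dplyr::count(.data$target, name = "hits") %>%
    rename(exemplar_id = "target")
  hits <- db %>%
    select("exemplar_id") %>%
    left_join(hits, by = "exemplar_id") %>%
    mutate(hits = dplyr::coalesce(.data$hits, 0L))

  mean_rl <- if ("read_length" %in% names(alignments)) {
    mean(distinct(as_tibble(alignments), .data$read_id,
                  .data$read_length)$read_length)
  } else NA_real_

  out <- te_counts(
    hits, accession_id = accession_id,
    fgs_hits = sum(per_read$set == "FGS"),
    knob_hits = sum(per_read$set == "KnobC"),
    mean_read_length = mean_rl,
    n_reads_total = dplyr::n_distinct(alignments$read_id)
  )
  attr(out, "filter_log") <- tibble(
    rule = c("alignment_length_le_30", "identity_below_threshold",
             "best_score_tie_across_exemplars"),
    n_removed = c(n_short, n_identity, n_ties)
  )
  out
}

# Resolve one read's surviving alignments to a single assignment.
resolve_read <- function(target_set, target_id, score) {
  if (any(target_set == "KnobC")) return(list(set = "KnobC", target = NA_character_))
  ute <- target_set == "UTE"
  if (any(ute)) {
    sc <- score[ute]
    tg <- target_id[ute]
    best <- tg[sc == max(sc)]
    if (length(unique(best)) > 1L) {
      return(list(set = "tie", target = NA_character_))
    }
    return(list(set = "UTE", target = best[1]))
  }
  if (any(target_set == "FGS")) return(list(set = "FGS", target = NA_character_))
  list(set = "none", target = NA_character_)
}

#' Count siRNA hits with fractional multi-target assignment
#'
#' Retains only zero-mismatch alignments of reads of the requested size
#' class; a read matching k distinct exemplars contributes 1/k to each, so
#' the per-exemplar totals sum to the number of retained reads.
#'
#' @param alignments Tibble with columns `read_id`, `target_id`,
#'   `mismatches`; optional `read_length` (filtered to `size_class` when
#'   present).
#' @param db Exemplar tibble.
#' @param size_class 22 or 24.
#' @param accession_id Label for the resulting library.
#' @return A [sirna_counts()] object.
#' @export
count_sirna_hits <- function(alignments, db, size_class,
                             accession_id = "library") {
  assert_db(db)
  size_class <- as.integer(size_class)
  if (!size_class %in% c(22L, 24L)) abort("size_class must be 22 or 24")
  aln <- as_tibble(alignments)
  req <- c("read_id", "target_id", "mismatches")
  missing <- setdiff(req, names(aln))
  if (length(missing)) {
    abort(paste0("alignments missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if ("read_length" %in% names(aln)) {
    aln <- filter(aln, .data$read_length == size_class)
  }
  aln <- filter(aln, .data$mismatches == 0)
  unknown <- setdiff(aln$target_id, db$exemplar_id)
  if (length(unknown)) {
    abort(paste0("alignments reference unknown exemplar(s): ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  frac <- aln %>%
    distinct(.data$read_id, .data$target_id) %>%
    group_by(.data$read_id) %>%
    mutate(weight = 1 / n()) %>%
    ungroup() %>%
    group_by(exemplar_id = .data$target_id) %>%
    summarise(hits = sum(.data$weight), .groups = "drop")
  counts <- db %>%
    select("exemplar_id") %>%
    left_join(frac, by = "exemplar_id") %>%
    mutate(hits = dplyr::coalesce(.data$hits, 0))
  sirna_counts(counts, accession_id = accession_id, size_class = size_class)
}

#' Genomic context of exemplars from read pairs
#'
#' For read pairs with exactly one mate assigned to a TE exemplar, the
#' other mate's assignment classifies the exemplar's neighbourhood:
#' another exemplar (`te_other`), the gene set (`fgs`), the knob set
#' (`knob`), or nothing (`unassigned`). Pairs with both mates in the same
#' exemplar are excluded entirely; pairs with mates in two different
#' exemplars anchor both. Fractions sum to 1 wherever the denominator is
#' positive; exemplars with no anchoring pairs get `NA` fractions.
#'
#' @param pairs Tibble with one row per read pair: `mate1_set`, `mate1_id`,
#'   `mate2_set`, `mate2_id` (sets as in [count_genomic_hits()], `"none"`
#'   or `NA` for unassigned mates; ids only meaningful for UTE).
#' @param db Exemplar tibble.
#' @return Tibble per exemplar: `n_pairs`, `fraction_te_other`,
#'   `fraction_fgs`, `fraction_knob`, `fraction_unassigned`.
#' @export
paired_context <- function(pairs, db) {
  assert_db(db)
  pairs <- as_tibble(pairs)
  req <- c("mate1_set", "mate1_id", "mate2_set", "mate2_id")
  missing <- setdiff(req, names(pairs))
  if (length(missing)) {
    abort(paste0("pairs missing column(s): ", paste(missing, collapse = ", ")))
  }
  classify_other <- function(anchor_id, other_set, other_id) {
    dplyr::case_when(
      !is.na(other_set) & other_set == "UTE" & other_id == anchor_id ~ "same",
      !is.na(other_set) & other_set == "UTE" ~ "te_other",
      !is.na(other_set) & other_set == "FGS" ~ "fgs",
      !is.na(other_set) & other_set == "KnobC" ~ "knob",
      TRUE ~ "unassigned"
    )
  }
  anchored <- bind_rows(
    pairs %>%
      filter(!is.na(.data$mate1_set), .data$mate1_set == "UTE") %>%
      mutate(exemplar_id = .data$mate1_id,
             context = classify_other(.data$mate1_id, .data$mate2_set,
                                      .data$mate2_id)),
    pairs %>%
      filter(!is.na(.data$mate2_set), .data$mate2_set == "UTE") %>%
      mutate(exemplar_id = .data$mate2_id,
             context = classify_other(.data$mate2_id, .data$mate1_set,
                                      .data$mate1_id))
  ) %>%
    filter(.data$context != "same")

  tallies <- anchored %>%
    dplyr::count(.data$exemplar_id, .data$context) %>%
    tidyr::pivot_wider(names_from = "context", values_from = "n",
                       values_fill = 0)
  for (col in c("te_other", "fgs", "knob", "unassigned")) {
    if (!col %in% names(tallies)) tallies[[col]] <- 0
  }
  db %>%
    select("exemplar_id") %>%
    left_join(tallies, by = "exemplar_id") %>%
    mutate(across(c("te_other", "fgs", "knob", "unassigned"),
                  ~ dplyr::coalesce(.x, 0))) %>%
    mutate(
      n_pairs = .data$te_other + .data$fgs + .data$knob + .data$unassigned,
      fraction_te_other = if_else(.data$n_pairs > 0,
                                  .data$te_other / .data$n_pairs, NA_real_),
      fraction_fgs = if_else(.data$n_pairs > 0,
                             .data$fgs / .data$n_pairs, NA_real_),
      fraction_knob = if_else(.data$n_pairs > 0,
                              .data$knob / .data$n_pairs, NA_real_),
      fraction_unassigned = if_else(.data$n_pairs > 0,
                                    .data$unassigned / .data$n_pairs,
                                    NA_real_)
    ) %>%
    select("exemplar_id", "n_pairs", dplyr::starts_with("fraction_"))
}

#' Read alignment records from a SAM file
#'
#' Converts a SAM file into the alignment-record tibble the counting
#' functions consume. Alignment length is the read-space width of the CIGAR
#' (M/I/=/X operations), mismatches come from the `NM` tag, the score from
#' the `AS` tag (falling back to minus the edit distance when absent), and
#' identity is `(alignment_length - NM) / alignment_length`.
#'
#' @param path SAM file path.
#' @param target_set Which reference set the file was aligned against
#'   (`"UTE"`, `"FGS"` or `"KnobC"`).
#' @return Tibble with the columns of [count_genomic_hits()]'s input.
#' @export
read_sam_alignments <- function(path, target_set = "UTE") {
  if (!target_set %in% c("UTE", "FGS", "KnobC")) {
    abort("target_set must be UTE, FGS or KnobC")
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "cigar", "seq"),
    tag = c("NM", "AS")
  )
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !is.na(b$rname)
  cig <- b$cigar[mapped]
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  aln_len <- vapply(seq_along(ops), function(i) {
    sum(lens[[i]][ops[[i]] %in% c("M", "I", "=", "X")])
  }, numeric(1))
  nm <- b$tag$NM[mapped]
  as_score <- b$tag$AS
  score <- if (is.null(as_score)) -as.numeric(nm) else as.numeric(as_score[mapped])
  score[is.na(score)] <- -as.numeric(nm)[is.na(score)]
  tibble(
    read_id = b$qname[mapped],
    target_set = target_set,
    target_id = as.character(b$rname[mapped]),
    alignment_length = aln_len,
    score = score,
    mismatches = as.numeric(nm),
    identity = if_else(aln_len > 0, (aln_len - as.numeric(nm)) / aln_len,
                       NA_real_),
    read_length = Biostrings::width(b$seq)[mapped]
  )
}
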