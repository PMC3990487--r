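#' Parameters for the synthetic TE world
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe a
#' maize-like stated world: 841 DNA-transposon subfamilies, 365 low-copy and
#' 198 high-copy retroelement subfamilies; exemplar lengths log-normal with
#' high-copy retroelements the longest; copy numbers log-normal for the DNA
#' class and a two-mode mixture for the RNA class (the R1/R2 bimodality);
#' 15% of genomic reads falling in genes and 6.1% in knob/centromere repeats;
#' 100 bp reads. Library sizes default to one million reads per library — a
#' desk-scale stand-in for lane-scale sequencing (tens of millions of reads);
#' pass larger values to emulate full libraries.
#'
#' @param seed Master seed; every generator stream is derived from it.
#' @param n_dna,n_r1,n_r2 Number of exemplars per true group.
#' @param length_meanlog,length_sdlog Per-group log-normal parameters for
#'   exemplar length (bp), named `dna`, `r1`, `r2`.
#' @param copy_meanlog,copy_sdlog Per-group log-normal parameters for true
#'   copy number.
#' @param library_size Genomic reads per accession.
#' @param fgs_fraction,knob_fraction Probability a genomic read falls in the
#'   gene / knob compartments (per accession defaults; must sum to < 1).
#' @param read_length Read length in bp.
#' @param sirna_rate_22,sirna_rate_24 Per-group expected siRNA hits per TE
#'   copy (relative rates) for the 22 nt and 24 nt classes.
#' @param sirna_library_size Total siRNA reads per size class.
#' @param fc_mop_fold Per-group expression fold change between wild type and
#'   a 24 nt siRNA-deficient mutant, on the linear fold scale: a positive
#'   value f means a log2(f) mean shift, a negative value -f means a
#'   decrease, log2(1/f). Defaults: DNA +1.2-fold, R1 -1.6-fold, R2 1.03.
#' @param fc_mop_sd_log2 Per-group sd of the log2 fold change.
#' @param overdispersion Optional non-negative gamma overdispersion of the
#'   multinomial siRNA allocation weights (0 = pure multinomial).
#'
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_dna = 841L, n_r1 = 365L, n_r2 = 198L,
                       length_meanlog = c(dna = log(1500), r1 = log(4000),
                                          r2 = log(8000)),
                       length_sdlog = c(dna = 0.6, r1 = 0.5, r2 = 0.4),
                       copy_meanlog = c(dna = log(30), r1 = log(15),
                                        r2 = log(2000)),
                       copy_sdlog = c(dna = 1.0, r1 = 0.8, r2 = 0.8),
                       library_size = 1e6,
                       fgs_fraction = 0.15,
                       knob_fraction = 0.061,
                       read_length = 100,
                       sirna_rate_22 = c(dna = 1.0, r1 = 1.2, r2 = 0.15),
                       sirna_rate_24 = c(dna = 3.0, r1 = 4.0, r2 = 0.3),
                       sirna_library_size = 1e6,
                       fc_mop_fold = c(dna = 1.2, r1 = -1.6, r2 = 1.03),
                       fc_mop_sd_log2 = c(dna = 1, r1 = 1, r2 = 1),
                       overdispersion = 0) {
  p <- list(
    seed = seed, n_dna = n_dna, n_r1 = n_r1, n_r2 = n_r2,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    copy_meanlog = copy_meanlog, copy_sdlog = copy_sdlog,
    library_size = library_size, fgs_fraction = fgs_fraction,
    knob_fraction = knob_fraction, read_length = read_length,
    sirna_rate_22 = sirna_rate_22, sirna_rate_24 = sirna_rate_24,
    sirna_library_size = sirna_library_size,
    fc_mop_fold = fc_mop_fold, fc_mop_sd_log2 = fc_mop_sd_log2,
    overdispersion = overdispersion
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  for (nm in c("n_dna", "n_r1", "n_r2", "library_size",
               "sirna_library_size")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0) {
      abort(sprintf("invalid parameter `%s`: must be a non-negative count",
                    nm))
    }
  }
  for (nm in c("fgs_fraction", "knob_fraction")) {
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1) {
      abort(sprintf("invalid parameter `%s`: must be in [0, 1]", nm))
    }
  }
  if (p$fgs_fraction + p$knob_fraction >= 1) {
    abort("invalid parameters `fgs_fraction` + `knob_fraction`: must sum to < 1")
  }
  grp <- c("dna", "r1", "r2")
  for (nm in c("length_meanlog", "length_sdlog", "copy_meanlog", "copy_sdlog",
               "sirna_rate_22", "sirna_rate_24", "fc_mop_fold",
               "fc_mop_sd_log2")) {
    v <- p[[nm]]
    if (length(v) != 3L || !all(grp %in% names(v))) {
      abort(sprintf(
        "invalid parameter `%s`: needs one named entry per group (dna, r1, r2)",
        nm))
    }
  }
  if (any(p$sirna_rate_22 < 0) || any(p$sirna_rate_24 < 0)) {
    abort("invalid parameter `sirna_rate_*`: rates must be >= 0")
  }
  assert_positive_scalar(p$read_length, "read_length")
  if (p$overdispersion < 0) {
    abort("invalid parameter `overdispersion`: must be >= 0")
  }
  invisible(p)
}

dna_family_codes <- c("DTA", "DTC", "DTH", "DTM", "DTT")
rna_family_codes <- c("RLC", "RLG", "RLX", "RIL", "RIT", "RST")

#' Generate a synthetic exemplar database with ground truth
#'
#' Draws one exemplar per simulated subfamily: DNA-class exemplars with
#' log-normal lengths and copy numbers, RNA-class exemplars from the two
#' configured modes (the low-copy R1 and high-copy R2 components of the
#' bimodal retroelement copy-number distribution).
#'
#' @param params A [sim_params()] object.
#' @return A list with `db` (tibble: `exemplar_id`, `te_class`,
#'   `family_code`, `length_bp`) and `truth` (tibble: `exemplar_id`,
#'   `true_group`, `true_copy_number`, `prop_deviation`). `prop_deviation`
#'   starts at 1 (exact copy-siRNA proportionality); modify it before
#'   calling [simulate_sirna_hits()] to plant deviations.
#' @export
simulate_exemplar_db <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- c(dna = params$n_dna, r1 = params$n_r1, r2 = params$n_r2)
  group_lab <- c(dna = "D", r1 = "R1", r2 = "R2")
  with_stream(params$seed, "exemplar_db", {
    pieces <- purrr::map(names(n), function(g) {
      ng <- n[[g]]
      if (ng == 0L) return(NULL)
      tibble(
        true_group = group_lab[[g]],
        te_class = if (g == "dna") "DNA" else "RNA",
        family_code = sample(
          if (g == "dna") dna_family_codes else rna_family_codes,
          ng, replace = TRUE),
        length_bp = pmax(100, round(rlnorm(ng, params$length_meanlog[[g]],
                                           params$length_sdlog[[g]]))),
        true_copy_number = rlnorm(ng, params$copy_meanlog[[g]],
                                  params$copy_sdlog[[g]])
      )
    })
    all <- bind_rows(pieces)
    if (nrow(all) == 0) abort("no exemplars requested")
    all$exemplar_id <- sprintf("TE%05d", seq_len(nrow(all)))
    list(
      db = all[c("exemplar_id", "te_class", "family_code", "length_bp")],
      truth = tibble(
        exemplar_id = all$exemplar_id,
        true_group = all$true_group,
        true_copy_number = all$true_copy_number,
        prop_deviation = 1
      )
    )
  })
}

#' Simulate a genomic sequencing library as multinomial hit counts
#'
#' Reads are allocated multinomially over three compartments: the gene set
#' (probability `fgs_fraction`), the knob/centromere set (`knob_fraction`)
#' and the TE exemplars, where exemplar i receives the remaining mass in
#' proportion to `true_copy_number * length_bp`. Totals therefore sum
#' exactly to `library_size`. The implied total gene-set length (the genome
#' consistent with those compartment fractions) is recorded on the result so
#' absolute copy numbers can be estimated from it.
#'
#' @param db,truth As returned by [simulate_exemplar_db()].
#' @param params A [sim_params()] object.
#' @param accession_id Label for the simulated accession; also selects the
#'   RNG stream, so different accessions get independent libraries.
#' @param library_size,fgs_fraction,knob_fraction Optional per-accession
#'   overrides of the corresponding `params` entries.
#' @return A [te_counts()] object.
#' @export
simulate_genomic_hits <- function(db, truth, params, accession_id,
                                  library_size = NULL, fgs_fraction = NULL,
                                  knob_fraction = NULL) {
  stopifnot(inherits(params, "sim_params"))
  assert_db(db)
  if (!all(db$exemplar_id %in% truth$exemplar_id)) {
    abort("truth must cover every exemplar in db")
  }
  truth <- truth[match(db$exemplar_id, truth$exemplar_id), ]
  size <- library_size %||% params$library_size
  f <- fgs_fraction %||% params$fgs_fraction
  k <- knob_fraction %||% params$knob_fraction
  if (f + k >= 1) abort("fgs_fraction + knob_fraction must be < 1")
  w <- truth$true_copy_number * db$length_bp
  W <- sum(w)
  if (W <= 0) abort("degenerate input: total copy-length weight is zero")
  prob <- c(f, k, (1 - f - k) * w / W)
  draws <- with_stream(params$seed, paste("genomic", accession_id),
                       rmultinom(1, size, prob)[, 1])
  te_counts(
    tibble(exemplar_id = db$exemplar_id, hits = draws[-(1:2)]),
    accession_id = accession_id,
    fgs_hits = draws[1], knob_hits = draws[2],
    mean_read_length = params$read_length,
    n_reads_total = size,
    # Gene-set length implied by the compartment fractions: the simulated
    # genome has (1-f-k) of its read mass on sum(c_i * L_i) bp of TE space.
    fgs_length_bp = f / (1 - f - k) * W
  )
}

#' Simulate an siRNA library for one size class
#'
#' Counts are multinomial with per-exemplar weight
#' `true_copy_number * rate(group) * prop_deviation`, so with
#' `prop_deviation == 1` throughout, siRNA targeting is exactly proportional
#' to copy number in expectation — the null of the proportionality test.
#' A positive `overdispersion` multiplies weights by gamma noise with that
#' squared coefficient of variation before the draw.
#'
#' @inheritParams simulate_genomic_hits
#' @param size_class 22 or 24 (nt).
#' @param sirna_library_size Optional override of the configured total.
#' @return A [sirna_counts()] object.
#' @export
simulate_sirna_hits <- function(db, truth, params, accession_id, size_class,
                                sirna_library_size = NULL) {
  stopifnot(inherits(params, "sim_params"))
  assert_db(db)
  size_class <- as.integer(size_class)
  if (!size_class %in% c(22L, 24L)) abort("unknown size_class; use 22 or 24")
  truth <- truth[match(db$exemplar_id, truth$exemplar_id), ]
  if (anyNA(truth$exemplar_id)) abort("truth must cover every exemplar in db")
  rates <- if (size_class == 22L) params$sirna_rate_22 else params$sirna_rate_24
  grp_key <- c(D = "dna", R1 = "r1", R2 = "r2")[truth$true_group]
  w <- truth$true_copy_number * unname(rates[grp_key]) * truth$prop_deviation
  size <- sirna_library_size %||% params$sirna_library_size
  if (sum(w) <= 0) abort("degenerate input: all siRNA weights are zero")
  counts <- with_stream(
    params$seed, paste("sirna", accession_id, size_class), {
      if (params$overdispersion > 0) {
        shape <- 1 / params$overdispersion
        w <- w * stats::rgamma(length(w), shape = shape, rate = shape)
      }
      rmultinom(1, size, w / sum(w))[, 1]
    })
  sirna_counts(tibble(exemplar_id = db$exemplar_id, hits = counts),
               accession_id = accession_id, size_class = size_class)
}

#' Simulate per-exemplar expression log2 fold changes
#'
#' Emulates a wild-type vs siRNA-pathway-mutant expression contrast: each
#' exemplar's log2 fold change is normal with a group-specific mean given on
#' the linear fold scale (see [sim_params()] for the sign convention).
#'
#' @inheritParams simulate_genomic_hits
#' @return Tibble with `exemplar_id`, `true_group`, `log2_fc`.
#' @export
simulate_expression_fc <- function(db, truth, params) {
  stopifnot(inherits(params, "sim_params"))
  truth <- truth[match(db$exemplar_id, truth$exemplar_id), ]
  grp_key <- c(D = "dna", R1 = "r1", R2 = "r2")[truth$true_group]
  mu <- fold_to_log2(params$fc_mop_fold)[grp_key]
  sdv <- params$fc_mop_sd_log2[grp_key]
  vals <- with_stream(params$seed, "expression_fc",
                      rnorm(nrow(truth), unname(mu), unname(sdv)))
  tibble(exemplar_id = truth$exemplar_id, true_group = truth$true_group,
         log2_fc = vals)
}

# Linear fold factor -> log2: +f => log2(f); -f (a decrease) => log2(1/f).
fold_to_log2 <- function(fold) {
  if (any(abs(fold) < 1)) {
    abort("fold factors must have magnitude >= 1 (sign encodes direction)")
  }
  sign(fold) * log2(abs(fold))
}
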