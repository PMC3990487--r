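#' Genomic hit counts for one accession
#'
#' A light container for per-exemplar genomic hit counts against the TE
#' exemplar database, together with the library-level totals the downstream
#' normalizations need: hits to the gene set (FGS, the coverage proxy), hits
#' to the knob/centromere set, the mean read length and the total read count.
#'
#' @param counts Tibble with columns `exemplar_id` and `hits` (non-negative).
#' @param accession_id Accession label (e.g. `"B73"`).
#' @param fgs_hits,knob_hits Reads assigned to the gene / knob reference sets.
#' @param mean_read_length Mean aligned-read length in bp.
#' @param n_reads_total Total reads in the library (counted or not).
#' @param fgs_length_bp Total length of the gene reference set in bp, when
#'   known; required only for absolute copy-number estimation.
#'
#' @return An object of class `te_counts`.
#' @export
te_counts <- function(counts, accession_id, fgs_hits, knob_hits,
                      mean_read_length, n_reads_total = NA_real_,
                      fgs_length_bp = NA_real_) {
  counts <- as_tibble(counts)
  if (!all(c("exemplar_id", "hits") %in% names(counts))) {
    abort("`counts` needs columns exemplar_id and hits")
  }
  if (anyDuplicated(counts$exemplar_id)) {
    dup <- counts$exemplar_id[duplicated(counts$exemplar_id)][1]
    abort(sprintf("duplicate exemplar row: %s", dup))
  }
  if (any(counts$hits < 0)) abort("negative hit counts")
  if (fgs_hits < 0 || knob_hits < 0) abort("negative set totals")
  structure(
    list(
      accession_id = as.character(accession_id),
      counts = counts[c("exemplar_id", "hits")],
      fgs_hits = as.numeric(fgs_hits),
      knob_hits = as.numeric(knob_hits),
      mean_read_length = as.numeric(mean_read_length),
      n_reads_total = as.numeric(n_reads_total),
      fgs_length_bp = as.numeric(fgs_length_bp)
    ),
    class = "te_counts"
  )
}

#' Total reads mapped to the TE exemplar set
#' @param x A `te_counts` object.
#' @return The scalar total (the `R` of the RPKM denominator).
#' @export
total_ute_hits <- function(x) {
  stopifnot(inherits(x, "te_counts"))
  sum(x$counts$hits)
}

#' @export
print.te_counts <- function(x, ...) {
  cat(sprintf(
    "<te_counts> accession %s: %d exemplars, %s UTE hits, %s FGS, %s Knob\n",
    x$accession_id, nrow(x$counts),
    format(total_ute_hits(x), big.mark = ","),
    format(x$fgs_hits, big.mark = ","), format(x$knob_hits, big.mark = ",")
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.te_counts <- function(x, ...) {
  mutate(x$counts, accession_id = x$accession_id, .before = 1)
}

#' @exportS3Method generics::glance
glance.te_counts <- function(x, ...) {
  tibble(
    accession_id = x$accession_id,
    n_exemplars = nrow(x$counts),
    total_ute_hits = total_ute_hits(x),
    fgs_hits = x$fgs_hits,
    knob_hits = x$knob_hits,
    mean_read_length = x$mean_read_length,
    n_reads_total = x$n_reads_total
  )
}

#' siRNA hit counts for one accession and size class
#'
#' Fractional counts are expected: a small-RNA read matching k exemplars
#' contributes 1/k to each, so per-exemplar counts need not be integers.
#'
#' @param counts Tibble with columns `exemplar_id` and `hits`.
#' @param accession_id Accession label.
#' @param size_class siRNA length class, 22 or 24 (nt).
#' @return An object of class `sirna_counts`.
#' @export
sirna_counts <- function(counts, accession_id, size_class) {
  size_class <- as.integer(size_class)
  if (!size_class %in% c(22L, 24L)) {
    abort("size_class must be 22 or 24")
  }
  counts <- as_tibble(counts)
  if (!all(c("exemplar_id", "hits") %in% names(counts))) {
    abort("`counts` needs columns exemplar_id and hits")
  }
  if (anyDuplicated(counts$exemplar_id)) {
    dup <- counts$exemplar_id[duplicated(counts$exemplar_id)][1]
    abort(sprintf("duplicate exemplar row: %s", dup))
  }
  if (any(counts$hits < 0)) abort("negative siRNA counts")
  structure(
    list(
      accession_id = as.character(accession_id),
      size_class = size_class,
      counts = counts[c("exemplar_id", "hits")],
      total_hits = sum(counts$hits)
    ),
    class = "sirna_counts"
  )
}

#' @export
print.sirna_counts <- function(x, ...) {
  cat(sprintf("<sirna_counts> accession %s, %d nt: %d exemplars, %.2f hits\n",
              x$accession_id, x$size_class, nrow(x$counts), x$total_hits))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sirna_counts <- function(x, ...) {
  mutate(x$counts, accession_id = x$accession_id,
         size_class = x$size_class, .before = 1)
}

# ---- TSV round-trip ---------------------------------------------------------

#' Write / read count tables as annotated TSV
#'
#' The file is a plain two-column TSV (`exemplar_id`, `hits`) preceded by
#' `#key\tvalue` header lines carrying the library metadata, so the round
#' trip is lossless (fractional counts kept to full double precision).
#'
#' @param x A `te_counts` or `sirna_counts` object.
#' @param path Output file path.
#' @return `write_counts_table()` returns `x` invisibly; `read_counts_table()`
#'   returns the reconstructed object.
#' @export
write_counts_table <- function(x, path) {
  if (inherits(x, "te_counts")) {
    hdr <- c(
      type = "te_counts", accession_id = x$accession_id,
      fgs_hits = format(x$fgs_hits, digits = 17),
      knob_hits = format(x$knob_hits, digits = 17),
      mean_read_length = format(x$mean_read_length, digits = 17),
      n_reads_total = format(x$n_reads_total, digits = 17),
      fgs_length_bp = format(x$fgs_length_bp, digits = 17)
    )
  } else if (inherits(x, "sirna_counts")) {
    hdr <- c(
      type = "sirna_counts", accession_id = x$accession_id,
      size_class = as.character(x$size_class)
    )
  } else {
    abort("x must be te_counts or sirna_counts")
  }
  lines <- c(
    paste0("#", names(hdr), "\t", unname(hdr)),
    "exemplar_id\thits",
    paste0(x$counts$exemplar_id, "\t",
           format(x$counts$hits, digits = 17, scientific = FALSE, trim = TRUE))
  )
  writeLines(lines, path)
  invisible(x)
}

#' @rdname write_counts_table
#' @export
read_counts_table <- function(path) {
  all_lines <- readLines(path)
  hdr_lines <- grep("^#", all_lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr_lines), "\t", fixed = TRUE)
  meta <- setNames(
    vapply(kv, function(p) if (length(p) > 1) p[2] else "", ""),
    vapply(kv, `[`, "", 1)
  )
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           exemplar_id = readr::col_character(),
                           hits = readr::col_double()
                         ))
  if (!all(c("exemplar_id", "hits") %in% names(tab))) {
    abort("counts table must have columns exemplar_id and hits")
  }
  get_meta <- function(key, default = NA_character_) {
    if (key %in% names(meta)) meta[[key]] else default
  }
  type <- get_meta("type", "te_counts")
  if (identical(type, "sirna_counts")) {
    sirna_counts(tab, accession_id = get_meta("accession_id"),
                 size_class = as.integer(get_meta("size_class")))
  } else {
    te_counts(tab,
              accession_id = get_meta("accession_id"),
              fgs_hits = as.numeric(get_meta("fgs_hits", "0")),
              knob_hits = as.numeric(get_meta("knob_hits", "0")),
              mean_read_length = as.numeric(get_meta("mean_read_length")),
              n_reads_total = as.numeric(get_meta("n_reads_total")),
              fgs_length_bp = as.numeric(get_meta("fgs_length_bp")))
  }
}
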