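#' Read and write a TE exemplar database as FASTA
#'
#' One record per TE subfamily exemplar. Class and family are encoded in the
#' description line as `id|class|family` (class is `DNA` or `RNA`; family is
#' a short code such as RLC/RLG/RLX for LTR retroelement superfamilies or a
#' DNA superfamily code). Sequences themselves are placeholders when the
#' database is synthetic: only the length enters the analysis.
#'
#' @param path FASTA file path.
#' @return `read_exemplar_db()`: a tibble with columns `exemplar_id`,
#'   `te_class`, `family_code`, `length_bp`.
#' @export
read_exemplar_db <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- stringr::str_split_fixed(names(seqs), stringr::fixed("|"), 3)
  if (any(parts[, 2] == "")) {
    abort("FASTA descriptions must be 'id|class|family'")
  }
  db <- tibble(
    exemplar_id = parts[, 1],
    te_class = parts[, 2],
    family_code = parts[, 3],
    length_bp = as.numeric(Biostrings::width(seqs))
  )
  assert_db(db)
  db
}

#' @rdname read_exemplar_db
#' @param db Exemplar tibble (`exemplar_id`, `te_class`, `family_code`,
#'   `length_bp`).
#' @export
write_exemplar_db <- function(db, path) {
  assert_db(db)
  # Placeholder sequence of the recorded length; composition is irrelevant.
  seqs <- Biostrings::DNAStringSet(vapply(
    db$length_bp,
    function(n) paste(rep("A", n), collapse = ""),
    character(1)
  ))
  names(seqs) <- paste(db$exemplar_id, db$te_class, db$family_code, sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(db)
}
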