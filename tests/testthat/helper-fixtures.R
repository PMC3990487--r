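# Shared fixtures, built in code at load time.

# A 6-exemplar database small enough to reason about by hand.
tiny_db <- function() {
  tibble::tibble(
    exemplar_id = paste0("TE", 1:6),
    te_class = c("DNA", "DNA", "RNA", "RNA", "RNA", "RNA"),
    family_code = c("DTA", "DTC", "RLC", "RLG", "RLX", "RIL"),
    length_bp = c(1000, 2000, 4000, 5000, 8000, 10000)
  )
}

# Build a te_counts object directly from a named hits vector.
make_counts <- function(hits, accession = "acc", fgs = 1000, knob = 100,
                        read_len = 100, fgs_length_bp = NA_real_) {
  te_counts(
    tibble::tibble(exemplar_id = names(hits), hits = unname(hits)),
    accession_id = accession, fgs_hits = fgs, knob_hits = knob,
    mean_read_length = read_len, n_reads_total = sum(hits) + fgs + knob,
    fgs_length_bp = fgs_length_bp
  )
}

make_sirna <- function(hits, accession = "acc", size_class = 24) {
  sirna_counts(
    tibble::tibble(exemplar_id = names(hits), hits = unname(hits)),
    accession_id = accession, size_class = size_class
  )
}

# A small but complete synthetic study reused by several test files.
small_params <- function(seed = 11) {
  sim_params(seed = seed, n_dna = 150, n_r1 = 100, n_r2 = 60,
             library_size = 4e5, sirna_library_size = 4e5)
}

shared_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(small_params(), c("A", "B"))
    cache
  }
})
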