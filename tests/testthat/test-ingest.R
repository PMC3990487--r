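aln_row <- function(read, set, target, len = 50, score = 100, identity = NA,
                    mismatches = 0) {
  tibble::tibble(read_id = read, target_set = set, target_id = target,
                 alignment_length = len, score = score, identity = identity,
                 mismatches = mismatches)
}

test_that("genomic counting applies the length, tie and priority rules", {
  db <- tiny_db()
  # 25 bp alignment is below the >30 bp cutoff
  short <- count_genomic_hits(aln_row("r1", "UTE", "TE1", len = 25), db)
  expect_equal(sum(short$counts$hits), 0)
  # exactly 31 bp passes (strictly greater than 30)
  edge <- count_genomic_hits(
    dplyr::bind_rows(aln_row("r1", "UTE", "TE1", len = 31),
                     aln_row("r2", "UTE", "TE1", len = 30)), db)
  expect_equal(edge$counts$hits[edge$counts$exemplar_id == "TE1"], 1)

  # equal-best across two exemplars -> discarded, absent from every total
  tie <- count_genomic_hits(
    dplyr::bind_rows(aln_row("r1", "UTE", "TE1", score = 90),
                     aln_row("r1", "UTE", "TE2", score = 90)), db)
  expect_equal(sum(tie$counts$hits), 0)
  expect_equal(tie$fgs_hits + tie$knob_hits, 0)
  expect_equal(attr(tie, "filter_log")$n_removed[3], 1)

  # strictly better score wins over the tie rule
  best <- count_genomic_hits(
    dplyr::bind_rows(aln_row("r1", "UTE", "TE1", score = 95),
                     aln_row("r1", "UTE", "TE2", score = 90)), db)
  expect_equal(best$counts$hits[best$counts$exemplar_id == "TE1"], 1)

  # KnobC beats UTE; UTE beats FGS
  knob <- count_genomic_hits(
    dplyr::bind_rows(aln_row("r1", "KnobC", "knob3"),
                     aln_row("r1", "UTE", "TE1")), db)
  expect_equal(knob$knob_hits, 1)
  expect_equal(sum(knob$counts$hits), 0)
  ute <- count_genomic_hits(
    dplyr::bind_rows(aln_row("r1", "FGS", "gene1"),
                     aln_row("r1", "UTE", "TE1")), db)
  expect_equal(ute$fgs_hits, 0)
  expect_equal(sum(ute$counts$hits), 1)

  # multiple best positions within one exemplar collapse to a single hit
  multi <- count_genomic_hits(
    dplyr::bind_rows(aln_row("r1", "UTE", "TE1", score = 90),
                     aln_row("r1", "UTE", "TE1", score = 90)), db)
  expect_equal(multi$counts$hits[multi$counts$exemplar_id == "TE1"], 1)

  # identity thresholds: 0.80 for UTE, 0.90 for FGS
  idf <- count_genomic_hits(
    dplyr::bind_rows(aln_row("r1", "UTE", "TE1", identity = 0.79),
                     aln_row("r2", "UTE", "TE1", identity = 0.80),
                     aln_row("r3", "FGS", "gene1", identity = 0.85)), db)
  expect_equal(sum(idf$counts$hits), 1)
  expect_equal(idf$fgs_hits, 0)

  expect_error(count_genomic_hits(aln_row("r1", "UTE", "NOPE"), db),
               "unknown exemplar")
  expect_error(count_genomic_hits(aln_row("r1", "UTE", "TE1", len = -1), db),
               "negative")
})

test_that("genomic counting is invariant to record order", {
  db <- tiny_db()
  set.seed(4)
  aln <- dplyr::bind_rows(purrr::map(1:200, function(i) {
    aln_row(paste0("r", i), sample(c("UTE", "FGS", "KnobC"), 1,
                                   prob = c(0.7, 0.2, 0.1)),
            sample(db$exemplar_id, 1), len = sample(25:100, 1),
            score = sample(80:100, 1))
  }))
  c1 <- count_genomic_hits(aln, db)
  c2 <- count_genomic_hits(aln[sample(nrow(aln)), ], db)
  expect_equal(c1$counts, c2$counts)
  expect_equal(c1$fgs_hits, c2$fgs_hits)
  expect_equal(c1$knob_hits, c2$knob_hits)
})

test_that("siRNA counting is fractional, mismatch-free and conservative", {
  db <- tiny_db()
  aln <- tibble::tibble(
    read_id = c("a", "a", "a", "a", "b", "c"),
    target_id = c("TE1", "TE2", "TE3", "TE4", "TE1", "TE2"),
    mismatches = c(0, 0, 0, 0, 1, 0)
  )
  s <- count_sirna_hits(aln, db, 24)
  h <- setNames(s$counts$hits, s$counts$exemplar_id)
  expect_equal(h[["TE1"]], 0.25)   # 4-target read: +0.25 each
  expect_equal(h[["TE2"]], 1.25)   # plus unique read c
  expect_equal(h[["TE3"]], 0.25)
  expect_equal(s$total_hits, 2)    # read b dropped by the mismatch rule

  # 10 unique reads to one exemplar
  uni <- count_sirna_hits(
    tibble::tibble(read_id = paste0("u", 1:10), target_id = "TE1",
                   mismatches = 0), db, 22)
  expect_equal(uni$counts$hits[uni$counts$exemplar_id == "TE1"], 10)
  expect_equal(uni$total_hits, 10)
  expect_error(count_sirna_hits(aln, db, 21), "size_class")
})

test_that("paired context classifies the non-anchor mate and sums to 1", {
  db <- tiny_db()
  pairs <- tibble::tibble(
    mate1_set = c("UTE", "UTE", "UTE", "UTE", "UTE"),
    mate1_id = c("TE1", "TE1", "TE1", "TE1", "TE2"),
    mate2_set = c("UTE", "FGS", "KnobC", NA, "UTE"),
    mate2_id = c("TE2", NA, NA, NA, "TE2")
  )
  ctx <- paired_context(pairs, db)
  te1 <- ctx[ctx$exemplar_id == "TE1", ]
  expect_equal(te1$n_pairs, 4)
  expect_equal(unlist(te1[c("fraction_te_other", "fraction_fgs",
                            "fraction_knob", "fraction_unassigned")]),
               c(fraction_te_other = 0.25, fraction_fgs = 0.25,
                 fraction_knob = 0.25, fraction_unassigned = 0.25))
  # both mates in TE2: excluded entirely; TE2 still anchors the first pair
  te2 <- ctx[ctx$exemplar_id == "TE2", ]
  expect_equal(te2$n_pairs, 1)
  expect_equal(te2$fraction_te_other, 1)
  # unanchored exemplar reports NA fractions, not zero
  te3 <- ctx[ctx$exemplar_id == "TE3", ]
  expect_true(is.na(te3$fraction_fgs))
  # fractions sum to 1 where defined
  sums <- rowSums(ctx[ctx$n_pairs > 0,
                      c("fraction_te_other", "fraction_fgs",
                        "fraction_knob", "fraction_unassigned")])
  expect_equal(unname(sums), rep(1, length(sums)))
})

test_that("count tables round-trip losslessly through TSV", {
  g <- make_counts(c(TE1 = 10, TE2 = 0, TE3 = 25), fgs = 500, knob = 50,
                   fgs_length_bp = 1.5e8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_table(g, path)
  expect_equal(read_counts_table(path), g)

  s <- make_sirna(c(TE1 = 1 / 3, TE2 = 0.25, TE3 = 7), size_class = 22)
  write_counts_table(s, path)
  back <- read_counts_table(path)
  expect_equal(back$counts$hits[1], 1 / 3, tolerance = 1e-12)
  expect_equal(back$size_class, 22L)

  writeLines(c("exemplar_id\thits", "TE1\t5", "TE1\t6"), path)
  expect_error(read_counts_table(path), "TE1")
})

test_that("SAM alignments are parsed with read-space lengths and identity", {
  db <- tiny_db()
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:", db$exemplar_id, "\tLN:", db$length_bp),
    # 50M perfect match
    "r1\t0\tTE1\t1\t60\t50M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*\tNM:i:0\tAS:i:50",
    # 20M30S: only 20 aligned bases -> excluded by the >30 bp rule
    "r2\t0\tTE2\t1\t60\t20M30S\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*\tNM:i:0\tAS:i:20",
    # 40M with 12 mismatches -> identity 0.7 < 0.8
    "r3\t0\tTE3\t1\t60\t40M10S\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*\tNM:i:12\tAS:i:16"
  ), sam)
  aln <- read_sam_alignments(sam, "UTE")
  expect_equal(nrow(aln), 3)
  expect_equal(aln$alignment_length, c(50, 20, 40))
  expect_equal(aln$identity, c(1, 1, 0.7))
  counts <- count_genomic_hits(aln, db)
  expect_equal(sum(counts$counts$hits), 1)
  expect_equal(counts$counts$hits[counts$counts$exemplar_id == "TE1"], 1)
})
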