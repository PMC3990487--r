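# Internal helpers shared across modules.

# Derive a child RNG seed (< 2^31) from a master seed and a stable text label,
# so each (library, purpose) pair gets its own reproducible stream.
derive_seed <- function(master_seed, label) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  chars <- utf8ToInt(label)
  h <- (master_seed %% 2147483647)
  for (c in chars) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded from (master_seed, label).
with_stream <- function(master_seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(master_seed, label))
  force(expr)
}

# Nearest-rank quantile: the ceiling(p * n)-th order statistic.
quantile_nearest_rank <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) abort("cannot take a quantile of zero values")
  x[max(1L, ceiling(p * n))]
}

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive finite scalar", name))
  }
  invisible(x)
}

assert_db <- function(db) {
  req <- c("exemplar_id", "te_class", "family_code", "length_bp")
  missing <- setdiff(req, names(db))
  if (length(missing)) {
    abort(paste0("exemplar db is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(db$exemplar_id)) {
    abort("exemplar db has duplicated exemplar_id values")
  }
  if (any(db$length_bp < 1)) abort("exemplar lengths must be >= 1 bp")
  if (!all(db$te_class %in% c("DNA", "RNA"))) {
    abort("te_class must be 'DNA' or 'RNA'")
  }
  invisible(db)
}
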