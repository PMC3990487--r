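#' Fit a log-normal distribution to abundance values
#'
#' Maximum-likelihood log-normal fit (mean and sd of log values) with a
#' Kolmogorov-Smirnov distance against the fitted distribution for
#' goodness-of-fit reporting — the check behind the empirical-distribution
#' (rank-frequency) comparison of DNA-transposon abundances.
#'
#' @param values Positive abundance values (e.g. filtered RPKM).
#' @return An object of class `lognormal_fit` with elements `meanlog`,
#'   `sdlog`, `ks_distance`, `n`.
#' @export
fit_lognormal_edf <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 10) abort("need at least 10 positive values")
  if (any(values <= 0)) abort("log-normal fit requires strictly positive values")
  lx <- log(values)
  meanlog <- mean(lx)
  sdlog <- sqrt(mean((lx - meanlog)^2))  # MLE (divisor n)
  edf <- stats::ecdf(values)
  xs <- sort(unique(values))
  theo <- if (sdlog > 0) plnorm(xs, meanlog, sdlog) else as.numeric(xs >= exp(meanlog))
  ks <- max(abs(edf(xs) - theo), abs(edf(xs) - c(0, head(theo, -1))))
  structure(list(meanlog = meanlog, sdlog = sdlog, ks_distance = ks,
                 n = length(values)),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("<lognormal_fit> meanlog=%.4f sdlog=%.4f KS=%.4f (n=%d)\n",
              x$meanlog, x$sdlog, x$ks_distance, x$n))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.lognormal_fit <- function(x, ...) {
  tibble(meanlog = x$meanlog, sdlog = x$sdlog,
         ks_distance = x$ks_distance, n = x$n)
}

#' Split a bimodal abundance distribution into low and high modes
#'
#' Fits a two-component Gaussian mixture to log(values) by EM with
#' deterministic initialization (component means at the 25th and 75th
#' percentiles, equal weights, pooled variance) and returns the abundance
#' threshold where the two posterior probabilities are equal — the boundary
#' between the low-copy (R1) and high-copy (R2) retroelement modes.
#' The procedure is deterministic, so permuting the input order leaves the
#' threshold unchanged. If a component collapses (variance below 1e-6) the
#' fit falls back to the midpoint between 2-means-style centers, with a
#' warning; a warning is also issued when the fitted components are too
#' close to call the data bimodal.
#'
#' @param values Positive abundance values (RPKM scale).
#' @param max_iter,tol EM stopping rule: at most `max_iter` iterations or
#'   relative log-likelihood change below `tol`.
#' @return An object of class `rna_split`: `split_threshold` (on the input
#'   scale), `means`, `sds`, `weights` (log-scale mixture parameters),
#'   `loglik`, `n_iter`, `converged`.
#' @export
split_rna_bimodal <- function(values, max_iter = 500L, tol = 1e-8) {
  values <- values[!is.na(values)]
  if (length(values) < 20) abort("need at least 20 positive values")
  if (any(values <= 0)) abort("values must be strictly positive")
  x <- log(values)
  n <- length(x)

  mu <- unname(quantile(x, c(0.25, 0.75), type = 1))
  sigma <- rep(max(sd(x), 1e-3), 2)
  w <- c(0.5, 0.5)
  var_floor <- 1e-6

  loglik <- -Inf
  converged <- FALSE
  collapsed <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sigma[1])
    d2 <- w[2] * dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    ll <- sum(log(tot))

    n1 <- sum(r); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) { collapsed <- TRUE; break }
    mu_new <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    var_new <- c(sum(r * (x - mu_new[1])^2) / n1,
                 sum((1 - r) * (x - mu_new[2])^2) / n2)
    if (any(var_new < var_floor)) { collapsed <- TRUE; break }
    mu <- mu_new; sigma <- sqrt(var_new); w <- c(n1, n2) / n

    if (is.finite(loglik) &&
        abs(ll - loglik) < tol * (abs(loglik) + tol)) {
      loglik <- ll; converged <- TRUE; break
    }
    loglik <- ll
  }

  # order components low -> high
  ord <- order(mu)
  mu <- mu[ord]; sigma <- sigma[ord]; w <- w[ord]

  if (collapsed) {
    warn("mixture fit degenerate; falling back to 2-means split")
    centers <- kmeans_1d_2(x)
    split_log <- mean(centers)
    mu <- centers; sigma <- c(NA_real_, NA_real_); w <- c(NA_real_, NA_real_)
  } else {
    split_log <- posterior_equal_point(mu, sigma, w)
    # the fitted mixture density must have a genuine valley between the
    # component means, else the data are effectively unimodal
    grid <- seq(mu[1], mu[2], length.out = 256)
    dens <- w[1] * dnorm(grid, mu[1], sigma[1]) +
      w[2] * dnorm(grid, mu[2], sigma[2])
    valley <- min(dens)
    peaks <- min(dens[1], dens[length(dens)])
    if (!is.finite(valley) || valley > 0.9 * peaks) {
      warn("fitted components are poorly separated; input may be unimodal")
    }
  }

  structure(list(split_threshold = exp(split_log), means = mu, sds = sigma,
                 weights = w, loglik = loglik, n_iter = iter,
                 converged = converged || collapsed, n = n),
            class = "rna_split")
}

# Deterministic 1-d 2-means (Lloyd from the quartile centers).
kmeans_1d_2 <- function(x) {
  c1 <- unname(quantile(x, 0.25, type = 1))
  c2 <- unname(quantile(x, 0.75, type = 1))
  for (i in 1:100) {
    assign1 <- abs(x - c1) <= abs(x - c2)
    c1n <- mean(x[assign1]); c2n <- mean(x[!assign1])
    if (isTRUE(all.equal(c(c1, c2), c(c1n, c2n)))) break
    c1 <- c1n; c2 <- c2n
  }
  sort(c(c1, c2))
}

# Point between the two component means where posterior probabilities are
# equal: solve w1 N(x; m1, s1) = w2 N(x; m2, s2) on [m1, m2].
posterior_equal_point <- function(mu, sigma, w) {
  f <- function(x) {
    log(w[1]) + dnorm(x, mu[1], sigma[1], log = TRUE) -
      log(w[2]) - dnorm(x, mu[2], sigma[2], log = TRUE)
  }
  lo <- mu[1]; hi <- mu[2]
  if (abs(hi - lo) < 1e-12) return(mu[1])
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0) return((lo + hi) / 2)  # no crossing between the means
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' @export
print.rna_split <- function(x, ...) {
  cat(sprintf(
    "<rna_split> threshold=%.4g; modes exp(%.3f)/exp(%.3f); weights %.2f/%.2f\n",
    x$split_threshold, x$means[1], x$means[2], x$weights[1], x$weights[2]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rna_split <- function(x, ...) {
  tibble(component = c("low", "high"), meanlog = x$means, sdlog = x$sds,
         weight = x$weights)
}

#' @exportS3Method generics::glance
glance.rna_split <- function(x, ...) {
  tibble(split_threshold = x$split_threshold, loglik = x$loglik,
         n_iter = x$n_iter, converged = x$converged, n = x$n)
}

#' Assign exemplars to the D / R1 / R2 / LOW groups
#'
#' Exemplars failing the low-copy RPKM filter become LOW; remaining
#' DNA-class exemplars are group D; remaining RNA-class exemplars are split
#' into R1 (below the fitted bimodal threshold) and R2 (at or above it).
#' Pass a previously fitted `split` to freeze group definitions from a
#' reference accession and reuse them for others.
#'
#' @param abundance A `te_abundance` tibble with `passes_filter` set.
#' @param split Optional [split_rna_bimodal()] fit to reuse; fitted from
#'   this accession's RNA abundances when `NULL`.
#' @return A tibble (class `group_assignment`): `exemplar_id`, `te_class`,
#'   `rpkm_te`, `group`; the `rna_split` fit is attached as attribute
#'   `split`.
#' @export
assign_groups <- function(abundance, split = NULL) {
  if (!all(c("rpkm_te", "passes_filter", "te_class") %in% names(abundance))) {
    abort("abundance must carry rpkm_te, te_class and passes_filter")
  }
  rna_vals <- abundance$rpkm_te[abundance$te_class == "RNA" &
                                  abundance$passes_filter]
  if (is.null(split)) {
    if (length(rna_vals) == 0) {
      abort("no RNA exemplars pass the low-copy filter; cannot fit the split")
    }
    split <- split_rna_bimodal(rna_vals)
  }
  stopifnot(inherits(split, "rna_split"))
  thr <- split$split_threshold
  out <- abundance %>%
    as_tibble() %>%
    mutate(group = dplyr::case_when(
      !.data$passes_filter ~ "LOW",
      .data$te_class == "DNA" ~ "D",
      .data$rpkm_te < thr ~ "R1",
      TRUE ~ "R2"
    )) %>%
    select("exemplar_id", "te_class", "rpkm_te", "group")
  attr(out, "split") <- split
  class(out) <- c("group_assignment", class(out))
  out
}

#' Cross-accession agreement of R1/R2 classification
#'
#' Restricted to RNA-class exemplars classified non-LOW in every compared
#' accession: the overall agreement is the fraction carrying an identical
#' R1/R2 label in all accessions; pairwise agreements are also reported.
#'
#' @param assignments Named list of [assign_groups()] outputs, one per
#'   accession.
#' @return List with `overall` (fraction), `n_shared`, and `pairwise`
#'   (tibble: `accession_a`, `accession_b`, `agreement`, `n`).
#' @export
group_agreement <- function(assignments) {
  if (length(assignments) < 2) abort("need at least two assignments")
  if (is.null(names(assignments)) || any(names(assignments) == "")) {
    abort("assignments must be a named list (one name per accession)")
  }
  labelled <- purrr::imap(assignments, function(a, nm) {
    a %>%
      as_tibble() %>%
      filter(.data$group %in% c("R1", "R2")) %>%
      select("exemplar_id", !!nm := "group")
  })
  shared <- purrr::reduce(labelled, inner_join, by = "exemplar_id")
  if (nrow(shared) == 0) abort("no RNA exemplar is classified in all accessions")
  labs <- as.matrix(shared[-1])
  overall <- mean(apply(labs, 1, function(r) length(unique(r)) == 1L))
  pairs <- utils::combn(names(assignments), 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    j <- inner_join(labelled[[pr[1]]], labelled[[pr[2]]], by = "exemplar_id")
    tibble(accession_a = pr[1], accession_b = pr[2],
           agreement = mean(j[[2]] == j[[3]]), n = nrow(j))
  })
  list(overall = overall, n_shared = nrow(shared), pairwise = pairwise)
}
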