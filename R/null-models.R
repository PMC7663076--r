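#' Generate null incidence matrices
#'
#' Produces randomized binary matrices for significance testing of the
#' co-occurrence statistics. Two algorithms are offered (both via
#' \pkg{vegan}'s null-model engine):
#'
#' * `"fixed_fixed"` — sequential curveball trades preserving every row sum
#'   (site richness) and column sum (species occurrence) exactly; the chain is
#'   burnt in and thinned in units of single trades.
#' * `"proportional_r1"` — non-sequential: row sums are preserved exactly and
#'   species are drawn with probability proportional to their observed
#'   occurrence.
#'
#' Defaults for the sequential chain are `burn_in = 5 * sum(m)` trades and
#' `thin = sum(m)` trades between saved matrices.
#'
#' @param x A cleaned incidence matrix.
#' @param method Null-model algorithm.
#' @param n_sim Number of null matrices (at least 2).
#' @param seed Integer seed; the ensemble is fully reproducible from it.
#' @param burn_in,thin Chain controls for `"fixed_fixed"` (ignored by
#'   `"proportional_r1"`).
#' @return A 3-d array (`n_sites` x `n_species` x `n_sim`).
#' @examples
#' m <- as_incidence(matrix(c(1, 0, 0, 1), 2))
#' a <- simulate_null_matrices(m, n_sim = 5, seed = 1)
#' apply(a, 3, rowSums)  # row sums preserved in every sample
#' @export
simulate_null_matrices <- function(x,
                                   method = c("fixed_fixed", "proportional_r1"),
                                   n_sim = 1000L, seed = NULL,
                                   burn_in = NULL, thin = NULL) {
  method <- match.arg(method)
  m <- unwrap(as_incidence(x))
  if (n_sim < 2) {
    abort("n_sim must be at least 2", class = "emstools_error_config")
  }
  fill <- sum(m)
  if (method == "fixed_fixed" && !has_checkerboard_unit(m)) {
    warn(paste0(
      "matrix contains no 2x2 checkerboard submatrix: the fixed-sum null ",
      "distribution is degenerate (every sample equals the observed matrix)"
    ))
  }
  run <- function() {
    if (method == "fixed_fixed") {
      nm <- vegan::nullmodel(m, "curveball")
      stats::simulate(nm, nsim = n_sim,
                      burnin = burn_in %||% (5L * fill),
                      thin = thin %||% fill)
    } else {
      nm <- vegan::nullmodel(m, "r1")
      stats::simulate(nm, nsim = n_sim)
    }
  }
  sims <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  storage.mode(sims) <- "integer"
  sims
}

# does any pair of rows/columns form a 2x2 checkerboard (swappable) unit?
has_checkerboard_unit <- function(m) {
  a <- m %*% (1 - t(m))
  any(a > 0 & t(a) > 0)
}

# order a null sample, tolerating non-convergence and degenerate axes:
# falls back to the last iterate, then to richness/occurrence ordering
order_null_matrix <- function(m, tol = 1e-10, max_iter = 10000L) {
  res <- ra_engine(m, tol = tol, max_iter = max_iter)
  if (is.null(res)) {
    return(m[order(rowSums(m)), order(colSums(m)), drop = FALSE])
  }
  m[order(res$site), order(res$species), drop = FALSE]
}

# both statistics for each null sample, each sample independently doubly
# ordered; empty rows/columns (possible under proportional_r1) are dropped
null_ensemble_stats <- function(sims, mode = "both", tol = 1e-10,
                                max_iter = 10000L) {
  n_sim <- dim(sims)[3]
  out <- vapply(seq_len(n_sim), function(k) {
    mk <- sims[, , k]
    keep_r <- rowSums(mk) > 0
    keep_c <- colSums(mk) > 0
    mk <- mk[keep_r, keep_c, drop = FALSE]
    mo <- order_null_matrix(mk, tol = tol, max_iter = max_iter)
    emb <- sum(range_index(mo)$extent) - sum(mo)
    if (mode == "both") {
      emb <- emb + sum(range_index(t(mo))$extent) - sum(mo)
    }
    ri <- range_index(mo)
    f <- (outer(seq_len(nrow(mo)), ri$first, ">=") &
            outer(seq_len(nrow(mo)), ri$last, "<=")) + 0L
    c(coherence = emb, turnover = replacements(f))
  }, numeric(2))
  tibble::tibble(
    sample = seq_len(n_sim),
    coherence = out[1, ],
    turnover = out[2, ]
  )
}

#' Null distribution of a co-occurrence statistic
#'
#' Generates `n_sim` null matrices with [simulate_null_matrices()], doubly
#' orders each one independently, computes the requested statistic
#' (coherence on the ordered matrix; turnover on the range-filled ordered
#' matrix), and summarizes the ensemble.
#'
#' @inheritParams simulate_null_matrices
#' @param statistic `"coherence"` or `"turnover"`.
#' @param mode Embedded-absence mode, see [embedded_absences()].
#' @return A list with `statistic`, `method`, `null_mean`, `null_sd`, and the
#'   vector of `samples`.
#' @export
null_distribution <- function(x, statistic = c("coherence", "turnover"),
                              method = c("fixed_fixed", "proportional_r1"),
                              n_sim = 1000L, seed = NULL,
                              burn_in = NULL, thin = NULL,
                              mode = c("both", "columns_only")) {
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  mode <- match.arg(mode)
  m <- clean_incidence(x, quiet = TRUE)
  sims <- simulate_null_matrices(m, method = method, n_sim = n_sim,
                                 seed = seed, burn_in = burn_in, thin = thin)
  st <- null_ensemble_stats(sims, mode = mode)
  samples <- st[[statistic]]
  list(statistic = statistic, method = method,
       null_mean = mean(samples), null_sd = sd(samples), samples = samples)
}
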