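## The three co-occurrence statistics, computed on doubly ordered matrices.
## All accept either an ordered_incidence object or a plain binary matrix that
## the caller asserts is already ordered.

ordered_values <- function(x) {
  if (inherits(x, "ordered_incidence")) unwrap(x$matrix) else unwrap(as_incidence(x))
}

# first/last occupied row per column; empty columns get extent 0
range_index <- function(m) {
  tm <- t(m)
  fi <- max.col(tm, ties.method = "first")
  la <- max.col(tm, ties.method = "last")
  ext <- la - fi + 1L
  z <- rowSums(tm) == 0
  if (any(z)) {
    fi[z] <- 0L
    la[z] <- 0L
    ext[z] <- 0L
  }
  list(first = fi, last = la, extent = ext)
}

#' Coherence: count embedded absences in an ordered matrix
#'
#' An embedded absence is a zero lying strictly inside a species' range (the
#' span between its first and last presence over the ordered sites). Few
#' embedded absences mean species distributions form unbroken ranges along the
#' ordination gradient: a coherent metacommunity. The default mode also counts
#' the analogous gaps in site ranges over the ordered species axis, matching
#' the usual doubly ordered treatment; `"columns_only"` restricts to species
#' ranges.
#'
#' @param x An `ordered_incidence` (from [doubly_order()]) or an already
#'   ordered binary matrix.
#' @param mode `"both"` (species and site ranges, default) or `"columns_only"`.
#' @return Integer count of embedded absences.
#' @examples
#' embedded_absences(matrix(c(1, 0, 1), ncol = 1))  # one gap inside the range
#' @export
embedded_absences <- function(x, mode = c("both", "columns_only")) {
  mode <- match.arg(mode)
  m <- ordered_values(x)
  out <- sum(range_index(m)$extent) - sum(m)
  if (mode == "both" && nrow(m) > 0L) {
    out <- out + sum(range_index(t(m))$extent) - sum(m)
  }
  as.integer(out)
}

#' Fill species ranges in an ordered matrix
#'
#' Replaces every embedded absence within each species' (column) range by a
#' presence, so each species occupies a contiguous block of ordered sites.
#' Turnover and boundary statistics are computed on range-filled matrices,
#' where only the positions of range limits matter.
#'
#' @inheritParams embedded_absences
#' @return The same type as the input, with filled columns. Filled objects
#'   have `embedded_absences(mode = "columns_only")` equal to zero.
#' @export
fill_ranges <- function(x) {
  if (inherits(x, "ordered_incidence")) {
    x$matrix <- fill_ranges(x$matrix)
    attr(x, "filled") <- TRUE
    return(x)
  }
  m <- unwrap(as_incidence(x))
  ri <- range_index(m)
  f <- (outer(seq_len(nrow(m)), ri$first, ">=") &
          outer(seq_len(nrow(m)), ri$last, "<=")) + 0L
  dimnames(f) <- dimnames(m)
  class(f) <- c("incidence", "matrix", "array")
  f
}

#' Turnover: count species replacements between range-filled distributions
#'
#' For every unordered pair of species, the number of replacements is the
#' product of the number of sites inside the first species' range but not the
#' second's and vice versa; the statistic is the sum over all pairs. High
#' values indicate species substituting one another along the gradient, low
#' values indicate ranges nested inside one another.
#'
#' @param x A range-filled `ordered_incidence` or binary matrix (see
#'   [fill_ranges()]).
#' @return The replacement count (numeric; can exceed integer range).
#' @examples
#' replacements(matrix(c(1, 0, 0, 1), nrow = 2))  # 2x2 checkerboard: 1
#' @export
replacements <- function(x) {
  mf <- ordered_values(x)
  s <- colSums(mf)
  co <- crossprod(mf)
  d <- s - co
  sum(d * t(d)) / 2
}

#' Boundary tallies: where species range limits fall
#'
#' Counts, at every interior position of the ordered site axis, how many
#' species range boundaries (first and last occupied site of each species in
#' the range-filled matrix) coincide there. Boundaries lying at the first or
#' last site of the matrix are not observable range limits (the range is
#' truncated by the sampled extent) and are not counted; in particular a
#' species occupying all sites contributes no interior boundaries.
#'
#' @inheritParams replacements
#' @param positions `"interior"` (default) returns tallies for positions
#'   `2..(n-1)`; `"all"` returns a tally for every site position, with zeros
#'   at the edges.
#' @return Named integer vector of boundary counts.
#' @export
boundary_counts <- function(x, positions = c("interior", "all")) {
  positions <- match.arg(positions)
  mf <- ordered_values(x)
  n <- nrow(mf)
  if (n < 3L) {
    abort("boundary tallies need at least 3 ordered sites",
          class = "emstools_error_degenerate")
  }
  ri <- range_index(mf)
  b <- c(ri$first[ri$first > 1L & ri$first < n],
         ri$last[ri$last > 1L & ri$last < n])
  tal <- tabulate(b, nbins = n)
  names(tal) <- rownames(mf)
  if (positions == "interior") tal[2:(n - 1L)] else tal
}

#' Morisita's index of boundary clumping
#'
#' Measures whether species range limits aggregate at the same positions.
#' Given boundary tallies \eqn{x_i} over \eqn{n} positions with total
#' \eqn{X}, the index is \eqn{I = n \sum x_i (x_i - 1) / (X (X - 1))}:
#' \eqn{I > 1} indicates clumped boundaries, \eqn{I \approx 1} random,
#' \eqn{I < 1} overdispersed. Departure from 1 is tested with the dispersion
#' chi-square \eqn{\chi^2 = I(X-1) + n - X} and a two-sided p-value.
#'
#' The degrees of freedom are a reporting convention encapsulated in
#' `df_convention`: `"table"` (default) uses `n_species - 3`, the convention
#' of the study tables this package mirrors; `"sites"` uses the classical
#' `n - 1` (tally positions minus one). Supplying `df` directly overrides
#' both.
#'
#' @param counts Nonnegative integer tallies (see [boundary_counts()]).
#' @param n_species Number of species, required for the `"table"` convention.
#' @param df_convention `"table"` or `"sites"`.
#' @param df Explicit degrees of freedom (overrides `df_convention`).
#' @return An object of class `morisita_test`: list with `index`,
#'   `chi_square`, `df`, `p_value`, `n_units`, `n_boundaries`.
#' @examples
#' morisita(c(4, 0, 0), df = 2)$index  # 3.0: all boundaries on one site
#' @export
morisita <- function(counts, n_species = NULL,
                     df_convention = c("table", "sites"), df = NULL) {
  df_convention <- match.arg(df_convention)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("boundary counts must be nonnegative integers",
          class = "emstools_error_parse")
  }
  n <- length(counts)
  X <- sum(counts)
  if (X < 2 || n < 2) {
    abort("Morisita's index needs at least two boundaries over two positions",
          class = "emstools_error_degenerate")
  }
  I <- n * sum(counts * (counts - 1)) / (X * (X - 1))
  if (is.null(df)) {
    df <- switch(df_convention,
      table = {
        if (is.null(n_species)) {
          abort("`n_species` is required for the \"table\" df convention",
                class = "emstools_error_config")
        }
        n_species - 3L
      },
      sites = n - 1L
    )
  }
  if (df < 1) {
    abort("nonpositive degrees of freedom", class = "emstools_error_degenerate")
  }
  chi <- I * (X - 1) + n - X
  p <- min(1, 2 * min(pchisq(chi, df), pchisq(chi, df, lower.tail = FALSE)))
  structure(
    list(index = I, chi_square = chi, df = df, p_value = p,
         n_units = n, n_boundaries = X),
    class = "morisita_test"
  )
}

#' @export
print.morisita_test <- function(x, ...) {
  cat(sprintf("Morisita's index %.3f (chi^2 = %.1f, df = %d, p = %.4g)\n",
              x$index, x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' z-test of an observed statistic against a null ensemble
#'
#' @param obs Observed value.
#' @param null_mean,null_sd Mean and standard deviation of the null ensemble.
#' @return List with `z` and the two-sided normal `p`.
#' @export
z_test <- function(obs, null_mean, null_sd) {
  if (!is.finite(null_sd) || null_sd <= 0) {
    abort("degenerate null distribution (sd = 0); cannot standardize",
          class = "emstools_error_degenerate")
  }
  z <- (obs - null_mean) / null_sd
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' All recognizable metacommunity structures
#'
#' @return Character vector of the 14 structure labels produced by
#'   [classify_structure()].
#' @export
ems_structures <- function() {
  c("checkerboard", "random",
    "nested_clumped_loss", "nested_random_loss", "nested_hyperdispersed_loss",
    "quasi_nested_clumped_loss", "quasi_nested_random_loss",
    "quasi_nested_hyperdispersed_loss",
    "clementsian", "gleasonian", "evenly_spaced",
    "quasi_clementsian", "quasi_gleasonian", "quasi_evenly_spaced")
}

#' Classify a metacommunity from its three elements
#'
#' Implements the decision flowchart over coherence, turnover, and boundary
#' clumping. Non-significant coherence is random; significant coherence with
#' more embedded absences than the null is a checkerboard. Otherwise the
#' turnover element decides between nested subsets (fewer replacements than
#' null) and gradient structures (more); when turnover is not significant the
#' family given by its direction is kept with a `quasi_` prefix. Within each
#' family Morisita's index resolves the final label: significantly clumped
#' boundaries give clumped species loss / Clementsian, significantly
#' overdispersed give hyperdispersed loss / evenly spaced, non-significant
#' give random loss / Gleasonian.
#'
#' @param coherence_p,turnover_p,morisita_p Two-sided p-values.
#' @param coherence_obs,coherence_null Observed embedded absences and null
#'   mean.
#' @param turnover_obs,turnover_null Observed replacements and null mean.
#' @param morisita_index Morisita boundary-clumping index.
#' @param alpha Significance level (default 0.05).
#' @return One of [ems_structures()].
#' @export
classify_structure <- function(coherence_p, coherence_obs, coherence_null,
                               turnover_p, turnover_obs, turnover_null,
                               morisita_index, morisita_p, alpha = 0.05) {
  if (coherence_p >= alpha) return("random")
  if (coherence_obs > coherence_null) return("checkerboard")
  clumping <- if (morisita_p >= alpha) {
    "none"
  } else if (morisita_index > 1) {
    "clumped"
  } else if (morisita_index < 1) {
    "over"
  } else {
    "none"
  }
  gradient <- turnover_obs > turnover_null
  base <- if (gradient) {
    switch(clumping, clumped = "clementsian", over = "evenly_spaced",
           none = "gleasonian")
  } else {
    switch(clumping, clumped = "nested_clumped_loss",
           over = "nested_hyperdispersed_loss", none = "nested_random_loss")
  }
  if (turnover_p >= alpha) paste0("quasi_", base) else base
}
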