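#' First-axis correspondence analysis by reciprocal averaging
#'
#' Computes the first non-trivial correspondence-analysis (CA) axis of a
#' binary incidence matrix by reciprocal averaging: site scores are the
#' occupancy-weighted averages of species scores and vice versa, iterated to a
#' fixed point. This is the ordination used to doubly order matrices for the
#' co-occurrence statistics, and its site scores are the response variable of
#' the environmental regression tree.
#'
#' The iteration runs on the transition operator of the smaller dimension and
#' performs four averaging cycles per convergence check; convergence is
#' declared when the maximum change in standardized scores falls below `tol`.
#' Site scores are standardized to zero mean and unit variance under row-sum
#' weights; the axis sign is fixed so the first site's score is nonnegative
#' (all downstream statistics are invariant under reflection).
#'
#' @param x An incidence matrix (cleaned: no empty rows/columns).
#' @param tol Convergence tolerance on the change in standardized scores.
#' @param max_iter Maximum number of averaging cycles.
#' @param check If `TRUE`, test for structural disconnection (block-diagonal
#'   bipartite structure) and warn, since the first axis then separates blocks
#'   degenerately rather than recovering a gradient.
#' @param strict If `TRUE` (default), failure to converge within `max_iter`
#'   is an error. If `FALSE`, the final iterate is returned with
#'   `converged = FALSE` and a warning: near-tied second and third axes make
#'   the iteration arbitrarily slow, while any vector in their span orders
#'   the matrix comparably well.
#'
#' @return An object of class `ca_ordination`: a list with `site_scores`,
#'   `species_scores` (named numeric vectors), `eigenvalue` (in (0, 1]),
#'   `converged`, and `iterations`.
#' @examples
#' banded <- as_incidence(matrix(c(1, 0, 0, 1, 1, 0, 0, 1, 1), nrow = 3))
#' ord <- reciprocal_averaging(banded)
#' order(ord$site_scores)  # recovers the band order (up to reflection)
#' @export
reciprocal_averaging <- function(x, tol = 1e-10, max_iter = 10000L,
                                 check = TRUE, strict = TRUE) {
  m <- unwrap(as_incidence(x))
  r <- rowSums(m)
  cc <- colSums(m)
  if (any(r == 0) || any(cc == 0)) {
    abort("matrix has empty rows or columns; run clean_incidence() first",
          class = "emstools_error_empty")
  }
  if (check && !is_connected(m)) {
    warn(paste0(
      "incidence matrix is structurally disconnected; ",
      "CA axis 1 separates the blocks degenerately"
    ))
  }
  res <- ra_engine(m, tol = tol, max_iter = max_iter)
  if (is.null(res)) {
    abort("matrix has no non-trivial ordination axis (constant structure)",
          class = "emstools_error_degenerate")
  }
  if (!res$converged) {
    if (strict) {
      abort(
        sprintf("ordination did not converge within %d cycles (last change %.3g)",
                max_iter, res$delta),
        class = "emstools_error_convergence"
      )
    }
    warn(sprintf(
      "ordination not fully converged after %d cycles (last change %.3g); using final iterate",
      max_iter, res$delta
    ))
  }
  structure(
    list(
      site_scores = stats::setNames(res$site, rownames(m)),
      species_scores = stats::setNames(res$species, colnames(m)),
      eigenvalue = res$lambda,
      converged = res$converged,
      iterations = res$iterations
    ),
    class = "ca_ordination"
  )
}

# Numeric core. Returns NULL when no non-trivial axis exists. Never errors on
# non-convergence; callers decide. One "iteration" is one full reciprocal
# averaging cycle; cycles are applied four at a time through a precomputed
# operator power for speed (the trivial axis is a left/right eigenpair of the
# transition operator, so the centered subspace is invariant and re-centering
# per check only removes numerical drift).
ra_engine <- function(m, tol = 1e-10, max_iter = 10000L) {
  r <- rowSums(m)
  cc <- colSums(m)
  flip <- ncol(m) < nrow(m)
  if (flip) {
    mm <- t(m); rr <- cc; ccc <- r
  } else {
    mm <- m; rr <- r; ccc <- cc
  }
  P <- (mm / rr) %*% (t(mm) / ccc)
  P4 <- P %*% P
  P4 <- P4 %*% P4
  w <- rr / sum(rr)
  # ramp plus an incommensurate oscillation: a plain ramp can be exactly
  # weight-orthogonal to the dominant non-trivial axis on small symmetric
  # matrices, which would silently lock onto a lower axis
  idx <- seq_along(rr)
  v <- idx + 0.5 * sin(2.3 * idx)
  v <- v - sum(w * v)
  nr <- sqrt(sum(w * v^2))
  if (nr < 1e-13) return(NULL)
  v <- v / nr
  converged <- FALSE
  it <- 0L
  delta <- Inf
  for (k in seq_len(max(1L, as.integer(max_iter) %/% 4L))) {
    vn <- drop(P4 %*% v)
    vn <- vn - sum(w * vn)
    nr <- sqrt(sum(w * vn^2))
    if (nr < 1e-14) return(NULL)
    vn <- vn / nr
    delta <- max(abs(vn - v))
    v <- vn
    it <- it + 4L
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  lambda <- nr^(1 / 4)
  if (flip) {
    species <- v
    wr <- r / sum(r)
    site <- drop(m %*% species) / r
    site <- site - sum(wr * site)
    sn <- sqrt(sum(wr * site^2))
    if (sn < 1e-14) return(NULL)
    site <- site / sn
  } else {
    site <- v
    species <- drop(crossprod(m, site)) / cc
  }
  if (site[1] < 0) {
    site <- -site
    species <- -species
  }
  list(site = site, species = species, lambda = lambda,
       iterations = it, converged = converged, delta = delta)
}

# bipartite connectivity via logical frontier expansion
is_connected <- function(m) {
  reach <- c(TRUE, logical(nrow(m) - 1L))
  repeat {
    sp <- drop(crossprod(m, reach)) > 0
    new <- drop(m %*% sp) > 0
    if (!any(new & !reach)) break
    reach <- reach | new
  }
  all(reach)
}

#' Doubly order an incidence matrix along its first CA axis
#'
#' Permutes sites and species by ascending first-axis ordination scores,
#' exposing the latent gradient: species with similar occurrence profiles and
#' sites with similar composition become neighbours, the precondition for
#' counting embedded absences, replacements, and range boundaries. Ties in
#' scores are broken by original input order, so the result is deterministic.
#'
#' @inheritParams reciprocal_averaging
#' @return An object of class `ordered_incidence`: a list with `matrix` (the
#'   permuted incidence matrix), `row_order` and `col_order` (permutations of
#'   the original indices), and `ordination` (the [reciprocal_averaging()]
#'   result, or `NULL` for degenerate single-row/column matrices, which are
#'   returned unchanged).
#' @seealso [embedded_absences()], [fill_ranges()], [ems()]
#' @export
doubly_order <- function(x, tol = 1e-10, max_iter = 10000L, check = TRUE,
                         strict = TRUE) {
  m <- as_incidence(x)
  if (nrow(m) == 1L || ncol(m) == 1L) {
    return(structure(
      list(matrix = m, row_order = seq_len(nrow(m)),
           col_order = seq_len(ncol(m)), ordination = NULL),
      class = "ordered_incidence"
    ))
  }
  ord <- reciprocal_averaging(m, tol = tol, max_iter = max_iter, check = check,
                              strict = strict)
  ro <- order(ord$site_scores)
  co <- order(ord$species_scores)
  om <- m[ro, co, drop = FALSE]
  class(om) <- c("incidence", "matrix", "array")
  structure(
    list(matrix = om, row_order = ro, col_order = co, ordination = ord),
    class = "ordered_incidence"
  )
}

#' @export
print.ordered_incidence <- function(x, ...) {
  cat(sprintf("<ordered_incidence> %d sites x %d species",
              nrow(x$matrix), ncol(x$matrix)))
  if (!is.null(x$ordination)) {
    cat(sprintf(", CA eigenvalue %.3f (%d cycles)",
                x$ordination$eigenvalue, x$ordination$iterations))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.ca_ordination <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(type = "site", id = names(x$site_scores),
                   score = unname(x$site_scores)),
    tibble::tibble(type = "species", id = names(x$species_scores),
                   score = unname(x$species_scores))
  )
}

#' @export
glance.ca_ordination <- function(x, ...) {
  tibble::tibble(
    eigenvalue = x$eigenvalue,
    converged = x$converged,
    iterations = x$iterations,
    n_sites = length(x$site_scores),
    n_species = length(x$species_scores)
  )
}
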