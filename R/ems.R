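#' Elements of metacommunity structure analysis
#'
#' Runs the full single-metacommunity workflow on a binary site-by-species
#' table: cleaning, double ordination along the first correspondence-analysis
#' axis, the three structure elements (coherence, turnover, boundary
#' clumping), null-model inference for coherence and turnover, the analytic
#' Morisita test for boundary clumping, and the final structure
#' classification via [classify_structure()].
#'
#' Coherence and turnover are tested against an ensemble of null matrices
#' (default: curveball trades preserving all row and column sums), each of
#' which is independently doubly ordered before its statistic is computed.
#' Significance is a two-sided z-test of the observed value against the
#' ensemble mean and standard deviation.
#'
#' @param x An incidence matrix, or a data frame with a site-id column
#'   (see [as_incidence()]).
#' @param null Null-model algorithm, see [simulate_null_matrices()].
#' @param n_sim Number of null matrices.
#' @param seed Integer seed for the null ensemble.
#' @param alpha Significance level used by the classification.
#' @param mode Embedded-absence mode, see [embedded_absences()].
#' @param burn_in,thin Chain controls for the sequential null model.
#' @param df_convention Morisita degrees-of-freedom convention, see
#'   [morisita()].
#' @param quiet Suppress cleaning warnings.
#'
#' @return An object of class `ems_result` with components `ordered` (the
#'   [doubly_order()] result), `coherence` and `turnover` (lists with `obs`,
#'   `null_mean`, `null_sd`, `z`, `p`, `obs_over_null`), `morisita` (a
#'   [morisita()] test), `label`, `alpha`, and `config`.
#' @seealso [tidy.ems_result()], [glance.ems_result()], [autoplot.ems_result()]
#' @examples
#' \donttest{
#' syn <- simulate_metacommunity("clementsian", n_sites = 30, n_species = 40,
#'                               seed = 1)
#' res <- ems(syn$incidence, n_sim = 50, seed = 1)
#' res$label
#' }
#' @export
ems <- function(x, null = c("fixed_fixed", "proportional_r1"),
                n_sim = 1000L, seed = NULL, alpha = 0.05,
                mode = c("both", "columns_only"),
                burn_in = NULL, thin = NULL,
                df_convention = c("table", "sites"),
                quiet = FALSE) {
  null <- match.arg(null)
  mode <- match.arg(mode)
  df_convention <- match.arg(df_convention)
  m <- clean_incidence(x, quiet = quiet)

  # the observed matrix is ordered with the same tolerant policy applied to
  # every null matrix: on a near-tied spectrum the final iterate is used
  om <- doubly_order(m, strict = FALSE)
  co_obs <- embedded_absences(om, mode = mode)
  omf <- fill_ranges(om)
  tu_obs <- replacements(omf)
  mor <- morisita(boundary_counts(omf), n_species = ncol(m),
                  df_convention = df_convention)

  sims <- simulate_null_matrices(m, method = null, n_sim = n_sim,
                                 seed = seed, burn_in = burn_in, thin = thin)
  nst <- null_ensemble_stats(sims, mode = mode)
  co_test <- z_test(co_obs, mean(nst$coherence), sd(nst$coherence))
  tu_test <- z_test(tu_obs, mean(nst$turnover), sd(nst$turnover))

  coherence <- list(
    obs = co_obs, null_mean = mean(nst$coherence), null_sd = sd(nst$coherence),
    z = co_test$z, p = co_test$p, obs_over_null = co_obs / mean(nst$coherence)
  )
  turnover <- list(
    obs = tu_obs, null_mean = mean(nst$turnover), null_sd = sd(nst$turnover),
    z = tu_test$z, p = tu_test$p, obs_over_null = tu_obs / mean(nst$turnover)
  )
  label <- classify_structure(
    coherence_p = coherence$p, coherence_obs = coherence$obs,
    coherence_null = coherence$null_mean,
    turnover_p = turnover$p, turnover_obs = turnover$obs,
    turnover_null = turnover$null_mean,
    morisita_index = mor$index, morisita_p = mor$p_value, alpha = alpha
  )
  structure(
    list(
      ordered = om, coherence = coherence, turnover = turnover,
      morisita = mor, label = label, alpha = alpha,
      null_samples = nst,
      config = list(null = null, n_sim = n_sim, seed = seed, mode = mode,
                    burn_in = burn_in, thin = thin,
                    df_convention = df_convention)
    ),
    class = "ems_result"
  )
}

#' @export
print.ems_result <- function(x, ...) {
  m <- x$ordered$matrix
  cat(sprintf("Elements of metacommunity structure (%d sites x %d species)\n",
              nrow(m), ncol(m)))
  cat(sprintf("  coherence: %d embedded absences (null %.1f +/- %.1f, z = %.2f, p = %.3g)\n",
              x$coherence$obs, x$coherence$null_mean, x$coherence$null_sd,
              x$coherence$z, x$coherence$p))
  cat(sprintf("  turnover:  %.0f replacements (null %.1f +/- %.1f, z = %.2f, p = %.3g)\n",
              x$turnover$obs, x$turnover$null_mean, x$turnover$null_sd,
              x$turnover$z, x$turnover$p))
  cat(sprintf("  boundary clumping: Morisita %.3f (df = %d, p = %.3g)\n",
              x$morisita$index, x$morisita$df, x$morisita$p_value))
  cat(sprintf("  structure: %s (alpha = %g, null = %s, n_sim = %d)\n",
              x$label, x$alpha, x$config$null, x$config$n_sim))
  invisible(x)
}

#' Tidy the three structure elements of an EMS analysis
#'
#' @param x An `ems_result`.
#' @param ... Unused.
#' @return A tibble with one row per element (coherence, turnover,
#'   boundary_clumping) and columns `statistic`, `observed`, `null_mean`,
#'   `null_sd`, `obs_over_null`, `z`, `df`, `p_value`.
#' @export
tidy.ems_result <- function(x, ...) {
  tibble::tibble(
    element = c("coherence", "turnover", "boundary_clumping"),
    statistic = c("embedded_absences", "replacements", "morisita_index"),
    observed = c(x$coherence$obs, x$turnover$obs, x$morisita$index),
    null_mean = c(x$coherence$null_mean, x$turnover$null_mean, NA),
    null_sd = c(x$coherence$null_sd, x$turnover$null_sd, NA),
    obs_over_null = c(x$coherence$obs_over_null, x$turnover$obs_over_null, NA),
    z = c(x$coherence$z, x$turnover$z, NA),
    df = c(NA, NA, x$morisita$df),
    p_value = c(x$coherence$p, x$turnover$p, x$morisita$p_value)
  )
}

#' One-row summary of an EMS analysis
#'
#' @inheritParams tidy.ems_result
#' @return A one-row tibble mirroring the usual report layout: dimensions,
#'   the three elements with their null comparisons, and the structure label.
#' @export
glance.ems_result <- function(x, ...) {
  m <- x$ordered$matrix
  tibble::tibble(
    n_sites = nrow(m),
    n_species = ncol(m),
    coherence_obs = x$coherence$obs,
    coherence_null_mean = x$coherence$null_mean,
    coherence_obs_over_null = x$coherence$obs_over_null,
    coherence_z = x$coherence$z,
    coherence_p = x$coherence$p,
    turnover_obs = x$turnover$obs,
    turnover_null_mean = x$turnover$null_mean,
    turnover_obs_over_null = x$turnover$obs_over_null,
    turnover_z = x$turnover$z,
    turnover_p = x$turnover$p,
    morisita_index = x$morisita$index,
    morisita_df = x$morisita$df,
    morisita_p = x$morisita$p_value,
    structure = x$label
  )
}

#' Plot a doubly ordered incidence matrix
#'
#' Tile plot of the ordered matrix with sites on the vertical axis and
#' species on the horizontal, the usual way of eyeballing coherence and
#' compartment structure.
#'
#' @param object An `ems_result` or `ordered_incidence`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ems_result <- function(object, ...) {
  autoplot.ordered_incidence(object$ordered, ...) +
    ggplot2::labs(subtitle = paste("structure:", object$label))
}

#' @rdname autoplot.ems_result
#' @export
autoplot.ordered_incidence <- function(object, ...) {
  m <- object$matrix
  df <- tibble::tibble(
    site = factor(rep(rownames(m), times = ncol(m)), levels = rev(rownames(m))),
    species = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    present = as.integer(m) == 1L
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$site)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$present), colour = NA) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey15", `FALSE` = "white"),
                               guide = "none") +
    ggplot2::labs(x = "species (ordered by CA axis 1)",
                  y = "sites (ordered by CA axis 1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
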