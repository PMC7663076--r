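#' Run the full metacommunity analysis workflow
#'
#' Orchestrates the study pipeline over a species pool: the pool itself, each
#' trophic guild with more than `min_guild_species - 1` species (when a guild
#' table is supplied), and the core-species subset (species occurring more
#' often than the mean). Each sub-metacommunity is independently re-cleaned,
#' doubly ordered, scored for the three structure elements with null-model
#' inference, and classified. When an environmental table is supplied, each
#' sub-metacommunity's first-axis CA site scores are additionally related to
#' the environmental predictors with a regression tree and its site groups
#' are reported.
#'
#' Reproducibility: the null ensemble of the k-th analyzed metacommunity uses
#' seed `seed + k - 1`, so a single seed fixes the whole report.
#'
#' @param incidence Incidence matrix or data frame (see [as_incidence()]),
#'   or a path to a CSV file.
#' @param env Optional environmental table (data frame with `site_id` and
#'   numeric predictors) or CSV path. Site ids must match the incidence
#'   matrix after cleaning.
#' @param guilds Optional guild table (`species_id`, `guild`) or CSV path.
#' @param null,n_sim,alpha,mode,df_convention Passed to [ems()].
#' @param seed Integer seed for all null ensembles.
#' @param min_guild_species Minimum guild size analyzed.
#' @param include_core Analyze the core-species sub-metacommunity?
#' @param tree_control List overriding [fit_gradient_tree()] defaults
#'   (`min_leaf`, `max_depth`, `cp`).
#' @param quiet Suppress progress messages.
#'
#' @return An object of class `ems_report`: list with `summary` (one row per
#'   analyzed metacommunity, the [glance.ems_result()] columns plus name),
#'   `results` (named list of `ems_result`s), `trees` (named list of
#'   `gradient_tree`s, if `env` given), `groups` (site-group assignments),
#'   `ordination` (site/species scores per metacommunity), `excluded_guilds`,
#'   `core` (the [core_satellite()] table), and `manifest` (configuration).
#' @seealso [write_report()]
#' @export
run_metacommunity_analysis <- function(incidence, env = NULL, guilds = NULL,
                                       null = "fixed_fixed", n_sim = 1000L,
                                       seed = 1L, alpha = 0.05,
                                       mode = "both",
                                       df_convention = "table",
                                       min_guild_species = 16L,
                                       include_core = TRUE,
                                       tree_control = list(),
                                       quiet = FALSE) {
  say <- function(...) if (!quiet) inform(sprintf(...))
  if (is.character(incidence) && length(incidence) == 1L) {
    incidence <- read_incidence(incidence, quiet = quiet)
  }
  pool <- clean_incidence(incidence, quiet = quiet)
  if (is.character(env) && length(env) == 1L) {
    env <- readr::read_csv(env, show_col_types = FALSE, progress = FALSE)
  }
  if (is.character(guilds) && length(guilds) == 1L) {
    guilds <- readr::read_csv(guilds, show_col_types = FALSE, progress = FALSE)
  }
  if (!is.null(env)) {
    if (!"site_id" %in% names(env)) {
      abort("env table must have a 'site_id' column",
            class = "emstools_error_alignment")
    }
    off <- setdiff(rownames(pool), as.character(env$site_id))
    if (length(off)) {
      abort(paste0("sites missing from env table: ", toString(head(off, 8))),
            class = "emstools_error_alignment")
    }
  }

  members <- list(pool = pool)
  if (!is.null(guilds)) {
    gs <- guild_subsets(pool, guilds, min_species = min_guild_species)
    members <- c(members, gs)
    excluded <- attr(gs, "excluded")
  } else {
    excluded <- tibble::tibble(guild = character(), n_species = integer(),
                               reason = character())
  }
  core_tab <- core_satellite(pool)
  if (include_core) {
    core_sp <- core_tab$species_id[core_tab$class == "core"]
    if (length(core_sp) >= 2) {
      members$core <- subset_species(pool, core_sp)
    } else {
      say("core subset skipped: fewer than 2 core species")
    }
  }

  tc <- utils::modifyList(list(min_leaf = 5L, max_depth = 5L, cp = 0.01),
                          tree_control)
  results <- list()
  trees <- list()
  groups <- tibble::tibble()
  ordin <- tibble::tibble()
  rows <- list()
  skipped <- tibble::tibble(metacommunity = character(), reason = character())
  for (k in seq_along(members)) {
    nm <- names(members)[k]
    m <- members[[k]]
    say("analyzing '%s' (%d sites x %d species)", nm, nrow(m), ncol(m))
    res <- tryCatch(
      ems(m, null = null, n_sim = n_sim,
          seed = (seed + k - 1L) %% .Machine$integer.max,
          alpha = alpha, mode = mode, df_convention = df_convention,
          quiet = TRUE),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      # e.g. a core or guild submatrix degenerating to a constant block
      skipped <- dplyr::bind_rows(skipped, tibble::tibble(
        metacommunity = nm, reason = conditionMessage(res)
      ))
      say("skipped '%s': %s", nm, conditionMessage(res))
      next
    }
    results[[nm]] <- res
    rows[[nm]] <- dplyr::bind_cols(
      tibble::tibble(metacommunity = nm), glance(res)
    )
    ordin <- dplyr::bind_rows(
      ordin,
      dplyr::mutate(tidy(res$ordered$ordination), metacommunity = nm,
                    .before = 1)
    )
    if (!is.null(env)) {
      sub_env <- env[match(rownames(res$ordered$matrix), as.character(env$site_id)), ,
                     drop = FALSE]
      scores <- res$ordered$ordination$site_scores
      tr <- fit_gradient_tree(as.data.frame(sub_env), scores,
                              min_leaf = tc$min_leaf,
                              max_depth = tc$max_depth, cp = tc$cp)
      trees[[nm]] <- tr
      groups <- dplyr::bind_rows(
        groups,
        dplyr::mutate(tr$groups, metacommunity = nm, .before = 1)
      )
    }
  }

  structure(
    list(
      summary = dplyr::bind_rows(rows),
      results = results,
      trees = if (length(trees)) trees,
      groups = if (nrow(groups)) groups,
      ordination = ordin,
      excluded_guilds = excluded,
      skipped = skipped,
      core = core_tab,
      manifest = list(
        package = "emstools",
        version = as.character(utils::packageVersion("emstools")),
        null = null, n_sim = n_sim, seed = seed, alpha = alpha, mode = mode,
        df_convention = df_convention, min_guild_species = min_guild_species,
        tree_control = tc,
        metacommunities = names(members)
      )
    ),
    class = "ems_report"
  )
}

#' @export
print.ems_report <- function(x, ...) {
  cat("EMS analysis report\n")
  cols <- c("metacommunity", "n_sites", "n_species", "coherence_obs",
            "turnover_obs", "morisita_index", "structure")
  print(as.data.frame(x$summary[cols]), row.names = FALSE, digits = 4)
  if (nrow(x$excluded_guilds)) {
    cat("excluded guilds:",
        paste0(x$excluded_guilds$guild, " (", x$excluded_guilds$reason, ")",
               collapse = "; "), "\n")
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits `report.csv` (the summary table), `report.json` (summary, groups,
#' excluded guilds and manifest), `ordination.csv` (site and species scores
#' per metacommunity), `tree.json` (nested tree structures, when trees were
#' fitted), and `manifest.json`. Outputs contain no timestamps, so two runs
#' from the same configuration and seed are byte-identical.
#'
#' @param report An `ems_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "report.csv")
  readr::write_csv(report$summary, p)
  paths <- c(paths, p)
  p <- file.path(dir, "ordination.csv")
  readr::write_csv(report$ordination, p)
  paths <- c(paths, p)
  p <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(summary = report$summary,
         groups = report$groups,
         excluded_guilds = report$excluded_guilds,
         core = report$core,
         manifest = report$manifest),
    p, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  paths <- c(paths, p)
  if (!is.null(report$trees)) {
    p <- file.path(dir, "tree.json")
    jsonlite::write_json(lapply(report$trees, tree_as_list), p,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(report$manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
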