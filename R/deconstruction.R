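#' Partition species into core and satellite sets
#'
#' Core species occur more often than the average species; satellite species
#' do not. The mean is taken over the occurrence fractions of all species in
#' the pool, and "greater than" is read strictly: a species exactly at the
#' mean is satellite. Core species are widespread and tend to carry the
#' non-random part of a metacommunity's structure; satellites are sparse and
#' often closer to random.
#'
#' @param x An incidence matrix (or anything [as_incidence()] accepts).
#' @return A tibble with one row per species: `species_id`, `n_occurrences`,
#'   `occurrence_fraction`, `class` (`"core"`/`"satellite"`). The mean
#'   occurrence fraction is attached as attribute `mean_occurrence`.
#' @examples
#' m <- as_incidence(matrix(c(1,1,1, 1,0,0, 1,1,0), nrow = 3,
#'                          dimnames = list(NULL, c("a", "b", "c"))))
#' core_satellite(m)  # occurrences 3,1,2; mean 2 -> only "a" is core
#' @export
core_satellite <- function(x) {
  m <- as_incidence(x)
  occ <- colSums(m)
  frac <- occ / nrow(m)
  mean_frac <- mean(frac)
  out <- tibble::tibble(
    species_id = colnames(m),
    n_occurrences = as.integer(occ),
    occurrence_fraction = unname(frac),
    class = unname(ifelse(frac > mean_frac, "core", "satellite"))
  )
  attr(out, "mean_occurrence") <- mean_frac
  out
}

#' Subset an incidence matrix to a set of species
#'
#' Keeps the named species and drops sites left empty, re-cleaning the
#' result. Community counts of sub-metacommunities therefore generally differ
#' from the pool's.
#'
#' @param x An incidence matrix.
#' @param species Character vector of species ids to keep.
#' @param quiet Suppress the cleaning warning.
#' @return A cleaned `incidence` matrix.
#' @export
subset_species <- function(x, species, quiet = TRUE) {
  m <- as_incidence(x)
  missing_sp <- setdiff(species, colnames(m))
  if (length(missing_sp)) {
    abort(paste0("species not in matrix: ", toString(head(missing_sp, 5))),
          class = "emstools_error_alignment")
  }
  clean_incidence(m[, species, drop = FALSE], quiet = quiet)
}

#' Split a metacommunity into trophic-guild sub-metacommunities
#'
#' Builds one incidence matrix per guild from a species-to-guild lookup
#' table. Each guild matrix is independently re-cleaned (sites hosting no
#' member of the guild are dropped), and guilds with fewer than `min_species`
#' species are excluded — by default 16, i.e. pools must have more than 15
#' species to be analyzed. Species present in the matrix but absent from the
#' guild table are ignored with a warning.
#'
#' @param x An incidence matrix.
#' @param guilds A data frame with columns `species_id` and `guild`.
#' @param min_species Minimum guild size retained (inclusive).
#' @return A named list of `incidence` matrices, one per retained guild, with
#'   an `excluded` attribute: a tibble of guilds left out and why.
#' @export
guild_subsets <- function(x, guilds, min_species = 16L) {
  m <- as_incidence(x)
  if (!is.data.frame(guilds) || !all(c("species_id", "guild") %in% names(guilds))) {
    abort("`guilds` must be a data frame with columns species_id and guild",
          class = "emstools_error_config")
  }
  if (nrow(guilds) == 0) {
    abort("empty guild table", class = "emstools_error_config")
  }
  if (anyDuplicated(guilds$species_id)) {
    abort("species listed more than once in the guild table",
          class = "emstools_error_config")
  }
  uncovered <- setdiff(colnames(m), guilds$species_id)
  if (length(uncovered)) {
    warn(sprintf("%d species have no guild assignment and are ignored",
                 length(uncovered)))
  }
  all_guilds <- unique(guilds$guild)
  guilds <- guilds[guilds$species_id %in% colnames(m), , drop = FALSE]
  split_sp <- split(guilds$species_id, guilds$guild)
  excluded <- tibble::tibble(guild = character(), n_species = integer(),
                             reason = character())
  out <- list()
  for (g in names(split_sp)) {
    sp <- split_sp[[g]]
    if (length(sp) < min_species) {
      excluded <- dplyr::bind_rows(excluded, tibble::tibble(
        guild = g, n_species = length(sp),
        reason = sprintf("fewer than %d species", min_species)
      ))
      inform(sprintf("guild '%s' excluded: %d species (< %d)",
                     g, length(sp), min_species))
      next
    }
    out[[g]] <- subset_species(m, sp)
  }
  absent <- setdiff(all_guilds, c(names(out), excluded$guild))
  if (length(absent)) {
    warn(paste0("guild(s) with no species in the matrix omitted: ",
                toString(absent)))
  }
  attr(out, "excluded") <- excluded
  out
}
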