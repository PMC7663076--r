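#' Coerce a table of species occurrences to an incidence matrix
#'
#' An incidence matrix is the central container of the package: a binary
#' sites-by-species matrix (rows are sites/communities, columns are species)
#' with unique site and species labels. Row sums are site richness, column
#' sums are species occurrence.
#'
#' @param x A numeric matrix, or a data frame with one site-identifier column
#'   and one numeric column per species (the layout produced by
#'   [read_incidence()]).
#' @param site_col For data frames, the position or name of the column holding
#'   site identifiers. Default first column.
#' @param abundance If `TRUE`, any value greater than zero is converted to a
#'   presence; if `FALSE` (default) the input must already be binary.
#' @param ... Passed between methods.
#'
#' @return An object of class `incidence`: an integer 0/1 matrix with site ids
#'   as row names and species ids as column names.
#' @seealso [clean_incidence()], [read_incidence()], [doubly_order()]
#' @examples
#' m <- as_incidence(matrix(c(1, 1, 0, 0, 1, 1), nrow = 3,
#'                   dimnames = list(paste0("s", 1:3), c("spA", "spB"))))
#' rowSums(m)  # site richness
#' @export
as_incidence <- function(x, ...) UseMethod("as_incidence")

#' @rdname as_incidence
#' @export
as_incidence.incidence <- function(x, ...) x

#' @rdname as_incidence
#' @export
as_incidence.matrix <- function(x, abundance = FALSE, ...) {
  if (!is.numeric(x)) {
    abort("incidence values must be numeric", class = "emstools_error_parse")
  }
  if (anyNA(x)) {
    abort("incidence values must not contain missing entries",
          class = "emstools_error_parse")
  }
  if (any(x < 0)) {
    abort("incidence values must be nonnegative", class = "emstools_error_parse")
  }
  if (abundance) {
    x[] <- as.integer(x > 0)
  } else if (!all(x == 0 | x == 1)) {
    abort(
      "matrix is not binary; use `abundance = TRUE` to threshold counts at > 0",
      class = "emstools_error_parse"
    )
  }
  storage.mode(x) <- "integer"
  if (is.null(rownames(x))) rownames(x) <- sprintf("site_%02d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("sp_%03d", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) {
    abort("site ids must be unique", class = "emstools_error_parse")
  }
  if (anyDuplicated(colnames(x))) {
    abort("species ids must be unique", class = "emstools_error_parse")
  }
  class(x) <- c("incidence", "matrix", "array")
  x
}

#' @rdname as_incidence
#' @export
as_incidence.data.frame <- function(x, site_col = 1, abundance = FALSE, ...) {
  if (ncol(x) < 2) {
    abort("need a site-id column plus at least one species column",
          class = "emstools_error_parse")
  }
  ids <- as.character(x[[site_col]])
  sp <- x[setdiff(seq_along(x), if (is.numeric(site_col)) site_col else match(site_col, names(x)))]
  bad <- names(sp)[!vapply(sp, is.numeric, logical(1))]
  if (length(bad)) {
    abort(
      paste0("non-numeric species column(s): ", toString(head(bad, 5))),
      class = "emstools_error_parse"
    )
  }
  m <- as.matrix(sp)
  rownames(m) <- ids
  as_incidence.matrix(m, abundance = abundance)
}

#' Drop empty sites and species from an incidence matrix
#'
#' Sites with no species and species with no occurrences carry no information
#' for any of the co-occurrence statistics and are removed. A warning reports
#' what was dropped; the removed labels are kept in the `dropped_sites` and
#' `dropped_species` attributes.
#'
#' @param x An incidence matrix (or anything [as_incidence()] accepts).
#' @param quiet Suppress the warning.
#' @return A cleaned `incidence` matrix (every row and column sum >= 1).
#' @export
clean_incidence <- function(x, quiet = FALSE) {
  m <- as_incidence(x)
  keep_r <- rowSums(m) > 0
  keep_c <- colSums(m) > 0
  if (!any(keep_r) || !any(keep_c)) {
    abort("incidence matrix is empty after removing all-zero rows and columns",
          class = "emstools_error_empty")
  }
  dropped_sites <- rownames(m)[!keep_r]
  dropped_species <- colnames(m)[!keep_c]
  if (!quiet && (length(dropped_sites) || length(dropped_species))) {
    warn(paste0(
      "dropped ", length(dropped_sites), " empty site(s) and ",
      length(dropped_species), " empty species"
    ))
  }
  out <- m[keep_r, keep_c, drop = FALSE]
  class(out) <- c("incidence", "matrix", "array")
  attr(out, "dropped_sites") <- dropped_sites
  attr(out, "dropped_species") <- dropped_species
  out
}

#' Read a site-by-species table from CSV
#'
#' Expects a header row of species names, a first column of site identifiers,
#' and nonnegative numeric cells. The matrix is cleaned on the way in (empty
#' rows/columns dropped with a warning).
#'
#' @inheritParams as_incidence
#' @param path Path to a CSV file.
#' @param quiet Suppress the cleaning warning.
#' @return A cleaned `incidence` matrix.
#' @export
read_incidence <- function(path, abundance = FALSE, site_col = 1, quiet = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  clean_incidence(as_incidence(as.data.frame(df), site_col = site_col,
                               abundance = abundance), quiet = quiet)
}

#' @export
print.incidence <- function(x, ...) {
  cat(sprintf(
    "<incidence> %d sites x %d species, %d presences (fill %.1f%%)\n",
    nrow(x), ncol(x), sum(x), 100 * mean(x)
  ))
  cat(sprintf("  site richness %d-%d, species occurrence %d-%d\n",
              min(rowSums(x)), max(rowSums(x)), min(colSums(x)), max(colSums(x))))
  invisible(x)
}

#' Long-format view of an incidence matrix
#'
#' @param x An `incidence` matrix.
#' @param ... Unused.
#' @return A tibble with columns `site_id`, `species_id`, `present`.
#' @importFrom tibble as_tibble
#' @export
as_tibble.incidence <- function(x, ...) {
  tibble::tibble(
    site_id = rep(rownames(x), times = ncol(x)),
    species_id = rep(colnames(x), each = nrow(x)),
    present = as.integer(x)
  )
}

#' Write an incidence matrix (or an ordered one) to CSV
#'
#' Writes the labelled matrix in the same layout [read_incidence()] accepts:
#' a `site_id` column followed by one column per species. Passing an
#' `ordered_incidence` writes the permuted matrix.
#'
#' @param x An `incidence` or `ordered_incidence` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_incidence <- function(x, path) {
  m <- if (inherits(x, "ordered_incidence")) x$matrix else as_incidence(x)
  df <- data.frame(site_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  readr::write_csv(df, path)
  invisible(path)
}

# strip class for fast numeric work
unwrap <- function(m) {
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  m
}
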