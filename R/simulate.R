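#' Simulate a metacommunity with known co-occurrence structure
#'
#' Generates a binary incidence matrix whose species ranges are organized
#' along a latent site gradient according to a chosen structural family,
#' together with an environmental table correlated with the gradient. This
#' is the package's test bed: every downstream stage (ordination, the three
#' elements, null inference, classification, the regression tree) can be
#' exercised against a known truth.
#'
#' Sites are placed uniformly at random on a gradient in \[0, 1\]. Species
#' ranges encode the structure:
#'
#' * `clementsian` — the gradient is cut into `compartments` equal blocks and
#'   every species occupies one whole block, so range boundaries coincide.
#' * `gleasonian` — independent uniform range midpoints with Beta-distributed
#'   widths (mean `mean_width`): boundaries fall independently.
#' * `evenly_spaced` — equal widths, midpoints evenly spaced: boundaries are
#'   maximally separated.
#' * `nested_clumped_loss`, `nested_random_loss`,
#'   `nested_hyperdispersed_loss` — ranges all start at the rich end of the
#'   gradient and extend to a species-specific loss position that is drawn
#'   from `loss_clusters` shared values (clumped), uniformly (random), or on
#'   a regular lattice (hyperdispersed). Within a range, sites are occupied
#'   with probability `within_occupancy`: a perfect common-end staircase is
#'   the unique binary matrix with its marginals, so imperfect occupancy is
#'   required for the fixed-sum null ensemble to have any variance at all
#'   (and is also the realistic condition).
#' * `checkerboard` — mutually exclusive species pairs confined to sparse
#'   shared site sets, refined by margin-preserving swap batches that
#'   increase post-ordination embedded absences. The refinement constructs
#'   the defining signal of the pattern — more embedded absences than a
#'   fixed-marginal randomization — which exclusivity alone does not produce
#'   (any property shared by the whole marginal class is invisible to the
#'   null).
#' * `random` — independent Bernoulli(`occupancy`) occupancy.
#'
#' A flip-noise rate can be applied last, and the matrix is cleaned (empty
#' sites/species dropped) before return. All randomness flows from `seed`.
#'
#' @param kind Structural family to generate (see Details).
#' @param n_sites,n_species Matrix dimensions before cleaning (at least 10
#'   each).
#' @param seed Integer seed; identical seeds reproduce the result bit for
#'   bit.
#' @param compartments Number of Clementsian compartments.
#' @param mean_width Mean species range width (fraction of the gradient) for
#'   the gradient families.
#' @param width_concentration Beta concentration of range widths.
#' @param occupancy Bernoulli occupancy for `random`; also the pair site-set
#'   density for `checkerboard`.
#' @param loss_clusters Number of shared loss positions for
#'   `nested_clumped_loss`.
#' @param within_occupancy Probability that a site inside a species' range is
#'   occupied (nested families).
#' @param checker_batches,checker_batch_size Refinement effort for
#'   `checkerboard`: number of swap batches and swaps per batch.
#' @param noise Cell flip probability applied after generation.
#' @param env Simulate an environmental table as well?
#' @param env_informative,env_noise_vars,env_noise_sd Passed to
#'   [simulate_environment()].
#'
#' @return An object of class `synthetic_metacommunity`: list with
#'   `incidence` (cleaned), `gradient` (named site positions for retained
#'   sites), `truth` (the generating family), `env` (tibble or `NULL`),
#'   `seed`, and `params`.
#' @examples
#' syn <- simulate_metacommunity("clementsian", n_sites = 30, n_species = 40,
#'                               seed = 42)
#' syn$truth
#' identical(syn$incidence,
#'           simulate_metacommunity("clementsian", n_sites = 30,
#'                                  n_species = 40, seed = 42)$incidence)
#' @export
simulate_metacommunity <- function(kind = c("clementsian", "gleasonian",
                                            "evenly_spaced",
                                            "nested_clumped_loss",
                                            "nested_random_loss",
                                            "nested_hyperdispersed_loss",
                                            "checkerboard", "random"),
                                   n_sites = 66L, n_species = 143L,
                                   seed = NULL,
                                   compartments = 3L,
                                   mean_width = 0.3,
                                   width_concentration = 10,
                                   occupancy = 0.3,
                                   loss_clusters = 4L,
                                   within_occupancy = 0.3,
                                   checker_batches = 120L,
                                   checker_batch_size = 40L,
                                   noise = 0,
                                   env = TRUE,
                                   env_informative = 3L,
                                   env_noise_vars = 4L,
                                   env_noise_sd = 0.1) {
  kind <- match.arg(kind)
  if (n_sites < 10 || n_species < 10) {
    abort("need n_sites >= 10 and n_species >= 10",
          class = "emstools_error_config")
  }
  if (compartments < 2 || compartments > n_species) {
    abort("compartments must be between 2 and n_species",
          class = "emstools_error_config")
  }
  if (loss_clusters < 2 || loss_clusters > n_species) {
    abort("loss_clusters must be between 2 and n_species",
          class = "emstools_error_config")
  }
  if (mean_width <= 0 || mean_width >= 1 || occupancy <= 0 || occupancy >= 1 ||
      within_occupancy <= 0 || within_occupancy > 1 || noise < 0 || noise > 0.5) {
    abort("generator rates out of range", class = "emstools_error_config")
  }
  params <- list(kind = kind, n_sites = n_sites, n_species = n_species,
                 compartments = compartments, mean_width = mean_width,
                 width_concentration = width_concentration,
                 occupancy = occupancy, loss_clusters = loss_clusters,
                 within_occupancy = within_occupancy, noise = noise)
  build <- function() {
    g <- runif(n_sites)
    m <- switch(kind,
      random = matrix(rbinom(n_sites * n_species, 1L, occupancy),
                      n_sites, n_species),
      clementsian = {
        comp <- sample(rep_len(seq_len(compartments), n_species))
        lo <- (comp - 1) / compartments
        hi <- comp / compartments
        (outer(g, lo, ">=") & outer(g, hi, "<=")) + 0L
      },
      gleasonian = {
        w <- rbeta(n_species, mean_width * width_concentration,
                   (1 - mean_width) * width_concentration)
        mid <- runif(n_species)
        (outer(g, pmax(0, mid - w / 2), ">=") &
           outer(g, pmin(1, mid + w / 2), "<=")) + 0L
      },
      evenly_spaced = {
        w <- mean_width
        mid <- seq(w / 2, 1 - w / 2, length.out = n_species)
        (outer(g, mid - w / 2, ">=") & outer(g, mid + w / 2, "<=")) + 0L
      },
      nested_clumped_loss = {
        centers <- seq(0.25, 1, length.out = loss_clusters)
        hi <- centers[sample(rep_len(seq_len(loss_clusters), n_species))]
        nested_matrix(g, hi, within_occupancy)
      },
      nested_random_loss = {
        hi <- runif(n_species, 0.25, 1)
        hi[1] <- 1
        nested_matrix(g, hi, within_occupancy)
      },
      nested_hyperdispersed_loss = {
        hi <- seq(0.25, 1, length.out = n_species)
        nested_matrix(g, sample(hi), within_occupancy)
      },
      checkerboard = checkerboard_matrix(n_sites, n_species, occupancy,
                                         checker_batches, checker_batch_size)
    )
    storage.mode(m) <- "integer"
    if (noise > 0) {
      fl <- matrix(runif(length(m)) < noise, nrow(m))
      m[fl] <- 1L - m[fl]
    }
    rownames(m) <- sprintf("site_%02d", seq_len(n_sites))
    colnames(m) <- sprintf("sp_%03d", seq_len(n_species))
    e <- if (env) {
      simulate_environment(stats::setNames(g, rownames(m)),
                           k_informative = env_informative,
                           k_noise = env_noise_vars,
                           noise_sd = env_noise_sd)
    }
    list(m = m, g = g, e = e)
  }
  res <- if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
  inc <- clean_incidence(as_incidence(res$m), quiet = TRUE)
  keep <- rownames(inc)
  envt <- if (env) res$e[match(keep, res$e$site_id), , drop = FALSE]
  structure(
    list(
      incidence = inc,
      gradient = stats::setNames(res$g[match(keep, rownames(res$m))], keep),
      truth = kind,
      env = if (env) tibble::as_tibble(envt),
      seed = seed,
      params = params
    ),
    class = "synthetic_metacommunity"
  )
}

# common-end ranges [0, hi] with within-range occupancy q
nested_matrix <- function(g, hi, q) {
  rng <- outer(g, hi, "<=")
  (rng & matrix(runif(length(rng)) < q, nrow(rng))) + 0L
}

# mutually exclusive sparse pairs, then margin-preserving swap batches that
# increase embedded absences after double ordination (the pattern's signal)
checkerboard_matrix <- function(n_sites, n_species, pair_occ,
                                batches, batch_size) {
  m <- matrix(0L, n_sites, n_species)
  for (p in seq_len(n_species %/% 2L)) {
    sites <- which(runif(n_sites) < pair_occ)
    if (length(sites) < 2L) sites <- sample.int(n_sites, 2L)
    a <- runif(length(sites)) < 0.5
    m[sites[a], 2L * p - 1L] <- 1L
    m[sites[!a], 2L * p] <- 1L
  }
  if (n_species %% 2L == 1L) {
    m[runif(n_sites) < pair_occ / 2, n_species] <- 1L
  }
  obj_emb <- function(mm) {
    keep_r <- rowSums(mm) > 0
    keep_c <- colSums(mm) > 0
    mo <- order_null_matrix(mm[keep_r, keep_c, drop = FALSE])
    sum(range_index(mo)$extent) + sum(range_index(t(mo))$extent) - 2L * sum(mo)
  }
  obj <- obj_emb(m)
  for (b in seq_len(batches)) {
    m2 <- m
    for (t in seq_len(batch_size)) {
      ij <- sample.int(n_sites, 2L)
      c10 <- which(m2[ij[1], ] == 1L & m2[ij[2], ] == 0L)
      c01 <- which(m2[ij[1], ] == 0L & m2[ij[2], ] == 1L)
      if (!length(c10) || !length(c01)) next
      j1 <- c10[sample.int(length(c10), 1L)]
      j2 <- c01[sample.int(length(c01), 1L)]
      m2[ij[1], j1] <- 0L; m2[ij[2], j1] <- 1L
      m2[ij[1], j2] <- 1L; m2[ij[2], j2] <- 0L
    }
    o2 <- obj_emb(m2)
    if (o2 > obj) {
      m <- m2
      obj <- o2
    }
  }
  m
}

#' @export
print.synthetic_metacommunity <- function(x, ...) {
  cat(sprintf("<synthetic_metacommunity> truth = %s, seed = %s\n",
              x$truth, x$seed %||% "NULL"))
  print(x$incidence)
  invisible(x)
}

#' Simulate environmental variables along a gradient
#'
#' Informative variables are monotone transforms of the latent gradient plus
#' Gaussian noise, rescaled into realistic ranges for the seven in-stream
#' predictors (turbidity in NTU, conductivity in uS/cm, pH, dissolved oxygen
#' in mg/L, temperature in degrees C, channel depth in cm, channel width in
#' m); noise variables are gradient-independent uniforms in the same ranges.
#' Variable names cycle through the seven predictors, informative first.
#'
#' @param gradient Numeric vector of site positions in \[0, 1\], named by
#'   site id.
#' @param k_informative Number of gradient-linked variables.
#' @param k_noise Number of gradient-independent variables.
#' @param noise_sd Noise standard deviation as a fraction of each variable's
#'   range.
#' @param seed Optional integer seed.
#' @return A tibble with `site_id` and one column per variable.
#' @export
simulate_environment <- function(gradient, k_informative = 3L, k_noise = 4L,
                                 noise_sd = 0.1, seed = NULL) {
  if (k_informative + k_noise < 1) {
    abort("need at least one environmental variable",
          class = "emstools_error_config")
  }
  n <- length(gradient)
  ids <- names(gradient) %||% sprintf("site_%02d", seq_len(n))
  specs <- list(
    turbidity = c(0, 20), conductivity = c(10, 200), ph = c(5.5, 8.5),
    dissolved_oxygen = c(5, 10), temperature = c(18, 26),
    depth = c(10, 60), width = c(1, 6)
  )
  transforms <- list(
    function(g) g,
    function(g) g^2,
    function(g) sqrt(g),
    function(g) stats::plogis(6 * (g - 0.5)),
    function(g) g^3
  )
  total <- k_informative + k_noise
  base_names <- names(specs)[(seq_len(total) - 1L) %% length(specs) + 1L]
  var_names <- make.unique(base_names, sep = "_")
  build <- function() {
    cols <- lapply(seq_len(total), function(i) {
      rng <- specs[[base_names[i]]]
      if (i <= k_informative) {
        tf <- transforms[[(i - 1L) %% length(transforms) + 1L]]
        rng[1] + diff(rng) * tf(gradient) +
          rnorm(n, 0, noise_sd * diff(rng))
      } else {
        runif(n, rng[1], rng[2])
      }
    })
    names(cols) <- var_names
    tibble::as_tibble(c(list(site_id = ids), cols))
  }
  if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
}
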