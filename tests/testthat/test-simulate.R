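test_that("generation is bit-reproducible from the seed", {
  a <- simulate_metacommunity("random", n_sites = 20, n_species = 20, seed = 31)
  b <- simulate_metacommunity("random", n_sites = 20, n_species = 20, seed = 31)
  expect_identical(a$incidence, b$incidence)
  expect_identical(a$env, b$env)
  c2 <- simulate_metacommunity("random", n_sites = 20, n_species = 20, seed = 32)
  expect_false(identical(a$incidence, c2$incidence))
  # occupancy close to the Bernoulli rate
  expect_gt(mean(a$incidence), 0.22)
  expect_lt(mean(a$incidence), 0.38)
})

test_that("infeasible generator parameters are rejected", {
  expect_error(simulate_metacommunity("random", n_sites = 5, n_species = 20),
               class = "emstools_error_config")
  expect_error(simulate_metacommunity("clementsian", compartments = 200,
                                      n_sites = 20, n_species = 20),
               class = "emstools_error_config")
  expect_error(simulate_metacommunity("random", occupancy = 0,
                                      n_sites = 20, n_species = 20),
               class = "emstools_error_config")
})

test_that("compartment ranges are perfectly coherent and clumped", {
  syn <- simulate_metacommunity("clementsian", n_sites = 30, n_species = 30,
                                seed = 12, env = FALSE)
  om <- suppressWarnings(doubly_order(syn$incidence))
  expect_equal(embedded_absences(om), 0L)
  mor <- morisita(boundary_counts(fill_ranges(om)),
                  n_species = ncol(syn$incidence))
  expect_gt(mor$index, 1)
})

test_that("checkerboard matrices carry more embedded absences than their null", {
  syn <- simulate_metacommunity("checkerboard", n_sites = 40, n_species = 60,
                                seed = 3, env = FALSE,
                                checker_batches = 60)
  om <- doubly_order(syn$incidence)
  obs <- embedded_absences(om)
  nd <- null_distribution(syn$incidence, "coherence", n_sim = 60, seed = 3)
  expect_gt(obs, nd$null_mean)
})

test_that("nested generators stay coherent with common-end ranges", {
  syn <- simulate_metacommunity("nested_clumped_loss", n_sites = 30,
                                n_species = 40, seed = 5, env = FALSE)
  m <- syn$incidence
  # species ranges on the true gradient all start at the gradient's rich end
  g <- syn$gradient
  occ_by_pos <- colSums(m[order(g), , drop = FALSE])
  expect_true(all(occ_by_pos >= 1))
  om <- suppressWarnings(doubly_order(m))
  res_emb <- embedded_absences(om)
  expect_lt(res_emb, embedded_absences(m[sample(nrow(m)), sample(ncol(m))]))
})

test_that("flip noise degrades but does not reverse the coherence signal", {
  for (i in 1:5) {
    syn <- simulate_metacommunity("clementsian", n_sites = 30, n_species = 40,
                                  seed = 100 + i, env = FALSE, noise = 0.02)
    res <- suppressWarnings(ems(syn$incidence, n_sim = 40, seed = i))
    expect_lt(res$coherence$z, 0)
  }
})

test_that("environmental tables track the gradient as configured", {
  g <- stats::setNames(runif(50), sprintf("s%02d", 1:50))
  e0 <- simulate_environment(g, k_informative = 1, k_noise = 0, noise_sd = 0,
                             seed = 2)
  expect_equal(cor(e0$turbidity, g, method = "spearman"), 1)
  expect_identical(e0, simulate_environment(g, k_informative = 1, k_noise = 0,
                                            noise_sd = 0, seed = 2))
  e <- simulate_environment(g, k_informative = 3, k_noise = 4, seed = 2)
  expect_equal(names(e), c("site_id", "turbidity", "conductivity", "ph",
                           "dissolved_oxygen", "temperature", "depth", "width"))
  expect_error(simulate_environment(g, k_informative = 0, k_noise = 0),
               class = "emstools_error_config")
})
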