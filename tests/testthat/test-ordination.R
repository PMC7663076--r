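test_that("reciprocal averaging agrees with the dense eigen oracle", {
  set.seed(11)
  checked <- 0
  for (i in 1:120) {
    m <- random_incidence(sample(3:8, 1), sample(3:8, 1), 0.45)
    o <- eigen_ca_oracle(m)
    # power iteration needs a spectral gap; disconnected matrices (eigenvalue
    # 1) have a rotatable eigenspace and are compared elsewhere
    if (o$gap < 0.05 || o$eigenvalue < 1e-8 || o$eigenvalue > 1 - 1e-8) next
    f <- suppressWarnings(reciprocal_averaging(m))
    err <- min(max(abs(f$site_scores - o$scores)),
               max(abs(f$site_scores + o$scores)))
    expect_lt(err, 1e-8)
    expect_equal(f$eigenvalue, o$eigenvalue, tolerance = 1e-8)
    checked <- checked + 1
  }
  expect_gt(checked, 50)
})

test_that("banded matrix yields monotone scores and zero-gap ordering", {
  ord <- reciprocal_averaging(banded3())
  expect_true(all(diff(ord$site_scores) > 0) || all(diff(ord$site_scores) < 0))
  expect_true(all(diff(ord$species_scores) > 0) ||
                all(diff(ord$species_scores) < 0))
  # standardization: weighted mean zero, weighted variance one
  w <- rowSums(banded3()) / sum(banded3())
  expect_equal(sum(w * ord$site_scores), 0, tolerance = 1e-12)
  expect_equal(sum(w * ord$site_scores^2), 1, tolerance = 1e-10)
  expect_gt(ord$eigenvalue, 0)
  expect_lte(ord$eigenvalue, 1)
})

test_that("degenerate and ill-conditioned inputs are signalled", {
  ones <- as_incidence(matrix(1, 3, 3))
  expect_error(reciprocal_averaging(ones), class = "emstools_error_degenerate")

  blocks <- as_incidence(rbind(cbind(matrix(1, 2, 2), matrix(0, 2, 2)),
                               cbind(matrix(0, 2, 2), matrix(1, 2, 2))))
  expect_warning(ordb <- reciprocal_averaging(blocks), "disconnected")
  expect_equal(length(unique(round(ordb$site_scores, 8))), 2L)

  expect_error(
    suppressWarnings(reciprocal_averaging(random_incidence(6, 6), max_iter = 2)),
    class = "emstools_error_convergence"
  )
})

test_that("double ordering recovers the band structure from a shuffle", {
  set.seed(3)
  b <- banded3()
  sh <- b[sample(3), sample(3)]
  class(sh) <- class(b)
  om <- doubly_order(sh)
  # oracle: the orderings minimizing embedded absences over all 3! x 3!
  # permutation pairs
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- min(vapply(perms, function(p) {
    min(vapply(perms, function(q) brute_embedded(sh[p, q]), numeric(1)))
  }, numeric(1)))
  expect_equal(brute_embedded(unclass(om$matrix)), best)
  expect_equal(best, 0)
})

test_that("double ordering is idempotent and preserves margins", {
  # exact idempotence on a tie-free case
  b <- banded3()
  ob <- doubly_order(b)
  ob2 <- doubly_order(ob$matrix)
  fwd <- identical(unclass(ob2$matrix)[, ], unclass(ob$matrix)[, ])
  bwd <- identical(unclass(ob2$matrix)[, ],
                   unclass(ob$matrix)[3:1, 3:1])
  expect_true(fwd || bwd)

  set.seed(21)
  for (i in 1:10) {
    m <- random_incidence(6, 7, 0.5)
    o <- eigen_ca_oracle(m)
    if (o$gap < 0.05 || o$eigenvalue > 1 - 1e-8) next
    om <- suppressWarnings(doubly_order(m))
    # permutation property: margins preserved as multisets
    expect_equal(sort(unname(rowSums(om$matrix))), sort(unname(rowSums(m))))
    expect_equal(sort(unname(colSums(om$matrix))), sort(unname(colSums(m))))
    # idempotence up to reflection and ties: re-ordinating an ordered matrix
    # yields monotone scores, so the ordering does not change
    ord2 <- suppressWarnings(reciprocal_averaging(om$matrix))
    s <- ord2$site_scores
    expect_true(!is.unsorted(s) || !is.unsorted(rev(s)))
    sp <- ord2$species_scores
    expect_true(!is.unsorted(sp) || !is.unsorted(rev(sp)))
    # and leaves the embedded-absence count unchanged
    expect_identical(
      embedded_absences(suppressWarnings(doubly_order(om$matrix))),
      embedded_absences(om)
    )
  }
})

test_that("degenerate shapes pass through double ordering unchanged", {
  one <- as_incidence(matrix(1, 1, 1))
  om <- doubly_order(one)
  expect_identical(dim(om$matrix), c(1L, 1L))
  expect_null(om$ordination)

  row1 <- as_incidence(matrix(c(1, 1, 0, 1), 1))
  expect_identical(doubly_order(row1)$col_order, 1:4)
})

test_that("ordination tidiers expose scores and fit summary", {
  ord <- reciprocal_averaging(banded3())
  td <- tidy(ord)
  expect_equal(nrow(td), 6L)
  expect_setequal(unique(td$type), c("site", "species"))
  gl <- glance(ord)
  expect_true(gl$converged)
  expect_equal(gl$n_sites, 3L)
})
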