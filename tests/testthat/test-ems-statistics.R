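test_that("embedded absences match their definition on canonical cases", {
  expect_equal(embedded_absences(matrix(c(1, 0, 1), ncol = 1)), 1L)
  expect_equal(embedded_absences(unclass(banded3())), 0L)
  expect_equal(embedded_absences(matrix(c(1, 0, 1), ncol = 1),
                                 mode = "columns_only"), 1L)
})

test_that("the three statistics agree with brute-force enumeration", {
  set.seed(5)
  for (i in 1:120) {
    m <- unclass(random_incidence(sample(2:6, 1), sample(2:6, 1), 0.5))
    expect_identical(embedded_absences(m), as.integer(brute_embedded(m)))
    expect_identical(embedded_absences(m, mode = "columns_only"),
                     as.integer(brute_embedded(m, mode = "columns_only")))
    mf <- unclass(fill_ranges(m))
    expect_equal(replacements(mf), brute_replacements(mf))
    if (nrow(m) >= 3) {
      expect_identical(unname(boundary_counts(mf)), brute_boundaries(mf))
    }
  }
})

test_that("range filling closes gaps and nothing else", {
  expect_equal(unname(unclass(fill_ranges(matrix(c(1, 0, 1), ncol = 1)))[, 1]),
               c(1L, 1L, 1L))
  expect_identical(unclass(fill_ranges(unclass(banded3())))[, ],
                   unclass(banded3())[, ])
  set.seed(8)
  for (i in 1:20) {
    m <- unclass(random_incidence(6, 6, 0.4))
    mf <- fill_ranges(m)
    expect_equal(embedded_absences(mf, mode = "columns_only"), 0L)
    # filling only adds presences inside ranges
    expect_true(all(mf >= m))
  }
})

test_that("replacements count species substitutions between site pairs", {
  expect_equal(replacements(matrix(c(1, 0, 0, 1), 2)), 1)   # checkerboard
  expect_equal(replacements(matrix(c(1, 1, 1, 0), 2)), 0)   # nested
  m <- matrix(c(1, 1, 0, 0, 1, 1), nrow = 3)                # ranges {1,2},{2,3}
  expect_equal(replacements(m), 1)
  expect_equal(brute_replacements(m), 1)
})

test_that("boundary tallies respect the interior-position convention", {
  b <- unclass(banded3())
  bc <- boundary_counts(b)
  # 2 boundaries per species minus those truncated at the matrix edges
  expect_equal(sum(bc), 2L * ncol(b) - 4L)

  everywhere <- cbind(b, 1L)   # species present at all sites
  expect_equal(sum(boundary_counts(everywhere)), sum(bc))

  twin <- cbind(b, b[, 2])     # coincident ranges double their tallies
  expect_equal(sum(boundary_counts(twin)), sum(bc) + 1L)

  expect_equal(length(boundary_counts(b, positions = "all")), nrow(b))
})

test_that("Morisita index, chi-square and df conventions behave", {
  expect_equal(morisita(c(1, 1, 1, 1), df = 3)$index, 0)
  m3 <- morisita(c(4, 0, 0), df = 2)
  expect_equal(m3$index, 3)
  expect_equal(m3$chi_square, 3 * 3 + 3 - 4)
  expect_error(morisita(c(1, 0, 0), df = 2), class = "emstools_error_degenerate")

  a <- morisita(c(3, 1, 2, 0), n_species = 10, df_convention = "table")
  expect_equal(a$df, 7L)
  b <- morisita(c(3, 1, 2, 0), df_convention = "sites")
  expect_equal(b$df, 3L)
  expect_true(a$p_value >= 0 && a$p_value <= 1)
  expect_equal(a$index, b$index)
})

test_that("z-test standardizes against the null ensemble", {
  r0 <- z_test(10, 10, 2)
  expect_equal(r0$z, 0)
  expect_equal(r0$p, 1)
  expect_equal(z_test(10 + 1.96 * 2, 10, 2)$p, 0.05, tolerance = 1e-3)
  expect_equal(z_test(4, 10, 2)$p, 0.0027, tolerance = 1e-4)
  expect_error(z_test(1, 1, 0), class = "emstools_error_degenerate")
})

test_that("the classification flowchart is total and reaches all 14 labels", {
  sig <- 0.001; ns <- 0.5
  labels <- character(0)
  for (co in list(c(ns, 1), c(sig, 2), c(sig, 0))) {       # p, obs (null = 1)
    for (tu in list(c(sig, 2), c(sig, 0), c(ns, 2), c(ns, 0))) {
      for (mo in list(c(sig, 3), c(sig, 0.2), c(ns, 1))) { # p, index
        labels <- c(labels, classify_structure(
          coherence_p = co[1], coherence_obs = co[2], coherence_null = 1,
          turnover_p = tu[1], turnover_obs = tu[2], turnover_null = 1,
          morisita_index = mo[2], morisita_p = mo[1], alpha = 0.05
        ))
      }
    }
  }
  expect_setequal(unique(labels), ems_structures())
  expect_length(ems_structures(), 14L)
})

test_that("published element combinations classify as reported", {
  # pool: significant coherence below null; turnover p = .576 below null;
  # Morisita 7.565 significant -> quasi-nested, clumped species loss
  expect_equal(classify_structure(
    coherence_p = 0.001, coherence_obs = 3188, coherence_null = 5936,
    turnover_p = 0.576, turnover_obs = 874297, turnover_null = 1089300,
    morisita_index = 7.565, morisita_p = 0.001
  ), "quasi_nested_clumped_loss")
  # core: turnover p = .47 above null; Morisita 5.05 -> quasi-Clementsian
  expect_equal(classify_structure(
    coherence_p = 0.001, coherence_obs = 2143, coherence_null = 3814,
    turnover_p = 0.47, turnover_obs = 462675, turnover_null = 374948,
    morisita_index = 5.05, morisita_p = 0.001
  ), "quasi_clementsian")
  # non-significant coherence dominates everything else
  expect_equal(classify_structure(
    coherence_p = 0.5, coherence_obs = 0, coherence_null = 10,
    turnover_p = 0.001, turnover_obs = 5, turnover_null = 1,
    morisita_index = 5, morisita_p = 0.001
  ), "random")
})

test_that("statistics are invariant under full reflection of the ordering", {
  set.seed(13)
  for (i in 1:15) {
    m <- unclass(random_incidence(5, 6, 0.5))
    r <- m[nrow(m):1, ncol(m):1]
    expect_identical(embedded_absences(m), embedded_absences(r))
    expect_equal(replacements(fill_ranges(m)), replacements(fill_ranges(r)))
    expect_identical(sort(unname(boundary_counts(fill_ranges(m)))),
                     sort(unname(boundary_counts(fill_ranges(r)))))
  }
})
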