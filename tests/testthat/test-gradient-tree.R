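step_data <- function(n = 40, noise_sd = 0, seed = 1, step_var = "dissolved_oxygen") {
  withr::with_seed(seed, {
    env <- tibble::tibble(
      site_id = sprintf("s%02d", seq_len(n)),
      turbidity = runif(n, 0, 20),
      conductivity = runif(n, 10, 200),
      ph = runif(n, 5.5, 8.5),
      dissolved_oxygen = runif(n, 5, 10),
      temperature = runif(n, 18, 26),
      depth = runif(n, 10, 60),
      width = runif(n, 1, 6)
    )
    x <- env[[step_var]]
    cutoff <- stats::median(x)
    y <- stats::setNames(ifelse(x < cutoff, 0, 1) + rnorm(n, 0, noise_sd),
                         env$site_id)
    list(env = env, y = y, cutoff = cutoff, x = x)
  })
}

test_that("a noiseless step function is recovered exactly at the root", {
  d <- step_data(seed = 3)
  fit <- fit_gradient_tree(d$env, d$y)
  root <- fit$nodes[fit$nodes$node_id == 1, ]
  expect_equal(root$variable, "dissolved_oxygen")
  lo <- max(d$x[d$x < d$cutoff]); hi <- min(d$x[d$x >= d$cutoff])
  expect_gt(root$threshold, lo)
  expect_lt(root$threshold, hi)
})

test_that("degenerate responses give a single leaf", {
  d <- step_data(seed = 4)
  fit <- fit_gradient_tree(d$env, stats::setNames(rep(2.5, 40), d$env$site_id))
  expect_equal(nrow(fit$nodes), 1L)
  expect_equal(fit$nodes$type, "leaf")
  expect_equal(fit$nodes$mean, 2.5)
})

test_that("splits never increase total SSE and saturate at zero", {
  d <- step_data(noise_sd = 0.3, seed = 7)
  fit <- fit_gradient_tree(d$env, d$y)
  gl <- glance(fit)
  expect_lte(gl$tree_sse, gl$root_sse + 1e-9)
  # every split strictly reduces SSE
  nodes <- fit$nodes
  for (id in nodes$node_id[nodes$type == "split"]) {
    parent <- nodes[nodes$node_id == id, ]
    kids <- nodes[nodes$node_id %in% c(2 * id, 2 * id + 1), ]
    expect_lt(sum(kids$sse), parent$sse)
  }
  # leaf sizes partition the sites
  expect_equal(sum(nodes$n[nodes$type == "leaf"]), 40L)

  # unconstrained tree drives training SSE to zero on distinct responses
  d2 <- step_data(noise_sd = 0.2, seed = 8)
  full <- fit_gradient_tree(d2$env, d2$y, min_leaf = 1L, max_depth = 30L, cp = 0)
  expect_equal(glance(full)$tree_sse, 0, tolerance = 1e-20)
})

test_that("the tree agrees with rpart on clean continuous data", {
  d <- step_data(noise_sd = 0.25, seed = 11)
  fit <- fit_gradient_tree(d$env, d$y, min_leaf = 5, max_depth = 3, cp = 0.01)
  df <- data.frame(y = unname(d$y), d$env[-1])
  rp <- rpart::rpart(y ~ ., data = df, control = rpart::rpart.control(
    minsplit = 10, minbucket = 5, maxdepth = 3, cp = 0.01, xval = 0,
    maxsurrogate = 0, usesurrogate = 0, maxcompete = 0
  ))
  root <- fit$nodes[fit$nodes$node_id == 1, ]
  rp_var <- as.character(rp$frame$var[1])
  rp_thr <- rp$splits[1, "index"]
  expect_equal(root$variable, rp_var)
  expect_equal(root$threshold, unname(rp_thr), tolerance = 1e-8)
  # same number of leaves under the same controls
  expect_equal(sum(fit$nodes$type == "leaf"), sum(rp$frame$var == "<leaf>"))
})

test_that("group assignment routes sites to consistent leaves", {
  d <- step_data(noise_sd = 0.1, seed = 13)
  fit <- fit_gradient_tree(d$env, d$y)
  gr <- assign_groups(fit, d$env)
  expect_identical(gr, fit$groups)
  # every assigned leaf mean is the mean response of the leaf's members
  means <- tapply(unname(d$y), gr$leaf_id, mean)
  expect_equal(as.numeric(means[as.character(gr$leaf_id)]), gr$leaf_mean,
               tolerance = 1e-12)

  one_split <- fit_gradient_tree(
    tibble::tibble(site_id = sprintf("t%d", 1:20), x = seq(0, 1, length.out = 20)),
    stats::setNames(rep(c(0, 1), each = 10), sprintf("t%d", 1:20))
  )
  newx <- tibble::tibble(site_id = "probe", x = 0.3)
  expect_equal(assign_groups(one_split, newx)$leaf_id, 2L)

  expect_error(assign_groups(one_split, tibble::tibble(site_id = "p", z = 1)),
               class = "emstools_error_routing")
})

test_that("misalignment and missing values are handled as documented", {
  d <- step_data(seed = 17)
  y_bad <- d$y
  names(y_bad)[1] <- "elsewhere"
  expect_error(fit_gradient_tree(d$env, y_bad),
               class = "emstools_error_alignment")

  env_na <- d$env
  env_na$dissolved_oxygen[3] <- NA
  expect_warning(fit <- fit_gradient_tree(env_na, d$y), "missing")
  expect_equal(sum(fit$nodes$n[fit$nodes$type == "leaf"]), 39L)
  expect_warning(assign_groups(fit, env_na), "not routed")
})
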