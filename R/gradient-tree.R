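#' Fit a regression tree of ordination scores on environmental predictors
#'
#' Greedy binary CART with a univariate response: at each node the
#' (variable, threshold) pair maximizing the reduction in the sum of squared
#' deviations is chosen, with thresholds placed at midpoints between adjacent
#' observed predictor values. Splitting stops when the depth limit is
#' reached, the node is too small (`< 2 * min_leaf`), or the best split's SSE
#' reduction relative to the root SSE falls below `cp`. Ties in SSE reduction
#' are broken by predictor column order, then by the lower threshold, so
#' fitted trees are deterministic.
#'
#' Typical use is to relate first-axis correspondence-analysis site scores to
#' in-stream environmental variables (turbidity, conductivity, pH, dissolved
#' oxygen, temperature, channel depth and width), identifying the
#' environmental thresholds that partition the site groups underlying a
#' metacommunity gradient.
#'
#' Missing predictor values: no surrogate splits are used. Sites missing the
#' value of a chosen split variable are dropped from that subtree with a
#' warning.
#'
#' @param env A data frame with a `site_col` identifier column and numeric
#'   predictor columns.
#' @param scores Response values: a numeric vector named by site id, or a
#'   two-column data frame (site id, score). Sites must match `env` exactly.
#' @param min_leaf Minimum number of sites in a leaf.
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param cp Complexity parameter: minimum SSE reduction, as a fraction of
#'   the root SSE, for a split to be kept.
#' @param site_col Name of the site-id column in `env`.
#' @return An object of class `gradient_tree`: list with `nodes` (a tibble:
#'   `node_id`, `parent`, `depth`, `type`, `variable`, `threshold`, `n`,
#'   `mean`, `sse`), `groups` (training-site leaf assignments, see
#'   [assign_groups()]), `response`, and `control`.
#' @examples
#' env <- data.frame(site_id = paste0("s", 1:40), x = seq(0, 1, length.out = 40),
#'                   noise = runif(40))
#' y <- stats::setNames(ifelse(env$x < 0.5, 0, 1), env$site_id)
#' fit <- fit_gradient_tree(env, y)
#' fit$nodes$variable[1]  # root splits on x
#' @export
fit_gradient_tree <- function(env, scores, min_leaf = 5L, max_depth = 5L,
                              cp = 0.01, site_col = "site_id") {
  if (!site_col %in% names(env)) {
    abort(sprintf("column '%s' not found in env", site_col),
          class = "emstools_error_alignment")
  }
  ids <- as.character(env[[site_col]])
  if (is.data.frame(scores)) {
    y <- stats::setNames(as.numeric(scores[[2]]), as.character(scores[[1]]))
  } else {
    y <- scores
  }
  if (is.null(names(y))) {
    if (length(y) != length(ids)) {
      abort("unnamed scores must have one value per env row",
            class = "emstools_error_alignment")
    }
    names(y) <- ids
  }
  off <- c(setdiff(ids, names(y)), setdiff(names(y), ids))
  if (length(off)) {
    abort(paste0("site ids of env and scores do not match: ",
                 toString(head(off, 8))),
          class = "emstools_error_alignment")
  }
  y <- unname(y[ids])
  vars <- setdiff(names(env), site_col)
  bad <- vars[!vapply(env[vars], is.numeric, logical(1))]
  if (length(bad)) {
    abort(paste0("non-numeric predictor(s): ", toString(bad)),
          class = "emstools_error_parse")
  }
  X <- as.matrix(env[vars])
  n <- length(y)
  if (n < 2L * min_leaf) {
    abort("need at least 2 * min_leaf sites", class = "emstools_error_config")
  }

  root_sse <- sum((y - mean(y))^2)
  nodes <- list()
  leaf_of <- rep(NA_integer_, n)
  dropped <- character(0)

  grow <- function(idx, depth, id, parent) {
    yy <- y[idx]
    mu <- mean(yy)
    sse <- sum((yy - mu)^2)
    node <- list(node_id = id, parent = parent, depth = depth, type = "leaf",
                 variable = NA_character_, threshold = NA_real_,
                 n = length(idx), mean = mu, sse = sse)
    make_leaf <- function() {
      nodes[[length(nodes) + 1L]] <<- node
      leaf_of[idx] <<- id
    }
    if (depth >= max_depth || length(idx) < 2L * min_leaf || sse <= 0) {
      make_leaf()
      return(invisible())
    }
    best <- NULL
    for (v in seq_along(vars)) {
      xv <- X[idx, v]
      ok <- !is.na(xv)
      if (sum(ok) < 2L * min_leaf) next
      xo <- xv[ok]; yo <- yy[ok]
      o <- order(xo)
      xs <- xo[o]; ys <- yo[o]
      k <- length(ys)
      csy <- cumsum(ys); csy2 <- cumsum(ys^2)
      tot_y <- csy[k]; tot_y2 <- csy2[k]
      sse_ok <- tot_y2 - tot_y^2 / k
      cut <- which(diff(xs) > 0)                     # split after position cut
      cut <- cut[cut >= min_leaf & (k - cut) >= min_leaf]
      if (!length(cut)) next
      sse_l <- csy2[cut] - csy[cut]^2 / cut
      sse_r <- (tot_y2 - csy2[cut]) - (tot_y - csy[cut])^2 / (k - cut)
      gain <- sse_ok - (sse_l + sse_r)
      b <- which.max(gain)                           # first max: lower threshold
      if (is.null(best) || gain[b] > best$gain + 1e-12) {
        best <- list(gain = gain[b], var = v,
                     threshold = (xs[cut[b]] + xs[cut[b] + 1L]) / 2,
                     n_na = sum(!ok))
      }
    }
    if (is.null(best) || best$gain < cp * root_sse || best$gain <= 0) {
      make_leaf()
      return(invisible())
    }
    xv <- X[idx, best$var]
    na_here <- is.na(xv)
    if (any(na_here)) {
      dropped <<- c(dropped, ids[idx[na_here]])
      warn(sprintf(
        "%d site(s) missing '%s' dropped from the subtree at node %d",
        sum(na_here), vars[best$var], id
      ))
    }
    node$type <- "split"
    node$variable <- vars[best$var]
    node$threshold <- best$threshold
    nodes[[length(nodes) + 1L]] <<- node
    grow(idx[!na_here & xv <= best$threshold], depth + 1L, 2L * id, id)
    grow(idx[!na_here & xv > best$threshold], depth + 1L, 2L * id + 1L, id)
  }
  grow(seq_len(n), 0L, 1L, NA_integer_)

  nodes_tb <- dplyr::bind_rows(lapply(nodes, tibble::as_tibble))
  nodes_tb <- dplyr::arrange(nodes_tb, .data$node_id)
  leaf_mean <- stats::setNames(nodes_tb$mean, nodes_tb$node_id)
  groups <- tibble::tibble(
    site_id = ids,
    leaf_id = leaf_of,
    leaf_mean = unname(leaf_mean[as.character(leaf_of)])
  )
  structure(
    list(nodes = nodes_tb, groups = groups,
         response = y, root_sse = root_sse,
         control = list(min_leaf = min_leaf, max_depth = max_depth, cp = cp,
                        site_col = site_col, variables = vars),
         dropped_sites = dropped),
    class = "gradient_tree"
  )
}

#' Route sites through a fitted gradient tree
#'
#' Assigns each site of an environmental table to the leaf it falls in,
#' reporting the leaf's mean response (the group mean ordination score).
#' Sites with a missing value at a needed split get `NA` with a warning; a
#' predictor column missing entirely is an error.
#'
#' @param tree A `gradient_tree`.
#' @param env A data frame with the tree's split variables and the same
#'   site-id column used at fit time.
#' @return A tibble `site_id`, `leaf_id`, `leaf_mean`.
#' @export
assign_groups <- function(tree, env) {
  site_col <- tree$control$site_col
  if (!site_col %in% names(env)) {
    abort(sprintf("column '%s' not found in env", site_col),
          class = "emstools_error_alignment")
  }
  nodes <- tree$nodes
  used <- unique(nodes$variable[nodes$type == "split"])
  miss <- setdiff(used, names(env))
  if (length(miss)) {
    abort(paste0("predictor(s) required by the tree are missing: ",
                 toString(miss)),
          class = "emstools_error_routing")
  }
  node_row <- function(id) nodes[match(id, nodes$node_id), ]
  route <- function(i) {
    id <- 1L
    repeat {
      nd <- node_row(id)
      if (nd$type == "leaf") return(id)
      xv <- env[[nd$variable]][i]
      if (is.na(xv)) return(NA_integer_)
      id <- if (xv <= nd$threshold) 2L * id else 2L * id + 1L
    }
  }
  leaf_id <- vapply(seq_len(nrow(env)), route, integer(1))
  if (anyNA(leaf_id)) {
    warn(sprintf("%d site(s) with missing split values were not routed",
                 sum(is.na(leaf_id))))
  }
  leaf_mean <- stats::setNames(nodes$mean, nodes$node_id)
  tibble::tibble(
    site_id = as.character(env[[site_col]]),
    leaf_id = leaf_id,
    leaf_mean = unname(leaf_mean[as.character(leaf_id)])
  )
}

#' @export
print.gradient_tree <- function(x, digits = 3, ...) {
  cat(format_tree(x, digits = digits), sep = "\n")
  invisible(x)
}

# indented-text rendering
format_tree <- function(tree, digits = 3) {
  nodes <- tree$nodes
  out <- character(0)
  walk <- function(id, indent) {
    nd <- nodes[match(id, nodes$node_id), ]
    pad <- strrep("  ", indent)
    if (nd$type == "leaf") {
      out <<- c(out, sprintf("%s* leaf %d: n = %d, mean = %s", pad, id, nd$n,
                             format(nd$mean, digits = digits)))
    } else {
      out <<- c(out, sprintf("%s%s <= %s (n = %d)", pad, nd$variable,
                             format(nd$threshold, digits = digits), nd$n))
      walk(2L * id, indent + 1L)
      out <<- c(out, sprintf("%s%s > %s", pad, nd$variable,
                             format(nd$threshold, digits = digits)))
      walk(2L * id + 1L, indent + 1L)
    }
  }
  walk(1L, 0L)
  out
}

#' @export
tidy.gradient_tree <- function(x, ...) x$nodes

#' @export
glance.gradient_tree <- function(x, ...) {
  leaves <- x$nodes[x$nodes$type == "leaf", ]
  tibble::tibble(
    n_sites = length(x$response),
    n_leaves = nrow(leaves),
    n_splits = sum(x$nodes$type == "split"),
    root_sse = x$root_sse,
    tree_sse = sum(leaves$sse),
    r_squared = 1 - sum(leaves$sse) / x$root_sse
  )
}

# nested-list form (for JSON export)
tree_as_list <- function(tree) {
  nodes <- tree$nodes
  build <- function(id) {
    nd <- nodes[match(id, nodes$node_id), ]
    if (nd$type == "leaf") {
      list(node = id, type = "leaf", n = nd$n, mean = nd$mean)
    } else {
      list(node = id, type = "split", variable = nd$variable,
           threshold = nd$threshold, n = nd$n, mean = nd$mean,
           left = build(2L * id), right = build(2L * id + 1L))
    }
  }
  build(1L)
}

#' Plot group mean scores of a gradient tree
#'
#' @param object A `gradient_tree`.
#' @param ... Unused.
#' @return A ggplot object: one bar per leaf, height = group mean ordination
#'   score, width annotated with the group size.
#' @export
autoplot.gradient_tree <- function(object, ...) {
  leaves <- object$nodes[object$nodes$type == "leaf", ]
  df <- tibble::tibble(
    leaf = factor(leaves$node_id, levels = leaves$node_id),
    mean = leaves$mean,
    n = leaves$n
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$leaf, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0("n=", .data$n)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "site group (tree leaf)",
                  y = "mean CA axis-1 score") +
    ggplot2::theme_minimal()
}
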