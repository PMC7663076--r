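# Independent brute-force oracles and small fixtures. These re-derive every
# statistic from its definition with plain loops, deliberately sharing no
# code with the package internals.

banded3 <- function() {
  as_incidence(matrix(c(1, 0, 0, 1, 1, 0, 0, 1, 1), nrow = 3,
                      dimnames = list(paste0("s", 1:3), paste0("sp", 1:3))))
}

random_incidence <- function(n, s, p = 0.5) {
  repeat {
    m <- matrix(rbinom(n * s, 1, p), n, s)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0) && !all(m == 1)) {
      return(as_incidence(m))
    }
  }
}

# embedded absences from the definition: zeros strictly between the first and
# last presence of each column (and each row for mode "both")
brute_embedded <- function(m, mode = "both") {
  count_gaps <- function(v) {
    idx <- which(v == 1)
    if (length(idx) < 2) return(0L)
    sum(v[idx[1]:idx[length(idx)]] == 0)
  }
  tot <- sum(apply(m, 2, count_gaps))
  if (mode == "both") tot <- tot + sum(apply(m, 1, count_gaps))
  tot
}

# replacements by enumerating site pairs: a pair of species replaces one
# another at a pair of sites when each site holds exactly one of the two
# (different ones); counted once per unordered species pair as the product
# definition requires
brute_replacements <- function(mf) {
  s <- ncol(mf)
  tot <- 0
  for (i in seq_len(s - 1)) {
    for (j in (i + 1):s) {
      in_i <- which(mf[, i] == 1 & mf[, j] == 0)
      in_j <- which(mf[, j] == 1 & mf[, i] == 0)
      tot <- tot + length(in_i) * length(in_j)
    }
  }
  tot
}

# boundary tallies from the definition: each species' first and last occupied
# site, counted only at interior positions of the ordered site axis
brute_boundaries <- function(mf) {
  n <- nrow(mf)
  tal <- integer(n)
  for (j in seq_len(ncol(mf))) {
    idx <- which(mf[, j] == 1)
    if (!length(idx)) next
    f <- idx[1]; l <- idx[length(idx)]
    if (f > 1 && f < n) tal[f] <- tal[f] + 1L
    if (l > 1 && l < n) tal[l] <- tal[l] + 1L
  }
  tal[2:(n - 1)]
}

# full eigen-decomposition of the symmetrized CA operator
eigen_ca_oracle <- function(m) {
  r <- rowSums(m); cc <- colSums(m)
  S <- diag(1 / sqrt(r), nrow = nrow(m)) %*% m %*% diag(1 / cc, nrow = ncol(m)) %*%
    t(m) %*% diag(1 / sqrt(r), nrow = nrow(m))
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 2] / sqrt(r)
  w <- r / sum(r)
  v <- v - sum(w * v)
  v <- v / sqrt(sum(w * v^2))
  if (v[1] < 0) v <- -v
  gap <- if (nrow(m) > 2) (e$values[2] - e$values[3]) / max(e$values[2], 1e-12) else 1
  list(scores = v, eigenvalue = e$values[2], gap = gap)
}

# all binary matrices with the same row and column sums as m (tiny cases)
enumerate_margin_class <- function(m) {
  n <- nrow(m); s <- ncol(m)
  r <- rowSums(m); cc <- colSums(m)
  out <- list()
  for (bits in 0:(2^(n * s) - 1)) {
    cand <- matrix(as.integer(intToBits(bits)[seq_len(n * s)]), n, s)
    if (all(rowSums(cand) == r) && all(colSums(cand) == cc)) {
      out[[length(out) + 1]] <- cand
    }
  }
  out
}

table1_guilds <- function(species_ids) {
  # synthetic guild table cycling three guilds over the species pool
  tibble::tibble(
    species_id = species_ids,
    guild = rep_len(c("detritivore", "insectivore", "omnivore"),
                    length(species_ids))
  )
}
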