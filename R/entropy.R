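# Shannon-entropy machinery behind H2' and d': heuristic minimisers used on
# real-size networks, plus exhaustive-enumeration counterparts that serve as
# exact references on small problems.

#' Shannon entropy of a (possibly unnormalized) non-negative vector
#'
#' Natural logarithm; cells equal to zero contribute nothing (0 * log 0 == 0).
#' The input is normalized to sum to one before the entropy is taken.
#'
#' @param x Non-negative numeric vector or matrix.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0)) abort("entropy requires non-negative input",
                        class = "pollennet_usage_error")
  s <- sum(x)
  if (s <= 0) abort("entropy of an all-zero vector is undefined",
                    class = "pollennet_usage_error")
  p <- x[x > 0] / s
  -sum(p * log(p))
}

#' Minimum-entropy matrix with fixed marginals (multi-start greedy)
#'
#' Finds a low-entropy non-negative matrix with the given row and column
#' totals by a deterministic multi-start concentration heuristic: for every
#' feasible choice of first cell, allocate `min(remaining row, remaining
#' column)` there, then repeatedly allocate the largest such amount to the
#' cell where it is largest (ties broken by lowest row index, then lowest
#' column index); the lowest-entropy completion over all starts is kept.
#' On every enumerated family of integer marginals with totals up to 12 this
#' matches the exhaustive minimum (see [min_entropy_exact()]), but it is a
#' heuristic: global optimality is not guaranteed in general.
#'
#' Works for real-valued totals as well; integer totals yield an integer
#' matrix.
#'
#' @param row_totals,col_totals Non-negative totals with equal sums.
#' @return The allocated matrix, with attribute `"entropy"`.
#' @export
min_entropy_greedy <- function(row_totals, col_totals) {
  check_marginals(row_totals, col_totals)
  n <- length(row_totals); k <- length(col_totals)
  best <- NULL
  best_e <- Inf
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      a <- min(row_totals[i], col_totals[j])
      if (a <= 0) next
      M <- matrix(0, n, k)
      M[i, j] <- a
      r <- row_totals; cl <- col_totals
      r[i] <- r[i] - a; cl[j] <- cl[j] - a
      M <- greedy_fill(M, r, cl)
      e <- shannon_entropy(M)
      if (e < best_e - 1e-12) {
        best_e <- e
        best <- M
      }
    }
  }
  attr(best, "entropy") <- best_e
  best
}

greedy_fill <- function(M, r, cl) {
  while (sum(r) > 1e-12) {
    A <- outer(r, cl, pmin)
    idx <- which(A == max(A), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    a <- A[idx[1], idx[2]]
    M[idx[1], idx[2]] <- M[idx[1], idx[2]] + a
    r[idx[1]] <- r[idx[1]] - a
    cl[idx[2]] <- cl[idx[2]] - a
  }
  M
}

#' Exact minimum-entropy matrix by exhaustive enumeration
#'
#' Enumerates every non-negative integer matrix with the given marginals and
#' returns the minimum entropy. Exponential cost; intended as an exact
#' reference for small problems (totals up to roughly 15).
#'
#' @inheritParams min_entropy_greedy
#' @return Minimum entropy (nats) over all integer matrices with the given
#'   marginals.
#' @export
min_entropy_exact <- function(row_totals, col_totals) {
  check_marginals(row_totals, col_totals)
  if (any(row_totals != round(row_totals)) || any(col_totals != round(col_totals))) {
    abort("exact enumeration requires integer marginals",
          class = "pollennet_usage_error")
  }
  m <- sum(row_totals)
  best <- Inf
  rec <- function(rows_left, cols_left, acc_cells) {
    if (length(rows_left) == 1) {
      cells <- c(acc_cells, cols_left)
      e <- shannon_entropy(cells / m)
      if (e < best) best <<- e
      return(invisible())
    }
    for (row in compositions(rows_left[1], cols_left)) {
      rec(rows_left[-1], cols_left - row, c(acc_cells, row))
    }
    invisible()
  }
  rec(row_totals, col_totals, numeric(0))
  best
}

#' Enumerate compositions of an integer into capped parts
#'
#' All vectors of non-negative integers summing to `n` with `parts[i] <=
#' caps[i]`. Used by the exhaustive entropy and d-minimum references.
#'
#' @param n Non-negative integer total.
#' @param caps Integer vector of per-part caps.
#' @return List of integer vectors.
#' @export
compositions <- function(n, caps) {
  k <- length(caps)
  if (k == 1) {
    if (n <= caps) return(list(n))
    return(list())
  }
  out <- list()
  for (x in 0:min(n, caps[1])) {
    for (rest in compositions(n - x, caps[-1])) {
      out[[length(out) + 1]] <- c(x, rest)
    }
  }
  out
}

# Kullback-Leibler divergence of an allocation of A grains against partner
# availability q (cells with zero allocation contribute nothing).
kl_divergence <- function(alloc, total, q) {
  p <- alloc / total
  i <- p > 0
  sum(p[i] * log(p[i] / q[i]))
}

#' Heuristic minimum of the species-level KL divergence d
#'
#' Minimum of `d = sum p_j log(p_j / q_j)` over non-negative integer
#' allocations of `total` grains across partners with availability `q`:
#' allocate proportionally to `q`, repair rounding by adding/removing single
#' grains where that costs least, then move single grains between partners
#' until no move lowers d (deterministic; first-improvement scan in index
#' order).
#'
#' @param total Positive integer number of interaction events to allocate.
#' @param q Partner availability distribution (positive, sums to 1).
#' @return List with `alloc` (integer vector) and `d` (the achieved minimum).
#' @export
d_min_heuristic <- function(total, q) {
  stopifnot(total >= 1, all(q > 0))
  q <- q / sum(q)
  alloc <- round(total * q)
  while (sum(alloc) > total) {
    cand <- which(alloc > 0)
    vals <- vapply(cand, function(j) {
      a <- alloc; a[j] <- a[j] - 1L
      kl_divergence(a, total, q)
    }, numeric(1))
    j <- cand[which.min(vals)]
    alloc[j] <- alloc[j] - 1L
  }
  while (sum(alloc) < total) {
    vals <- vapply(seq_along(alloc), function(j) {
      a <- alloc; a[j] <- a[j] + 1L
      kl_divergence(a, total, q)
    }, numeric(1))
    j <- which.min(vals)
    alloc[j] <- alloc[j] + 1L
  }
  repeat {
    best <- kl_divergence(alloc, total, q)
    improved <- FALSE
    for (j in which(alloc > 0)) {
      for (k in seq_along(alloc)) {
        if (j == k) next
        a <- alloc; a[j] <- a[j] - 1L; a[k] <- a[k] + 1L
        v <- kl_divergence(a, total, q)
        if (v < best - 1e-12) {
          alloc <- a
          best <- v
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(alloc = alloc, d = kl_divergence(alloc, total, q))
}

#' Exact minimum of the species-level KL divergence d by enumeration
#'
#' Enumerates every allocation of `total` grains across the partners and
#' returns the minimum divergence. Exponential cost; exact reference for
#' small problems.
#'
#' @inheritParams d_min_heuristic
#' @return The minimum d over all integer allocations.
#' @export
d_min_exact <- function(total, q) {
  stopifnot(total >= 1, all(q > 0))
  q <- q / sum(q)
  min(vapply(compositions(total, rep(total, length(q))),
             function(a) kl_divergence(a, total, q), numeric(1)))
}

check_marginals <- function(row_totals, col_totals) {
  if (any(row_totals < 0) || any(col_totals < 0)) {
    abort("marginal totals must be non-negative", class = "pollennet_usage_error")
  }
  if (abs(sum(row_totals) - sum(col_totals)) > 1e-8) {
    abort("row and column totals must have equal sums",
          class = "pollennet_usage_error")
  }
  if (sum(row_totals) <= 0) {
    abort("marginal totals must have positive sum",
          class = "pollennet_usage_error")
  }
}
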