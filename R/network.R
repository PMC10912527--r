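#' Build a bipartite plant-pollinator network from an edge list
#'
#' Assembles the weighted plant x pollinator interaction matrix. Duplicate
#' edges are merged by summing weights. With `binarize = TRUE` every positive
#' weight is replaced by 1, the qualitative convention used for presence/
#' absence interaction networks.
#'
#' @param edges Data frame with columns `plant`, `pollinator` and optionally
#'   `weight` (default 1).
#' @param binarize Replace positive weights with 1?
#' @return An object of class `bipartite_network`: a list with the interaction
#'   `matrix` (plants in rows, pollinators in columns, labels sorted) and the
#'   `binarized` flag.
#' @examples
#' net <- build_network(data.frame(plant = c("A", "B"), pollinator = c("X", "Y"),
#'                                 weight = c(3, 1)))
#' net
#' @export
build_network <- function(edges, binarize = FALSE) {
  edges <- as_tibble(edges)
  if (nrow(edges) == 0) {
    abort("edge list is empty", class = "pollennet_usage_error")
  }
  if (!"weight" %in% names(edges)) edges$weight <- 1
  if (any(edges$weight < 0)) {
    abort("edge weights must be non-negative", class = "pollennet_validation_error")
  }
  edges <- edges %>%
    group_by(.data$plant, .data$pollinator) %>%
    summarise(weight = sum(.data$weight), .groups = "drop")
  plants <- sort(unique(edges$plant))
  polls <- sort(unique(edges$pollinator))
  A <- matrix(0, length(plants), length(polls), dimnames = list(plants, polls))
  A[cbind(match(edges$plant, plants), match(edges$pollinator, polls))] <-
    edges$weight
  if (binarize) A[A > 0] <- 1
  structure(list(matrix = A, binarized = binarize),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  A <- x$matrix
  cat(sprintf(
    "Bipartite network: %d plants x %d pollinators, %d links, total weight %g%s\n",
    nrow(A), ncol(A), sum(A > 0), sum(A),
    if (x$binarized) " (binarized)" else ""))
  invisible(x)
}

#' Mean number of links per species
#'
#' Number of realized links divided by the total number of species in both
#' modes, `L / (n_plants + n_pollinators)`.
#'
#' @param network A `bipartite_network`.
#' @return A single number.
#' @export
links_per_species <- function(network) {
  A <- network$matrix
  sum(A > 0) / (nrow(A) + ncol(A))
}

#' Network-level specialization H2'
#'
#' The two-dimensional Shannon-entropy specialization index. With
#' `p_ij = a_ij / m`, the observed entropy `H2 = -sum p_ij log p_ij` is
#' standardized between its maximum (the entropy of the outer product of the
#' marginal distributions, the exact supremum under independence) and a
#' minimum found over matrices sharing the observed marginals:
#' `H2' = (H2_max - H2) / (H2_max - H2_min)`, so 0 means maximal
#' generalization and 1 maximal specialization.
#'
#' `bounds = "integer"` (default) takes the minimum over non-negative integer
#' matrices via the multi-start greedy of [min_entropy_greedy()] and requires
#' integer weights; `bounds = "continuous"` runs the same allocation on the
#' real-valued marginals.
#'
#' @param network A `bipartite_network`.
#' @param bounds `"integer"` or `"continuous"` convention for `H2_min`.
#' @return A one-row tibble: `h2_observed`, `h2_max`, `h2_min`, `h2_prime`.
#' @export
h2_prime <- function(network, bounds = c("integer", "continuous")) {
  bounds <- arg_match(bounds)
  A <- network$matrix
  m <- sum(A)
  if (m <= 0) abort("network has zero total weight", class = "pollennet_usage_error")
  r <- rowSums(A)
  cl <- colSums(A)
  if (bounds == "integer" && any(A != round(A))) {
    abort(paste0("integer H2_min requires integer weights; ",
                 "round the weights or use bounds = 'continuous'"),
          class = "pollennet_usage_error")
  }
  h_obs <- shannon_entropy(A)
  h_max <- shannon_entropy(r) + shannon_entropy(cl)
  h_min <- attr(min_entropy_greedy(r, cl), "entropy")
  # the observed matrix shares the marginals, so it bounds the minimum from
  # above; the independence product bounds the joint entropy from above
  h_min <- min(h_min, h_obs)
  h_max <- max(h_max, h_obs)
  h2p <- if (h_max - h_min < 1e-12) 0 else (h_max - h_obs) / (h_max - h_min)
  tibble(h2_observed = h_obs, h2_max = h_max, h2_min = h_min,
         h2_prime = min(max(h2p, 0), 1))
}

#' Species-level specialization d'
#'
#' For each species at the chosen level, the Kullback-Leibler divergence of
#' its partner-use distribution `p'_ij = a_ij / A_i` from partner
#' availability `q_j = A_j / m`, standardized between `d_min` and
#' `d_max = log(m / A_i)`. Species with zero interactions are omitted with a
#' warning.
#'
#' @param network A `bipartite_network`.
#' @param level `"plants"` (rows) or `"pollinators"` (columns).
#' @param d_min `"integer"` uses the integer-allocation heuristic of
#'   [d_min_heuristic()]; `"zero"` sets `d_min = 0` (the continuous
#'   convention).
#' @return A tibble with one row per species: `species`, `degree`, `d`,
#'   `d_min`, `d_max`, `d_prime`.
#' @export
d_prime <- function(network, level = c("plants", "pollinators"),
                    d_min = c("integer", "zero")) {
  level <- arg_match(level)
  d_min <- arg_match(d_min)
  A <- network$matrix
  if (level == "pollinators") A <- t(A)
  m <- sum(A)
  totals <- rowSums(A)
  q <- colSums(A) / m
  if (any(totals == 0)) {
    warn(paste0("omitting species with no interactions: ",
                paste(rownames(A)[totals == 0], collapse = ", ")))
  }
  keep <- which(totals > 0)
  if (d_min == "integer" && any(A != round(A))) {
    abort(paste0("integer d_min requires integer weights; ",
                 "round the weights or use d_min = 'zero'"),
          class = "pollennet_usage_error")
  }
  rows <- purrr::map(keep, function(i) {
    ai <- unname(totals[i])
    d <- kl_divergence(A[i, ], ai, q)
    dmax <- log(m / ai)
    dmin <- if (d_min == "integer") d_min_heuristic(ai, q)$d else 0
    dmin <- min(dmin, d)  # observed allocation bounds the minimum from above
    dp <- if (dmax - dmin < 1e-12) 0 else (d - dmin) / (dmax - dmin)
    tibble(species = rownames(A)[i], degree = sum(A[i, ] > 0),
           d = d, d_min = dmin, d_max = dmax,
           d_prime = min(max(dp, 0), 1))
  })
  bind_rows(rows)
}

#' Species strength
#'
#' The sum over a species' partners of the fraction of each partner's
#' interactions devoted to that species: for plant i,
#' `strength_i = sum_j a_ij / A_j`. Summed over one mode it equals the number
#' of species in the other mode exactly.
#'
#' @param network A `bipartite_network`.
#' @param level `"plants"` or `"pollinators"`.
#' @return A tibble: `species`, `strength`.
#' @export
species_strength <- function(network, level = c("plants", "pollinators")) {
  level <- arg_match(level)
  A <- network$matrix
  if (level == "pollinators") A <- t(A)
  partner_totals <- colSums(A)
  dep <- A
  pos <- partner_totals > 0
  dep[, pos] <- sweep(A[, pos, drop = FALSE], 2, partner_totals[pos], "/")
  dep[, !pos] <- 0
  tibble(species = rownames(A), strength = unname(rowSums(dep)))
}

#' Closeness centrality on the bipartite graph
#'
#' The network is viewed as an unweighted graph on the union of plant and
#' pollinator nodes with an edge wherever `a_ij > 0`. `"standard"` closeness
#' for a node in a connected component of size `nc` (out of `n` nodes total)
#' is `((nc - 1) / sum of distances within the component) * ((nc - 1) /
#' (n - 1))`, the component-size correction for disconnected graphs;
#' `"harmonic"` closeness is `sum(1 / dist) / (n - 1)`. Isolated nodes score
#' 0.
#'
#' @param network A `bipartite_network`.
#' @param variant `"standard"` or `"harmonic"`.
#' @return A tibble: `species`, `mode` (`"plant"`/`"pollinator"`),
#'   `closeness`.
#' @export
closeness_centrality <- function(network, variant = c("standard", "harmonic")) {
  variant <- arg_match(variant)
  A <- network$matrix
  g <- igraph::graph_from_biadjacency_matrix(A > 0)
  D <- igraph::distances(g)
  n <- nrow(D)
  cl <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    if (variant == "harmonic") {
      return(sum(1 / d[is.finite(d)]) / (n - 1))
    }
    comp <- d[is.finite(d)]
    nc <- length(comp) + 1
    if (nc == 1 || sum(comp) == 0) return(0)
    ((nc - 1) / sum(comp)) * ((nc - 1) / (n - 1))
  }, numeric(1))
  tibble(
    species = rownames(D),
    mode = rep(c("plant", "pollinator"), c(nrow(A), ncol(A))),
    closeness = cl
  )
}

#' Chao1 species richness and sampling completeness
#'
#' From an abundance vector of non-negative integer counts (e.g. interaction
#' events per species): with `S_obs` the number of species observed, `f1` the
#' singletons and `f2` the doubletons, the classic estimator is
#' `S_obs + f1^2 / (2 f2)` (or `S_obs + f1 (f1 - 1) / 2` when `f2 = 0`) and
#' the bias-corrected estimator is
#' `S_obs + ((n - 1) / n) * f1 (f1 - 1) / (2 (f2 + 1))` with `n` the total
#' count. Sampling completeness is `100 * S_obs / S_est`.
#'
#' @param abundances Non-negative integer vector.
#' @param variant `"bias_corrected"` (default) or `"classic"`.
#' @return A one-row tibble: `s_obs`, `f1`, `f2`, `s_est`, `completeness`,
#'   `variant`.
#' @export
chao1_completeness <- function(abundances, variant = c("bias_corrected", "classic")) {
  variant <- arg_match(variant)
  check_counts(abundances, "abundances")
  if (sum(abundances) == 0) {
    abort("all-zero abundance vector", class = "pollennet_usage_error")
  }
  s_obs <- sum(abundances > 0)
  f1 <- sum(abundances == 1)
  f2 <- sum(abundances == 2)
  n <- sum(abundances)
  s_est <- if (variant == "classic") {
    if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
  } else {
    s_obs + ((n - 1) / n) * f1 * (f1 - 1) / (2 * (f2 + 1))
  }
  tibble(s_obs = s_obs, f1 = f1, f2 = f2, s_est = s_est,
         completeness = 100 * s_obs / s_est, variant = variant)
}

#' All network metrics in one pass
#'
#' Convenience wrapper computing the network-level index (H2', links per
#' species, Chao1 completeness of the plant mode) and the per-species tables
#' (d', strength, closeness, degree) for both modes.
#'
#' @param network A `bipartite_network`.
#' @param closeness_variant Passed to [closeness_centrality()].
#' @param chao1_variant Passed to [chao1_completeness()].
#' @param d_min Passed to [d_prime()].
#' @return An object of class `network_metrics` with elements `network`
#'   (one-row tibble), `plants` and `pollinators` (per-species tibbles).
#'   `glance()` returns the network-level row; `tidy()` stacks the
#'   per-species tables with a `mode` column.
#' @export
network_metrics <- function(network,
                            closeness_variant = c("standard", "harmonic"),
                            chao1_variant = c("bias_corrected", "classic"),
                            d_min = c("integer", "zero")) {
  closeness_variant <- arg_match(closeness_variant)
  chao1_variant <- arg_match(chao1_variant)
  d_min <- arg_match(d_min)
  h2 <- h2_prime(network)
  chao <- chao1_completeness(round(rowSums(network$matrix)), chao1_variant)
  cc <- closeness_centrality(network, closeness_variant)
  per_level <- function(level, mode_label) {
    d_prime(network, level, d_min = d_min) %>%
      left_join(species_strength(network, level), by = "species") %>%
      left_join(cc %>% filter(.data$mode == mode_label) %>%
                  select("species", "closeness"),
                by = "species")
  }
  out <- list(
    network = tibble(
      n_plants = nrow(network$matrix),
      n_pollinators = ncol(network$matrix),
      n_links = sum(network$matrix > 0),
      links_per_species = links_per_species(network),
      h2_observed = h2$h2_observed,
      h2_max = h2$h2_max,
      h2_min = h2$h2_min,
      h2_prime = h2$h2_prime,
      chao1_s_obs = chao$s_obs,
      chao1_s_est = chao$s_est,
      sampling_completeness = chao$completeness
    ),
    plants = per_level("plants", "plant"),
    pollinators = per_level("pollinators", "pollinator")
  )
  class(out) <- "network_metrics"
  out
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(
    "Network metrics: %d plants x %d pollinators, %d links (%.1f per species)\n",
    x$network$n_plants, x$network$n_pollinators, x$network$n_links,
    x$network$links_per_species))
  cat(sprintf("  H2' = %.3f, Chao1 completeness = %.1f%%\n",
              x$network$h2_prime, x$network$sampling_completeness))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.network_metrics <- function(x, ...) x$network

#' @exportS3Method generics::tidy
tidy.network_metrics <- function(x, ...) {
  bind_rows(
    x$plants %>% mutate(mode = "plant"),
    x$pollinators %>% mutate(mode = "pollinator")
  ) %>% select("species", "mode", dplyr::everything())
}

#' @exportS3Method ggplot2::autoplot
autoplot.bipartite_network <- function(object, ...) {
  A <- object$matrix
  df <- as_tibble(as.data.frame.table(A, responseName = "weight")) %>%
    rename(plant = "Var1", pollinator = "Var2")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pollinator, y = .data$plant,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkgreen") +
    ggplot2::labs(x = "Pollinator", y = "Plant", fill = "Weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
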