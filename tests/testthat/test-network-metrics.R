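test_that("network assembly sums duplicate edges and binarizes on request", {
  edges <- tibble::tibble(plant = c("A", "B"), pollinator = c("X", "Y"),
                          weight = c(3, 1))
  net <- build_network(edges)
  expect_equal(unname(net$matrix), matrix(c(3, 0, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(sum(net$matrix), 4)
  expect_equal(sum(net$matrix > 0), 2)
  netb <- build_network(edges, binarize = TRUE)
  expect_equal(sum(netb$matrix), 2)
  expect_error(build_network(edges[0, ]), class = "pollennet_usage_error")
})

test_that("links per species follows L / (n_plants + n_pollinators)", {
  expect_equal(links_per_species(as_network(diag(2))), 0.5)
  expect_equal(links_per_species(as_network(matrix(1, 3, 3))), 1.5)
})

test_that("H2' hits its closed-form anchor cases", {
  # perfect specialization
  h <- h2_prime(as_network(diag(2) * 2))
  expect_equal(h$h2_observed, log(2), tolerance = 1e-12)
  expect_equal(h$h2_max, log(4), tolerance = 1e-12)
  expect_equal(h$h2_min, log(2), tolerance = 1e-12)
  expect_equal(h$h2_prime, 1)
  # marginal independence
  h0 <- h2_prime(as_network(matrix(1, 2, 2)))
  expect_equal(h0$h2_observed, h0$h2_max, tolerance = 1e-12)
  expect_equal(h0$h2_prime, 0)
  # [[2,1],[1,0]]: integer minimum from exhaustive enumeration of the
  # marginals (3,1)/(3,1) is attained by [[3,0],[0,1]]
  h2 <- h2_prime(as_network(matrix(c(2, 1, 1, 0), 2, 2, byrow = TRUE)))
  expect_equal(h2$h2_observed, 1.0397208, tolerance = 1e-6)
  expect_equal(h2$h2_max, 1.1245747, tolerance = 1e-4)
  expect_equal(h2$h2_min, min_entropy_exact(c(3, 1), c(3, 1)), tolerance = 1e-12)
  expect_equal(h2$h2_prime, 0.151, tolerance = 1e-2)
})

test_that("non-integer weights are rejected for integer bounds only", {
  net <- as_network(matrix(c(1.5, 0.5, 0.5, 1.5), 2, 2))
  expect_error(h2_prime(net, bounds = "integer"),
               class = "pollennet_usage_error")
  expect_no_error(h2_prime(net, bounds = "continuous"))
})

test_that("d' anchors: proportional use scores 0, exclusive use scores 1", {
  # every row uses partners proportionally to availability
  prop <- as_network(matrix(c(2, 2, 1, 1), 2, 2, byrow = TRUE))
  d <- d_prime(prop)
  expect_equal(d$d, c(0, 0), tolerance = 1e-12)
  expect_equal(d$d_prime, c(0, 0))
  # perfect specialization: d = d_max = log 2, d_min = 0 via allocation (1,1)
  d1 <- d_prime(as_network(diag(2) * 2))
  expect_equal(d1$d_prime, c(1, 1))
  expect_equal(d1$d_max, c(log(2), log(2)), tolerance = 1e-12)
})

test_that("d' matches exhaustive-enumeration standardization on a 3x3 case", {
  M <- matrix(c(4, 1, 0, 1, 2, 1, 0, 1, 4), 3, 3, byrow = TRUE)
  net <- as_network(M)
  d <- d_prime(net)
  m <- sum(M)
  q <- colSums(M) / m
  for (i in 1:3) {
    ai <- sum(M[i, ])
    d_obs <- sum((M[i, ] / ai)[M[i, ] > 0] *
                   log((M[i, ] / ai)[M[i, ] > 0] / q[M[i, ] > 0]))
    dmin_ex <- d_min_exact(ai, q)
    dmax <- log(m / ai)
    expect_equal(d$d[i], d_obs, tolerance = 1e-12)
    expect_equal(d$d_min[i], dmin_ex, tolerance = 1e-9)
    expect_equal(d$d_prime[i], (d_obs - dmin_ex) / (dmax - dmin_ex),
                 tolerance = 1e-9)
  }
})

test_that("species strength sums partner dependencies", {
  net <- as_network(matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE))
  s <- species_strength(net)
  expect_equal(s$strength, c(1.5, 0.5))
  id <- as_network(diag(4))
  expect_equal(species_strength(id)$strength, rep(1, 4))
})

test_that("strength conservation holds exactly on random networks", {
  set.seed(402)
  for (i in 1:25) {
    edges <- random_edges(sample(3:8, 1), sample(3:8, 1))
    net <- build_network(edges)
    expect_equal(sum(species_strength(net, "plants")$strength),
                 ncol(net$matrix), tolerance = 1e-12)
    expect_equal(sum(species_strength(net, "pollinators")$strength),
                 nrow(net$matrix), tolerance = 1e-12)
  }
})

test_that("closeness centrality matches hand-computed path lengths", {
  # complete 2x2 bipartite graph: plant distances (1,1,2)
  cc <- closeness_centrality(as_network(matrix(1, 2, 2)))
  expect_equal(cc$closeness, rep(0.75, 4))
  # path plant1 - pollinator - plant2: the pollinator is the centre
  path <- as_network(matrix(c(1, 1), 2, 1))
  ccp <- closeness_centrality(path)
  expect_equal(ccp$closeness[ccp$mode == "pollinator"], 1.0)
  expect_equal(ccp$closeness[ccp$mode == "plant"], c(2 / 3, 2 / 3))
  # isolated plant scores 0; others are computed within their component
  iso <- as_network(matrix(c(1, 0), 2, 1))
  cci <- closeness_centrality(iso)
  expect_equal(cci$closeness[cci$species == "P2"], 0)
  expect_true(all(cci$closeness >= 0 & cci$closeness <= 1))
  # harmonic equals standard when all distances are uniform from a node
  ch <- closeness_centrality(as_network(matrix(1, 1, 3)), "harmonic")
  cs <- closeness_centrality(as_network(matrix(1, 1, 3)), "standard")
  expect_equal(ch$closeness[ch$mode == "plant"],
               cs$closeness[cs$mode == "plant"])
})

test_that("specialization indices are permutation and scale invariant", {
  set.seed(11)
  M <- matrix(rpois(12, 2), 3, 4)
  M[1, ] <- M[1, ] + 1  # no empty rows
  M[, colSums(M) == 0] <- 1
  net <- as_network(M)
  perm <- as_network(M[c(2, 3, 1), c(4, 1, 3, 2)],
                     plants = rownames(net$matrix)[c(2, 3, 1)],
                     polls = colnames(net$matrix)[c(4, 1, 3, 2)])
  h <- h2_prime(net)
  hp <- h2_prime(perm)
  expect_equal(h$h2_prime, hp$h2_prime, tolerance = 1e-12)
  d1 <- d_prime(net) |> dplyr::arrange(species)
  d2 <- d_prime(perm) |> dplyr::arrange(species)
  expect_equal(d1$d_prime, d2$d_prime, tolerance = 1e-12)
  # scaling all weights by a positive integer (continuous bounds)
  scaled <- as_network(M * 5)
  expect_equal(h2_prime(net, bounds = "continuous")$h2_prime,
               h2_prime(scaled, bounds = "continuous")$h2_prime,
               tolerance = 1e-9)
})

test_that("H2' is 1 on identity matrices and 0 on rank-1 marginal products", {
  for (n in 2:5) {
    expect_equal(h2_prime(as_network(diag(n)))$h2_prime, 1)
  }
  outerM <- outer(c(1, 2), c(1, 2))  # realizes its own marginal product
  h <- h2_prime(as_network(outerM), bounds = "continuous")
  expect_equal(h$h2_observed, h$h2_max, tolerance = 1e-9)
  expect_equal(h$h2_prime, 0, tolerance = 1e-9)
})

test_that("Chao1 estimators follow the closed formulas", {
  # no singletons: estimator equals the observed richness
  c1 <- chao1_completeness(c(3, 5, 2, 7), "classic")
  expect_equal(c1$s_est, c1$s_obs)
  expect_equal(c1$completeness, 100)
  # classic spot value S_obs = 10, f1 = 4, f2 = 2
  ab <- c(1, 1, 1, 1, 2, 2, 3, 3, 3, 3)
  c2 <- chao1_completeness(ab, "classic")
  expect_equal(c2$s_obs, 10)
  expect_equal(c2$s_est, 14)
  expect_equal(c2$completeness, 100 * 10 / 14, tolerance = 1e-9)
  # every abundance >= 3: both variants at 100%
  for (v in c("classic", "bias_corrected")) {
    expect_equal(chao1_completeness(c(3, 4, 5), v)$completeness, 100)
  }
  expect_error(chao1_completeness(c(0, 0)), class = "pollennet_usage_error")
})

test_that("network_metrics bundles all levels with tidy/glance access", {
  fx <- make_metric_fixtures()
  net <- as_network(fx$m2110$matrix)
  m <- network_metrics(net)
  g <- glance(m)
  expect_equal(g$h2_prime, fx$m2110$expected$h2_prime, tolerance = 1e-4)
  td <- tidy(m)
  expect_true(all(c("species", "mode", "d_prime", "strength", "closeness")
                  %in% names(td)))
  expect_true(all(td$d_prime >= 0 & td$d_prime <= 1))
})
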