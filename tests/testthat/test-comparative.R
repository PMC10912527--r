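test_that("transforms follow the cross-species conventions", {
  df <- tibble::tibble(
    species = c("a", "b", "c"),
    symmetry = c("bilateral", "radial", "radial"),
    flower_size = c(488.5, 100, 10),
    hp_proportion = c(11.3, 0, 2),
    d_prime = c(0.25, 0.04, 1),
    strength = c(1.5, 0.2, 4),
    closeness = c(0.03, 0.01, 0.02)
  )
  tr <- apply_transforms(df)
  expect_equal(tr$symmetry_code, c(1, 2, 2))
  expect_equal(tr$log10_flower_size[1], log10(488.5), tolerance = 1e-9)
  expect_equal(round(tr$log10_flower_size[1], 3), 2.689)
  expect_true(is.na(tr$log10_hp_prop[2]))
  expect_equal(attr(tr, "zero_hp_species"), "b")
  expect_equal(tr$sqrt_d_prime, sqrt(df$d_prime))
  err <- expect_error(
    apply_transforms(dplyr::mutate(df, d_prime = c(-1, 0.1, 0.2))),
    class = "pollennet_validation_error")
  expect_match(conditionMessage(err), "a")
})

test_that("standardized coefficients behave like correlations", {
  df <- tibble::tibble(x = c(1, 2, 3, 4, 5, 6), y = 2 * c(1, 2, 3, 4, 5, 6))
  m <- suppressWarnings(fit_std_regression(df, "y", "x"))
  td <- tidy(m)
  expect_equal(td$std_estimate[td$term == "x"], 1, tolerance = 1e-12)
  expect_equal(glance(m)$r_squared, 1, tolerance = 1e-12)
  # orthogonal predictors: each b_std equals its marginal correlation with y
  df2 <- tibble::tibble(
    x1 = c(1, 1, 0, 0, -1, -1),
    x2 = c(1, -1, 1, -1, 1, -1)
  )
  df2$y <- 2 * df2$x1 + 1 * df2$x2 + c(0.1, -0.1, 0.05, -0.05, 0.02, -0.02)
  m2 <- fit_std_regression(df2, "y", c("x1", "x2"))
  td2 <- tidy(m2)
  expect_equal(td2$std_estimate[td2$term == "x1"], stats::cor(df2$y, df2$x1),
               tolerance = 1e-9)
  expect_equal(td2$std_estimate[td2$term == "x2"], stats::cor(df2$y, df2$x2),
               tolerance = 1e-9)
})

test_that("standardized coefficients are invariant to predictor rescaling", {
  set.seed(9)
  df <- tibble::tibble(x1 = rnorm(20), x2 = rnorm(20))
  df$y <- df$x1 - 0.5 * df$x2 + rnorm(20, 0, 0.3)
  a <- tidy(fit_std_regression(df, "y", c("x1", "x2")))
  df_resc <- dplyr::mutate(df, x1 = 100 * x1 + 7)
  b <- tidy(fit_std_regression(df_resc, "y", c("x1", "x2")))
  expect_equal(a$std_estimate[-1], b$std_estimate[-1], tolerance = 1e-9)
})

test_that("regression errors on collinear or constant predictors", {
  df <- tibble::tibble(x1 = c(1, 2, 3, 4, 5), x2 = c(2, 4, 6, 8, 10),
                       y = rnorm(5))
  expect_error(fit_std_regression(df, "y", c("x1", "x2")),
               class = "pollennet_validation_error")
  df$x3 <- 1
  expect_error(fit_std_regression(df, "y", c("x1", "x3")),
               class = "pollennet_validation_error")
})

test_that("one-way ANOVA matches its textbook anchors", {
  a <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("g1", "g2"), each = 3))
  expect_equal(a$statistic, 0)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_within, 4)
  # two-group F equals the squared pooled-variance t statistic
  set.seed(12)
  x <- rnorm(30)
  g <- rep(c("a", "b"), 15)
  f <- one_way_anova(x, g)
  t2 <- stats::t.test(x ~ g, var.equal = TRUE)$statistic^2
  expect_equal(f$statistic, unname(t2), tolerance = 1e-9)
  # invariant to shifting all values and relabeling groups
  f2 <- one_way_anova(x + 100, ifelse(g == "a", "z", "y"))
  expect_equal(f2$statistic, f$statistic, tolerance = 1e-9)
  expect_error(one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               class = "pollennet_degenerate_fit")
  expect_error(one_way_anova(1:3, rep("a", 3)),
               class = "pollennet_usage_error")
})

test_that("pattern groups merge no_hp and signed variants correctly", {
  pats <- c("increasing_linear", "decreasing_linear", "increasing_exponential",
            "decreasing_exponential", "no_pattern", "no_hp")
  expect_equal(pattern_group(pats),
               c("linear", "linear", "exponential", "exponential",
                 "no_pattern", "no_pattern"))
  expect_equal(strategy_group(pats),
               c(rep("significant", 4), rep("non_significant", 2)))
})

test_that("pattern-group comparison applies per-variable transforms", {
  set.seed(33)
  df <- tibble::tibble(
    species = sprintf("sp%02d", 1:12),
    pattern = rep(c("increasing_linear", "increasing_exponential",
                    "no_pattern", "no_hp"), each = 3),
    flower_size = c(10, 20, 30, 1000, 2000, 3000, 50, 60, 70, 80, 90, 100),
    mean_hp = rpois(12, 20)
  )
  pc <- pattern_group_comparison(df, c("flower_size", "mean_hp"))
  g <- pc$groups
  lin <- g[g$variable == "flower_size" & g$group == "linear", ]
  expect_equal(lin$mean, mean(log10(c(10, 20, 30))), tolerance = 1e-9)
  expect_equal(g$n[g$variable == "flower_size" & g$group == "no_pattern"], 6L)
  expect_equal(unique(g$transform[g$variable == "mean_hp"]), "identity")
  expect_true(all(is.finite(pc$tests$statistic)))
  # a single-group table yields group stats but no F test
  one <- df[df$pattern == "no_pattern", ]
  expect_warning(pc1 <- pattern_group_comparison(one, "flower_size"),
                 "fewer than 2")
  expect_equal(nrow(pc1$tests), 0)
})

test_that("the full cross-species regression stack runs on a synthetic table", {
  sim <- simulate_community(sim_config(seed = 55))
  s <- summarize_species(sim$loads)
  net <- build_network(sim$edges, binarize = TRUE)
  metrics <- d_prime(net) |>
    dplyr::left_join(species_strength(net), by = "species") |>
    dplyr::left_join(
      dplyr::filter(closeness_centrality(net), mode == "plant")[
        , c("species", "closeness")], by = "species")
  tbl <- s |>
    dplyr::left_join(sim$traits, by = "species") |>
    dplyr::left_join(metrics, by = "species") |>
    apply_transforms()
  responses <- c("mean_hp", "cv_hp", "mean_cp", "cv_cp", "mean_hp_div",
                 "cv_hp_div", "hp_proportion")
  predictors <- c("symmetry_code", "log10_flower_size", "sqrt_d_prime",
                  "sqrt_strength", "sqrt_closeness")
  for (resp in responses) {
    m <- fit_std_regression(tbl, resp, predictors)
    g <- glance(m)
    expect_true(is.finite(g$r_squared) && g$r_squared >= 0 && g$r_squared <= 1)
    expect_true(all(is.finite(tidy(m)$estimate)))
  }
})
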