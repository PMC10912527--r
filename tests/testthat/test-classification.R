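test_that("linear fit recovers an exact line and rejects degenerate CP", {
  f <- suppressWarnings(fit_cp_hp_linear(c(1, 2, 3), c(2, 4, 6)))
  expect_equal(f$b, 2, tolerance = 1e-9)
  expect_equal(f$adj_r_squared, 1, tolerance = 1e-9)
  expect_error(fit_cp_hp_linear(c(5, 5, 5), c(1, 2, 3)),
               class = "pollennet_degenerate_fit")
  expect_error(fit_cp_hp_linear(c(1, 2), c(1, 2)),
               class = "pollennet_usage_error")
})

test_that("constant HP yields a flat, non-significant linear fit", {
  f <- suppressWarnings(fit_cp_hp_linear(c(1, 2, 3, 4), c(3, 3, 3, 3)))
  expect_equal(f$b, 0, tolerance = 1e-12)
  expect_equal(f$p_value, 1)
})

test_that("linear fit agrees with the closed-form OLS solution", {
  set.seed(7)
  cp <- rpois(50, 100)
  hp <- 0.1 * cp + rnorm(50, 0, 1)
  f <- fit_cp_hp_linear(cp, hp)
  # independent closed-form slope and intercept from the normal equations
  b_ref <- sum((cp - mean(cp)) * (hp - mean(hp))) / sum((cp - mean(cp))^2)
  a_ref <- mean(hp) - b_ref * mean(cp)
  expect_equal(f$b, b_ref, tolerance = 1e-9)
  expect_equal(f$intercept, a_ref, tolerance = 1e-9)
  se_b <- sqrt(sum((hp - a_ref - b_ref * cp)^2) / 48 /
                 sum((cp - mean(cp))^2))
  expect_lt(abs(f$b - 0.1), 1.96 * se_b + 1e-9)
})

test_that("exponential fit recovers exact exponential points", {
  cp <- seq(10, 200, length.out = 20)
  hp <- exp(0.5 + 0.01 * cp)
  f <- fit_cp_hp_exponential(cp, hp)
  expect_true(f$converged)
  expect_equal(f$intercept, 0.5, tolerance = 1e-5)
  expect_equal(f$b, 0.01, tolerance = 1e-6)
  expect_equal(f$adj_r_squared, 1, tolerance = 1e-8)
})

test_that("constant HP yields a flat, non-significant exponential fit", {
  f <- fit_cp_hp_exponential(c(10, 20, 30, 40), c(3, 3, 3, 3))
  expect_true(f$converged)
  expect_equal(f$b, 0, tolerance = 1e-6)
  expect_gte(f$p_value, 0.99)
})

test_that("exponential fit detects a positive rate under Poisson noise", {
  set.seed(11)
  hits <- 0
  for (r in 1:50) {
    a <- rgamma(50, shape = 2, scale = 50)
    cp <- rpois(50, a)
    hp <- rpois(50, exp(0.2 + 0.02 * a))
    f <- fit_cp_hp_exponential(cp, hp)
    if (f$converged && !is.na(f$p_value) && f$p_value < 0.05 && f$b > 0) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / 50, 0.9)
})

test_that("species without any HP are labelled no_hp and left unfitted", {
  cls <- classify_species(c(10, 20, 30, 40), c(0, 0, 0, 0), species = "X")
  expect_equal(cls$pattern, "no_hp")
  expect_null(cls$chosen)
  g <- glance(cls)
  expect_true(is.na(g$b) && is.na(g$f_statistic))
})

test_that("the decision tree separates the three accrual regimes", {
  set.seed(3)
  # independence: CP and HP unrelated
  cls_a <- classify_species(rpois(50, 100), rpois(50, 1))
  expect_equal(cls_a$pattern, "no_pattern")
  # strong shared-visitation linear coupling
  set.seed(5)
  v <- rnbinom(50, mu = 10, size = 3)
  cls_l <- classify_species(rpois(50, v * 10.8), rpois(50, v * 1.2))
  expect_equal(cls_l$pattern, "increasing_linear")
  # latent-rate exponential coupling
  set.seed(5)
  a <- rgamma(50, shape = 2, scale = 50)
  cls_e <- classify_species(rpois(50, a), rpois(50, exp(0.5 + 0.015 * a)))
  expect_equal(cls_e$pattern, "increasing_exponential")
  expect_gt(cls_e$chosen$b, 0)
})

test_that("with both fits significant the larger adjusted R-squared wins", {
  set.seed(21)
  for (r in 1:10) {
    v <- rnbinom(60, mu = 10, size = 3)
    cp <- rpois(60, v * 10.8)
    hp <- rpois(60, v * 1.2)
    cls <- classify_species(cp, hp)
    lin <- cls$fits$linear
    expf <- cls$fits$exponential
    if (lin$p_value < 0.05 && !is.na(expf$p_value) && expf$p_value < 0.05) {
      ref <- if (lin$adj_r_squared >= expf$adj_r_squared) "linear" else "exponential"
      expect_equal(cls$chosen$model, ref)
    }
  }
})

test_that("classify_all tallies patterns and is invariant to empty stigmas", {
  set.seed(31)
  make_sp <- function(sp, cp, hp) {
    tibble::tibble(stigma_id = sprintf("%s_%d", sp, seq_along(cp)),
                   species = sp, cp = as.integer(cp), hp = as.integer(hp),
                   hp_diversity = as.integer(pmin(hp, 1)))
  }
  v <- rnbinom(50, mu = 10, size = 3)
  a <- rgamma(50, shape = 2, scale = 50)
  loads <- dplyr::bind_rows(
    make_sp("lin", rpois(50, v * 10.8), rpois(50, v * 1.2)),
    make_sp("exp", rpois(50, a), rpois(50, exp(0.5 + 0.015 * a))),
    make_sp("none", rpois(50, 100), rpois(50, 1)),
    make_sp("pure", rpois(50, 80) + 1L, rep(0, 50))
  )
  res <- classify_all(loads)
  expect_equal(res$pattern[res$species == "lin"], "increasing_linear")
  expect_equal(res$pattern[res$species == "exp"], "increasing_exponential")
  expect_equal(res$pattern[res$species == "none"], "no_pattern")
  expect_equal(res$pattern[res$species == "pure"], "no_hp")
  tally <- attr(res, "tally")
  expect_equal(sum(tally$n_species), 4)
  # no-pattern rows tabulate the linear fit's statistics
  expect_equal(res$model[res$species == "none"], "linear")
  # adding empty stigmas and permuting rows changes nothing
  with_empty <- dplyr::bind_rows(
    loads, make_sp("none", rep(0, 5), rep(0, 5)))
  set.seed(1)
  shuffled <- with_empty[sample(nrow(with_empty)), ]
  res2 <- classify_all(shuffled)
  expect_equal(res2$pattern[match(res$species, res2$species)], res$pattern)
  expect_equal(res2$b[match(res$species, res2$species)], res$b,
               tolerance = 1e-6)
})

test_that("species with too few analyzed stigmas are skipped with a warning", {
  loads <- tibble::tibble(
    stigma_id = c("a", "b", "c", "d", "e"),
    species = c("tiny", "tiny", "ok", "ok", "ok"),
    cp = c(1L, 2L, 3L, 4L, 5L), hp = c(0L, 1L, 1L, 2L, 1L),
    hp_diversity = c(0L, 1L, 1L, 1L, 1L)
  )
  expect_warning(res <- classify_all(loads), "tiny")
  expect_equal(res$species, "ok")
})
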