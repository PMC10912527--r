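#' Pollinator guild specification
#'
#' Describes one pollinator guild for the visitation/deposition simulator:
#' its fidelity (expected fraction of deposited grains that are conspecific),
#' visit rate per stigma, mean grains deposited per visit, and the
#' concentration of its donor pool (lower concentration gives a patchier
#' spread of HP donors).
#'
#' @param label Guild name.
#' @param fidelity Fraction of deposited grains that are conspecific, in
#'   `[0, 1]`.
#' @param visit_rate Expected visits per stigma (> 0).
#' @param grains_per_visit Mean grains deposited per visit (> 0).
#' @param donor_concentration Dirichlet concentration of the donor pool.
#' @return A `guild_spec` list.
#' @export
guild_spec <- function(label, fidelity, visit_rate, grains_per_visit,
                       donor_concentration = 1) {
  stopifnot(fidelity >= 0, fidelity <= 1, visit_rate > 0,
            grains_per_visit > 0, donor_concentration > 0)
  structure(list(label = label, fidelity = fidelity, visit_rate = visit_rate,
                 grains_per_visit = grains_per_visit,
                 donor_concentration = donor_concentration),
            class = "guild_spec")
}

#' Synthetic community configuration
#'
#' Defines the study conditions the generator emulates: community size
#' (29 plant and 45 pollinator species, 494 unique links), sampling depth
#' (50 stigmas per species), and the mixture of per-species deposition
#' regimes. The default regime mixture mirrors a community dominated by HP
#' avoidance: 19 of 29 species avoidance (2 of them receiving no HP at all),
#' 6 with linear tolerance and 4 with increasing-exponential tolerance;
#' for other community sizes the proportions are scaled.
#'
#' Deposition regimes:
#' * `avoidance`: CP and HP independent; CP around `cp_mean`, HP a small
#'   Poisson (`hp_eps`) trickle.
#' * `tolerance_linear`: visits arrive at rate `visit_rate`; each visit
#'   deposits Poisson CP and HP grains in proportion `fidelity :
#'   (1 - fidelity)` of `grains_per_visit`, so E(HP | CP) grows linearly.
#' * `tolerance_exp_increasing` / `tolerance_exp_decreasing`: a latent
#'   per-stigma attractiveness `a ~ Gamma(shape, scale)` drives
#'   `CP ~ Poisson(a)` and `HP ~ Poisson(exp(c0 + c1 a))` with positive or
#'   negative rate `c1`.
#'
#' Counts are negative-binomially overdispersed by default
#' (`overdispersion` is the NB size parameter; `NULL` gives pure Poisson),
#' reflecting the strong per-stigma variability of field pollen loads.
#'
#' @param n_plants,n_pollinators Community size.
#' @param n_stigmas Stigmas sampled per plant species (scalar or vector).
#' @param target_links Unique links the visitation network is thinned to.
#' @param regimes Optional character vector (length `n_plants`) of regime
#'   names; `NULL` uses the default mixture.
#' @param n_zero_hp Number of avoidance species whose HP rate is zero.
#' @param overdispersion NB size parameter for count draws, or `NULL`.
#' @param donor_pool_size Co-flowering donor species per plant.
#' @param donor_concentration Dirichlet concentration of donor shares.
#' @param attractiveness_sd SD (log scale) of the latent species
#'   attractiveness/activity modulating visitation rates.
#' @param regime_params Named list overriding per-regime parameters (see
#'   Details above for the defaults).
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_plants = 29, n_pollinators = 45, n_stigmas = 50,
                       target_links = 494, regimes = NULL, n_zero_hp = 2,
                       overdispersion = 3, donor_pool_size = 5,
                       donor_concentration = 1, attractiveness_sd = 0.6,
                       regime_params = list(), seed) {
  if (missing(seed)) {
    abort("a seed is mandatory for reproducibility",
          class = "pollennet_usage_error")
  }
  defaults <- list(
    avoidance = list(cp_mean = 100, hp_eps = 1),
    tolerance_linear = list(fidelity = 0.9, visit_rate = 10,
                            grains_per_visit = 12),
    tolerance_exp_increasing = list(gamma_shape = 2, gamma_scale = 50,
                                    c0 = 0.5, c1 = 0.015),
    tolerance_exp_decreasing = list(gamma_shape = 2, gamma_scale = 50,
                                    c0 = 3, c1 = -0.02)
  )
  for (nm in names(regime_params)) {
    defaults[[nm]] <- utils::modifyList(defaults[[nm]], regime_params[[nm]])
  }
  if (is.null(regimes)) {
    n_lin <- round(6 / 29 * n_plants)
    n_exp <- round(4 / 29 * n_plants)
    n_avoid <- n_plants - n_lin - n_exp
    regimes <- c(rep("avoidance", n_avoid), rep("tolerance_linear", n_lin),
                 rep("tolerance_exp_increasing", n_exp))
  }
  if (length(regimes) != n_plants) {
    abort("regimes must cover every plant species",
          class = "pollennet_usage_error")
  }
  bad <- setdiff(unique(regimes), names(defaults))
  if (length(bad) > 0) {
    abort(paste0("unknown regime(s): ", paste(bad, collapse = ", ")),
          class = "pollennet_usage_error")
  }
  structure(list(
    n_plants = n_plants, n_pollinators = n_pollinators,
    n_stigmas = n_stigmas, target_links = target_links, regimes = regimes,
    n_zero_hp = n_zero_hp, overdispersion = overdispersion,
    donor_pool_size = donor_pool_size,
    donor_concentration = donor_concentration,
    attractiveness_sd = attractiveness_sd,
    regime_params = defaults, seed = as.integer(seed)
  ), class = "sim_config")
}

# overdispersed (or Poisson) count draw
rcount <- function(n, mu, size = NULL) {
  mu <- pmax(mu, 0)
  if (is.null(size)) rpois(n, mu) else rnbinom(n, mu = mu, size = size)
}

#' Simulate a plant-pollinator visitation network
#'
#' Visit counts are drawn as Poisson with rates proportional to the product
#' of lognormal latent plant attractiveness and pollinator activity, with
#' the base rate calibrated so the expected number of realized links matches
#' `target_links`; the realized network is then thinned (or topped up with
#' the highest-rate missing links) to hit the target exactly. Identical
#' config and seed give an identical edge list.
#'
#' @param config A [sim_config()].
#' @return A tibble of edges (`plant`, `pollinator`, `weight`).
#' @export
simulate_visitation_network <- function(config) {
  np <- config$n_plants
  na <- config$n_pollinators
  cells <- np * na
  if (config$target_links > cells) {
    abort(sprintf("target_links (%d) exceeds n_plants * n_pollinators (%d)",
                  config$target_links, cells),
          class = "pollennet_usage_error")
  }
  withr::with_seed(config$seed + 1L, {
    attract <- rlnorm(np, 0, config$attractiveness_sd)
    activity <- rlnorm(na, 0, config$attractiveness_sd)
    R <- outer(attract, activity)
    expected_links <- function(base) sum(1 - exp(-base * R))
    base <- stats::uniroot(function(b) expected_links(b) - config$target_links,
                           lower = 1e-9, upper = 1e6, tol = 1e-9)$root
    lambda <- base * R
    counts <- matrix(rpois(cells, lambda), np, na)
    # exact-link adjustment: drop weakest links / add strongest missing ones
    linked <- which(counts > 0)
    excess <- length(linked) - config$target_links
    if (excess > 0) {
      ord <- linked[order(counts[linked], lambda[linked])]
      counts[ord[seq_len(excess)]] <- 0
    } else if (excess < 0) {
      zero <- which(counts == 0)
      ord <- zero[order(-lambda[zero])]
      counts[ord[seq_len(-excess)]] <- 1
    }
  })
  plants <- sprintf("plant_%02d", seq_len(np))
  polls <- sprintf("poll_%02d", seq_len(na))
  idx <- which(counts > 0, arr.ind = TRUE)
  tibble(
    plant = plants[idx[, 1]],
    pollinator = polls[idx[, 2]],
    weight = counts[idx]
  ) %>% arrange(.data$plant, .data$pollinator)
}

#' Simulate per-stigma pollen records with known ground truth
#'
#' Draws CP and HP loads per stigma under each plant species' deposition
#' regime (see [sim_config()]) and spreads the HP grains across a
#' co-flowering donor pool by a Dirichlet-multinomial, which yields the HP
#' donor diversity. Returns long-format pollen records (one row per stigma x
#' donor, with the focal-species CP row always present so empty stigmas are
#' representable), the aggregated stigma loads, and the ground-truth regime
#' per species.
#'
#' @param config A [sim_config()].
#' @return A list with `records`, `loads` and `truth` tibbles.
#' @export
simulate_stigma_records <- function(config) {
  np <- config$n_plants
  plants <- sprintf("plant_%02d", seq_len(np))
  n_stigmas <- rep(config$n_stigmas, length.out = np)
  regimes <- config$regimes
  size <- config$overdispersion
  # the first n_zero_hp avoidance species receive no HP at all
  eps <- vapply(seq_len(np), function(i) {
    if (regimes[i] != "avoidance") return(NA_real_)
    config$regime_params$avoidance$hp_eps
  }, numeric(1))
  zero_idx <- head(which(regimes == "avoidance"), config$n_zero_hp)
  eps[zero_idx] <- 0
  records <- list()
  withr::with_seed(config$seed + 2L, {
    for (i in seq_len(np)) {
      ns <- n_stigmas[i]
      p <- config$regime_params[[regimes[i]]]
      if (regimes[i] == "avoidance") {
        cp <- rcount(ns, p$cp_mean, size)
        hp <- rpois(ns, eps[i])
      } else if (regimes[i] == "tolerance_linear") {
        v <- rcount(ns, p$visit_rate, size)
        cp <- rpois(ns, v * p$grains_per_visit * p$fidelity)
        hp <- rpois(ns, v * p$grains_per_visit * (1 - p$fidelity))
      } else {
        a <- rgamma(ns, shape = p$gamma_shape, scale = p$gamma_scale)
        cp <- rpois(ns, a)
        hp <- rpois(ns, exp(p$c0 + p$c1 * a))
      }
      pool <- if (np > 1) {
        sample(plants[-i], min(config$donor_pool_size, np - 1))
      } else {
        "UNKNOWN"  # single-species community: donors are unidentifiable
      }
      rec_focal <- tibble(
        stigma_id = sprintf("%s_s%03d", plants[i], seq_len(ns)),
        focal_species = plants[i], donor_species = plants[i], grains = cp
      )
      rec_hp <- list()
      for (s in seq_len(ns)) {
        if (hp[s] == 0) next
        w <- rgamma(length(pool), shape = config$donor_concentration)
        w <- w / sum(w)
        split <- as.integer(rmultinom(1, hp[s], w))
        pos <- split > 0
        rec_hp[[s]] <- tibble(
          stigma_id = sprintf("%s_s%03d", plants[i], s),
          focal_species = plants[i],
          donor_species = pool[pos], grains = split[pos]
        )
      }
      records[[i]] <- bind_rows(rec_focal, bind_rows(rec_hp))
    }
  })
  records <- bind_rows(records)
  truth <- tibble(species = plants, regime = regimes,
                  hp_eps = eps, n_stigmas = n_stigmas)
  list(records = records, loads = aggregate_stigma_records(records),
       truth = truth)
}

#' Simulate species traits
#'
#' Flower sizes are lognormal, spanning the few-mm^2 to ~10^4-mm^2 range
#' observed across real communities; symmetry is radial with probability
#' 20/29.
#'
#' @param config A [sim_config()].
#' @return A tibble: `species`, `symmetry`, `flower_size`.
#' @export
simulate_traits <- function(config) {
  np <- config$n_plants
  withr::with_seed(config$seed + 3L, {
    tibble(
      species = sprintf("plant_%02d", seq_len(np)),
      symmetry = ifelse(rbinom(np, 1, 20 / 29) == 1, "radial", "bilateral"),
      flower_size = rlnorm(np, meanlog = log(250), sdlog = 1.6)
    )
  })
}

#' Simulate a complete synthetic community
#'
#' Runs the visitation-network, stigma-record and trait generators under one
#' seed and bundles their outputs with the ground truth.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_community`: `edges`, `records`, `loads`,
#'   `traits`, `truth`, `config`.
#' @export
simulate_community <- function(config) {
  stig <- simulate_stigma_records(config)
  out <- list(
    edges = simulate_visitation_network(config),
    records = stig$records,
    loads = stig$loads,
    traits = simulate_traits(config),
    truth = stig$truth,
    config = config
  )
  class(out) <- "sim_community"
  out
}

#' @export
print.sim_community <- function(x, ...) {
  cat(sprintf(
    "Synthetic community: %d plants, %d pollinators, %d links, %d stigmas (seed %d)\n",
    x$config$n_plants, x$config$n_pollinators, nrow(x$edges),
    nrow(x$loads), x$config$seed))
  invisible(x)
}

#' Fixed small networks with analytically known metric values
#'
#' A named set of interaction matrices used throughout the test suite, each
#' bundled with its expected metric values: `identity2` (perfect
#' specialization, H2' = 1, every d' = 1), `ones2` (marginal independence,
#' H2' = 0), `m2110` (the matrix `[[2,1],[1,0]]`, whose integer minimum
#' entropy 0.5623 and H2' = 0.1511 come from exhaustive enumeration of the
#' marginals (3,1)/(3,1)), `strength2` (`[[1,1],[0,1]]`, plant strengths
#' 1.5 and 0.5), and `net29x45`, a seeded community-scale network with
#' exactly 494 links.
#'
#' @return A named list; each element has `matrix` and `expected`.
#' @export
make_metric_fixtures <- function() {
  as_net <- function(M) {
    dimnames(M) <- list(sprintf("P%d", seq_len(nrow(M))),
                        sprintf("A%d", seq_len(ncol(M))))
    M
  }
  big <- simulate_visitation_network(
    sim_config(n_plants = 29, n_pollinators = 45, target_links = 494,
               seed = 101L))
  list(
    identity2 = list(
      matrix = as_net(diag(2) * 2),
      expected = list(h2_prime = 1, d_prime = c(1, 1),
                      h2_observed = log(2), h2_max = log(4), h2_min = log(2))
    ),
    ones2 = list(
      matrix = as_net(matrix(1, 2, 2)),
      expected = list(h2_prime = 0, h2_observed = log(4), h2_max = log(4))
    ),
    m2110 = list(
      matrix = as_net(matrix(c(2, 1, 1, 0), 2, 2, byrow = TRUE)),
      expected = list(h2_observed = 1.0397208, h2_max = 1.1246703,
                      h2_min = 0.5623351, h2_prime = 0.1510669)
    ),
    strength2 = list(
      matrix = as_net(matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE)),
      expected = list(plant_strength = c(1.5, 0.5))
    ),
    net29x45 = list(
      matrix = {
        net <- build_network(big)
        net$matrix
      },
      expected = list(n_links = 494, n_plants = 29, n_pollinators = 45)
    )
  )
}
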