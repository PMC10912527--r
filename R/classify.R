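#' Linear CP-HP regression for one species
#'
#' Ordinary least squares of the per-stigma HP load on the CP load,
#' `HP = b0 + b1 * CP`. Significance is the overall F test of the model.
#'
#' @param cp,hp Per-stigma grain counts (equal length, n >= 3).
#' @return An object of class `cp_hp_fit` with fields `model` (`"linear"`),
#'   `intercept`, `b` (slope), `r_squared`, `adj_r_squared`, `f_statistic`,
#'   `p_value`, `n`, `converged`.
#' @export
fit_cp_hp_linear <- function(cp, hp) {
  check_fit_input(cp, hp)
  if (var(cp) == 0) {
    abort("CP loads are constant; the linear fit is degenerate",
          class = "pollennet_degenerate_fit")
  }
  fit <- lm(hp ~ cp)
  s <- summary(fit)
  n <- length(cp)
  if (is.null(s$fstatistic) || !is.finite(s$fstatistic[1])) {
    # zero-variance response: slope 0, no evidence of a relationship
    fstat <- 0
    p <- 1
  } else {
    fstat <- unname(s$fstatistic[1])
    p <- pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
            lower.tail = FALSE)
  }
  new_cp_hp_fit(
    model = "linear",
    intercept = unname(coef(fit)[1]),
    b = unname(coef(fit)[2]),
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    f_statistic = fstat,
    p_value = unname(p),
    n = n,
    converged = TRUE
  )
}

#' Exponential CP-HP regression for one species
#'
#' Nonlinear least squares of `HP = exp(c0 + c1 * CP)`, initialized from the
#' log-linear fit of `log(HP + 1)` on CP and optimized with
#' Levenberg-Marquardt. The functional form supports both increasing
#' (`c1 > 0`) and decreasing (`c1 < 0`) accrual. Significance is an F test
#' of the fitted curve against the intercept-only (mean) model with the same
#' residual degrees of freedom as the one-slope linear model; the adjusted
#' R-squared uses the matching penalty `1 - (1 - R^2)(n - 1)/(n - 2)`.
#' Non-convergence is returned as a flagged (`converged = FALSE`) fit that
#' downstream classification treats as non-significant.
#'
#' @param cp,hp Per-stigma grain counts (equal length, n >= 3).
#' @param tol Convergence tolerance on the objective.
#' @param max_iter Maximum optimizer iterations.
#' @return An object of class `cp_hp_fit` with `model = "exponential"`,
#'   `intercept` (c0), `b` (rate c1) and the same statistics as the linear
#'   fit.
#' @export
fit_cp_hp_exponential <- function(cp, hp, tol = 1e-8, max_iter = 500) {
  check_fit_input(cp, hp)
  n <- length(cp)
  if (var(hp) == 0) {
    # constant response: flat curve at the mean, no evidence of accrual
    return(new_cp_hp_fit(
      model = "exponential",
      intercept = if (all(hp > 0)) log(hp[1]) else NA_real_, b = 0,
      r_squared = 0, adj_r_squared = 0, f_statistic = 0, p_value = 1,
      n = n, converged = TRUE
    ))
  }
  start <- coef(lm(log(hp + 1) ~ cp))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      hp ~ exp(c0 + c1 * cp),
      start = list(c0 = unname(start[1]), c1 = unname(start[2])),
      control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = tol)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(new_cp_hp_fit(
      model = "exponential", intercept = NA_real_, b = NA_real_,
      r_squared = NA_real_, adj_r_squared = NA_real_,
      f_statistic = NA_real_, p_value = NA_real_, n = n,
      converged = FALSE, diagnostics = conditionMessage(fit)
    ))
  }
  sse <- sum(resid(fit)^2)
  sst <- sum((hp - mean(hp))^2)
  if (sst <= 0) {
    r2 <- 0
    fstat <- 0
    p <- 1
  } else {
    r2 <- 1 - sse / sst
    fstat <- (sst - sse) / (sse / (n - 2))
    p <- if (!is.finite(fstat) || fstat <= 0) 1 else {
      pf(fstat, 1, n - 2, lower.tail = FALSE)
    }
  }
  new_cp_hp_fit(
    model = "exponential",
    intercept = unname(coef(fit)[1]),
    b = unname(coef(fit)[2]),
    r_squared = r2,
    adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
    f_statistic = fstat,
    p_value = p,
    n = n,
    converged = TRUE
  )
}

new_cp_hp_fit <- function(...) {
  structure(list(...), class = "cp_hp_fit")
}

#' @export
print.cp_hp_fit <- function(x, ...) {
  cat(sprintf("CP-HP %s fit (n = %d)%s\n", x$model, x$n,
              if (!x$converged) " [did not converge]" else ""))
  if (x$converged) {
    cat(sprintf("  b = %.4g, adj R^2 = %.3f, F = %.3f, p = %.4g\n",
                x$b, x$adj_r_squared, x$f_statistic, x$p_value))
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.cp_hp_fit <- function(x, ...) {
  tibble(model = x$model, intercept = x$intercept, b = x$b,
         r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
         f_statistic = x$f_statistic, p_value = x$p_value, n = x$n,
         converged = x$converged)
}

#' @exportS3Method generics::tidy
tidy.cp_hp_fit <- function(x, ...) {
  terms <- if (x$model == "linear") c("(Intercept)", "cp") else c("c0", "c1")
  tibble(term = terms, estimate = c(x$intercept, x$b))
}

#' Classify one species' CP-HP accrual pattern
#'
#' Implements the decision tree used to assign each species to an accrual
#' pattern at level `alpha`:
#'
#' 1. all HP loads zero: `no_hp` (no fit is possible);
#' 2. fit both the linear and the exponential model;
#' 3. only the linear fit significant: `increasing_linear` (or
#'    `decreasing_linear` when the slope is negative);
#' 4. only the exponential fit significant: `increasing_exponential` if the
#'    rate is positive, else `decreasing_exponential`;
#' 5. both significant: the model with the larger adjusted R-squared wins,
#'    exact ties going to the linear model (parsimony);
#' 6. neither significant: `no_pattern`.
#'
#' A non-converged exponential fit counts as non-significant.
#'
#' @param cp,hp Per-stigma grain counts for the analyzed (non-empty) stigmas
#'   of one species.
#' @param species Optional species label carried into the result.
#' @param alpha Significance level.
#' @return An object of class `cp_hp_pattern`: `species`, `n`, `pattern`,
#'   `alpha`, `chosen` (the winning `cp_hp_fit` or `NULL`) and `fits` (both
#'   candidates).
#' @export
classify_species <- function(cp, hp, species = NA_character_, alpha = 0.05) {
  check_fit_input(cp, hp)
  if (sum(hp) == 0) {
    return(structure(
      list(species = species, n = length(cp), pattern = "no_hp",
           alpha = alpha, chosen = NULL, fits = list()),
      class = "cp_hp_pattern"))
  }
  lin <- tryCatch(fit_cp_hp_linear(cp, hp), error = function(e) NULL)
  expf <- fit_cp_hp_exponential(cp, hp)
  sig <- function(f) {
    !is.null(f) && isTRUE(f$converged) && !is.na(f$p_value) && f$p_value < alpha
  }
  lin_sig <- sig(lin)
  exp_sig <- sig(expf)
  exp_label <- function(f) {
    if (f$b >= 0) "increasing_exponential" else "decreasing_exponential"
  }
  lin_label <- function(f) {
    if (f$b >= 0) "increasing_linear" else "decreasing_linear"
  }
  if (lin_sig && exp_sig) {
    if (lin$adj_r_squared >= expf$adj_r_squared) {
      pattern <- lin_label(lin); chosen <- lin
    } else {
      pattern <- exp_label(expf); chosen <- expf
    }
  } else if (lin_sig) {
    pattern <- lin_label(lin); chosen <- lin
  } else if (exp_sig) {
    pattern <- exp_label(expf); chosen <- expf
  } else {
    pattern <- "no_pattern"; chosen <- NULL
  }
  structure(
    list(species = species, n = length(cp), pattern = pattern, alpha = alpha,
         chosen = chosen, fits = list(linear = lin, exponential = expf)),
    class = "cp_hp_pattern")
}

#' @export
print.cp_hp_pattern <- function(x, ...) {
  cat(sprintf("%s (n = %d): %s\n",
              if (is.na(x$species)) "species" else x$species, x$n, x$pattern))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.cp_hp_pattern <- function(x, ...) {
  stats <- pattern_row_stats(x)
  tibble(species = x$species, n_stigmas = x$n, pattern = x$pattern,
         model = stats$model, b = stats$b, adj_r_squared = stats$adj_r_squared,
         f_statistic = stats$f_statistic, p_value = stats$p_value)
}

# Table row statistics for a classified species: the chosen fit where one
# exists, the linear fit for no-pattern rows (the conventional tabulation),
# and NA slashes for species that received no HP at all.
pattern_row_stats <- function(x) {
  f <- x$chosen
  if (is.null(f) && x$pattern == "no_pattern") f <- x$fits$linear
  if (is.null(f) || !isTRUE(f$converged)) {
    return(list(model = NA_character_, b = NA_real_, adj_r_squared = NA_real_,
                f_statistic = NA_real_, p_value = NA_real_))
  }
  list(model = f$model, b = f$b, adj_r_squared = f$adj_r_squared,
       f_statistic = f$f_statistic, p_value = f$p_value)
}

#' Classify every species' CP-HP pattern
#'
#' Runs [classify_species()] per species on the analyzed (non-empty) stigmas.
#' Species with fewer than 3 analyzed stigmas are skipped with a warning.
#' The returned table mirrors a published pattern table: one row per species
#' with the stigma count, pattern label and the tabulated fit statistics
#' (the chosen model's where a pattern was found, the linear fit's for
#' no-pattern species, and `NA` for species without any HP). A per-pattern
#' tally is attached as the `"tally"` attribute.
#'
#' @param loads Stigma loads.
#' @param alpha Significance level.
#' @return A tibble: `species`, `n_stigmas`, `pattern`, `model`, `b`,
#'   `adj_r_squared`, `f_statistic`, `p_value`.
#' @export
classify_all <- function(loads, alpha = 0.05) {
  loads <- as_tibble(loads)
  analyzed <- exclude_empty(loads)
  species <- unique(loads$species)
  n_collected <- table(loads$species)
  rows <- list()
  skipped <- character(0)
  details <- list()
  for (sp in species) {
    sub <- analyzed %>% filter(.data$species == sp)
    if (nrow(sub) < 3) {
      skipped <- c(skipped, sp)
      next
    }
    cls <- classify_species(sub$cp, sub$hp, species = sp, alpha = alpha)
    row <- glance(cls)
    # n in the pattern table counts collected stigmas, not just analyzed ones
    row$n_stigmas <- as.integer(n_collected[[sp]])
    rows[[sp]] <- row
    details[[sp]] <- cls
  }
  if (length(skipped) > 0) {
    warn(paste0("species with fewer than 3 analyzed stigmas skipped: ",
                paste(skipped, collapse = ", ")))
  }
  out <- bind_rows(rows)
  attr(out, "tally") <- out %>%
    group_by(.data$pattern) %>%
    summarise(n_species = n(), .groups = "drop")
  attr(out, "details") <- details
  out
}

#' Scatter plot of CP against HP loads with both candidate fits
#'
#' @param loads Stigma loads for one or more species.
#' @param species Optional subset of species to plot (facets).
#' @param alpha Significance level used for the pattern annotation.
#' @return A ggplot object.
#' @export
plot_cp_hp <- function(loads, species = NULL, alpha = 0.05) {
  loads <- exclude_empty(as_tibble(loads))
  if (!is.null(species)) {
    loads <- loads %>% filter(.data$species %in% !!species)
  }
  curves <- loads %>%
    group_by(.data$species) %>%
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3 || sum(d$hp) == 0 || var(d$cp) == 0) return(tibble())
      cls <- classify_species(d$cp, d$hp, alpha = alpha)
      grid <- seq(min(d$cp), max(d$cp), length.out = 80)
      bind_rows(
        if (!is.null(cls$fits$linear)) {
          tibble(cp = grid, model = "linear",
                 hp = cls$fits$linear$intercept + cls$fits$linear$b * grid)
        },
        if (isTRUE(cls$fits$exponential$converged)) {
          tibble(cp = grid, model = "exponential",
                 hp = exp(cls$fits$exponential$intercept +
                            cls$fits$exponential$b * grid))
        }
      )
    }) %>% ungroup()
  p <- ggplot2::ggplot(loads, ggplot2::aes(x = .data$cp, y = .data$hp)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Conspecific pollen grains",
                  y = "Heterospecific pollen grains") +
    ggplot2::theme_minimal()
  if (nrow(curves) > 0) {
    p <- p + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$cp, y = .data$hp, colour = .data$model))
  }
  p + ggplot2::facet_wrap(~species, scales = "free")
}

check_fit_input <- function(cp, hp) {
  if (length(cp) != length(hp)) {
    abort("cp and hp must have equal length", class = "pollennet_usage_error")
  }
  if (length(cp) < 3) {
    abort("at least 3 stigmas are required for a fit",
          class = "pollennet_usage_error")
  }
  invisible(NULL)
}
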