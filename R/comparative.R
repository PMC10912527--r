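#' Apply the standard cross-species transformations
#'
#' Prepares a per-species table for among-species regressions: flower size
#' and HP proportion are log10-transformed, the specialization index d',
#' species strength and closeness centrality are square-root-transformed,
#' and floral symmetry is coded numerically (bilateral = 1, radial = 2).
#' Species with a zero HP proportion cannot be log-transformed; their
#' `log10_hp_prop` is `NA` and their labels are attached as the
#' `"zero_hp_species"` attribute so log-using analyses can exclude them while
#' other analyses retain them.
#'
#' @param data Per-species data frame with a `species` column and any of
#'   `symmetry`, `flower_size`, `hp_proportion`, `d_prime`, `strength`,
#'   `closeness`.
#' @return The input with transformed columns added (`symmetry_code`,
#'   `log10_flower_size`, `log10_hp_prop`, `sqrt_d_prime`, `sqrt_strength`,
#'   `sqrt_closeness` as applicable).
#' @export
apply_transforms <- function(data) {
  data <- as_tibble(data)
  out <- data
  if ("symmetry" %in% names(data)) {
    out$symmetry_code <- ifelse(data$symmetry == "bilateral", 1,
                                ifelse(data$symmetry == "radial", 2, NA_real_))
  }
  if ("flower_size" %in% names(data)) {
    check_nonneg(data$flower_size, data$species, "flower_size", strict = TRUE)
    out$log10_flower_size <- log10(data$flower_size)
  }
  zero_hp <- character(0)
  if ("hp_proportion" %in% names(data)) {
    check_nonneg(data$hp_proportion, data$species, "hp_proportion")
    zero_hp <- data$species[data$hp_proportion == 0]
    out$log10_hp_prop <- ifelse(data$hp_proportion > 0,
                                log10(data$hp_proportion), NA_real_)
  }
  for (col in c("d_prime", "strength", "closeness")) {
    if (col %in% names(data)) {
      check_nonneg(data[[col]], data$species, col)
      out[[paste0("sqrt_", col)]] <- sqrt(data[[col]])
    }
  }
  attr(out, "zero_hp_species") <- zero_hp
  out
}

check_nonneg <- function(x, species, what, strict = FALSE) {
  bad <- if (strict) which(x <= 0) else which(x < 0)
  if (length(bad) > 0) {
    abort(paste0(what, if (strict) " must be positive" else " must be non-negative",
                 " (species: ", paste(species[bad], collapse = ", "), ")"),
          class = "pollennet_validation_error")
  }
}

#' Multiple regression with standardized coefficients
#'
#' Ordinary least squares with an intercept. Alongside each raw coefficient
#' the standardized coefficient `b_std = b * SD(x) / SD(y)` is reported so
#' predictors on different scales can be compared; for a single-predictor
#' model `|b_std|` equals the Pearson correlation. Rows with missing values
#' in the response or any predictor are dropped.
#'
#' @param data Data frame of per-species values.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names.
#' @return An object of class `std_regression`. `tidy()` gives the per-term
#'   table (raw and standardized estimates, t, p); `glance()` gives the model
#'   R-squared, overall F and p, and n.
#' @export
fit_std_regression <- function(data, response, predictors) {
  data <- as_tibble(data)
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("column(s) not found: ", paste(missing_cols, collapse = ", ")),
          class = "pollennet_usage_error")
  }
  d <- data[, c(response, predictors)]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n <= length(predictors) + 1) {
    abort("not enough complete rows for the number of predictors",
          class = "pollennet_usage_error")
  }
  const <- predictors[vapply(predictors, function(p) var(d[[p]]) == 0, logical(1))]
  if (length(const) > 0) {
    abort(paste0("constant predictor(s): ", paste(const, collapse = ", ")),
          class = "pollennet_validation_error")
  }
  f <- stats::as.formula(paste(response, "~",
                               paste(sprintf("`%s`", predictors), collapse = " + ")))
  fit <- lm(f, data = d)
  if (any(is.na(coef(fit)))) {
    collinear <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("rank-deficient design; collinear term(s): ",
                 paste(collinear, collapse = ", ")),
          class = "pollennet_validation_error")
  }
  s <- summary(fit)
  ct <- s$coefficients
  sdy <- sd(d[[response]])
  terms <- rownames(ct)
  b_std <- vapply(seq_along(terms), function(i) {
    term <- gsub("`", "", terms[i])
    if (term == "(Intercept)") return(NA_real_)
    ct[i, 1] * sd(d[[term]]) / sdy
  }, numeric(1))
  out <- list(
    fit = fit,
    response = response,
    terms = tibble(
      term = gsub("`", "", terms),
      estimate = unname(ct[, 1]),
      std_estimate = b_std,
      statistic = unname(ct[, 3]),
      p_value = unname(ct[, 4])
    ),
    r_squared = s$r.squared,
    f_statistic = unname(s$fstatistic[1]),
    p_value = unname(pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                        lower.tail = FALSE)),
    n = n
  )
  class(out) <- "std_regression"
  out
}

#' @export
print.std_regression <- function(x, ...) {
  cat(sprintf("Regression of %s (n = %d): R^2 = %.3f, p = %.4g\n",
              x$response, x$n, x$r_squared, x$p_value))
  print(x$terms)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.std_regression <- function(x, ...) x$terms

#' @exportS3Method generics::glance
glance.std_regression <- function(x, ...) {
  tibble(response = x$response, r_squared = x$r_squared,
         f_statistic = x$f_statistic, p_value = x$p_value, n = x$n)
}

#' One-way analysis of variance
#'
#' Classic between/within decomposition: `F = MSB / MSW` with
#' `df_between = groups - 1` and `df_within = N - groups`, p from the F
#' distribution. Per-group sample sizes, means and standard errors are
#' reported alongside.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (same length as `values`).
#' @return An object of class `oneway_anova`. `tidy()` gives the per-group
#'   table; `glance()` the F statistic, p value and degrees of freedom.
#' @export
one_way_anova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2) {
    abort("at least 2 groups are required", class = "pollennet_usage_error")
  }
  if (length(values) - nlevels(groups) < 1) {
    abort("no within-group degrees of freedom", class = "pollennet_usage_error")
  }
  rss <- sum((values - stats::ave(values, groups))^2)
  if (rss == 0) {
    abort("zero within-group variance; F is undefined",
          class = "pollennet_degenerate_fit")
  }
  tab <- anova(lm(values ~ groups))
  grp <- tibble(group = levels(groups)) %>%
    mutate(
      n = unname(as.integer(table(groups)[.data$group])),
      mean = unname(vapply(.data$group, function(g) mean(values[groups == g]),
                           numeric(1))),
      se = unname(vapply(.data$group, function(g) {
        v <- values[groups == g]
        if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
      }, numeric(1)))
    )
  out <- list(
    groups = grp,
    statistic = tab$`F value`[1],
    p_value = tab$`Pr(>F)`[1],
    df_between = tab$Df[1],
    df_within = tab$Df[2]
  )
  class(out) <- "oneway_anova"
  out
}

#' @export
print.oneway_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$statistic, x$p_value))
  print(x$groups)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.oneway_anova <- function(x, ...) x$groups

#' @exportS3Method generics::glance
glance.oneway_anova <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         df_between = x$df_between, df_within = x$df_within)
}

#' Compare per-species variables across CP-HP pattern groups
#'
#' For each requested variable, reports the per-group mean and SE and a
#' one-way ANOVA across the three pattern groups (linear / exponential /
#' no pattern). Species without any HP are merged into the no-pattern group,
#' matching the conventional tabulation; increasing and decreasing variants
#' of a pattern are merged. By default flower size and HP proportion are
#' log10-transformed (species with zero HP are dropped from the
#' log-transformed variable, with no offset) and d' is square-root
#' transformed; other variables are compared untransformed.
#'
#' @param data Per-species data frame containing a `species` column, the
#'   variables and a pattern column.
#' @param variables Character vector of variable names to compare.
#' @param pattern_col Name of the pattern-label column.
#' @param transforms Named character vector mapping variable names to
#'   `"log10"` or `"sqrt"`.
#' @return An object of class `pattern_comparison` with `groups` (variable x
#'   group means and SEs) and `tests` (per-variable F, p, dfs). `tidy()`
#'   joins the two.
#' @export
pattern_group_comparison <- function(
    data, variables, pattern_col = "pattern",
    transforms = c(flower_size = "log10", hp_proportion = "log10",
                   d_prime = "sqrt")) {
  data <- as_tibble(data)
  missing_cols <- setdiff(c(variables, pattern_col), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("column(s) not found: ", paste(missing_cols, collapse = ", ")),
          class = "pollennet_usage_error")
  }
  grp <- pattern_group(data[[pattern_col]])
  groups_out <- list()
  tests_out <- list()
  for (v in variables) {
    x <- data[[v]]
    tr <- if (v %in% names(transforms)) transforms[[v]] else "identity"
    if (tr == "log10") {
      keep <- !is.na(x) & x > 0
      x <- ifelse(keep, log10(x), NA_real_)
    } else if (tr == "sqrt") {
      check_nonneg(x, data$species, v)
      x <- sqrt(x)
    }
    keep <- !is.na(x) & !is.na(grp)
    gl <- unique(grp[keep])
    g_stats <- tibble(group = sort(gl)) %>%
      mutate(
        n = unname(vapply(.data$group, function(g) sum(grp[keep] == g),
                          integer(1))),
        mean = unname(vapply(.data$group, function(g) mean(x[keep][grp[keep] == g]),
                             numeric(1))),
        se = unname(vapply(.data$group, function(g) {
          v2 <- x[keep][grp[keep] == g]
          if (length(v2) > 1) sd(v2) / sqrt(length(v2)) else NA_real_
        }, numeric(1))),
        variable = v, transform = tr
      )
    groups_out[[v]] <- g_stats
    if (length(gl) < 2) {
      warn(paste0("variable '", v, "' has fewer than 2 pattern groups; ",
                  "no F test performed"))
      next
    }
    aov1 <- one_way_anova(x[keep], grp[keep])
    tests_out[[v]] <- glance(aov1) %>%
      mutate(variable = v, transform = tr, n_used = sum(keep))
  }
  out <- list(
    groups = bind_rows(groups_out) %>%
      select("variable", "transform", "group", "n", "mean", "se"),
    tests = if (length(tests_out) == 0) {
      tibble(variable = character(), transform = character(),
             statistic = numeric(), p_value = numeric(),
             df_between = integer(), df_within = integer(),
             n_used = integer())
    } else {
      bind_rows(tests_out) %>%
        select("variable", "transform", "statistic", "p_value",
               "df_between", "df_within", "n_used")
    }
  )
  class(out) <- "pattern_comparison"
  out
}

#' Collapse detailed pattern labels into comparison groups
#'
#' `*_linear` labels map to `"linear"`, `*_exponential` to `"exponential"`,
#' and both `no_pattern` and `no_hp` to `"no_pattern"`.
#'
#' @param patterns Character vector of pattern labels.
#' @return Character vector of group labels.
#' @export
pattern_group <- function(patterns) {
  case_when(
    grepl("_linear$", patterns) ~ "linear",
    grepl("_exponential$", patterns) ~ "exponential",
    patterns %in% c("no_pattern", "no_hp") ~ "no_pattern",
    TRUE ~ NA_character_
  )
}

#' Two-group strategy labels from pattern labels
#'
#' Species with a significant CP-HP relationship (any linear or exponential
#' pattern) are labelled `"significant"`, those without (`no_pattern`,
#' `no_hp`) `"non_significant"` — the HP-tolerance vs HP-avoidance contrast.
#'
#' @param patterns Character vector of pattern labels.
#' @return Character vector with two levels.
#' @export
strategy_group <- function(patterns) {
  ifelse(pattern_group(patterns) == "no_pattern", "non_significant",
         "significant")
}

#' @export
print.pattern_comparison <- function(x, ...) {
  cat("Pattern-group comparison\n")
  print(x$tests)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pattern_comparison <- function(x, ...) {
  x$groups %>%
    left_join(x$tests %>% select("variable", "statistic", "p_value"),
              by = "variable")
}

#' @exportS3Method ggplot2::autoplot
autoplot.pattern_comparison <- function(object, ...) {
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      width = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "CP-HP pattern group", y = "Group mean") +
    ggplot2::theme_minimal()
}
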