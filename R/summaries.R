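#' Exclude empty stigmas from the analysis set
#'
#' Stigmas that received neither conspecific nor heterospecific grains
#' (`cp + hp = 0`) carry no deposition information and are removed before
#' per-species statistics are computed. The exclusion tally is attached as
#' the `"exclusion"` attribute (`n_total`, `n_excluded`, `pct_excluded`).
#'
#' @param loads Stigma loads (columns `stigma_id`, `species`, `cp`, `hp`,
#'   `hp_diversity`).
#' @return The analyzed loads (empty stigmas removed) with the exclusion
#'   attribute.
#' @export
exclude_empty <- function(loads) {
  loads <- as_tibble(loads)
  empty <- loads$cp + loads$hp == 0
  out <- loads[!empty, , drop = FALSE]
  attr(out, "exclusion") <- list(
    n_total = nrow(loads),
    n_excluded = sum(empty),
    pct_excluded = if (nrow(loads) > 0) 100 * sum(empty) / nrow(loads) else NA_real_
  )
  out
}

#' Pooled heterospecific pollen proportion
#'
#' `100 * sum(hp) / (sum(cp) + sum(hp))`, the share of all deposited grains
#' that are heterospecific.
#'
#' @param cp,hp Grain counts (vectors or scalars, summed internally).
#' @return Percentage in `[0, 100]`.
#' @export
hp_proportion <- function(cp, hp) {
  tot <- sum(cp) + sum(hp)
  if (tot == 0) return(NA_real_)
  100 * sum(hp) / tot
}

#' Per-species pollen deposition statistics
#'
#' For each species, over its analyzed (non-empty) stigmas: mean, standard
#' error (sample SD / sqrt(n), n - 1 denominator) and coefficient of
#' variation (100 * SD / mean, `NA` when the mean is zero) of the CP load,
#' HP load and HP donor diversity, plus the HP proportion. The HP proportion
#' defaults to the pooled form `100 * sum(hp) / (sum(cp) + sum(hp))`;
#' `hp_prop_mode = "per_stigma"` averages the per-stigma proportions instead.
#' Species with no analyzed stigmas are skipped with a warning.
#'
#' @param loads Stigma loads.
#' @param hp_prop_mode `"pooled"` or `"per_stigma"`.
#' @return A tibble with one row per species: stigma counts, means, SEs, CVs
#'   and `hp_proportion` (%).
#' @export
summarize_species <- function(loads, hp_prop_mode = c("pooled", "per_stigma")) {
  hp_prop_mode <- arg_match(hp_prop_mode)
  loads <- as_tibble(loads)
  totals <- loads %>%
    group_by(.data$species) %>%
    summarise(n_stigmas_total = n(), .groups = "drop")
  analyzed <- exclude_empty(loads)
  skipped <- setdiff(totals$species, unique(analyzed$species))
  if (length(skipped) > 0) {
    warn(paste0("species with no analyzed (non-empty) stigmas skipped: ",
                paste(skipped, collapse = ", ")))
  }
  cv <- function(x) {
    m <- mean(x)
    if (m == 0) NA_real_ else 100 * sd(x) / m
  }
  se <- function(x) sd(x) / sqrt(length(x))
  analyzed %>%
    group_by(.data$species) %>%
    summarise(
      n_stigmas_analyzed = n(),
      mean_cp = mean(.data$cp), se_cp = se(.data$cp), cv_cp = cv(.data$cp),
      mean_hp = mean(.data$hp), se_hp = se(.data$hp), cv_hp = cv(.data$hp),
      mean_hp_div = mean(.data$hp_diversity),
      se_hp_div = se(.data$hp_diversity),
      cv_hp_div = cv(.data$hp_diversity),
      hp_proportion = if (hp_prop_mode == "pooled") {
        hp_proportion(.data$cp, .data$hp)
      } else {
        mean(100 * .data$hp / (.data$cp + .data$hp))
      },
      .groups = "drop"
    ) %>%
    left_join(totals, by = "species") %>%
    select("species", "n_stigmas_total", "n_stigmas_analyzed",
           dplyr::everything())
}

#' Community-level pollen deposition summary
#'
#' Grain totals are pooled over all examined stigmas (empty stigmas
#' contribute zero), so the conspecific and heterospecific percentage shares
#' always sum to 100. The share of stigmas that received at least one HP
#' grain is computed over all examined stigmas, and the mean and SE of the
#' per-species stigma counts are reported.
#'
#' @param loads Stigma loads.
#' @return A one-row tibble with totals, shares and stigma-count statistics.
#' @export
summarize_community <- function(loads) {
  loads <- as_tibble(loads)
  counts <- loads %>%
    group_by(.data$species) %>%
    summarise(n = n(), .groups = "drop")
  n_empty <- sum(loads$cp + loads$hp == 0)
  total_cp <- sum(loads$cp)
  total_hp <- sum(loads$hp)
  tibble(
    n_stigmas = nrow(loads),
    n_species = nrow(counts),
    total_grains = total_cp + total_hp,
    total_cp = total_cp,
    total_hp = total_hp,
    pct_cp = 100 * total_cp / (total_cp + total_hp),
    pct_hp = 100 * total_hp / (total_cp + total_hp),
    pct_stigmas_with_hp = 100 * mean(loads$hp > 0),
    n_empty = n_empty,
    pct_empty = 100 * n_empty / nrow(loads),
    mean_stigmas_per_species = mean(counts$n),
    se_stigmas_per_species = sd(counts$n) / sqrt(nrow(counts))
  )
}

#' Flower display area from shape class and linear dimensions
#'
#' Areas (mm^2) of the floral visual unit by outline class:
#' * `circle`: `pi * r^2` (r = corolla radius);
#' * `flat_rect`: `L * W` (corolla length x width);
#' * `circle_plus_tube`: `pi * r^2 + pi * B * D` (tube bore diameter B,
#'   tube depth D);
#' * `rect_plus_tube`: `L * W + pi * B * D`;
#' * `legume`: `L * W + l * w` (banner plus wing).
#'
#' @param shape_class One of the classes above.
#' @param r,L,W,l,w,B,D Linear dimensions in mm; only those the shape
#'   requires need be given.
#' @return Area in mm^2.
#' @examples
#' flower_area("circle", r = 10)
#' flower_area("legume", L = 20, W = 10, l = 8, w = 5)
#' @export
flower_area <- function(shape_class, r = NULL, L = NULL, W = NULL,
                        l = NULL, w = NULL, B = NULL, D = NULL) {
  shape_class <- arg_match(shape_class,
    c("circle", "flat_rect", "circle_plus_tube", "rect_plus_tube", "legume"))
  need <- switch(shape_class,
    circle = "r",
    flat_rect = c("L", "W"),
    circle_plus_tube = c("r", "B", "D"),
    rect_plus_tube = c("L", "W", "B", "D"),
    legume = c("L", "W", "l", "w")
  )
  given <- list(r = r, L = L, W = W, l = l, w = w, B = B, D = D)
  for (d in need) {
    if (is.null(given[[d]]) || is.na(given[[d]])) {
      abort(paste0("shape '", shape_class, "' requires dimension '", d, "'"),
            class = "pollennet_validation_error")
    }
    if (given[[d]] <= 0) {
      abort(paste0("dimension '", d, "' must be positive"),
            class = "pollennet_validation_error")
    }
  }
  switch(shape_class,
    circle = pi * r^2,
    flat_rect = L * W,
    circle_plus_tube = pi * r^2 + pi * B * D,
    rect_plus_tube = L * W + pi * B * D,
    legume = L * W + l * w
  )
}

#' Share of species at or below an HP-proportion threshold
#'
#' Counts the species whose HP proportion, rounded to `digits` decimal places
#' (the precision of a printed summary table), is less than or equal to
#' `threshold`, and returns the share as a percentage. The inclusive
#' comparison on rounded values means a species tabulated at exactly the
#' threshold counts as at-or-below.
#'
#' @param summaries Per-species summary table with an `hp_proportion` column
#'   (percent), as from [summarize_species()].
#' @param threshold Threshold in percent.
#' @param digits Rounding precision applied before comparing.
#' @return A one-row tibble: `threshold`, `n_species`, `n_at_or_below`,
#'   `share_pct`.
#' @export
hp_threshold_census <- function(summaries, threshold = 10, digits = 1) {
  if (nrow(summaries) == 0) {
    abort("no species in summary table", class = "pollennet_usage_error")
  }
  hit <- round(summaries$hp_proportion, digits) <= threshold
  tibble(
    threshold = threshold,
    n_species = nrow(summaries),
    n_at_or_below = sum(hit),
    share_pct = 100 * mean(hit)
  )
}

#' Table-style per-species summary for printing
#'
#' Replaces undefined CVs (species whose mean load is zero) with 0, matching
#' the convention of printing 0 for species that received no HP, and rounds
#' to the given precision.
#'
#' @param summaries As from [summarize_species()].
#' @param digits Decimal places.
#' @return A tibble formatted for display/export.
#' @export
format_species_table <- function(summaries, digits = 1) {
  summaries %>%
    mutate(dplyr::across(dplyr::starts_with("cv_"),
                         ~ ifelse(is.na(.x), 0, .x))) %>%
    mutate(dplyr::across(dplyr::where(is.numeric), ~ round(.x, digits)))
}

#' Mean and SE of per-species pollen loads (plotting table)
#'
#' Long-format helper for plots comparing CP and HP loads per species.
#'
#' @param summaries As from [summarize_species()].
#' @return A tibble: `species`, `component` (`cp`/`hp`), `mean`, `se`.
#' @export
species_load_table <- function(summaries) {
  bind_rows(
    summaries %>%
      select("species", mean = "mean_cp", se = "se_cp") %>%
      mutate(component = "cp"),
    summaries %>%
      select("species", mean = "mean_hp", se = "se_hp") %>%
      mutate(component = "hp")
  )
}

#' @rdname species_load_table
#' @param se_width Width of the error bars.
#' @export
plot_species_loads <- function(summaries, se_width = 0.4) {
  df <- species_load_table(summaries)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$mean,
                                   fill = .data$component)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(width = 0.9), width = se_width) +
    ggplot2::labs(x = NULL, y = "Pollen grains per stigma",
                  fill = "Component") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
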