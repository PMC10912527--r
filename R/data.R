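#' Published per-species summary of the Yongxing Island community survey
#'
#' Per-species values from the published survey of 29 flowering plant
#' species on Yongxing Island (Paracel Islands, South China Sea): floral
#' symmetry (`R` radial / `B` bilateral), flower shape class and display
#' area (mm^2), heterospecific pollen percentage, number of stigmas
#' collected, and the CP-HP accrual pattern with its tabulated fit
#' statistics (adjusted R-squared, coefficient, F; the printed significance
#' string is kept verbatim in `p_printed`). The two species that received no
#' HP at all carry `NA` fit statistics. The raw per-stigma data behind these
#' summaries are not publicly deposited; these printed values are the
#' finest-grained real inputs available, and the synthetic-community
#' generator stands in for the rest.
#'
#' @return A tibble with 29 rows.
#' @seealso [yongxing_community()] for the community-level totals.
#' @examples
#' yongxing_survey()
#' @export
yongxing_survey <- function() {
  path <- system.file("extdata", "yongxing_survey.csv", package = "pollennet",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Community-level totals of the Yongxing Island survey
#'
#' Published community totals: stigmas examined and empty, pooled pollen
#' grain counts by origin, network size (plant and pollinator species,
#' unique links) and the Chao1 richness point estimate for the plant mode.
#'
#' @return A named numeric vector.
#' @examples
#' yongxing_community()["n_links"]
#' @export
yongxing_community <- function() {
  path <- system.file("extdata", "yongxing_community.csv",
                      package = "pollennet", mustWork = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  setNames(df$value, df$quantity)
}
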