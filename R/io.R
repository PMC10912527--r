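#' Read a plant-pollinator interaction edge list
#'
#' Reads a delimited text file (comma or tab separated, auto-detected) with
#' header columns `plant`, `pollinator` and optionally `weight` (defaulting
#' to 1). Species labels are whitespace-trimmed and treated as case-sensitive
#' opaque strings. Duplicate edges are merged by summing their weights.
#'
#' @param path Path to a CSV/TSV file.
#' @param quiet If `TRUE`, suppress the load-report message.
#' @return A tibble with columns `plant`, `pollinator`, `weight`, one row per
#'   unique link, sorted by plant then pollinator. A load report (number of
#'   distinct plants, pollinators and unique links) is attached as the
#'   `"report"` attribute and emitted as a message unless `quiet = TRUE`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("plant,pollinator,weight", "A,X,1", "A,X,2", "B,Y,1"), f)
#' read_interactions(f, quiet = TRUE)
#' @export
read_interactions <- function(path, quiet = FALSE) {
  df <- read_delim_auto(path)
  need <- c("plant", "pollinator")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "pollennet_schema_error"
    )
  }
  if (!"weight" %in% names(df)) df$weight <- 1
  df <- df %>%
    mutate(
      plant = trimws(as.character(.data$plant)),
      pollinator = trimws(as.character(.data$pollinator)),
      weight = as.numeric(.data$weight)
    )
  bad <- which(is.na(df$weight) | df$weight < 0)
  if (length(bad) > 0) {
    abort(
      paste0("Negative or non-numeric weight at data row(s): ",
             paste(head(bad, 5), collapse = ", ")),
      class = "pollennet_validation_error"
    )
  }
  edges <- df %>%
    group_by(.data$plant, .data$pollinator) %>%
    summarise(weight = sum(.data$weight), .groups = "drop") %>%
    arrange(.data$plant, .data$pollinator)
  report <- list(
    n_plants = n_distinct(edges$plant),
    n_pollinators = n_distinct(edges$pollinator),
    n_links = nrow(edges)
  )
  attr(edges, "report") <- report
  if (!quiet) {
    inform(sprintf(
      "Loaded %d unique links between %d plant and %d pollinator species.",
      report$n_links, report$n_plants, report$n_pollinators
    ))
  }
  edges
}

#' Read a stigma pollen table
#'
#' Two formats are supported. `"long"` files carry one row per (stigma, pollen
#' donor) pair with columns `stigma_id`, `focal_species`, `donor_species`,
#' `grains`; rows are aggregated per stigma into conspecific (CP) grains,
#' heterospecific (HP) grains and HP donor diversity. `"summary"` files carry
#' the per-stigma aggregates directly in columns `stigma_id`, `species`, `cp`,
#' `hp`, `hp_diversity`.
#'
#' Stigmas with `cp + hp = 0` ("empty" stigmas) are retained at load time and
#' excluded later at analysis time (see [exclude_empty()]).
#'
#' @param path Path to a CSV/TSV file.
#' @param format `"long"` or `"summary"`.
#' @return A tibble of stigma loads with columns `stigma_id`, `species`, `cp`,
#'   `hp`, `hp_diversity`.
#' @seealso [aggregate_stigma_records()] for the long-format aggregation rule.
#' @export
read_stigma_table <- function(path, format = c("long", "summary")) {
  if (length(format) == 1 && !format %in% c("long", "summary")) {
    abort(paste0("Unknown stigma table format: '", format,
                 "'. Use 'long' or 'summary'."),
          class = "pollennet_usage_error")
  }
  format <- arg_match(format)
  df <- read_delim_auto(path)
  if (format == "long") {
    need <- c("stigma_id", "focal_species", "donor_species", "grains")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols) > 0) {
      abort(paste0("Missing required column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "pollennet_schema_error")
    }
    records <- df %>%
      mutate(
        stigma_id = trimws(as.character(.data$stigma_id)),
        focal_species = trimws(as.character(.data$focal_species)),
        donor_species = trimws(as.character(.data$donor_species)),
        grains = .data$grains
      )
    check_counts(records$grains, "grains")
    aggregate_stigma_records(records)
  } else {
    need <- c("stigma_id", "species", "cp", "hp", "hp_diversity")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols) > 0) {
      abort(paste0("Missing required column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "pollennet_schema_error")
    }
    loads <- df %>%
      mutate(
        stigma_id = trimws(as.character(.data$stigma_id)),
        species = trimws(as.character(.data$species))
      ) %>%
      select("stigma_id", "species", "cp", "hp", "hp_diversity")
    validate_stigma_loads(loads)
    loads %>% mutate(
      cp = as.integer(.data$cp), hp = as.integer(.data$hp),
      hp_diversity = as.integer(.data$hp_diversity)
    )
  }
}

#' Aggregate long-format pollen records into per-stigma loads
#'
#' For each stigma of a focal species: `cp` is the total grains whose donor is
#' the focal species itself, `hp` the total grains from all other donors, and
#' `hp_diversity` the number of distinct non-focal donor species with at least
#' one grain. Duplicate (stigma, donor) rows are merged by summing grains, so
#' splitting a record across rows does not change the result. Donor labels of
#' `"UNKNOWN"` count toward `hp` and count as one donor species.
#'
#' @param records A data frame with columns `stigma_id`, `focal_species`,
#'   `donor_species`, `grains`.
#' @return A tibble of stigma loads (`stigma_id`, `species`, `cp`, `hp`,
#'   `hp_diversity`), one row per stigma, in order of first appearance.
#' @export
aggregate_stigma_records <- function(records) {
  records <- as_tibble(records)
  check_counts(records$grains, "grains")
  loads <- records %>%
    group_by(.data$focal_species, .data$stigma_id) %>%
    summarise(
      cp = sum(.data$grains[.data$donor_species == .data$focal_species[1]]),
      hp = sum(.data$grains[.data$donor_species != .data$focal_species[1]]),
      hp_diversity = n_distinct(
        .data$donor_species[.data$donor_species != .data$focal_species[1] &
                              .data$grains > 0]
      ),
      .groups = "drop"
    ) %>%
    rename(species = "focal_species") %>%
    select("stigma_id", "species", "cp", "hp", "hp_diversity") %>%
    mutate(cp = as.integer(.data$cp), hp = as.integer(.data$hp),
           hp_diversity = as.integer(.data$hp_diversity))
  # preserve input stigma order within species-independent first appearance
  first_seen <- records %>%
    distinct(.data$stigma_id, .data$focal_species) %>%
    mutate(.ord = row_number()) %>%
    rename(species = "focal_species")
  loads %>%
    left_join(first_seen, by = c("stigma_id", "species")) %>%
    arrange(.data$.ord) %>%
    select(-".ord")
}

#' Read a species trait table
#'
#' Expects columns `species`, `symmetry` and either a `flower_size` column
#' (area in mm^2) or a `shape_class` column plus the linear dimensions (mm)
#' the shape requires (see [flower_area()]). Symmetry codes `R`/`radial` and
#' `B`/`bilateral` (case-insensitive) are normalized to `"radial"` and
#' `"bilateral"`.
#'
#' @param path Path to a CSV/TSV file.
#' @return A tibble with columns `species`, `symmetry`, `flower_size`.
#' @export
read_traits <- function(path) {
  df <- read_delim_auto(path)
  need <- c("species", "symmetry")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pollennet_schema_error")
  }
  df <- df %>% mutate(species = trimws(as.character(.data$species)))
  sym <- tolower(trimws(as.character(df$symmetry)))
  codes <- c(r = "radial", radial = "radial", b = "bilateral",
             bilateral = "bilateral")
  unknown <- unique(sym[!sym %in% names(codes)])
  if (length(unknown) > 0) {
    abort(paste0("Unknown symmetry code(s): ",
                 paste(unknown, collapse = ", "),
                 ". Legal codes: R, B, radial, bilateral."),
          class = "pollennet_validation_error")
  }
  df$symmetry <- unname(codes[sym])
  if (!"flower_size" %in% names(df) && !"shape_class" %in% names(df)) {
    abort("Provide either a flower_size column or a shape_class column with dimensions.",
          class = "pollennet_schema_error")
  }
  size <- rep(NA_real_, nrow(df))
  if ("flower_size" %in% names(df)) size <- as.numeric(df$flower_size)
  if ("shape_class" %in% names(df)) {
    dims <- c("r", "L", "W", "l", "w", "B", "D")
    for (i in which(is.na(size) & !is.na(df$shape_class))) {
      args <- lapply(dims, function(d) {
        if (d %in% names(df)) as.numeric(df[[d]][i]) else NULL
      })
      names(args) <- dims
      args <- args[!vapply(args, function(x) is.null(x) || is.na(x), logical(1))]
      size[i] <- do.call(flower_area, c(list(shape_class = df$shape_class[i]), args))
    }
  }
  if (anyNA(size)) {
    abort(paste0("Species without flower size or computable shape: ",
                 paste(df$species[is.na(size)], collapse = ", ")),
          class = "pollennet_validation_error")
  }
  if (any(size <= 0)) {
    abort("flower_size must be positive.", class = "pollennet_validation_error")
  }
  tibble(species = df$species, symmetry = df$symmetry, flower_size = size)
}

#' Cross-check the three input tables
#'
#' Produces a report-only consistency summary: species present in the stigma
#' table but absent from the traits table or the interaction network
#' (warnings, not errors), the number of empty stigmas that will be excluded
#' from analysis, and per-species stigma counts.
#'
#' @param loads Stigma loads, as from [read_stigma_table()].
#' @param traits Optional traits table, as from [read_traits()].
#' @param edges Optional interaction edge list, as from [read_interactions()].
#' @return An object of class `dataset_validation` with elements `warnings`
#'   (tibble: `species`, `issue`), `n_stigmas`, `n_empty`, `pct_empty` and
#'   `stigma_counts` (tibble: `species`, `n_stigmas`).
#' @export
validate_dataset <- function(loads, traits = NULL, edges = NULL) {
  loads <- as_tibble(loads)
  validate_stigma_loads(loads)
  warnings <- tibble(species = character(), issue = character())
  sp <- unique(loads$species)
  if (!is.null(traits)) {
    miss <- setdiff(sp, traits$species)
    if (length(miss) > 0) {
      warnings <- bind_rows(warnings,
        tibble(species = miss, issue = "absent from traits table"))
    }
  }
  if (!is.null(edges)) {
    miss <- setdiff(sp, unique(edges$plant))
    if (length(miss) > 0) {
      warnings <- bind_rows(warnings,
        tibble(species = miss, issue = "absent from interaction network"))
    }
  }
  n_empty <- sum(loads$cp + loads$hp == 0)
  out <- list(
    warnings = warnings,
    n_stigmas = nrow(loads),
    n_empty = n_empty,
    pct_empty = if (nrow(loads) > 0) 100 * n_empty / nrow(loads) else NA_real_,
    stigma_counts = loads %>%
      group_by(.data$species) %>%
      summarise(n_stigmas = n(), .groups = "drop")
  )
  class(out) <- "dataset_validation"
  out
}

#' @export
print.dataset_validation <- function(x, ...) {
  cat(sprintf("Stigma table: %d stigmas across %d species\n",
              x$n_stigmas, nrow(x$stigma_counts)))
  cat(sprintf("%d excluded-from-analysis candidates (empty stigmas, %.1f%%)\n",
              x$n_empty, x$pct_empty))
  if (nrow(x$warnings) == 0) {
    cat("No cross-table warnings.\n")
  } else {
    cat(sprintf("%d warning(s):\n", nrow(x$warnings)))
    for (i in seq_len(nrow(x$warnings))) {
      cat(sprintf("  - %s: %s\n", x$warnings$species[i], x$warnings$issue[i]))
    }
  }
  invisible(x)
}

#' Write result tables and run metadata to a directory
#'
#' Writes each data frame in `results` as a CSV named after its list element,
#' plus a `run_metadata.txt` file recording the package version and any
#' scalar entries of `config`. Output is deterministic: re-running with the
#' same inputs produces byte-identical files (no timestamps).
#'
#' @param results Named list of data frames (and optionally a `config` list).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, mode = 2) != 0) {
    abort(paste0("Cannot write to directory: ", dir), class = "pollennet_io_error")
  }
  config <- results$config
  tables <- results[vapply(results, is.data.frame, logical(1))]
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p)
    paths <- c(paths, p)
  }
  meta <- c(
    paste0("pollennet_version: ", as.character(utils::packageVersion("pollennet")))
  )
  if (!is.null(config)) {
    scalars <- config[vapply(config, function(x) is.atomic(x) && length(x) == 1,
                             logical(1))]
    meta <- c(meta, paste0(names(scalars), ": ",
                           vapply(scalars, as.character, character(1))))
  }
  mp <- file.path(dir, "run_metadata.txt")
  writeLines(meta, mp)
  invisible(c(paths, mp))
}

# ---- internal helpers -------------------------------------------------------

read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "pollennet_io_error")
  }
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    trim_ws = TRUE, progress = FALSE)
}

check_counts <- function(x, what) {
  if (anyNA(x) || any(x < 0) || any(x != round(x))) {
    bad <- which(is.na(x) | x < 0 | x != round(x))
    abort(paste0(what, " must be non-negative integers (data row(s) ",
                 paste(head(bad, 5), collapse = ", "), ")"),
          class = "pollennet_validation_error")
  }
}

validate_stigma_loads <- function(loads) {
  for (col in c("cp", "hp", "hp_diversity")) {
    check_counts(loads[[col]], col)
  }
  bad <- which(loads$hp_diversity > loads$hp |
                 (loads$hp_diversity == 0) != (loads$hp == 0))
  if (length(bad) > 0) {
    abort(paste0(
      "hp_diversity must be <= hp and zero exactly when hp is zero ",
      "(data row(s) ", paste(head(bad, 5), collapse = ", "), ")"),
      class = "pollennet_validation_error")
  }
  invisible(loads)
}
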