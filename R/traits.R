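# Environment-independence trait: classify peptides by their coefficient of
# variation across timepoints against a replicate-culture-derived cutoff, and
# compute the environment-independent proteomic mass fraction (a proxy for
# low regulatory cost).

#' Coefficient of variation of a peptide abundance series
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean of the
#' taxon-normalized, filter-combined abundances across timepoints.
#'
#' @param values Numeric abundance series (one value per timepoint; `NA`s
#'   dropped).
#' @return CV (dimensionless); `NA` when fewer than two values are defined
#'   or the mean is zero.
#' @export
#' @examples
#' peptide_cv(c(1, 3))  # sqrt(2) / 2
peptide_cv <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / m
}

#' Filter-combined, taxon-normalized peptide series
#'
#' Builds the per-peptide abundance series that the CV classification runs
#' on: presence filtering, per-injection normalization, injection averaging,
#' taxon normalization (each taxon's unique peptides sum to 1 per sample),
#' then combination across filter sizes with per-(taxon, timepoint) filter
#' weights derived from taxon-unique peptide counts. Weights are
#' renormalized over the filters where a peptide is observed.
#'
#' @param table IntensityTable (see [presence_filter()]).
#' @param peptide_map [build_peptide_map()] output.
#' @param normalization,tic_table See [normalize_and_average()].
#' @param combine_filters Combine across filters (default) or keep per-filter
#'   series (then a `filter` column is retained).
#' @return Tibble `taxon`, `peptide`, `pool`, `timepoint`, `value`.
#' @export
taxon_peptide_series <- function(table, peptide_map,
                                 normalization = c("sum", "tic"),
                                 tic_table = NULL, combine_filters = TRUE) {
  averaged <- normalize_and_average(presence_filter(table),
                                    match.arg(normalization), tic_table)
  tn <- taxon_normalize(averaged, peptide_map)
  if (!combine_filters) return(tn)
  weights <- tn |>
    dplyr::group_by(.data$taxon, .data$timepoint, .data$filter) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop_last") |>
    dplyr::mutate(weight = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  tn |>
    dplyr::left_join(weights[, c("taxon", "timepoint", "filter", "weight")],
                     by = c("taxon", "timepoint", "filter")) |>
    dplyr::group_by(.data$taxon, .data$peptide, .data$pool, .data$timepoint) |>
    dplyr::summarise(value = sum(.data$weight * .data$value) /
                       sum(.data$weight), .groups = "drop")
}

#' Per-peptide CV records
#'
#' Summarises a filter-combined series into one row per (taxon, peptide):
#' the CV across timepoints and the mean abundance.
#'
#' @param series Output of [taxon_peptide_series()].
#' @param min_timepoints Minimum timepoints required for a defined CV
#'   (default 2); peptides below it get `cv = NA` and are excluded by
#'   [classify_peptides()].
#' @return Tibble (`CVRecord`s): `taxon`, `peptide`, `pool`,
#'   `mean_norm_intensity`, `cv`, `n_timepoints`.
#' @export
peptide_cv_table <- function(series, min_timepoints = 2L) {
  series |>
    dplyr::group_by(.data$taxon, .data$peptide, .data$pool) |>
    dplyr::summarise(
      mean_norm_intensity = mean(.data$value),
      cv = if (dplyr::n() >= min_timepoints) peptide_cv(.data$value)
           else NA_real_,
      n_timepoints = dplyr::n(),
      .groups = "drop"
    )
}

#' Derive the environment-dependence CV cutoff from replicate cultures
#'
#' For each culture condition, computes protein-level CVs across replicate
#' measurements, takes the third quartile (linear-interpolation quantile) of
#' that distribution, and averages the third quartiles over conditions.
#' Proteins whose expression varies more than this cutoff across field
#' conditions are considered environment-dependent: replicate cultures bound
#' the variation expected without any environmental change.
#'
#' @param cultures A `replicate_cultures` object from
#'   [simulate_replicate_cultures()], or a tibble with columns `condition`,
#'   `protein`, `replicate`, `abundance`.
#' @return List of class `cutoff_spec`: `q3_by_condition` (named numeric)
#'   and `cutoff` (their mean).
#' @export
derive_cutoff <- function(cultures) {
  ab <- if (inherits(cultures, "replicate_cultures")) cultures$abundance
        else cultures
  stopifnot(all(c("condition", "protein", "replicate", "abundance")
                %in% names(ab)))
  reps <- ab |>
    dplyr::group_by(.data$condition, .data$protein) |>
    dplyr::summarise(n = dplyr::n(), cv = peptide_cv(.data$abundance),
                     .groups = "drop")
  bad <- reps$condition[reps$n < 2]
  if (length(bad)) {
    stop("condition(s) with fewer than 2 replicates: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  q3 <- reps |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(q3 = stats::quantile(.data$cv, 0.75, type = 7,
                                          names = FALSE), .groups = "drop")
  structure(list(q3_by_condition = stats::setNames(q3$q3, q3$condition),
                 cutoff = mean(q3$q3)),
            class = "cutoff_spec")
}

#' Classify peptides as environment-dependent or -independent
#'
#' Peptides with `cv <= cutoff` are environment-independent (ties fall to
#' independent, a deterministic boundary rule); `cv > cutoff` are
#' environment-dependent. Peptides with undefined CV are excluded and their
#' count stored in attribute `"n_undefined"`.
#'
#' @param cv_table [peptide_cv_table()] output.
#' @param cutoff A `cutoff_spec` from [derive_cutoff()], or a single number.
#' @return `cv_table` rows with defined CV plus an `env_class` column.
#' @export
classify_peptides <- function(cv_table, cutoff) {
  cut <- if (inherits(cutoff, "cutoff_spec")) cutoff$cutoff else cutoff
  stopifnot(is.numeric(cut), length(cut) == 1L, cut >= 0)
  defined <- !is.na(cv_table$cv)
  out <- cv_table[defined, ]
  out$env_class <- ifelse(out$cv <= cut, "independent", "dependent")
  attr(out, "n_undefined") <- sum(!defined)
  out
}

#' Environment-independent proteomic mass fraction
#'
#' Per taxon: the summed mean abundance of environment-independent peptides
#' divided by the summed mean abundance of all classified peptides of that
#' taxon. The independent and dependent fractions sum to 1.
#'
#' @param classified [classify_peptides()] output.
#' @param taxon Optional single taxon; default all taxa in the table.
#' @return Tibble `taxon`, `fraction` (environment-independent),
#'   `n_independent`, `n_dependent`.
#' @export
environment_independent_fraction <- function(classified, taxon = NULL) {
  tab <- if (is.null(taxon)) classified
         else classified[classified$taxon %in% taxon, ]
  if (nrow(tab) == 0L) {
    stop("no classified peptides", if (!is.null(taxon))
      paste0(" for taxon ", taxon), call. = FALSE)
  }
  tab |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(
      fraction = sum(.data$mean_norm_intensity[.data$env_class ==
                                                 "independent"]) /
        sum(.data$mean_norm_intensity),
      n_independent = sum(.data$env_class == "independent"),
      n_dependent = sum(.data$env_class == "dependent"),
      .groups = "drop"
    )
}

#' Dependence balance of protein functional clusters
#'
#' For each protein cluster, the number of environment-dependent peptides
#' minus the number of environment-independent peptides: positive values
#' flag clusters whose members are mostly regulated with the environment.
#'
#' @param classified [classify_peptides()] output.
#' @param clusters Tibble `peptide`, `cluster` mapping peptides to protein
#'   functional clusters.
#' @return Tibble `cluster`, `n_dependent`, `n_independent`, `balance`.
#' @export
functional_class_balance <- function(classified, clusters) {
  stopifnot(all(c("peptide", "cluster") %in% names(clusters)))
  classified |>
    dplyr::inner_join(clusters, by = "peptide") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_dependent = sum(.data$env_class == "dependent"),
      n_independent = sum(.data$env_class == "independent"),
      .groups = "drop"
    ) |>
    dplyr::mutate(balance = .data$n_dependent - .data$n_independent)
}
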