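# Coarse-grained quantification: normalization, presence filtering, proteomic
# mass fractions, filter-size weighting and combination, and taxon relative
# abundance.
#
# The working representation (IntensityTable) is a tidy tibble with columns
# peptide, timepoint, filter, injection, intensity; one row per observed
# (identified) peptide per injection. TICs live in a separate tibble keyed by
# (timepoint, filter, injection).

#' Presence filter across replicate injections
#'
#' A peptide is considered present at a (timepoint, filter) sample only if it
#' was observed (intensity > 0) in every injection of that sample; otherwise
#' all its rows for that sample are dropped. Injections present in the table
#' define the sample's injection set.
#'
#' @param table IntensityTable tibble (`peptide`, `timepoint`, `filter`,
#'   `injection`, `intensity`).
#' @return Filtered IntensityTable.
#' @export
presence_filter <- function(table) {
  stopifnot(all(c("peptide", "timepoint", "filter", "injection", "intensity")
                %in% names(table)))
  table |>
    dplyr::filter(.data$intensity > 0) |>
    dplyr::group_by(.data$timepoint, .data$filter) |>
    dplyr::mutate(.n_inj = dplyr::n_distinct(.data$injection)) |>
    dplyr::group_by(.data$peptide, .add = TRUE) |>
    dplyr::filter(dplyr::n_distinct(.data$injection) == .data$.n_inj[1]) |>
    dplyr::ungroup() |>
    dplyr::select(-".n_inj")
}

#' Normalization factor of one injection
#'
#' The sum of identified peptide intensities in one injection, used to scale
#' peptide abundances. Database-dependent: peptides missing from the search
#' database shrink it.
#'
#' @param table IntensityTable.
#' @param timepoint,filter,injection Sample key.
#' @return Intensity sum (scalar).
#' @export
normalization_factor <- function(table, timepoint, filter, injection) {
  rows <- table$timepoint == timepoint & table$filter == filter &
    table$injection == injection
  if (!any(rows)) {
    stop("no identified peptides for sample (", timepoint, ", ", filter,
         ", ", injection, "): normalization undefined", call. = FALSE)
  }
  sum(table$intensity[rows])
}

#' Database-independent TIC normalization factor
#'
#' Returns the recorded total ion current of one injection: the sum of all
#' MS1 signal, identified or not, hence independent of the search database.
#'
#' @param tic_table Tibble `timepoint`, `filter`, `injection`, `tic`.
#' @param timepoint,filter,injection Sample key.
#' @return TIC (scalar).
#' @export
tic_normalization_factor <- function(tic_table, timepoint, filter, injection) {
  rows <- tic_table$timepoint == timepoint & tic_table$filter == filter &
    tic_table$injection == injection
  if (!any(rows) || is.na(tic_table$tic[rows][1])) {
    stop("no TIC recorded for sample (", timepoint, ", ", filter, ", ",
         injection, ")", call. = FALSE)
  }
  tic_table$tic[rows][1]
}

#' Sensitivity of an inferred abundance to normalization-factor variation
#'
#' A relative variation `v` in the normalization factor perturbs an inferred
#' peptide abundance symmetrically: a raw intensity `x` maps to the interval
#' `x * (1 - v/2)` .. `x * (1 + v/2)`. For example an intensity of 100 under
#' 16% variation yields the interval (92, 108).
#'
#' @param raw_intensity Non-negative intensity.
#' @param relative_variation Relative variation of the normalization factor,
#'   in `[0, 2)`.
#' @return Named numeric `c(low, high)`.
#' @export
#' @examples
#' normalization_sensitivity(100, 0.16)
normalization_sensitivity <- function(raw_intensity, relative_variation) {
  if (any(raw_intensity < 0)) stop("raw_intensity must be >= 0", call. = FALSE)
  if (relative_variation < 0 || relative_variation >= 2) {
    stop("relative_variation must be in [0, 2)", call. = FALSE)
  }
  c(low = raw_intensity * (1 - relative_variation / 2),
    high = raw_intensity * (1 + relative_variation / 2))
}

#' Normalize injections and average replicates
#'
#' Divides each injection's peptide intensities by its normalization factor
#' (identified-peptide sum, or TIC when `normalization = "tic"`), then
#' averages the normalized abundances across replicate injections of each
#' (timepoint, filter) sample.
#'
#' @param table IntensityTable (apply [presence_filter()] first for the
#'   standard pipeline).
#' @param normalization `"sum"` (default) or `"tic"`.
#' @param tic_table Required when `normalization = "tic"`.
#' @return Tibble `peptide`, `timepoint`, `filter`, `norm` (mean normalized
#'   abundance).
#' @export
normalize_and_average <- function(table, normalization = c("sum", "tic"),
                                  tic_table = NULL) {
  normalization <- match.arg(normalization)
  tbl <- table |>
    dplyr::group_by(.data$timepoint, .data$filter, .data$injection)
  if (normalization == "sum") {
    tbl <- dplyr::mutate(tbl, norm = .data$intensity / sum(.data$intensity))
  } else {
    if (is.null(tic_table)) stop("tic_table required for TIC normalization",
                                 call. = FALSE)
    tbl <- tbl |>
      dplyr::group_modify(function(df, key) {
        f <- tic_normalization_factor(tic_table, key$timepoint, key$filter,
                                      key$injection)
        df$norm <- df$intensity / f
        df
      })
  }
  tbl |>
    dplyr::group_by(.data$peptide, .data$timepoint, .data$filter) |>
    dplyr::summarise(norm = mean(.data$norm), .groups = "drop")
}

#' Normalize a taxon's peptides to its own biomass
#'
#' Divides each taxon-unique peptide's (averaged, normalized) abundance by
#' the summed abundance of all that taxon's unique peptides in the same
#' (timepoint, filter) sample, so the taxon's peptides sum to 1 there.
#'
#' @param averaged Output of [normalize_and_average()].
#' @param peptide_map [build_peptide_map()] output.
#' @param taxon Optional single taxon to restrict to.
#' @return Tibble `taxon`, `peptide`, `timepoint`, `filter`, `value`; samples
#'   with no taxon-unique peptide for a taxon simply yield no rows (the
#'   estimate is undefined, not zero).
#' @export
taxon_normalize <- function(averaged, peptide_map, taxon = NULL) {
  um <- peptide_map[peptide_map$taxon_unique, c("peptide", "taxon", "pool")]
  if (!is.null(taxon)) um <- um[um$taxon %in% taxon, ]
  averaged |>
    dplyr::inner_join(um, by = "peptide") |>
    dplyr::group_by(.data$taxon, .data$timepoint, .data$filter) |>
    dplyr::mutate(value = .data$norm / sum(.data$norm)) |>
    dplyr::ungroup() |>
    dplyr::select("taxon", "peptide", "pool", "timepoint", "filter", "value")
}

#' Proteomic mass fraction of a coarse-grained pool
#'
#' The mass fraction of `pool` in `taxon` at one (timepoint, filter): the
#' summed abundance of peptides unique to both the taxon and the pool,
#' divided by the summed abundance of all peptides unique to the taxon.
#'
#' @param averaged Output of [normalize_and_average()] (presence-filtered,
#'   per-injection normalized, injection-averaged abundances).
#' @param taxon,pool,timepoint,filter Estimate context.
#' @param peptide_map [build_peptide_map()] output.
#' @return One-row tibble `taxon`, `pool`, `timepoint`, `filter`, `value`,
#'   `n_peptides` (taxon-and-pool-unique peptides supporting the numerator).
#'   `value` is `NA` when the taxon-specific denominator is zero (undefined
#'   estimate).
#' @export
mass_fraction <- function(averaged, taxon, pool, timepoint, filter,
                          peptide_map) {
  um <- peptide_map[peptide_map$taxon_unique, ]
  sub <- averaged[averaged$timepoint == timepoint & averaged$filter == filter, ]
  sub <- dplyr::inner_join(sub, um[, c("peptide", "taxon", "pool",
                                       "pool_unique")], by = "peptide")
  sub <- sub[sub$taxon == taxon, ]
  denom <- sum(sub$norm)
  in_pool <- sub$pool_unique & sub$pool == pool
  tibble::tibble(
    taxon = taxon, pool = pool, timepoint = timepoint, filter = filter,
    value = if (denom > 0) sum(sub$norm[in_pool]) / denom else NA_real_,
    n_peptides = sum(in_pool)
  )
}

#' Filter weights from per-filter peptide counts
#'
#' Weights each filter by the number of relevant peptides observed on it at
#' a timepoint, divided by the total across filters: `w_f = n_f / sum(n)`.
#' Weights sum to 1; filters with no observations get weight 0.
#'
#' @param counts Named non-negative numeric vector of per-filter peptide
#'   counts.
#' @return Named numeric weights summing to 1.
#' @export
#' @examples
#' filter_weights(c("3.0" = 90, "0.8" = 10, "0.1" = 0))
filter_weights <- function(counts) {
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("all-zero peptide counts: weights undefined",
                       call. = FALSE)
  counts / total
}

#' Combine per-filter estimates into one weighted estimate
#'
#' Multiplies each filter's estimate by its weight and sums. Filters with an
#' undefined (`NA`) estimate are dropped and the remaining weights are
#' renormalized, so the result is a convex combination of the defined
#' estimates.
#'
#' @param values Named numeric per-filter estimates (may contain `NA`).
#' @param weights Named numeric weights covering the filters of `values`.
#' @return Combined estimate (scalar; `NA` if no estimate is defined).
#' @export
#' @examples
#' combine_across_filters(c("3.0" = 0.2, "0.8" = 0.4),
#'                        c("3.0" = 0.9, "0.8" = 0.1))
combine_across_filters <- function(values, weights) {
  keep <- names(values)[!is.na(values)]
  if (length(keep) == 0L) return(NA_real_)
  w <- weights[keep]
  if (anyNA(w)) stop("weights missing for filters: ",
                     paste(setdiff(keep, names(weights)), collapse = ", "),
                     call. = FALSE)
  if (sum(w) == 0) return(NA_real_)
  w <- w / sum(w)
  sum(w * values[keep])
}

#' Full coarse-grained mass-fraction table
#'
#' The standard pipeline from an IntensityTable to per-(taxon, pool,
#' timepoint) mass fractions: presence filter, per-injection normalization,
#' injection averaging, per-filter mass fractions, then filter-weighted
#' combination. Filter weights are estimate-specific: for each (taxon, pool,
#' timepoint) they derive from the counts of taxon-and-pool-unique peptides
#' observed per filter.
#'
#' @param table IntensityTable.
#' @param peptide_map [build_peptide_map()] output.
#' @param normalization,tic_table See [normalize_and_average()].
#' @param pools Pools to quantify (default ribosomal and photosynthetic).
#' @return Tidy tibble `taxon`, `pool`, `timepoint`, `filter` (the three
#'   filter classes plus `"combined"`), `value`, `n_peptides`, `weight`.
#' @export
pool_fraction_table <- function(table, peptide_map,
                                normalization = c("sum", "tic"),
                                tic_table = NULL,
                                pools = c("ribosomal", "photosynthetic")) {
  averaged <- normalize_and_average(presence_filter(table),
                                    match.arg(normalization), tic_table)
  taxa <- sort(unique(peptide_map$taxon[peptide_map$taxon_unique]))
  tps <- sort(unique(averaged$timepoint))
  filters <- intersect(FILTER_CLASSES, unique(averaged$filter))
  grid <- tidyr::expand_grid(taxon = taxa, pool = pools, timepoint = tps)
  out <- list()
  for (i in seq_len(nrow(grid))) {
    per_filter <- dplyr::bind_rows(lapply(filters, function(f) {
      mass_fraction(averaged, grid$taxon[i], grid$pool[i], grid$timepoint[i],
                    f, peptide_map)
    }))
    counts <- stats::setNames(per_filter$n_peptides, per_filter$filter)
    if (sum(counts) > 0) {
      w <- filter_weights(counts)
      comb <- combine_across_filters(
        stats::setNames(per_filter$value, per_filter$filter), w)
    } else {
      w <- stats::setNames(rep(NA_real_, length(filters)), filters)
      comb <- NA_real_
    }
    per_filter$weight <- unname(w[per_filter$filter])
    out[[i]] <- dplyr::bind_rows(
      per_filter,
      tibble::tibble(taxon = grid$taxon[i], pool = grid$pool[i],
                     timepoint = grid$timepoint[i], filter = "combined",
                     value = comb, n_peptides = sum(counts),
                     weight = NA_real_)
    )
  }
  dplyr::bind_rows(out)
}

#' Taxon relative abundance at a timepoint
#'
#' Each filter contributes the taxon's share of that filter's normalized
#' peptide signal (the sum of its taxon-unique normalized abundances),
#' scaled by the filter's share of total protein mass that day. The scaled
#' per-filter estimates are combined with weights from the taxon's
#' per-filter unique-peptide counts, renormalized over the filters where
#' the taxon is observed. Abundances over taxa sum to at most 1 per
#' timepoint (peptides mapping to multiple taxa support no taxon).
#'
#' @param table IntensityTable.
#' @param peptide_map [build_peptide_map()] output.
#' @param protein_mass Named numeric: total protein mass per filter at this
#'   timepoint (all three filters required for observed filters).
#' @param timepoint Timepoint label.
#' @param normalization,tic_table See [normalize_and_average()].
#' @return Tibble `taxon`, `timepoint`, `abundance`.
#' @export
taxon_relative_abundance <- function(table, peptide_map, protein_mass,
                                     timepoint,
                                     normalization = c("sum", "tic"),
                                     tic_table = NULL) {
  averaged <- normalize_and_average(presence_filter(table),
                                    match.arg(normalization), tic_table)
  averaged <- averaged[averaged$timepoint == timepoint, ]
  filters <- intersect(FILTER_CLASSES, unique(averaged$filter))
  if (anyNA(protein_mass[filters]) || any(protein_mass[filters] <= 0)) {
    stop("protein_mass must be a positive value for every observed filter",
         call. = FALSE)
  }
  mass_share <- protein_mass[filters] / sum(protein_mass[filters])
  um <- peptide_map[peptide_map$taxon_unique, c("peptide", "taxon")]
  per <- averaged |>
    dplyr::inner_join(um, by = "peptide") |>
    dplyr::group_by(.data$taxon, .data$filter) |>
    dplyr::summarise(share = sum(.data$norm), n = dplyr::n(), .groups = "drop")
  per |>
    dplyr::group_by(.data$taxon) |>
    dplyr::group_modify(function(df, key) {
      w <- df$n / sum(df$n)
      tibble::tibble(abundance = sum(
        w * mass_share[as.character(df$filter)] * df$share))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(timepoint = timepoint) |>
    dplyr::select("taxon", "timepoint", "abundance")
}
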