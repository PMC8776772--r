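# Data-dependent acquisition (DDA) simulator: top-N precursor selection with
# dynamic exclusion over a simulated LC gradient, producing observed peptide
# intensity tables that can be scored against the generator's ground truth.

#' DDA acquisition and cofragmentation parameters
#'
#' @param gradient_length LC gradient length, minutes (default 125).
#' @param max_injection_time Maximum ion injection time, minutes (default
#'   0.008333, i.e. 0.5 s); consumed by the cofragmentation score, not the
#'   acquisition loop.
#' @param isolation_window Precursor selection window, m/z (default 3).
#' @param peak_width Chromatographic ion peak width, minutes (default 1.44);
#'   the elution profile is Gaussian with `sigma = peak_width / 4`, so about
#'   95% of the ion signal falls within one peak width of the apex.
#' @param sparse_sampling_degree Degree of sparse sampling (default 5);
#'   divides the cofragmentation score.
#' @param top_n Precursors fragmented per MS1 cycle (default 10).
#' @param exclusion_duration Dynamic-exclusion duration, minutes (default
#'   0.5): a selected precursor cannot be re-selected for this long.
#' @param ms1_cycle_time Time between MS1 survey scans, minutes (default
#'   0.02).
#' @return List of class `dda_params`.
#' @export
dda_params <- function(gradient_length = 125,
                       max_injection_time = 0.008333,
                       isolation_window = 3,
                       peak_width = 1.44,
                       sparse_sampling_degree = 5,
                       top_n = 10,
                       exclusion_duration = 0.5,
                       ms1_cycle_time = 0.02) {
  vals <- c(gradient_length = gradient_length,
            max_injection_time = max_injection_time,
            isolation_window = isolation_window, peak_width = peak_width,
            sparse_sampling_degree = sparse_sampling_degree, top_n = top_n,
            ms1_cycle_time = ms1_cycle_time)
  if (any(vals <= 0)) {
    stop("dda_params: ", paste(names(vals)[vals <= 0], collapse = ", "),
         " must be positive", call. = FALSE)
  }
  if (top_n < 1) stop("top_n must be >= 1", call. = FALSE)
  if (exclusion_duration < 0) stop("exclusion_duration must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "dda_params")
}

#' Generate MS1 features for one injection
#'
#' Converts ground-truth protein abundances at one (timepoint, filter) into
#' peptide-level MS1 features. Each peptide's total intensity is the sum of
#' its parent proteins' abundances, scaled by the taxon-specific filter
#' retention and (optionally) injection-level multiplicative lognormal noise
#' with CV `noise_cv` from the community configuration. Apex retention times
#' come from the additive RT model, mapped to the gradient.
#'
#' @param peptide_map Peptide map from [build_peptide_map()] built on the
#'   same protein database as `truth`.
#' @param truth `truth_table` from [simulate_community()].
#' @param timepoint Timepoint label (1..n_timepoints).
#' @param filter Filter class, one of `"3.0"`, `"0.8"`, `"0.1"`.
#' @param params [dda_params()].
#' @param model [rt_model()].
#' @param noise Apply injection noise (default TRUE). Noise draws use the
#'   current RNG state; seed upstream for reproducibility.
#' @return Tibble (`FeatureMap`): `peptide`, `mz` (2+ m/z), `rt` (apex,
#'   minutes), `intensity` (> 0; zero-intensity peptides are dropped).
#' @export
generate_features <- function(peptide_map, truth, timepoint, filter,
                              params = dda_params(), model = rt_model(),
                              noise = TRUE) {
  stopifnot(inherits(truth, "truth_table"), filter %in% FILTER_CLASSES)
  config <- truth$config
  info <- truth$protein_info
  ab <- truth$abundance[truth$abundance$timepoint == timepoint, ]
  if (nrow(ab) == 0L) stop("no truth abundances at timepoint ", timepoint,
                           call. = FALSE)
  long <- tibble::tibble(
    peptide = rep(peptide_map$peptide, lengths(peptide_map$parents)),
    protein = unlist(peptide_map$parents)
  )
  unknown <- setdiff(long$protein, info$protein)
  if (length(unknown)) {
    stop("peptide parents missing from truth table: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  retention <- config$filter_retention[, filter]
  long <- long |>
    dplyr::left_join(ab[, c("protein", "abundance")], by = "protein") |>
    dplyr::left_join(info[, c("protein", "taxon")], by = "protein")
  long$contrib <- long$abundance * retention[long$taxon]
  feats <- long |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(intensity = sum(.data$contrib), .groups = "drop") |>
    dplyr::filter(.data$intensity > 0)
  if (noise && config$noise_cv > 0) {
    sdl <- sqrt(log(1 + config$noise_cv^2))
    feats$intensity <- feats$intensity *
      stats::rlnorm(nrow(feats), -sdl^2 / 2, sdl)
  }
  feats$rt <- predict_rt(feats$peptide, model, params$gradient_length)
  feats$mz <- peptide_mz(peptide_mass(feats$peptide), 2L)
  feats[, c("peptide", "mz", "rt", "intensity")]
}

#' Simulate one DDA acquisition run
#'
#' Steps through the gradient in MS1 cycles of `ms1_cycle_time`. At each
#' cycle the `top_n` most intense non-excluded precursors (by instantaneous
#' Gaussian elution intensity) are selected; a selected peptide is
#' "identified", its full MS1 feature intensity is integrated, and it enters
#' the dynamic-exclusion list for `exclusion_duration` minutes. The run is
#' deterministic given its input features.
#'
#' @param features Feature tibble from [generate_features()].
#' @param params [dda_params()].
#' @return Tibble (`ObservedTable`): `peptide`, `identified` (logical),
#'   `intensity` (MS1-integrated feature intensity). The run's total ion
#'   current (sum over all features, identified or not) is stored in
#'   attribute `"tic"`.
#' @export
simulate_dda_run <- function(features, params = dda_params()) {
  stopifnot(is.data.frame(features),
            all(c("peptide", "rt", "intensity") %in% names(features)))
  tic <- sum(features$intensity)
  if (nrow(features) == 0L) {
    out <- tibble::tibble(peptide = character(0), identified = logical(0),
                          intensity = numeric(0))
    attr(out, "tic") <- 0
    return(out)
  }
  sigma <- params$peak_width / 4
  ord <- order(features$rt, features$peptide)
  rt <- features$rt[ord]
  inten <- features$intensity[ord]
  n <- length(rt)
  excluded_until <- rep(-Inf, n)
  identified <- rep(FALSE, n)
  cycles <- seq(0, params$gradient_length, by = params$ms1_cycle_time)
  lo <- findInterval(cycles - 2 * sigma, rt) + 1L
  hi <- findInterval(cycles + 2 * sigma, rt)
  for (k in seq_along(cycles)) {
    if (hi[k] < lo[k]) next
    w <- lo[k]:hi[k]
    elig <- w[excluded_until[w] <= cycles[k]]
    if (length(elig) == 0L) next
    inst <- inten[elig] * stats::dnorm(cycles[k], rt[elig], sigma)
    elig <- elig[inst > 0]
    if (length(elig) == 0L) next
    inst <- inst[inst > 0]
    sel <- elig[order(inst, decreasing = TRUE)[
      seq_len(min(params$top_n, length(elig)))]]
    identified[sel] <- TRUE
    excluded_until[sel] <- cycles[k] + params$exclusion_duration
  }
  out <- tibble::tibble(peptide = features$peptide[ord],
                        identified = identified,
                        intensity = inten)
  attr(out, "tic") <- tic
  out
}

#' Score coarse-grained quantification bias against ground truth
#'
#' Runs the mass-fraction inference on the observed (identified) peptides of
#' one or more replicate injections at a single (timepoint, filter) and
#' compares each (taxon, pool) inferred mass fraction with its true value.
#' Inference uses only peptides that uniquely map to one taxon, applies the
#' presence rule across injections, per-injection sum normalization, and
#' injection averaging.
#'
#' @param observed Tibble binding one or more [simulate_dda_run()] outputs
#'   with an added `injection` column.
#' @param truth `truth_table` from [simulate_community()].
#' @param peptide_map Matching [build_peptide_map()] output.
#' @param timepoint Timepoint the observations were generated at.
#' @return Tibble per (taxon, pool): `true_fraction`, `inferred_fraction`,
#'   `bias` (inferred - true), `rel_bias` (bias / true), and
#'   `n_unique_identified` - the number of taxon-and-pool-unique peptides
#'   supporting the estimate.
#' @export
assess_bias <- function(observed, truth, peptide_map, timepoint = 1) {
  stopifnot(inherits(truth, "truth_table"))
  if (!"injection" %in% names(observed)) observed$injection <- 1L
  obs <- observed[observed$identified & observed$intensity > 0, ]
  n_inj <- length(unique(observed$injection))
  # presence rule: identified in every injection
  obs <- obs |>
    dplyr::group_by(.data$peptide) |>
    dplyr::filter(dplyr::n_distinct(.data$injection) == n_inj) |>
    dplyr::ungroup()
  # per-injection sum normalization, then average across injections
  obs <- obs |>
    dplyr::group_by(.data$injection) |>
    dplyr::mutate(norm = .data$intensity / sum(.data$intensity)) |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(norm = mean(.data$norm), .groups = "drop")
  um <- peptide_map[peptide_map$taxon_unique,
                    c("peptide", "taxon", "pool", "pool_unique")]
  obs <- dplyr::inner_join(obs, um, by = "peptide")
  denom <- obs |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(denom = sum(.data$norm), .groups = "drop")
  inferred <- obs |>
    dplyr::filter(.data$pool_unique) |>
    dplyr::group_by(.data$taxon, .data$pool) |>
    dplyr::summarise(num = sum(.data$norm), n_unique_identified = dplyr::n(),
                     .groups = "drop") |>
    dplyr::left_join(denom, by = "taxon") |>
    dplyr::mutate(inferred_fraction = .data$num / .data$denom)
  truth_fr <- truth$pool_fractions[truth$pool_fractions$timepoint == timepoint,
                                   c("taxon", "pool", "fraction")]
  names(truth_fr)[3] <- "true_fraction"
  out <- dplyr::full_join(truth_fr, inferred[, c("taxon", "pool",
                                                 "inferred_fraction",
                                                 "n_unique_identified")],
                          by = c("taxon", "pool"))
  out$n_unique_identified[is.na(out$n_unique_identified)] <- 0L
  out$inferred_fraction[is.na(out$inferred_fraction) &
                          out$n_unique_identified == 0L] <- 0
  out$bias <- out$inferred_fraction - out$true_fraction
  out$rel_bias <- out$bias / out$true_fraction
  out
}

#' Sequence-diversity bias sweep
#'
#' Simulates communities over a grid of inter-taxon sequence-sharing
#' fractions and seeds, acquires one DDA injection per community at one
#' (timepoint, filter), and scores coarse-grained bias for every (taxon,
#' pool) grain. This is the experiment behind the support-threshold rule:
#' grains backed by many uniquely-mapping identified peptides are quantified
#' without systematic underestimation, low-diversity grains are not.
#'
#' @param shared_fractions Numeric vector of sharing fractions to sweep.
#' @param seeds Integer vector of community seeds.
#' @param config_args Named list of overrides passed to [community_config()]
#'   (besides `shared_sequence_fraction` and `seed`).
#' @param params [dda_params()].
#' @param timepoint,filter Acquisition context (defaults 1, `"3.0"`).
#' @return Tibble: one row per (shared_fraction, seed, taxon, pool) with the
#'   [assess_bias()] columns.
#' @export
bias_sweep <- function(shared_fractions = c(0, 0.3, 0.6, 0.9),
                       seeds = 1:10, config_args = list(),
                       params = dda_params(), timepoint = 1, filter = "3.0") {
  res <- list()
  for (s in shared_fractions) {
    for (sd_i in seeds) {
      args <- utils::modifyList(list(shared_sequence_fraction = s,
                                     seed = sd_i, n_injections = c(
                                       "3.0" = 1L, "0.8" = 1L, "0.1" = 1L)),
                                config_args)
      cfg <- do.call(community_config, args)
      sim <- simulate_community(cfg)
      map <- build_peptide_map(sim$proteins, cfg$missed_cleavages,
                               cfg$length_bounds)
      feats <- generate_features(map, sim$truth, timepoint, filter, params)
      obs <- simulate_dda_run(feats, params)
      b <- assess_bias(obs, sim$truth, map, timepoint)
      b$shared_fraction <- s
      b$seed <- sd_i
      res[[length(res) + 1L]] <- b
    }
  }
  dplyr::bind_rows(res)
}

#' Peptide-support threshold for unbiased quantification
#'
#' Given a grain-level bias table, finds the smallest peptide-support
#' threshold `T` (on a grid of `bin_width`) such that grains supported by at
#' least `T` uniquely-mapping identified peptides have a median relative
#' bias within `tolerance`.
#'
#' @param bias_table Output of [bias_sweep()] (or [assess_bias()] rows).
#' @param tolerance Allowed absolute median relative bias (default 0.05).
#' @param bin_width Grid step for candidate thresholds (default 10).
#' @return Integer threshold (peptide count), or `NA` if no threshold on the
#'   grid satisfies the tolerance.
#' @export
support_threshold <- function(bias_table, tolerance = 0.05, bin_width = 10) {
  ok <- is.finite(bias_table$rel_bias)
  tab <- bias_table[ok, ]
  if (nrow(tab) == 0L) stop("no finite relative biases", call. = FALSE)
  thresholds <- seq(0, max(tab$n_unique_identified), by = bin_width)
  for (th in thresholds) {
    sel <- tab$n_unique_identified >= th
    if (!any(sel)) break
    if (abs(stats::median(tab$rel_bias[sel])) <= tolerance) return(as.integer(th))
  }
  NA_integer_
}
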