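# Synthetic multi-taxon metaproteome generator: ground-truth communities with
# functionally structured proteomes (ribosomal / photosynthetic / other pools),
# controllable inter-taxon sequence sharing, environment-dependent protein
# expression across timepoints, and size-fractionation (filter) structure.

FILTER_CLASSES <- c("3.0", "0.8", "0.1")
POOL_LEVELS <- c("ribosomal", "photosynthetic", "other")

#' Configuration for a synthetic microbial community
#'
#' Bundles and validates every knob of the ground-truth generator. Defaults
#' describe a small bloom-like community: three taxa sampled over four weekly
#' timepoints on three sequential filter sizes (3.0, 0.8, 0.1 um), with a
#' proteome partitioned into ribosomal, photosynthetic and other pools.
#'
#' @param n_taxa Number of taxa (>= 1).
#' @param taxon_names Character vector of taxon labels.
#' @param biomass_series Matrix `n_taxa x n_timepoints` of relative biomass
#'   fractions; each timepoint column must sum to 1. Default: equal shares.
#' @param pool_fractions Matrix `n_taxa x 3` (columns ribosomal,
#'   photosynthetic, other) of proteomic mass fractions; rows sum to 1.
#'   Default `c(0.2, 0.15, 0.65)` for every taxon.
#' @param n_proteins_per_pool Proteins generated per (taxon, pool).
#' @param shared_sequence_fraction Probability in `[0, 1]` that a protein of
#'   taxa 2..n is a byte-identical copy of a same-pool protein from an
#'   earlier taxon (models low inter-taxon sequence diversity).
#' @param env_dependent_fraction Per-taxon fraction of proteins whose
#'   expression is modulated across timepoints.
#' @param env_effect_sd Log-scale standard deviation of the per-(protein,
#'   timepoint) environmental modulation of dependent proteins.
#' @param noise_cv Injection-level multiplicative noise CV applied when
#'   features are generated.
#' @param filter_retention Matrix `n_taxa x 3` (columns "3.0", "0.8", "0.1")
#'   giving each taxon's protein-mass split across filters, rows summing
#'   to 1; leakage to smaller filters models cell breakage during
#'   filtration. Default `c(0.80, 0.15, 0.05)` per taxon.
#' @param abundance_sdlog Log-sd of within-pool relative protein abundances.
#' @param protein_length_range Uniform range of protein lengths (residues).
#' @param n_timepoints Number of timepoints (default 4).
#' @param n_injections Named integer vector of replicate injections per
#'   filter, default `c("3.0" = 3, "0.8" = 2, "0.1" = 2)`.
#' @param missed_cleavages,length_bounds Digestion settings used to define
#'   protein mass in quantifiable-peptide units (must match the downstream
#'   peptide map).
#' @param seed Integer RNG seed.
#' @return A validated list of class `community_config`.
#' @export
community_config <- function(n_taxa = 3,
                             taxon_names = paste0("taxon", seq_len(n_taxa)),
                             biomass_series = NULL,
                             pool_fractions = NULL,
                             n_proteins_per_pool = 70,
                             shared_sequence_fraction = 0,
                             env_dependent_fraction = 0.5,
                             env_effect_sd = 0.75,
                             noise_cv = 0.1,
                             filter_retention = NULL,
                             abundance_sdlog = 1.2,
                             protein_length_range = c(120L, 360L),
                             n_timepoints = 4,
                             n_injections = c("3.0" = 3L, "0.8" = 2L, "0.1" = 2L),
                             missed_cleavages = 1,
                             length_bounds = c(6L, 40L),
                             seed = 1L) {
  if (n_taxa < 1) stop("invalid n_taxa: must be >= 1", call. = FALSE)
  if (n_timepoints < 1) stop("invalid n_timepoints: must be >= 1", call. = FALSE)
  if (n_proteins_per_pool < 1) {
    stop("invalid n_proteins_per_pool: must be >= 1", call. = FALSE)
  }
  if (length(taxon_names) != n_taxa || anyDuplicated(taxon_names)) {
    stop("invalid taxon_names: need ", n_taxa, " distinct labels", call. = FALSE)
  }
  if (is.null(biomass_series)) {
    biomass_series <- matrix(1 / n_taxa, n_taxa, n_timepoints)
  }
  biomass_series <- as.matrix(biomass_series)
  dimnames(biomass_series) <- list(taxon_names, seq_len(n_timepoints))
  if (is.null(pool_fractions)) {
    pool_fractions <- matrix(rep(c(0.2, 0.15, 0.65), each = n_taxa), n_taxa, 3)
  }
  pool_fractions <- as.matrix(pool_fractions)
  dimnames(pool_fractions) <- list(taxon_names, POOL_LEVELS)
  if (is.null(filter_retention)) {
    filter_retention <- matrix(rep(c(0.80, 0.15, 0.05), each = n_taxa), n_taxa, 3)
  }
  filter_retention <- as.matrix(filter_retention)
  dimnames(filter_retention) <- list(taxon_names, FILTER_CLASSES)

  check_unit <- function(x, name) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop("invalid ", name, ": fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  check_simplex <- function(sums, name) {
    if (any(abs(sums - 1) > 1e-9)) {
      stop("invalid ", name, ": must sum to 1 (got ",
           paste(signif(sums, 8), collapse = ", "), ")", call. = FALSE)
    }
  }
  check_unit(biomass_series, "biomass_series")
  check_simplex(colSums(biomass_series), "biomass_series")
  check_unit(pool_fractions, "pool_fractions")
  check_simplex(rowSums(pool_fractions), "pool_fractions")
  check_unit(filter_retention, "filter_retention")
  check_simplex(rowSums(filter_retention), "filter_retention")
  check_unit(shared_sequence_fraction, "shared_sequence_fraction")
  check_unit(env_dependent_fraction, "env_dependent_fraction")
  if (env_effect_sd < 0) stop("invalid env_effect_sd: must be >= 0", call. = FALSE)
  if (noise_cv < 0) stop("invalid noise_cv: must be >= 0", call. = FALSE)
  if (any(n_injections < 1)) {
    stop("invalid n_injections: must be >= 1", call. = FALSE)
  }

  structure(list(
    n_taxa = as.integer(n_taxa), taxon_names = taxon_names,
    biomass_series = biomass_series, pool_fractions = pool_fractions,
    n_proteins_per_pool = as.integer(n_proteins_per_pool),
    shared_sequence_fraction = shared_sequence_fraction,
    env_dependent_fraction = env_dependent_fraction,
    env_effect_sd = env_effect_sd, noise_cv = noise_cv,
    filter_retention = filter_retention,
    abundance_sdlog = abundance_sdlog,
    protein_length_range = as.integer(protein_length_range),
    n_timepoints = as.integer(n_timepoints),
    n_injections = n_injections,
    missed_cleavages = missed_cleavages, length_bounds = length_bounds,
    seed = as.integer(seed)
  ), class = "community_config")
}

# Annotation phrase templates per pool; ribosomal/photosynthetic phrases are
# drawn from the keyword families recognised by assign_coarse_grains(),
# "other" phrases deliberately avoid them.
pool_annotation <- function(pool, k) {
  switch(pool,
    ribosomal = sprintf(c("50S ribosomal protein L%d", "30S ribosomal protein S%d",
                          "60S ribosomal protein L%d", "40S ribosomal protein S%d")[
                            (k - 1L) %% 4L + 1L], k),
    photosynthetic = c("photosystem II reaction center protein",
                       "photosystem I P700 apoprotein",
                       "light harvesting complex protein",
                       "chlorophyll a-b binding protein",
                       "plastocyanin", "flavodoxin")[(k - 1L) %% 6L + 1L],
    other = c("hypothetical protein", "ATP synthase subunit beta",
              "elongation factor Tu", "heat shock protein 70",
              "ketol-acid reductoisomerase", "actin",
              "glyceraldehyde-3-phosphate dehydrogenase")[(k - 1L) %% 7L + 1L]
  )
}

random_protein_sequence <- function(len, freqs) {
  paste(sample(names(freqs), len, replace = TRUE, prob = freqs), collapse = "")
}

#' Simulate a ground-truth community metaproteome
#'
#' Generates a FASTA-serializable protein database (taxon and annotation per
#' protein, with the coarse-grained pool encoded in the annotation phrase)
#' together with a truth table of per-(protein, timepoint) abundances and
#' per-(taxon, pool, timepoint) true mass fractions.
#'
#' Protein mass is expressed in quantifiable-peptide units: each protein's
#' relative molar abundance is scaled so that, per unit taxon biomass, the
#' summed peptide-level signal of a pool equals its configured pool fraction.
#' Environment-dependent proteins receive a multiplicative lognormal
#' modulation per timepoint (unit mean); independent proteins have identical
#' expected abundance at every timepoint. With sharing probability `s`,
#' proteins of taxa 2..n are byte-identical copies of same-pool proteins from
#' earlier taxa, which erodes taxon-unique peptides downstream.
#'
#' @param config A [community_config()].
#' @return List of class `community_simulation` with elements:
#'   * `proteins`: tibble `id`, `taxon`, `pool`, `annotations`, `sequence`,
#'     `shared` (logical: copied from another taxon);
#'   * `truth`: list of class `truth_table` with `abundance` (tibble
#'     `protein`, `timepoint`, `abundance`), `protein_info` (tibble
#'     `protein`, `taxon`, `pool`, `env_class`, `n_peptides`),
#'     `pool_fractions` (tibble `taxon`, `pool`, `timepoint`, `fraction`,
#'     `configured`), and the `config`.
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  set.seed(config$seed)
  freqs <- aa_generator_freqs()
  n_pp <- config$n_proteins_per_pool

  prot <- list()
  for (ti in seq_len(config$n_taxa)) {
    for (pool in POOL_LEVELS) {
      lens <- sample(seq(config$protein_length_range[1],
                         config$protein_length_range[2]), n_pp, replace = TRUE)
      seqs <- vapply(lens, random_protein_sequence, character(1), freqs = freqs)
      prot[[length(prot) + 1L]] <- tibble::tibble(
        taxon = config$taxon_names[ti],
        pool = pool,
        annotations = vapply(seq_len(n_pp), function(k) pool_annotation(pool, k),
                             character(1)),
        sequence = seqs,
        shared = FALSE
      )
    }
  }
  proteins <- dplyr::bind_rows(prot)
  proteins$id <- sprintf("prot%05d", seq_len(nrow(proteins)))

  # inter-taxon sequence sharing: copy sequences (identically) from a
  # same-pool protein of a uniformly chosen earlier taxon
  s <- config$shared_sequence_fraction
  if (s > 0 && config$n_taxa > 1) {
    for (ti in 2:config$n_taxa) {
      for (pool in POOL_LEVELS) {
        idx <- which(proteins$taxon == config$taxon_names[ti] &
                       proteins$pool == pool)
        copy <- stats::runif(length(idx)) < s
        if (!any(copy)) next
        src_taxa <- sample(config$taxon_names[seq_len(ti - 1L)],
                           sum(copy), replace = TRUE)
        for (j in seq_along(idx[copy])) {
          src_pool_idx <- which(proteins$taxon == src_taxa[j] &
                                  proteins$pool == pool)
          src <- sample(src_pool_idx, 1L)
          proteins$sequence[idx[copy][j]] <- proteins$sequence[src]
          proteins$shared[idx[copy][j]] <- TRUE
        }
      }
    }
  }

  # protein mass in quantifiable-peptide units: weight = number of distinct
  # peptides the protein yields under the configured digestion
  n_pep <- vapply(proteins$sequence, function(sq) {
    length(unique(digest_protein(sq, config$missed_cleavages,
                                 config$length_bounds)))
  }, numeric(1), USE.NAMES = FALSE)
  if (any(n_pep == 0)) {
    # regenerate degenerate sequences (no quantifiable peptides)
    for (i in which(n_pep == 0)) {
      repeat {
        proteins$sequence[i] <- random_protein_sequence(
          config$protein_length_range[2], freqs)
        n_pep[i] <- length(unique(digest_protein(
          proteins$sequence[i], config$missed_cleavages, config$length_bounds)))
        if (n_pep[i] > 0) break
      }
    }
  }

  # relative molar abundances, normalised so sum(molar * n_pep) over a pool
  # equals the configured pool fraction per unit taxon biomass
  u <- stats::rlnorm(nrow(proteins), 0, config$abundance_sdlog)
  molar <- numeric(nrow(proteins))
  for (ti in seq_len(config$n_taxa)) {
    for (pool in POOL_LEVELS) {
      idx <- which(proteins$taxon == config$taxon_names[ti] &
                     proteins$pool == pool)
      pf <- config$pool_fractions[config$taxon_names[ti], pool]
      molar[idx] <- pf * u[idx] / sum(u[idx] * n_pep[idx])
    }
  }

  # environment-dependence: modulate a fraction of proteins per taxon
  env_class <- rep("independent", nrow(proteins))
  for (ti in seq_len(config$n_taxa)) {
    idx <- which(proteins$taxon == config$taxon_names[ti])
    dep <- stats::runif(length(idx)) < config$env_dependent_fraction
    env_class[idx[dep]] <- "dependent"
  }

  tp <- seq_len(config$n_timepoints)
  ab <- tidyr::expand_grid(protein = proteins$id, timepoint = tp)
  ab$taxon <- rep(proteins$taxon, each = length(tp))
  ab$pool <- rep(proteins$pool, each = length(tp))
  base <- rep(molar, each = length(tp))
  biomass <- config$biomass_series[cbind(ab$taxon, ab$timepoint)]
  mod <- rep(1, nrow(ab))
  dep_rows <- rep(env_class == "dependent", each = length(tp))
  if (config$env_effect_sd > 0 && any(dep_rows)) {
    sdl <- config$env_effect_sd
    mod[dep_rows] <- stats::rlnorm(sum(dep_rows), -sdl^2 / 2, sdl)
  }
  ab$abundance <- base * biomass * mod
  ab$weight <- rep(n_pep, each = length(tp))

  pool_fr <- ab |>
    dplyr::group_by(.data$taxon, .data$pool, .data$timepoint) |>
    dplyr::summarise(mass = sum(.data$abundance * .data$weight), .groups = "drop") |>
    dplyr::group_by(.data$taxon, .data$timepoint) |>
    dplyr::mutate(fraction = .data$mass / sum(.data$mass)) |>
    dplyr::ungroup()
  pool_fr$configured <- config$pool_fractions[cbind(pool_fr$taxon, pool_fr$pool)]

  truth <- structure(list(
    abundance = ab[, c("protein", "timepoint", "abundance")],
    protein_info = tibble::tibble(
      protein = proteins$id, taxon = proteins$taxon, pool = proteins$pool,
      env_class = env_class, n_peptides = n_pep, molar = molar
    ),
    pool_fractions = pool_fr[, c("taxon", "pool", "timepoint", "fraction",
                                 "configured")],
    config = config
  ), class = "truth_table")

  structure(list(
    proteins = proteins[, c("id", "taxon", "pool", "annotations", "sequence",
                            "shared")],
    truth = truth
  ), class = "community_simulation")
}

#' Simulate replicate-culture proteomic calibration data
#'
#' Generates the kind of dataset used to calibrate the environment-dependence
#' cutoff: several culture conditions, each with replicate measurements of
#' the same proteome, where each protein's across-replicate coefficient of
#' variation is drawn from a configurable profile. Abundances are lognormal,
#' so a protein with target CV `c` uses log-sd `sqrt(log(1 + c^2))`.
#'
#' @param n_conditions Number of culture conditions (>= 1).
#' @param n_replicates Replicates per condition (>= 2; CV is undefined
#'   otherwise).
#' @param n_proteins Proteins per condition.
#' @param cv_profile Either a single non-negative number (every protein has
#'   that target CV), or a function `f(n)` returning `n` target CVs, or a
#'   list `list(meanlog =, sdlog =)` describing a lognormal CV distribution.
#' @param seed Integer RNG seed.
#' @return List of class `replicate_cultures` with `abundance` (tibble
#'   `condition`, `protein`, `replicate`, `abundance`) and `true_cv` (tibble
#'   `condition`, `protein`, `cv`).
#' @export
simulate_replicate_cultures <- function(n_conditions, n_replicates, n_proteins,
                                        cv_profile = 0.2, seed = 1L) {
  if (n_replicates < 2) {
    stop("n_replicates must be >= 2: CV is undefined for a single replicate",
         call. = FALSE)
  }
  stopifnot(n_conditions >= 1, n_proteins >= 1)
  set.seed(seed)
  draw_cv <- function(n) {
    if (is.numeric(cv_profile) && length(cv_profile) == 1L) {
      rep(cv_profile, n)
    } else if (is.function(cv_profile)) {
      cv_profile(n)
    } else if (is.list(cv_profile)) {
      stats::rlnorm(n, cv_profile$meanlog, cv_profile$sdlog)
    } else {
      stop("unsupported cv_profile", call. = FALSE)
    }
  }
  out <- list(); tcv <- list()
  for (ci in seq_len(n_conditions)) {
    cond <- sprintf("condition%02d", ci)
    cv <- draw_cv(n_proteins)
    if (any(cv < 0)) stop("cv_profile produced negative CVs", call. = FALSE)
    sdl <- sqrt(log(1 + cv^2))
    base <- stats::rlnorm(n_proteins, log(100), 1)
    abm <- base * matrix(stats::rlnorm(n_proteins * n_replicates,
                                       -rep(sdl^2, n_replicates) / 2,
                                       rep(sdl, n_replicates)),
                         n_proteins, n_replicates)
    out[[ci]] <- tibble::tibble(
      condition = cond,
      protein = rep(sprintf("prot%05d", seq_len(n_proteins)), n_replicates),
      replicate = rep(seq_len(n_replicates), each = n_proteins),
      abundance = as.vector(abm)
    )
    tcv[[ci]] <- tibble::tibble(condition = cond,
                                protein = sprintf("prot%05d", seq_len(n_proteins)),
                                cv = cv)
  }
  structure(list(abundance = dplyr::bind_rows(out),
                 true_cv = dplyr::bind_rows(tcv)),
            class = "replicate_cultures")
}
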