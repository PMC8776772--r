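# Normalization, presence filtering, mass fractions, filter weighting.

test_that("presence filter keeps peptides seen in every injection only", {
  tbl <- tibble::tibble(
    peptide = c(rep("full", 3), rep("partial", 2), "single"),
    timepoint = 1, filter = "3.0",
    injection = c(1, 2, 3, 1, 2, 1),
    intensity = c(10, 11, 12, 5, 6, 3))
  out <- presence_filter(tbl)
  expect_setequal(unique(out$peptide), "full")
  # a single-injection sample passes everything observed
  tbl1 <- tbl[tbl$injection == 1, ]
  expect_equal(nrow(presence_filter(tbl1)), 3)
  # zero intensity counts as unobserved
  tbl$intensity[1] <- 0
  expect_equal(nrow(presence_filter(tbl)), 0)
})

test_that("normalization factor sums identified intensities per injection", {
  tbl <- tibble::tibble(peptide = c("a", "b", "c"), timepoint = 1,
                        filter = "3.0", injection = 1,
                        intensity = c(10, 30, 60))
  expect_equal(normalization_factor(tbl, 1, "3.0", 1), 100)
  expect_equal(normalization_factor(tbl[c(3, 1, 2), ], 1, "3.0", 1), 100)
  norm <- tbl$intensity / normalization_factor(tbl, 1, "3.0", 1)
  expect_equal(sum(norm), 1)
  expect_error(normalization_factor(tbl, 2, "3.0", 1), "undefined")
})

test_that("TIC factor is database-independent and tracks identified sum", {
  tic <- tibble::tibble(timepoint = 1, filter = "3.0", injection = 1:2,
                        tic = c(1000, 1100))
  expect_equal(tic_normalization_factor(tic, 1, "3.0", 2), 1100)
  expect_error(tic_normalization_factor(tic, 1, "0.8", 1), "no TIC")
  # full identification: identified sum equals TIC; dropping peptides from
  # the table changes the identified sum but never the TIC
  cfg <- community_config(n_taxa = 2, n_proteins_per_pool = 5, noise_cv = 0,
                          protein_length_range = c(80, 140), seed = 51)
  sim <- simulate_community(cfg)
  map <- build_peptide_map(sim$proteins)
  params <- dda_params(top_n = 1e6, exclusion_duration = 0)
  feats <- generate_features(map, sim$truth, 1, "3.0", params, noise = FALSE)
  obs <- simulate_dda_run(feats, params)
  tbl <- tibble::tibble(peptide = obs$peptide, timepoint = 1, filter = "3.0",
                        injection = 1, intensity = obs$intensity)
  expect_equal(normalization_factor(tbl, 1, "3.0", 1), attr(obs, "tic"),
               tolerance = 1e-12)
  dropped <- tbl[seq_len(nrow(tbl) %/% 2), ]
  expect_lt(normalization_factor(dropped, 1, "3.0", 1), attr(obs, "tic"))
})

test_that("identified-sum/TIC correlation degrades with identification rate", {
  cfg <- community_config(n_taxa = 2, n_proteins_per_pool = 8,
                          protein_length_range = c(80, 140), seed = 53)
  sim <- simulate_community(cfg)
  map <- build_peptide_map(sim$proteins)
  set.seed(5)
  obs <- exhaustive_observed(map, sim$truth, timepoints = 1:4,
                             filters = "3.0", injections = 2)
  key <- unique(obs[, c("timepoint", "injection")])
  factor_at_rate <- function(rate) {
    vapply(seq_len(nrow(key)), function(i) {
      x <- obs[obs$timepoint == key$timepoint[i] &
                 obs$injection == key$injection[i], ]
      kept <- x[x$intensity >= stats::quantile(x$intensity, 1 - rate), ]
      sum(kept$intensity)
    }, numeric(1))
  }
  tic <- factor_at_rate(1)
  r_full <- stats::cor(factor_at_rate(1), tic)
  r_half <- stats::cor(factor_at_rate(0.5), tic)
  expect_equal(r_full, 1, tolerance = 1e-12)
  expect_lte(r_half, r_full + 1e-12)
})

test_that("normalization sensitivity spans the symmetric interval", {
  expect_equal(normalization_sensitivity(100, 0.16),
               c(low = 92, high = 108))
  expect_equal(normalization_sensitivity(50, 0.16), c(low = 46, high = 54))
  expect_equal(normalization_sensitivity(7, 0), c(low = 7, high = 7))
  expect_error(normalization_sensitivity(-1, 0.1), ">= 0")
  expect_error(normalization_sensitivity(10, 2), "relative_variation")
})

test_that("taxon normalization makes each taxon's peptides sum to one", {
  map <- build_peptide_map(toy_proteins(), missed_cleavages = 0,
                           length_bounds = c(2, 50))
  averaged <- tibble::tibble(
    peptide = c("MMMNNNKPPPQQQR", "SSSTTTK", "VVVWWWK"),
    timepoint = 1, filter = "3.0", norm = c(0.2, 0.3, 0.5))
  tn <- taxon_normalize(averaged, map)
  diatom <- tn[tn$taxon == "diatom", ]
  expect_equal(sort(diatom$value), c(0.4, 0.6))
  expect_equal(sum(tn$value[tn$taxon == "hapto"]), 1)
  sums <- tn |> dplyr::group_by(taxon) |>
    dplyr::summarise(s = sum(value))
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("mass fraction is pool-unique signal over taxon-unique signal", {
  prot <- tibble::tibble(
    id = c("r1", "o1"), taxon = "diatom", pool = c("ribosomal", "other"),
    sequence = c("AAAGGGKCCCDDDK", "EEEFFFKMMMNNNK"))
  map <- build_peptide_map(prot, missed_cleavages = 0,
                           length_bounds = c(2, 50))
  averaged <- tibble::tibble(peptide = map$peptide, timepoint = 1,
                             filter = "3.0", norm = 1)
  mf <- mass_fraction(averaged, "diatom", "ribosomal", 1, "3.0", map)
  expect_equal(mf$value, 0.5)
  expect_equal(mf$n_peptides, 2L)
  # all-pool and no-pool edge cases
  averaged2 <- averaged[map$pool == "ribosomal", ]
  expect_equal(mass_fraction(averaged2, "diatom", "ribosomal", 1, "3.0",
                             map)$value, 1)
  expect_equal(mass_fraction(averaged2, "diatom", "other", 1, "3.0",
                             map)$value, 0)
  # brute-force recomputation on a random table
  set.seed(61)
  averaged$norm <- stats::runif(nrow(averaged))
  mf2 <- mass_fraction(averaged, "diatom", "ribosomal", 1, "3.0", map)
  ribo_peps <- map$peptide[map$pool == "ribosomal"]
  expect_equal(mf2$value,
               sum(averaged$norm[averaged$peptide %in% ribo_peps]) /
                 sum(averaged$norm),
               tolerance = 1e-12)
  # undefined when the taxon has no signal
  expect_true(is.na(mass_fraction(averaged, "hapto", "ribosomal", 1, "3.0",
                                  map)$value))
})

test_that("filter weights are observation counts over the total", {
  expect_equal(filter_weights(c("3.0" = 90, "0.8" = 10, "0.1" = 0)),
               c("3.0" = 0.9, "0.8" = 0.1, "0.1" = 0))
  expect_equal(filter_weights(c("0.8" = 7)), c("0.8" = 1))
  expect_equal(filter_weights(c(50, 30, 20)), c(0.5, 0.3, 0.2),
               ignore_attr = TRUE)
  expect_error(filter_weights(c(0, 0, 0)), "all-zero")
  w <- filter_weights(c("3.0" = 13, "0.8" = 5, "0.1" = 2))
  expect_equal(sum(w), 1, tolerance = 1e-9)
})

test_that("combined estimates are convex combinations of defined inputs", {
  expect_equal(combine_across_filters(c("3.0" = 0.2, "0.8" = 0.4),
                                      c("3.0" = 0.9, "0.8" = 0.1)), 0.22)
  expect_equal(combine_across_filters(
    c("3.0" = 0.35, "0.8" = 0.35, "0.1" = 0.35),
    c("3.0" = 0.5, "0.8" = 0.3, "0.1" = 0.2)), 0.35)
  # undefined estimates drop out with weight renormalization
  expect_equal(combine_across_filters(
    c("3.0" = 0.2, "0.8" = NA, "0.1" = 0.6),
    c("3.0" = 0.5, "0.8" = 0.3, "0.1" = 0.5)), 0.4)
  expect_true(is.na(combine_across_filters(
    c("3.0" = NA_real_), c("3.0" = 1))))
  fl <- c("3.0", "0.8", "0.1")
  set.seed(71)
  for (i in 1:20) {
    v <- stats::setNames(stats::runif(3), fl)
    w <- filter_weights(stats::setNames(stats::runif(3, 1, 10), fl))
    cmb <- combine_across_filters(v, w)
    expect_gte(cmb, min(v)); expect_lte(cmb, max(v))
  }
  # permutation invariance over filters
  v <- c("3.0" = 0.1, "0.8" = 0.5, "0.1" = 0.9)
  w <- c("3.0" = 0.6, "0.8" = 0.3, "0.1" = 0.1)
  expect_equal(combine_across_filters(v, w),
               combine_across_filters(rev(v), rev(w)))
})

test_that("taxon relative abundance follows the protein-mass weighting", {
  prot <- tibble::tibble(
    id = c("d1", "h1"), taxon = c("diatom", "hapto"), pool = "other",
    sequence = c("AAAGGGKCCCDDDK", "EEEFFFKMMMNNNK"))
  map <- build_peptide_map(prot, missed_cleavages = 0,
                           length_bounds = c(2, 50))
  tbl <- tibble::tibble(
    peptide = rep(map$peptide, 2),
    timepoint = 1,
    filter = rep(c("3.0", "0.8"), each = 4),
    injection = 1,
    intensity = c(30, 30, 20, 20, 10, 10, 40, 40))
  pm <- c("3.0" = 300, "0.8" = 100, "0.1" = 0.001)
  out <- taxon_relative_abundance(tbl, map, pm, 1)
  # brute force: per filter shares, count weights 0.5/0.5, protein shares
  shares_d <- c("3.0" = 60 / 100, "0.8" = 20 / 100)
  pshare <- c("3.0" = 300 / 400, "0.8" = 100 / 400)
  w <- c("3.0" = 0.5, "0.8" = 0.5)
  expect_equal(out$abundance[out$taxon == "diatom"],
               sum(w * pshare * shares_d), tolerance = 1e-12)
  # equal protein mass: proportional to the plain combined estimate
  pm_eq <- c("3.0" = 50, "0.8" = 50, "0.1" = 50)
  out_eq <- taxon_relative_abundance(tbl, map, pm_eq, 1)
  comb_d <- combine_across_filters(shares_d, w)
  expect_equal(out_eq$abundance[out_eq$taxon == "diatom"], comb_d / 2,
               tolerance = 1e-12)
  # a taxon observed on one filter only scales with that filter's share
  tbl_one <- tbl[tbl$filter == "0.8", ]
  out_one <- taxon_relative_abundance(tbl_one, map, pm, 1)
  expect_equal(out_one$abundance[out_one$taxon == "diatom"],
               1 * (100 / 100) * 0.2, tolerance = 1e-12)
  expect_error(taxon_relative_abundance(tbl, map, c("3.0" = 1), 1),
               "protein_mass")
})

test_that("normalized quantities are invariant to per-injection rescaling", {
  cfg <- community_config(n_taxa = 2, n_proteins_per_pool = 6,
                          protein_length_range = c(80, 140), seed = 55)
  sim <- simulate_community(cfg)
  map <- build_peptide_map(sim$proteins)
  set.seed(3)
  obs <- exhaustive_observed(map, sim$truth, timepoints = 1:2,
                             injections = 2)
  scaled <- obs |>
    dplyr::group_by(timepoint, filter, injection) |>
    dplyr::mutate(intensity = intensity * (dplyr::cur_group_id() * 13.7)) |>
    dplyr::ungroup()
  f1 <- pool_fraction_table(obs, map)
  f2 <- pool_fraction_table(scaled, map)
  expect_equal(f1$value, f2$value, tolerance = 1e-12)
  expect_equal(f1$weight, f2$weight, tolerance = 1e-12)
})
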