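# CV-based environment-dependence classification and the regulatory-cost
# proxy (environment-independent proteomic mass fraction).

# replicate pairs x * (1 +/- d) have mean x and sd x*d*sqrt(2): protein CVs
# can be planted exactly
cultures_with_cvs <- function(cv_by_condition) {
  rows <- list()
  for (cond in names(cv_by_condition)) {
    cvs <- cv_by_condition[[cond]]
    d <- cvs / sqrt(2)
    for (i in seq_along(cvs)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition = cond, protein = sprintf("p%03d", i), replicate = 1:2,
        abundance = 10 * c(1 + d[i], 1 - d[i]))
    }
  }
  dplyr::bind_rows(rows)
}

test_that("peptide CV is the sample sd over the mean", {
  expect_equal(peptide_cv(c(0.1, 0.1, 0.1, 0.1)), 0)
  expect_equal(peptide_cv(c(1, 3)), sqrt(2) / 2, tolerance = 1e-12)
  expect_true(is.na(peptide_cv(c(2))))
  expect_true(is.na(peptide_cv(c(0, 0))))
  set.seed(81)
  for (i in 1:10) {
    x <- stats::rlnorm(6, 0, 0.7)
    expect_equal(peptide_cv(x), brute_cv(x), tolerance = 1e-12)
  }
})

test_that("cutoff is the mean third quartile of per-condition CVs", {
  # planted CVs: condition quartiles computed by an independent oracle
  cvs <- list(a = c(0.1, 0.2, 0.3, 0.4, 0.5), b = c(0.2, 0.4, 0.6, 0.8))
  spec <- derive_cutoff(cultures_with_cvs(cvs))
  expect_equal(unname(spec$q3_by_condition),
               c(brute_q3(cvs$a), brute_q3(cvs$b)), tolerance = 1e-12)
  expect_equal(spec$cutoff, mean(c(brute_q3(cvs$a), brute_q3(cvs$b))),
               tolerance = 1e-12)
  # all CVs equal c in every condition: cutoff = c
  const <- cultures_with_cvs(list(a = rep(0.3, 5), b = rep(0.3, 4)))
  expect_equal(derive_cutoff(const)$cutoff, 0.3, tolerance = 1e-12)
  # two conditions with Q3 values 0.2 and 0.4 average to 0.3
  two <- cultures_with_cvs(list(a = rep(0.2, 4), b = rep(0.4, 4)))
  expect_equal(derive_cutoff(two)$cutoff, 0.3, tolerance = 1e-12)
  # a condition with a single replicate is rejected
  bad <- cultures_with_cvs(list(a = c(0.1, 0.2)))
  bad <- bad[!(bad$condition == "a" & bad$replicate == 2 &
                 bad$protein == "p001"), ]
  expect_error(derive_cutoff(bad), "fewer than 2 replicates")
})

test_that("classification is a deterministic threshold with ties independent", {
  cv_tab <- tibble::tibble(
    taxon = "t", peptide = sprintf("pep%d", 1:5), pool = "other",
    mean_norm_intensity = rep(0.2, 5),
    cv = c(0, 0.3, 0.30000001, 0.8, NA), n_timepoints = 4L)
  cl <- classify_peptides(cv_tab, 0.3)
  expect_equal(cl$env_class, c("independent", "independent", "dependent",
                               "dependent"))
  expect_equal(attr(cl, "n_undefined"), 1L)
  # counts match a brute-force threshold scan
  set.seed(91)
  cv_tab2 <- tibble::tibble(taxon = "t", peptide = sprintf("q%d", 1:200),
                            pool = "other", mean_norm_intensity = 1 / 200,
                            cv = stats::rlnorm(200, -1.5, 0.8),
                            n_timepoints = 4L)
  for (cut in c(0.1, 0.2, 0.4)) {
    cl2 <- classify_peptides(cv_tab2, cut)
    expect_equal(sum(cl2$env_class == "independent"), sum(cv_tab2$cv <= cut))
  }
})

test_that("environment-independent fraction is the independent mass share", {
  cl <- tibble::tibble(
    taxon = "t", peptide = c("a", "b"), pool = "other",
    mean_norm_intensity = c(0.6, 0.4), cv = c(0.1, 0.9),
    n_timepoints = 4L, env_class = c("independent", "dependent"))
  out <- environment_independent_fraction(cl)
  expect_equal(out$fraction, 0.6)
  # all independent -> 1; complement identity
  cl$env_class <- "independent"
  expect_equal(environment_independent_fraction(cl)$fraction, 1)
  cl$env_class <- c("dependent", "independent")
  expect_equal(environment_independent_fraction(cl)$fraction, 0.4)
  expect_error(environment_independent_fraction(cl, "missing_taxon"),
               "no classified")
})

test_that("raising the cutoff never lowers the independent fraction", {
  set.seed(93)
  cv_tab <- tibble::tibble(taxon = "t", peptide = sprintf("q%d", 1:100),
                           pool = "other",
                           mean_norm_intensity = stats::runif(100),
                           cv = stats::rlnorm(100, -1.5, 1),
                           n_timepoints = 4L)
  fracs <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(cut) {
    environment_independent_fraction(
      classify_peptides(cv_tab, cut))$fraction
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("trait fractions are invariant to uniform taxon rescaling", {
  cfg <- community_config(n_taxa = 2, n_proteins_per_pool = 6,
                          protein_length_range = c(80, 140), seed = 97)
  sim <- simulate_community(cfg)
  map <- build_peptide_map(sim$proteins)
  set.seed(4)
  obs <- exhaustive_observed(map, sim$truth)
  series <- taxon_peptide_series(obs, map)
  cl <- classify_peptides(peptide_cv_table(series), 0.3)
  f1 <- environment_independent_fraction(cl)
  obs2 <- obs
  obs2$intensity <- obs2$intensity * 37.5
  series2 <- taxon_peptide_series(obs2, map)
  cl2 <- classify_peptides(peptide_cv_table(series2), 0.3)
  f2 <- environment_independent_fraction(cl2)
  expect_equal(f1$fraction, f2$fraction, tolerance = 1e-12)
})

test_that("constitutive proteomes classify fully independent and modulated
           proteomes recover the dependent mass share", {
  cultures <- simulate_replicate_cultures(
    4, 3, 800, cv_profile = list(meanlog = log(0.15), sdlog = 0.4),
    seed = 11)
  cutoff <- derive_cutoff(cultures)
  run_traits <- function(env_sd, edf) {
    cfg <- community_config(n_taxa = 2, n_proteins_per_pool = 30,
                            env_dependent_fraction = edf,
                            env_effect_sd = env_sd, noise_cv = 0.02,
                            protein_length_range = c(100, 200), seed = 99)
    sim <- simulate_community(cfg)
    map <- build_peptide_map(sim$proteins)
    set.seed(7)
    obs <- exhaustive_observed(map, sim$truth)
    series <- taxon_peptide_series(obs, map)
    cl <- classify_peptides(peptide_cv_table(series), cutoff)
    list(cl = cl, sim = sim,
         frac = environment_independent_fraction(cl))
  }
  # no environmental effect, noise far below the cutoff: fraction is 1
  quiet <- run_traits(0, 0.5)
  expect_equal(quiet$frac$fraction, c(1, 1))
  # strong modulation of 30% of proteins: recovered dependent mass share
  # within 0.1 of the configured 0.3
  strong <- run_traits(0.75, 0.3)
  dep_share <- 1 - mean(strong$frac$fraction)
  expect_lt(abs(dep_share - 0.3), 0.1)
})

test_that("cluster dependence balances conserve classification totals", {
  cl <- tibble::tibble(
    taxon = "t", peptide = sprintf("p%d", 1:10), pool = "other",
    mean_norm_intensity = 0.1, cv = c(rep(0.5, 7), rep(0.05, 3)),
    n_timepoints = 4L,
    env_class = c(rep("dependent", 7), rep("independent", 3)))
  clusters <- tibble::tibble(peptide = sprintf("p%d", 1:10),
                             cluster = c(rep("actin", 5), rep("kari", 5)))
  out <- functional_class_balance(cl, clusters)
  expect_equal(out$balance[out$cluster == "actin"], 5)
  expect_equal(out$balance[out$cluster == "kari"], -1)
  expect_equal(sum(out$n_dependent), 7)
  expect_equal(sum(out$n_independent), 3)
})
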