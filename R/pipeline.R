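# File formats and end-to-end orchestration. Interchange dialect: FASTA for
# protein databases, tab-separated UTF-8 tables with a header row and '.'
# decimal for everything tabular, JSON or YAML for configuration, JSON for
# the run manifest.

#' Write a protein database as FASTA
#'
#' Header format: `>prot{ID} taxon={name} annot="{annotation}"`.
#'
#' @param proteins Tibble with `id`, `taxon`, `annotations`, `sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- sprintf('%s taxon=%s annot="%s"', proteins$id, proteins$taxon,
                       proteins$annotations)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a protein database from FASTA
#'
#' Parses headers of the form `>id taxon={name} annot="{annotation}"` and
#' derives coarse-grained pools from the annotation strings.
#'
#' @param path FASTA file.
#' @return Tibble `id`, `taxon`, `annotations`, `sequence`, `pool`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("input FASTA not found: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  out <- tibble::tibble(
    id = sub("^(\\S+).*$", "\\1", hdr),
    taxon = sub('.*taxon=(\\S+).*', "\\1", hdr),
    annotations = sub('.*annot="([^"]*)".*', "\\1", hdr),
    sequence = unname(as.character(aa))
  )
  out$pool <- vapply(out$annotations, assign_coarse_grains, character(1),
                     USE.NAMES = FALSE)
  out
}

#' Tabular writers and readers (TSV dialect)
#'
#' Tab-separated, header row, UTF-8, '.' decimal. List-columns (e.g. a
#' peptide map's parent sets) are serialized as `;`-joined strings and
#' re-split on read.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return `path` invisibly (writers); a tibble (readers).
#' @name table_io
#' @export
write_table_tsv <- function(x, path) {
  x <- dplyr::mutate(x, dplyr::across(
    dplyr::where(is.list),
    function(col) vapply(col, paste, character(1), collapse = ";")))
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname table_io
#' @param list_columns Column names to re-split into list-columns.
#' @export
read_table_tsv <- function(path, list_columns = character(0)) {
  if (!file.exists(path)) stop("input table not found: ", path, call. = FALSE)
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  # filter labels ("3.0", "0.8", "0.1") must survive as character, not 3/0.8
  ct <- if ("filter" %in% hdr) {
    readr::cols(filter = readr::col_character())
  } else {
    readr::cols()
  }
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = ct)
  for (cl in intersect(list_columns, names(x))) {
    x[[cl]] <- strsplit(x[[cl]], ";", fixed = TRUE)
  }
  x
}

#' Read or write a configuration file
#'
#' JSON or YAML, chosen by file extension.
#'
#' @param path Config path ending in `.json`, `.yaml` or `.yml`.
#' @param config Named list to write.
#' @return A named list (read) or `path` invisibly (write).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(config, path)
  }
  invisible(path)
}

#' Correlate a single-protein biomarker with a coarse-grained mass fraction
#'
#' Pearson and Spearman correlations between paired series of a
#' coarse-grained mass fraction (e.g. the photosynthetic pool) and a
#' single-protein biomarker mass fraction (e.g. plastocyanin).
#'
#' @param fractions Numeric series of coarse-grained mass fractions.
#' @param biomarker Numeric series of biomarker mass fractions, same length.
#' @return List: `pearson`, `spearman`, `n`, and `scatter` (tibble of the
#'   pairs, for plotting).
#' @export
biomarker_vs_coarse_grain <- function(fractions, biomarker) {
  keep <- is.finite(fractions) & is.finite(biomarker)
  x <- fractions[keep]; y <- biomarker[keep]
  if (length(x) < 3L) {
    stop("need at least 3 paired observations, got ", length(x), call. = FALSE)
  }
  list(
    pearson = stats::cor(x, y, method = "pearson"),
    spearman = stats::cor(x, y, method = "spearman"),
    n = length(x),
    scatter = tibble::tibble(coarse_grain = x, biomarker = y)
  )
}

#' Run the full synthetic pipeline
#'
#' Orchestrates simulate -> acquire -> quantify -> traits -> cofragmentation
#' on a synthetic community and writes all outputs plus a JSON manifest to a
#' run directory. Deterministic given the seeds in the configuration:
#' rerunning with the same config reproduces the outputs byte for byte.
#'
#' @param config Named list (or path to a JSON/YAML file) with optional
#'   entries: `community` (arguments to [community_config()]), `dda`
#'   (arguments to [dda_params()]), `cultures` (arguments to
#'   [simulate_replicate_cultures()]), `normalization` (`"sum"` or `"tic"`),
#'   and `seed` (used where a stage seed is not given).
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly. Writes `proteins.fasta`, `peptide_map.tsv`,
#'   `observed.tsv`, `tic.tsv`, `fractions.tsv`, `abundance.tsv`,
#'   `traits.tsv`, `peptide_cv.tsv`, `bias.tsv`, `cofrag.tsv`,
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("ctrun")) {
  if (is.character(config)) config <- read_config(config)
  seed <- config$seed %||% 1L
  comm_args <- config$community %||% list()
  if (is.null(comm_args$seed)) comm_args$seed <- seed
  cfg <- do.call(community_config, comm_args)
  params <- do.call(dda_params, config$dda %||% list())
  normalization <- config$normalization %||% "sum"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- simulate_community(cfg)
  map <- build_peptide_map(sim$proteins, cfg$missed_cleavages,
                           cfg$length_bounds)
  write_protein_fasta(sim$proteins, file.path(out_dir, "proteins.fasta"))
  write_table_tsv(map[, c("peptide", "parents", "taxa", "pools", "n_parents",
                          "taxon_unique", "pool_unique", "mass", "mz2",
                          "mz3")],
                  file.path(out_dir, "peptide_map.tsv"))

  # acquisition: one DDA run per (timepoint, filter, injection)
  set.seed(seed)
  obs <- list(); tics <- list()
  for (tp in seq_len(cfg$n_timepoints)) {
    for (f in FILTER_CLASSES) {
      for (inj in seq_len(cfg$n_injections[[f]])) {
        feats <- generate_features(map, sim$truth, tp, f, params)
        run <- simulate_dda_run(feats, params)
        run_tic <- attr(run, "tic")
        run <- run[run$identified, c("peptide", "intensity")]
        if (nrow(run)) {
          run$timepoint <- tp; run$filter <- f; run$injection <- inj
          obs[[length(obs) + 1L]] <- run
        }
        tics[[length(tics) + 1L]] <- tibble::tibble(
          timepoint = tp, filter = f, injection = inj, tic = run_tic)
      }
    }
  }
  observed <- dplyr::bind_rows(obs)
  tic_table <- dplyr::bind_rows(tics)
  write_table_tsv(observed, file.path(out_dir, "observed.tsv"))
  write_table_tsv(tic_table, file.path(out_dir, "tic.tsv"))

  fractions <- pool_fraction_table(observed, map, normalization, tic_table)
  write_table_tsv(fractions, file.path(out_dir, "fractions.tsv"))

  protein_mass <- config$protein_mass %||%
    stats::setNames(colMeans(cfg$filter_retention), FILTER_CLASSES)
  abundance <- dplyr::bind_rows(lapply(seq_len(cfg$n_timepoints), function(tp) {
    taxon_relative_abundance(observed, map, protein_mass, tp, normalization,
                             tic_table)
  }))
  write_table_tsv(abundance, file.path(out_dir, "abundance.tsv"))

  cult_args <- config$cultures %||% list(n_conditions = 4, n_replicates = 3,
                                         n_proteins = 500,
                                         cv_profile = list(meanlog = log(0.15),
                                                           sdlog = 0.4))
  if (is.null(cult_args$seed)) cult_args$seed <- seed
  cultures <- do.call(simulate_replicate_cultures, cult_args)
  cutoff <- derive_cutoff(cultures)
  series <- taxon_peptide_series(observed, map, normalization, tic_table)
  cv_tab <- peptide_cv_table(series)
  classified <- classify_peptides(cv_tab, cutoff)
  traits <- environment_independent_fraction(classified)
  write_table_tsv(classified, file.path(out_dir, "peptide_cv.tsv"))
  write_table_tsv(traits, file.path(out_dir, "traits.tsv"))

  bias <- assess_bias(
    {
      o <- observed[observed$timepoint == 1 & observed$filter == "3.0", ]
      o$identified <- TRUE
      o
    }, sim$truth, map, timepoint = 1)
  write_table_tsv(bias, file.path(out_dir, "bias.tsv"))

  cofrag <- cofragmentation_score(map, params)
  write_table_tsv(cofrag, file.path(out_dir, "cofrag.tsv"))

  manifest <- list(
    package = "coarsetraits",
    version = as.character(utils::packageVersion("coarsetraits")),
    seed = seed,
    normalization = normalization,
    community = comm_args,
    dda = config$dda %||% list(),
    cultures = cult_args[setdiff(names(cult_args), "cv_profile")],
    cutoff = cutoff$cutoff,
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
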