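# Retention-time prediction and cofragmentation-risk scoring.
#
# The score estimates, for each peptide, how many database peptides share its
# precursor isolation window (m/z) and elution window (RT) - a proxy for the
# risk that co-isolated peptides bias its quantification.

#' Additive retention-time model
#'
#' A deterministic additive model: the raw retention index of a peptide is
#' `intercept + sum of per-residue coefficients`, affinely mapped from
#' `raw_range` onto `[0, gradient_length]` and clipped. The default
#' coefficients are Kyte-Doolittle hydropathy indices, so more hydrophobic
#' peptides elute later, as on a C18 column. The model is a swappable
#' stand-in for trained RT predictors: only the relative co-elution
#' structure matters downstream.
#'
#' @param coefficients Named numeric vector of per-residue coefficients.
#' @param intercept Added to every raw retention index.
#' @param raw_range Length-2 numeric; raw indices at this range's ends map to
#'   the gradient's start and end (values outside are clipped).
#' @return List of class `rt_model`.
#' @export
rt_model <- function(coefficients = AA_HYDROPATHY, intercept = 0,
                     raw_range = c(-55, 45)) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            raw_range[2] > raw_range[1])
  structure(list(coefficients = coefficients, intercept = intercept,
                 raw_range = raw_range), class = "rt_model")
}

#' Predict peptide retention times
#'
#' @param peptides Character vector of peptide sequences.
#' @param model An [rt_model()].
#' @param gradient_length LC gradient length in minutes (default 125).
#' @param raw Return the raw (unmapped) retention index instead of minutes.
#' @return Numeric vector of retention times in `[0, gradient_length]`
#'   minutes (or raw indices).
#' @export
#' @examples
#' predict_rt(c("LLLLLLK", "DDDDDDK"), rt_model())
predict_rt <- function(peptides, model = rt_model(), gradient_length = 125,
                       raw = FALSE) {
  stopifnot(inherits(model, "rt_model"))
  coef_by_code <- rep(NA_real_, 128)
  coef_by_code[utf8ToInt(paste(names(model$coefficients), collapse = ""))] <-
    model$coefficients
  idx <- vapply(peptides, function(p) {
    v <- coef_by_code[utf8ToInt(p)]
    if (anyNA(v) || length(v) == 0L) {
      stop("invalid residue in peptide '", p, "'", call. = FALSE)
    }
    sum(v)
  }, numeric(1), USE.NAMES = FALSE) + model$intercept
  if (raw) return(idx)
  lo <- model$raw_range[1]; hi <- model$raw_range[2]
  rt <- gradient_length * (idx - lo) / (hi - lo)
  pmin(pmax(rt, 0), gradient_length)
}

#' Cofragmentation-risk scores
#'
#' For each peptide, counts database peptides (at any modeled charge) whose
#' m/z lies within half the precursor isolation window of the peptide's own
#' m/z and whose predicted retention time lies within one ion peak width;
#' the count is averaged over the peptide's charge states (2+ and 3+) and
#' divided by the degree of sparse sampling. The peptide itself never
#' contributes. A high score flags a peptide at risk of quantification bias
#' from co-isolated precursors.
#'
#' @param peptide_map Peptide map from [build_peptide_map()] (columns
#'   `peptide`, `mz2`, `mz3`), or a character vector of peptide sequences.
#' @param params [dda_params()]; uses `isolation_window`, `peak_width`,
#'   `sparse_sampling_degree`, `gradient_length`.
#' @param model [rt_model()] used for retention-time prediction.
#' @return Tibble `peptide`, `rt`, `score`, `n_contributors` (distinct
#'   co-located peptides over all charge pairs), sorted as the input.
#' @export
cofragmentation_score <- function(peptide_map, params = dda_params(),
                                  model = rt_model()) {
  if (is.character(peptide_map)) {
    mass <- peptide_mass(peptide_map)
    peptide_map <- tibble::tibble(peptide = peptide_map, mass = mass,
                                  mz2 = peptide_mz(mass, 2L),
                                  mz3 = peptide_mz(mass, 3L))
  }
  stopifnot(is.data.frame(peptide_map),
            all(c("peptide", "mz2", "mz3") %in% names(peptide_map)))
  if (nrow(peptide_map) == 0L) stop("empty peptide database", call. = FALSE)
  rt <- predict_rt(peptide_map$peptide, model, params$gradient_length)
  n <- nrow(peptide_map)
  # long table of precursor entries: one per (peptide, charge)
  ent <- tibble::tibble(
    pep = rep(seq_len(n), 2L),
    mz = c(peptide_map$mz2, peptide_map$mz3),
    rt = rep(rt, 2L)
  )
  ord <- order(ent$mz)
  ent_mz <- ent$mz[ord]; ent_pep <- ent$pep[ord]; ent_rt <- ent$rt[ord]
  half_win <- params$isolation_window / 2

  count_partners <- function(q_mz, q_rt, q_pep) {
    lo <- findInterval(q_mz - half_win, ent_mz, left.open = TRUE) + 1L
    hi <- findInterval(q_mz + half_win, ent_mz)
    if (hi < lo) return(integer(0))
    in_win <- lo:hi
    keep <- abs(ent_rt[in_win] - q_rt) <= params$peak_width &
      ent_pep[in_win] != q_pep
    unique(ent_pep[in_win][keep])
  }

  score <- numeric(n); n_contrib <- integer(n)
  for (i in seq_len(n)) {
    p2 <- count_partners(peptide_map$mz2[i], rt[i], i)
    p3 <- count_partners(peptide_map$mz3[i], rt[i], i)
    score[i] <- (length(p2) + length(p3)) / 2 / params$sparse_sampling_degree
    n_contrib[i] <- length(unique(c(p2, p3)))
  }
  tibble::tibble(peptide = peptide_map$peptide, rt = rt, score = score,
                 n_contributors = n_contrib)
}
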