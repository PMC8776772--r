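# In-silico tryptic digestion and peptide -> protein -> taxon/pool mapping.

#' Tryptic digestion of a protein sequence
#'
#' Cleaves C-terminal to K or R except when the next residue is P, and
#' returns all peptides (including missed-cleavage variants) whose length
#' falls within `length_bounds`, ordered by position in the protein.
#'
#' @param sequence Single protein sequence (character scalar, standard
#'   residues).
#' @param missed_cleavages Maximum number of missed cleavage sites per
#'   peptide (0-2). Default 1.
#' @param length_bounds Length-2 integer vector `c(min, max)` of retained
#'   peptide lengths. Default `c(6, 40)`.
#' @return Character vector of peptide sequences.
#' @export
#' @examples
#' digest_protein("AAAKGGGR", missed_cleavages = 0, length_bounds = c(2, 50))
digest_protein <- function(sequence, missed_cleavages = 1, length_bounds = c(6L, 40L)) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty protein sequence", call. = FALSE)
  if (missed_cleavages < 0 || missed_cleavages > 2) {
    stop("missed_cleavages must be in [0, 2]", call. = FALSE)
  }
  frags <- tryptic_fragments(sequence)
  n <- length(frags)
  out <- character(0)
  for (i in seq_len(n)) {
    for (mc in 0:missed_cleavages) {
      j <- i + mc
      if (j > n) break
      pep <- paste(frags[i:j], collapse = "")
      if (nchar(pep) >= length_bounds[1] && nchar(pep) <= length_bounds[2]) {
        out <- c(out, pep)
      }
    }
  }
  out
}

# Fully cleaved tryptic fragments (no length filtering).
tryptic_fragments <- function(sequence) {
  sites <- gregexpr("[KR](?!P)", sequence, perl = TRUE)[[1]]
  if (sites[1] == -1L) return(sequence)
  starts <- c(1L, sites + 1L)
  ends <- c(sites, nchar(sequence))
  keep <- starts <= ends
  substring(sequence, starts[keep], ends[keep])
}

#' Assign a coarse-grained pool from annotation strings
#'
#' Greedy, case-insensitive keyword matching of free-text protein annotations
#' to one of two coarse-grained functional pools. The photosynthetic family
#' covers light harvesting proteins, chlorophyll a-b binding proteins,
#' photosystems, plastocyanin and flavodoxin. The ribosomal family is the
#' prefix "ribosom", minus annotations describing ribosome synthesis or
#' biogenesis (and rRNA machinery), which are excluded. An annotation set
#' matching both families is conservatively assigned `"none"` with a warning,
#' standing in for manual curation of conflicting grains.
#'
#' @param annotations Character vector of free-text annotation strings for
#'   one protein.
#' @return One of `"ribosomal"`, `"photosynthetic"`, `"none"`.
#' @export
#' @examples
#' assign_coarse_grains("50S ribosomal protein L2")
#' assign_coarse_grains("ribosome biogenesis GTPase")  # excluded -> "none"
#' assign_coarse_grains("chlorophyll a-b binding protein")
assign_coarse_grains <- function(annotations) {
  if (length(annotations) == 0L) return("none")
  ann <- tolower(annotations)
  photo_keys <- c("light harvesting", "chlorophyll a-b binding", "photosystem",
                  "plastocyanin", "flavodoxin")
  ribo_excl <- c("ribosome biogenesis", "ribosomal rna", "ribosome synthesis",
                 "ribosomal synthesis", "rrna")
  is_photo <- any(vapply(photo_keys, function(k) any(grepl(k, ann, fixed = TRUE)),
                         logical(1)))
  ribo_hit <- grepl("ribosom", ann, fixed = TRUE)
  excl_hit <- vapply(seq_along(ann), function(i) {
    any(vapply(ribo_excl, function(k) grepl(k, ann[i], fixed = TRUE), logical(1)))
  }, logical(1))
  is_ribo <- any(ribo_hit & !excl_hit)
  if (is_photo && is_ribo) {
    warning("annotations match both ribosomal and photosynthetic families; ",
            "assigning 'none'", call. = FALSE)
    return("none")
  }
  if (is_ribo) return("ribosomal")
  if (is_photo) return("photosynthetic")
  "none"
}

#' Build a peptide map from a protein database
#'
#' Digests every protein, deduplicates peptides by sequence, and records for
#' each peptide its parent proteins, the taxa and coarse-grained pools those
#' parents span, uniqueness flags, monoisotopic mass and m/z at charges 2
#' and 3. Peptides are returned in lexicographic order, so the map is
#' invariant under protein input order.
#'
#' @param proteins Tibble with columns `id`, `taxon`, `sequence` and either
#'   `pool` or `annotations` (if `pool` is absent it is derived with
#'   [assign_coarse_grains()]).
#' @param missed_cleavages,length_bounds Digestion parameters, see
#'   [digest_protein()].
#' @return Tibble with one row per distinct peptide sequence: `peptide`,
#'   `parents` (list of protein ids), `taxa` (list), `pools` (list),
#'   `n_parents`, `taxon_unique`, `pool_unique`, `taxon` (the single taxon if
#'   taxon-unique, else `NA`), `pool` (single pool if pool-unique, else
#'   `NA`), `mass`, `mz2`, `mz3`.
#' @export
build_peptide_map <- function(proteins, missed_cleavages = 1,
                              length_bounds = c(6L, 40L)) {
  stopifnot(is.data.frame(proteins), nrow(proteins) > 0L,
            all(c("id", "taxon", "sequence") %in% names(proteins)))
  if (anyDuplicated(proteins$id)) stop("protein ids must be unique", call. = FALSE)
  if (!"pool" %in% names(proteins)) {
    stopifnot("annotations" %in% names(proteins))
    proteins$pool <- vapply(proteins$annotations, assign_coarse_grains, character(1))
  }
  pep_list <- lapply(proteins$sequence, digest_protein,
                     missed_cleavages = missed_cleavages,
                     length_bounds = length_bounds)
  long <- tibble::tibble(
    peptide = unlist(pep_list),
    protein = rep(proteins$id, lengths(pep_list)),
    taxon = rep(proteins$taxon, lengths(pep_list)),
    pool = rep(proteins$pool, lengths(pep_list))
  )
  # set semantics: a peptide occurring twice in one protein counts that
  # parent once
  long <- dplyr::distinct(long)
  map <- long |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(
      parents = list(sort(.data$protein)),
      taxa = list(sort(unique(.data$taxon))),
      pools = list(sort(unique(.data$pool))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$peptide)
  map$n_parents <- lengths(map$parents)
  map$taxon_unique <- lengths(map$taxa) == 1L
  map$pool_unique <- lengths(map$pools) == 1L
  map$taxon <- ifelse(map$taxon_unique,
                      vapply(map$taxa, `[`, character(1), 1L), NA_character_)
  map$pool <- ifelse(map$pool_unique,
                     vapply(map$pools, `[`, character(1), 1L), NA_character_)
  map$mass <- peptide_mass(map$peptide)
  map$mz2 <- peptide_mz(map$mass, 2L)
  map$mz3 <- peptide_mz(map$mass, 3L)
  map
}
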