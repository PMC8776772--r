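# Residue-level constants shared across modules.

#' Standard amino-acid alphabet
#'
#' The 20 standard residues, one-letter code.
#' @keywords internal
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")

# Monoisotopic residue masses (Da); peptide mass = sum + one water.
AA_MONO_MASS <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  Q = 128.05858, E = 129.04259, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333
)

WATER_MONO <- 18.010565
PROTON_MASS <- 1.007276

# Kyte-Doolittle hydropathy indices, used as additive retention coefficients
# by the default RT model (more hydrophobic -> retained longer on C18).
AA_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

# Residue sampling frequencies for the synthetic-community generator:
# uniform background reweighted so K+R jointly make up ~11% of residues,
# giving tryptic peptides of realistic length (~9 residues between sites).
aa_generator_freqs <- function() {
  p <- stats::setNames(rep(1, 20), AA_ALPHABET)
  kr <- c("K", "R")
  p[kr] <- 0
  p <- p / sum(p) * 0.89
  p[kr] <- 0.11 / 2
  p
}

#' Monoisotopic peptide mass
#'
#' Computes the monoisotopic mass of peptide sequences (sum of residue masses
#' plus one water).
#'
#' @param peptides Character vector of peptide sequences (standard one-letter
#'   residues).
#' @return Numeric vector of masses in Da.
#' @export
#' @examples
#' peptide_mass("PEPTIDEK")
peptide_mass <- function(peptides) {
  stopifnot(is.character(peptides))
  mass_by_code <- numeric(128)
  mass_by_code[utf8ToInt(paste(names(AA_MONO_MASS), collapse = ""))] <- AA_MONO_MASS
  vapply(peptides, function(p) {
    codes <- utf8ToInt(p)
    m <- mass_by_code[codes]
    if (length(codes) == 0L || any(m == 0)) {
      stop("invalid residue in peptide '", p, "'", call. = FALSE)
    }
    sum(m) + WATER_MONO
  }, numeric(1), USE.NAMES = FALSE)
}

#' Peptide m/z for a charge state
#'
#' @param mass Monoisotopic mass (Da).
#' @param charge Positive integer charge.
#' @return m/z = (mass + charge * proton mass) / charge.
#' @export
peptide_mz <- function(mass, charge) {
  stopifnot(all(charge >= 1))
  (mass + charge * PROTON_MASS) / charge
}
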