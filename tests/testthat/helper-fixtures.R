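# Fixtures and independent brute-force oracles used across test files.

# --- brute-force tryptic digestion: enumerate all cleavage-site pairs -------
brute_digest <- function(sequence, missed_cleavages, length_bounds) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  sites <- which(chars %in% c("K", "R") & c(chars[-1], "") != "P")
  bounds <- unique(c(0L, sites, n))
  starts <- utils::head(bounds, -1) + 1L
  ends <- bounds[-1]
  out <- character(0)
  for (i in seq_along(starts)) {
    for (j in i:min(length(starts), i + missed_cleavages)) {
      pep <- substr(sequence, starts[i], ends[j])
      if (nchar(pep) >= length_bounds[1] && nchar(pep) <= length_bounds[2]) {
        out <- c(out, pep)
      }
    }
  }
  out
}

# --- brute-force CV and linear-interpolation quartile -----------------------
brute_cv <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1)) / m
}

brute_q3 <- function(x) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * 0.75 + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# --- random sequences over the standard alphabet ----------------------------
random_seq <- function(len, kr_boost = TRUE) {
  freqs <- if (kr_boost) coarsetraits:::aa_generator_freqs() else
    stats::setNames(rep(1 / 20, 20), coarsetraits:::AA_ALPHABET)
  paste(sample(names(freqs), len, replace = TRUE, prob = freqs), collapse = "")
}

# --- tiny protein databases -------------------------------------------------
toy_proteins <- function() {
  tibble::tibble(
    id = c("p1", "p2", "p3", "p4"),
    taxon = c("diatom", "diatom", "hapto", "hapto"),
    pool = c("ribosomal", "other", "ribosomal", "other"),
    annotations = c("50S ribosomal protein L2", "hypothetical protein",
                    "40S ribosomal protein S3", "elongation factor Tu"),
    sequence = c("AAAGGGKCCCDDDREEEFFFK",
                 "MMMNNNKPPPQQQRSSSTTTK",
                 "VVVWWWKYYYHHHRIIILLLK",
                 "AAAGGGKCCCDDDREEEFFFK")  # identical to p1, different taxon
  )
}

# small intensity table: 2 timepoints x 2 filters x 2 injections
toy_intensity_table <- function() {
  peps <- c("AAAGGGK", "CCCDDDR", "EEEFFFK", "MMMNNNKPPPQQQR")
  grid <- tidyr::expand_grid(peptide = peps, timepoint = 1:2,
                             filter = c("3.0", "0.8"), injection = 1:2)
  set.seed(41)
  grid$intensity <- stats::runif(nrow(grid), 10, 100)
  grid
}

# exhaustively sampled observed table (every feature identified), built
# straight from generated features so tests can bypass the acquisition loop
exhaustive_observed <- function(map, truth, timepoints = 1:4,
                                filters = c("3.0", "0.8", "0.1"),
                                injections = 1, params = dda_params(),
                                noise = TRUE) {
  obs <- list()
  for (tp in timepoints) {
    for (f in filters) {
      for (inj in seq_len(injections)) {
        feats <- generate_features(map, truth, tp, f, params, noise = noise)
        o <- feats[, c("peptide", "intensity")]
        o$timepoint <- tp
        o$filter <- f
        o$injection <- inj
        obs[[length(obs) + 1L]] <- o
      }
    }
  }
  dplyr::bind_rows(obs)
}
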