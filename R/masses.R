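#' Monoisotopic residue masses
#'
#' Monoisotopic masses of the 20 canonical amino acid residues, in Dalton.
#' Cysteine is reported with the carbamidomethyl adduct (+57.02146 Da), the
#' fixed modification assumed throughout prediction and mass bookkeeping.
#'
#' @format Named numeric vector of length 20.
#' @export
residue_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919 + 57.02146, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_WATER  <- 18.0105646863
MASS_PROTON <- 1.007276466879

AA_ALPHABET <- names(residue_masses)

#' Monoisotopic peptide mass
#'
#' @param peptide Character vector of peptide sequences (uppercase, 20-letter
#'   alphabet).
#' @return Numeric vector of neutral monoisotopic masses (Da).
#' @export
peptide_mass <- function(peptide) {
  vapply(peptide, function(p) {
    aa <- strsplit(p, "")[[1]]
    bad <- setdiff(aa, AA_ALPHABET)
    if (length(bad) > 0L) {
      stop("invalid residue(s) in peptide '", p, "': ",
           paste(bad, collapse = ", "))
    }
    sum(residue_masses[aa]) + MASS_WATER
  }, numeric(1), USE.NAMES = FALSE)
}

# Deterministic string hash onto [0, 1): 31-based polynomial rolling hash
# folded mod 2^31 - 1. Used to give the mock predictor reproducible
# pseudo-random fragment intensities without touching the RNG stream.
hash01 <- function(s) {
  m <- 2147483647
  vapply(s, function(x) {
    h <- 0
    for (c in utf8ToInt(x)) h <- (h * 31 + c) %% m
    # one extra scramble round to decorrelate similar strings
    h <- (h * 48271 + 11) %% m
    h / m
  }, numeric(1), USE.NAMES = FALSE)
}
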