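# Average residue masses (Da) and the Bjellqvist pKa set used by the
# molecular-weight and isoelectric-point calculators.
AA_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326,
  X = 110.0000
)
WATER_MASS <- 18.0153

PKA_BJELLQVIST <- list(
  nterm = 7.50, cterm = 3.55,
  positive = c(K = 10.00, R = 12.00, H = 5.98),
  negative = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
)

#' Compute the molecular weight of a protein
#'
#' Sum of average residue masses plus one water, reported in kDa. Sequences
#' containing `X` are computed with a generic residue mass and flagged
#' approximate (attribute `approximate`).
#'
#' @param sequence Amino-acid string.
#' @return Molecular weight in kDa (numeric scalar) with a logical
#'   `approximate` attribute.
#' @export
compute_mw <- function(sequence) {
  assert_aa_sequence(sequence)
  chars <- seq_chars(sequence)
  mw <- (sum(AA_MASS[chars]) + WATER_MASS) / 1000
  attr(mw, "approximate") <- any(chars == "X")
  mw
}

# Henderson-Hasselbalch net charge of a peptide at a given pH.
peptide_charge <- function(counts, pH, pka = PKA_BJELLQVIST) {
  pos <- 1 / (1 + 10^(pH - pka$nterm))
  for (res in names(pka$positive)) {
    pos <- pos + counts[[res]] / (1 + 10^(pH - pka$positive[[res]]))
  }
  neg <- 1 / (1 + 10^(pka$cterm - pH))
  for (res in names(pka$negative)) {
    neg <- neg + counts[[res]] / (1 + 10^(pka$negative[[res]] - pH))
  }
  pos - neg
}

#' Compute the isoelectric point of a protein
#'
#' Finds the pH at which the Henderson-Hasselbalch net charge crosses zero,
#' by bisection on the interval pH 0-14. Uses the Bjellqvist pKa constants
#' (see `PKA_BJELLQVIST` in the package sources).
#'
#' @param sequence Amino-acid string.
#' @param tolerance Bisection stopping width in pH units.
#' @return Isoelectric point (pH, numeric scalar).
#' @export
compute_pi <- function(sequence, tolerance = 0.01) {
  assert_aa_sequence(sequence)
  chars <- seq_chars(sequence)
  ionizable <- c(names(PKA_BJELLQVIST$positive), names(PKA_BJELLQVIST$negative))
  counts <- as.list(vapply(ionizable, function(r) sum(chars == r), numeric(1)))
  lo <- 0; hi <- 14
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (peptide_charge(counts, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
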