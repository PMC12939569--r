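# Shared amino-acid constants: alphabet, average residue masses, pKa sets,
# hydropathy scales. All sequence code in the package validates against
# AA_ALPHABET; 'X' marks an unknown residue and never matches anything.

#' Amino-acid alphabet used throughout the package
#'
#' The 20 proteinogenic one-letter codes plus `"X"` for an unknown residue.
#' `"X"` is legal in chains (collagen entries from translated genomes often
#' carry them) but blocks cleavage on adjacent bonds and never matches a
#' reference peptide.
#'
#' @format Character vector of length 21.
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

# Average (not monoisotopic) residue masses in Da; a free peptide adds one
# water (AA_WATER). Values from standard element averages.
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

# Monoisotopic residue masses, available behind the `monoisotopic` flag.
AA_MONO_MASS <- c(
  A = 71.03711,  R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146,  H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203,  T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
)

AA_WATER      <- 18.0153
AA_WATER_MONO <- 18.010565

#' Default pKa set for the isoelectric-point solver
#'
#' Lehninger-style textbook pKa values. `positive` holds the protonatable
#' groups (the N-terminus plus K, R, H side chains), `negative` the
#' deprotonatable ones (the C-terminus plus D, E, C, Y). Pass a modified
#' copy to [isoelectric_point()] to use another convention.
#'
#' @format List of two named numeric vectors, `positive` and `negative`.
#' @export
PKA_DEFAULT <- list(
  positive = c(nterm = 9.69, K = 10.53, R = 12.48, H = 6.00),
  negative = c(cterm = 2.34, D = 3.65, E = 4.25, C = 8.33, Y = 10.07)
)

# Kyte-Doolittle hydropathy scale (dimensionless GRAVY units).
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5, E = -3.5, Q = -3.5,
  G = -0.4, H = -3.2, I =  4.5, L =  3.8, K = -3.9, M =  1.9, F =  2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# internal: validate a residue string, returning the position of the first
# offending character or 0L when clean
.bad_residue_at <- function(residues, allow_x = TRUE) {
  alpha <- if (allow_x) AA_ALPHABET else setdiff(AA_ALPHABET, "X")
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alpha)
  if (length(bad)) bad[1] else 0L
}
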