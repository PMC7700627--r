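# Physicochemical constant tables.
#
# Sources (published constants, shipped with the package):
#   - Kyte & Doolittle (1982) hydropathy scale.
#   - Ikai (1980) aliphatic-index coefficients (2.9, 3.9).
#   - Guruprasad, Reddy & Pandit (1990) DIWV dipeptide instability weights
#     (inst/extdata/diwv_dipeptide_weights.tsv).
#   - Expasy/ProtParam average residue masses
#     (inst/extdata/residue_avg_masses.tsv); one water (18.0153 Da) is added
#     per chain.
#   - Bjellqvist et al. (1993) pKa set as used by ProtParam, including the
#     residue-specific terminal pKa values.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

WATER_MASS_DA <- 18.0153

KYTE_DOOLITTLE <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Bjellqvist pKa values (ProtParam). Positive groups gain charge below their
# pKa; negative groups above. Terminal pKa depends on the terminal residue.
PKA_POSITIVE <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
PKA_NEGATIVE <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
PKA_NTERM_BY_RESIDUE <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36,
                          T = 6.82, V = 7.44, E = 7.7)
PKA_CTERM_BY_RESIDUE <- c(D = 4.55, E = 4.75)

.residue_masses <- function() {
  if (is.null(.gf_cache$masses)) {
    tab <- utils::read.delim(.gf_extdata("residue_avg_masses.tsv"))
    .gf_cache$masses <- setNames(tab$mass_da, tab$aa)
  }
  .gf_cache$masses
}

.diwv <- function() {
  if (is.null(.gf_cache$diwv)) {
    tab <- utils::read.delim(.gf_extdata("diwv_dipeptide_weights.tsv"),
                             row.names = 1, check.names = FALSE)
    .gf_cache$diwv <- as.matrix(tab)
  }
  .gf_cache$diwv
}
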