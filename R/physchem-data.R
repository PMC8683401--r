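# Reference tables for protein physicochemical calculations.
# Average (isotopic-abundance-weighted) residue masses, Kyte-Doolittle
# hydropathy, residue elemental formulas, the Guruprasad dipeptide instability
# weights (DIWV), and the Bjellqvist pKa set used by the ProtParam service.

AA_MONOMER_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# aliphatic index relative-volume coefficients for V and I/L
ALIPHATIC_COEF <- c(V = 2.9, IL = 3.9)

# residue elemental composition (C, H, N, O, S), water excluded; one water is
# added per chain
AA_ATOMS <- matrix(c(
  # C   H   N  O  S
    3,  5,  1, 1, 0,  # A
    3,  5,  1, 1, 1,  # C
    4,  5,  1, 3, 0,  # D
    5,  7,  1, 3, 0,  # E
    9,  9,  1, 1, 0,  # F
    2,  3,  1, 1, 0,  # G
    6,  7,  3, 1, 0,  # H
    6, 11,  1, 1, 0,  # I
    6, 12,  2, 1, 0,  # K
    6, 11,  1, 1, 0,  # L
    5,  9,  1, 1, 1,  # M
    4,  6,  2, 2, 0,  # N
    5,  7,  1, 1, 0,  # P
    5,  8,  2, 2, 0,  # Q
    6, 12,  4, 1, 0,  # R
    3,  5,  1, 2, 0,  # S
    4,  7,  1, 2, 0,  # T
    5,  9,  1, 1, 0,  # V
   11, 10,  2, 1, 0,  # W
    9,  9,  1, 2, 0   # Y
), ncol = 5, byrow = TRUE,
  dimnames = list(c("A","C","D","E","F","G","H","I","K","L",
                    "M","N","P","Q","R","S","T","V","W","Y"),
                  c("C", "H", "N", "O", "S")))

# Guruprasad dipeptide instability weight values (DIWV), 20 x 20:
# rows = first residue, columns = second residue, order ACDEFGHIKLMNPQRSTVWY
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE,
  dimnames = list(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))

# Bjellqvist pKa values (as used by ProtParam): side chains plus
# residue-specific terminal pKas
PKA_BJELLQVIST <- list(
  positive = c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98),
  negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0),
  ntermByResidue = c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                     V = 7.44, E = 7.7),
  ctermByResidue = c(D = 4.55, E = 4.75)
)
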