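# Physicochemical constant tables used by the characterization module.
# Values are the standard published sets (sources noted per table); the
# Guruprasad dipeptide weights live in inst/extdata because of their size.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte & Doolittle (1982) hydropathy scale
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# Average residue masses (Da), ExPASy ProtParam convention; add one water
# (18.01524 Da) for the intact chain.
RESIDUE_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326)
WATER_MASS <- 18.01524

# Residue elemental composition (free amino acid minus one water).
# Columns C, H, N, O, S; one water is added for the whole chain.
RESIDUE_FORMULA <- matrix(c(
  # C  H  N  O  S
    3,  5, 1, 1, 0,  # A
    6, 12, 4, 1, 0,  # R
    4,  6, 2, 2, 0,  # N
    4,  5, 1, 3, 0,  # D
    3,  5, 1, 1, 1,  # C
    5,  8, 2, 2, 0,  # Q
    5,  7, 1, 3, 0,  # E
    2,  3, 1, 1, 0,  # G
    6,  7, 3, 1, 0,  # H
    6, 11, 1, 1, 0,  # I
    6, 11, 1, 1, 0,  # L
    6, 12, 2, 1, 0,  # K
    5,  9, 1, 1, 1,  # M
    9,  9, 1, 1, 0,  # F
    5,  7, 1, 1, 0,  # P
    3,  5, 1, 2, 0,  # S
    4,  7, 1, 2, 0,  # T
   11, 10, 2, 1, 0,  # W
    9,  9, 1, 2, 0,  # Y
    5,  9, 1, 1, 0), # V
  nrow = 20, byrow = TRUE,
  dimnames = list(AA1, c("C", "H", "N", "O", "S")))

# Bjellqvist pKa set as used for isoelectric-point calculation: terminal
# groups plus the seven ionizable side chains.
PKA_SET <- list(
  positive = c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98),
  negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0))

# IUPAC nucleotide degeneracy codes
IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# Extended amino-acid alphabet used in consensus motifs
MOTIF_ALPHABET <- list(B = c("N", "D"), Z = c("Q", "E"), J = c("I", "L"),
                       X = AA1)

# package-local cache for lazily loaded tables
.fs_cache <- new.env(parent = emptyenv())

#' Dipeptide instability weight table
#'
#' The 20 x 20 dipeptide instability weight values (DIWV) of Guruprasad,
#' Reddy & Pandit (1990), as used by the instability index.
#'
#' @return A 20 x 20 numeric matrix indexed `[first, second]` residue.
#' @export
diwv_table <- function() {
  if (is.null(.fs_cache$diwv)) {
    path <- system.file("extdata", "diwv_guruprasad1990.tsv",
                        package = "famsurvey", mustWork = TRUE)
    tab <- utils::read.delim(path, comment.char = "#", row.names = 1,
                             check.names = FALSE)
    .fs_cache$diwv <- as.matrix(tab)[AA1, AA1]
  }
  .fs_cache$diwv
}

#' BLOSUM62 substitution matrix
#'
#' The default protein scoring matrix, taken from Biostrings.
#'
#' @return Integer matrix with amino-acid row/column names.
#' @export
blosum62 <- function() {
  if (is.null(.fs_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .fs_cache$blosum62 <- e$BLOSUM62
  }
  .fs_cache$blosum62
}
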