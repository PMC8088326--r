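# Internal constants: tuple layout, codon order, alphabets, IUPAC table.
#
# Codons are 12-tuples laid out as (T1,C1,A1,G1, T2,C2,A2,G2, T3,C3,A3,G3):
# three 4-blocks in nucleotide order T, C, A, G.  All concrete-codon
# indexing in the package follows the classical code-table order (first
# position slowest): index(x,y,z) = 16*(x-1) + 4*(y-1) + z.

.NUC <- c("T", "C", "A", "G")

.TUPLE_NAMES <- paste0(rep(.NUC, 3), rep(1:3, each = 4))

.CODONS64 <- paste0(rep(.NUC, each = 16),
                    rep(rep(.NUC, each = 4), times = 4),
                    rep(.NUC, times = 16))

# 21-symbol alphabet: the 20 canonical residues plus "*" for STOP.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AA21 <- c(.AA20, "*")

.AA3TO1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
             Ter = "*", Stp = "*")

# 15 IUPAC nucleotide ambiguity codes as 0/1 masks over (T,C,A,G).
# Built from Biostrings' IUPAC_CODE_MAP at load time.
.iupac_masks <- function() {
  map <- Biostrings::IUPAC_CODE_MAP
  m <- t(vapply(strsplit(unname(map), ""), function(comp) {
    as.integer(.NUC %in% comp)
  }, integer(4)))
  dimnames(m) <- list(names(map), .NUC)
  m
}

.pkg_cache <- new.env(parent = emptyenv())

.IUPAC_MASKS <- function() {
  if (is.null(.pkg_cache$iupac)) .pkg_cache$iupac <- .iupac_masks()
  .pkg_cache$iupac
}

# mask integer key for a 4-block: sum(bits * c(8,4,2,1))
.mask_key <- function(block) sum(block * c(8L, 4L, 2L, 1L))

.IUPAC_BY_KEY <- function() {
  if (is.null(.pkg_cache$bykey)) {
    m <- .IUPAC_MASKS()
    keys <- apply(m, 1, .mask_key)
    v <- character(15)
    v[keys] <- rownames(m)
    .pkg_cache$bykey <- v
  }
  .pkg_cache$bykey
}

# Average and monoisotopic residue masses (Da), residue = amino acid - water.
.RESIDUE_MASS_AVG <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

.RESIDUE_MASS_MONO <- c(
  A = 71.03711,  R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146,  H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203,  T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)

.WATER_AVG <- 18.01528
.WATER_MONO <- 18.010565

# index helpers -----------------------------------------------------------

.codon_index <- function(codon) match(codon, .CODONS64)

.block <- function(tuple, i) tuple[(4L * (i - 1L) + 1L):(4L * i)]

.stopifnot_tuple <- function(x) {
  if (!is.numeric(x) || length(x) != 12L)
    stop("a codon tuple must be a numeric vector of length 12 ",
         "(blocks T,C,A,G for positions 1-3)", call. = FALSE)
  invisible(x)
}
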