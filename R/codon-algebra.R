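# Codon algebra: base-codons as binary 12-tuples, spiked codons as
# fractional 12-tuples, expansion into concrete codons, amino-acid
# distributions, the forbidden-codon test and IUPAC interconversion.

#' Convert IUPAC degenerate triplets to base-codon tuples
#'
#' A base-codon is a 12-tuple of 0/1 values, three 4-blocks in nucleotide
#' order T, C, A, G, marking which nucleotides are allowed at each codon
#' position.  The 3375 valid base-codons (each block non-empty) are in
#' bijection with 3-letter strings over the 15 IUPAC ambiguity codes.
#'
#' @param s character vector of 3-letter IUPAC strings (e.g. `"NNK"`).
#' @return for a single string, an integer vector of length 12 (named
#'   T1..G3); for several, a matrix with one row per string.
#' @examples
#' fromIUPAC("NNS")   # (1,1,1,1, 1,1,1,1, 0,1,0,1)
#' toIUPAC(fromIUPAC("NNK"))
#' @export
fromIUPAC <- function(s) {
  s <- toupper(as.character(s))
  if (any(nchar(s) != 3L))
    stop("IUPAC codon strings must have exactly 3 characters")
  masks <- .IUPAC_MASKS()
  chars <- strsplit(s, "")
  rows <- lapply(chars, function(cc) {
    if (!all(cc %in% rownames(masks)))
      stop("invalid IUPAC nucleotide code(s): ",
           paste(setdiff(cc, rownames(masks)), collapse = ", "))
    as.integer(t(masks[cc, , drop = FALSE]))
  })
  if (length(rows) == 1L)
    return(setNames(rows[[1L]], .TUPLE_NAMES))
  out <- do.call(rbind, rows)
  dimnames(out) <- list(s, .TUPLE_NAMES)
  out
}

#' @rdname fromIUPAC
#' @param b a base-codon tuple (length-12 0/1 vector), a fractional codon
#'   tuple (its support is used), or a matrix of such rows.
#' @export
toIUPAC <- function(b) {
  if (is.matrix(b))
    return(vapply(seq_len(nrow(b)), function(i) toIUPAC(b[i, ]), ""))
  .stopifnot_tuple(b)
  bits <- as.integer(b > 0)
  bykey <- .IUPAC_BY_KEY()
  letters3 <- vapply(1:3, function(i) {
    key <- .mask_key(.block(bits, i))
    if (key == 0L) stop("empty positional block: not a valid codon support")
    bykey[key]
  }, "")
  paste(letters3, collapse = "")
}

#' Expand a codon support into its concrete codons
#'
#' @param b a base-codon tuple, fractional tuple, or IUPAC triplet string.
#' @return character vector of concrete codons (the Cartesian product of
#'   allowed nucleotides per position), in code-table order.
#' @examples
#' length(expandCodon("NNK"))  # 32
#' @export
expandCodon <- function(b) {
  if (is.character(b)) b <- fromIUPAC(b)
  .stopifnot_tuple(b)
  bits <- b > 0
  .CODONS64[as.logical(kronecker(.block(bits, 1),
                                 kronecker(.block(bits, 2), .block(bits, 3))))]
}

#' Symbols encoded by a codon support
#'
#' @inheritParams expandCodon
#' @param code a [GeneticCode-class].
#' @return sorted character vector of the distinct symbols the expansion
#'   translates to (may include `"*"`).
#' @examples
#' encodedSymbols("NNK")  # all 20 residues and "*"
#' @export
encodedSymbols <- function(b, code = standardGeneticCode()) {
  sort(unique(unname(code@table[expandCodon(b)])))
}

#' Equimolar (degenerate) fractions on a codon support
#'
#' @inheritParams expandCodon
#' @return numeric 12-tuple with each positional block uniform over its
#'   support (the degenerate special case of a spiked codon).
#' @export
equimolarFractions <- function(b) {
  if (is.character(b)) b <- fromIUPAC(b)
  .stopifnot_tuple(b)
  bits <- as.numeric(b > 0)
  for (i in 1:3) {
    idx <- (4L * (i - 1L) + 1L):(4L * i)
    bits[idx] <- bits[idx] / sum(bits[idx])
  }
  setNames(bits, .TUPLE_NAMES)
}

.check_fractions <- function(f, tol = 1e-9) {
  .stopifnot_tuple(f)
  if (any(f < 0)) stop("codon fractions must be non-negative")
  s <- vapply(1:3, function(i) sum(.block(f, i)), 0)
  if (any(abs(s - 1) > tol))
    stop("each positional 4-block of a spiked codon must sum to 1")
  invisible(f)
}

#' Amino-acid distribution encoded by a spiked codon
#'
#' The probability of symbol s is the sum, over concrete codons xyz
#' translating to s, of f1(x) f2(y) f3(z) — positions are independent.
#'
#' @param f a fractional 12-tuple (each block summing to 1), a base-codon
#'   tuple of 0/1 (taken as equimolar), or an IUPAC triplet string.
#' @param code a [GeneticCode-class].
#' @return named numeric over `codeAlphabet(code)`, summing to 1.
#' @examples
#' codonAADistribution("NNK")["*"]  # 1/32 (TAG only)
#' @export
codonAADistribution <- function(f, code = standardGeneticCode()) {
  if (is.character(f)) f <- fromIUPAC(f)
  .stopifnot_tuple(f)
  if (all(f %in% c(0, 1))) f <- equimolarFractions(f)
  .check_fractions(f)
  p64 <- kronecker(.block(f, 1), kronecker(.block(f, 2), .block(f, 3)))
  w <- vapply(split(p64, factor(code@table, levels = code@alphabet)),
              sum, 0)
  setNames(w, code@alphabet)
}

#' Can a codon support produce a given concrete codon?
#'
#' `excludesCodon(m, f)` is TRUE iff some tuple position is required by
#' the concrete codon `f` but has zero weight in `m` — i.e. `m` cannot
#' generate `f`.  This is the forbidden-codon condition for designs.
#'
#' @param m a base-codon or fractional 12-tuple, an IUPAC triplet, or a
#'   matrix of tuples (one row per codon).
#' @param f a concrete codon string (3 letters over T,C,A,G) or a vector
#'   of them.
#' @return logical; for matrix `m` and/or vector `f`, an `m`-by-`f`
#'   logical matrix.
#' @export
excludesCodon <- function(m, f) {
  if (is.character(m)) m <- fromIUPAC(m)
  fbits <- fromIUPAC(f)                    # concrete codons are valid IUPAC
  if (!is.matrix(fbits)) fbits <- matrix(fbits, nrow = 1L,
                                         dimnames = list(f, .TUPLE_NAMES))
  if (!all(rowSums(fbits) == 3L))
    stop("'f' must be concrete codons (no ambiguity codes)")
  single <- !is.matrix(m)
  if (single) m <- matrix(m, nrow = 1L)
  # m excludes f  <=>  some position with f==1 has m==0
  out <- tcrossprod(m == 0, fbits) > 0
  colnames(out) <- rownames(fbits)
  if (single && ncol(out) == 1L) out[1L, 1L] else
    if (single) out[1L, ] else if (ncol(out) == 1L) out[, 1L] else out
}

#' Mixture amino-acid distribution of a codon multiset
#'
#' The distribution encoded by a template is the unweighted average of
#' its codons' distributions.
#'
#' @param M a [CodonMultiset-class], a fractions matrix (rows = codons,
#'   12 columns), or a character vector of IUPAC triplets (equimolar).
#' @param code a [GeneticCode-class].
#' @return named numeric over `codeAlphabet(code)`, summing to 1.
#' @examples
#' mixtureDistribution(c("ATG", "TGG"))[c("M", "W")]  # 0.5, 0.5
#' @export
mixtureDistribution <- function(M, code = standardGeneticCode()) {
  fr <- .as_fractions_matrix(M)
  if (nrow(fr) == 0L) stop("the codon multiset is empty")
  d <- colMeans(t(apply(fr, 1L, codonAADistribution, code = code)))
  setNames(d, code@alphabet)
}

.as_fractions_matrix <- function(M) {
  if (is(M, "CodonMultiset")) return(M@fractions)
  if (is(M, "DesignResult")) return(M@multiset@fractions)
  if (is.character(M)) {
    fr <- t(vapply(M, function(s) equimolarFractions(fromIUPAC(s)),
                   numeric(12)))
    colnames(fr) <- .TUPLE_NAMES
    return(fr)
  }
  if (is.numeric(M) && !is.matrix(M)) M <- matrix(M, nrow = 1L)
  stopifnot(is.matrix(M), ncol(M) == 12L)
  M
}

#' Enumerate base-codons under constraints
#'
#' Generates the valid base-codons (each positional block non-empty; 3375
#' with no further constraint) and keeps those whose expansion contains no
#' forbidden codon, encodes only allowed symbols, and has at most
#' `maxDegeneracy` concrete codons.
#'
#' @param forbidden character vector of concrete codons that no kept
#'   support may be able to produce.
#' @param allowedSymbols symbols the expansion may encode; defaults to the
#'   whole alphabet of `code`.
#' @param code a [GeneticCode-class].
#' @param maxDegeneracy optional cap on the expansion size.
#' @return integer matrix (rows = base-codons, 12 columns, rownames the
#'   IUPAC triplets), in canonical enumeration order.  A constraint set
#'   that removes all candidates yields a 0-row matrix with a warning.
#' @examples
#' nrow(enumerateBaseCodons())  # 3375
#' @export
enumerateBaseCodons <- function(forbidden = character(),
                                allowedSymbols = NULL,
                                code = standardGeneticCode(),
                                maxDegeneracy = NULL) {
  stopifnot(is(code, "GeneticCode"))
  if (is.null(allowedSymbols)) allowedSymbols <- code@alphabet
  if (!length(allowedSymbols)) stop("'allowedSymbols' must be non-empty")
  bad <- setdiff(forbidden, .CODONS64)
  if (length(bad))
    stop("not concrete codons: ", paste(bad, collapse = ", "))

  B <- .all_base_codons()
  E <- .expansion_matrix(B)           # 3375 x 64 logical
  disallowed <- .CODONS64[!(code@table %in% allowedSymbols)]
  badcod <- .CODONS64 %in% union(forbidden, disallowed)
  keep <- rowSums(E[, badcod, drop = FALSE]) == 0
  if (!is.null(maxDegeneracy))
    keep <- keep & rowSums(E) <= maxDegeneracy
  out <- B[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("constraints eliminate all 3375 base-codons")
  out
}

# all 3375 base-codons, canonical order (block patterns by ascending
# integer key, position 1 slowest)
.all_base_codons <- function() {
  if (is.null(.pkg_cache$allbc)) {
    pats <- as.matrix(expand.grid(G = 0:1, A = 0:1, C = 0:1, T = 0:1))
    pats <- pats[-1L, c("T", "C", "A", "G"), drop = FALSE]  # drop 0000
    n <- nrow(pats)  # 15
    i1 <- rep(seq_len(n), each = n * n)
    i2 <- rep(rep(seq_len(n), each = n), times = n)
    i3 <- rep(seq_len(n), times = n * n)
    B <- cbind(pats[i1, ], pats[i2, ], pats[i3, ])
    storage.mode(B) <- "integer"
    dimnames(B) <- list(NULL, .TUPLE_NAMES)
    rownames(B) <- toIUPAC(B)
    .pkg_cache$allbc <- B
  }
  .pkg_cache$allbc
}

# n x 64 logical: which concrete codons each support row can produce
.expansion_matrix <- function(B) {
  c64 <- seq_len(64L) - 1L
  i1 <- c64 %/% 16L + 1L
  i2 <- (c64 %/% 4L) %% 4L + 1L
  i3 <- c64 %% 4L + 1L
  (B[, i1, drop = FALSE] * B[, 4L + i2, drop = FALSE] *
     B[, 8L + i3, drop = FALSE]) > 0
}

# equimolar aa distribution of every row of B: n x nsym
.pool_distributions <- function(B, code) {
  E <- .expansion_matrix(B)
  deg <- rowSums(E)
  S <- outer(code@table, code@alphabet, "==") * 1  # 64 x nsym
  D <- (E / deg) %*% S
  colnames(D) <- code@alphabet
  D
}
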