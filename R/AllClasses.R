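#' Genetic code with optional codon reassignment
#'
#' A `GeneticCode` maps each of the 64 concrete DNA codons (triplets over
#' T, C, A, G) to one symbol of a translation alphabet.  The default
#' alphabet has 21 symbols: the 20 canonical residues plus `"*"` (STOP).
#' Codon reassignment — e.g. repurposing an amber stop for an unnatural
#' residue — may extend the alphabet with user-defined labels.
#'
#' @slot table named character vector of length 64; names are the codons
#'   in code-table order (TTT, TTC, ...), values are symbols.
#' @slot alphabet character vector of the distinct symbols, in the order
#'   used for all distribution vectors derived from this code.
#'
#' @seealso [standardGeneticCode()], [geneticCode()], [reassignCodons()]
#' @export
setClass("GeneticCode",
         representation(table = "character", alphabet = "character"))

setValidity("GeneticCode", function(object) {
  msg <- character()
  if (length(object@table) != 64L)
    msg <- c(msg, "table must have exactly 64 entries")
  if (!identical(sort(names(object@table)), sort(.CODONS64)))
    msg <- c(msg, "table names must be the 64 codons over T,C,A,G")
  if (!all(object@table %in% object@alphabet))
    msg <- c(msg, "every codon must map to a symbol of the alphabet")
  if (anyDuplicated(object@alphabet))
    msg <- c(msg, "alphabet symbols must be unique")
  if (length(msg)) msg else TRUE
})

#' Ordered multiset of designed codons
#'
#' The optimizer's state and the designed randomized region: `l` codons,
#' each a 12-tuple of per-position nucleotide fractions.  In
#' `"degenerate"` mode every block is equimolar over its support (the
#' codon is one of the 3375 degenerate codons); in `"spiked"` mode
#' fractions are arbitrary non-negative values summing to 1 per block.
#'
#' @slot fractions numeric matrix, one row per codon, 12 columns in the
#'   (T,C,A,G) x position layout.
#' @slot mode `"degenerate"` or `"spiked"`.
#' @export
setClass("CodonMultiset",
         representation(fractions = "matrix", mode = "character"))

setValidity("CodonMultiset", function(object) {
  fr <- object@fractions
  msg <- character()
  if (ncol(fr) != 12L) msg <- c(msg, "fractions must have 12 columns")
  if (any(fr < 0)) msg <- c(msg, "fractions must be non-negative")
  for (i in 1:3) {
    s <- rowSums(fr[, (4 * i - 3):(4 * i), drop = FALSE])
    if (any(abs(s - 1) > 1e-9)) {
      msg <- c(msg, "each positional 4-block must sum to 1")
      break
    }
  }
  if (!object@mode %in% c("degenerate", "spiked"))
    msg <- c(msg, "mode must be 'degenerate' or 'spiked'")
  if (object@mode == "degenerate" && nrow(fr)) {
    eq <- t(apply(fr, 1, function(f) equimolarFractions(as.numeric(f > 0))))
    if (max(abs(eq - fr)) > 1e-9)
      msg <- c(msg, "degenerate codons must be equimolar on their support")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a codon multiset
#'
#' @param x a character vector of IUPAC triplets (degenerate codons) or a
#'   numeric fractions matrix (rows = codons, 12 columns).
#' @param mode `"degenerate"` or `"spiked"`; defaults to `"degenerate"`
#'   for IUPAC input and `"spiked"` for a fractions matrix.
#' @return a [CodonMultiset-class].
#' @examples
#' CodonMultiset(c("NNK", "NNK"))
#' @export
CodonMultiset <- function(x, mode = NULL) {
  if (is.character(x)) {
    fr <- .as_fractions_matrix(x)
    if (is.null(mode)) mode <- "degenerate"
  } else {
    fr <- x
    stopifnot(is.matrix(fr), ncol(fr) == 12L)
    colnames(fr) <- .TUPLE_NAMES
    if (is.null(mode)) mode <- "spiked"
  }
  rownames(fr) <- NULL
  new("CodonMultiset", fractions = fr, mode = mode)
}

#' @describeIn CodonMultiset-class the fractions matrix.
#' @param x,object a `CodonMultiset`.
#' @export
codonFractions <- function(x) .as_fractions_matrix(x)

#' @describeIn CodonMultiset-class binary support matrix (base-codons).
#' @export
codonSupport <- function(x) {
  fr <- .as_fractions_matrix(x)
  s <- (fr > 0) * 1L
  storage.mode(s) <- "integer"
  s
}

#' @describeIn CodonMultiset-class concatenated IUPAC string of the
#'   codon supports (the degenerate template sequence).
#' @export
iupacTemplate <- function(x) paste(toIUPAC(codonSupport(x)), collapse = "")

#' @rdname CodonMultiset-class
#' @export
setMethod("length", "CodonMultiset", function(x) nrow(x@fractions))

#' @rdname CodonMultiset-class
#' @export
setMethod("show", "CodonMultiset", function(object) {
  l <- nrow(object@fractions)
  cat("CodonMultiset of", l, object@mode, "codon(s)\n")
  if (l) cat("  support:", paste(toIUPAC(codonSupport(object)),
                                 collapse = " "), "\n")
})

#' Full template design: randomized region plus constant context
#'
#' Bundles the designed codon multiset with optional constant DNA flanks
#' (primer/cassette context) and constant protein prefix/suffix (e.g. a
#' linker plus purification tag) used in mass accounting.
#'
#' @slot codons a [CodonMultiset-class].
#' @slot fivePrime,threePrime constant DNA strings (no ambiguity codes).
#' @slot proteinPrefix,proteinSuffix constant residue strings.
#' @export
setClass("TemplateDesign",
         representation(codons = "CodonMultiset",
                        fivePrime = "character", threePrime = "character",
                        proteinPrefix = "character",
                        proteinSuffix = "character"))

setValidity("TemplateDesign", function(object) {
  msg <- character()
  for (s in c(object@fivePrime, object@threePrime))
    if (nzchar(s) && grepl("[^TCAG]", s))
      msg <- c(msg, "constant DNA regions must contain only T,C,A,G")
  aa_ok <- paste(c(.AA20, "*"), collapse = "")
  for (s in c(object@proteinPrefix, object@proteinSuffix))
    if (nzchar(s) && !all(strsplit(s, "")[[1]] %in% .AA20))
      msg <- c(msg, "constant protein regions must use 1-letter residues")
  if (length(msg)) msg else TRUE
})

#' @rdname TemplateDesign-class
#' @param codons a [CodonMultiset-class] (or IUPAC character vector).
#' @param fivePrime,threePrime constant DNA flanks.
#' @param proteinPrefix,proteinSuffix constant residue strings for mass
#'   accounting.
#' @export
TemplateDesign <- function(codons, fivePrime = "", threePrime = "",
                           proteinPrefix = "", proteinSuffix = "") {
  if (!is(codons, "CodonMultiset")) codons <- CodonMultiset(codons)
  new("TemplateDesign", codons = codons,
      fivePrime = toupper(fivePrime), threePrime = toupper(threePrime),
      proteinPrefix = proteinPrefix, proteinSuffix = proteinSuffix)
}

#' @rdname TemplateDesign-class
#' @export
setMethod("show", "TemplateDesign", function(object) {
  cat("TemplateDesign:", length(object@codons), "randomized codon(s),",
      nchar(object@fivePrime), "nt 5' /", nchar(object@threePrime),
      "nt 3' constant DNA\n")
})

.as_design <- function(x) {
  if (is(x, "TemplateDesign")) return(x)
  if (is(x, "DesignResult")) return(TemplateDesign(x@multiset))
  TemplateDesign(if (is(x, "CodonMultiset")) x else CodonMultiset(x))
}

#' Result of a library design run
#'
#' @slot multiset the best [CodonMultiset-class] found.
#' @slot mode,norm search mode and distance norm used.
#' @slot target,achieved named distributions over the code alphabet.
#' @slot distance final distance of the best replicate.
#' @slot trace accepted-objective values of the best replicate
#'   (non-increasing, starting at the initial state's distance).
#' @slot accepted,rejected proposal counts of the best replicate.
#' @slot seed seed of the best replicate.
#' @slot replicateSummary data.frame with one row per replicate.
#' @slot poolSize number of base-codons after pre-selection.
#' @slot geneticCode the [GeneticCode-class] used.
#' @export
setClass("DesignResult",
         representation(multiset = "CodonMultiset", mode = "character",
                        norm = "character", target = "numeric",
                        achieved = "numeric", distance = "numeric",
                        trace = "numeric", accepted = "integer",
                        rejected = "integer", seed = "integer",
                        replicateSummary = "data.frame",
                        poolSize = "integer", geneticCode = "GeneticCode"))

#' @describeIn DesignResult-class final distance (chosen norm) between
#'   target and achieved distribution.
#' @param x a `DesignResult`.
#' @export
designDistance <- function(x) x@distance

#' @describeIn DesignResult-class accepted-objective trace of the best
#'   replicate.
#' @export
distanceTrace <- function(x) x@trace

#' @describeIn DesignResult-class amino-acid distribution encoded by the
#'   returned multiset.
#' @export
achievedDistribution <- function(x) x@achieved

#' @describeIn DesignResult-class per-symbol deviation achieved - target
#'   in percentage points (0-100 scale).
#' @export
deviationPercent <- function(x) (x@achieved - x@target) * 100

#' @describeIn DesignResult-class the designed codon multiset.
#' @export
bestMultiset <- function(x) x@multiset

#' @rdname DesignResult-class
#' @export
setMethod("show", "DesignResult", function(object) {
  cat("DesignResult:", length(object@multiset), object@mode,
      "codon(s), norm", object@norm, "\n")
  cat("  pool size:", object@poolSize,
      " replicates:", nrow(object@replicateSummary), "\n")
  cat(sprintf("  final distance: %.6g  (accepted %d, rejected %d)\n",
              object@distance, object@accepted, object@rejected))
  cat("  template:", iupacTemplate(object@multiset), "\n")
})

#' Composition statistics of a sampled sequence set
#'
#' @slot n number of sequences.
#' @slot composition pooled residue frequencies over the randomized
#'   region (sums to 1).
#' @slot deviationPct per-symbol observed - target, percentage points.
#' @slot distances named numeric: L1, L2, Linf, meanSquared deviations on
#'   the (0,1) scale (all `NA` when no target was supplied).
#' @slot uniquenessFraction distinct / total sequences.
#' @slot positionFreqs 4 x (3l) matrix of nucleotide frequencies
#'   (rows T, C, A, G; columns sum to 1).
#' @export
setClass("SampleStats",
         representation(n = "integer", composition = "numeric",
                        deviationPct = "numeric", distances = "numeric",
                        uniquenessFraction = "numeric",
                        positionFreqs = "matrix"))

#' @describeIn SampleStats-class distinct / total sequences.
#' @param x a `SampleStats`.
#' @export
uniquenessFraction <- function(x) x@uniquenessFraction

#' @describeIn SampleStats-class per-position nucleotide frequency matrix.
#' @export
positionFrequencies <- function(x) x@positionFreqs

#' @describeIn SampleStats-class pooled residue frequencies.
#' @export
sampleComposition <- function(x) x@composition

#' @rdname SampleStats-class
#' @export
setMethod("show", "SampleStats", function(object) {
  cat("SampleStats over", object@n, "sequences\n")
  cat(sprintf("  uniqueness fraction: %.4f\n", object@uniquenessFraction))
  if (!all(is.na(object@distances)))
    cat(sprintf("  L2 deviation from target: %.6g\n",
                object@distances[["L2"]]))
})
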