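# In-silico validation of a designed template: sequence sampling,
# translation and composition statistics.

#' Sample concrete DNA sequences from a template design
#'
#' At every randomized position a nucleotide is drawn independently
#' according to the codon's fractional 12-tuple; constant flanks are
#' appended verbatim when requested.
#'
#' @param design a [TemplateDesign-class], [DesignResult-class],
#'   [CodonMultiset-class] or IUPAC character vector.
#' @param n number of sequences.
#' @param seed optional integer seed.
#' @param includeConstant prepend/append the design's constant DNA flanks.
#' @return character vector of `n` DNA strings.
#' @examples
#' sampleSequences(c("ATG", "ATG"), n = 2)  # "ATGATG" twice
#' @export
sampleSequences <- function(design, n, seed = NULL,
                            includeConstant = FALSE) {
  stopifnot(n >= 1)
  design <- .as_design(design)
  if (!is.null(seed)) set.seed(seed)
  fr <- codonFractions(design@codons)
  l <- nrow(fr)
  if (l == 0L) stop("the design has no randomized codons")
  cols <- vector("list", 3L * l)
  for (i in seq_len(l)) {
    for (p in 1:3) {
      pr <- fr[i, (4L * p - 3L):(4L * p)]
      cols[[3L * (i - 1L) + p]] <-
        .NUC[sample.int(4L, n, replace = TRUE, prob = pr)]
    }
  }
  seqs <- do.call(paste0, cols)
  if (includeConstant)
    seqs <- paste0(design@fivePrime, seqs, design@threePrime)
  seqs
}

#' Translate concrete DNA sequences
#'
#' Codon-wise translation through a [GeneticCode-class]; STOP is rendered
#' as `"*"`.  Sequences must be concrete (no ambiguity codes) and of
#' length divisible by 3.
#'
#' @param x character vector of DNA strings.
#' @param code a [GeneticCode-class].
#' @return character vector of residue strings.
#' @examples
#' translateDNA(c("ATGTGG", "ATGTAA"))  # "MW" "M*"
#' @export
translateDNA <- function(x, code = standardGeneticCode()) {
  x <- toupper(x)
  nc <- nchar(x)
  if (any(nc %% 3L != 0L))
    stop("sequence length must be divisible by 3")
  if (any(grepl("[^TCAG]", x)))
    stop("sequences must be concrete DNA over T,C,A,G (no ambiguity codes)")
  vapply(x, function(s) {
    cods <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    paste(code@table[cods], collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Composition statistics of sampled library sequences
#'
#' Pools residue frequencies of the translated randomized region across
#' all sequences and compares them to a target distribution; also
#' reports the uniqueness fraction (distinct / total, at the DNA level
#' by default) and the per-position nucleotide frequency matrix.
#'
#' @param seqs character vector of concrete DNA sequences covering the
#'   randomized region only (as returned by [sampleSequences()] with
#'   `includeConstant = FALSE`).
#' @param target optional named target weights; deviations are `NA`
#'   without it.
#' @param code a [GeneticCode-class].
#' @param uniquenessLevel `"dna"` (default) or `"protein"`.
#' @return a [SampleStats-class].
#' @export
compositionStats <- function(seqs, target = NULL,
                             code = standardGeneticCode(),
                             uniquenessLevel = c("dna", "protein")) {
  uniquenessLevel <- match.arg(uniquenessLevel)
  if (!length(seqs)) stop("empty sequence set")
  n <- length(seqs)
  prot <- translateDNA(seqs, code)
  res <- unlist(strsplit(prot, ""), use.names = FALSE)
  comp <- table(factor(res, levels = code@alphabet))
  comp <- as.numeric(comp) / sum(comp)
  names(comp) <- code@alphabet

  if (!is.null(target)) {
    tg <- targetDistribution(target, code)
    diff <- comp - tg
    distances <- c(L1 = sum(abs(diff)), L2 = sqrt(sum(diff^2)),
                   Linf = max(abs(diff)), meanSquared = mean(diff^2))
    devpct <- diff * 100
  } else {
    distances <- c(L1 = NA_real_, L2 = NA_real_, Linf = NA_real_,
                   meanSquared = NA_real_)
    devpct <- setNames(rep(NA_real_, length(comp)), names(comp))
  }

  uq <- if (uniquenessLevel == "dna") length(unique(seqs)) / n
        else length(unique(prot)) / n

  chars <- strsplit(seqs, "")
  width <- unique(lengths(chars))
  if (length(width) != 1L) stop("sequences must have equal length")
  mat <- matrix(unlist(chars, use.names = FALSE), nrow = width)
  pf <- vapply(seq_len(width), function(p)
    as.numeric(table(factor(mat[p, ], levels = .NUC))) / n,
    numeric(4))
  dimnames(pf) <- list(.NUC, paste0("pos", seq_len(width)))

  new("SampleStats", n = as.integer(n), composition = comp,
      deviationPct = devpct, distances = distances,
      uniquenessFraction = uq, positionFreqs = pf)
}

#' Write sampled sequences as FASTA or FASTQ
#'
#' @param seqs character vector of DNA strings.
#' @param file output path.
#' @param format `"fasta"` or `"fastq"` (constant quality `"I"`).
#' @export
writeSequences <- function(seqs, file, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("seq%0*d", nchar(length(seqs)), seq_along(seqs))
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, file)
  } else {
    q <- Biostrings::BStringSet(vapply(nchar(seqs), function(w)
      paste(rep("I", w), collapse = ""), ""))
    Biostrings::writeXStringSet(x, file, format = "fastq", qualities = q)
  }
  invisible(file)
}
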