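# Readers, template export, reports and the programmatic entry points
# used by the command-line scripts.

#' Read a target amino-acid distribution from TSV or JSON
#'
#' TSV: two columns (residue, weight), with or without a header line.
#' JSON: a single object of residue -> weight.  Residues may use 1- or
#' 3-letter codes; weights are normalized to sum to 1 and omitted
#' residues get weight 0.
#'
#' @param path input file.
#' @param code a [GeneticCode-class].
#' @return named distribution over `codeAlphabet(code)`.
#' @export
readTargetDistribution <- function(path, code = standardGeneticCode()) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
    return(targetDistribution(x, code))
  }
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("target TSV needs two columns: residue, weight")
  if (is.na(suppressWarnings(as.numeric(df[1L, 2L]))))
    df <- df[-1L, , drop = FALSE]
  w <- as.numeric(df[[2L]])
  if (anyNA(w)) stop("non-numeric weight in target file")
  targetDistribution(setNames(w, as.character(df[[1L]])), code)
}

#' Read a codon-usage table
#'
#' TSV of (codon, frequency).  Frequencies may be per-thousand (as in
#' standard usage tables; detected when they sum to roughly 1000) or
#' relative; both are rescaled to sum to 1.
#'
#' @param path input file.
#' @return named numeric over the 64 codons, summing to 1.
#' @export
readCodonUsage <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  if (is.na(suppressWarnings(as.numeric(df[1L, 2L]))))
    df <- df[-1L, , drop = FALSE]
  codons <- toupper(gsub("U", "T", as.character(df[[1L]])))
  bad <- setdiff(codons, .CODONS64)
  if (length(bad)) stop("not concrete codons: ", paste(bad, collapse = ", "))
  u <- setNames(as.numeric(df[[2L]]), codons)
  if (any(u < 0) || anyNA(u)) stop("usage values must be non-negative")
  full <- setNames(numeric(64), .CODONS64)
  full[names(u)] <- u
  full / sum(full)
}

#' Count oligonucleotides required by a vertical design
#'
#' A vertical scheme synthesizes one oligo per combination of codon
#' options; with `options` choices at each of `positions` mutagenized
#' sites it needs `options ^ positions` separate oligos — the
#' combinatorial cost a one-pot degenerate template avoids.
#'
#' @param options codon options per position.
#' @param positions number of mutagenized positions.
#' @return exact count; numeric when below 2^53, otherwise a decimal
#'   string.
#' @examples
#' verticalOligoCount(3, 3)  # 27
#' @export
verticalOligoCount <- function(options, positions) {
  stopifnot(options >= 1, positions >= 1)
  if (positions * log2(options) < 53) return(options^positions)
  .big_product(rep(options, positions))
}

#' Quantize spiked-codon fractions into a per-position ratio table
#'
#' @param M a [CodonMultiset-class] (or coercible).
#' @param quantizationStep resolution of the exported ratios (default
#'   0.01, i.e. 1%).  Blocks are re-normalized so quantized percentages
#'   sum to exactly 100; a step that would zero a support nucleotide is
#'   raised to one step (logged).
#' @return data.frame with columns position, T, C, A, G (percent).
#' @export
spikedRatioTable <- function(M, quantizationStep = 0.01) {
  fr <- .as_fractions_matrix(M)
  stopifnot(quantizationStep > 0, quantizationStep <= 0.25)
  steps <- round(1 / quantizationStep)
  out <- matrix(0, nrow = 3L * nrow(fr), ncol = 4L,
                dimnames = list(NULL, .NUC))
  for (i in seq_len(nrow(fr))) {
    for (p in 1:3) {
      f <- fr[i, (4L * p - 3L):(4L * p)]
      q <- round(f * steps)
      zeroed <- f > 0 & q == 0
      if (any(zeroed)) {
        q[zeroed] <- 1L
        message("quantization floor applied at codon ", i, " position ", p)
      }
      # repair the block sum without changing the support: with
      # steps >= 4 there is always an entry > 1 while the sum is high
      excess <- sum(q) - steps
      while (excess > 0) {
        j <- which(q > 1L)
        j <- j[which.max(q[j])]
        q[j] <- q[j] - 1L
        excess <- excess - 1L
      }
      while (excess < 0) {
        j <- which.max(f - q / steps)
        q[j] <- q[j] + 1L
        excess <- excess + 1L
      }
      out[3L * (i - 1L) + p, ] <- 100 * q / steps
    }
  }
  data.frame(position = seq_len(nrow(out)), out, check.names = FALSE)
}

#' Export a designed template
#'
#' Degenerate designs are written as a single FASTA record whose sequence
#' concatenates the codons' IUPAC triplets.  Spiked designs are written
#' as a per-position nucleotide ratio TSV (columns position, T, C, A, G
#' in percent, quantized via [spikedRatioTable()]).
#'
#' @param x a [DesignResult-class] or [CodonMultiset-class].
#' @param file output path.
#' @param quantizationStep spiked mode ratio resolution (default 1%).
#' @param shuffle randomly permute codon order before export (the encoded
#'   composition is order-invariant).
#' @param seed seed for the shuffle.
#' @return the output path, invisibly.
#' @export
exportTemplate <- function(x, file, quantizationStep = 0.01,
                           shuffle = FALSE, seed = NULL) {
  ms <- if (is(x, "DesignResult")) x@multiset else
    if (is(x, "CodonMultiset")) x else CodonMultiset(x)
  fr <- ms@fractions
  if (shuffle) {
    if (!is.null(seed)) set.seed(seed)
    fr <- fr[sample.int(nrow(fr)), , drop = FALSE]
  }
  if (ms@mode == "degenerate") {
    tmpl <- paste(toIUPAC((fr > 0) * 1L), collapse = "")
    x <- Biostrings::DNAStringSet(tmpl)
    names(x) <- sprintf("degenerate_template_%d_codons", nrow(fr))
    Biostrings::writeXStringSet(x, file)
  } else {
    tab <- spikedRatioTable(fr, quantizationStep)
    write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}

#' Parse a degenerate template string back into a codon multiset
#'
#' Inverse of the degenerate [exportTemplate()]: splits an IUPAC string
#' into triplets and rebuilds the equimolar multiset.
#'
#' @param x an IUPAC DNA string of length divisible by 3, or the path to
#'   a FASTA file holding one.
#' @return a [CodonMultiset-class] in degenerate mode.
#' @export
parseTemplate <- function(x) {
  if (file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    x <- as.character(ss[[1L]])
  }
  if (nchar(x) %% 3L != 0L)
    stop("template length must be divisible by 3")
  cods <- substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
  CodonMultiset(cods, mode = "degenerate")
}

#' Read a per-position nucleotide ratio table back into a codon multiset
#'
#' Inverse of the spiked [exportTemplate()]: a TSV with columns position,
#' T, C, A, G (percent per randomized nucleotide position, three rows per
#' codon) becomes a spiked [CodonMultiset-class].
#'
#' @param path ratio TSV path.
#' @return a [CodonMultiset-class] in spiked mode.
#' @export
readRatioTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("T", "C", "A", "G")
  if (!all(need %in% names(df)))
    stop("ratio table needs columns T, C, A, G")
  m <- as.matrix(df[, need]) / 100
  if (nrow(m) %% 3L != 0L)
    stop("ratio table must have three rows per codon")
  fr <- matrix(t(m), ncol = 12L, byrow = TRUE)
  colnames(fr) <- .TUPLE_NAMES
  CodonMultiset(fr, mode = "spiked")
}

#' Build a design report
#'
#' A machine-readable account of one design run: configuration echo,
#' pre-selection pool size, the template (IUPAC string and ratio table),
#' the achieved-vs-target composition on the 0-100% scale, distance
#' metrics and the per-replicate summary.  Regenerating the report from
#' the same configuration and seed reproduces it bit-identically.
#'
#' @param result a [DesignResult-class].
#' @return a nested list (serialize with [writeDesignReport()]).
#' @export
designReport <- function(result) {
  stopifnot(is(result, "DesignResult"))
  ms <- result@multiset
  tg <- result@target
  ach <- result@achieved
  diff <- ach - tg
  list(
    config = list(length = length(ms), mode = result@mode,
                  norm = result@norm, seed = result@seed,
                  replicates = nrow(result@replicateSummary),
                  poolSize = result@poolSize),
    template = list(iupac = iupacTemplate(ms),
                    codons = toIUPAC(codonSupport(ms)),
                    ratioTable = spikedRatioTable(ms)),
    composition = data.frame(symbol = names(tg),
                             target_pct = 100 * unname(tg),
                             achieved_pct = 100 * unname(ach),
                             deviation_pct = 100 * unname(diff)),
    distance = list(value = result@distance, norm = result@norm,
                    L2 = sqrt(sum(diff^2)),
                    sumSquared = sum(diff^2),
                    meanSquared = mean(diff^2),
                    L1 = sum(abs(diff))),
    acceptance = list(accepted = result@accepted,
                      rejected = result@rejected),
    replicates = result@replicateSummary)
}

#' @rdname designReport
#' @param file output JSON path.
#' @export
writeDesignReport <- function(result, file) {
  rep <- designReport(result)
  jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(file)
}

#' Run a full design from files to artifacts
#'
#' Programmatic equivalent of the `design` command-line call: reads the
#' target, runs the replicated optimization, and writes the template
#' (`template.fasta` or `ratios.tsv`) and `report.json` into `outDir`.
#'
#' @param targetFile path to a target distribution (TSV/JSON), or a named
#'   numeric vector of weights.
#' @param outDir output directory (created if missing).
#' @param codonUsageFile optional codon-usage TSV.
#' @param geneticCode translation-table id or TSV path (see
#'   [geneticCode()]), or a [GeneticCode-class].
#' @param ... remaining [designLibrary()] arguments (`length`, `mode`,
#'   `seed`, `replicates`, ...).
#' @inheritParams designLibrary
#' @return the [DesignResult-class], invisibly; artifacts on disk.
#' @export
runDesign <- function(targetFile, outDir, length,
                      mode = c("degenerate", "spiked"),
                      geneticCode = standardGeneticCode(),
                      codonUsageFile = NULL, minUsage = 0, ...) {
  mode <- match.arg(mode)
  code <- if (is(geneticCode, "GeneticCode")) geneticCode
          else geneticCode(geneticCode)
  target <- if (is.numeric(targetFile)) targetDistribution(targetFile, code)
            else readTargetDistribution(targetFile, code)
  usage <- if (!is.null(codonUsageFile)) readCodonUsage(codonUsageFile)
  res <- designLibrary(target, length = length, mode = mode, code = code,
                       codonUsage = usage, minUsage = minUsage, ...)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (mode == "degenerate")
    exportTemplate(res, file.path(outDir, "template.fasta"))
  else
    exportTemplate(res, file.path(outDir, "ratios.tsv"))
  writeDesignReport(res, file.path(outDir, "report.json"))
  message(sprintf("final %s distance: %.6g (template: %s)", res@norm,
                  res@distance, iupacTemplate(res@multiset)))
  invisible(res)
}

#' Validate a template by in-silico sampling
#'
#' Programmatic equivalent of the `validate` command-line call: samples
#' `n` sequences from a template, computes [compositionStats()],
#' [massDistribution()] (closed form) and [libraryDiversity()], and
#' optionally writes a JSON stats file and the position-frequency TSV.
#'
#' @param template an IUPAC template string, FASTA path, or
#'   [CodonMultiset-class]/[TemplateDesign-class].
#' @param n sample size.
#' @param target optional target distribution (named vector or file).
#' @param seed integer seed.
#' @param outDir optional output directory for `stats.json` and
#'   `position_freqs.tsv`.
#' @param code a [GeneticCode-class].
#' @return list with `stats` ([SampleStats-class]), `mass`, `diversity`.
#' @export
validateTemplate <- function(template, n = 10000, target = NULL,
                             seed = 1, outDir = NULL,
                             code = standardGeneticCode()) {
  design <- if (is.character(template) && length(template) == 1L &&
                file.exists(template)) {
    first <- readLines(template, n = 1L)
    if (grepl("\tT\tC\tA\tG", first, fixed = TRUE))
      .as_design(readRatioTable(template))
    else .as_design(parseTemplate(template))
  } else if (is.character(template) && length(template) == 1L &&
             !grepl("[^ACGTRYSWKMBDHVN]", template)) {
    .as_design(parseTemplate(template))
  } else .as_design(template)
  if (is.character(target) && length(target) == 1L && file.exists(target))
    target <- readTargetDistribution(target, code)
  seqs <- sampleSequences(design, n, seed = seed)
  stats <- compositionStats(seqs, target = target, code = code)
  mass <- massDistribution(design, mode = "closed_form", code = code)
  div <- libraryDiversity(design, nSample = min(n, 10000),
                          seed = seed, code = code)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    out <- list(n = stats@n, composition = as.list(stats@composition),
                deviation_pct = as.list(stats@deviationPct),
                distances = as.list(stats@distances),
                uniqueness_fraction = stats@uniquenessFraction,
                mass = mass, diversity = div)
    jsonlite::write_json(out, file.path(outDir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(stats@positionFreqs,
                file.path(outDir, "position_freqs.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
  }
  list(stats = stats, mass = mass, diversity = div)
}
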