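.new_code <- function(table, alphabet = NULL) {
  table <- table[.CODONS64]
  if (is.null(alphabet)) {
    extra <- setdiff(unique(table), .AA21)
    alphabet <- c(.AA21, extra)
  }
  new("GeneticCode", table = table, alphabet = alphabet)
}

#' The standard genetic code
#'
#' @return a [GeneticCode-class] with the standard table (stops TAA, TAG,
#'   TGA mapped to `"*"`) over the 21-symbol alphabet.
#' @examples
#' code <- standardGeneticCode()
#' codonTable(code)[c("ATG", "TAA")]
#' @export
standardGeneticCode <- function() {
  if (is.null(.pkg_cache$std_code)) {
    tab <- Biostrings::GENETIC_CODE
    .pkg_cache$std_code <- .new_code(setNames(as.character(tab), names(tab)),
                                     .AA21)
  }
  .pkg_cache$std_code
}

#' Build a genetic code from a translation-table id or a TSV file
#'
#' @param x an NCBI translation-table identifier (e.g. `1`, `"2"`, or a
#'   name understood by [Biostrings::getGeneticCode()]), or the path to a
#'   64-row TSV with columns codon and symbol (DNA alphabet, T not U).
#' @return a [GeneticCode-class].
#' @export
geneticCode <- function(x = 1L) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    df <- read.table(x, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(df) < 2L)
      stop("genetic-code TSV needs two columns: codon, symbol")
    if (!is.na(suppressWarnings(match("codon", tolower(df[1L, 1L])))))
      df <- df[-1L, , drop = FALSE]
    codons <- toupper(gsub("U", "T", df[[1L]]))
    if (anyDuplicated(codons) || !setequal(codons, .CODONS64))
      stop("genetic-code TSV must list each of the 64 codons exactly once")
    return(.new_code(setNames(as.character(df[[2L]]), codons)))
  }
  tab <- Biostrings::getGeneticCode(as.character(x))
  .new_code(setNames(as.character(tab), names(tab)))
}

#' Reassign codons to new symbols
#'
#' Replaces the symbol of selected codons, e.g. to model amber suppression
#' with an unnatural residue: `reassignCodons(code, c(TAG = "Uaa"))`.
#' New labels are appended to the alphabet.
#'
#' @param code a [GeneticCode-class].
#' @param reassignments named character vector, codon -> replacement symbol.
#' @return a new [GeneticCode-class].
#' @export
reassignCodons <- function(code, reassignments) {
  stopifnot(is(code, "GeneticCode"), is.character(reassignments))
  bad <- setdiff(names(reassignments), .CODONS64)
  if (length(bad))
    stop("not concrete codons: ", paste(bad, collapse = ", "))
  tab <- code@table
  tab[names(reassignments)] <- reassignments
  extra <- setdiff(unique(tab), code@alphabet)
  .new_code(tab, c(code@alphabet, extra))
}

#' @describeIn GeneticCode-class the codon -> symbol lookup vector.
#' @param code a `GeneticCode`.
#' @export
codonTable <- function(code) code@table

#' @describeIn GeneticCode-class the symbol alphabet (distribution index).
#' @export
codeAlphabet <- function(code) code@alphabet

#' @describeIn GeneticCode-class codons translating to `"*"`.
#' @export
stopCodons <- function(code) names(code@table)[code@table == "*"]

#' @rdname GeneticCode-class
#' @export
setMethod("show", "GeneticCode", function(object) {
  nstop <- sum(object@table == "*")
  cat("GeneticCode: 64 codons ->", length(object@alphabet),
      "symbols (", nstop, "stop codon(s) )\n")
})

# 0-based symbol index of each of the 64 codons, for the C++ core
.aa_index0 <- function(code) match(code@table, code@alphabet) - 1L
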