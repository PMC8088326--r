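# Molecular-weight accounting for designed libraries.

#' Residue mass table
#'
#' @param type `"average"` (default; matches linear-mode MALDI-TOF) or
#'   `"monoisotopic"`.
#' @return named numeric of the 20 residue masses (Da, amino acid minus
#'   water).
#' @export
residueMasses <- function(type = c("average", "monoisotopic")) {
  type <- match.arg(type)
  if (type == "average") .RESIDUE_MASS_AVG else .RESIDUE_MASS_MONO
}

#' Mass of a peptide from its residue string
#'
#' @param aa character vector of 1-letter residue strings (no `"*"`).
#' @param type `"average"` or `"monoisotopic"`.
#' @return numeric vector of masses in Da (residues + one water).
#' @export
peptideMass <- function(aa, type = c("average", "monoisotopic")) {
  type <- match.arg(type)
  m <- residueMasses(type)
  water <- if (type == "average") .WATER_AVG else .WATER_MONO
  vapply(strsplit(aa, ""), function(r) {
    if (!all(r %in% names(m)))
      stop("unknown residue(s): ",
           paste(setdiff(r, names(m)), collapse = ", "))
    sum(m[r]) + water
  }, 0)
}

#' Expected molecular-weight distribution of a designed library
#'
#' `mode = "sampled"` draws `n` sequences, translates them, drops
#' stop-containing ones (they would not yield the full-length tagged
#' protein) and reports the empirical mean and standard deviation of the
#' peptide masses.  `mode = "closed_form"` computes the exact mean and
#' standard deviation under per-position independence, conditioning each
#' codon's residue distribution on not being a stop — which matches the
#' stop-exclusion rule of the sampled mode exactly.  Constant protein
#' prefix/suffix residues of the design are included in both modes.
#'
#' @param design a [TemplateDesign-class] (or coercible; see
#'   [sampleSequences()]).
#' @param n sample size (sampled mode).
#' @param mode `"closed_form"` or `"sampled"`.
#' @param type mass table, `"average"` or `"monoisotopic"`.
#' @param seed optional integer seed (sampled mode).
#' @param code a [GeneticCode-class].
#' @return list with `mean`, `sd`, `mode`, and for the sampled mode
#'   `nUsed` and `nStopExcluded`; the closed form adds `stopFraction`,
#'   the probability that a random sequence contains at least one stop.
#' @export
massDistribution <- function(design, n = 10000,
                             mode = c("closed_form", "sampled"),
                             type = c("average", "monoisotopic"),
                             seed = NULL, code = standardGeneticCode()) {
  mode <- match.arg(mode)
  type <- match.arg(type)
  design <- .as_design(design)
  m <- residueMasses(type)
  water <- if (type == "average") .WATER_AVG else .WATER_MONO
  const_aa <- paste0(design@proteinPrefix, design@proteinSuffix)
  const_mass <- if (nzchar(const_aa))
    sum(m[strsplit(const_aa, "")[[1]]]) else 0

  if (mode == "sampled") {
    seqs <- sampleSequences(design, n, seed = seed)
    prot <- translateDNA(seqs, code)
    has_stop <- grepl("*", prot, fixed = TRUE)
    kept <- prot[!has_stop]
    if (!length(kept))
      stop("all sampled sequences contain a stop codon")
    masses <- peptideMass(kept, type) + const_mass
    return(list(mean = mean(masses),
                sd = if (length(masses) > 1L) sd(masses) else 0,
                mode = "sampled", nUsed = length(kept),
                nStopExcluded = sum(has_stop)))
  }

  fr <- codonFractions(.as_design(design)@codons)
  mass64 <- ifelse(code@table == "*", NA_real_, m[code@table])
  mu <- 0; v <- 0; p_no_stop <- 1
  for (i in seq_len(nrow(fr))) {
    d <- codonAADistribution(fr[i, ], code)
    p_stop <- if ("*" %in% names(d)) d[["*"]] else 0
    p_no_stop <- p_no_stop * (1 - p_stop)
    keep <- names(d) != "*" & d > 0
    if (!any(keep)) stop("a codon encodes only stops")
    pk <- d[keep] / sum(d[keep])
    mk <- m[names(pk)]
    if (anyNA(mk))
      stop("closed-form masses are undefined for non-canonical symbol(s): ",
           paste(names(pk)[is.na(mk)], collapse = ", "))
    mu_i <- sum(pk * mk)
    mu <- mu + mu_i
    v <- v + sum(pk * (mk - mu_i)^2)
  }
  list(mean = mu + const_mass + water, sd = sqrt(v),
       mode = "closed_form", stopFraction = 1 - p_no_stop)
}
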