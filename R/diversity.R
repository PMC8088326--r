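# Library diversity: exact DNA counts (arbitrary precision) and a
# collision-based protein diversity estimate.

# Minimal non-negative big integer arithmetic on base-1e4 digit vectors
# (least significant first); enough for products of per-position
# degeneracies (e.g. 64^33) without external dependencies.
.big_from_int <- function(x) {
  stopifnot(x >= 0)
  if (x == 0) return(0L)
  d <- integer(0)
  while (x > 0) { d <- c(d, as.integer(x %% 10000)); x <- x %/% 10000 }
  d
}

.big_mul_small <- function(d, k) {
  carry <- 0
  out <- integer(0)
  for (i in seq_along(d)) {
    p <- d[i] * k + carry
    out[i] <- p %% 10000
    carry <- p %/% 10000
  }
  while (carry > 0) { out <- c(out, carry %% 10000); carry <- carry %/% 10000 }
  as.integer(out)
}

.big_to_string <- function(d) {
  n <- length(d)
  paste0(d[n], paste(rev(sprintf("%04d", d[-n])), collapse = ""))
}

# exact product of a vector of small positive integers, as decimal string
.big_product <- function(xs) {
  d <- .big_from_int(1)
  for (x in xs) d <- .big_mul_small(d, as.integer(x))
  .big_to_string(d)
}

#' Diversity of a designed library
#'
#' The DNA diversity is the exact number of distinct DNA sequences the
#' randomized region can produce: the product of the per-position support
#' sizes, computed in arbitrary precision.  Protein diversity has no
#' closed form (synonymous codons collapse), so it is estimated by
#' birthday-collision counting on a seeded sample of translated
#' sequences: with `c` colliding pairs among `n` draws from `N`
#' near-uniform outcomes, `E[c] ~ n^2 / (2N)`, giving
#' `N_hat = choose(n, 2) / c`.
#'
#' @param design a [TemplateDesign-class] (or coercible).
#' @param nSample sample size for the protein-diversity estimate.
#' @param seed optional integer seed.
#' @param code a [GeneticCode-class].
#' @return list with `dnaDiversity` (exact decimal string),
#'   `dnaDiversityLog10`, `proteinDiversityEstimate` (`Inf` when the
#'   sample is collision-free, i.e. diversity exceeds what `nSample` can
#'   resolve), `sampledDistinct` and `nSample`.
#' @examples
#' libraryDiversity(c("NNK", "NNK"), nSample = 100)$dnaDiversity  # "1024"
#' @export
libraryDiversity <- function(design, nSample = 10000, seed = NULL,
                             code = standardGeneticCode()) {
  design <- .as_design(design)
  fr <- codonFractions(design@codons)
  support_sizes <- unlist(lapply(seq_len(nrow(fr)), function(i)
    vapply(1:3, function(p) sum(fr[i, (4 * p - 3):(4 * p)] > 0), 0L)))
  dna <- .big_product(support_sizes)
  log10dna <- sum(log10(support_sizes))

  seqs <- sampleSequences(design, nSample, seed = seed)
  prot <- translateDNA(seqs, code)
  counts <- table(prot)
  collisions <- sum(choose(as.numeric(counts), 2))
  est <- if (collisions == 0) Inf else choose(nSample, 2) / collisions
  list(dnaDiversity = dna, dnaDiversityLog10 = log10dna,
       proteinDiversityEstimate = est,
       sampledDistinct = length(counts), nSample = as.integer(nSample))
}
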