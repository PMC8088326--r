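# Library design: target handling, pool pre-selection, the distance
# objective, proposals, and the replicated stochastic search.

#' Coerce a target amino-acid composition to a full distribution vector
#'
#' @param x a named numeric vector of non-negative weights (1- or
#'   3-letter residue codes, `"*"` or `"Ter"` for STOP); symbols omitted
#'   get weight 0.  Weights are normalized to sum to 1.
#' @param code a [GeneticCode-class] fixing the alphabet and its order.
#' @return named numeric over `codeAlphabet(code)`, summing to 1.
#' @examples
#' targetDistribution(c(M = 1))
#' @export
targetDistribution <- function(x, code = standardGeneticCode()) {
  stopifnot(is.numeric(x))
  nm <- names(x)
  if (is.null(nm)) stop("target weights must be named by residue")
  three <- nm %in% names(.AA3TO1)
  nm[three] <- .AA3TO1[nm[three]]
  unknown <- setdiff(nm, code@alphabet)
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "))
  if (any(x < 0)) stop("target weights must be non-negative")
  if (anyDuplicated(nm)) stop("duplicated residue in target")
  out <- setNames(numeric(length(code@alphabet)), code@alphabet)
  out[nm] <- x
  s <- sum(out)
  if (s <= 0) stop("target weights are all zero")
  out / s
}

#' Distance between a target distribution and a codon multiset
#'
#' @param target named distribution (see [targetDistribution()]).
#' @param M a [CodonMultiset-class], fractions matrix or IUPAC vector.
#' @param norm `"L2"` (default; square root of the sum of squared
#'   differences), `"L1"` or `"Linf"`.
#' @param code a [GeneticCode-class].
#' @return non-negative scalar.
#' @export
distToTarget <- function(target, M, norm = c("L2", "L1", "Linf"),
                         code = standardGeneticCode()) {
  norm <- match.arg(norm)
  target <- targetDistribution(target, code)
  diff <- target - mixtureDistribution(M, code)
  switch(norm,
         L1 = sum(abs(diff)),
         L2 = sqrt(sum(diff^2)),
         Linf = max(abs(diff)))
}

#' Pre-select the base-codon pool for a design
#'
#' Restricts the 3375 base-codons by (i) user-forbidden concrete codons,
#' (ii) stop codons (on by default, so designs cannot encode premature
#' terminators), (iii) all codons of residues with zero target weight
#' (designs are composed only of input residues), (iv) codons below a
#' codon-usage threshold, and (v) a degeneracy cap.
#'
#' @param target named target weights (see [targetDistribution()]).
#' @param code a [GeneticCode-class].
#' @param forbidden concrete codons to exclude.
#' @param forbidStops forbid the code's stop codons (default TRUE).
#' @param codonUsage optional named numeric, codon -> relative usage (see
#'   [readCodonUsage()]); codons with usage below `minUsage` are forbidden.
#' @param minUsage usage threshold, same scale as `codonUsage`.
#' @param maxDegeneracy optional cap on concrete codons per base-codon.
#' @return integer base-codon matrix as from [enumerateBaseCodons()].
#' @export
preselectPool <- function(target, code = standardGeneticCode(),
                          forbidden = character(), forbidStops = TRUE,
                          codonUsage = NULL, minUsage = 0,
                          maxDegeneracy = NULL) {
  target <- targetDistribution(target, code)
  if (forbidStops) forbidden <- union(forbidden, stopCodons(code))
  zero <- names(target)[target == 0]
  forbidden <- union(forbidden, names(code@table)[code@table %in% zero])
  if (!is.null(codonUsage)) {
    rare <- names(codonUsage)[codonUsage < minUsage]
    forbidden <- union(forbidden, intersect(rare, .CODONS64))
  }
  allowed <- names(target)[target > 0]
  pool <- enumerateBaseCodons(forbidden = forbidden,
                              allowedSymbols = allowed, code = code,
                              maxDegeneracy = maxDegeneracy)
  message("pre-selected pool: ", nrow(pool), " of 3375 base-codons")
  pool
}

#' Propose a random codon from a pool
#'
#' Degenerate mode draws a uniformly random base-codon and returns its
#' equimolar fractions; spiked mode additionally draws the fractions of
#' each positional block from a flat Dirichlet over the support.
#'
#' @param pool base-codon matrix (rows = supports).
#' @param mode `"degenerate"` or `"spiked"`.
#' @return a fractional 12-tuple.
#' @export
proposeCodon <- function(pool, mode = c("degenerate", "spiked")) {
  mode <- match.arg(mode)
  if (!is.matrix(pool)) pool <- matrix(pool, nrow = 1L)
  if (nrow(pool) == 0L)
    stop("empty pool: the constraints admit no codon")
  b <- pool[sample.int(nrow(pool), 1L), ]
  if (mode == "degenerate") return(equimolarFractions(as.numeric(b)))
  f <- numeric(12)
  for (i in 1:3) {
    idx <- (4L * i - 3L):(4L * i)
    g <- ifelse(b[idx] > 0, stats::rexp(4), 0)
    f[idx] <- g / sum(g)
  }
  setNames(f, .TUPLE_NAMES)
}

#' Design a codon library matching a target amino-acid distribution
#'
#' Runs a stochastic local search over multisets of `length` codons.
#' The state is initialized with random proposals from the pre-selected
#' pool; each iteration replaces a uniformly random element with a fresh
#' random proposal and accepts the move iff the chosen norm of
#' target-minus-mixture strictly decreases.  The search stops after
#' `rejectionFactor * length` consecutive rejections.  With
#' `replicates > 1` the search is repeated with seeds
#' `seed, seed + 1, ...` and the best replicate (lowest final distance,
#' ties to the lowest index) is returned.
#'
#' @param target named target weights (see [targetDistribution()]).
#' @param length number of codons in the randomized region.
#' @param mode `"degenerate"` (equimolar codons) or `"spiked"`
#'   (arbitrary per-position nucleotide ratios).
#' @param norm distance norm, `"L2"` (default), `"L1"` or `"Linf"`.
#' @param rejectionFactor stop after `rejectionFactor * length`
#'   consecutive rejections (default 1000).
#' @param replicates number of independent seeded runs.
#' @param seed integer seed of the first replicate; drawn from the
#'   session RNG when `NULL`.
#' @param localPerturb spiked mode only: also propose in-place ratio
#'   shifts of one positional block of an existing codon (off by
#'   default; the default move set re-draws whole codons).
#' @param perturbProb probability of a ratio-shift move when
#'   `localPerturb` is on.
#' @inheritParams preselectPool
#' @return a [DesignResult-class].
#' @examples
#' res <- designLibrary(c(M = 1), length = 1, mode = "degenerate", seed = 1)
#' iupacTemplate(bestMultiset(res))   # "ATG"
#' @export
designLibrary <- function(target, length, mode = c("degenerate", "spiked"),
                          norm = c("L2", "L1", "Linf"),
                          code = standardGeneticCode(),
                          forbidden = character(), forbidStops = TRUE,
                          codonUsage = NULL, minUsage = 0,
                          maxDegeneracy = NULL, rejectionFactor = 1000,
                          replicates = 1, seed = NULL,
                          localPerturb = FALSE, perturbProb = 0.5) {
  mode <- match.arg(mode)
  norm <- match.arg(norm)
  stopifnot(length >= 1, rejectionFactor >= 1, replicates >= 1)
  target <- targetDistribution(target, code)
  pool <- preselectPool(target, code, forbidden, forbidStops,
                        codonUsage, minUsage, maxDegeneracy)
  if (nrow(pool) == 0L)
    stop("the constraints admit no codon: empty base-codon pool")
  poolDist <- .pool_distributions(pool, code)
  covered <- colSums(poolDist) > 0
  missing <- names(target)[target > 0 & !covered]
  if (length(missing))
    stop("no selectable codon encodes target residue(s): ",
         paste(missing, collapse = ", "))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - replicates, 1L)
  seed <- as.integer(seed)
  normCode <- match(norm, c("L1", "L2", "Linf"))

  reps <- vector("list", replicates)
  for (k in seq_len(replicates)) {
    set.seed(seed + k - 1L)
    reps[[k]] <- cpp_optimize(pool, poolDist, .aa_index0(code), target,
                              as.integer(length), mode == "spiked",
                              normCode, rejectionFactor * length,
                              localPerturb, perturbProb)
  }
  dists <- vapply(reps, `[[`, 0, "distance")
  best <- which.min(dists)                       # ties -> lowest index
  r <- reps[[best]]
  fr <- r$fractions
  colnames(fr) <- .TUPLE_NAMES
  ms <- new("CodonMultiset", fractions = fr, mode = mode)
  summary <- data.frame(
    replicate = seq_len(replicates),
    seed = seed + seq_len(replicates) - 1L,
    distance = dists,
    accepted = vapply(reps, `[[`, 0, "accepted"),
    rejected = vapply(reps, function(x) x$proposals - x$accepted, 0))
  new("DesignResult", multiset = ms, mode = mode, norm = norm,
      target = target, achieved = setNames(r$achieved, code@alphabet),
      distance = r$distance, trace = r$trace,
      accepted = as.integer(r$accepted),
      rejected = as.integer(r$proposals - r$accepted),
      seed = seed + best - 1L, replicateSummary = summary,
      poolSize = nrow(pool), geneticCode = code)
}

#' Benchmark design precision over distributions and lengths
#'
#' Runs [designLibrary()] for every (distribution, length) cell with
#' `replicates` independent seeded runs and returns a tidy table of
#' final distances.
#'
#' @param distributions named list of target weight vectors.
#' @param lengths integer vector of library lengths.
#' @param replicates seeded runs per cell.
#' @param mode,norm,seed,... passed to [designLibrary()]; replicate `k`
#'   of cell `j` uses seed `seed + (j - 1) * replicates + k - 1`.
#' @return data.frame with columns distribution, length, mode, replicate,
#'   seed, distance.
#' @seealso [summarizeBenchmark()]
#' @export
benchmarkDesign <- function(distributions, lengths, replicates = 10,
                            mode = c("degenerate", "spiked"),
                            norm = "L2", seed = 1, ...) {
  mode <- match.arg(mode)
  stopifnot(is.list(distributions), length(names(distributions)) > 0)
  grid <- expand.grid(length = as.integer(lengths),
                      distribution = names(distributions),
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (j in seq_len(nrow(grid))) {
    cell_seed <- seed + (j - 1L) * replicates
    res <- suppressMessages(designLibrary(
      distributions[[grid$distribution[j]]], grid$length[j], mode = mode,
      norm = norm, replicates = replicates, seed = cell_seed, ...))
    rs <- res@replicateSummary
    out[[j]] <- data.frame(distribution = grid$distribution[j],
                           length = grid$length[j], mode = mode,
                           replicate = rs$replicate, seed = rs$seed,
                           distance = rs$distance)
  }
  do.call(rbind, out)
}

#' Summarize a benchmark table
#'
#' @param bench output of [benchmarkDesign()].
#' @return data.frame with per-cell mean distance, best distance and
#'   coefficient of variation of the final distances.
#' @export
summarizeBenchmark <- function(bench) {
  agg <- aggregate(distance ~ distribution + length + mode, data = bench,
                   FUN = function(x) c(mean = mean(x), best = min(x),
                                       cv = stats::sd(x) / mean(x)))
  cbind(agg[c("distribution", "length", "mode")],
        as.data.frame(agg$distance))
}
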