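test_that("distance to target follows the chosen norm", {
  # perfect match is zero under every norm
  for (nrm in c("L1", "L2", "Linf"))
    expect_equal(distToTarget(c(M = 0.5, W = 0.5), c("ATG", "TGG"),
                              norm = nrm), 0)
  # uniform-20 target vs a single ATG codon: direct arithmetic
  expect_equal(distToTarget(uniform20, "ATG", norm = "L2"),
               sqrt(0.95^2 + 19 * 0.05^2))
  expect_equal(distToTarget(uniform20, "ATG", norm = "L1"),
               0.95 + 19 * 0.05)
  expect_equal(distToTarget(uniform20, "ATG", norm = "Linf"), 0.95)
  # norm ordering on random spiked multisets
  set.seed(7)
  pool <- enumerateBaseCodons()
  for (rep in 1:10) {
    fr <- t(vapply(1:4, function(i) proposeCodon(pool, "spiked"),
                   numeric(12)))
    tg <- targetDistribution(setNames(runif(20), names(uniform20)))
    linf <- distToTarget(tg, fr, "Linf")
    l2 <- distToTarget(tg, fr, "L2")
    l1 <- distToTarget(tg, fr, "L1")
    expect_true(linf <= l2 + 1e-12 && l2 <= l1 + 1e-12)
  }
})

test_that("proposals are equimolar in degenerate mode and flat-Dirichlet in spiked", {
  atg <- matrix(fromIUPAC("ATG"), nrow = 1)
  set.seed(1)
  expect_equal(unname(proposeCodon(atg, "degenerate")),
               unname(equimolarFractions("ATG")))
  # degenerate blocks are equimolar over their support
  set.seed(2)
  pool <- enumerateBaseCodons()
  for (rep in 1:20) {
    f <- proposeCodon(pool, "degenerate")
    for (i in 1:3) {
      blk <- f[(4 * i - 3):(4 * i)]
      sup <- blk[blk > 0]
      expect_equal(unname(sup), rep(1 / length(sup), length(sup)))
    }
  }
  # spiked over NNS: Monte-Carlo means match the flat Dirichlet
  set.seed(3)
  nns <- matrix(fromIUPAC("NNS"), nrow = 1)
  draws <- t(vapply(1:10000, function(i) proposeCodon(nns, "spiked"),
                    numeric(12)))
  mns <- colMeans(draws)
  se4 <- sqrt(3 / 80) / sqrt(10000)   # Dirichlet(1,1,1,1) component sd
  se2 <- sqrt(1 / 12) / sqrt(10000)   # Dirichlet(1,1) component sd
  expect_true(all(abs(mns[1:8] - 0.25) < 3 * se4))
  expect_equal(unname(mns[c(9, 11)]), c(0, 0))
  expect_true(all(abs(mns[c(10, 12)] - 0.5) < 3 * se2))
  expect_error(proposeCodon(matrix(0, 0, 12), "degenerate"), "empty pool")
})

test_that("pool pre-selection restricts to encodable, permitted codons", {
  all21 <- c(uniform20, "*" = 1)
  expect_equal(nrow(suppressMessages(
    preselectPool(all21, forbidStops = FALSE))), 3375L)
  # zero-weight residues are forbidden at the codon level even without
  # the stop filter
  expect_lt(nrow(suppressMessages(
    preselectPool(uniform20, forbidStops = FALSE))), 3375L)
  metpool <- suppressMessages(preselectPool(c(M = 1)))
  expect_equal(rownames(metpool), "ATG")
  # early-alphabet pool vs exhaustive filter oracle
  B <- enumerateBaseCodons()
  tab <- codonTable(standardGeneticCode())
  allowed <- names(early10)
  keep <- vapply(seq_len(nrow(B)), function(i)
    all(tab[brute_expand(B[i, ])] %in% allowed), NA)
  pool <- suppressMessages(preselectPool(early10))
  expect_equal(nrow(pool), sum(keep))
  # codon-usage threshold forbids rare codons
  usage <- setNames(rep(1 / 64, 64), degenDesign:::.CODONS64)
  usage["ATG"] <- 0
  pool2 <- suppressMessages(
    preselectPool(c(M = 1, W = 1), codonUsage = usage, minUsage = 1e-3))
  expect_equal(rownames(pool2), "TGG")
})

test_that("trivial designs find the unique optimum", {
  res <- suppressMessages(
    designLibrary(c(M = 1), length = 1, mode = "degenerate", seed = 1))
  expect_equal(iupacTemplate(bestMultiset(res)), "ATG")
  expect_equal(designDistance(res), 0)
  expect_error(suppressWarnings(suppressMessages(
    designLibrary(c(M = 1), length = 1, forbidden = "ATG", seed = 1))),
    "empty|no selectable")
})

test_that("small-instance search attains the exhaustive optimum in >= 9/10 seeds", {
  # restrict to a pool of <= 10 supports via a three-residue target
  target <- c(M = 0.4, W = 0.35, F = 0.25)
  pool <- suppressMessages(preselectPool(target))
  expect_lte(nrow(pool), 10)
  best <- brute_best_distance(pool, target, size = 2)
  hits <- 0L
  for (s in 1:10) {
    r <- suppressMessages(designLibrary(target, length = 2,
                                        mode = "degenerate", seed = s))
    if (designDistance(r) <= best + 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("objective traces are non-increasing and distances recompute exactly", {
  r <- suppressMessages(designLibrary(early10, length = 8, mode = "spiked",
                                      seed = 11))
  tr <- distanceTrace(r)
  expect_true(all(diff(tr) <= 0))
  expect_equal(tr[length(tr)], designDistance(r))
  # distance recomputed from scratch through the R-side codon algebra
  expect_equal(distToTarget(r@target, bestMultiset(r), norm = "L2"),
               designDistance(r), tolerance = 1e-12)
  # achieved distribution is a valid mixture
  expect_equal(sum(achievedDistribution(r)), 1, tolerance = 1e-9)
  expect_equal(unname(achievedDistribution(r)),
               unname(mixtureDistribution(bestMultiset(r))),
               tolerance = 1e-12)
})

test_that("no forbidden codon is producible from any designed multiset", {
  forb <- c("TAA", "TAG", "TGA", "GCC", "CCC")
  r <- suppressMessages(designLibrary(uniform20, length = 6,
                                      mode = "degenerate",
                                      forbidden = c("GCC", "CCC"), seed = 5))
  ex <- excludesCodon(codonSupport(bestMultiset(r)), forb)
  expect_true(all(ex))
  r2 <- suppressMessages(designLibrary(early10, length = 6, mode = "spiked",
                                       seed = 6))
  expect_true(all(excludesCodon(codonFractions(bestMultiset(r2)),
                                c("TAA", "TAG", "TGA"))))
})

test_that("identical configuration and seed reproduce the result bit for bit", {
  a <- suppressMessages(designLibrary(early10, length = 5, mode = "spiked",
                                      replicates = 2, seed = 123))
  b <- suppressMessages(designLibrary(early10, length = 5, mode = "spiked",
                                      replicates = 2, seed = 123))
  expect_identical(codonFractions(bestMultiset(a)),
                   codonFractions(bestMultiset(b)))
  expect_identical(distanceTrace(a), distanceTrace(b))
  expect_identical(a@replicateSummary, b@replicateSummary)
})

test_that("spiked mode is at least as precise as degenerate on average", {
  ds <- dd <- numeric(10)
  for (s in 1:10) {
    ds[s] <- designDistance(suppressMessages(
      designLibrary(early10, 10, mode = "spiked", seed = 100 + s)))
    dd[s] <- designDistance(suppressMessages(
      designLibrary(early10, 10, mode = "degenerate", seed = 100 + s)))
  }
  expect_lte(mean(ds), mean(dd))
})

test_that("benchmark grids are tidy and summarize per cell", {
  bench <- benchmarkDesign(list(early = early10), lengths = c(5, 10),
                           replicates = 2, mode = "degenerate", seed = 1)
  expect_equal(nrow(bench), 4L)
  expect_named(bench, c("distribution", "length", "mode", "replicate",
                        "seed", "distance"))
  expect_false(anyDuplicated(bench$seed) > 0)
  smry <- summarizeBenchmark(bench)
  expect_equal(nrow(smry), 2L)
  expect_true(all(c("mean", "best", "cv") %in% names(smry)))
  # replicates = 1 reduces to one optimize call per cell
  one <- benchmarkDesign(list(early = early10), lengths = 5,
                         replicates = 1, mode = "degenerate", seed = 3)
  expect_equal(nrow(one), 1L)
})
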