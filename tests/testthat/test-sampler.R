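test_that("sampling respects fixed codons and constant flanks", {
  expect_equal(sampleSequences(c("ATG", "ATG"), n = 5),
               rep("ATGATG", 5))
  des <- TemplateDesign(c("ATG"), fivePrime = "GGG", threePrime = "TT")
  expect_equal(sampleSequences(des, 2, includeConstant = TRUE),
               rep("GGGATGTT", 2))
  expect_error(TemplateDesign("ATG", fivePrime = "GGN"), "only T,C,A,G")
})

test_that("stop-codon incidence matches the closed form for NNN repeats", {
  n <- 50000
  seqs <- sampleSequences(rep("NNN", 10), n = n, seed = 42)
  prot <- translateDNA(seqs)
  p_hat <- mean(grepl("*", prot, fixed = TRUE))
  p <- 1 - (61 / 64)^10
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("per-position nucleotide frequencies converge to the design fractions", {
  n <- 100000
  seqs <- sampleSequences("NNK", n = n, seed = 7)
  st <- compositionStats(seqs)
  pf <- positionFrequencies(st)
  expect_equal(dim(pf), c(4L, 3L))
  expect_equal(unname(colSums(pf)), rep(1, 3))
  design <- matrix(equimolarFractions("NNK"), nrow = 3, byrow = TRUE,
                   dimnames = list(NULL, c("T", "C", "A", "G")))
  expect_lt(max(abs(pf - t(design))), 0.01)
})

test_that("translation follows the genetic code and matches Biostrings", {
  expect_equal(translateDNA("ATGTGG"), "MW")
  expect_equal(translateDNA("ATGTAA"), "M*")
  expect_error(translateDNA("ATGT"), "divisible")
  expect_error(translateDNA("ATGNNN"), "ambiguity")
  set.seed(9)
  seqs <- sampleSequences(rep("NNN", 7), n = 50)
  ours <- translateDNA(seqs)
  ref <- as.character(Biostrings::translate(Biostrings::DNAStringSet(seqs),
                                            no.init.codon = TRUE))
  expect_equal(ours, unname(ref))
})

test_that("sampled composition converges to the design mixture", {
  n <- 100000
  seqs <- sampleSequences("NNK", n = n, seed = 13)
  st <- compositionStats(seqs, target = NULL)
  exact <- codonAADistribution("NNK")
  bound <- 3 * sqrt(exact * (1 - exact) / n)
  expect_true(all(abs(sampleComposition(st) - exact) <=
                    pmax(bound, 1e-12)))
})

test_that("composition statistics report deviations and uniqueness", {
  st <- compositionStats(rep("ATG", 50), target = c(M = 1))
  expect_equal(unname(st@distances["L2"]), 0)
  expect_equal(unname(st@deviationPct), rep(0, 21))
  expect_equal(uniquenessFraction(st), 1 / 50)
  # a high-diversity design yields almost entirely unique sequences
  seqs <- sampleSequences(rep("NNK", 33), n = 20000, seed = 3)
  st2 <- compositionStats(seqs)
  expect_gt(uniquenessFraction(st2), 0.999)
  # self-consistency: sampled deviation close to the design's own distance
  r <- suppressMessages(designLibrary(early10, 6, mode = "spiked", seed = 2))
  seqs3 <- sampleSequences(bestMultiset(r), n = 100000, seed = 4)
  st3 <- compositionStats(seqs3, target = early10)
  expect_lt(abs(st3@distances[["L2"]] - designDistance(r)), 0.005)
})

test_that("closed-form and sampled mass distributions agree", {
  # fixed single-sequence design: sd 0, mean = residue masses + water
  fixed <- massDistribution(c("ATG", "TGG"), mode = "closed_form")
  expect_equal(fixed$sd, 0)
  expect_equal(fixed$mean, peptideMass("MW"))
  samp0 <- massDistribution(c("ATG", "TGG"), n = 10, mode = "sampled",
                            seed = 1)
  expect_equal(samp0$mean, fixed$mean)
  expect_equal(samp0$sd, 0)

  cf <- massDistribution(rep("NNK", 10), mode = "closed_form")
  sm <- massDistribution(rep("NNK", 10), n = 20000, mode = "sampled",
                         seed = 5)
  expect_lt(abs(sm$mean - cf$mean), 3 * sm$sd / sqrt(sm$nUsed))
  expect_equal(sm$sd, cf$sd, tolerance = 0.05)
  # sampled mode counts its stop exclusions
  expect_equal(sm$nUsed + sm$nStopExcluded, 20000)
  expect_equal(cf$stopFraction, 1 - (31 / 32)^10)

  # doubling the randomized region doubles its closed-form mass share
  m1 <- massDistribution(rep("NNK", 5), mode = "closed_form")
  m2 <- massDistribution(rep("NNK", 10), mode = "closed_form")
  w <- degenDesign:::.WATER_AVG
  expect_equal(m2$mean - w, 2 * (m1$mean - w), tolerance = 1e-9)

  # constant protein context shifts the mean by its residue mass
  tagged <- TemplateDesign(rep("NNK", 5), proteinSuffix = "KSHHHHHHHHQH")
  mt <- massDistribution(tagged, mode = "closed_form")
  expect_equal(mt$mean - m1$mean,
               sum(residueMasses()[strsplit("KSHHHHHHHHQH", "")[[1]]]))
})

test_that("library diversity counts DNA variants exactly and estimates protein variants", {
  expect_equal(libraryDiversity(c("ATG", "ATG"), nSample = 10,
                                seed = 1)$dnaDiversity, "1")
  expect_equal(libraryDiversity(c("NNK", "NNK"), nSample = 100,
                                seed = 1)$dnaDiversity, "1024")
  # big-integer contract: 64^33 without overflow (reference value from
  # exact integer arithmetic)
  div <- libraryDiversity(rep("NNN", 33), nSample = 200, seed = 2)
  expect_equal(div$dnaDiversity, format(2^198, scientific = FALSE))
  expect_equal(nchar(div$dnaDiversity), 60L)
  expect_equal(div$dnaDiversityLog10, 33 * log10(64))
  # low-diversity design: collision estimate close to the truth (16 codons)
  est <- libraryDiversity("RYK", nSample = 5000, seed = 3)
  expect_lt(abs(est$proteinDiversityEstimate -
                  length(unique(translateDNA(expandCodon("RYK"))))), 2)
})

test_that("sequence sets round-trip through FASTA and FASTQ", {
  seqs <- sampleSequences(rep("NNK", 4), n = 6, seed = 8)
  fa <- tempfile(fileext = ".fasta")
  writeSequences(seqs, fa)
  back <- as.character(Biostrings::readDNAStringSet(fa))
  expect_equal(unname(back), seqs)
  fq <- tempfile(fileext = ".fastq")
  writeSequences(seqs, fq, format = "fastq")
  backq <- as.character(Biostrings::readDNAStringSet(fq, format = "fastq"))
  expect_equal(unname(backq), seqs)
})
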