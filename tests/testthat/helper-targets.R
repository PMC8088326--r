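# Shared targets and small independent oracles used across test files.

early10 <- c(A = 1, S = 1, D = 1, G = 1, L = 1, E = 1, T = 1, I = 1,
             P = 1, V = 1)

uniform20 <- setNames(rep(1, 20),
                      c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))

# brute-force expansion of a base-codon tuple, written independently of
# the package's kronecker-based expandCodon()
brute_expand <- function(bits) {
  nuc <- c("T", "C", "A", "G")
  out <- character(0)
  for (i in which(bits[1:4] > 0))
    for (j in which(bits[5:8] > 0))
      for (k in which(bits[9:12] > 0))
        out <- c(out, paste0(nuc[i], nuc[j], nuc[k]))
  out
}

# exhaustive search over all multisets of a given size from a degenerate
# pool; returns the minimal L2 distance to the target
brute_best_distance <- function(pool, target, size,
                                code = standardGeneticCode()) {
  # all multisets with replacement
  combos <- expand.grid(rep(list(seq_len(nrow(pool))), size))
  combos <- combos[!duplicated(t(apply(combos, 1, sort))), , drop = FALSE]
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    fr <- t(vapply(unlist(combos[r, ]), function(i)
      equimolarFractions(as.numeric(pool[i, ])), numeric(12)))
    d <- distToTarget(target, fr, norm = "L2", code = code)
    if (d < best) best <- d
  }
  best
}
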