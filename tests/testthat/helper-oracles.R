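# Independent brute-force oracles used to check the package's closed-form
# implementations.  These deliberately take different computational routes
# (pair enumeration, ANOVA, 2x2 table counting) from the code under test.

# Hudson FST from the heterozygosity definition (1 - Hw/Hb) with unbiased
# within-population heterozygosity, computed from allele counts.
hudsonOracle <- function(k1, n1, k2, n2) {
  hw1 <- 2 * k1 * (n1 - k1) / (n1 * (n1 - 1))
  hw2 <- 2 * k2 * (n2 - k2) / (n2 * (n2 - 1))
  hb <- (k1 * (n2 - k2) + k2 * (n1 - k1)) / (n1 * n2)
  list(num = hb - (hw1 + hw2) / 2, den = hb)
}

# Weir-Cockerham haploid theta via one-way ANOVA mean squares on the 0/1
# allele indicators (lm/anova route, independent of the closed form).
wcOracle <- function(k1, n1, k2, n2) {
  y <- c(rep(1, k1), rep(0, n1 - k1), rep(1, k2), rep(0, n2 - k2))
  g <- factor(c(rep("a", n1), rep("b", n2)))
  av <- suppressWarnings(anova(stats::lm(y ~ g)))
  msp <- av$`Mean Sq`[1]
  msg <- av$`Mean Sq`[2]
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2))
  (msp - msg) / (msp + (nc - 1) * msg)
}

# EHH by exhaustive pair enumeration: fraction of carrier pairs identical
# over every site from the core to marker x inclusive.
ehhOracle <- function(m, core, x, allele) {
  rows <- which(m[, core] == allele)
  span <- min(core, x):max(core, x)
  pairs <- utils::combn(rows, 2)
  mean(apply(pairs, 2, function(pr)
    all(m[pr[1], span] == m[pr[2], span])))
}

# r^2 and D' from the four phased haplotype-class counts.
ldOracle <- function(hapA, hapB) {
  n <- length(hapA)
  pAB <- mean(hapA == 1 & hapB == 1)
  pA <- mean(hapA); pB <- mean(hapB)
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D, r2 = r2, dprime = if (dmax > 0) abs(D) / dmax else 0)
}

# Nucleotide diversity by exhaustive pairwise difference counting.
piOracle <- function(m, win_len) {
  n <- nrow(m)
  pairs <- utils::combn(n, 2)
  diffs <- apply(pairs, 2, function(pr) sum(m[pr[1], ] != m[pr[2], ]))
  mean(diffs) / win_len
}

# Sliding-window start enumeration by explicit loop.
windowCountOracle <- function(L, size, step) {
  n <- 0; s <- 0
  while (s + size <= L) { n <- n + 1; s <- s + step }
  n
}

# Small deterministic panel builder for unit tests.
makeTestPanel <- function(m, positions = NULL, pops = NULL,
                          ancestral = NULL, chrom = "1") {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  nh <- nrow(m)
  stopifnot(nh %% 2 == 0)
  if (is.null(positions)) positions <- seq_len(ncol(m)) * 1000L
  if (is.null(pops)) pops <- rep("pop1", nh / 2)
  ids <- paste0("s", seq_len(nh / 2))
  HaplotypePanel(chrom = chrom, positions = positions, haplotypes = m,
                 sampleIds = ids, popOf = stats::setNames(pops, ids),
                 ancestral = if (is.null(ancestral))
                   rep(0L, ncol(m)) else as.integer(ancestral))
}

# Random panel generator for property tests.
randomPanel <- function(n_hap = 8, n_site = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_hap * n_site, 1, runif(1, 0.2, 0.8)),
                nrow = n_hap)
    p <- colMeans(m)
    if (all(p > 0 & p < 1)) break
  }
  makeTestPanel(m, positions = sort(sample.int(1e6, n_site)))
}
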