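## Per-site and windowed FST (Hudson and Weir-Cockerham haploid forms), the
## PBS transform, and windowed nucleotide diversity.

pop_counts <- function(panel, pop) {
  rows <- which(hapPopulations(panel) == pop)
  if (!length(rows)) stop("unknown population: ", pop)
  m <- panel@haplotypes[rows, , drop = FALSE]
  list(n = nrow(m), p = colMeans(m))
}

#' Per-site FST between two populations
#'
#' Hudson estimator (Bhatia et al. form):
#' numerator \code{(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)},
#' denominator \code{p1(1-p2) + p2(1-p1)}.
#' Weir-Cockerham: 1984 variance components in the two-population haploid
#' form, numerator = between-population component a, denominator = a + b.
#' Per-site ratios are reported unclamped; sites monomorphic across both
#' populations are excluded.
#'
#' @param panel a [HaplotypePanel-class] containing both populations.
#' @param popA,popB population labels.
#' @param estimator \code{"wc"} (default, mirroring vcftools) or
#'   \code{"hudson"}.
#' @return data.frame: position, p1, p2, n1, n2, num, den, fst
#'   (\code{NA} where den = 0).
#' @export
fstSites <- function(panel, popA, popB, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  a <- pop_counts(panel, popA); b <- pop_counts(panel, popB)
  stopifnot(a$n >= 2, b$n >= 2)
  p1 <- a$p; p2 <- b$p; n1 <- a$n; n2 <- b$n
  poly <- !(p1 %in% c(0, 1) & p2 %in% c(0, 1) & p1 == p2)
  p1 <- p1[poly]; p2 <- p2[poly]
  if (estimator == "hudson") {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
  } else {
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
    msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 - 1 + n2 - 1)
    num <- msp - msg            # a-hat, up to the common 1/nc scale
    den <- msp + (nc - 1) * msg
  }
  data.frame(position = sitePositions(panel)[poly],
             p1 = p1, p2 = p2, n1 = n1, n2 = n2,
             num = num, den = den,
             fst = ifelse(den > 0, num / den, NA_real_))
}

#' Windowed FST as a ratio of sums
#'
#' Weighted ("ratio of averages") windowed estimate: sum of per-site
#' numerators over sum of denominators within each window; windows without
#' sites give \code{NA}.
#'
#' @param sites data.frame from [fstSites()].
#' @param windows \code{GRanges} windows ([makeWindows()]).
#' @param chrom chromosome of the sites.
#' @return data.frame: chrom, start, end (0-based half-open), n_snps, fst.
#' @export
fstWindows <- function(sites, windows, chrom = "1") {
  bed <- bedBounds(windows)
  idx <- sitesInWindows(sites$position, windows, chrom)
  agg <- vapply(idx, function(i) {
    if (!length(i)) return(c(0, NA_real_))
    den <- sum(sites$den[i])
    c(length(i), if (den > 0) sum(sites$num[i]) / den else NA_real_)
  }, numeric(2))
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             n_snps = as.integer(agg[1, ]), fst = agg[2, ])
}

#' Population branch statistic
#'
#' Each FST is clamped to \code{[0, 1 - 1e-9]} and transformed to a branch
#' length \code{T = -ln(1 - FST)}; the focal branch is
#' \code{(T_S_L1 + T_S_L2 - T_L1_L2) / 2}.  May be negative.
#'
#' @param fst_S_L1,fst_S_L2 FST of the focal population against the two
#'   others.
#' @param fst_L1_L2 FST between the two non-focal populations.
#' @return PBS value(s); vectorized.
#' @export
pbs <- function(fst_S_L1, fst_S_L2, fst_L1_L2) {
  tr <- function(f) -log(1 - pmin(pmax(f, 0), 1 - 1e-9))
  (tr(fst_S_L1) + tr(fst_S_L2) - tr(fst_L1_L2)) / 2
}

#' Windowed PBS for a focal population
#'
#' Computes windowed FST (ratio of sums) for the three population pairs and
#' applies [pbs()] per window.  In pipeline mode the windows are the 10 kb /
#' 5 kb grid restricted to candidate regions; a genome-wide run just passes
#' genome-wide windows.
#'
#' @param panel panel containing all three populations.
#' @param focal,low1,low2 population labels (focal branch, comparator,
#'   outgroup).
#' @param windows \code{GRanges} windows.
#' @param estimator FST estimator (see [fstSites()]).
#' @return data.frame: chrom, start, end, n_snps (focal/low1 pair),
#'   fst_S_L1, fst_S_L2, fst_L1_L2, T_S_L1, T_S_L2, T_L1_L2, pbs.
#' @export
pbsWindows <- function(panel, focal, low1, low2, windows,
                       estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  chrom <- chromName(panel)
  w1 <- fstWindows(fstSites(panel, focal, low1, estimator), windows, chrom)
  w2 <- fstWindows(fstSites(panel, focal, low2, estimator), windows, chrom)
  w3 <- fstWindows(fstSites(panel, low1, low2, estimator), windows, chrom)
  tr <- function(f) -log(1 - pmin(pmax(f, 0), 1 - 1e-9))
  out <- data.frame(chrom = w1$chrom, start = w1$start, end = w1$end,
                    n_snps = w1$n_snps,
                    fst_S_L1 = w1$fst, fst_S_L2 = w2$fst, fst_L1_L2 = w3$fst)
  out$T_S_L1 <- tr(out$fst_S_L1)
  out$T_S_L2 <- tr(out$fst_S_L2)
  out$T_L1_L2 <- tr(out$fst_L1_L2)
  out$pbs <- pbs(out$fst_S_L1, out$fst_S_L2, out$fst_L1_L2)
  out
}

#' Windowed nucleotide diversity
#'
#' Per site the unbiased heterozygosity \code{2 p (1-p) n / (n-1)}; the
#' window value is the sum over contained sites divided by the window
#' length in bp (invariant positions contribute zero through the
#' denominator), matching the per-bp windowed pi of vcftools.
#'
#' @param panel a [HaplotypePanel-class].
#' @param pop population label (needs >= 2 haplotypes).
#' @param windows \code{GRanges} windows (default 10 kb / 5 kb step over
#'   the data span).
#' @return data.frame: chrom, start, end, n_snps, pi.
#' @export
piWindows <- function(panel, pop, windows = NULL) {
  pc <- pop_counts(panel, pop)
  if (pc$n < 2) stop("population ", pop, " has fewer than 2 haplotypes")
  if (is.null(windows))
    windows <- makeWindows(max(sitePositions(panel)), size = 1e4, step = 5e3,
                           chrom = chromName(panel))
  h <- 2 * pc$p * (1 - pc$p) * pc$n / (pc$n - 1)
  bed <- bedBounds(windows)
  idx <- sitesInWindows(sitePositions(panel), windows, chromName(panel))
  len <- bed$end - bed$start
  pi_val <- vapply(seq_along(idx), function(w) sum(h[idx[[w]]]) / len[w],
                   numeric(1))
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             n_snps = vapply(idx, length, integer(1)), pi = pi_val)
}

#' Write vcftools-style windowed TSVs
#'
#' Column layouts mirror the vcftools windowed outputs (1-based BIN_START).
#'
#' @param wins data.frame from [fstWindows()] / [piWindows()].
#' @param path output path.
#' @param what \code{"fst"} or \code{"pi"}.
#' @export
writeWindowTsv <- function(wins, path, what = c("fst", "pi")) {
  what <- match.arg(what)
  df <- data.frame(CHROM = wins$chrom, BIN_START = wins$start + 1L,
                   BIN_END = wins$end, N_VARIANTS = wins$n_snps)
  df[[if (what == "fst") "WEIGHTED_FST" else "PI"]] <-
    if (what == "fst") wins$fst else wins$pi
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
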