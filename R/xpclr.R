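## Cross-population composite likelihood ratio (XP-CLR) sweep scan.
##
## Model: per site, the object-population derived count k of n is binomial
## with frequency p2 drawn from a drift distribution around the reference
## frequency p1 -- Normal(p1, omega * p1(1-p1)) truncated to [0,1] with the
## escaped mass as point masses at the boundaries.  Under a sweep with
## escape probability c at distance d from the putative sweep site, a
## lineage escapes (prob c) and keeps its pre-sweep frequency, or derives
## from the single swept background (prob 1-c), whose allele is derived
## with probability p2; so given pre-sweep p2 the post-sweep sampling
## frequency is c*p2 + (1-c) with probability p2 and c*p2 with probability
## 1-p2.  c(d) = 1 - (2N s)^(-r d / s) with a fixed recombination map.
## The window score is 2 * (max over the s-grid of the composite sweep
## log-likelihood - the neutral composite log-likelihood); at c = 1 the
## sweep model reduces exactly to the neutral one, so scores are >= 0 up to
## optimization tolerance.

QUAD_N <- 512L

drift_weights <- function(p1, omega, nq = QUAD_N) {
  # midpoint grid on (0,1) plus boundary point masses; rows = sites
  x <- (seq_len(nq) - 0.5) / nq
  sigma <- sqrt(omega * p1 * (1 - p1))
  W <- t(vapply(seq_along(p1), function(i) {
    stats::dnorm(x, p1[i], sigma[i]) / nq
  }, numeric(nq)))
  m0 <- stats::pnorm(0, p1, sigma)
  m1 <- stats::pnorm(1, p1, sigma, lower.tail = FALSE)
  # renormalize the interior weights to the non-escaped mass so the site
  # distribution is proper even when sigma is near the grid resolution
  rs <- rowSums(W)
  scale <- ifelse(rs > 0, (1 - m0 - m1) / rs, 0)
  W <- W * scale
  list(x = x, W = W, m0 = m0, m1 = m1)
}

#' Method-of-moments drift variance between two panels
#'
#' Estimates the genome-wide drift scale omega relating object-population
#' allele frequencies to reference-population frequencies:
#' the average over sites of
#' \code{((p1-p2)^2 - p1(1-p1)/n1 - p2(1-p2)/n2) / (p1(1-p1))},
#' floored at a small positive constant.  Sites monomorphic in the
#' reference are excluded.
#'
#' @param panelRef,panelObj [HaplotypePanel-class] objects on the same
#'   sites (reference and object populations).
#' @param floor lower bound for the estimate (default 1e-4).
#' @return omega (dimensionless).
#' @export
estimateOmega <- function(panelRef, panelObj, floor = 1e-4) {
  stopifnot(identical(sitePositions(panelRef), sitePositions(panelObj)))
  p1 <- colMeans(hapMatrix(panelRef))
  p2 <- colMeans(hapMatrix(panelObj))
  n1 <- nHaplotypes(panelRef); n2 <- nHaplotypes(panelObj)
  use <- p1 > 0 & p1 < 1
  if (sum(use) < 50)
    stop("need at least 50 sites polymorphic in the reference; have ",
         sum(use))
  num <- (p1[use] - p2[use])^2 - p1[use] * (1 - p1[use]) / n1 -
    p2[use] * (1 - p2[use]) / n2
  max(mean(num / (p1[use] * (1 - p1[use]))), floor)
}

#' Per-site XP-CLR log-likelihood
#'
#' Numerical quadrature (512-point midpoint plus boundary masses) of the
#' sweep / neutral site model; \code{c = 1} is the neutral model.
#'
#' @param p1 reference-population frequency, in (0,1).
#' @param k,n derived count and haplotype count in the object population.
#' @param omega drift variance scale.
#' @param c escape probability in [0,1]; 1 = neutral.
#' @return log-likelihood.
#' @export
xpclrSiteLoglik <- function(p1, k, n, omega, c) {
  stopifnot(p1 > 0, p1 < 1, k >= 0, k <= n)
  q <- drift_weights(p1, omega)
  x <- q$x
  g <- x * stats::dbinom(k, n, c * x + (1 - c)) +
    (1 - x) * stats::dbinom(k, n, c * x)
  lik <- sum(q$W[1, ] * g) + q$m0 * (k == 0) + q$m1 * (k == n)
  if (!is.finite(lik) || lik <= 0)
    stop("non-finite site likelihood at p1=", p1, " k=", k)
  log(lik)
}

#' Sweep escape probability at a physical distance
#'
#' \code{c(d) = 1 - (2N s)^(-r d / s)} with recombination fraction
#' \code{r * d} from a fixed uniform map.
#'
#' @param d distance (bp) from the putative sweep site.
#' @param s selection intensity.
#' @param rPerBp recombination fraction per bp (default 1e-8, i.e. 1 cM/Mb).
#' @param twoN 2N of the sweep model (default 1e4).
#' @return escape probabilities in [0,1].
#' @export
sweepEscapeProb <- function(d, s, rPerBp = 1e-8, twoN = 1e4) {
  pmin(pmax(1 - (twoN * s)^(-(rPerBp * d) / s), 0), 1)
}

ld_weights <- function(m, r2Max = 0.95) {
  # shared weight over connected components of the r^2 > r2Max graph
  S <- ncol(m)
  if (S < 2) return(rep(1, S))
  sds <- apply(m, 2, sd)
  r2 <- suppressWarnings(stats::cor(m))^2
  r2[is.na(r2)] <- 0
  g <- r2 > r2Max
  diag(g) <- FALSE
  comp <- seq_len(S)
  repeat {  # label propagation to connected components
    nxt <- vapply(seq_len(S), function(j)
      min(comp[c(j, which(g[, j]))]), numeric(1))
    if (identical(nxt, comp)) break
    comp <- nxt
  }
  1 / as.numeric(table(comp)[as.character(comp)])
}

#' XP-CLR window scan
#'
#' Scores sliding windows for a sweep in the object population relative to
#' the reference.  The putative sweep site sits at the window center; the
#' escape probability of each SNP follows from its distance and the
#' selection-intensity grid value; SNPs in near-perfect LD share weight.
#'
#' @param panelRef,panelObj reference / object [HaplotypePanel-class]
#'   objects on the same sites (use [subsetPanel()] per population).
#' @param windows \code{GRanges} from [makeWindows()]; default 100 kb /
#'   50 kb step over the span of the data.
#' @param grid selection-intensity grid; default 10 log-spaced values in
#'   \code{[1e-4, 0.1]}.
#' @param omega drift scale; estimated from the panels when \code{NULL}.
#' @param rPerBp,twoN sweep-model map constants (see [sweepEscapeProb()]).
#' @param minSnps windows with fewer usable SNPs score \code{NA}
#'   (default 10).
#' @param ldTrim share weight across SNPs with r-squared > \code{r2Max} in
#'   the reference panel (default TRUE).
#' @param r2Max LD trimming threshold (default 0.95).
#' @return data.frame: chrom, start, end (0-based half-open), n_snps,
#'   score, argmax_intensity.
#' @export
xpclrScan <- function(panelRef, panelObj, windows = NULL,
                      grid = 10^seq(log10(1e-4), log10(0.1), length.out = 10),
                      omega = NULL, rPerBp = 1e-8, twoN = 1e4,
                      minSnps = 10, ldTrim = TRUE, r2Max = 0.95) {
  if (!length(grid)) stop("selection-intensity grid is empty")
  stopifnot(identical(sitePositions(panelRef), sitePositions(panelObj)))
  if (is.null(omega)) omega <- estimateOmega(panelRef, panelObj)
  pos <- sitePositions(panelRef)
  if (is.null(windows)) {
    chrlen <- max(pos)
    windows <- makeWindows(chrlen, chrom = chromName(panelRef))
  }
  p1 <- colMeans(hapMatrix(panelRef))
  n <- nHaplotypes(panelObj)
  kvec <- colSums(hapMatrix(panelObj))
  usable <- p1 > 0 & p1 < 1
  x <- (seq_len(QUAD_N) - 0.5) / QUAD_N
  bed <- bedBounds(windows)
  idx_by_win <- sitesInWindows(pos, windows, chromName(panelRef))
  out <- data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
                    n_snps = 0L, score = NA_real_,
                    argmax_intensity = NA_real_)
  for (w in seq_along(windows)) {
    idx <- idx_by_win[[w]]
    idx <- idx[usable[idx]]
    out$n_snps[w] <- length(idx)
    if (length(idx) < minSnps) next
    center <- (bed$start[w] + bed$end[w]) / 2
    d <- abs(pos[idx] - center)
    wts <- if (ldTrim)
      ld_weights(hapMatrix(panelRef)[, idx, drop = FALSE], r2Max)
    else rep(1, length(idx))
    Wq <- drift_weights(p1[idx], omega)
    kk <- kvec[idx]
    boundary <- Wq$m0 * (kk == 0) + Wq$m1 * (kk == n)
    site_ll <- function(cvec) {
      # cvec: per-site escape probability
      ll <- numeric(length(idx))
      for (i in seq_along(idx)) {
        ci <- cvec[i]; k <- kk[i]
        g <- x * stats::dbinom(k, n, ci * x + (1 - ci)) +
          (1 - x) * stats::dbinom(k, n, ci * x)
        lik <- sum(Wq$W[i, ] * g) + boundary[i]
        ll[i] <- log(max(lik, 1e-300))
      }
      if (any(!is.finite(ll)))
        stop("non-finite quadrature in window ", w)
      ll
    }
    ll_neutral <- sum(wts * site_ll(rep(1, length(idx))))
    ll_sweep <- vapply(grid, function(sv) {
      cv <- sweepEscapeProb(d, sv, rPerBp, twoN)
      sum(wts * site_ll(cv))
    }, numeric(1))
    best <- which.max(ll_sweep)
    # the model family includes the neutral model (c = 1), so the score is
    # bounded below by 0; degenerate grid values never push it negative
    out$score[w] <- max(2 * (ll_sweep[best] - ll_neutral), 0)
    out$argmax_intensity[w] <- if (ll_sweep[best] > ll_neutral)
      grid[best] else NA_real_
  }
  out
}
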