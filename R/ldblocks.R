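## Pairwise LD (r^2, D') from phased haplotypes and a deterministic
## solid-spine haplotype-block caller, for the candidate-region LD-contrast
## between population groups.

#' Pairwise LD matrix for a region
#'
#' From phased haplotypes: \code{D = p_AB - p_A p_B},
#' \code{r^2 = D^2 / (p_A(1-p_A) p_B(1-p_B))}, and \code{D' = |D| / D_max}
#' with \code{D_max = min(p_A(1-p_B), (1-p_A)p_B)} for \code{D > 0} and
#' \code{min(p_A p_B, (1-p_A)(1-p_B))} for \code{D < 0}.  Monomorphic
#' sites in the selected haplotypes are excluded (message).
#'
#' @param panel a [HaplotypePanel-class].
#' @param pop optional population label to restrict haplotypes.
#' @param region optional 0-based half-open \code{c(start, end)} in bp.
#' @return an [LDMatrix-class].
#' @export
ldMatrix <- function(panel, pop = NULL, region = NULL) {
  rows <- if (is.null(pop)) seq_len(nHaplotypes(panel))
          else which(hapPopulations(panel) == pop)
  if (!length(rows)) stop("unknown population: ", pop)
  keep <- rep(TRUE, nSites(panel))
  if (!is.null(region)) {
    pos <- sitePositions(panel)
    keep <- pos > region[1] & pos <= region[2]  # [a,b) for 1-based sites
  }
  m <- panel@haplotypes[rows, keep, drop = FALSE]
  pos <- sitePositions(panel)[keep]
  p <- colMeans(m)
  poly <- p > 0 & p < 1
  if (any(!poly))
    message("excluded ", sum(!poly), " monomorphic site(s) from LD matrix")
  m <- m[, poly, drop = FALSE]; pos <- pos[poly]; p <- p[poly]
  if (ncol(m) < 2) stop("need at least 2 polymorphic sites in the region")
  pAB <- crossprod(m) / nrow(m)
  D <- pAB - outer(p, p)
  r2 <- D^2 / outer(p * (1 - p), p * (1 - p))
  dmax_pos <- pmin(outer(p, 1 - p), outer(1 - p, p))
  dmax_neg <- pmin(outer(p, p), outer(1 - p, 1 - p))
  dmax <- ifelse(D >= 0, dmax_pos, dmax_neg)
  dp <- ifelse(dmax > 0, abs(D) / dmax, 0)
  diag(dp) <- 1
  diag(r2) <- 1
  new("LDMatrix", positions = as.integer(pos),
      r2 = unname(r2), dprime = unname(dp))
}

#' Solid-spine haplotype blocks
#'
#' Calls maximal runs of consecutive sites in which every site is in strong
#' LD (r^2 >= \code{r2Min}) with both the first and the last site of the
#' run.  Deterministic greedy scan; blocks have at least two sites.
#'
#' @param ld an [LDMatrix-class].
#' @param r2Min spine threshold; default 0.5.
#' @return data.frame: start_index, end_index (inclusive site indices),
#'   start_bp, end_bp (0-based half-open bounds of the spanned interval),
#'   n_sites.
#' @export
ldBlocks <- function(ld, r2Min = 0.5) {
  r2 <- ld@r2
  S <- length(ld@positions)
  blocks <- list()
  i <- 1L
  while (i < S) {
    j_best <- i
    for (j in seq(i + 1L, S)) {
      run <- i:j
      if (all(r2[run, i] >= r2Min) && all(r2[run, j] >= r2Min))
        j_best <- j
    }
    if (j_best > i) {
      blocks[[length(blocks) + 1L]] <-
        data.frame(start_index = i, end_index = j_best,
                   start_bp = ld@positions[i] - 1L,
                   end_bp = ld@positions[j_best],
                   n_sites = j_best - i + 1L)
      i <- j_best + 1L
    } else i <- i + 1L
  }
  if (!length(blocks))
    return(data.frame(start_index = integer(0), end_index = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_sites = integer(0)))
  do.call(rbind, blocks)
}

#' Mean r-squared within a distance
#'
#' Average pairwise r^2 over site pairs at most \code{maxDist} bp apart;
#' the group-level LD-contrast summary.
#'
#' @param ld an [LDMatrix-class].
#' @param maxDist maximum pair distance in bp (default Inf).
#' @return mean r^2, or \code{NA} when no pair is eligible.
#' @export
meanR2 <- function(ld, maxDist = Inf) {
  S <- length(ld@positions)
  if (S < 2) return(NA_real_)
  dist <- abs(outer(ld@positions, ld@positions, "-"))
  sel <- upper.tri(dist) & dist <= maxDist
  if (!any(sel)) return(NA_real_)
  mean(ld@r2[sel])
}

#' Write an LD matrix as TSV
#' @param ld an [LDMatrix-class].
#' @param path output path (r^2 matrix with positions as dimnames).
#' @export
writeLdTsv <- function(ld, path) {
  m <- ld@r2
  dimnames(m) <- list(ld@positions, ld@positions)
  write.table(m, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Base-graphics LD heatmap with block overlays
#'
#' @param ld an [LDMatrix-class].
#' @param blocks optional data.frame from [ldBlocks()].
#' @param main plot title.
#' @return invisibly, the block data.frame used.
#' @export
plotLdHeatmap <- function(ld, blocks = NULL, main = "pairwise r2") {
  if (is.null(blocks)) blocks <- ldBlocks(ld)
  S <- length(ld@positions)
  graphics::image(seq_len(S), seq_len(S), ld@r2, zlim = c(0, 1),
                  col = grDevices::hcl.colors(64, "Reds", rev = TRUE),
                  xlab = "site index", ylab = "site index", main = main)
  if (nrow(blocks))
    graphics::rect(blocks$start_index - 0.5, blocks$start_index - 0.5,
                   blocks$end_index + 0.5, blocks$end_index + 0.5,
                   border = "blue", lwd = 2)
  invisible(blocks)
}
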