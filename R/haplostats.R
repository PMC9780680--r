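## Within-population haplotype scan: EHH, integrated EHH, and the
## standardized iHS with its normal-tail p-value transform.
##
## EHH at a flanking marker x for a core-allele class is the probability that
## two randomly chosen carrier haplotypes are identical over the interval
## core..x inclusive: sum over distinct extended haplotypes h of
## C(n_h, 2) / C(n_c, 2).  iHH is the trapezoidal integral of EHH over
## physical distance, each side integrated from the core out to the first
## marker where EHH drops below the cutoff (the sub-cutoff trapezoid is
## included), sides summed.  uniHS = ln(iHH_ancestral / iHH_derived) is
## standardized within derived-allele-frequency bins.

#' Extended haplotype homozygosity around a core site
#'
#' Computes the left and right EHH curves for one core-allele class,
#' walking outward marker by marker until EHH falls below \code{cutoff} or
#' the chromosome ends (then \code{truncated_at_border = TRUE}).
#'
#' @param panel a [HaplotypePanel-class] (already subset to one population).
#' @param core site index of the core SNP.
#' @param alleleClass \code{"ancestral"} or \code{"derived"} (requires
#'   polarized sites), or \code{"ref"} / \code{"alt"}.
#' @param cutoff EHH level at which the outward walk stops (default 0.05);
#'   use 0 for the full curve.
#' @return list with \code{left} and \code{right} data.frames
#'   (\code{position}, \code{ehh}; first row is the core with EHH 1) and
#'   logical \code{truncated_at_border}.
#' @export
ehh <- function(panel, core, alleleClass = c("ancestral", "derived",
                                             "ref", "alt"),
                cutoff = 0.05) {
  alleleClass <- match.arg(alleleClass)
  m <- hapMatrix(panel)
  pos <- sitePositions(panel)
  stopifnot(core >= 1, core <= ncol(m))
  allele <- switch(alleleClass,
    ref = 0L, alt = 1L,
    ancestral = panel@ancestral[core],
    derived = 1L - panel@ancestral[core])
  if (is.na(allele)) stop("site ", core, " is not polarized")
  rows <- which(m[, core] == allele)
  if (length(rows) < 2)
    stop("fewer than 2 carriers of the ", alleleClass, " allele at site ",
         core, "; EHH undefined")
  truncated <- FALSE
  one_side <- function(dir) {
    out_pos <- pos[core]; out_ehh <- 1
    grp <- rep(1L, length(rows))
    k <- core + dir
    n <- length(rows)
    denom <- choose(n, 2)
    while (k >= 1 && k <= ncol(m)) {
      grp <- as.integer(factor(paste(grp, m[rows, k])))
      e <- sum(choose(tabulate(grp), 2)) / denom
      out_pos <- c(out_pos, pos[k]); out_ehh <- c(out_ehh, e)
      if (e < cutoff) return(data.frame(position = out_pos, ehh = out_ehh))
      k <- k + dir
    }
    truncated <<- TRUE
    data.frame(position = out_pos, ehh = out_ehh)
  }
  list(left = one_side(-1L), right = one_side(+1L),
       truncated_at_border = truncated)
}

#' Integrated EHH from a pair of curves
#'
#' Trapezoidal integral of EHH over physical distance, both sides summed.
#' Integration stops at the first marker where EHH < \code{cutoff}; the
#' trapezoid down to that marker is included.  For a curve truncated at the
#' chromosome border, \code{borderPolicy = "discard"} (the default of the
#' scan) returns \code{NA}; \code{"keep"} integrates to the border.
#'
#' @param curves result of [ehh()].
#' @param cutoff EHH cutoff in (0,1); default 0.05.
#' @param borderPolicy \code{"keep"} or \code{"discard"}.
#' @return iHH in bp x EHH units, or \code{NA} under discard.
#' @export
ihh <- function(curves, cutoff = 0.05, borderPolicy = c("keep", "discard")) {
  borderPolicy <- match.arg(borderPolicy)
  stopifnot(cutoff > 0, cutoff < 1)
  if (curves$truncated_at_border && borderPolicy == "discard")
    return(NA_real_)
  side_int <- function(df) {
    below <- which(df$ehh < cutoff)
    last <- if (length(below)) below[1] else nrow(df)
    if (last < 2) return(0)
    p <- df$position[1:last]; e <- df$ehh[1:last]
    sum(0.5 * (e[-1] + e[-last]) * abs(diff(p)))
  }
  side_int(curves$left) + side_int(curves$right)
}

#' Genome scan: standardized integrated haplotype score (iHS)
#'
#' For every polarized, MAF-filtered site computes iHH for the ancestral and
#' derived allele classes (compiled core), uniHS = ln(iHH_A / iHH_D), then
#' standardizes within equal-width derived-allele-frequency bins:
#' iHS = (uniHS - bin mean) / bin sd, and
#' piHS = -log10(2 * pnorm(-|iHS|)), the two-sided normal tail on the
#' -log10 scale.
#'
#' @param panel a polarized [HaplotypePanel-class]; pass the haplotypes of
#'   one population (or one pooled altitude class).
#' @param pops optional population labels to subset to first.
#' @param mafMin minor-allele-frequency filter (strictly greater than);
#'   default 0.05.
#' @param cutoff EHH integration cutoff; default 0.05.
#' @param binWidth derived-frequency bin width on
#'   \code{[mafMin, 1 - mafMin]}; default 0.025.  Ties at bin edges fall to
#'   the lower bin.
#' @param maxGap adjacent-marker gap (bp) beyond which integration stops and
#'   the site is flagged; default 200 kb.
#' @param borderPolicy \code{"discard"} (default): sites whose EHH never
#'   drops below \code{cutoff} before the chromosome end, or that hit a gap,
#'   are excluded from standardization; \code{"keep"} retains them.
#' @return data.frame with chrom, position, derived_freq, ihh_A, ihh_D,
#'   uniHS, iHS, piHS and a flags column ("" / "border" / "gap" /
#'   "few_carriers" / "unpolarized" / "thin_bin"); unscored sites carry NA
#'   statistics.
#' @export
ihsScan <- function(panel, pops = NULL, mafMin = 0.05, cutoff = 0.05,
                    binWidth = 0.025, maxGap = 2e5,
                    borderPolicy = c("discard", "keep")) {
  borderPolicy <- match.arg(borderPolicy)
  if (!is.null(pops)) panel <- subsetPanel(panel, pops, mafMin = mafMin)
  m <- hapMatrix(panel)
  pos <- sitePositions(panel)
  p_alt <- colMeans(m)
  maf_ok <- pmin(p_alt, 1 - p_alt) > mafMin
  anc <- panel@ancestral
  core <- .ihh_scan_cpp(m, as.integer(pos), as.integer(anc), cutoff, maxGap)
  dfreq <- derivedFreq(panel)
  flags <- character(length(pos))
  flags[bitwAnd(core$flags, 1L) > 0] <- "border"
  flags[bitwAnd(core$flags, 2L) > 0] <- "gap"
  flags[bitwAnd(core$flags, 4L) > 0] <- "few_carriers"
  flags[bitwAnd(core$flags, 8L) > 0] <- "unpolarized"
  uniHS <- ifelse(core$ihh_a > 0 & core$ihh_d > 0,
                  log(core$ihh_a / core$ihh_d), NA_real_)
  scored <- maf_ok & !is.na(uniHS) &
    (flags == "" | (borderPolicy == "keep" & flags %in% c("border", "gap")))
  std <- standardizeIhs(uniHS, dfreq, scored, mafMin = mafMin,
                        binWidth = binWidth)
  flags[std$thin_bin & scored] <- "thin_bin"
  data.frame(chrom = chromName(panel), position = pos,
             derived_freq = dfreq,
             ihh_A = core$ihh_a, ihh_D = core$ihh_d,
             uniHS = ifelse(scored, uniHS, NA_real_),
             iHS = std$ihs, piHS = std$pihs,
             flags = flags, stringsAsFactors = FALSE)
}

#' Standardize uniHS within derived-allele-frequency bins
#'
#' @param uniHS raw log-ratio per site.
#' @param dfreq derived-allele frequency per site.
#' @param scored logical: sites entering standardization.
#' @param mafMin,binWidth define equal-width bins on
#'   \code{[mafMin, 1 - mafMin]}.
#' @return list with \code{ihs}, \code{pihs}, and logical \code{thin_bin}
#'   (bins with fewer than 2 scored sites give no score).
#' @keywords internal
standardizeIhs <- function(uniHS, dfreq, scored = !is.na(uniHS),
                           mafMin = 0.05, binWidth = 0.025) {
  n <- length(uniHS)
  ihs <- rep(NA_real_, n); thin <- rep(FALSE, n)
  breaks <- seq(mafMin, 1 - mafMin, by = binWidth)
  if (max(breaks) < 1 - mafMin + 1e-12)
    breaks <- c(breaks, 1 - mafMin)
  # ties at edges fall to the lower bin: intervals (lo, hi]
  bin <- findInterval(dfreq, breaks, left.open = TRUE, rightmost.closed = TRUE)
  bin[!scored | is.na(dfreq)] <- NA
  for (b in unique(bin[!is.na(bin)])) {
    idx <- which(!is.na(bin) & bin == b)
    if (length(idx) < 2) { thin[idx] <- TRUE; next }
    s <- sd(uniHS[idx])
    if (s == 0) {
      # bins holding only duplicated (perfect-LD) sites carry no
      # standardizable information; treat like thin bins
      thin[idx] <- TRUE
      next
    }
    ihs[idx] <- (uniHS[idx] - mean(uniHS[idx])) / s
  }
  pihs <- -log10(2 * pnorm(-abs(ihs)))
  list(ihs = ihs, pihs = pihs, thin_bin = thin)
}

#' Write an iHS scan as TSV
#' @param scan data.frame from [ihsScan()].
#' @param path output TSV path.
#' @export
writeIhsTsv <- function(scan, path) {
  write.table(scan, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
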