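#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom stats pnorm qnorm rbinom runif sd setNames
#' @importFrom utils read.table write.table head tail
NULL

#' HaplotypePanel: phased biallelic haplotype data for one chromosome
#'
#' The substrate of every statistic in the package: a haplotype-by-site
#' 0/1 allele matrix with physical positions, ref/alt alleles, ancestral
#' polarity, and a sample-to-population map.  Rows \code{2k-1} and \code{2k}
#' are the two phased haplotypes of diploid sample \code{k}.
#'
#' @slot chrom single chromosome identifier.
#' @slot positions integer vector of 1-based physical positions (bp),
#'   strictly increasing.
#' @slot ref,alt per-site reference / alternate allele strings.
#' @slot ancestral integer per-site code: 0 if the ref allele is ancestral,
#'   1 if the alt allele is ancestral, \code{NA} if unknown.
#' @slot haplotypes integer matrix (haplotypes x sites) with entries in
#'   \{0, 1\}; 0 = ref allele, 1 = alt allele.
#' @slot sampleIds character vector, one entry per haplotype row; each
#'   diploid sample id appears on two consecutive rows.
#' @slot popOf named character vector mapping sample id to population label.
#'
#' @seealso [readVcfPanel()], [subsetPanel()], [simulateSweep()]
#' @export
setClass("HaplotypePanel",
  representation(
    chrom = "character",
    positions = "integer",
    ref = "character",
    alt = "character",
    ancestral = "integer",
    haplotypes = "matrix",
    sampleIds = "character",
    popOf = "character"
  )
)

setValidity("HaplotypePanel", function(object) {
  msg <- character(0)
  m <- object@haplotypes
  if (length(object@chrom) != 1L)
    msg <- c(msg, "chrom must be a single identifier")
  if (nrow(m) %% 2L != 0L)
    msg <- c(msg, "haplotype matrix must have an even number of rows")
  if (length(object@sampleIds) != nrow(m))
    msg <- c(msg, "sampleIds must have one entry per haplotype row")
  if (nrow(m) >= 2L) {
    odd <- object@sampleIds[seq(1L, nrow(m), by = 2L)]
    evn <- object@sampleIds[seq(2L, nrow(m), by = 2L)]
    if (!identical(odd, evn))
      msg <- c(msg, "rows 2k-1 and 2k must belong to the same sample")
    if (anyDuplicated(odd))
      msg <- c(msg, "each sample must contribute exactly two haplotype rows")
  }
  ns <- ncol(m)
  if (length(object@positions) != ns || length(object@ref) != ns ||
      length(object@alt) != ns || length(object@ancestral) != ns)
    msg <- c(msg, "positions/ref/alt/ancestral must match the number of sites")
  if (ns > 1L && any(diff(object@positions) <= 0L))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(m) && !all(m %in% c(0L, 1L)))
    msg <- c(msg, "haplotype matrix entries must be 0 or 1")
  if (!all(is.na(object@ancestral) | object@ancestral %in% c(0L, 1L)))
    msg <- c(msg, "ancestral codes must be 0, 1 or NA")
  if (length(object@popOf) && is.null(names(object@popOf)))
    msg <- c(msg, "popOf must be a named sample -> population vector")
  if (!all(unique(object@sampleIds) %in% names(object@popOf)))
    msg <- c(msg, "every sample must appear in the population map")
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypePanel
#'
#' @param chrom chromosome identifier.
#' @param positions 1-based physical positions, strictly increasing.
#' @param haplotypes integer 0/1 matrix, haplotypes x sites.
#' @param sampleIds per-haplotype sample ids (two consecutive rows per
#'   sample).  If one id per sample is given it is expanded.
#' @param popOf named character vector, sample id -> population label.
#' @param ref,alt per-site allele strings (defaults "A"/"G").
#' @param ancestral per-site ancestral code (0/1/NA); default all NA.
#' @return a validated [HaplotypePanel-class] object.
#' @export
HaplotypePanel <- function(chrom, positions, haplotypes, sampleIds, popOf,
                           ref = NULL, alt = NULL, ancestral = NULL) {
  ns <- ncol(haplotypes)
  if (length(sampleIds) * 2L == nrow(haplotypes))
    sampleIds <- rep(sampleIds, each = 2L)
  storage.mode(haplotypes) <- "integer"
  if (is.null(ref)) ref <- rep("A", ns)
  if (is.null(alt)) alt <- rep("G", ns)
  if (is.null(ancestral)) ancestral <- rep(NA_integer_, ns)
  new("HaplotypePanel",
      chrom = as.character(chrom),
      positions = as.integer(positions),
      ref = as.character(ref), alt = as.character(alt),
      ancestral = as.integer(ancestral),
      haplotypes = haplotypes,
      sampleIds = as.character(sampleIds),
      popOf = popOf)
}

#' @describeIn HaplotypePanel number of haplotype rows
#' @param x,object a \code{HaplotypePanel}
#' @export
nHaplotypes <- function(x) nrow(x@haplotypes)

#' @describeIn HaplotypePanel number of variant sites
#' @export
nSites <- function(x) ncol(x@haplotypes)

#' @describeIn HaplotypePanel 1-based physical positions
#' @export
sitePositions <- function(x) x@positions

#' @describeIn HaplotypePanel chromosome identifier
#' @export
chromName <- function(x) x@chrom

#' @describeIn HaplotypePanel haplotype-by-site 0/1 matrix
#' @export
hapMatrix <- function(x) x@haplotypes

#' @describeIn HaplotypePanel per-haplotype population label
#' @export
hapPopulations <- function(x) unname(x@popOf[x@sampleIds])

#' @describeIn HaplotypePanel sample -> population map
#' @export
popMap <- function(x) x@popOf

#' @describeIn HaplotypePanel per-site ancestral code (0/1/NA)
#' @export
ancestralCode <- function(x) x@ancestral

#' @describeIn HaplotypePanel per-site ref/alt alleles as a DataFrame
#' @export
siteAlleles <- function(x) DataFrame(ref = x@ref, alt = x@alt)

#' Per-site derived-allele frequency
#'
#' Frequency of the derived (non-ancestral) allele among the selected
#' haplotypes.  Sites with unknown ancestral state get \code{NA}.
#'
#' @param x a \code{HaplotypePanel}
#' @param rows optional haplotype row subset
#' @return numeric vector, one frequency per site
#' @export
derivedFreq <- function(x, rows = seq_len(nHaplotypes(x))) {
  m <- x@haplotypes[rows, , drop = FALSE]
  alt_f <- colMeans(m)
  ifelse(is.na(x@ancestral), NA_real_,
         ifelse(x@ancestral == 0L, alt_f, 1 - alt_f))
}

#' Subset a panel to a set of site indices (internal)
#' @keywords internal
takeSites <- function(panel, idx) {
  initialize(panel,
             positions = panel@positions[idx],
             ref = panel@ref[idx], alt = panel@alt[idx],
             ancestral = panel@ancestral[idx],
             haplotypes = panel@haplotypes[, idx, drop = FALSE])
}

setMethod("show", "HaplotypePanel", function(object) {
  pops <- table(hapPopulations(object))
  cat("HaplotypePanel on chrom ", object@chrom, ": ",
      nHaplotypes(object), " haplotypes (",
      nHaplotypes(object) / 2L, " diploids) x ",
      nSites(object), " sites\n", sep = "")
  if (nSites(object))
    cat("  positions ", min(object@positions), "-", max(object@positions),
        "; ancestral known at ", sum(!is.na(object@ancestral)),
        " sites\n", sep = "")
  cat("  populations: ",
      paste0(names(pops), " (", as.integer(pops), ")", collapse = ", "),
      "\n", sep = "")
})

#' LDMatrix: pairwise linkage disequilibrium for a set of sites
#'
#' Symmetric r-squared and D-prime matrices over the polymorphic sites of a
#' region, computed from phased haplotypes.
#'
#' @slot positions site positions (bp).
#' @slot r2 symmetric matrix of squared correlation between sites.
#' @slot dprime symmetric matrix of normalized |D|.
#' @seealso [ldMatrix()], [ldBlocks()], [meanR2()]
#' @export
setClass("LDMatrix",
  representation(positions = "integer", r2 = "matrix", dprime = "matrix"))

setValidity("LDMatrix", function(object) {
  k <- length(object@positions)
  if (!all(dim(object@r2) == k) || !all(dim(object@dprime) == k))
    return("matrix dimensions must match the number of positions")
  if (k && max(abs(object@r2 - t(object@r2))) > 1e-8)
    return("r2 must be symmetric")
  TRUE
})

setMethod("show", "LDMatrix", function(object) {
  k <- length(object@positions)
  cat("LDMatrix over ", k, " sites", sep = "")
  if (k) cat(" (", min(object@positions), "-", max(object@positions), " bp)",
             sep = "")
  cat("\n")
})
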