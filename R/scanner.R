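## Windowing, outlier calling, region merging, cross-method intersection and
## region -> gene annotation: the logic that turns per-SNP score tracks into
## candidate-region and candidate-gene lists.

#' Sliding windows over a chromosome
#'
#' Half-open windows starting at 0, step, 2*step, ... with
#' \code{start + size <= chromLength}.  The default 100 kb / 50 kb grid is
#' the candidate-region grid of the haplotype and XP-CLR scans.
#'
#' @param chromLength chromosome length (bp).
#' @param size window size (bp); default 1e5.
#' @param step step (bp), \code{0 < step <= size}; default 5e4.
#' @param chrom chromosome name.
#' @return \code{GRanges} (package convention; BED bounds via
#'   [bedBounds()]); empty with a warning when \code{size > chromLength}.
#' @export
makeWindows <- function(chromLength, size = 1e5, step = 5e4, chrom = "1") {
  stopifnot(step > 0, step <= size)
  if (size > chromLength) {
    warning("window size exceeds chromosome length; no windows")
    return(GenomicRanges::GRanges())
  }
  starts <- seq(0, chromLength - size, by = step)
  bedRanges(chrom, starts, starts + size)
}

#' Aggregate a per-SNP score track into windows
#'
#' @param positions 1-based SNP positions.
#' @param values per-SNP statistic values.
#' @param windows \code{GRanges} from [makeWindows()].
#' @param reducer \code{"max"}, \code{"mean"} or \code{"count_above"}.
#' @param threshold required for \code{count_above}.
#' @param chrom chromosome of the track.
#' @param method label recorded in the output.
#' @return data.frame: chrom, start, end (0-based half-open), value,
#'   n_snps, method; empty windows get \code{NA}.
#' @export
summarizeTrack <- function(positions, values, windows,
                           reducer = c("max", "mean", "count_above"),
                           threshold = NULL, chrom = "1", method = "score") {
  reducer <- match.arg(reducer)
  if (reducer == "count_above" && is.null(threshold))
    stop("count_above needs a threshold")
  ok <- !is.na(values)
  idx <- sitesInWindows(positions[ok], windows, chrom)
  vals <- values[ok]
  red <- switch(reducer,
    max = function(v) if (length(v)) max(v) else NA_real_,
    mean = function(v) if (length(v)) mean(v) else NA_real_,
    count_above = function(v) if (length(v)) sum(v >= threshold) else NA_real_)
  bed <- bedBounds(windows)
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             value = vapply(idx, function(i) red(vals[i]), numeric(1)),
             n_snps = vapply(idx, length, integer(1)),
             method = method, stringsAsFactors = FALSE)
}

#' Call outlier windows
#'
#' \code{threshold} keeps windows with value >= \code{value};
#' \code{top_fraction} keeps the \code{ceiling(q * M)} highest of the M
#' non-NA windows, ties broken deterministically by (value desc, chrom,
#' start).  Windows with fewer than \code{minSnps} SNPs are excluded first.
#'
#' @param windows data.frame from [summarizeTrack()], [xpclrScan()] or
#'   [pbsWindows()] (needs chrom, start, end, value-or-score, n_snps).
#' @param rule \code{"threshold"} or \code{"top_fraction"}.
#' @param value threshold value or fraction q in (0,1).
#' @param minSnps minimum SNPs per eligible window (default 10).
#' @param valueCol column holding the statistic (auto-detects
#'   \code{value} / \code{score} / \code{pbs}).
#' @return the outlier subset, ordered by chrom, start.
#' @export
callOutliers <- function(windows, rule = c("threshold", "top_fraction"),
                         value, minSnps = 10, valueCol = NULL) {
  rule <- match.arg(rule)
  if (is.null(valueCol))
    valueCol <- intersect(c("value", "score", "pbs"), names(windows))[1]
  v <- windows[[valueCol]]
  elig <- !is.na(v) & windows$n_snps >= minSnps
  if (!any(elig)) stop("no eligible (non-NA) windows")
  w <- windows[elig, , drop = FALSE]
  v <- v[elig]
  if (rule == "threshold") {
    out <- w[v >= value, , drop = FALSE]
  } else {
    if (value <= 0 || value >= 1) stop("top fraction must be in (0,1)")
    k <- ceiling(value * nrow(w))
    ord <- order(-v, w$chrom, w$start)
    out <- w[ord[seq_len(k)], , drop = FALSE]
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Merge outlier windows into candidate regions
#'
#' Overlapping or book-ended windows on the same chromosome are unioned;
#' each region carries the contributing method and its peak value.
#'
#' @param outliers data.frame of outlier windows ([callOutliers()]).
#' @param valueCol statistic column (auto-detected as in [callOutliers()]).
#' @return \code{GRanges} of candidate regions with \code{method} and
#'   \code{peak_value} columns.
#' @export
mergeRegions <- function(outliers, valueCol = NULL) {
  if (is.null(valueCol))
    valueCol <- intersect(c("value", "score", "pbs"), names(outliers))[1]
  if (!nrow(outliers)) {
    gr <- GenomicRanges::GRanges()
    gr$method <- character(0); gr$peak_value <- numeric(0)
    return(gr)
  }
  gr <- bedRanges(outliers$chrom, outliers$start, outliers$end)
  gr$value <- outliers[[valueCol]]
  red <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(red, gr)
  peak <- vapply(split(gr$value[S4Vectors::subjectHits(hits)],
                       factor(S4Vectors::queryHits(hits),
                              levels = seq_along(red))),
                 max, numeric(1))
  red$method <- if ("method" %in% names(outliers))
    as.character(outliers$method[1]) else "score"
  red$peak_value <- unname(peak)
  red
}

#' Intersect two candidate sets
#'
#' Region mode returns base-pair overlaps of the two region sets; gene mode
#' returns the intersection of their gene-name sets (requires
#' [annotateGenes()] first).
#'
#' @param regionsA,regionsB \code{GRanges} from [mergeRegions()].
#' @param mode \code{"region"} or \code{"gene"}.
#' @return \code{GRanges} of shared intervals, or a character vector of
#'   shared gene names.
#' @export
intersectRegions <- function(regionsA, regionsB, mode = c("region", "gene")) {
  mode <- match.arg(mode)
  if (mode == "region")
    return(GenomicRanges::intersect(regionsA, regionsB,
                                    ignore.strand = TRUE))
  intersect(unique(unlist(regionsA$genes)), unique(unlist(regionsB$genes)))
}

#' Annotate candidate regions with overlapping genes
#'
#' A gene is assigned iff its interval overlaps the region by at least one
#' base pair (half-open semantics: a gene starting exactly at a region's
#' end does not overlap).
#'
#' @param regions \code{GRanges} regions.
#' @param genes \code{GRanges} with a \code{name} column ([readGenes()]).
#' @return \code{regions} with a \code{genes} CharacterList column.
#' @export
annotateGenes <- function(regions, genes) {
  hits <- GenomicRanges::findOverlaps(regions, genes, minoverlap = 1L,
                                      ignore.strand = TRUE)
  lst <- split(genes$name[S4Vectors::subjectHits(hits)],
               factor(S4Vectors::queryHits(hits),
                      levels = seq_along(regions)))
  regions$genes <- IRanges::CharacterList(lapply(lst, unique))
  regions
}

#' Write regions as BED
#' @param regions \code{GRanges} (package convention).
#' @param path output BED path.
#' @export
writeRegionsBed <- function(regions, path) {
  bed <- bedBounds(regions)
  if (!is.null(regions$genes))
    bed$name <- vapply(regions$genes, paste, character(1), collapse = ",")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
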