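## Readers/writers for the standard formats the pipeline touches, plus the
## panel subsetting (population + MAF) every statistic builds on.

#' Centralized coordinate conversion
#'
#' All windows, regions and gene intervals in this package are 0-based
#' half-open \code{[start, end)}; variant sites keep their 1-based VCF
#' positions.  A position p lies in \code{[a, b)} iff \code{a < p <= b},
#' which is exactly containment in the 1-based closed interval
#' \code{[a+1, b]} that \code{GRanges} stores.  This is the only place the
#' conversion happens.
#'
#' @param chrom chromosome id (recycled).
#' @param start0,end0 0-based half-open bounds (bp).
#' @return a \code{GRanges}; its BED-style bounds can be recovered with
#'   [bedBounds()].
#' @export
bedRanges <- function(chrom, start0, end0) {
  stopifnot(all(end0 > start0))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1, end = end0))
}

#' @rdname bedRanges
#' @param gr a \code{GRanges} created under the package convention
#' @return \code{bedBounds}: data.frame with chrom, start, end (0-based
#'   half-open).
#' @export
bedBounds <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' Map 1-based site positions to windows
#'
#' @param positions 1-based site positions on one chromosome.
#' @param windows \code{GRanges} windows (package convention).
#' @param chrom chromosome the positions live on.
#' @return integer list: for each window, indices of contained sites.
#' @keywords internal
sitesInWindows <- function(positions, windows, chrom) {
  if (!length(positions))
    return(rep(list(integer(0)), length(windows)))
  pts <- GenomicRanges::GRanges(chrom,
           IRanges::IRanges(start = positions, width = 1L))
  hits <- GenomicRanges::findOverlaps(windows, pts)
  split(S4Vectors::subjectHits(hits),
        factor(S4Vectors::queryHits(hits), levels = seq_along(windows)))
}

vcf_open <- function(path, mode = "rt") {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a phased VCF into a HaplotypePanel
#'
#' Retains only biallelic SNP records whose genotypes are fully called and
#' phased ("|" separator) in every sample.  Records failing this are skipped
#' and counted (message).  The ancestral allele is taken from the INFO
#' \code{AA} tag when present and matching ref or alt (case-insensitive);
#' otherwise it is left unknown (see [polarizePanel()]).
#'
#' @param path VCF v4.x file (optionally gzipped).
#' @param popOf named character vector mapping sample -> population; samples
#'   absent from the map are handled per \code{onUnmapped}.
#' @param region optional \code{"chrom:start-end"} filter (1-based closed).
#' @param onUnmapped \code{"error"} (default) or \code{"drop"} for VCF
#'   samples missing from \code{popOf}.
#' @return a [HaplotypePanel-class].
#' @export
readVcfPanel <- function(path, popOf = NULL, region = NULL,
                         onUnmapped = c("error", "drop")) {
  onUnmapped <- match.arg(onUnmapped)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- v@gt
  samples <- colnames(gt)[-1]
  if (is.null(popOf)) {
    popOf <- setNames(rep("pop1", length(samples)), samples)
  } else {
    missing_s <- setdiff(samples, names(popOf))
    if (length(missing_s)) {
      if (onUnmapped == "error")
        stop("samples absent from population map: ",
             paste(missing_s, collapse = ", "))
      keep_s <- samples %in% names(popOf)
      gt <- gt[, c(TRUE, keep_s), drop = FALSE]
      samples <- samples[keep_s]
      message("dropped ", sum(!keep_s), " unmapped sample(s)")
    }
  }
  if (!length(samples)) stop("VCF contains no samples")

  chroms <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("region must be 'chrom:start-end'")
    keep <- chroms == m[2] & pos >= as.integer(m[3]) & pos <= as.integer(m[4])
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(alt) & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  n_multi <- sum(keep & !snp)
  keep <- keep & snp

  ## GT field only, fully called and phased
  gtm <- sub(":.*$", "", gt[, -1, drop = FALSE])
  ok_gt <- rowSums(matrix(gtm %in% c("0|0", "0|1", "1|0", "1|1"),
                          nrow = nrow(gt))) == length(samples)
  n_badgt <- sum(keep & !ok_gt)
  keep <- keep & ok_gt
  if (n_multi || n_badgt)
    message("skipped ", n_multi, " non-biallelic-SNP and ", n_badgt,
            " unphased/half-called record(s)")
  if (!any(keep)) stop("no usable phased biallelic SNP records in ", path)
  if (length(unique(chroms[keep])) > 1)
    stop("panel must be single-chromosome; use `region` to select one")

  gtm <- gtm[keep, , drop = FALSE]
  a1 <- matrix(as.integer(substr(gtm, 1, 1)), nrow = nrow(gtm))
  a2 <- matrix(as.integer(substr(gtm, 3, 3)), nrow = nrow(gtm))
  hap <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(gtm))
  hap[seq(1, nrow(hap), 2), ] <- t(a1)
  hap[seq(2, nrow(hap), 2), ] <- t(a2)

  info <- fix[keep, "INFO"]
  aa <- rep(NA_character_, length(info))
  has <- grepl("(^|;)AA=", info)
  aa[has] <- sub(".*(?:^|;)AA=([^;]*).*", "\\1", info[has])
  anc <- rep(NA_integer_, length(info))
  anc[!is.na(aa) & toupper(aa) == toupper(ref[keep])] <- 0L
  anc[!is.na(aa) & toupper(aa) == toupper(alt[keep])] <- 1L

  ord <- order(pos[keep])
  HaplotypePanel(chrom = unique(chroms[keep]),
                 positions = pos[keep][ord],
                 haplotypes = hap[, ord, drop = FALSE],
                 sampleIds = samples,
                 popOf = popOf[samples],
                 ref = ref[keep][ord], alt = alt[keep][ord],
                 ancestral = anc[ord])
}

#' Write a HaplotypePanel as phased VCF v4.2
#'
#' Emits one canonical record per site with phased GT and, where the
#' ancestral state is known, an \code{AA} INFO tag.  Output of this writer
#' read back with [readVcfPanel()] and written again is byte-identical.
#'
#' @param panel a [HaplotypePanel-class].
#' @param path output file; ".gz" suffix writes gzip.
#' @return \code{path}, invisibly.
#' @export
writeVcfPanel <- function(panel, path) {
  samples <- panel@sampleIds[seq(1, nHaplotypes(panel), 2)]
  con <- vcf_open(path, "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", panel@chrom, ">"),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  if (nSites(panel)) {
    anc <- panel@ancestral
    info <- ifelse(is.na(anc), ".",
                   paste0("AA=", ifelse(anc == 0L, panel@ref, panel@alt)))
    m <- panel@haplotypes
    gtrows <- matrix(paste0(m[seq(1, nrow(m), 2), , drop = FALSE], "|",
                            m[seq(2, nrow(m), 2), , drop = FALSE]),
                     nrow = nrow(m) / 2L)
    gtcols <- apply(gtrows, 2, paste, collapse = "\t")
    writeLines(paste(panel@chrom, panel@positions, ".", panel@ref, panel@alt,
                     ".", ".", info, "GT", gtcols, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a two-column sample -> population TSV
#'
#' @param path TSV with sample id in column 1 and population label in
#'   column 2; no header required (a "sample" header row is tolerated).
#' @return named character vector, sample -> population.
#' @export
readPopMap <- function(path) {
  df <- tryCatch(read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            colClasses = "character"),
                 error = function(e) stop("empty or unreadable population map: ",
                                          path, call. = FALSE))
  if (ncol(df) < 2) stop("population map needs two tab-separated columns")
  if (tolower(df[1, 1]) %in% c("sample", "sample_id", "id"))
    df <- df[-1, , drop = FALSE]
  if (!nrow(df)) stop("population map is empty")
  if (anyDuplicated(df[[1]]))
    stop("duplicated sample id(s) in population map: ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  setNames(df[[2]], df[[1]])
}

#' @rdname readPopMap
#' @param popOf named sample -> population vector
#' @export
writePopMap <- function(popOf, path) {
  write.table(data.frame(sample = names(popOf), population = unname(popOf)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Subset a panel by population and minor-allele frequency
#'
#' Keeps the haplotypes of the named populations, then keeps sites whose
#' pooled minor-allele frequency is strictly greater than \code{mafMin}.
#' Monomorphic sites are always removed when \code{mafMin >= 0} (MAF 0 is
#' not > 0).
#'
#' @param panel a [HaplotypePanel-class].
#' @param pops population labels to retain.
#' @param mafMin minor-allele-frequency cutoff in \code{[0, 0.5)};
#'   default 0.05, the within-population site filter used for haplotype
#'   statistics.
#' @return the filtered [HaplotypePanel-class].
#' @export
subsetPanel <- function(panel, pops, mafMin = 0.05) {
  stopifnot(length(pops) >= 1, mafMin >= 0, mafMin < 0.5)
  valid <- unique(unname(panel@popOf))
  bad <- setdiff(pops, valid)
  if (length(bad))
    stop("unknown population label(s): ", paste(bad, collapse = ", "),
         "; valid labels: ", paste(valid, collapse = ", "))
  rows <- which(hapPopulations(panel) %in% pops)
  m <- panel@haplotypes[rows, , drop = FALSE]
  p <- colMeans(m)
  maf <- pmin(p, 1 - p)
  keep_sites <- which(maf > mafMin)
  samples_kept <- unique(panel@sampleIds[rows])
  out <- initialize(panel,
                    positions = panel@positions[keep_sites],
                    ref = panel@ref[keep_sites], alt = panel@alt[keep_sites],
                    ancestral = panel@ancestral[keep_sites],
                    haplotypes = m[, keep_sites, drop = FALSE],
                    sampleIds = panel@sampleIds[rows],
                    popOf = panel@popOf[samples_kept])
  validObject(out)
  out
}

#' Assign ancestral states where unknown
#'
#' The iHS scan needs every site polarized.  When the VCF carried no usable
#' AA tag three policies are available: treat the reference allele as
#' ancestral (default; a common fallback, logged because it biases iHS
#' where wrong), take the major allele of an outgroup population as
#' ancestral, or leave sites unknown so they are skipped.
#'
#' @param panel a [HaplotypePanel-class].
#' @param policy one of \code{"ref-ancestral"}, \code{"outgroup-major"},
#'   \code{"skip"}.
#' @param outgroup population label, required for \code{"outgroup-major"};
#'   ties (frequency exactly 0.5) stay unknown.
#' @return the panel with its \code{ancestral} slot filled where possible.
#' @export
polarizePanel <- function(panel,
                          policy = c("ref-ancestral", "outgroup-major", "skip"),
                          outgroup = NULL) {
  policy <- match.arg(policy)
  anc <- panel@ancestral
  unk <- is.na(anc)
  if (!any(unk) || policy == "skip") return(panel)
  if (policy == "ref-ancestral") {
    message("polarizing ", sum(unk),
            " site(s) as ref-is-ancestral (no AA information)")
    anc[unk] <- 0L
  } else {
    if (is.null(outgroup)) stop("outgroup population required")
    rows <- which(hapPopulations(panel) == outgroup)
    if (!length(rows)) stop("unknown outgroup population: ", outgroup)
    p_alt <- colMeans(panel@haplotypes[rows, , drop = FALSE])
    anc[unk & p_alt < 0.5] <- 0L
    anc[unk & p_alt > 0.5] <- 1L
  }
  initialize(panel, ancestral = anc)
}

#' Read gene models from BED or GFF3
#'
#' BED input is 0-based half-open; GFF3 is 1-based closed and only rows of
#' type \code{gene} are kept.  Both are returned under the package's
#' internal convention (a \code{GRanges} whose BED-style bounds are
#' available via [bedBounds()]), with a \code{name} column from BED column
#' 4 or the GFF3 \code{Name}/\code{ID} attribute.  Rows with end <= start
#' are rejected with a message.
#'
#' @param path BED or GFF3 file (optionally gzipped).
#' @param format \code{"auto"} (from extension), \code{"bed"} or
#'   \code{"gff3"}.
#' @return \code{GRanges} with a \code{name} metadata column.
#' @export
readGenes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.bed$", base, ignore.case = TRUE)) "bed"
              else if (grepl("\\.(gff3?|gff)$", base, ignore.case = TRUE)) "gff3"
              else stop("cannot infer format of ", path)
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    nm <- if (!is.null(gr$name)) gr$name else paste0("gene", seq_along(gr))
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    gr <- gr[!is.na(gr$type) & gr$type == "gene"]
    nm <- if (!is.null(gr$Name) && !all(is.na(gr$Name))) {
      ifelse(is.na(gr$Name), as.character(gr$ID), as.character(gr$Name))
    } else as.character(gr$ID)
  }
  bad <- GenomicRanges::width(gr) < 1L
  if (any(bad)) {
    message("rejected ", sum(bad), " gene row(s) with end <= start")
    gr <- gr[!bad]; nm <- nm[!bad]
  }
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::IRanges(GenomicRanges::start(gr),
                                                 GenomicRanges::end(gr)))
  out$name <- nm
  unique(out)
}
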