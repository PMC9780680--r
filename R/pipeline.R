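## End-to-end orchestration mirroring the study's analysis order:
## iHS (focal group) -> XP-CLR (focal vs reference) -> outlier windows ->
## merged candidate regions -> PBS on the candidate regions -> three-way
## intersection -> gene annotation -> FST / pi / LD tracks at candidates.
## Every artifact is listed in a JSON manifest with parameters, seed and
## md5 checksums; identical config + seed give byte-identical manifests.

#' Assemble a pipeline configuration
#'
#' @param out_dir output directory (created if needed).
#' @param vcf,pop_map input paths (phased VCF + sample->population TSV);
#'   leave \code{NULL} to simulate input with \code{sim}.
#' @param sim a [simConfig()] used when no VCF is given.
#' @param genes optional BED/GFF3 gene annotation.
#' @param chrom_length chromosome length in bp (default: max position).
#' @param focal,reference population labels of the focal (selected) and
#'   reference groups; \code{outgroup} roots the PBS branch.
#' @param polarize_policy ancestral fallback (see [polarizePanel()]).
#' @param maf_min MAF filter for the haplotype statistics.
#' @param window_size,window_step candidate-region window grid (bp).
#' @param fine_size,fine_step FST/pi/PBS fine window grid (bp).
#' @param pihs_threshold per-SNP -log10 p cutoff for iHS outliers
#'   (default 6, i.e. p < 1e-6).
#' @param ihs_min_hits qualifying SNPs needed per iHS outlier window.
#' @param xpclr_top_fraction top fraction of XP-CLR windows kept
#'   (default 0.005).
#' @param pbs_threshold windowed PBS outlier cutoff (default 0.2).
#' @param min_snps minimum SNPs per candidate-grid window;
#'   \code{pbs_min_snps} for the fine grid.
#' @param scan_reference also run the iHS scan on the reference group.
#' @param seed RNG seed for the whole run.
#' @return a \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(out_dir, vcf = NULL, pop_map = NULL, sim = NULL,
                           genes = NULL, chrom_length = NULL,
                           focal = "hi", reference = "lo", outgroup = "out",
                           polarize_policy = "ref-ancestral",
                           maf_min = 0.05,
                           window_size = 1e5, window_step = 5e4,
                           fine_size = 1e4, fine_step = 5e3,
                           pihs_threshold = 6, ihs_min_hits = 1,
                           xpclr_top_fraction = 0.005, pbs_threshold = 0.2,
                           min_snps = 10, pbs_min_snps = 3,
                           scan_reference = FALSE, seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(vcf) && is.null(sim))
    stop("either a VCF or a simulation config is required")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipelineConfig()] arguments; a \code{sim}
#' block holds [simConfig()] fields.
#'
#' @param path YAML file.
#' @return a \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(simConfig, y$sim)
  do.call(pipelineConfig, y)
}

#' Extract the haplotypes of one or more populations
#'
#' Row subset only: all sites are kept (unlike [subsetPanel()], which also
#' applies a MAF filter).  Used to split a pooled panel into the object /
#' reference panels of the cross-population statistics.
#'
#' @param panel a [HaplotypePanel-class].
#' @param pops population label(s).
#' @return a [HaplotypePanel-class] with the selected haplotypes.
#' @export
popPanel <- function(panel, pops) {
  rows <- which(hapPopulations(panel) %in% pops)
  keep <- unique(panel@sampleIds[rows])
  initialize(panel, haplotypes = panel@haplotypes[rows, , drop = FALSE],
             sampleIds = panel@sampleIds[rows], popOf = panel@popOf[keep])
}

#' Run the full selection-signature pipeline
#'
#' Executes subset/polarize, the iHS scan of the focal group, the XP-CLR
#' scan of focal vs reference, outlier calling and region merging for both,
#' windowed PBS restricted to the candidate regions, the three-way region
#' intersection, gene annotation, and FST/pi/LD tracks over the candidate
#' regions.  Any stage error aborts with the stage name; the partial
#' manifest written so far is kept with a note.
#'
#' @param config a [pipelineConfig()] or [readPipelineConfig()] result.
#' @return the manifest (list), invisibly; written as
#'   \code{manifest.json} in \code{out_dir}.
#' @export
runPipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  art <- list()
  put <- function(name, path) art[[name]] <<- path
  stage <- "setup"
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  fail <- function(e) {
    note <- paste0("aborted at stage '", stage, "': ", conditionMessage(e))
    writeManifest(cfg, art, manifest_path, note = note)
    stop(note, call. = FALSE)
  }
  tryCatch({
    stage <- "load"
    if (!is.null(cfg$vcf)) {
      pm <- readPopMap(cfg$pop_map)
      panel <- readVcfPanel(cfg$vcf, popOf = pm)
      truth <- NULL
    } else {
      simres <- simulateSweep(cfg$sim)
      panel <- simres$panel
      truth <- simres$truth
      put("vcf", writeVcfPanel(panel, file.path(cfg$out_dir, "sim.vcf")))
      put("pop_map", writePopMap(popMap(panel),
                                 file.path(cfg$out_dir, "sim.popmap.tsv")))
      put("truth", writeTruth(truth, file.path(cfg$out_dir, "sim.truth.tsv")))
    }
    valid <- unique(unname(popMap(panel)))
    roles <- c(cfg$focal, cfg$reference, cfg$outgroup)
    bad <- setdiff(roles, valid)
    if (length(bad))
      stop("population(s) not in the data: ", paste(bad, collapse = ", "),
           "; available: ", paste(valid, collapse = ", "))
    chrlen <- if (is.null(cfg$chrom_length)) max(sitePositions(panel))
              else cfg$chrom_length
    windows <- makeWindows(chrlen, cfg$window_size, cfg$window_step,
                           chrom = chromName(panel))
    genes <- if (!is.null(cfg$genes)) readGenes(cfg$genes) else NULL

    stage <- "polarize"
    panel <- polarizePanel(panel, policy = cfg$polarize_policy,
                           outgroup = cfg$outgroup)

    stage <- "ihs"
    focal_panel <- subsetPanel(panel, cfg$focal, mafMin = cfg$maf_min)
    ihs <- ihsScan(focal_panel, mafMin = cfg$maf_min)
    put("ihs_tsv", writeIhsTsv(ihs, file.path(cfg$out_dir, "ihs_focal.tsv")))
    ihs_win <- summarizeTrack(ihs$position, ihs$piHS, windows,
                              reducer = "count_above",
                              threshold = cfg$pihs_threshold,
                              chrom = chromName(panel), method = "ihs")
    ihs_out <- tryCatch(
      callOutliers(ihs_win, "threshold", cfg$ihs_min_hits,
                   minSnps = cfg$min_snps),
      error = function(e) ihs_win[0, , drop = FALSE])
    regions_ihs <- mergeRegions(ihs_out)
    if (isTRUE(cfg$scan_reference)) {
      ihs_ref <- ihsScan(subsetPanel(panel, cfg$reference,
                                     mafMin = cfg$maf_min),
                         mafMin = cfg$maf_min)
      put("ihs_reference_tsv",
          writeIhsTsv(ihs_ref, file.path(cfg$out_dir, "ihs_reference.tsv")))
    }

    stage <- "xpclr"
    both <- subsetPanel(panel, c(cfg$focal, cfg$reference),
                        mafMin = cfg$maf_min)
    xp <- xpclrScan(popPanel(both, cfg$reference), popPanel(both, cfg$focal),
                    windows = windows, minSnps = cfg$min_snps)
    xp_path <- file.path(cfg$out_dir, "xpclr.tsv")
    write.table(xp, xp_path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    put("xpclr_tsv", xp_path)
    xp$method <- "xpclr"
    xp_out <- callOutliers(xp, "top_fraction", cfg$xpclr_top_fraction,
                           minSnps = cfg$min_snps)
    regions_xpclr <- mergeRegions(xp_out)

    stage <- "pbs"
    candidates <- GenomicRanges::reduce(c(GenomicRanges::granges(regions_ihs),
                                          GenomicRanges::granges(regions_xpclr)))
    fine_all <- makeWindows(chrlen, cfg$fine_size, cfg$fine_step,
                            chrom = chromName(panel))
    fine <- IRanges::subsetByOverlaps(fine_all, candidates)
    low_pops <- cfg$reference
    low1 <- low_pops[1]
    low2 <- if (length(low_pops) > 1) low_pops[2] else cfg$outgroup
    pbs_w <- if (length(fine))
      pbsWindows(panel, cfg$focal[1], low1, low2, fine)
    else pbsWindows(panel, cfg$focal[1], low1, low2, fine_all)[0, ]
    pbs_path <- file.path(cfg$out_dir, "pbs.tsv")
    write.table(pbs_w, pbs_path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
    put("pbs_tsv", pbs_path)
    pbs_w$method <- "pbs"
    pbs_out <- if (nrow(pbs_w))
      tryCatch(callOutliers(pbs_w, "threshold", cfg$pbs_threshold,
                            minSnps = cfg$pbs_min_snps),
               error = function(e) pbs_w[0, , drop = FALSE])
    else pbs_w
    regions_pbs <- mergeRegions(pbs_out)

    stage <- "intersect"
    inter <- intersectRegions(intersectRegions(regions_ihs, regions_xpclr),
                              regions_pbs)

    stage <- "annotate"
    region_sets <- list(ihs = regions_ihs, xpclr = regions_xpclr,
                        pbs = regions_pbs, intersection = inter)
    shared_genes <- character(0)
    if (!is.null(genes)) {
      region_sets <- lapply(region_sets, annotateGenes, genes = genes)
      shared_genes <- Reduce(intersect,
                             lapply(region_sets[c("ihs", "xpclr", "pbs")],
                                    function(r) unique(unlist(r$genes))))
    }
    for (nm in names(region_sets))
      put(paste0("regions_", nm),
          writeRegionsBed(region_sets[[nm]],
                          file.path(cfg$out_dir,
                                    paste0("regions_", nm, ".bed"))))

    # combined candidate table: intersection regions with per-method peaks
    inter_ann <- region_sets$intersection
    if (length(inter_ann)) {
      bedi <- bedBounds(inter_ann)
      peak_in <- function(tab, col) vapply(seq_len(nrow(bedi)), function(i) {
        sel <- tab$chrom == bedi$chrom[i] & tab$start < bedi$end[i] &
          tab$end > bedi$start[i]
        v <- tab[[col]][sel]
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
      }, numeric(1))
      cand <- data.frame(
        chrom = bedi$chrom, start = bedi$start, end = bedi$end,
        peak_ihs_hits = peak_in(ihs_win, "value"),
        peak_xpclr = peak_in(xp, "score"),
        peak_pbs = if (nrow(pbs_w)) peak_in(pbs_w, "pbs") else NA_real_,
        genes = if (!is.null(inter_ann$genes))
          vapply(inter_ann$genes, paste, character(1), collapse = ",")
        else "")
      cand_path <- file.path(cfg$out_dir, "candidates.tsv")
      write.table(cand, cand_path, sep = "\t", quote = FALSE,
                  row.names = FALSE, na = "NA")
      put("candidates_tsv", cand_path)
    }

    stage <- "tracks"
    track_regions <- if (length(region_sets$intersection))
      region_sets$intersection else candidates
    if (length(track_regions)) {
      fine_tr <- IRanges::subsetByOverlaps(fine_all, track_regions)
      fs <- fstSites(panel, cfg$focal[1], low1)
      put("fst_tsv", writeWindowTsv(fstWindows(fs, fine_tr,
                                               chromName(panel)),
                                    file.path(cfg$out_dir, "fst_10kb.tsv"),
                                    "fst"))
      for (grp in unique(c(cfg$focal[1], low1)))
        put(paste0("pi_", grp, "_tsv"),
            writeWindowTsv(piWindows(panel, grp, fine_tr),
                           file.path(cfg$out_dir,
                                     paste0("pi_", grp, "_10kb.tsv")), "pi"))
      reg1 <- bedBounds(track_regions[1])
      for (grp in unique(c(cfg$focal[1], low1))) {
        ld <- tryCatch(ldMatrix(panel, grp,
                                c(reg1$start[1], reg1$end[1])),
                       error = function(e) NULL)
        if (!is.null(ld))
          put(paste0("ld_", grp, "_tsv"),
              writeLdTsv(ld, file.path(cfg$out_dir,
                                       paste0("ld_", grp, ".tsv"))))
      }
    }

    stage <- "manifest"
    extra <- list(
      n_sites = nSites(panel),
      n_candidate_regions = vapply(region_sets, length, integer(1)),
      shared_genes = shared_genes)
    writeManifest(cfg, art, manifest_path, extra = extra)
  }, error = fail)
  invisible(jsonlite::read_json(manifest_path))
}

writeManifest <- function(cfg, art, path, note = NULL, extra = list()) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (inherits(v, "SimConfig") || is.list(v))
      strip(v) else v)
  }
  manifest <- list(
    tool = "altiscan",
    seed = cfg$seed,
    parameters = strip(cfg),
    artifacts = lapply(art, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))),
    summary = extra)
  if (!is.null(note)) manifest$note <- note
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  path
}
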