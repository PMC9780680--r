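## Forward Wright-Fisher simulator of the three-population altitude design:
## an outgroup branch, then a highland/lowland sister split, with an optional
## hard sweep on the highland branch.  The engine (src/wf.cpp) is haploid WF
## with Poisson crossovers, infinite-sites mutation on distinct integer bp,
## and genic selection (fitness 1+s per carrier haplotype).

#' Simulation configuration
#'
#' Bundles demography, mutation/recombination rates, the optional sweep, and
#' sampling into a validated config.  Defaults are the package's reference
#' study conditions (see the methods vignette for the reasoning).
#'
#' @param region_length simulated region length in bp.
#' @param N_anc,N_out,N_hi,N_lo haploid population sizes.
#' @param t_out_split generations before present at which the outgroup
#'   splits; \code{NULL} for a two-population (or single-population) design.
#' @param t_hilo_split generations before present of the highland/lowland
#'   split; \code{NULL} for a single panmictic population.
#' @param mu,rho per-bp per-generation mutation and recombination rates.
#' @param sweep \code{NULL} (neutral) or a list with \code{position} (bp),
#'   \code{s} (selection coefficient per generation, in (0,1]),
#'   \code{t_start} (generations before present, on the highland branch so
#'   \code{t_start < t_hilo_split}), and optional
#'   \code{condition_on_establishment} (default \code{TRUE}: on loss the
#'   state at \code{t_start} is restored and the allele re-injected, up to
#'   \code{retry_cap} times).
#' @param n_sample diploids sampled per population at generation 0; scalar
#'   or named vector with elements \code{hi}, \code{lo}, \code{out}.
#' @param burnin_factor the ancestral population evolves
#'   \code{burnin_factor * N_anc} generations before the first split.
#' @param retry_cap maximum sweep re-injection attempts.
#' @param seed integer RNG seed; every stochastic draw flows from it.
#' @return a \code{SimConfig} list.
#' @export
simConfig <- function(region_length = 1e6,
                      N_anc = 1000, N_out = 1000, N_hi = 1000, N_lo = 1000,
                      t_out_split = 600, t_hilo_split = 200,
                      mu = 1e-7, rho = 1e-7,
                      sweep = list(position = 5e5, s = 0.05, t_start = 180,
                                   condition_on_establishment = TRUE),
                      n_sample = 10, burnin_factor = 10, retry_cap = 1000,
                      seed = 1L) {
  cfg <- list(region_length = as.numeric(region_length),
              N_anc = as.integer(N_anc), N_out = as.integer(N_out),
              N_hi = as.integer(N_hi), N_lo = as.integer(N_lo),
              t_out_split = if (is.null(t_out_split)) NULL else as.integer(t_out_split),
              t_hilo_split = if (is.null(t_hilo_split)) NULL else as.integer(t_hilo_split),
              mu = mu, rho = rho, sweep = sweep,
              n_sample = n_sample, burnin_factor = burnin_factor,
              retry_cap = as.integer(retry_cap), seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  stopifnot(cfg$region_length >= 1e3, cfg$mu >= 0, cfg$rho >= 0)
  if (!is.null(cfg$t_out_split)) {
    if (is.null(cfg$t_hilo_split))
      stop("an outgroup requires a highland/lowland split (t_hilo_split)")
    if (cfg$t_out_split <= cfg$t_hilo_split)
      stop("t_out_split must exceed t_hilo_split")
  }
  if (!is.null(cfg$t_hilo_split) && cfg$t_hilo_split <= 0)
    stop("t_hilo_split must be positive")
  sw <- cfg$sweep
  if (!is.null(sw)) {
    stopifnot(!is.null(sw$position), !is.null(sw$s), !is.null(sw$t_start))
    if (sw$s <= 0 || sw$s > 1) stop("sweep s must be in (0, 1]")
    if (sw$position < 1 || sw$position > cfg$region_length)
      stop("sweep position outside the simulated region")
    if (!is.null(cfg$t_hilo_split) && sw$t_start >= cfg$t_hilo_split)
      stop("sweep t_start must postdate the highland/lowland split")
  }
  invisible(TRUE)
}

sampleSizes <- function(cfg) {
  ns <- cfg$n_sample
  if (length(ns) == 1L && is.null(names(ns)))
    ns <- c(hi = ns, lo = ns, out = ns)
  ns <- ns[c("hi", "lo", "out")]
  ns[is.na(ns)] <- 0
  as.integer(ns)
}

#' Simulate the three-population design with an optional highland sweep
#'
#' Runs the forward Wright-Fisher engine under \code{config} and returns the
#' sampled phased haplotypes as one pooled [HaplotypePanel-class] (sites =
#' SNPs segregating in the pooled sample; ancestral state known exactly
#' since derived mutations are tracked), the per-population panels on the
#' same site set, and the ground truth.  The same seed gives bit-identical
#' output.
#'
#' @param config a [simConfig()] object.
#' @param chrom chromosome name given to the output.
#' @return list with elements \code{panel} (pooled), \code{panels} (named
#'   list per population), and \code{truth} (a \code{SimTruth} list:
#'   \code{sweep_position}, \code{s}, \code{beneficial_frequency_per_pop},
#'   \code{fixation_generation}, \code{retries}).
#' @export
simulateSweep <- function(config = simConfig(), chrom = "1") {
  validateSimConfig(config)
  set.seed(config$seed)
  sw <- config$sweep
  ns <- sampleSizes(config)
  res <- .wf_sim_cpp(config$region_length, config$N_anc, config$N_out,
                     config$N_hi, config$N_lo,
                     if (is.null(config$t_out_split)) 0L else config$t_out_split,
                     if (is.null(config$t_hilo_split)) 0L else config$t_hilo_split,
                     as.integer(config$burnin_factor * config$N_anc),
                     config$mu, config$rho,
                     if (is.null(sw)) 0 else sw$position,
                     if (is.null(sw)) 0 else sw$s,
                     if (is.null(sw)) 0L else as.integer(sw$t_start),
                     if (is.null(sw)) TRUE else
                       !isFALSE(sw$condition_on_establishment),
                     config$retry_cap,
                     2L * ns[1], 2L * ns[2], 2L * ns[3])
  labels <- res$pop_labels
  pop_of_hap <- labels[res$pop_index + 1L]
  n_hap <- length(pop_of_hap)
  pop_first <- pop_of_hap[seq(1, n_hap, 2)]
  within_idx <- stats::ave(seq_along(pop_first), pop_first, FUN = seq_along)
  ids <- paste0(pop_first, "_", within_idx)
  sample_ids <- rep(ids, each = 2)
  pm <- setNames(pop_first, ids)
  panel <- HaplotypePanel(chrom = chrom, positions = res$positions,
                          haplotypes = res$matrix, sampleIds = sample_ids,
                          popOf = pm,
                          ancestral = rep(0L, length(res$positions)))
  panels <- lapply(setNames(as.character(labels), labels), function(lb) {
    rows <- which(hapPopulations(panel) == lb)
    keep_samples <- unique(panel@sampleIds[rows])
    initialize(panel,
               haplotypes = panel@haplotypes[rows, , drop = FALSE],
               sampleIds = panel@sampleIds[rows],
               popOf = panel@popOf[keep_samples])
  })
  bf <- setNames(as.numeric(res$beneficial_freq), labels)
  truth <- list(sweep_position = if (is.null(sw)) NA_real_ else sw$position,
                s = if (is.null(sw)) NA_real_ else sw$s,
                beneficial_frequency_per_pop = if (is.null(sw))
                  setNames(rep(NA_real_, length(bf)), names(bf)) else bf,
                fixation_generation = if (is.null(sw) ||
                                          res$fixation_generation < 0)
                  NA_integer_ else res$fixation_generation,
                retries = res$retries,
                sweep_lost = isTRUE(res$sweep_lost))
  class(truth) <- "SimTruth"
  list(panel = panel, panels = panels, truth = truth)
}

#' Simulate a single panmictic Wright-Fisher population
#'
#' Neutral-equilibrium single-population runs used for calibration (site
#' frequency spectrum, iHS standardization).  Same engine as
#' [simulateSweep()].
#'
#' @param region_length region length (bp).
#' @param N haploid population size.
#' @param mu,rho per-bp per-generation rates.
#' @param n_sample diploids sampled.
#' @param burnin_factor burn-in of \code{burnin_factor * N} generations.
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @return a [HaplotypePanel-class] (population label \code{"hi"}).
#' @export
wfPanmictic <- function(region_length = 1e6, N = 1000, mu = 1e-7, rho = 1e-7,
                        n_sample = 10, burnin_factor = 10, seed = 1L,
                        chrom = "1") {
  cfg <- simConfig(region_length = region_length, N_anc = N, N_out = N,
                   N_hi = N, N_lo = N, t_out_split = NULL,
                   t_hilo_split = NULL, mu = mu, rho = rho, sweep = NULL,
                   n_sample = c(hi = n_sample, lo = 0, out = 0),
                   burnin_factor = burnin_factor, seed = seed)
  simulateSweep(cfg, chrom = chrom)$panel
}

#' Write / read simulation ground truth as TSV
#'
#' @param truth a \code{SimTruth} list from [simulateSweep()].
#' @param path output TSV; missing values are written as \code{"NA"}.
#' @return \code{path} (write) / a \code{SimTruth} list (read).
#' @export
writeTruth <- function(truth, path) {
  bf <- truth$beneficial_frequency_per_pop
  df <- data.frame(
    sweep_position = truth$sweep_position, s = truth$s,
    fixation_generation = truth$fixation_generation,
    retries = truth$retries,
    pop = names(bf), beneficial_frequency = unname(bf))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  truth <- list(sweep_position = df$sweep_position[1], s = df$s[1],
                beneficial_frequency_per_pop =
                  setNames(df$beneficial_frequency, df$pop),
                fixation_generation = as.integer(df$fixation_generation[1]),
                retries = df$retries[1],
                sweep_lost = FALSE)
  class(truth) <- "SimTruth"
  truth
}
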