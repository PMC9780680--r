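# Shared simulation replicate sets for the stochastic checks.  Built once
# per test session and reused across files.  The configs are the package's
# reference study conditions: 1 Mb, N = 1000 haploids per population,
# hi/lo split 200 generations ago, outgroup 600, hard sweep s = 0.05 at
# the region centre on the highland branch; 30 diploids sampled per
# altitude-class branch (the pooled-class scale of the study design) and
# 10 from the outgroup.

.repcache <- new.env(parent = emptyenv())

accConfig <- function(seed, sweep = TRUE) {
  simConfig(
    sweep = if (sweep) list(position = 5e5, s = 0.05, t_start = 180,
                            condition_on_establishment = TRUE) else NULL,
    n_sample = c(hi = 30, lo = 30, out = 10),
    seed = seed)
}

getReps <- function(kind = c("sweep", "neutral"), n = 20) {
  kind <- match.arg(kind)
  key <- paste0(kind, "_", n)
  if (!exists(key, envir = .repcache)) {
    base <- if (kind == "sweep") 7000L else 8000L
    reps <- lapply(seq_len(n), function(i)
      simulateSweep(accConfig(base + i, sweep = kind == "sweep")))
    assign(key, reps, envir = .repcache)
  }
  get(key, envir = .repcache)
}

# distance (bp) from a half-open window row to a 1-based site; 0 if inside
windowSiteDist <- function(start0, end0, site) {
  if (site > start0 && site <= end0) return(0)
  min(abs(start0 + 1 - site), abs(end0 - site))
}

# desk-scale three-way intersection rule: top-decile iHS and XP-CLR windows,
# windowed PBS >= 0.2; scans with no eligible windows contribute nothing
threeWayIntersection <- function(ws, xp, pw) {
  safeOut <- function(tab, ...) tryCatch(callOutliers(tab, ...),
                                         error = function(e) tab[0, ])
  ihs_out <- safeOut(ws, "top_fraction", 0.1, minSnps = 10)
  xp$method <- "xpclr"
  xp_out <- safeOut(xp, "top_fraction", 0.1, minSnps = 10)
  pw$method <- "pbs"
  pbs_out <- safeOut(pw, "threshold", 0.2, minSnps = 3)
  intersectRegions(
    intersectRegions(mergeRegions(ihs_out), mergeRegions(xp_out)),
    mergeRegions(pbs_out))
}
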