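# Forward Wright-Fisher simulator: contracts, determinism, neutral
# expectations.

test_that("config validation enforces the demography and sweep contracts", {
  expect_error(simConfig(t_out_split = 100, t_hilo_split = 200),
               "must exceed")
  expect_error(simConfig(sweep = list(position = 2e6, s = 0.05,
                                      t_start = 100)),
               "outside")
  expect_error(simConfig(sweep = list(position = 5e5, s = 1.5,
                                      t_start = 100)), "in \\(0, 1\\]")
  expect_error(simConfig(sweep = list(position = 5e5, s = 0.05,
                                      t_start = 300)), "postdate")
})

test_that("mu = 0 with no sweep yields zero segregating sites", {
  cfg <- simConfig(region_length = 1e4, N_anc = 50, N_hi = 50, N_lo = 50,
                   N_out = 50, t_out_split = 30, t_hilo_split = 20,
                   mu = 0, rho = 1e-5, sweep = NULL, n_sample = 5, seed = 3)
  res <- simulateSweep(cfg)
  expect_equal(nSites(res$panel), 0L)
  expect_true(all(vapply(res$panels, nSites, integer(1)) == 0L))
})

test_that("a fixed seed reproduces the VCF byte for byte", {
  cfg <- simConfig(region_length = 5e4, N_anc = 100, N_hi = 100, N_lo = 100,
                   N_out = 100, t_out_split = 60, t_hilo_split = 30,
                   mu = 1e-6, rho = 1e-6,
                   sweep = list(position = 2.5e4, s = 0.1, t_start = 25),
                   n_sample = 5, seed = 99)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  writeVcfPanel(simulateSweep(cfg)$panel, f1)
  writeVcfPanel(simulateSweep(cfg)$panel, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("simulated panels carry exact ancestral polarity and pop labels", {
  cfg <- simConfig(region_length = 5e4, N_anc = 100, N_hi = 100, N_lo = 100,
                   N_out = 100, t_out_split = 60, t_hilo_split = 30,
                   mu = 1e-6, rho = 1e-6, sweep = NULL, n_sample = 5,
                   seed = 12)
  res <- simulateSweep(cfg)
  expect_true(all(ancestralCode(res$panel) == 0L))
  expect_equal(sort(unique(hapPopulations(res$panel))),
               c("hi", "lo", "out"))
  expect_equal(nHaplotypes(res$panels$hi), 10L)
  # per-population panels share the pooled site set
  expect_identical(sitePositions(res$panels$lo),
                   sitePositions(res$panel))
})

test_that("truth files round-trip, with NA for neutral runs", {
  truth <- list(sweep_position = 5e5, s = 0.05,
                beneficial_frequency_per_pop = c(hi = 0.95, lo = 0, out = 0),
                fixation_generation = NA_integer_, retries = 3,
                sweep_lost = FALSE)
  class(truth) <- "SimTruth"
  f <- tempfile(fileext = ".tsv")
  writeTruth(truth, f)
  back <- readTruth(f)
  expect_equal(back$sweep_position, truth$sweep_position)
  expect_equal(back$beneficial_frequency_per_pop,
               truth$beneficial_frequency_per_pop)
  expect_true(is.na(back$fixation_generation))
  neutral <- truth
  neutral$sweep_position <- NA_real_; neutral$s <- NA_real_
  writeTruth(neutral, f)
  expect_true(any(grepl("NA\tNA", readLines(f))))
  expect_true(is.na(readTruth(f)$s))
})

test_that("neutral site frequency spectrum is consistent with 1/i", {
  # aggregate >= 10,000 SNPs over panmictic replicates; recombination is
  # set high enough that sites are effectively independent, as the
  # chi-square requires (tightly linked sites share a genealogy and
  # inflate the statistic regardless of the true SFS)
  counts <- integer(0)
  n_hap <- NULL
  for (s in 1:6) {
    p <- wfPanmictic(region_length = 5e5, N = 500, mu = 1e-6, rho = 2e-5,
                     n_sample = 10, seed = 500 + s)
    n_hap <- nHaplotypes(p)
    counts <- c(counts, colSums(hapMatrix(p)))
  }
  expect_gte(length(counts), 10000)
  obs <- tabulate(counts, nbins = n_hap - 1)
  expected <- (1 / seq_len(n_hap - 1)) / sum(1 / seq_len(n_hap - 1))
  gof <- chisq.test(obs, p = expected)
  expect_gt(gof$p.value, 0.01)
})

test_that("conditioned sweeps establish and approach fixation", {
  reps <- getReps("sweep")
  freqs <- vapply(reps, function(r)
    r$truth$beneficial_frequency_per_pop[["hi"]], numeric(1))
  expect_true(all(freqs > 0))
  expect_gte(mean(freqs > 0.9), 0.8)
  # the sweep allele never leaks into the other branches
  others <- vapply(reps, function(r)
    max(r$truth$beneficial_frequency_per_pop[c("lo", "out")]), numeric(1))
  expect_true(all(others == 0))
})

test_that("diversity dips at the sweep site relative to the region edges", {
  reps <- getReps("sweep")
  win <- makeWindows(1e6, size = 1e5, step = 1e5, chrom = "1")
  ratio <- vapply(reps, function(r) {
    pw <- piWindows(r$panels$hi, "hi", win)
    centre <- pw$pi[pw$start == 4e5 | pw$start == 5e5]
    edges <- pw$pi[pw$start %in% c(0, 9e5)]
    mean(centre) - mean(edges)
  }, numeric(1))
  expect_lt(mean(ratio), 0)
  expect_gt(mean(ratio < 0), 0.8)
})
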