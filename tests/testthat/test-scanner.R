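# Windowing, outlier calling, region merging, intersection, annotation.

test_that("window grids enumerate correctly", {
  w <- makeWindows(1e6)
  expect_equal(length(w), 19L)
  b <- bedBounds(w)
  expect_equal(b$start[1], 0L)
  expect_equal(c(b$start[19], b$end[19]), c(900000L, 1000000L))
  expect_equal(length(makeWindows(5000, size = 5000, step = 5000)), 1L)
  expect_warning(w0 <- makeWindows(99999, size = 100000), "no windows")
  expect_equal(length(w0), 0L)
})

test_that("window count matches loop enumeration on random geometries", {
  set.seed(5)
  for (i in 1:100) {
    L <- sample(1e4:1e6, 1)
    size <- sample(1e3:2e5, 1)
    step <- sample(1e2:size, 1)
    n <- suppressWarnings(length(makeWindows(L, size, step)))
    expect_equal(n, windowCountOracle(L, size, step))
  }
})

test_that("the coordinate rule puts 1-based positions into half-open windows", {
  w <- bedRanges("1", c(0, 100), c(100, 200))
  # position p in [a, b) iff a < p <= b
  idx <- altiscan:::sitesInWindows(c(1L, 100L, 101L, 200L, 201L), w, "1")
  expect_equal(idx[[1]], c(1L, 2L))
  expect_equal(idx[[2]], c(3L, 4L))
})

test_that("summarizeTrack reducers behave and empty windows give NA", {
  w <- makeWindows(30000, 10000, 10000)
  s <- summarizeTrack(c(5000L, 15000L, 16000L), c(5.9, 6.1, 7.2), w,
                      reducer = "count_above", threshold = 6)
  expect_equal(s$value, c(0, 2, NA))
  s2 <- summarizeTrack(c(5000L, 15000L, 16000L), c(5.9, 6.1, 7.2), w, "max")
  expect_equal(s2$value, c(5.9, 7.2, NA))
  s3 <- summarizeTrack(c(5000L, 15000L, 16000L), c(5.9, 6.1, 7.2), w, "mean")
  expect_true(all(s2$value >= s3$value, na.rm = TRUE))
  expect_error(summarizeTrack(1L, 1, w, "count_above"), "threshold")
})

test_that("outlier calling honours thresholds, fractions and tie rules", {
  w <- data.frame(chrom = "1", start = seq(0, 999) * 1000,
                  end = seq(0, 999) * 1000 + 1000,
                  value = c(0.19, 0.2, 0.35, runif(997, 0, 0.1)),
                  n_snps = 20L)
  thr <- callOutliers(w, "threshold", 0.2, minSnps = 10)
  expect_equal(nrow(thr), 2L)   # >= semantics keeps 0.2
  top <- callOutliers(w, "top_fraction", 0.005, minSnps = 10)
  expect_equal(nrow(top), 5L)   # ceiling(0.005 * 1000)
  # deterministic tie-breaking at the cut
  w2 <- data.frame(chrom = "1", start = seq(0, 9) * 1000,
                   end = seq(0, 9) * 1000 + 1000,
                   value = c(rep(1, 5), rep(0.5, 5)), n_snps = 20L)
  t1 <- callOutliers(w2, "top_fraction", 0.3)
  t2 <- callOutliers(w2, "top_fraction", 0.3)
  expect_identical(t1, t2)
  expect_equal(t1$start, c(0, 1000, 2000))
  expect_error(callOutliers(w2, "top_fraction", 1.5), "in \\(0,1\\)")
  # min_snps excludes before ranking
  w$n_snps[2] <- 3L
  expect_equal(nrow(callOutliers(w, "threshold", 0.2, minSnps = 10)), 1L)
})

test_that("region merging unions overlapping and book-ended windows", {
  o <- data.frame(chrom = "1", start = c(100000, 150000),
                  end = c(200000, 250000), value = c(1, 2),
                  n_snps = 10L, method = "ihs")
  r <- mergeRegions(o)
  expect_equal(bedBounds(r)$start, 100000L)
  expect_equal(bedBounds(r)$end, 250000L)     # 150 kb from one overlap
  expect_equal(r$peak_value, 2)
  # chain of k consecutive 50 kb-step outliers -> 50k*(k-1) + 100k
  k <- 5
  chain <- data.frame(chrom = "1", start = seq(0, by = 50000, length.out = k),
                      end = seq(0, by = 50000, length.out = k) + 100000,
                      value = 1, n_snps = 10L, method = "ihs")
  rc <- mergeRegions(chain)
  expect_equal(length(rc), 1L)
  expect_equal(bedBounds(rc)$end - bedBounds(rc)$start,
               50000 * (k - 1) + 100000)
  # disjoint windows unchanged; merging is order independent and idempotent
  dis <- data.frame(chrom = "1", start = c(0, 300000), end = c(100000, 400000),
                    value = 1:2, n_snps = 10L, method = "ihs")
  expect_equal(length(mergeRegions(dis)), 2L)
  shuf <- chain[sample(nrow(chain)), ]
  expect_equal(bedBounds(mergeRegions(shuf)), bedBounds(rc))
})

test_that("intersection works in region and gene modes", {
  a <- bedRanges("1", 100000, 300000)
  b <- bedRanges("1", 250000, 400000)
  ov <- intersectRegions(a, b)
  expect_equal(bedBounds(ov)$start, 250000L)
  expect_equal(bedBounds(ov)$end, 300000L)
  expect_equal(length(intersectRegions(a, bedRanges("1", 5e5, 6e5))), 0L)
  a$genes <- IRanges::CharacterList(list(c("x", "y", "z")))
  b$genes <- IRanges::CharacterList(list(c("y", "z", "w")))
  expect_setequal(intersectRegions(a, b, "gene"), c("y", "z"))
})

test_that("gene annotation respects half-open overlap semantics", {
  genes <- bedRanges("1", c(120000, 200000, 90000), c(140000, 220000, 110000))
  genes$name <- c("inside", "abutting", "spanning")
  region <- bedRanges("1", 100000, 200000)
  ann <- annotateGenes(region, genes)
  got <- unlist(ann$genes)
  expect_true("inside" %in% got)
  expect_true("spanning" %in% got)
  expect_false("abutting" %in% got)  # gene starting at region end
})
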