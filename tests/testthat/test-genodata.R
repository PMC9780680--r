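# VCF / population-map / gene ingestion and panel subsetting.

write_test_vcf <- function(path, records,
                           samples = c("s1", "s2")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

test_that("phased biallelic records ingest into a haplotype panel", {
  f <- write_test_vcf(tempfile(fileext = ".vcf"), c(
    "1\t100\t.\tA\tG\t.\t.\t.\tGT\t0|1\t1|1",
    "1\t200\t.\tC\tT\t.\t.\tAA=T\tGT\t0|0\t0|1",
    "1\t300\t.\tG\tA\t.\t.\tAA=C\tGT\t1|0\t0|0"))
  p <- readVcfPanel(f)
  expect_equal(nHaplotypes(p), 4L)
  expect_equal(nSites(p), 3L)
  expect_equal(sitePositions(p), c(100L, 200L, 300L))
  expect_equal(hapMatrix(p)[, 1], c(0L, 1L, 1L, 1L))
  # AA=T matches ALT at site 2 -> ancestral code 1; AA=C matches neither
  expect_equal(ancestralCode(p), c(NA_integer_, 1L, NA_integer_))
})

test_that("unphased, half-called and multi-allelic records are skipped", {
  f <- write_test_vcf(tempfile(fileext = ".vcf"), c(
    "1\t100\t.\tA\tG\t.\t.\t.\tGT\t0|1\t1|1",
    "1\t150\t.\tA\tG\t.\t.\t.\tGT\t0/1\t1|1",
    "1\t160\t.\tA\tG\t.\t.\t.\tGT\t.|1\t1|1",
    "1\t170\t.\tA\tG,T\t.\t.\t.\tGT\t0|1\t1|1"))
  expect_message(p <- readVcfPanel(f), "skipped")
  expect_equal(nSites(p), 1L)
  expect_equal(sitePositions(p), 100L)
})

test_that("a VCF with no usable records errors explicitly", {
  f <- write_test_vcf(tempfile(fileext = ".vcf"),
                      "1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/1\t0/0")
  expect_error(suppressMessages(readVcfPanel(f)), "no usable")
})

test_that("VCF round-trip is byte-identical for conforming input", {
  f <- write_test_vcf(tempfile(fileext = ".vcf"), c(
    "1\t100\t.\tA\tG\t.\t.\tAA=A\tGT\t0|1\t1|1",
    "1\t200\t.\tC\tT\t.\t.\t.\tGT\t0|0\t0|1",
    "1\t300\t.\tG\tA\t.\t.\tAA=A\tGT\t1|0\t0|0"))
  p <- readVcfPanel(f)
  f2 <- tempfile(fileext = ".vcf")
  writeVcfPanel(p, f2)
  expect_identical(readLines(f2), readLines(f))
  # and a second cycle through the canonical writer is a fixed point
  f3 <- tempfile(fileext = ".vcf")
  writeVcfPanel(readVcfPanel(f2), f3)
  expect_identical(readBin(f3, "raw", file.size(f3)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("population map rejects duplicates and empty files", {
  f <- tempfile()
  writeLines(c("s1\thi", "s2\tlo", "s3\thi"), f)
  pm <- readPopMap(f)
  expect_equal(unname(pm["s3"]), "hi")
  expect_length(pm, 3)
  writeLines(c("s1\thi", "s1\tlo"), f)
  expect_error(readPopMap(f), "duplicated")
  writeLines(character(0), f)
  expect_error(readPopMap(f), "empty|unreadable")
})

test_that("subsetPanel filters by population and strict MAF", {
  m <- rbind(c(1, 0, 1, 0), c(0, 0, 1, 0), c(0, 0, 1, 1), c(0, 0, 0, 1),
             c(0, 1, 0, 1), c(0, 1, 0, 1))
  p <- makeTestPanel(m, pops = c("hi", "hi", "lo"))
  # hi only: site1 freq 1/4 kept at maf 0.05; site2 monomorphic dropped;
  # site3 2/4 kept; site4 1/4 kept
  s <- subsetPanel(p, "hi", mafMin = 0.05)
  expect_equal(nHaplotypes(s), 4L)
  expect_equal(nSites(s), 3L)
  # pooled MAF exactly at the cutoff is excluded (strict >)
  s2 <- subsetPanel(p, c("hi", "lo"), mafMin = 1 / 6)
  expect_false(1000L %in% sitePositions(s2))  # site1 freq 1/6
  expect_error(subsetPanel(p, "nope"), "valid labels")
})

test_that("subsetPanel is idempotent and bounds retained frequencies", {
  for (seed in 1:10) {
    p <- randomPanel(10, 30, seed = seed)
    pops <- sample(c("hi", "lo"), 5, replace = TRUE)
    p@popOf <- stats::setNames(pops, names(p@popOf))
    s1 <- subsetPanel(p, "hi", mafMin = 0.1)
    if (!any(pops == "hi")) next
    s2 <- subsetPanel(s1, "hi", mafMin = 0.1)
    expect_identical(hapMatrix(s1), hapMatrix(s2))
    expect_identical(sitePositions(s1), sitePositions(s2))
    if (nSites(s1)) {
      f <- colMeans(hapMatrix(s1))
      expect_true(all(f > 0.1 & f < 0.9))
    }
  }
})

test_that("monomorphic sites are removed even at mafMin = 0", {
  m <- rbind(c(1, 1), c(0, 1), c(1, 1), c(0, 1))
  p <- makeTestPanel(m)
  s <- subsetPanel(p, "pop1", mafMin = 0)
  expect_equal(nSites(s), 1L)
  expect_equal(sitePositions(s), 1000L)
})

test_that("BED and GFF3 genes land on the shared half-open convention", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("1\t100\t200\tgeneA", "1\t300\t400\tgeneB"), bed)
  gb <- readGenes(bed)
  expect_equal(bedBounds(gb)$start, c(100L, 300L))
  expect_equal(bedBounds(gb)$end, c(200L, 400L))
  expect_equal(gb$name, c("geneA", "geneB"))

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1;Name=geneA",
               "1\tsrc\texon\t101\t150\t.\t+\t.\tID=e1;Parent=g1",
               "1\tsrc\tgene\t301\t400\t.\t-\t.\tID=g2"), gff)
  gg <- readGenes(gff)
  expect_equal(length(gg), 2L)  # exon ignored
  # GFF3 1-based closed 101..200 == BED 100..200
  expect_equal(bedBounds(gg)$start[1], 100L)
  expect_equal(bedBounds(gg)$end[1], 200L)
  expect_equal(gg$name, c("geneA", "g2"))
})

test_that("polarization policies fill unknown ancestral states", {
  m <- rbind(c(1, 0), c(0, 0), c(1, 1), c(1, 1))
  p <- makeTestPanel(m, pops = c("hi", "out"),
                     ancestral = c(NA, NA))
  expect_message(r <- polarizePanel(p, "ref-ancestral"), "polarizing")
  expect_equal(ancestralCode(r), c(0L, 0L))
  o <- polarizePanel(p, "outgroup-major", outgroup = "out")
  # outgroup (rows 3-4) alt freq: site1 = 1 -> alt ancestral; site2 = 1
  expect_equal(ancestralCode(o), c(1L, 1L))
  expect_identical(ancestralCode(polarizePanel(p, "skip")),
                   c(NA_integer_, NA_integer_))
})
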