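gr <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

test_that("merge fuses at gap <= 100 bp and is idempotent", {
  ## 0-based half-open [0,100) and [150,250) have gap 50: fuse
  m <- mergePeaks(gr("chr1", c(1, 151), c(100, 250)))
  expect_equal(length(m), 1L)
  expect_equal(c(GenomicRanges::start(m), GenomicRanges::end(m)),
               c(1L, 250L))

  ## [0,100) and [201,300): gap 101, strict rule keeps them apart
  m2 <- mergePeaks(gr("chr1", c(1, 202), c(100, 300)))
  expect_equal(length(m2), 2L)
  ## gap exactly 100 fuses
  m3 <- mergePeaks(gr("chr1", c(1, 201), c(100, 300)))
  expect_equal(length(m3), 1L)

  single <- gr("chr1", 10, 60)
  expect_equal(grToDf(mergePeaks(single)), grToDf(single))

  set.seed(17)
  for (i in 1:30) {
    x <- gr(sample(c("chr1", "chr2"), 30, TRUE),
            s <- sample(1:5000, 30), s + sample(50:400, 30, TRUE))
    once <- mergePeaks(x)
    expect_equal(grToDf(mergePeaks(once)), grToDf(once))
  }
})

test_that("merge equals the brute-force pairwise-fusion oracle", {
  set.seed(18)
  for (i in 1:200) {
    n <- sample(2:50, 1)
    start <- sample(1:8000, n, replace = TRUE)
    x <- gr(sample(c("chr1", "chr2"), n, TRUE), start,
            start + sample(10:500, n, replace = TRUE))
    expect_equal(grToDf(mergePeaks(x)), mergeOracle(grToDf(x)),
                 ignore_attr = TRUE)
  }
})

test_that("reference construction merges the union of conditions", {
  a <- gr("chr1", c(1, 1000), c(200, 1200))
  b <- gr("chr1", c(1, 1000), c(200, 1200))
  ref <- buildReference(list(A = a, B = b))
  expect_equal(grToDf(ref), grToDf(a))

  far <- gr("chr1", 5000, 5200)
  ref2 <- buildReference(list(A = a, B = far))
  expect_equal(length(ref2), 3L)

  ## overlapping peaks across conditions fuse per the gap rule
  c1 <- gr("chr1", c(1, 500, 2000), c(100, 700, 2100))
  c2 <- gr("chr1", c(150, 760, 5000), c(300, 900, 5100))
  ref3 <- buildReference(list(A = c1, B = c2))
  ## by hand: 1-100 + 150-300 fuse (gap 49); 500-700 + 760-900 fuse
  ## (gap 59); 2000-2100 and 5000-5100 stay
  expect_equal(grToDf(ref3),
               data.frame(chrom = "chr1",
                          start = c(1L, 500L, 2000L, 5000L),
                          end = c(300L, 900L, 2100L, 5100L)),
               ignore_attr = TRUE)

  expect_warning(empty <- buildReference(list(A = gr("chr1", 1, 10)[0])),
                 "empty union")
  expect_equal(length(empty), 0L)
})

test_that("occupancy labels open on >= 1 bp overlap", {
  ref <- gr("chr1", c(100, 500, 900), c(200, 600, 1000))
  conds <- list(
    X = gr("chr1", 50, 250),       # covers peak 1 fully
    Y = gr("chr1", 200, 251)       # 1-bp overlap with peak 1 only
  )
  occ <- labelOccupancy(ref, conds)
  st <- occupancyStates(occ)
  expect_identical(unname(st[, "X"]), c(TRUE, FALSE, FALSE))
  expect_identical(unname(st[, "Y"]), c(TRUE, FALSE, FALSE))
  expect_identical(occupancyConditions(occ), c("X", "Y"))

  ## half-open arithmetic: [100,200) vs [199,250) share exactly 1 bp
  occ1 <- labelOccupancy(gr("chr1", 101, 200),
                         list(Z = gr("chr1", 200, 250)))
  expect_true(occupancyStates(occ1)[1, "Z"])
  occ0 <- labelOccupancy(gr("chr1", 101, 200),
                         list(Z = gr("chr1", 201, 250)))
  expect_false(occupancyStates(occ0)[1, "Z"])
})

test_that("pattern encoding produces C/O codes in condition order", {
  ref <- gr("chr1", 100, 200)
  st <- matrix(c(FALSE, FALSE, TRUE, FALSE), nrow = 1,
               dimnames = list(NULL, c("WT", "FL", "TR", "LTR")))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(state = st), rowRanges = ref,
    colData = S4Vectors::DataFrame(row.names = colnames(st)))
  occ <- new("OccupancyMatrix", se)
  enc <- encodePatterns(occ, c("WT", "FL", "TR", "LTR"))
  expect_identical(enc$codes, "CCOC")

  ## 16 rows covering every combination appear once each
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 4)))
  colnames(grid) <- c("WT", "FL", "TR", "LTR")
  se16 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(state = grid),
    rowRanges = gr("chr1", seq(1, by = 1000, length.out = 16),
                   seq(200, by = 1000, length.out = 16)),
    colData = S4Vectors::DataFrame(row.names = colnames(grid)))
  enc16 <- encodePatterns(new("OccupancyMatrix", se16),
                          c("WT", "FL", "TR", "LTR"))
  expect_length(enc16$counts, 16L)
  expect_true(all(enc16$counts == 1L))
  expect_equal(sum(enc16$counts), 16L)

  expect_error(encodePatterns(occ, c("WT", "FL", "TR", "XX")),
               "permutation")
})

test_that("generator patterns are recovered exactly (round trip)", {
  freq <- c(OOOO = 0.3, CCOC = 0.25, CCOO = 0.2, OCCO = 0.15,
            CCCC = 0.1)
  sim <- simulatePeakSets(n = 200, patternFreq = freq, seed = 23)
  merged <- lapply(sim$peakSets, mergePeaks)
  ref <- buildReference(merged)
  occ <- labelOccupancy(ref, merged)
  enc <- encodePatterns(occ, c("EV", "FL", "TR", "LTR"))
  expect_identical(enc$counts[order(names(enc$counts))],
                   sim$pattern_counts[order(names(sim$pattern_counts))])
  ## conservation: pattern counts sum to the number of reference peaks
  expect_equal(sum(enc$counts), length(ref))
})

test_that("transition queries compute conditional fractions", {
  freq <- c(CCOO = 0.35, CCOC = 0.45, OOOO = 0.2)
  sim <- simulatePeakSets(n = 400, patternFreq = freq, seed = 29)
  occ <- labelOccupancy(buildReference(sim$peakSets), sim$peakSets)
  ## of the peaks closed in FL and open in TR, fraction open in LTR
  q <- queryTransition(occ,
    function(st) !st[, "FL"] & st[, "TR"],
    fractionOpenIn = "LTR")
  counts <- table(sim$truth$pattern)
  expect_equal(q$n, sum(counts[c("CCOO", "CCOC")]))
  expect_equal(q$fraction,
               counts[["CCOO"]] / (counts[["CCOO"]] + counts[["CCOC"]]))

  ## empty base set is flagged
  q0 <- queryTransition(occ, function(st) rep(FALSE, nrow(st)),
                        fractionOpenIn = "LTR")
  expect_true(q0$flagged)
  expect_true(is.na(q0$fraction))

  ## predicate always true: marginal open rate of the queried condition
  qa <- queryTransition(occ, function(st) rep(TRUE, nrow(st)),
                        fractionOpenIn = "TR")
  expect_equal(qa$fraction, mean(occupancyStates(occ)[, "TR"]))
})

test_that("peak sampling is seeded and preserves pattern frequencies", {
  sim <- simulatePeakSets(n = 600,
                          patternFreq = c(OOOO = 0.5, CCOC = 0.5),
                          seed = 31)
  occ <- labelOccupancy(buildReference(sim$peakSets), sim$peakSets)
  s1 <- samplePeaks(occ, n = 200, seed = 7)
  s2 <- samplePeaks(occ, n = 200, seed = 7)
  expect_identical(s1$index, s2$index)
  expect_length(s1$index, 200L)
  expect_equal(nrow(s1$long), 200L * 4L)

  all <- samplePeaks(occ, n = nrow(occ), seed = 1)
  expect_identical(all$index, seq_len(nrow(occ)))
  expect_warning(samplePeaks(occ, n = nrow(occ) + 10, seed = 1),
                 "exceeds")
})

test_that("BED round trip preserves intervals", {
  x <- gr("chr1", c(101, 501), c(200, 700))
  tmp <- withr::local_tempfile(fileext = ".bed")
  writePeakBed(x, tmp)
  y <- readPeakBed(tmp)
  expect_equal(grToDf(y), grToDf(x), ignore_attr = TRUE)
  ## BED is 0-based half-open on disk
  raw <- read.table(tmp, sep = "\t")
  expect_equal(raw$V2, c(100L, 500L))
  expect_equal(raw$V3, c(200L, 700L))
  expect_error(readPeakBed("does-not-exist.bed"), "no such BED")
})
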