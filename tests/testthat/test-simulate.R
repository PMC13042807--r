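test_that("sequence generator honors block layout and is seed-deterministic", {
  b <- data.frame(label = "k", length = 10)
  b$weights <- list(c(K = 1))
  expect_identical(simulateSequence(b, seed = 1)$sequence, "KKKKKKKKKK")

  b2 <- data.frame(label = c("basic", "acidic"), length = c(30, 30))
  b2$weights <- list(c(K = 1), c(E = 1))
  sim <- simulateSequence(b2, seed = 7)
  expect_equal(sim$annotation$ncpr, c(1, -1))
  expect_equal(sim$annotation$charge_sign, c(1, -1))
  expect_equal(sim$annotation$start, c(1, 31))
  expect_equal(sim$annotation$end, c(30, 60))

  b3 <- data.frame(label = c("a", "b"), length = c(50, 50))
  b3$weights <- list(c(K = 0.3, G = 0.7), c(E = 0.5, S = 0.5))
  expect_identical(simulateSequence(b3, seed = 3)$sequence,
                   simulateSequence(b3, seed = 3)$sequence)

  bad <- data.frame(label = "x", length = 0)
  bad$weights <- list(c(K = 1))
  expect_error(simulateSequence(bad, seed = 1), "zero-length")
})

test_that("image generator: background, zero-amplitude puncta, determinism, bounds", {
  flat <- simulateNucleusImage(shape = c(40, 40), nucleusRadius = 15,
                               background = 30, seed = 1)
  expect_true(all(imageIntensity(flat$image)[nucleusMask(flat$image)] == 30))
  expect_true(all(imageIntensity(flat$image)[!nucleusMask(flat$image)] == 0))
  expect_equal(flat$area_fraction, 0)

  zeroAmp <- simulateNucleusImage(shape = c(40, 40), nucleusRadius = 15,
                                  background = 30,
                                  puncta = data.frame(row = 20, col = 20,
                                                      sigma = 2,
                                                      amplitude = 0),
                                  seed = 1)
  expect_identical(imageIntensity(zeroAmp$image),
                   imageIntensity(flat$image))

  a <- simulateNucleusImage(noiseSd = 3, seed = 9,
    puncta = data.frame(row = 60, col = 60, sigma = 3, amplitude = 20))
  b <- simulateNucleusImage(noiseSd = 3, seed = 9,
    puncta = data.frame(row = 60, col = 60, sigma = 3, amplitude = 20))
  expect_identical(imageIntensity(a$image), imageIntensity(b$image))

  expect_error(
    simulateNucleusImage(shape = c(40, 40), nucleusRadius = 5,
                         puncta = data.frame(row = 2, col = 2, sigma = 1,
                                             amplitude = 5)),
    "inside the nucleus")
})

test_that("pbFRET generator satisfies the forward model when noiseless", {
  r <- simulatePbfretRois(efficiency = 0, drift = 1, dPre = 90)
  expect_equal(r$D_post, r$D_pre)

  r <- simulatePbfretRois(efficiency = 0.1, drift = 1, dPre = 90)
  expect_equal(r$D_post, 100)

  r <- simulatePbfretRois(efficiency = 0.25, drift = 0.8, dPre = 60,
                          background = 12)
  expect_equal(r$D_post - 12, (r$D_pre - 12) * 0.8 / (1 - 0.25))
  expect_equal((r$DN_post - 12) / (r$DN_pre - 12), 0.8)

  expect_error(simulatePbfretRois(efficiency = 1), "< 1")
})

test_that("FRAP generator: immobile trace stays flat at bleach level", {
  tr <- simulateFrapTrace(mobileFraction = 0, background = 10,
                          preLevel = 100, bleachDepth = 0.2)
  post <- 6:nrow(tr)
  expect_true(all(tr$bleach[post] == 100 * 0.2 + 10))
  expect_error(simulateFrapTrace(mobileFraction = 1.5), "\\[0, 1\\]")
})

test_that("population generator: degenerate probabilities and intensity dependence", {
  allNeg <- simulatePopulation(model = list(intercept = -50,
                                            groupEffect = 0,
                                            intensityEffect = 0),
                               seed = 1)
  expect_false(any(allNeg$condensate))
  allPos <- simulatePopulation(model = list(intercept = 50,
                                            groupEffect = 0,
                                            intensityEffect = 0),
                               seed = 1)
  expect_true(all(allPos$condensate))
  expect_error(simulatePopulation(nPerGroup = c(A = 0L, B = 10L)),
               "empty group")

  ## intensity-only model: condensation frequency rises across terciles
  pop <- simulatePopulation(nPerGroup = c(A = 5000L, B = 5000L),
                            model = list(intercept = -4,
                                         groupEffect = 0,
                                         intensityEffect = 0.04),
                            seed = 11)
  terc <- cut(pop$intensity,
              stats::quantile(pop$intensity, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE)
  rates <- tapply(pop$condensate, terc, mean)
  expect_true(all(diff(rates) > 0))
})

test_that("peak-set generator: degenerate patterns and seed determinism", {
  allOpen <- simulatePeakSets(n = 50, patternFreq = c(OOOO = 1), seed = 4)
  expect_true(all(vapply(allOpen$peakSets, length, integer(1)) == 50L))

  allClosed <- simulatePeakSets(n = 50, patternFreq = c(CCCC = 1), seed = 4)
  expect_true(all(vapply(allClosed$peakSets, length, integer(1)) == 0L))
  expect_length(allClosed$pattern_counts, 0)

  a <- simulatePeakSets(n = 80, patternFreq = c(OOOO = 0.5, CCOC = 0.5),
                        seed = 6)
  b <- simulatePeakSets(n = 80, patternFreq = c(OOOO = 0.5, CCOC = 0.5),
                        seed = 6)
  expect_identical(a$truth, b$truth)

  expect_error(
    simulatePeakSets(n = 10, patternFreq = c(OOOO = 1),
                     gapRange = c(50, 80)),
    "exceed the merge gap")
})
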