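plateauImage <- function() {
  img <- matrix(5, 30, 30)
  mask <- matrix(TRUE, 30, 30)
  img[10:12, 10:12] <- 30           # 9-px plateau inside the window
  img[20:22, 20:21] <- 30           # 6-px plateau, separated
  NucleusImage(img, mask)
}

test_that("intensity-window segmentation finds connected plateaus", {
  ## constant background below the window: zero foci
  flat <- NucleusImage(matrix(5, 20, 20), matrix(TRUE, 20, 20))
  expect_equal(countPuncta(segmentFoci(flat, window = c(10, 50))), 0)

  img <- plateauImage()
  foci <- segmentFoci(img, window = c(10, 50), minArea = 4)
  expect_equal(countPuncta(foci), 2)
  tab <- fociTable(foci)
  expect_setequal(tab$area, c(9L, 6L))
  expect_setequal(tab$integrated_intensity, c(9 * 30, 6 * 30))

  ## min-area filter removes the smaller plateau
  foci7 <- segmentFoci(img, window = c(10, 50), minArea = 7)
  expect_equal(countPuncta(foci7), 1)
  expect_equal(fociTable(foci7)$area, 9L)
})

test_that("labeling is 8-connected", {
  img <- matrix(0, 10, 10)
  ## two 2x2 blocks touching only diagonally
  img[2:3, 2:3] <- 20
  img[4:5, 4:5] <- 20
  ni <- NucleusImage(img, matrix(TRUE, 10, 10))
  expect_equal(countPuncta(segmentFoci(ni, window = c(10, 50))), 1)
  ## moved apart they are two foci
  img2 <- matrix(0, 10, 10)
  img2[2:3, 2:3] <- 20
  img2[6:7, 6:7] <- 20
  ni2 <- NucleusImage(img2, matrix(TRUE, 10, 10))
  expect_equal(countPuncta(segmentFoci(ni2, window = c(10, 50))), 2)
})

test_that("condensed fractions are ratios of areas and intensities", {
  ## 100-px mask at uniform intensity with a 10-px focus: (0.1, 0.1)
  img <- matrix(0, 10, 12)
  mask <- matrix(FALSE, 10, 12)
  mask[1:10, 1:10] <- TRUE
  img[mask] <- 20
  img[1:2, 1:5] <- 30                        # 10 px inside the window...
  ni <- NucleusImage(img, mask)
  foci <- segmentFoci(ni, window = c(25, 35))
  expect_equal(countPuncta(foci), 1)
  fr <- condensedFractions(ni, foci)
  expect_equal(fr[["area_fraction"]], 0.1)
  expect_equal(fr[["intensity_fraction"]],
               10 * 30 / (10 * 30 + 90 * 20))

  ## zero foci -> (0, 0); foci = whole mask -> (1, 1)
  none <- segmentFoci(ni, window = c(100, 200))
  expect_equal(unname(condensedFractions(ni, none)), c(0, 0))
  all <- segmentFoci(ni, window = c(0, 100))
  expect_equal(unname(condensedFractions(ni, all)), c(1, 1))
})

test_that("fractions recover generator ground truth on a noiseless image", {
  bg <- 20; amp <- 30; sigma <- 3
  sim <- simulateNucleusImage(background = bg,
    puncta = data.frame(row = c(45, 64, 85), col = c(60, 90, 55),
                        sigma = sigma, amplitude = amp))
  ## threshold at the punctum intensity exactly 2*sigma out, so the
  ## segmented disks coincide with the ground-truth radius
  foci <- segmentFoci(sim$image,
                      window = c(bg + amp * exp(-2), bg + amp + 1))
  expect_equal(countPuncta(foci), 3)
  fr <- condensedFractions(sim$image, foci)
  expect_lt(abs(fr[["area_fraction"]] - sim$area_fraction), 0.02)
  expect_lt(abs(fr[["intensity_fraction"]] - sim$intensity_fraction), 0.02)
})

test_that("Pearson colocalization within the mask", {
  set.seed(31)
  a <- matrix(stats::runif(100, 10, 50), 10, 10)
  mask <- matrix(TRUE, 10, 10)
  expect_equal(pearsonColocalization(a, a, mask), 1)
  expect_equal(pearsonColocalization(a, max(a) - a, mask), -1)
  expect_error(pearsonColocalization(a, matrix(1, 10, 10), mask),
               "zero variance")
  ## independent fields decorrelate
  big <- matrix(stats::rnorm(10000), 100, 100)
  big2 <- matrix(stats::rnorm(10000), 100, 100)
  expect_lt(abs(pearsonColocalization(big, big2,
                                      matrix(TRUE, 100, 100))), 0.05)
})
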