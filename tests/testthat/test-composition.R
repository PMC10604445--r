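make_manual_region <- function(values, spacing = c(1, 1)) {
  # values fill a 10x10 region embedded in a 12x12 image
  img <- matrix(0, 12, 12)
  lab <- matrix(0L, 12, 12)
  img[2:11, 2:11] <- values
  lab[2:11, 2:11] <- 1L
  list(image = slice_image(img, spacing),
       mask = roi_mask(lab, data.frame(label = 1L, muscle = "psoas",
                                       side = "left")))
}

test_that("areas convert pixels to cm^2 and FI follows its definition", {
  vals <- matrix(70, 10, 10); vals[1:5, 1:5] <- 100   # 25 fat of 100 px
  fx <- make_manual_region(vals)
  comp <- measure_muscle(fx$image, fx$mask, 1L)
  expect_equal(comp$CSA, 1.00)
  expect_equal(comp$FAT, 0.25)
  expect_equal(comp$fCSA, 0.75)
  expect_equal(comp$FI, 25.0)
  expect_identical(comp$n_pixels, 100L)

  # anisotropic spacing: 0.5 x 2 mm pixels -> same areas
  fx2 <- make_manual_region(vals, spacing = c(0.5, 2))
  expect_equal(measure_muscle(fx2$image, fx2$mask, 1L)$CSA, 1.00)
})

test_that("noiseless bias-free phantom FI equals the recorded truth exactly", {
  ph <- single_region_phantom(0.4, size = 50, seed = 2)
  comp <- measure_muscle(ph$image, ph$masks, 1L)
  expect_equal(comp$FI, 100 * ph$truth_fat_fraction[["1"]])
})

test_that("FI recovery across fat fractions is within one pixel of area and monotone", {
  fis <- truths <- numeric(0)
  for (f in seq(0.05, 0.60, by = 0.05)) {
    ph <- single_region_phantom(f, size = 50, seed = 13)
    comp <- measure_muscle(ph$image, ph$masks, 1L)
    one_px <- 100 / comp$n_pixels
    expect_lte(abs(comp$FI - 100 * ph$truth_fat_fraction[["1"]]), one_px)
    fis <- c(fis, comp$FI); truths <- c(truths, ph$truth_fat_fraction[["1"]])
  }
  expect_true(all(diff(fis) >= 0))
})

test_that("bias plus noise stays within 2 FI points and correction beats none", {
  # max/min surface ratio ~1.5, noise at 2% of the class gap
  ph <- single_region_phantom(0.4, mu_muscle = 70, mu_fat = 100,
                              bias = c(1, 0.25, 0.15, 0, 0, 0),
                              noise_sd = 0.6, size = 60, seed = 8)
  corr <- measure_muscle(ph$image, ph$masks, 1L)
  raw <- measure_muscle(ph$image, ph$masks, 1L,
                        measure_config(bias_correction = FALSE))
  truth <- 100 * ph$truth_fat_fraction[["1"]]
  expect_lte(abs(corr$FI - truth), 2)
  expect_lte(abs(corr$FI - truth), abs(raw$FI - truth))
})

test_that("single-tissue regions flag a degenerate histogram with FI zero", {
  vals <- matrix(70, 10, 10)
  fx <- make_manual_region(vals)
  expect_warning(comp <- measure_muscle(fx$image, fx$mask, 1L),
                 "single-tissue")
  expect_equal(comp$FI, 0)
  expect_true(comp$single_tissue)
  expect_equal(comp$CSA, comp$fCSA)
})

test_that("missing and empty labels produce errors", {
  fx <- make_manual_region(matrix(rnorm(100, 80, 10), 10, 10))
  expect_error(measure_muscle(fx$image, fx$mask, 7L), "not present")
})

test_that("side combination sums areas and recomputes FI area-weighted", {
  mk <- function(CSA, FAT, muscle = "PPM", side = "left")
    musclefi:::new_composition(CSA, FAT, threshold_used = NA, n_pixels = 1L,
                               muscle = muscle, side = side)
  sym <- combine_sides(mk(5, 1), mk(5, 1, side = "right"))
  expect_equal(sym$CSA, 10); expect_equal(sym$FAT, 2); expect_equal(sym$FI, 20)

  asym <- combine_sides(mk(8, 4), mk(2, 0, side = "right"))
  expect_equal(asym$FI, 40)           # 100*4/10, not the 25% mean of side FIs
  onesided <- combine_sides(mk(6, 0), mk(4, 1, side = "right"))
  expect_equal(onesided$FI, 100 * 1 / 10)
  expect_error(combine_sides(mk(5, 1), mk(5, 1, muscle = "psoas")),
               "different muscles")
})

test_that("height normalization divides areas by height squared, FI untouched", {
  comp <- musclefi:::new_composition(20, 5, threshold_used = NA, n_pixels = 1L,
                                     muscle = "PPM", side = "bilateral")
  nn <- normalize_by_height(comp, 2.0)
  expect_equal(nn$CSA, 5.0)
  expect_equal(nn$FAT, 1.25)
  expect_equal(nn$FI, comp$FI)
  almost_unit <- normalize_by_height(comp, 1.0001)
  expect_equal(almost_unit$CSA, 20 / 1.0001^2)
  expect_error(normalize_by_height(comp, 0.9), "implausible height")
  expect_error(normalize_by_height(comp, 2.6), "implausible height")
})

test_that("CSA = fCSA + FAT holds for every emitted composition", {
  set.seed(30)
  for (f in c(0, 0.2, 0.55)) {
    ph <- single_region_phantom(f, noise_sd = 1.5, size = 40,
                                seed = sample.int(1e6, 1))
    comp <- suppressWarnings(measure_muscle(ph$image, ph$masks, 1L))
    expect_equal(comp$CSA, comp$fCSA + comp$FAT)
    nn <- normalize_by_height(comp, 1.72)
    expect_equal(nn$CSA, nn$fCSA + nn$FAT)
  }
  a <- suppressWarnings(measure_muscle(
    single_region_phantom(0.3)$image, single_region_phantom(0.3)$masks, 1L))
  b <- a; b$side <- "right"
  comb <- combine_sides(a, b)
  expect_equal(comb$CSA, comb$fCSA + comb$FAT)
})

test_that("measured FI is invariant to a global intensity rescaling", {
  ph <- single_region_phantom(0.35, noise_sd = 1, size = 50, seed = 17)
  scaled <- ph
  scaled$image <- slice_image(ph$image$intensities * 12.5,
                              ph$image$pixel_spacing_mm)
  expect_equal(measure_muscle(ph$image, ph$masks, 1L)$FI,
               measure_muscle(scaled$image, scaled$masks, 1L)$FI)
})

test_that("Cobb angle reproduces parallel, perpendicular and 45-degree cases", {
  line <- function(p1, p2) rbind(p1, p2)
  expect_equal(cobb_angle(endplate_landmarks(
    line(c(0, 0), c(10, 0)), line(c(0, 5), c(10, 5)))), 0)
  expect_equal(cobb_angle(endplate_landmarks(
    line(c(0, 0), c(10, 0)), line(c(3, 0), c(3, 8)))), 90)
  expect_equal(cobb_angle(endplate_landmarks(
    line(c(0, 0), c(1, 0)), line(c(0, 0), c(1, 1)))), 45)
  # order of points and of endplates must not matter
  expect_equal(cobb_angle(endplate_landmarks(
    line(c(1, 1), c(0, 0)), line(c(1, 0), c(0, 0)))), 45)
  expect_error(endplate_landmarks(line(c(1, 1), c(1, 1)),
                                  line(c(0, 0), c(1, 0))), "coincident")
})
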