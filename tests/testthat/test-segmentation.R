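test_that("RGB to 8-bit HSL conversion matches closed forms", {
  grey <- array(c(128, 128, 128), c(1, 1, 3))
  expect_equal(rgbToHsl8(grey)[1, 1, 2], 0)   # achromatic: S = 0
  expect_equal(rgbToHsl8(grey)[1, 1, 1], 0)   # hue defined as 0
  green <- array(c(0, 255, 0), c(1, 1, 3))
  expect_equal(rgbToHsl8(green)[1, 1, ], c(85, 255, 128))  # 120 deg -> 85
  black <- array(0, c(1, 1, 3))
  expect_equal(rgbToHsl8(black)[1, 1, 3], 0)
})

test_that("HSL -> RGB -> HSL round trip is stable", {
  set.seed(42)
  n <- 5000
  h <- sample(0:255, n, TRUE)
  s <- sample(34:255, n, TRUE)
  l <- sample(30:233, n, TRUE)
  rgb <- hsl8ToRgb(h, s, l)
  back <- rgbToHsl8(array(rgb, c(n, 1, 3)))
  hueErr <- pmin(abs(back[, 1, 1] - h), 255 - abs(back[, 1, 1] - h))
  expect_lte(max(hueErr), 4)                 # hue is circular
  expect_lte(max(abs(back[, 1, 2] - s)), 7)  # worst near the L extremes
  expect_lte(max(abs(back[, 1, 3] - l)), 1)
  # moderate chroma (leaf-like colours): tighter
  sel <- s >= 60 & l >= 60 & l <= 200
  expect_lte(max(hueErr[sel]), 2)
  expect_lte(max(abs(back[sel, 1, 2] - s[sel])), 2)
})

test_that("band masks implement inclusive box thresholds", {
  bands <- defaultBands()
  hsl <- array(0, c(1, 3, 3))
  hsl[1, , 1] <- c(38, 39, 131)   # hue just below / at band edges
  hsl[1, , 2] <- 100
  hsl[1, , 3] <- 100
  m <- bandMask(hsl, getBand(bands, "green"))
  expect_identical(as.vector(m), c(FALSE, TRUE, TRUE))
  all255 <- Band("all", c(0, 255), c(0, 255), c(0, 255))
  expect_true(all(bandMask(hsl, all255)))
})

test_that("synthetic leaf masks match the truth labels exactly", {
  task <- smallTask(3, seed = 5, classMix = c(green3 = 1))
  scan <- renderScan(task, smallProfile())
  hsl <- rgbToHsl8(scan$rgb)
  m <- bandMask(hsl, getBand(defaultBands(), "green3"))
  expect_identical(m, scan$labels > 0)
})

test_that("impurity removal deletes only sub-threshold components", {
  mask <- matrix(FALSE, 200, 120)
  mask[30:129, 20:119] <- TRUE       # 10000-px leaf
  mask[5:9, 5] <- TRUE               # 5-px speck
  out <- removeImpurities(mask, 50)
  expect_equal(sum(out), 10000)
  expect_identical(removeImpurities(mask, 1), mask)
  empty <- matrix(FALSE, 10, 10)
  expect_identical(removeImpurities(empty, 50), empty)
  expect_error(removeImpurities(mask, 0), ">= 1")
})

test_that("band masks are monotone in the band bounds", {
  set.seed(7)
  hsl <- array(sample(0:255, 40 * 40 * 3, TRUE), c(40, 40, 3))
  for (k in 1:5) {
    lo <- sort(sample(0:200, 2))
    small <- Band("a", c(lo[1] + 10, lo[2] + 20), c(40, 200), c(40, 200))
    big <- Band("b", c(lo[1], lo[2] + 40), c(30, 220), c(30, 220))
    expect_true(all(bandMask(hsl, big) | !bandMask(hsl, small)))
  }
})

test_that("class masks partition the total mask via intersection", {
  task <- smallTask(4, seed = 9, dustDensity = 60)
  scan <- renderScan(task, smallProfile())
  hsl <- rgbToHsl8(scan$rgb)
  bands <- defaultBands()
  total <- removeImpurities(totalLeafMask(hsl, bands), 50)
  cm <- classMasks(total, hsl, bands)
  # pairwise disjoint
  expect_equal(max(cm$green2 + cm$green3 + cm$green4 + cm$yellow), 1)
  # contained in and (bands tile the green+yellow space) summing to total
  expect_true(all(total | !(cm$green2 | cm$green3 | cm$green4 | cm$yellow)))
  expect_equal(sum(cm$green2) + sum(cm$green3) + sum(cm$green4) +
                 sum(cm$yellow), sum(total))
  # dust inside a class band but outside the total mask is excluded
  raw2 <- bandMask(hsl, getBand(bands, "green2"))
  expect_true(all(!(cm$green2 & !total)))
  expect_identical(cm$green2, raw2 & total)
  # empty total mask gives empty class masks
  cm0 <- classMasks(matrix(FALSE, 5, 5), array(100, c(5, 5, 3)), bands)
  expect_false(any(unlist(cm0)))
})

test_that("default band set is valid and yellow+green tile the L/H plan", {
  bands <- defaultBands()
  expect_true(validObject(bands))
  g <- getBand(bands, "green")
  expect_identical(g@h, c(39L, 131L))
  expect_identical(g@s, c(34L, 255L))
  expect_identical(g@l, c(30L, 233L))
  expect_identical(getBand(bands, "yellow")@h, c(0L, 38L))
  # class bands tile the green band's lightness range
  ls <- rbind(bands@green4@l, bands@green3@l, bands@green2@l)
  expect_identical(as.integer(ls[1, 1]), 30L)
  expect_identical(as.integer(ls[3, 2]), 233L)
  expect_true(all(ls[-1, 1] == ls[-3, 2] + 1L))
  expect_error(BandSet(green = g, yellow = getBand(bands, "yellow"),
                       green2 = Band("green2", c(0, 50)),
                       green3 = bands@green3, green4 = bands@green4),
               "contained")
})
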