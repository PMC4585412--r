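fakeRecords <- function(n, seed = 1) {
  set.seed(seed)
  LL <- runif(n, 80, 300); LW <- runif(n, 6, 15)
  A <- LL * LW * runif(n, 0.7, 1)
  P <- 2 * (LL + LW) * runif(n, 0.95, 1.05)
  g2 <- A * runif(n, 0, 0.5); g3 <- A * runif(n, 0, 0.3)
  g4 <- pmax(A - g2 - g3 - A * 0.05, 0)
  data.frame(LL_mm = LL, LW_mm = LW, perimeter_mm = P, area_mm2 = A,
             compactness = 4 * pi * A / P^2, area_g2 = g2, area_g3 = g3,
             area_g4 = g4, area_yellow = A - g2 - g3 - g4)
}

test_that("the trait vector has 29 entries grouped 6/7/16", {
  expect_length(traitNames(), 29)
  g <- traitGroups()
  expect_equal(lengths(g), c(size = 6L, colour = 7L, shape = 16L))
  expect_identical(unname(unlist(g)), traitNames())
  tr <- aggregateTraits(fakeRecords(5))
  expect_length(traitValues(tr), 29)
  expect_identical(names(traitValues(tr)), traitNames())
})

test_that("a single leaf collapses averages, maxima and SDs", {
  rec <- fakeRecords(1)
  v <- traitValues(aggregateTraits(rec))
  expect_equal(v[["LN"]], 1)
  expect_equal(v[["ALA"]], v[["MLA"]])
  expect_equal(v[["ALA"]], rec$area_mm2)
  expect_equal(v[["LASD"]], 0)
  expect_equal(v[["LLSD"]], 0)
  expect_equal(v[["LCSD"]], 0)
})

test_that("aggregation matches a direct arithmetic oracle", {
  rec <- fakeRecords(10, seed = 3)
  v <- traitValues(aggregateTraits(rec))
  popSD <- function(x) sqrt(sum((x - mean(x))^2) / length(x))
  gla <- sum(rec$area_g2 + rec$area_g3 + rec$area_g4)
  expect_equal(v[["LN"]], 10)
  expect_equal(v[["TLA"]], sum(rec$area_mm2))
  expect_equal(v[["GLA"]], gla)
  expect_equal(v[["ALA"]] * v[["LN"]], sum(rec$area_mm2))
  expect_equal(v[["MLA"]], max(rec$area_mm2))
  expect_equal(v[["LASD"]], popSD(rec$area_mm2))
  expect_equal(v[["GLAR2"]], sum(rec$area_g2) / gla)
  expect_equal(v[["GLAR2"]] + v[["GLAR3"]] + v[["GLAR4"]], 1)
  expect_equal(v[["GLCC"]], (2 * sum(rec$area_g2) + 3 * sum(rec$area_g3) +
                               4 * sum(rec$area_g4)) / gla)
  expect_true(v[["GLCC"]] >= 2 && v[["GLCC"]] <= 4)
  expect_equal(v[["ALWR"]], mean(rec$LL_mm) / mean(rec$LW_mm))
  expect_equal(v[["MLWR"]], max(rec$LL_mm) / max(rec$LW_mm))
  expect_equal(v[["APAR"]], mean(rec$perimeter_mm) / mean(rec$area_mm2))
  expect_equal(v[["MPAR"]], max(rec$perimeter_mm / rec$area_mm2))
  expect_true(v[["GLA"]] <= v[["TLA"]])
  expect_true(v[["MLA"]] >= v[["ALA"]])
})

test_that("aggregation is invariant to leaf order", {
  rec <- fakeRecords(8, seed = 5)
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(traitValues(aggregateTraits(rec)),
               traitValues(aggregateTraits(shuffled)))
})

test_that("colour ratios are missing when no green area exists", {
  rec <- fakeRecords(3, seed = 7)
  rec$area_g2 <- rec$area_g3 <- rec$area_g4 <- 0
  rec$area_yellow <- rec$area_mm2
  v <- traitValues(aggregateTraits(rec))
  expect_true(is.na(v[["GLAR2"]]))
  expect_true(is.na(v[["GLCC"]]))
  expect_equal(v[["GLA"]], 0)
  expect_error(aggregateTraits(rec[0, ]), "non-empty")
})

test_that("length-width-number products behave like area proxies", {
  rec <- fakeRecords(1, seed = 9)
  tr <- aggregateTraits(rec)
  expect_equal(alwn(tr), rec$LL_mm * rec$LW_mm)
  # identical rectangular leaves: ALWN equals TLA exactly
  rect <- data.frame(LL_mm = 100, LW_mm = 10, perimeter_mm = 220,
                     area_mm2 = 1000, compactness = 4 * pi * 1000 / 220^2,
                     area_g2 = 0, area_g3 = 1000, area_g4 = 0,
                     area_yellow = 0)[rep(1, 5), ]
  trR <- aggregateTraits(rect)
  expect_equal(alwn(trR), traitValues(trR)[["TLA"]])
  for (seed in 1:5) {
    trX <- aggregateTraits(fakeRecords(6, seed = seed))
    expect_gte(mlwn(trX), alwn(trX))
  }
})

test_that("the rectangular APAR approximation and its thin-blade limit", {
  v <- aparRectangular(100, 10)
  expect_equal(unname(v["rect"]), 0.22)
  expect_equal(unname(v["limit"]), 0.20)
  # the limit is approached as blades get much longer than wide
  long <- aparRectangular(1e9, 10)
  expect_equal(unname(long["rect"]), unname(long["limit"]), tolerance = 1e-6)
  expect_error(aparRectangular(-1, 10), "positive")
})

test_that("measured APAR on rectangle-only plants matches the closed form", {
  masks <- list(matrix(TRUE, 120, 30), matrix(TRUE, 180, 40),
                matrix(TRUE, 220, 35))
  leaves <- lapply(masks, function(m)
    list(mask = m, bbox = c(row0 = 1, col0 = 1, row1 = nrow(m) + 1,
                            col1 = ncol(m) + 1),
         pixelCount = sum(m),
         classPixelCounts = c(green2 = 0, green3 = sum(m), green4 = 0,
                              yellow = 0)))
  rec <- measureLeaves(leaves, 1)
  v <- traitValues(aggregateTraits(rec))
  approx <- aparRectangular(v[["ALL"]], v[["ALW"]])
  expect_equal(v[["APAR"]], unname(approx["rect"]), tolerance = 0.04)
})
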