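rectMask <- function(L, W) matrix(TRUE, L, W)

discMask <- function(r) {
  n <- 2L * r + 21L
  ctr <- (n + 1) / 2
  xy <- expand.grid(seq_len(n), seq_len(n))
  matrix((xy[, 1] - ctr)^2 + (xy[, 2] - ctr)^2 <= r^2, n, n)
}

test_that("straight-blade morphometrics recover rectangle dimensions", {
  m <- rectMask(100, 10)
  expect_equal(leafLength(m, 1), 100, tolerance = 0.02)
  expect_equal(leafWidth(m, 1), 10, tolerance = 0.06)
  expect_equal(leafPerimeter(m, 1), 220, tolerance = 0.04)
})

test_that("random rectangles meet the recovery bands", {
  set.seed(21)
  for (k in 1:6) {
    L <- sample(91:270, 1); W <- sample(27:64, 1)
    m <- rectMask(L, W)
    expect_lt(abs(leafLength(m, 1) - L) / L, 0.02)
    expect_lt(abs(leafWidth(m, 1) - W) / W, 0.02)
    expect_lt(abs(sum(m) - L * W) / (L * W), 1e-12)
    expect_lt(abs(leafPerimeter(m, 1) - 2 * (L + W)) / (2 * (L + W)), 0.04)
  }
})

test_that("curved blades measure their arc length", {
  # quarter-circle blade: arc 300 px, width 40 px
  m <- leafScoreR:::.rasterLeaf("curved-blade", 300, 40, 1.0)
  expect_equal(leafLength(m, 1), 300, tolerance = 0.03)
  expect_equal(leafWidth(m, 1), 40, tolerance = 0.03)
  # analytic perimeter of the annular blade
  expect_equal(leafPerimeter(m, 1), 2 * 300 + 2 * 40, tolerance = 0.04)
})

test_that("tapered ellipses recover their axes", {
  m <- leafScoreR:::.rasterLeaf("tapered-ellipse", 200, 40, 0)
  expect_equal(leafWidth(m, 1), 40, tolerance = 0.03)
  # skeleton ends short of the sharp tips; modest underestimate expected
  expect_equal(leafLength(m, 1), 200, tolerance = 0.06)
  expect_equal(sum(m), pi * 100 * 20, tolerance = 0.02)
})

test_that("disc shapes bound the compactness scale", {
  m <- discMask(50)
  p <- leafPerimeter(m, 1)
  expect_equal(p, 2 * pi * 50, tolerance = 0.03)
  cmp <- leafCompactness(sum(m), p)
  expect_equal(cmp, 1, tolerance = 0.05)
  # square: isoperimetric quotient pi/4
  sq <- rectMask(100, 100)
  cs <- leafCompactness(sum(sq), leafPerimeter(sq, 1))
  expect_equal(cs, pi / 4, tolerance = 0.08)
  # closed forms and the isoperimetric inequality
  expect_equal(leafCompactness(1000, 220), 4 * pi * 1000 / 220^2)
  expect_error(leafCompactness(1000, 0), "positive")
  for (msk in list(rectMask(60, 9), discMask(20))) {
    p2 <- leafPerimeter(msk, 1)
    expect_lt(leafCompactness(sum(msk), p2), 1.05)
  }
})

test_that("length and width behave under symmetry and scale", {
  sq <- rectMask(80, 80)
  expect_identical(leafLength(sq, 1), leafLength(t(sq), 1))
  expect_gte(leafLength(sq, 1), leafWidth(sq, 1))
  m <- leafScoreR:::.rasterLeaf("curved-blade", 150, 30, 0.6)
  # doubling the resolution doubles lengths and quadruples areas
  expect_equal(leafLength(m, 0.44), 2 * leafLength(m, 0.22))
  expect_equal(leafWidth(m, 0.44), 2 * leafWidth(m, 0.22))
  expect_equal(leafPerimeter(m, 0.44), 2 * leafPerimeter(m, 0.22))
  expect_equal(pixelsToArea(sum(m), 0.44^2), 4 * pixelsToArea(sum(m), 0.22^2))
  expect_equal(leafCompactness(sum(m) * 0.44^2, leafPerimeter(m, 0.44)),
               leafCompactness(sum(m) * 0.22^2, leafPerimeter(m, 0.22)))
})

test_that("degenerate single-pixel masks fall back to one pixel", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_equal(leafLength(m, 0.22), 0.22)
  expect_equal(leafWidth(m, 0.22), 0.22)
})

test_that("dominant class is the area argmax with dark-tie preference", {
  expect_equal(classifyLeaf(c(green2 = 10, green3 = 0, green4 = 0,
                              yellow = 0)), "green2")
  expect_equal(classifyLeaf(c(green2 = 60, green3 = 30, green4 = 10,
                              yellow = 0)), "green2")
  expect_equal(classifyLeaf(c(green2 = 50, green3 = 50, green4 = 0,
                              yellow = 0)), "green3")
  expect_equal(classifyLeaf(c(green2 = 0, green3 = 0, green4 = 0,
                              yellow = 0)), "unclassified")
})

test_that("a single-class batch is classified without error", {
  task <- smallTask(10, seed = 31, classMix = c(green3 = 1))
  res <- scoreSynthetic(task, smallProfile(), minLeafPx = 100)
  expect_equal(nrow(res$leaves), 10)
  expect_true(all(res$leaves$dominant_class == "green3"))
})

test_that("measureLeaves emits consistent per-leaf records", {
  task <- smallTask(4, seed = 17)
  res <- scoreSynthetic(task, smallProfile(), minLeafPx = 100)
  rec <- res$leaves
  expect_named(rec, c("task_id", "leaf_id", "LL_mm", "LW_mm",
                      "perimeter_mm", "area_mm2", "compactness",
                      "area_g2", "area_g3", "area_g4", "area_yellow",
                      "dominant_class"))
  expect_true(all(rec$LL_mm >= rec$LW_mm))
  expect_true(all(rec$area_g2 + rec$area_g3 + rec$area_g4 +
                    rec$area_yellow <= rec$area_mm2 + 1e-9))
  expect_true(all(rec$compactness > 0 & rec$compactness < 1.05))
})
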