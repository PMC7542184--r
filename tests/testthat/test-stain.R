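test_that("white reference is the per-channel background median, robust to specks", {
  img <- array(0, dim = c(10, 100, 3))
  img[, , 1] <- 240; img[, , 2] <- 235; img[, , 3] <- 242
  bg <- matrix(TRUE, 10, 100)
  expect_equal(estimate_white_reference(img, bg), c(240, 235, 242))
  img[1, 1, ] <- 0  # dust speck
  expect_equal(estimate_white_reference(img, bg), c(240, 235, 242))
})

test_that("empty background mask errors in marrow mode and falls back in adipo mode", {
  img <- array(200, dim = c(8, 8, 3))
  none <- matrix(FALSE, 8, 8)
  expect_error(estimate_white_reference(img, none, mode = "marrow"),
               "Background annotation required")
  expect_message(
    ref <- estimate_white_reference(img, none, mode = "adipo",
                                    analysis_mask = matrix(TRUE, 8, 8)),
    "99th")
  expect_equal(unname(ref), c(200, 200, 200))
})

test_that("optical density follows log10(white/I) with floor and clip", {
  white <- c(240, 240, 240)
  img <- array(240, dim = c(1, 3, 3))
  img[1, 2, ] <- 24    # one tenth of white
  img[1, 3, ] <- 0     # floored to 1
  od <- rgb_to_od(img, white)
  expect_equal(od[1, 1, ], c(0, 0, 0))
  expect_equal(od[1, 2, ], c(1, 1, 1))
  expect_equal(od[1, 3, ], rep(log10(240), 3), tolerance = 1e-12)
  # monotonically decreasing in intensity, channel-wise
  ints <- seq(1, 239, by = 2)   # above the white point the OD clips at 0
  ramp <- array(rep(ints, 3), dim = c(1, length(ints), 3))
  odr <- rgb_to_od(ramp, white)
  expect_true(all(diff(odr[1, , 1]) < 0))
})

test_that("deconvolution inverts the stain basis", {
  v <- stain_vectors()
  od_h <- array(rep(v$hema, each = 1), dim = c(1, 1, 3))
  maps <- deconvolve(od_h, v)
  expect_equal(maps$hema[1, 1], 1, tolerance = 1e-9)
  expect_equal(maps$eosin[1, 1], 0, tolerance = 1e-9)
  zero <- deconvolve(array(0, dim = c(2, 2, 3)), v)
  expect_true(all(zero$hema == 0) && all(zero$eosin == 0))
  mix <- array(0.7 * v$hema + 0.2 * v$eosin, dim = c(1, 1, 3))
  maps <- deconvolve(mix, v)
  expect_equal(maps$hema[1, 1], 0.7, tolerance = 1e-9)
  expect_equal(maps$eosin[1, 1], 0.2, tolerance = 1e-9)
})

test_that("unmix-after-mix recovers random concentration fields", {
  set.seed(7)
  v <- stain_vectors()
  H <- 12; W <- 9
  ch <- matrix(runif(H * W, 0, 1.5), H, W)
  ce <- matrix(runif(H * W, 0, 1.2), H, W)
  od <- array(0, dim = c(H, W, 3))
  for (k in 1:3) od[, , k] <- ch * v$hema[k] + ce * v$eosin[k]
  maps <- deconvolve(od, v)
  expect_lt(max(abs(maps$hema - ch)), 1e-6)
  expect_lt(max(abs(maps$eosin - ce)), 1e-6)
})

test_that("degenerate stain vectors are rejected", {
  expect_error(stain_vectors(hema = c(1, 0, 0), eosin = c(2, 0, 0)),
               "collinear")
  expect_error(stain_vectors(hema = c(0, 0, 0)), "zero norm")
})

test_that("white estimate is invariant to background pixel permutation", {
  set.seed(3)
  img <- array(sample(180:250, 300, replace = TRUE), dim = c(10, 10, 3))
  bg1 <- matrix(FALSE, 10, 10); bg1[1:5, ] <- TRUE
  ref1 <- estimate_white_reference(img, bg1)
  # same pixel multiset, different arrangement
  img2 <- img
  for (c in 1:3) img2[, , c][bg1] <- sample(img[, , c][bg1])
  expect_equal(estimate_white_reference(img2, bg1), ref1)
})
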