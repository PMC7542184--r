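test_that("disk, square and line morphometry match analytic shape values", {
  # digitized disk of radius 40 px at 0.5 um/px
  m <- disk_mask(120, 120, 60, 60, 40)
  lab <- matrix(0L, 120, 120); lab[m] <- 1L
  g <- measure_ghosts(lab, 0.5)
  expect_equal(g$area_um2, pi * 20^2, tolerance = 0.02)
  expect_gte(g$circularity, 0.95)
  expect_equal(g$perimeter_um, 2 * pi * 20, tolerance = 0.02)
  # filled square: circularity ~ pi/4
  sq <- matrix(0L, 80, 80); sq[15:64, 15:64] <- 1L
  gs <- measure_ghosts(sq, 1)
  expect_lt(abs(gs$circularity - pi / 4), 0.05)
  # 1-px line of 50 px: elongated, far below the circularity filter
  ln <- matrix(0L, 60, 60); ln[30, 5:54] <- 1L
  gl <- measure_ghosts(ln, 1)
  expect_lt(gl$circularity, 0.3)
})

test_that("centroids and edge flags are reported in pixel coordinates", {
  lab <- matrix(0L, 20, 30)
  lab[5:8, 10:13] <- 1L   # 4x4 square, centers x 9.5..12.5, y 4.5..7.5
  lab[1, 25:28] <- 2L     # touches the frame
  g <- measure_ghosts(lab, 1)
  expect_equal(g$centroid_x[1], 11)
  expect_equal(g$centroid_y[1], 6)
  expect_false(g$edge_touching[1])
  expect_true(g$edge_touching[2])
  # artifact borders count as edges too
  analysis <- matrix(TRUE, 20, 30); analysis[5:8, 14] <- FALSE
  g2 <- measure_ghosts(lab, 1, analysis)
  expect_true(g2$edge_touching[1])
})

test_that("ghost filters apply in order with inclusive boundaries", {
  cfg <- default_config("marrow")
  mk <- function(area, circ, edge = FALSE)
    data.frame(id = 1L, n_px = area, area_um2 = area, perimeter_um = 1,
               circularity = circ, centroid_x = 0, centroid_y = 0,
               edge_touching = edge)
  expect_equal(filter_ghosts(mk(100, 0.9), cfg)$rejection_reason, "too_small")
  expect_equal(filter_ghosts(mk(6000, 0.9), cfg)$rejection_reason, "too_large")
  expect_equal(filter_ghosts(mk(600, 0.2), cfg)$rejection_reason,
               "low_circularity")
  expect_true(filter_ghosts(mk(120, 0.3), cfg)$retained)   # boundaries inclusive
  expect_true(filter_ghosts(mk(5000, 0.3), cfg)$retained)
  expect_true(filter_ghosts(mk(600, 0.9, edge = TRUE), cfg)$retained)
  acfg <- default_config("adipo")
  expect_equal(filter_ghosts(mk(1000, 0.9, edge = TRUE), acfg)$rejection_reason,
               "edge")
  # first failed test wins: too small beats low circularity
  expect_equal(filter_ghosts(mk(100, 0.1), cfg)$rejection_reason, "too_small")
})

test_that("watershed splits touching disks on the membrane and keeps singles whole", {
  cfg <- default_config("marrow"); cfg$pixel_size <- 0.5
  H <- 80; W <- 120
  d1 <- disk_mask(H, W, 45, 40, 22)
  d2 <- disk_mask(H, W, 78, 40, 22)
  cand <- d1 | d2            # merged through a neck at x ~ 61.5
  membrane <- matrix(0, H, W)
  membrane[, 61:62] <- 0.8   # residual eosin wall at the contact
  lab <- fragment_ghosts(cand, membrane, cfg)
  expect_equal(max(lab), 2)
  expect_true(all(lab[cand] > 0))          # labels partition the candidates
  expect_true(all(lab[!cand] == 0))
  single <- disk_mask(H, W, 30, 30, 12)
  lab1 <- fragment_ghosts(single, NULL, cfg)
  expect_equal(max(lab1), 1)
  expect_equal(unname(lab1 > 0), unname(single))
  # empty input
  expect_equal(max(fragment_ghosts(matrix(FALSE, 10, 10), NULL, cfg)), 0)
})

test_that("fragmentation is deterministic", {
  set.seed(9)
  cand <- matrix(runif(60 * 60) < 0.4, 60, 60)
  cand <- marrowquant:::mask_close(cand, 2)
  memb <- matrix(runif(60 * 60, 0, 0.3), 60, 60)
  cfg <- default_config("marrow"); cfg$pixel_size <- 1
  l1 <- fragment_ghosts(cand, memb, cfg)
  l2 <- fragment_ghosts(cand, memb, cfg)
  expect_identical(l1, l2)
})

test_that("size distribution bins are half-open and conserve counts", {
  h <- size_distribution(c(400, 600, 620), 250, upper = 1000)
  expect_equal(h$count, c(0, 1, 2, 0))
  expect_equal(sum(h$count), 3)
  expect_equal(h$bin_lo, c(0, 250, 500, 750))
  # bin edges: a value exactly at a boundary goes in the upper bin
  h2 <- size_distribution(c(250), 250, upper = 500)
  expect_equal(h2$count, c(0, 1))
  h0 <- size_distribution(numeric(0), 250)
  expect_true(all(h0$count == 0) && all(h0$freq == 0))
  set.seed(4)
  areas <- rlnorm(1000, log(700), 0.4)
  h3 <- size_distribution(areas, 250)
  expect_equal(sum(h3$count), 1000)
  expect_equal(sum(h3$freq), 1)
})

test_that("retained ghost area equals the ADIPO compartment area exactly", {
  fix <- small_segmentation()
  seg <- fix$seg
  adipo_px <- sum(seg$labelmap$labels == MQ_LABELS[["ADIPO"]])
  retained_px <- sum(seg$ghosts$n_px[seg$ghosts$retained])
  expect_identical(adipo_px, as.integer(retained_px))
})
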