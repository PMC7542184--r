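test_that("cellularity (H over H+A) handles extremes and undefined input", {
  expect_equal(cellularity_eq1(60, 40), 0.60)
  expect_equal(cellularity_eq1(0, 50), 0)
  expect_equal(cellularity_eq1(50, 0), 1)
  expect_true(is.na(cellularity_eq1(0, 0)))
})

test_that("marrow percentages divide by Ma.Ar and go NA on empty marrow", {
  expect_equal(pct_of_marrow(50, 100), 50)
  expect_equal(pct_of_marrow(0, 100), 0)
  expect_true(is.na(pct_of_marrow(0, 0)))
  expect_error(pct_of_marrow(10, 5))
})

test_that("areas convert pixel counts exactly through pixel_size^2", {
  labels <- matrix(MQ_LABELS[["EXCLUDED"]], 10, 10)
  labels[1:4, 1:10] <- MQ_LABELS[["HEMATO"]]   # 40 px
  labels[5, 1:10] <- MQ_LABELS[["INTERSTITIUM"]]
  lm <- structure(list(labels = labels, pixel_size = 0.5),
                  class = "compartment_labels")
  a <- compartment_areas(lm)
  expect_equal(a$um2$hematopoietic, 40 * 0.25)
  expect_equal(a$px$marrow, 50)
  all_ex <- structure(list(labels = matrix(0L, 5, 5), pixel_size = 1),
                      class = "compartment_labels")
  a0 <- compartment_areas(all_ex)
  expect_true(all(unlist(a0$um2) == 0))
})

test_that("the two cellularity conventions are ordered on every partition", {
  set.seed(17)
  for (k in 1:1000) {
    parts <- rmultinom(1, size = sample(10:10000, 1), prob = runif(4))
    H <- parts[1]; A <- parts[2]; ma <- sum(parts)
    if (H + A == 0) next
    expect_gte(cellularity_eq1(H, A), pct_of_marrow(H, ma) / 100)
  }
})

test_that("cellularity is invariant to relabeling interstitium vs undetected", {
  set.seed(31)
  labels <- matrix(sample(MQ_LABELS[c("HEMATO", "ADIPO", "INTERSTITIUM",
                                      "UNDETECTED")], 400, replace = TRUE),
                   20, 20)
  lm1 <- structure(list(labels = labels, pixel_size = 1),
                   class = "compartment_labels")
  eq1 <- function(lm) {
    a <- compartment_areas(lm)$um2
    cellularity_eq1(a$hematopoietic, a$adipocyte)
  }
  flipped <- labels
  int <- which(labels == MQ_LABELS[["INTERSTITIUM"]])
  flipped[int[1:50]] <- MQ_LABELS[["UNDETECTED"]]
  lm2 <- structure(list(labels = flipped, pixel_size = 1),
                   class = "compartment_labels")
  expect_equal(eq1(lm2), eq1(lm1))
})

test_that("summarize fills every field consistently on the synthetic fixture", {
  fix <- small_segmentation()
  res <- summarize_quant(fix$seg$labelmap, fix$seg$ghosts, fix$masks,
                         fix$seg$cfg, image_id = "fixture")
  pcts <- c(res$pct_hematopoietic, res$pct_adiposity, res$pct_interstitium,
            res$pct_undetected)
  expect_equal(sum(pcts), 100, tolerance = 1e-9)
  expect_equal(res$hematopoietic_area_um2 + res$adipocyte_area_um2 +
                 res$interstitium_area_um2 + res$undetected_area_um2,
               res$marrow_area_um2, tolerance = 1e-9)
  expect_gte(res$cellularity_eq1, res$pct_hematopoietic / 100)
  expect_equal(res$adipocyte_count,
               sum(fix$seg$ghosts$retained))
  expect_equal(sum(res$histogram$count), res$adipocyte_count)
  # inconsistent ghost table trips the internal identity check
  bad <- fix$seg$ghosts
  bad$area_um2 <- bad$area_um2 * 2
  expect_error(summarize_quant(fix$seg$labelmap, bad, fix$masks, fix$seg$cfg),
               "internal error")
})

test_that("zero-adipocyte maps report a count of zero and NA mean area", {
  labels <- matrix(MQ_LABELS[["HEMATO"]], 8, 8)
  lm <- structure(list(labels = labels, pixel_size = 1),
                  class = "compartment_labels")
  masks <- structure(list(tissue_mask = matrix(TRUE, 8, 8),
                          artifact_mask = matrix(FALSE, 8, 8),
                          background_mask = matrix(FALSE, 8, 8),
                          analysis_mask = matrix(TRUE, 8, 8)),
                     class = "region_masks")
  ghosts <- filter_ghosts(measure_ghosts(matrix(0L, 8, 8), 1),
                          default_config("marrow"))
  res <- summarize_quant(lm, ghosts, masks, default_config("marrow"))
  expect_equal(res$adipocyte_count, 0)
  expect_true(is.na(res$mean_adipocyte_area_um2))
  expect_equal(res$pct_hematopoietic, 100)
})
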