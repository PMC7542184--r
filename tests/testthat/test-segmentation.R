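cfg_px <- function(mode = "marrow", pixel_size = 1) {
  cfg <- default_config(mode)
  cfg$pixel_size <- pixel_size
  cfg
}

test_that("composed labels partition the analysis region on random mask stacks", {
  set.seed(21)
  for (k in 1:10) {
    H <- 24; W <- 24
    rmask <- function(p) matrix(runif(H * W) < p, H, W)
    analysis <- rmask(0.8)
    bone <- rmask(0.2); ma <- rmask(0.7)
    lm <- compose_labels(analysis, bone, ma, rmask(0.4), rmask(0.3),
                         rmask(0.3), 1)
    lab <- lm$labels
    marrow_px <- sum(lab %in% MQ_LABELS[c("HEMATO", "ADIPO", "INTERSTITIUM",
                                          "UNDETECTED")])
    expect_equal(marrow_px, sum(ma & analysis & !(bone & analysis)))
    expect_true(all(lab[!analysis] == MQ_LABELS[["EXCLUDED"]]))
  }
})

test_that("composition is idempotent and respects the priority order", {
  set.seed(22)
  H <- 20; W <- 20
  rmask <- function(p) matrix(runif(H * W) < p, H, W)
  analysis <- rmask(0.9); bone <- rmask(0.25); ma <- rmask(0.8)
  hem <- rmask(0.5); adi <- rmask(0.4); int <- rmask(0.4)
  lm1 <- compose_labels(analysis, bone, ma, hem, adi, int, 1)
  # recompose from the map's own masks
  lab <- lm1$labels
  in_marrow <- matrix(lab %in% MQ_LABELS[c("HEMATO", "ADIPO",
                                           "INTERSTITIUM", "UNDETECTED")],
                      nrow(lab), ncol(lab))
  lm2 <- compose_labels(analysis,
                        lab == MQ_LABELS[["BONE"]],
                        in_marrow,
                        lab == MQ_LABELS[["HEMATO"]],
                        lab == MQ_LABELS[["ADIPO"]],
                        lab == MQ_LABELS[["INTERSTITIUM"]], 1)
  expect_identical(lm2$labels, lm1$labels)
  # a pixel claimed by bone and hemato resolves to bone
  both <- analysis & bone & ma & hem
  if (any(both))
    expect_true(all(lm1$labels[both] == MQ_LABELS[["BONE"]]))
  expect_error(compose_labels(analysis, bone[1:10, ], ma, hem, adi, int, 1),
               "dimension mismatch")
})

test_that("marrow mask subtracts the dilated bone by the configured ring", {
  H <- 41; W <- 41
  analysis <- matrix(TRUE, H, W)
  bone <- disk_mask(H, W, 20, 20, 6)
  cfg <- cfg_px(pixel_size = 0.5)
  cfg$bone_dilation_radius <- 0
  expect_equal(marrow_mask(analysis, bone, cfg), analysis & !bone)
  # 2 um at 0.5 um/px -> 4 px disc dilation; oracle by brute force
  cfg$bone_dilation_radius <- 2
  ma <- marrow_mask(analysis, bone, cfg)
  brush <- EBImage::makeBrush(9, "disc")
  dil <- matrix(as.numeric(EBImage::dilate(bone * 1, brush)) > 0.5, H, W)
  expect_equal(ma, analysis & !dil)
  expect_gt(sum(analysis & !ma & !bone), 0)  # the ring is excluded
})

test_that("an eosin-dense acellular blob inside the marrow is labeled bone", {
  # megakaryocyte-like blob: eosin-bright, texture-flat, hematoxylin-poor
  H <- 120; W <- 120
  hema <- matrix(0, H, W); eosin <- matrix(0.18, H, W)
  blob <- disk_mask(H, W, 60, 60, 18)
  eosin[blob] <- 0.6
  set.seed(5)
  nuc <- matrix(runif(H * W) < 0.25, H, W) & !blob
  hema[nuc] <- 0.9
  stains <- structure(list(hema = hema, eosin = eosin,
                           residual = matrix(0, H, W)), class = "stain_maps")
  analysis <- matrix(TRUE, H, W)
  cfg <- cfg_px()
  bone <- segment_bone(stains, analysis, cfg)
  expect_gt(sum(bone & blob) / sum(blob), 0.8)
  ma <- marrow_mask(analysis, bone, cfg)
  expect_true(all(!ma[blob]))  # subtracted from Ma.Ar
})

test_that("a section with no eosin-dense objects yields an empty bone mask", {
  H <- 64; W <- 64
  stains <- structure(list(hema = matrix(0.02, H, W),
                           eosin = matrix(0.15, H, W),
                           residual = matrix(0, H, W)), class = "stain_maps")
  bone <- segment_bone(stains, matrix(TRUE, H, W), cfg_px())
  expect_equal(sum(bone), 0)
})

test_that("hematopoietic mask is empty on a nucleus-free field", {
  H <- 48; W <- 48
  stains <- structure(list(hema = matrix(0.01, H, W),
                           eosin = matrix(0.2, H, W),
                           residual = matrix(0, H, W)), class = "stain_maps")
  expect_warning(
    hem <- segment_hematopoietic(stains, matrix(TRUE, H, W), cfg_px()),
    "degenerate")
  expect_equal(sum(hem), 0)
})

test_that("eosin-bright regions yield no ghost candidates, near-white pixels do", {
  H <- 60; W <- 60
  eosin <- matrix(0.5, H, W)               # hemorrhagic lake
  ghost <- disk_mask(H, W, 30, 30, 12)
  eosin[ghost] <- 0.01
  stains <- structure(list(hema = matrix(0, H, W), eosin = eosin,
                           residual = matrix(0, H, W)), class = "stain_maps")
  ma <- matrix(TRUE, H, W)
  cand <- candidate_ghost_mask(stains, ma, ma & FALSE, cfg_px())
  expect_gt(sum(cand & ghost) / sum(ghost), 0.95)
  expect_equal(sum(cand & !ghost), 0)
  # all-bright region: no candidates at all
  stains$eosin <- matrix(0.5, H, W)
  expect_equal(sum(candidate_ghost_mask(stains, ma, ma & FALSE, cfg_px())), 0)
})

test_that("interstitium floor separates serous signal from background white", {
  H <- 30; W <- 30
  eosin <- matrix(0, H, W)
  eosin[, 16:30] <- 0.15   # pale serous wash
  stains <- structure(list(hema = matrix(0, H, W), eosin = eosin,
                           residual = matrix(0, H, W)), class = "stain_maps")
  int <- segment_interstitium(stains, matrix(TRUE, H, W), cfg_px())
  expect_gt(mean(int[, 20:30]), 0.95)
  expect_lt(mean(int[, 1:10]), 0.05)
})

test_that("enlarging the artifact set never increases any compartment area", {
  fix <- small_segmentation()
  sec <- fix$section
  dims <- dim(sec$truth$labels)
  masks2 <- fix$masks
  art <- matrix(FALSE, dims[1], dims[2])
  art[80:140, 80:140] <- TRUE
  masks2$artifact_mask <- masks2$artifact_mask | art
  masks2$analysis_mask <- masks2$tissue_mask & !masks2$artifact_mask
  seg2 <- segment_section(sec$image, masks2, default_config("marrow"))
  a1 <- compartment_areas(fix$seg$labelmap)$px
  a2 <- compartment_areas(seg2$labelmap)$px
  for (k in c("bone", "hematopoietic", "adipocyte", "interstitium",
              "undetected", "marrow"))
    expect_lte(a2[[k]], a1[[k]])
})
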