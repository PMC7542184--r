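test_that("identical seeds render bitwise-identical sections", {
  spec <- synthetic_spec(dims = c(192L, 192L), seed = 8L)
  s1 <- generate_marrow_section(spec)
  s2 <- generate_marrow_section(spec)
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$truth$labels, s2$truth$labels)
  s3 <- generate_marrow_section(spec, seed = 9L)
  expect_false(identical(s1$image$pixels, s3$image$pixels))
})

test_that("a zero-adiposity target renders a ghost-free section", {
  spec <- synthetic_spec(dims = c(192L, 192L), frac_adipo = 0,
                         frac_hemato = 0.6, frac_interstitium = 0.3,
                         seed = 3L)
  sec <- generate_marrow_section(spec)
  expect_equal(nrow(sec$truth$ghosts), 0)
  expect_equal(sum(sec$truth$labels == MQ_LABELS[["ADIPO"]]), 0)
})

test_that("realized compartment fractions stay within 3 points of targets", {
  for (adipo in c(0.1, 0.3, 0.5)) {
    spec <- synthetic_spec(frac_adipo = adipo, frac_hemato = 0.35,
                           frac_interstitium = max(0, 0.6 - adipo),
                           frac_undetected = 0.03,
                           dims = c(320L, 320L), seed = 60L + round(100 * adipo))
    sec <- generate_marrow_section(spec)
    fr <- sec$truth$fractions
    expect_lt(abs(fr[["adipo"]] - adipo), 0.03)
    expect_lt(abs(fr[["hemato"]] - 0.35), 0.03)
  }
})

test_that("forward rendering is the exact Beer-Lambert inverse of unmixing", {
  set.seed(12)
  H <- 24; W <- 24
  # fields span the renderer's own stain gamut (densest structures ~0.9 OD
  # per stain; the 8-bit quantization bound applies while no channel
  # saturates toward black)
  hema <- matrix(runif(H * W, 0, 0.9), H, W)
  eosin <- pmin(matrix(runif(H * W, 0, 0.8), H, W),
                (0.85 - 0.70 * hema) / 0.99)
  conc <- list(hema = hema, eosin = pmax(eosin, 0))
  white <- c(242, 240, 244)
  img <- forward_stain_render(conc, white = white)
  expect_true(all(img >= 0 & img <= 255))
  # zero concentration renders pure white
  blank <- forward_stain_render(list(hema = matrix(0, 2, 2),
                                     eosin = matrix(0, 2, 2)), white = white)
  for (k in 1:3) expect_true(all(blank[, , k] == white[k]))
  # a hematoxylin impulse darkens the red channel most (H&E hue direction)
  imp <- forward_stain_render(list(hema = matrix(c(1, 0), 1, 2),
                                   eosin = matrix(0, 1, 2)), white = white)
  expect_lt(imp[1, 1, 1], imp[1, 2, 1])
  # roundtrip through the stain module within the 8-bit quantization bound
  od <- rgb_to_od(img, white)
  maps <- deconvolve(od)
  expect_lt(max(abs(maps$hema - conc$hema)), 0.02)
  expect_lt(max(abs(maps$eosin - conc$eosin)), 0.02)
})

test_that("adipose sheets carry one truth row per seeded ghost", {
  spec <- synthetic_spec(dims = c(512L, 512L), ghost_logmean = log(18),
                         seed = 14L)
  sh <- generate_adipose_sheet(spec, n_ghosts = 80L)
  expect_equal(nrow(sh$truth$ghosts), 80)
  expect_equal(sum(sh$truth$ghosts$n_px),
               sum(sh$truth$cell_ids > 0))
  sh2 <- generate_adipose_sheet(spec, n_ghosts = 80L)
  expect_identical(sh$image$pixels, sh2$image$pixels)
})

test_that("membrane removal merges adjacent ghost candidates (hypo-fragmentation)", {
  base <- synthetic_spec(dims = c(512L, 512L), ghost_logmean = log(18),
                         seed = 14L)
  cfg <- default_config("adipo")
  masks <- rasterize(structure(list(), class = "annotation_set"),
                     c(512L, 512L), whole_image_tissue = TRUE)
  count_components <- function(spec) {
    sh <- generate_adipose_sheet(spec, n_ghosts = 80L)
    st <- suppressMessages(separate_stains(sh$image, masks$background_mask,
                                           "adipo", masks$analysis_mask))
    cfg$pixel_size <- 1
    cand <- candidate_ghost_mask(st, masks$analysis_mask,
                                 masks$analysis_mask & FALSE, cfg)
    max(EBImage::bwlabel(cand * 1))
  }
  intact <- count_components(base)
  erased <- base
  erased$membrane_thickness <- 0.01
  merged <- count_components(erased)
  expect_lt(merged, intact)
})

test_that("the generated background window sits on rendered background white", {
  sec <- small_section()
  masks <- rasterize(sec$annotations, dim(sec$truth$labels))
  expect_gt(sum(masks$background_mask), 50)
  px <- sec$image$pixels
  white <- c(242, 240, 244)  # the spec's default white reference
  for (k in 1:3) {
    med <- median(px[, , k][masks$background_mask])
    expect_lt(abs(med - white[k]), 3)
  }
})
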