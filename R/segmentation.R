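# Internal OD constants used to keep region-restricted Otsu thresholds away
# from degenerate splits (e.g. an all-noise hematoxylin map on a pure
# adipose sheet would otherwise be bisected). Values are ODs well below the
# stain signal of the structure each threshold detects.
.BONE_MIN_EOSIN_OD <- 0.30   # bone matrix is densely eosinophilic
.HEMA_MIN_OD <- 0.15         # nuclei sit far above this
.VOID_MAX_OD <- 0.12         # ghost interiors are near background white
.BONE_TEXTURE_SD <- 0.08     # max local eosin-OD sd for acellular matrix
.BONE_TEXTURE_WINDOW_UM <- 3

.threshold <- function(values, cfg, which, floor_od = NULL, ceiling_od = NULL) {
  thr <- if (identical(cfg$threshold_method, "fixed"))
    cfg$fixed_od_thresholds[[which]]
  else otsu_threshold(values)
  if (is.null(thr)) thr <- NA_real_
  if (!is.na(thr)) {
    if (!is.null(floor_od)) thr <- max(thr, floor_od)
    if (!is.null(ceiling_od)) thr <- min(thr, ceiling_od)
  }
  thr
}

#' Segment the bone compartment
#'
#' Bone (cortical and trabecular) is detected inside the analysis region as
#' eosin-dense, hematoxylin-poor, texturally flat matrix: the eosin map is
#' Gaussian-smoothed and Otsu-thresholded within the region, pixels with
#' high local eosin variance (nuclear-scale texture, e.g. RBC lakes) or high
#' hematoxylin are removed, and the mask is closed (2 um), hole-filled and
#' cleaned of objects below `cfg$min_bone_object_area`.
#'
#' An empty bone mask is a valid outcome (e.g. trephine-like input with no
#' mineralized matrix in the ROI). Eosin-dense acellular blobs inside the
#' marrow (megakaryocyte cytoplasm is the documented case) land in the bone
#' mask and are thereby subtracted from the total marrow area.
#'
#' @param stains A `stain_maps` list from [deconvolve()].
#' @param analysis_mask H x W logical: tissue minus artifacts.
#' @param cfg An `mq_config` with `pixel_size` set.
#' @return H x W logical bone mask.
#' @export
segment_bone <- function(stains, analysis_mask, cfg) {
  validate_config(cfg, require_pixel_size = TRUE)
  ps <- cfg$pixel_size
  eosin_s <- smooth_map(stains$eosin, cfg$smoothing_sigma, ps)
  hema_s <- smooth_map(stains$hema, cfg$smoothing_sigma, ps)
  if (!any(analysis_mask)) return(analysis_mask)
  thr_e <- .threshold(eosin_s[analysis_mask], cfg, "eosin",
                      floor_od = .BONE_MIN_EOSIN_OD)
  if (is.na(thr_e)) return(analysis_mask & FALSE)
  thr_h <- .threshold(hema_s[analysis_mask], cfg, "hema",
                      floor_od = .HEMA_MIN_OD)
  dense <- analysis_mask & eosin_s > thr_e
  if (!is.na(thr_h)) dense <- dense & hema_s < thr_h
  # bone matrix is texturally flat at nuclear scale, RBC lakes are speckled:
  # keep eosin-dense pixels within one window radius of a flat pixel (the
  # sd window straddles the bone border, so flatness is dilated back over
  # it before intersecting)
  w_px <- um_to_px(.BONE_TEXTURE_WINDOW_UM, ps)
  tex_flat <- local_sd(stains$eosin, w_px) < .BONE_TEXTURE_SD
  bone <- dense & mask_dilate(dense & tex_flat, w_px + 1L)
  bone <- mask_close(bone, um_to_px(2, ps))
  bone <- fill_small_holes(bone, 4 * cfg$min_bone_object_area / ps^2)
  bone <- drop_small_objects(bone, cfg$min_bone_object_area / ps^2)
  bone & analysis_mask
}

#' Total marrow area mask
#'
#' Subtracts the bone mask, dilated by `cfg$bone_dilation_radius`, from the
#' analysis region. The dilation ring suppresses the endosteal lining so
#' that bone-lining cells in direct endosteal position are not counted in
#' the hematopoietic compartment; ring pixels are excluded from the marrow
#' area (and from all marrow compartments).
#'
#' @param analysis_mask,bone_mask H x W logical masks.
#' @inheritParams segment_bone
#' @return H x W logical total-marrow-area (Ma.Ar) mask.
#' @export
marrow_mask <- function(analysis_mask, bone_mask, cfg) {
  r <- um_to_px(cfg$bone_dilation_radius, cfg$pixel_size)
  analysis_mask & !mask_dilate(bone_mask, r)
}

#' Segment the hematopoietic (nucleated-cell) compartment
#'
#' The hematoxylin map is smoothed and thresholded within the marrow area
#' (lower cut of a two-threshold Otsu, see Details); detections are closed
#' with a 2 um radius (merging densely packed nuclei into a cellularity
#' mask) and objects under 10 um^2 are dropped.
#' A degenerate threshold (constant hematoxylin, e.g. a section with no
#' nuclei) yields an empty mask with a warning.
#'
#' Nuclei of any cell type inside the marrow are included: adipocyte rim
#' nuclei and detached bone-lining cells contribute to this mask (a
#' documented bias of the method).
#'
#' @inheritParams segment_bone
#' @param ma_mask H x W logical marrow-area mask from [marrow_mask()].
#' @return H x W logical hematopoietic mask.
#' @export
segment_hematopoietic <- function(stains, ma_mask, cfg) {
  ps <- cfg$pixel_size
  if (!any(ma_mask)) return(ma_mask)
  hema_s <- smooth_map(stains$hema, cfg$smoothing_sigma, ps)
  # the hematoxylin histogram inside the marrow is typically trimodal
  # (background / diffuse basophilic cytoplasm / dense chromatin); the
  # cellularity mask must include the cytoplasmic wash between packed
  # nuclei, so the lower cut of a two-threshold Otsu is used, floored so a
  # nucleus-free section cannot be bisected on noise
  thr <- if (identical(cfg$threshold_method, "fixed"))
    cfg$fixed_od_thresholds[["hema"]]
  else otsu_threshold2(hema_s[ma_mask])[1]
  if (is.null(thr) || is.na(thr)) {
    warning("degenerate hematoxylin threshold; empty hematopoietic mask")
    return(ma_mask & FALSE)
  }
  thr <- max(thr, .HEMA_MIN_OD)
  hem <- ma_mask & hema_s > thr
  hem <- mask_close(hem, um_to_px(2, ps))
  hem <- drop_small_objects(hem, 10 / ps^2)
  hem & ma_mask
}

#' Candidate adipocyte-ghost mask
#'
#' Adipocyte ghosts are delipidated voids: near-background-white pixels
#' bounded by thin eosinophilic membranes. Candidates are the pixels of the
#' marrow area, minus the hematopoietic mask, whose total stain OD
#' (hematoxylin + eosin) falls below an Otsu threshold computed on that same
#' region (capped at a low OD ceiling so eosin-bright regions can never
#' produce candidates), hole-filled and lightly opened (1 um) to detach
#' membrane remnants.
#'
#' @inheritParams segment_hematopoietic
#' @param hemato_mask Mask from [segment_hematopoietic()].
#' @return H x W logical candidate mask (individual ghosts still merged).
#' @export
candidate_ghost_mask <- function(stains, ma_mask, hemato_mask, cfg) {
  ps <- cfg$pixel_size
  region <- ma_mask & !hemato_mask
  if (!any(region)) return(region)
  # raw (unsmoothed) total OD: blurring would bleed membrane stain into the
  # ghost interiors and shave their rims
  total <- stains$hema + stains$eosin
  thr <- .threshold(total[region], cfg, "void", ceiling_od = .VOID_MAX_OD)
  if (is.na(thr)) thr <- .VOID_MAX_OD
  cand <- region & total < thr
  cand <- fill_small_holes(cand, cfg$max_adipocyte_area / ps^2) & region
  cand <- mask_open(cand, um_to_px(1, ps))
  cand & region
}

#' Segment the interstitium / microvasculature compartment
#'
#' Serous infiltrate and red blood cells (inside microvessels or dispersed
#' across the marrow space) are detected by their eosinophilic signal: any
#' remaining marrow pixel whose smoothed eosin OD reaches
#' `cfg$interstitium_od_floor` (default 0.08) is interstitium. Pixels at
#' background white stay unclaimed and fall to the undetected remainder.
#'
#' @inheritParams segment_hematopoietic
#' @param remaining_mask Marrow pixels not claimed by the hematopoietic or
#'   retained-adipocyte masks.
#' @return H x W logical interstitium mask.
#' @export
segment_interstitium <- function(stains, remaining_mask, cfg) {
  eosin_s <- smooth_map(stains$eosin, cfg$smoothing_sigma, cfg$pixel_size)
  remaining_mask & eosin_s >= cfg$interstitium_od_floor
}

#' Compose the mutually exclusive compartment label map
#'
#' Applies the fixed priority BONE > HEMATO > ADIPO > INTERSTITIUM >
#' UNDETECTED. Pixels outside the analysis region are EXCLUDED, as is the
#' endosteal bone-dilation ring (analysis pixels that are neither bone nor
#' inside the marrow mask). By construction the HEMATO + ADIPO +
#' INTERSTITIUM + UNDETECTED pixel counts sum exactly to the marrow-area
#' pixel count on any input, and composition is idempotent.
#'
#' @param analysis_mask,bone_mask,ma_mask,hemato_mask,adipo_mask,interstitium_mask
#'   H x W logical masks (any stack; claims outside their regions are
#'   resolved here).
#' @param pixel_size um/pixel, carried on the result.
#' @return A `compartment_labels` list: integer `labels` matrix over the
#'   `MQ_LABELS` codes and `pixel_size`.
#' @export
compose_labels <- function(analysis_mask, bone_mask, ma_mask, hemato_mask,
                           adipo_mask, interstitium_mask, pixel_size) {
  dims <- dim(analysis_mask)
  same <- function(m) identical(dim(m), dims)
  if (!all(same(bone_mask), same(ma_mask), same(hemato_mask),
           same(adipo_mask), same(interstitium_mask)))
    stop("mask dimension mismatch")
  bone <- bone_mask & analysis_mask
  ma <- ma_mask & analysis_mask & !bone
  labels <- matrix(MQ_LABELS[["EXCLUDED"]], dims[1], dims[2])
  labels[ma] <- MQ_LABELS[["UNDETECTED"]]
  labels[interstitium_mask & ma] <- MQ_LABELS[["INTERSTITIUM"]]
  labels[adipo_mask & ma] <- MQ_LABELS[["ADIPO"]]
  labels[hemato_mask & ma] <- MQ_LABELS[["HEMATO"]]
  labels[bone] <- MQ_LABELS[["BONE"]]
  structure(list(labels = labels, pixel_size = pixel_size),
            class = "compartment_labels")
}
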