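#' Per-compartment areas from a composed label map
#'
#' Pixel counts per label converted to um^2 via `pixel_size^2`. The marrow
#' area (Ma.Ar) is the exact sum of the hematopoietic, adipocytic,
#' interstitial and undetected counts. When region masks are supplied, the
#' EXCLUDED pool is split into outside-tissue, artifact, and the endosteal
#' dilation ring (excluded analysis pixels that are neither bone nor
#' marrow).
#'
#' @param labelmap A `compartment_labels` from [compose_labels()].
#' @param region_masks Optional `region_masks` from [rasterize()].
#' @return Named list of areas in um^2 (`bone`, `hematopoietic`,
#'   `adipocyte`, `interstitium`, `undetected`, `marrow`, plus `tissue`,
#'   `artifact`, `dilation_ring` when region masks are given) and the
#'   matching pixel counts in `px`.
#' @export
compartment_areas <- function(labelmap, region_masks = NULL) {
  lab <- labelmap$labels
  ps2 <- labelmap$pixel_size^2
  cnt <- function(code) sum(lab == MQ_LABELS[[code]])
  px <- c(bone = cnt("BONE"), hematopoietic = cnt("HEMATO"),
          adipocyte = cnt("ADIPO"), interstitium = cnt("INTERSTITIUM"),
          undetected = cnt("UNDETECTED"))
  px["marrow"] <- px[["hematopoietic"]] + px[["adipocyte"]] +
    px[["interstitium"]] + px[["undetected"]]
  if (!is.null(region_masks)) {
    px["tissue"] <- sum(region_masks$tissue_mask)
    px["artifact"] <- sum(region_masks$artifact_mask)
    px["dilation_ring"] <- sum(region_masks$analysis_mask) -
      px[["bone"]] - px[["marrow"]]
  }
  list(um2 = as.list(px * ps2), px = as.list(px))
}

#' Cellularity, pathologists' convention
#'
#' Hematopoietic area over the sum of the hematopoietic and adipocytic
#' areas - the proportion of cellular elements relative to marrow adipose
#' tissue. Undefined (NA, never 0) when both areas are zero.
#'
#' @param hematopoietic_area,adipocyte_area Areas in consistent units.
#' @return Fraction in \[0, 1\], or `NA` when the denominator is zero.
#' @export
cellularity_eq1 <- function(hematopoietic_area, adipocyte_area) {
  stopifnot(hematopoietic_area >= 0, adipocyte_area >= 0)
  denom <- hematopoietic_area + adipocyte_area
  if (denom == 0) return(NA_real_)
  hematopoietic_area / denom
}

#' Percentage of the total marrow area
#'
#' `100 * compartment / Ma.Ar`; the marrow area is the denominator for all
#' compartment percentages. `NA` when the marrow area is zero.
#'
#' @param compartment_area,marrow_area Areas in consistent units, with
#'   `0 <= compartment_area <= marrow_area`.
#' @return Percentage, or `NA`.
#' @export
pct_of_marrow <- function(compartment_area, marrow_area) {
  stopifnot(compartment_area >= 0, marrow_area >= compartment_area)
  if (marrow_area == 0) return(NA_real_)
  100 * compartment_area / marrow_area
}

#' Aggregate a full quantification result
#'
#' Fills every reported field: absolute compartment areas, the four
#' percentages of Ma.Ar, cellularity under both conventions (the
#' hematopoietic + adipocytic denominator of Eq. 1 and the total-marrow
#' denominator of Eq. 2), adipocyte count, mean adipocyte area and the size
#' histogram. Percent bone is reported relative to the tissue ROI and is
#' user-interpretable: its meaning depends on whether the ROI includes the
#' cortex.
#'
#' @param labelmap A `compartment_labels`.
#' @param ghosts Filtered ghost data frame from [filter_ghosts()] (may have
#'   zero rows).
#' @param region_masks A `region_masks` from [rasterize()].
#' @param cfg The effective `mq_config`.
#' @param image_id Identifier written to the results table.
#' @return A `quant_result` list; fields map one-to-one onto the results
#'   TSV columns.
#' @export
summarize_quant <- function(labelmap, ghosts, region_masks, cfg,
                            image_id = "image") {
  ar <- compartment_areas(labelmap, region_masks)
  a <- ar$um2
  retained <- ghosts[which(ghosts$retained), , drop = FALSE]
  ghost_area <- sum(retained$area_um2)
  if (abs(ghost_area - a$adipocyte) > 1e-6 * max(1, a$adipocyte))
    stop("internal error: retained ghost area (", ghost_area,
         ") != ADIPO label area (", a$adipocyte, ")")
  hist <- size_distribution(retained$area_um2, cfg$bin_width)
  res <- list(
    image = image_id,
    mode = cfg$mode,
    tissue_area_um2 = a$tissue,
    artifact_area_um2 = a$artifact,
    bone_area_um2 = a$bone,
    marrow_area_um2 = a$marrow,
    hematopoietic_area_um2 = a$hematopoietic,
    adipocyte_area_um2 = a$adipocyte,
    interstitium_area_um2 = a$interstitium,
    undetected_area_um2 = a$undetected,
    pct_hematopoietic = pct_of_marrow(a$hematopoietic, a$marrow),
    pct_adiposity = pct_of_marrow(a$adipocyte, a$marrow),
    pct_interstitium = pct_of_marrow(a$interstitium, a$marrow),
    pct_undetected = pct_of_marrow(a$undetected, a$marrow),
    cellularity_eq1 = cellularity_eq1(a$hematopoietic, a$adipocyte),
    pct_bone_of_tissue = if (!is.null(a$tissue) && a$tissue > 0)
      100 * a$bone / a$tissue else NA_real_,
    adipocyte_count = nrow(retained),
    mean_adipocyte_area_um2 = if (nrow(retained)) mean(retained$area_um2)
      else NA_real_,
    histogram = hist,
    areas_px = ar$px
  )
  structure(res, class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat("<quant_result>", x$image, "mode:", x$mode, "\n")
  cat(sprintf("  Ma.Ar %.0f um^2 | bone %.0f | hemato %.0f | adipo %.0f | interstitium %.0f | undetected %.0f\n",
              x$marrow_area_um2, x$bone_area_um2, x$hematopoietic_area_um2,
              x$adipocyte_area_um2, x$interstitium_area_um2,
              x$undetected_area_um2))
  cat(sprintf("  %%hemato %.1f | %%adiposity %.1f | cellularity (H/(H+A)) %s | adipocytes n=%d\n",
              x$pct_hematopoietic, x$pct_adiposity,
              ifelse(is.na(x$cellularity_eq1), "NA",
                     sprintf("%.3f", x$cellularity_eq1)),
              x$adipocyte_count))
  invisible(x)
}
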