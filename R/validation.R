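#' Measured-vs-truth recovery sweep on synthetic sections
#'
#' Renders `n` synthetic marrow sections sweeping truth adiposity from 0 to
#' 60% of the marrow area and truth hematopoietic fraction from ~95% down
#' to ~5% (capped so the compartments fit), runs the full segmentation on
#' each, and returns per-section truth and measured fractions plus
#' per-compartment intersection-over-union scores.
#'
#' @param n Number of sections.
#' @param seed Base seed; section i uses `seed * 1000 + i`.
#' @param dims Section size in pixels.
#' @param noise_sd Rendering noise (0 for noise-free IoU checks).
#' @return Data frame with columns `truth_adipo`, `meas_adipo`,
#'   `truth_hemato`, `meas_hemato` (fractions of the respective marrow
#'   areas), `iou_bone`, `iou_hemato`, `iou_adipo`, `iou_interstitium`,
#'   `n_px` (analysis pixels).
#' @export
recovery_sweep <- function(n = 20, seed = 1, dims = c(384L, 384L),
                           noise_sd = 0) {
  adip_t <- seq(0, 0.60, length.out = n)
  hem_t <- pmin(seq(0.95, 0.05, length.out = n), 0.92 - adip_t)
  iou <- function(a, b) if (any(a | b)) sum(a & b) / sum(a | b) else NA_real_
  out <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- synthetic_spec(
      frac_adipo = adip_t[i], frac_hemato = hem_t[i],
      frac_interstitium = max(0, 1 - adip_t[i] - hem_t[i] - 0.03) * 0.8,
      frac_undetected = 0.03, dims = dims, noise_sd = noise_sd,
      seed = seed * 1000L + i)
    sec <- generate_marrow_section(spec)
    masks <- rasterize(sec$annotations, dims)
    seg <- segment_section(sec$image, masks, default_config("marrow"))
    res <- summarize_quant(seg$labelmap, seg$ghosts, masks, seg$cfg,
                           paste0("sweep_", i))
    tl <- sec$truth$labels; ml <- seg$labelmap$labels
    out[[i]] <- data.frame(
      truth_adipo = sec$truth$fractions[["adipo"]],
      meas_adipo = res$pct_adiposity / 100,
      truth_hemato = sec$truth$fractions[["hemato"]],
      meas_hemato = res$pct_hematopoietic / 100,
      truth_interstitium = sec$truth$fractions[["interstitium"]],
      iou_bone = iou(tl == MQ_LABELS[["BONE"]], ml == MQ_LABELS[["BONE"]]),
      iou_hemato = iou(tl == MQ_LABELS[["HEMATO"]], ml == MQ_LABELS[["HEMATO"]]),
      iou_adipo = iou(tl == MQ_LABELS[["ADIPO"]], ml == MQ_LABELS[["ADIPO"]]),
      iou_interstitium = iou(tl == MQ_LABELS[["INTERSTITIUM"]],
                             ml == MQ_LABELS[["INTERSTITIUM"]]),
      n_px = sum(masks$analysis_mask))
  }
  do.call(rbind, out)
}

#' Fragmentation validation on a synthetic adipose sheet
#'
#' Renders a sheet of `n_ghosts` adjacent adipocyte ghosts, runs the
#' stand-alone adipocyte quantification (whole image, extramedullary
#' defaults), and compares against the per-ghost truth: retained-count
#' error, mean per-ghost absolute area error (truth cells matched to
#' measured ghosts by majority pixel overlap), the total-variation distance
#' between the 250-um^2-binned size histograms, and the relative change of
#' total adipocyte area when membranes are partially erased
#' (`erase_frac` of every shared wall).
#'
#' @param n_ghosts Number of ghost cells in the sheet.
#' @param seed Seed.
#' @param dims Sheet size in pixels.
#' @param erase_frac Stress level of the membrane-erasure rerun.
#' @return List: `count_truth`, `count_measured`, `count_err_frac`,
#'   `mean_area_err_frac`, `hist_tv`, `area_change_frac`, and the two ghost
#'   tables.
#' @export
sheet_validation <- function(n_ghosts = 200L, seed = 1,
                             dims = c(768L, 768L), erase_frac = 0.2) {
  spec <- synthetic_spec(dims = dims, ghost_logmean = log(20),
                         ghost_logsd = 0.25, seed = seed)
  cfg <- default_config("adipo")
  masks <- rasterize(structure(list(), class = "annotation_set"), dims,
                     whole_image_tissue = TRUE)
  sheet <- generate_adipose_sheet(spec, n_ghosts = n_ghosts)
  seg <- suppressMessages(segment_section(sheet$image, masks, cfg))
  retained <- seg$ghosts[seg$ghosts$retained, , drop = FALSE]
  truth <- sheet$truth$ghosts
  truth_kept <- truth[truth$area_um2 >= cfg$min_adipocyte_area &
                        truth$area_um2 <= cfg$max_adipocyte_area, ,
                      drop = FALSE]
  area_err <- vapply(seq_len(nrow(truth_kept)), function(k) {
    sel <- sheet$truth$cell_ids == truth_kept$id[k]
    mlab <- seg$ghost_labels[sel]
    mlab <- mlab[mlab > 0L]
    if (!length(mlab)) return(NA_real_)
    mid <- as.integer(names(which.max(table(mlab))))
    a <- seg$ghosts$area_um2[seg$ghosts$id == mid]
    abs(a - truth_kept$area_um2[k]) / truth_kept$area_um2[k]
  }, 0)
  upper <- max(truth_kept$area_um2, retained$area_um2, 1)
  h_t <- size_distribution(truth_kept$area_um2, cfg$bin_width, upper)
  h_m <- size_distribution(retained$area_um2, cfg$bin_width, upper)
  stress <- spec
  stress$membrane_erase_frac <- erase_frac
  sheet2 <- generate_adipose_sheet(stress, n_ghosts = n_ghosts)
  seg2 <- suppressMessages(segment_section(sheet2$image, masks, cfg))
  a1 <- sum(retained$area_um2)
  a2 <- sum(seg2$ghosts$area_um2[seg2$ghosts$retained])
  list(
    count_truth = nrow(truth_kept),
    count_measured = nrow(retained),
    count_err_frac = (nrow(retained) - nrow(truth_kept)) / nrow(truth_kept),
    mean_area_err_frac = mean(area_err, na.rm = TRUE),
    hist_tv = 0.5 * sum(abs(h_t$freq - h_m$freq)),
    area_change_frac = (a2 - a1) / a1,
    ghosts_measured = seg$ghosts,
    ghosts_truth = truth)
}
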