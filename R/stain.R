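#' Stain vectors for H&E optical-density unmixing
#'
#' Builds the 3x3 optical-density basis used by [deconvolve()]. Columns are
#' unit vectors for hematoxylin, eosin and a residual channel (the normalized
#' cross product of the first two). Defaults are the standard published H&E
#' triplet; both stain vectors can be overridden, e.g. to match a scanner
#' profile.
#'
#' @param hema,eosin Length-3 numeric OD direction vectors (any positive
#'   scale; normalized internally).
#' @return A list with unit vectors `hema`, `eosin`, `residual` and the 3x3
#'   matrix `M` (columns in that order).
#' @export
stain_vectors <- function(hema = c(0.65, 0.70, 0.29),
                          eosin = c(0.07, 0.99, 0.11)) {
  normalize <- function(v, name) {
    n <- sqrt(sum(v^2))
    if (!is.finite(n) || n <= 0) stop("stain vector '", name, "' has zero norm")
    v / n
  }
  h <- normalize(hema, "hema")
  e <- normalize(eosin, "eosin")
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  nr <- sqrt(sum(r^2))
  if (nr < 1e-8)
    stop("degenerate stain vectors: hema and eosin are collinear")
  r <- r / nr
  M <- cbind(hema = h, eosin = e, residual = r)
  if (abs(det(M)) < 1e-8) stop("stain matrix is singular")
  list(hema = h, eosin = e, residual = r, M = M)
}

#' Estimate the white reference from the background annotation
#'
#' The per-channel median intensity over the user-drawn background region
#' serves as the background correction reference for the whole ROI. The
#' median makes the estimate robust to dust specks and debris inside the
#' background annotation.
#'
#' In marrow mode an empty background is an error (the annotation is
#' required); in adipo mode the estimator falls back to the per-channel 99th
#' percentile of the analysis region, with a message.
#'
#' @param image A `calibrated_image` (see [load_image()]) or plain H x W x 3
#'   array of 0-255 intensities.
#' @param background_mask H x W logical matrix.
#' @param mode `"marrow"` or `"adipo"` (controls the empty-mask policy).
#' @param analysis_mask Fallback region for adipo mode.
#' @return Numeric length-3 vector of per-channel intensities, each >= 1.
#' @export
estimate_white_reference <- function(image, background_mask,
                                     mode = "marrow", analysis_mask = NULL) {
  px <- if (is.list(image)) image$pixels else image
  if (!any(background_mask)) {
    if (identical(mode, "marrow"))
      stop("Background annotation required: empty background mask in marrow mode")
    message("empty background mask; falling back to 99th-percentile intensity")
    if (is.null(analysis_mask)) analysis_mask <- matrix(TRUE, dim(px)[1], dim(px)[2])
    ref <- vapply(1:3, function(c)
      stats::quantile(px[, , c][analysis_mask], 0.99, names = FALSE), 0)
  } else {
    ref <- vapply(1:3, function(c)
      stats::median(px[, , c][background_mask]), 0)
  }
  pmax(ref, 1)
}

#' Convert RGB intensities to optical density
#'
#' Per channel, `OD = log10(white / max(I, 1))`, clipped to `[0, od_max]`.
#' Background-corrected: intensities are divided by the white reference
#' before the log, so the background region sits at OD 0 and stains mix
#' approximately linearly (Beer-Lambert).
#'
#' @param image A `calibrated_image` or H x W x 3 array (0-255).
#' @param white_reference Length-3 positive vector from
#'   [estimate_white_reference()].
#' @param od_max Upper clip for OD values (default 3, i.e. 0.1% transmission).
#' @return H x W x 3 array of optical densities.
#' @export
rgb_to_od <- function(image, white_reference, od_max = 3) {
  px <- if (is.list(image)) image$pixels else image
  stopifnot(length(white_reference) == 3, all(white_reference > 0))
  od <- array(0, dim = dim(px))
  for (c in 1:3) {
    od[, , c] <- log10(white_reference[c] / pmax(px[, , c], 1))
  }
  od[od < 0] <- 0
  od[od > od_max] <- od_max
  od
}

#' Unmix optical densities into stain concentrations
#'
#' Solves `od = M c` per pixel, where the columns of `M` are the stain OD
#' unit vectors; negative components (noise beyond the basis) are clipped to
#' zero.
#'
#' @param od H x W x 3 optical-density array from [rgb_to_od()].
#' @param vectors Stain basis from [stain_vectors()].
#' @return A `stain_maps` list with H x W concentration matrices `hema`,
#'   `eosin`, `residual` (OD units).
#' @export
deconvolve <- function(od, vectors = stain_vectors()) {
  M <- vectors$M
  if (abs(det(M)) < 1e-8) stop("stain matrix is singular")
  Minv <- solve(M)
  H <- dim(od)[1]; W <- dim(od)[2]
  flat <- matrix(od, H * W, 3)          # rows = pixels
  conc <- flat %*% t(Minv)              # c = Minv od
  conc[conc < 0] <- 0
  structure(list(
    hema = matrix(conc[, 1], H, W),
    eosin = matrix(conc[, 2], H, W),
    residual = matrix(conc[, 3], H, W)
  ), class = "stain_maps")
}

#' Full stain-separation step
#'
#' Convenience wrapper: white reference from the background annotation, OD
#' conversion, then deconvolution.
#'
#' @inheritParams estimate_white_reference
#' @inheritParams deconvolve
#' @param vectors Stain basis from [stain_vectors()].
#' @return A `stain_maps` list, with the `white_reference` used attached as
#'   an attribute.
#' @export
separate_stains <- function(image, background_mask, mode = "marrow",
                            analysis_mask = NULL, vectors = stain_vectors()) {
  white <- estimate_white_reference(image, background_mask, mode, analysis_mask)
  od <- rgb_to_od(image, white)
  maps <- deconvolve(od, vectors)
  attr(maps, "white_reference") <- white
  maps
}
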