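#' Compartment label codes
#'
#' Integer codes of the composed compartment map (also the byte values of
#' the optional label TIFF): EXCLUDED 0, BONE 1, HEMATO 2, ADIPO 3,
#' INTERSTITIUM 4, UNDETECTED 5.
#' @export
MQ_LABELS <- c(EXCLUDED = 0L, BONE = 1L, HEMATO = 2L, ADIPO = 3L,
               INTERSTITIUM = 4L, UNDETECTED = 5L)

#' Fixed overlay palette
#'
#' RGB rows (0-1) per compartment: bone green, nucleated cells violet,
#' adipocyte ghosts yellow, interstitium/microvasculature pink, undetected
#' gray.
#' @export
MQ_PALETTE <- rbind(
  BONE         = c(0.20, 0.75, 0.25),
  HEMATO       = c(0.55, 0.25, 0.75),
  ADIPO        = c(0.95, 0.85, 0.10),
  INTERSTITIUM = c(0.98, 0.60, 0.75),
  UNDETECTED   = c(0.60, 0.60, 0.60)
)

#' Load a calibrated RGB image
#'
#' Reads a flat TIFF or PNG into an H x W x 3 array of 0-255 intensities
#' together with its pixel calibration. For TIFF, the calibration is parsed
#' from the resolution tags when present; otherwise (and always for PNG) it
#' must be supplied via `pixel_size_override`.
#'
#' @param path Path to a TIFF or PNG file.
#' @param pixel_size_override Pixel size in um/pixel, used when the file
#'   carries no resolution metadata (it wins over tags when both exist).
#' @return A `calibrated_image`: list with `pixels` (H x W x 3, 0-255),
#'   `pixel_size` (um/px) and `source_path`.
#' @export
load_image <- function(path, pixel_size_override = NULL) {
  if (!file.exists(path)) stop("cannot read image: '", path, "' does not exist")
  ext <- tolower(tools::file_ext(path))
  pixel_size <- pixel_size_override
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    if (is.null(pixel_size)) {
      xres <- attr(img, "x.resolution")
      unit <- attr(img, "resolution.unit")
      if (!is.null(xres) && is.finite(xres) && xres > 0 && !is.null(unit)) {
        um_per_unit <- switch(as.character(unit), inch = 25400, cm = 10000,
                              NA_real_)
        if (is.finite(um_per_unit)) pixel_size <- um_per_unit / xres
      }
    }
  } else if (ext == "png") {
    img <- png::readPNG(path)
  } else {
    stop("unsupported image format: '", ext, "' (expected TIFF or PNG)")
  }
  if (length(dim(img)) == 2L)
    stop("non-RGB image: '", path, "' is single-channel")
  if (dim(img)[3] < 3L) stop("non-RGB image: '", path, "'")
  px <- img[, , 1:3, drop = FALSE] * 255
  if (is.null(pixel_size))
    stop("pixel size unknown for '", path,
         "': no resolution metadata and no override given")
  if (pixel_size <= 0) stop("pixel size must be > 0")
  structure(list(pixels = px, pixel_size = pixel_size, source_path = path),
            class = "calibrated_image")
}

#' Write a calibrated image as TIFF
#'
#' Stores the RGB array as an uncompressed 8-bit TIFF. Resolution metadata
#' is not embedded (the linked TIFF writer does not expose the tags), so
#' the pixel size must travel alongside the file: pass it back through
#' `pixel_size_override` / the `--pixel-size` flag when reloading.
#'
#' @param image A `calibrated_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  tiff::writeTIFF(image$pixels / 255, path, bits.per.sample = 8L,
                  compression = "none", reduce = TRUE)
  invisible(path)
}

.norm_class <- function(x) gsub("[[:space:]_]+", "", tolower(x))

#' Load classed annotations from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection (QuPath export dialect: the class is in
#' the feature property `classification$name`, with a plain `name` property
#' also accepted). Classes `"Tissue Boundaries"`, `"Artifacts"`/`"Artifact"`
#' and `"Background"` are recognized case- and whitespace-insensitively;
#' other classes are ignored with a warning. Vertex coordinates are clipped
#' to the image bounds.
#'
#' @param path GeoJSON file path.
#' @param dims Image dimensions `c(H, W)` used for clipping.
#' @param mode `"marrow"` requires at least one tissue polygon; `"adipo"`
#'   does not (no tissue polygon means the whole image is analyzed).
#' @return An `annotation_set`: list of polygons, each with `class` in
#'   `{"Tissue", "Artifact", "Background"}` and `rings` (list of N x 2
#'   vertex matrices in pixel coordinates, x = column, y = row, origin at
#'   the top-left corner).
#' @export
load_annotations <- function(path, dims, mode = "marrow") {
  gj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) stop("malformed GeoJSON: ", conditionMessage(e)))
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else if (identical(gj$type, "Feature")) list(gj)
           else stop("malformed GeoJSON: not a FeatureCollection")
  H <- dims[1]; W <- dims[2]
  polys <- list()
  for (f in feats) {
    cls <- f$properties$classification$name
    if (is.null(cls)) cls <- f$properties$name
    if (is.null(cls)) cls <- ""
    key <- .norm_class(cls)
    class_label <- if (key == "tissueboundaries") "Tissue"
      else if (key %in% c("artifact", "artifacts", "artefact", "artefacts")) "Artifact"
      else if (key == "background") "Background"
      else { warning("ignoring annotation of unknown class '", cls, "'"); next }
    geom <- f$geometry
    ring_sets <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      { warning("ignoring non-polygon geometry of type '", geom$type, "'"); next })
    for (rs in ring_sets) {
      rings <- lapply(rs, function(ring) {
        m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
        m[, 1] <- pmin(pmax(m[, 1], 0), W)
        m[, 2] <- pmin(pmax(m[, 2], 0), H)
        m
      })
      rings <- rings[vapply(rings, nrow, 0L) >= 3L]
      if (length(rings))
        polys[[length(polys) + 1L]] <- list(class = class_label, rings = rings)
    }
  }
  if (identical(mode, "marrow") &&
      !any(vapply(polys, function(p) p$class == "Tissue", TRUE)))
    stop("no 'Tissue Boundaries' annotation found (required in marrow mode)")
  structure(polys, class = "annotation_set")
}

#' Rasterize annotations into region masks
#'
#' A pixel belongs to a polygon iff its center lies inside under the
#' even-odd rule (ring containment is XORed, so holes are respected).
#' Overlapping polygons of one class are unioned. The background mask is
#' intersected with the tissue mask (background must lie within the ROI);
#' artifact pixels stay in `tissue_mask` but are removed from the analysis
#' region.
#'
#' @param annotations An `annotation_set` from [load_annotations()].
#' @param dims `c(H, W)`.
#' @param whole_image_tissue If `TRUE` and no tissue polygon is present, the
#'   whole image becomes the tissue region (adipo-mode convention).
#' @return A `region_masks` list: `tissue_mask`, `artifact_mask`,
#'   `background_mask`, `analysis_mask` (= tissue minus artifacts), all
#'   H x W logical.
#' @export
rasterize <- function(annotations, dims, whole_image_tissue = FALSE) {
  H <- dims[1]; W <- dims[2]
  empty <- matrix(FALSE, H, W)
  masks <- list(Tissue = empty, Artifact = empty, Background = empty)
  for (p in annotations) {
    pm <- empty
    for (ring in p$rings) pm <- xor(pm, polygon_mask(ring, dims))
    if (!any(pm)) { warning("annotation polygon lies outside the image"); next }
    masks[[p$class]] <- masks[[p$class]] | pm
  }
  if (!any(masks$Tissue) && whole_image_tissue)
    masks$Tissue <- matrix(TRUE, H, W)
  background <- masks$Background & masks$Tissue
  structure(list(
    tissue_mask = masks$Tissue,
    artifact_mask = masks$Artifact,
    background_mask = background,
    analysis_mask = masks$Tissue & !masks$Artifact
  ), class = "region_masks")
}

# results TSV column order (the package's output contract)
.result_cols <- c(
  "image", "mode", "tissue_area_um2", "artifact_area_um2", "bone_area_um2",
  "marrow_area_um2", "hematopoietic_area_um2", "adipocyte_area_um2",
  "interstitium_area_um2", "undetected_area_um2", "pct_hematopoietic",
  "pct_adiposity", "pct_interstitium", "pct_undetected", "cellularity_eq1",
  "adipocyte_count", "mean_adipocyte_area_um2")

#' Write and read quantification results
#'
#' One tab-separated row per image, full double precision, `NA` for
#' undefined ratios. `read_results()` parses the same file back so results
#' round-trip numerically.
#'
#' @param results A `quant_result` (see [summarize_quant()]) or a list of
#'   them.
#' @param path Output TSV path.
#' @return `write_results()` returns `path` invisibly; `read_results()` a
#'   data.frame.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "quant_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    vals <- lapply(.result_cols, function(col) {
      v <- r[[col]]
      if (is.null(v)) NA else v
    })
    names(vals) <- .result_cols
    as.data.frame(vals, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[num] <- lapply(df[num], function(v) {
    s <- vapply(v, function(x)
      if (is.na(x)) "NA" else format(x, digits = 17, scientific = FALSE), "")
    s
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write the per-adipocyte table
#'
#' CSV with one row per measured ghost: id, area (um^2), perimeter (um),
#' circularity, centroid (pixel coordinates), edge flag, retention and the
#' rejection reason for filtered-out ghosts.
#'
#' @param ghosts Data frame from [measure_ghosts()] / [filter_ghosts()].
#' @param path Output CSV path.
#' @param retained_only Write only retained ghosts (default writes all).
#' @return `path`, invisibly.
#' @export
write_ghost_table <- function(ghosts, path, retained_only = FALSE) {
  cols <- c("id", "area_um2", "perimeter_um", "circularity",
            "centroid_x", "centroid_y", "edge_touching")
  if ("retained" %in% names(ghosts)) cols <- c(cols, "retained", "rejection_reason")
  rows <- if (retained_only && "retained" %in% names(ghosts))
    which(ghosts$retained) else seq_len(nrow(ghosts))
  df <- ghosts[rows, intersect(cols, names(ghosts)), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write the compartment overlay
#'
#' Blends the fixed compartment palette (bone green, hematopoietic violet,
#' adipocyte yellow, interstitium pink, undetected gray) into the original
#' image at 50% opacity; excluded pixels keep the original intensities.
#'
#' @param image A `calibrated_image`.
#' @param labels Integer H x W label matrix over the `MQ_LABELS` codes.
#' @param path Output PNG path.
#' @param alpha Tint opacity in \[0, 1\].
#' @return `path`, invisibly.
#' @export
write_overlay <- function(image, labels, path, alpha = 0.5) {
  px <- image$pixels / 255
  out <- px
  for (lab in rownames(MQ_PALETTE)) {
    sel <- labels == MQ_LABELS[[lab]]
    if (!any(sel)) next
    for (c in 1:3)
      out[, , c][sel] <- (1 - alpha) * px[, , c][sel] + alpha * MQ_PALETTE[lab, c]
  }
  png::writePNG(out, path)
  invisible(path)
}

#' Write the label map as an 8-bit TIFF
#'
#' Stores the raw label codes (0 = EXCLUDED .. 5 = UNDETECTED) one byte per
#' pixel.
#'
#' @inheritParams write_overlay
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  tiff::writeTIFF(labels / 255, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' Read a label TIFF written by [write_label_tiff()]
#' @param path TIFF path.
#' @return Integer H x W matrix of label codes.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}
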