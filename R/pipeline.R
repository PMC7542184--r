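#' Segment one calibrated image into compartments
#'
#' Runs the full chain on in-memory objects: stain separation, bone and
#' marrow masks, hematopoietic detection, ghost candidates, watershed
#' fragmentation, morphometry and filtering, interstitium, and the final
#' label composition.
#'
#' @param image A `calibrated_image`.
#' @param region_masks A `region_masks` from [rasterize()].
#' @param cfg An `mq_config`; its `pixel_size` defaults to the image's.
#' @param vectors Stain basis from [stain_vectors()].
#' @return List: `stains`, `bone_mask`, `ma_mask`, `hemato_mask`,
#'   `ghost_labels`, `ghosts` (filtered data frame), `labelmap`
#'   (a `compartment_labels`), `cfg` (effective config).
#' @export
segment_section <- function(image, region_masks, cfg = default_config("marrow"),
                            vectors = stain_vectors()) {
  if (is.na(cfg$pixel_size)) cfg$pixel_size <- image$pixel_size
  validate_config(cfg, require_pixel_size = TRUE)
  stains <- separate_stains(image, region_masks$background_mask,
                            mode = cfg$mode,
                            analysis_mask = region_masks$analysis_mask,
                            vectors = vectors)
  analysis <- region_masks$analysis_mask
  bone <- segment_bone(stains, analysis, cfg)
  ma <- marrow_mask(analysis, bone, cfg)
  hemato <- segment_hematopoietic(stains, ma, cfg)
  cand <- candidate_ghost_mask(stains, ma, hemato, cfg)
  ghost_labels <- fragment_ghosts(cand, stains$eosin, cfg)
  ghosts <- measure_ghosts(ghost_labels, cfg$pixel_size, analysis)
  ghosts <- filter_ghosts(ghosts, cfg)
  adipo <- retained_ghost_mask(ghost_labels, ghosts)
  remaining <- ma & !hemato & !adipo
  interstitium <- segment_interstitium(stains, remaining, cfg)
  labelmap <- compose_labels(analysis, bone, ma, hemato, adipo, interstitium,
                             cfg$pixel_size)
  list(stains = stains, bone_mask = bone, ma_mask = ma, hemato_mask = hemato,
       ghost_labels = ghost_labels, ghosts = ghosts, labelmap = labelmap,
       cfg = cfg)
}

#' Quantify one image end to end
#'
#' Load, rasterize, segment, summarize and (optionally) write outputs:
#' the results TSV, the per-adipocyte CSV, the histogram TSV, the overlay
#' PNG and the label TIFF.
#'
#' In adipo mode an absent annotation file (or one without a tissue
#' polygon) means the entire image is analyzed.
#'
#' @param image_path Path to a TIFF/PNG image.
#' @param annotations_path Path to a GeoJSON annotation file, or `NULL`.
#' @param cfg An `mq_config`.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param pixel_size_override um/px used when the image has no calibration.
#' @return The `quant_result`, with the segmentation attached as attribute
#'   `"segmentation"`.
#' @export
run_single <- function(image_path, annotations_path = NULL,
                       cfg = default_config("marrow"), out_dir = NULL,
                       pixel_size_override = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  image <- stage("load_image", load_image(image_path, pixel_size_override))
  dims <- dim(image$pixels)[1:2]
  ann <- if (!is.null(annotations_path))
    stage("load_annotations", load_annotations(annotations_path, dims, cfg$mode))
  else if (identical(cfg$mode, "adipo"))
    structure(list(), class = "annotation_set")
  else stop("stage 'load_annotations': annotations required in marrow mode")
  masks <- stage("rasterize",
                 rasterize(ann, dims, whole_image_tissue = cfg$mode == "adipo"))
  seg <- stage("segment", segment_section(image, masks, cfg))
  image_id <- tools::file_path_sans_ext(basename(image_path))
  result <- stage("summarize",
                  summarize_quant(seg$labelmap, seg$ghosts, masks, seg$cfg,
                                  image_id = image_id))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stage("write", {
      write_results(result, file.path(out_dir, paste0(image_id, "_results.tsv")))
      write_ghost_table(seg$ghosts, file.path(out_dir, paste0(image_id, "_adipocytes.csv")))
      utils::write.table(result$histogram,
                         file.path(out_dir, paste0(image_id, "_histogram.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_overlay(image, seg$labelmap$labels,
                    file.path(out_dir, paste0(image_id, "_overlay.png")))
      write_label_tiff(seg$labelmap$labels,
                       file.path(out_dir, paste0(image_id, "_labels.tif")))
    })
  }
  attr(result, "segmentation") <- seg
  result
}

#' Batch quantification of a directory
#'
#' Processes every TIFF/PNG in `input_dir` (lexicographic order by file
#' stem), pairing annotations by stem (`image.tif` with `image.geojson`).
#' Per-image failures are recorded in the run manifest and do not stop the
#' batch; successful images contribute one row to the aggregate TSV.
#'
#' @param input_dir Directory of images (+ GeoJSON annotation files).
#' @param cfg An `mq_config`.
#' @param out_dir Output directory for per-image files, `results.tsv` and
#'   `manifest.tsv`.
#' @param pixel_size_override um/px fallback for uncalibrated images.
#' @return List: `results` (list of `quant_result`), `manifest` (data frame
#'   with one row per image: stem, status `ok`/`error`, message).
#' @export
run_batch <- function(input_dir, cfg = default_config("marrow"),
                      out_dir = NULL, pixel_size_override = NULL) {
  imgs <- list.files(input_dir, pattern = "\\.(tif|tiff|png)$",
                     ignore.case = TRUE, full.names = TRUE)
  imgs <- imgs[!grepl("_truth|_labels|_overlay", basename(imgs))]
  imgs <- imgs[order(tools::file_path_sans_ext(basename(imgs)))]
  if (!length(imgs)) stop("no images found in '", input_dir, "'")
  results <- list()
  manifest <- data.frame(stem = character(), status = character(),
                         message = character(), stringsAsFactors = FALSE)
  for (img in imgs) {
    stem <- tools::file_path_sans_ext(basename(img))
    ann <- file.path(input_dir, paste0(stem, ".geojson"))
    if (!file.exists(ann)) ann <- NULL
    res <- tryCatch(
      run_single(img, ann, cfg, out_dir = out_dir,
                 pixel_size_override = pixel_size_override),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("image '", stem, "' failed: ", conditionMessage(res))
      manifest <- rbind(manifest, data.frame(
        stem = stem, status = "error", message = conditionMessage(res)))
    } else {
      results[[stem]] <- res
      manifest <- rbind(manifest, data.frame(
        stem = stem, status = "ok", message = ""))
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (length(results))
      write_results(results, file.path(out_dir, "results.tsv"))
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(results = results, manifest = manifest)
}
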