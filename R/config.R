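#' Analysis configuration
#'
#' An `mq_config` object holds every tunable parameter of the workflow, all in
#' physical units (um, um^2). Pixel conversions happen only at segmentation
#' time through `pixel_size`.
#'
#' @section Fields:
#' \describe{
#'   \item{mode}{`"marrow"` (whole bone-marrow quantification) or `"adipo"`
#'     (stand-alone extramedullary adipocyte quantification).}
#'   \item{min_adipocyte_area, max_adipocyte_area}{Ghost size filter, um^2.}
#'   \item{min_circularity}{Ghost circularity filter, in \[0, 1\].}
#'   \item{exclude_edges}{Drop ghosts touching the image frame or excluded
#'     regions.}
#'   \item{bin_width}{Size-distribution bin width, um^2.}
#'   \item{pixel_size}{um per pixel; `NA` until supplied by image metadata or
#'     the user.}
#'   \item{bone_dilation_radius}{Endosteal suppression ring width, um.}
#'   \item{smoothing_sigma}{Gaussian smoothing applied to stain maps before
#'     thresholding, um.}
#'   \item{min_bone_object_area}{Smallest object kept in the bone mask, um^2.}
#'   \item{threshold_method}{`"otsu"` (default) or `"fixed"`.}
#'   \item{fixed_od_thresholds}{Optional named list of per-stain OD cutoffs
#'     (`eosin`, `hema`, `void`), used when `threshold_method = "fixed"`.}
#'   \item{h_maxima}{Seed-suppression depth for the ghost watershed, um.}
#'   \item{interstitium_od_floor}{Minimum eosin OD counted as interstitium.}
#' }
#'
#' @param mode One of `"marrow"`, `"adipo"`.
#' @return `default_config()` returns a validated `mq_config` list.
#' @examples
#' cfg <- default_config("marrow")
#' cfg$min_adipocyte_area  # 120
#' @export
default_config <- function(mode = c("marrow", "adipo")) {
  if (length(mode) == 1L && !mode %in% c("marrow", "adipo"))
    stop("unknown mode: '", mode, "' (expected 'marrow' or 'adipo')")
  mode <- match.arg(mode)
  base <- list(
    mode = mode,
    # recommended bone-marrow values: size 120-5000 um^2, circularity 0.3,
    # edges kept; extramedullary: 300-2500 um^2, circularity off, edges dropped
    min_adipocyte_area = if (mode == "marrow") 120 else 300,
    max_adipocyte_area = if (mode == "marrow") 5000 else 2500,
    min_circularity = if (mode == "marrow") 0.3 else 0,
    exclude_edges = mode == "adipo",
    bin_width = 250,
    pixel_size = NA_real_,
    bone_dilation_radius = 2.0,
    smoothing_sigma = 1.0,
    min_bone_object_area = 500,
    threshold_method = "otsu",
    fixed_od_thresholds = NULL,
    h_maxima = 1.5,
    interstitium_od_floor = 0.08
  )
  structure(base, class = "mq_config")
}

#' Validate a configuration
#'
#' Checks the configuration invariants and returns the object unchanged if
#' they all hold; otherwise stops with the first violated invariant named.
#'
#' @param cfg An `mq_config` list (or a plain named list with the same
#'   fields).
#' @param require_pixel_size If `TRUE`, additionally require a positive
#'   `pixel_size` (needed at segmentation time, not at configuration time).
#' @return `cfg`, invisibly unchanged.
#' @export
validate_config <- function(cfg, require_pixel_size = FALSE) {
  stopifnot(is.list(cfg))
  if (!cfg$mode %in% c("marrow", "adipo"))
    stop("unknown mode: '", cfg$mode, "'")
  if (!is.numeric(cfg$min_adipocyte_area) || cfg$min_adipocyte_area <= 0)
    stop("min_adipocyte_area must be > 0")
  if (cfg$min_adipocyte_area >= cfg$max_adipocyte_area)
    stop("min_adipocyte_area >= max_adipocyte_area")
  if (cfg$min_circularity < 0 || cfg$min_circularity > 1)
    stop("min_circularity outside [0, 1]")
  if (!is.na(cfg$pixel_size) && cfg$pixel_size <= 0)
    stop("pixel_size must be > 0")
  if (require_pixel_size && (is.na(cfg$pixel_size) || cfg$pixel_size <= 0))
    stop("pixel_size must be > 0")
  if (cfg$bin_width <= 0) stop("bin_width must be > 0")
  if (cfg$bone_dilation_radius < 0) stop("bone_dilation_radius must be >= 0")
  if (cfg$smoothing_sigma < 0) stop("smoothing_sigma must be >= 0")
  if (!cfg$threshold_method %in% c("otsu", "fixed"))
    stop("threshold_method must be 'otsu' or 'fixed'")
  if (identical(cfg$threshold_method, "fixed") &&
      is.null(cfg$fixed_od_thresholds))
    stop("threshold_method 'fixed' requires fixed_od_thresholds")
  invisible(cfg)
}

# config file keys <-> field names (flat key = value text file)
.cfg_keys <- c(
  mode = "mode",
  min_adipocyte_area_um2 = "min_adipocyte_area",
  max_adipocyte_area_um2 = "max_adipocyte_area",
  min_circularity = "min_circularity",
  exclude_edges = "exclude_edges",
  bin_width_um2 = "bin_width",
  pixel_size_um = "pixel_size",
  bone_dilation_radius_um = "bone_dilation_radius",
  smoothing_sigma_um = "smoothing_sigma",
  min_bone_object_area_um2 = "min_bone_object_area",
  threshold_method = "threshold_method"
)

#' Read / write configuration files
#'
#' The on-disk format is a flat `key = value` text file (TOML-style scalars
#' only). Unknown keys raise an error; keys absent from the file keep the
#' mode's default. Values given in a file override mode defaults, and CLI
#' flags in turn override file values.
#'
#' @param path File path.
#' @param cfg An `mq_config`.
#' @return `read_config()` returns an `mq_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: '", lines[bad][1], "'")
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  vals <- gsub('^"|"$', "", vals)
  unknown <- setdiff(keys, names(.cfg_keys))
  if (length(unknown)) stop("unknown config key: '", unknown[1], "'")
  mode <- if ("mode" %in% keys) vals[match("mode", keys)] else "marrow"
  cfg <- default_config(mode)
  for (i in seq_along(keys)) {
    f <- .cfg_keys[[keys[i]]]
    cfg[[f]] <- switch(f,
      mode = , threshold_method = vals[i],
      exclude_edges = as.logical(vals[i]),
      as.numeric(vals[i]))
  }
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  fmt <- function(f) {
    v <- cfg[[f]]
    if (is.character(v)) v else if (is.logical(v)) tolower(as.character(v))
    else format(v, scientific = FALSE)
  }
  lines <- vapply(names(.cfg_keys),
                  function(k) paste(k, "=", fmt(.cfg_keys[[k]])), "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.mq_config <- function(x, ...) {
  cat("<mq_config> mode:", x$mode, "\n")
  cat(sprintf("  adipocyte size filter: [%g, %g] um^2, circularity >= %g, %s\n",
              x$min_adipocyte_area, x$max_adipocyte_area, x$min_circularity,
              if (x$exclude_edges) "edges excluded" else "edges kept"))
  cat(sprintf("  pixel size: %s um/px; bone dilation %g um; smoothing %g um\n",
              ifelse(is.na(x$pixel_size), "unset", format(x$pixel_size)),
              x$bone_dilation_radius, x$smoothing_sigma))
  invisible(x)
}
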