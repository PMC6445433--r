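# En face angiogram container and physical scan geometry.

#' Construct an en face angiogram
#'
#' An en face OCTA angiogram is a square 2-D grid of decorrelation values
#' normalized to `[0, 1]`, together with its physical scan geometry: the
#' field width in millimetres (3.0 mm macular scans centred on the fovea,
#' 4.5 mm disc scans centred on the optic nerve head), the centre landmark
#' in pixel coordinates, the segmented vascular layer, and the device image
#' quality scores.
#'
#' @param pixels Square numeric matrix with values in `[0, 1]`.
#' @param field_width_mm Physical side length of the scan in mm (> 0).
#' @param scan_type `"macula"` or `"disc"`.
#' @param layer Segmented layer: one of `"SCP"`, `"DCP"`, `"whole_retina"`,
#'   `"RPC"`, `"SVC"`.
#' @param center_px Numeric `(row, col)` of the fovea or disc centre,
#'   1-based pixel coordinates (may be fractional). Defaults to the
#'   geometric image centre `(n + 1) / 2`.
#' @param quality Named numeric vector with elements `SQ` (signal quality,
#'   integer score) and `SSI` (signal strength index); `NA` when unknown.
#' @return An object of class `en_face_angiogram`.
#' @export
en_face_angiogram <- function(pixels, field_width_mm,
                              scan_type = c("macula", "disc"),
                              layer = c("SCP", "DCP", "whole_retina",
                                        "RPC", "SVC"),
                              center_px = NULL,
                              quality = c(SQ = NA_real_, SSI = NA_real_)) {
  scan_type <- match.arg(scan_type)
  layer <- match.arg(layer)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix")
  }
  if (nrow(pixels) != ncol(pixels)) {
    stop("non-square image rejected (", nrow(pixels), "x", ncol(pixels), ")")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop("pixel values must lie in [0, 1] with no missing values")
  }
  if (!is.numeric(field_width_mm) || length(field_width_mm) != 1L ||
      field_width_mm <= 0) {
    stop("field_width_mm must be a single positive number")
  }
  n <- nrow(pixels)
  if (is.null(center_px)) center_px <- c((n + 1) / 2, (n + 1) / 2)
  if (length(center_px) != 2L || any(center_px < 1) || any(center_px > n)) {
    stop("center_px must be a (row, col) pair inside the image grid")
  }
  structure(
    list(pixels = pixels, field_width_mm = field_width_mm,
         scan_type = scan_type, layer = layer,
         center_px = as.numeric(center_px),
         quality = c(SQ = unname(quality["SQ"]),
                     SSI = unname(quality["SSI"]))),
    class = "en_face_angiogram"
  )
}

#' @export
print.en_face_angiogram <- function(x, ...) {
  cat(sprintf(
    "<en_face_angiogram> %dx%d px, %.1f mm %s scan, layer %s\n",
    nrow(x$pixels), ncol(x$pixels), x$field_width_mm, x$scan_type, x$layer))
  cat(sprintf("  centre (%.1f, %.1f) px; SQ=%s SSI=%s; %.2f um/px\n",
              x$center_px[1], x$center_px[2],
              format(x$quality[["SQ"]]), format(x$quality[["SSI"]]),
              scale_info(x)$um_per_px))
  invisible(x)
}

#' Physical pixel scale of an angiogram
#'
#' The scan pitch implied by the field width and grid size:
#' `um_per_px = 1000 * field_width_mm / width` (9.87 um/px for a 3.0 mm
#' macular scan at 304 px; 14.8 um/px for a 4.5 mm disc scan).
#'
#' @param image An `en_face_angiogram`.
#' @return List with `um_per_px` and `px_area_um2` (`um_per_px^2`).
#' @export
scale_info <- function(image) {
  stopifnot(inherits(image, "en_face_angiogram"))
  um <- 1000 * image$field_width_mm / ncol(image$pixels)
  list(um_per_px = um, px_area_um2 = um^2)
}

#' Read an en face angiogram from a raster file
#'
#' Accepts single-channel 8- or 16-bit greyscale rasters (PNG, baseline
#' TIFF, PGM). Integer intensities are mapped linearly to `[0, 1]` by
#' dividing by the dtype maximum. Multi-channel or non-square images are
#' rejected.
#'
#' @inheritParams en_face_angiogram
#' @param path Path to the image file.
#' @return An `en_face_angiogram`.
#' @export
read_angiogram <- function(path, field_width_mm,
                           scan_type = c("macula", "disc"),
                           layer = c("SCP", "DCP", "whole_retina",
                                     "RPC", "SVC"),
                           center_px = NULL,
                           quality = c(SQ = NA_real_, SSI = NA_real_)) {
  raster <- read_raster(path)
  en_face_angiogram(raster$pixels, field_width_mm = field_width_mm,
                    scan_type = scan_type, layer = layer,
                    center_px = center_px, quality = quality)
}

#' Write an angiogram to a raster file
#'
#' @param image An `en_face_angiogram`.
#' @param path Output path (`.png`, `.tif`, `.tiff`, `.pgm`).
#' @param bit_depth 8 or 16 (PNG always written 8-bit).
#' @return `path`, invisibly.
#' @export
write_angiogram <- function(image, path, bit_depth = 8) {
  stopifnot(inherits(image, "en_face_angiogram"))
  write_raster(image$pixels, path, bit_depth = bit_depth)
}
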