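# Annular regions of interest with optional quadrant partition.
#
# Every vascular metric is computed over one of these regions: the
# parafovea (annulus between 1.0 and 3.0 mm diameters centred on the
# fovea) or the peripapillary "donut" (between 2.0 and 4.0 mm diameters
# centred on the optic nerve head). Membership is half-open,
# inner_radius <= d < outer_radius, with d measured between pixel centres,
# so concentric rings and the four 90-degree quadrants partition exactly.

#' Construct an annular region of interest
#'
#' Builds the boolean pixel mask of a donut-shaped region on the grid of a
#' host angiogram. The quadrant partition cuts the annulus along the two
#' 45-degree diagonals through the centre; `superior` is the sector
#' containing the "up" image direction. Anatomic `temporal`/`nasal`
#' labelling depends on eye laterality: for a right eye (OD) temporal is
#' image-left, for a left eye (OS) image-right (the default follows the
#' OD convention).
#'
#' @param image An `en_face_angiogram` providing grid shape, centre and
#'   physical scale.
#' @param inner_diameter_mm,outer_diameter_mm Ring diameters in mm,
#'   `0 <= inner < outer` (equal diameters give an empty mask). The outer
#'   ring may clip at the image edge; densities are then computed over the
#'   clipped mask.
#' @param quadrant One of `"all"`, `"superior"`, `"inferior"`,
#'   `"temporal"`, `"nasal"`.
#' @param eye `"OD"` (right) or `"OS"` (left); controls which image side
#'   is temporal.
#' @return An object of class `annular_roi` with fields `mask` (logical
#'   matrix), `center_px`, `inner_diameter_mm`, `outer_diameter_mm`,
#'   `quadrant`, `eye`, `n_px`.
#' @export
make_annulus <- function(image, inner_diameter_mm, outer_diameter_mm,
                         quadrant = c("all", "superior", "inferior",
                                      "temporal", "nasal"),
                         eye = c("OD", "OS")) {
  stopifnot(inherits(image, "en_face_angiogram"))
  quadrant <- match.arg(quadrant)
  eye <- match.arg(eye)
  if (!is.numeric(inner_diameter_mm) || !is.numeric(outer_diameter_mm) ||
      inner_diameter_mm < 0) {
    stop("diameters must be non-negative numbers")
  }
  if (inner_diameter_mm > outer_diameter_mm) {
    stop("inner diameter must not exceed outer diameter")
  }
  n <- nrow(image$pixels)
  ctr <- image$center_px
  if (any(ctr < 1) || any(ctr > n)) stop("centre outside image")
  um <- scale_info(image)$um_per_px
  r_inner_px <- inner_diameter_mm / 2 * 1000 / um
  r_outer_px <- outer_diameter_mm / 2 * 1000 / um

  dr <- matrix(seq_len(n) - ctr[1], nrow = n, ncol = n)          # down +
  dc <- matrix(seq_len(n) - ctr[2], nrow = n, ncol = n, byrow = TRUE)
  d <- sqrt(dr^2 + dc^2)
  mask <- d >= r_inner_px & d < r_outer_px
  if (quadrant != "all") {
    mask <- mask & quadrant_mask(dr, dc, quadrant, eye)
  }
  structure(
    list(mask = mask, center_px = ctr,
         inner_diameter_mm = inner_diameter_mm,
         outer_diameter_mm = outer_diameter_mm,
         quadrant = quadrant, eye = eye, n_px = sum(mask)),
    class = "annular_roi"
  )
}

# Sector membership from pixel offsets (dr down-positive, dc right-positive).
# Angle measured with "up" = +90 degrees; sectors are half-open
# [45, 135) = superior, [135, 225) = image-left, [225, 315) = inferior,
# [315, 45) = image-right, so the four sectors partition the plane.
quadrant_mask <- function(dr, dc, quadrant, eye) {
  theta <- atan2(-dr, dc) * 180 / pi          # (-180, 180], up = +90
  theta <- (theta + 360) %% 360
  sector <- switch(quadrant,
    superior = "up", inferior = "down",
    temporal = if (eye == "OD") "left" else "right",
    nasal    = if (eye == "OD") "right" else "left"
  )
  switch(sector,
    up    = theta >= 45  & theta < 135,
    left  = theta >= 135 & theta < 225,
    down  = theta >= 225 & theta < 315,
    right = theta >= 315 | theta < 45
  )
}

#' @export
print.annular_roi <- function(x, ...) {
  cat(sprintf(
    "<annular_roi> %.1f-%.1f mm, quadrant %s (%s), %d px\n",
    x$inner_diameter_mm, x$outer_diameter_mm, x$quadrant, x$eye, x$n_px))
  invisible(x)
}

# Resolve an ROI argument (annular_roi or plain logical matrix) to a mask.
roi_mask <- function(roi) {
  if (inherits(roi, "annular_roi")) return(roi$mask)
  if (is.matrix(roi) && is.logical(roi)) return(roi)
  stop("roi must be an annular_roi or a logical matrix")
}

# Resolve a binary-map argument (binary_vessel_map, large_vessel_mask,
# skeleton_map or plain logical matrix) to its mask.
binary_mask <- function(x) {
  if (inherits(x, c("binary_vessel_map", "large_vessel_mask",
                    "skeleton_map"))) {
    return(x$mask)
  }
  if (is.matrix(x) && is.logical(x)) return(x)
  stop("expected a binary map object or a logical matrix")
}
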