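# Synthetic en face angiograms with known ground truth.
#
# The vessel geometry model is deliberately simple and controllable
# rather than biologically realistic: random branching trees stand in for
# arterioles/venules (higher decorrelation, larger calibre) and a
# jittered grid mesh stands in for the capillary bed (1 px calibre, lower
# decorrelation). Macular scans carry a circular avascular zone at the
# centre bounded by a terminal capillary ring, so FAZ delineation and the
# FAZ-background threshold can be validated against analytic truth.
# Background pixels follow a folded-normal noise floor. Everything is
# deterministic given the seed.

default_vessel_params <- function(scan_type) {
  list(
    n_major_trees = if (scan_type == "disc") 6L else 4L,
    branch_depth = 3L,
    branch_angle_sd_deg = 22,
    segment_length_px = c(25, 45),
    major_radius_px = c(2L, 1L, 0L),  # dilation radius per tree level
    capillary_spacing_px = 13,
    capillary_radius_px = 1L,   # dilation radius: capillaries ~3 px wide
    capillary_density = 1,
    capillary_jitter_px = 1.5,
    vessel_mean = 0.5, vessel_sd = 0.05,        # capillary decorrelation
    large_vessel_mean = 0.68, large_vessel_sd = 0.04,
    faz_radius_mm = 0.25
  )
}

default_noise_params <- function() {
  list(floor = 0.05, sigma = 0.02)
}

#' Generate a synthetic en face angiogram with ground truth
#'
#' @param size_px Grid side length (304 emulates the native scan raster).
#' @param field_width_mm Physical field width; defaults to 3.0 for macular
#'   and 4.5 for disc scans.
#' @param scan_type `"macula"` or `"disc"`.
#' @param layer Layer label for the angiogram metadata (default SCP for
#'   macula, RPC for disc).
#' @param seed Integer seed; generation is deterministic given it.
#' @param vessel_params,noise_params Named lists overriding the defaults
#'   (see `octaq:::default_vessel_params`): tree count/depth/calibres,
#'   capillary mesh spacing/density/jitter, perfused decorrelation
#'   mean/SD for capillaries and large vessels, FAZ radius; background
#'   noise `floor` and folded-normal `sigma`.
#' @param quality `c(SQ=, SSI=)` metadata attached to the angiogram.
#' @param truth_skeleton Also skeletonize the truth mask (adds the
#'   `skeleton_length_px` truth field).
#' @return List with `image` (an `en_face_angiogram`) and `truth` (class
#'   `angiogram_truth`): `vessel_mask`, `large_vessel_mask` (subset of
#'   `vessel_mask`), `faz_mask`/`faz_area_mm2` (macula), `roi` (the
#'   standard annulus for the scan type), `true_vd_percent`, `true_afi`,
#'   `skeleton_length_px`, `params`, `seed`.
#' @export
generate_angiogram <- function(size_px = 304L, field_width_mm = NULL,
                               scan_type = c("macula", "disc"),
                               layer = NULL, seed = 1L,
                               vessel_params = list(),
                               noise_params = list(),
                               quality = c(SQ = 8, SSI = 60),
                               truth_skeleton = TRUE) {
  scan_type <- match.arg(scan_type)
  if (is.null(field_width_mm)) {
    field_width_mm <- if (scan_type == "macula") 3.0 else 4.5
  }
  if (is.null(layer)) layer <- if (scan_type == "macula") "SCP" else "RPC"
  vp <- utils::modifyList(default_vessel_params(scan_type), vessel_params)
  np <- utils::modifyList(default_noise_params(), noise_params)
  set.seed(seed)
  n <- as.integer(size_px)
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  um_per_px <- 1000 * field_width_mm / n

  # --- capillary mesh: jittered grid of wavy lines ------------------------
  spacing <- max(2, vp$capillary_spacing_px / vp$capillary_density)
  mesh_idx <- integer(0)
  for (orient in c("h", "v")) {
    positions <- if (1 + spacing / 2 <= n) {
      seq(1 + spacing / 2, n, by = spacing)
    } else numeric(0)
    for (pos in positions) {
      tt <- seq(1, n, by = 1)
      wobble <- cumsum(stats::rnorm(length(tt), 0, 0.35))
      wobble <- wobble - seq(wobble[1], wobble[length(wobble)],
                             length.out = length(wobble))
      line <- pos + vp$capillary_jitter_px * wobble /
        max(1, max(abs(wobble)))
      rr <- if (orient == "h") round(line) else tt
      cc <- if (orient == "h") tt else round(line)
      ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
      mesh_idx <- c(mesh_idx, (round(cc[ok]) - 1L) * n + round(rr[ok]))
    }
  }
  mesh <- matrix(FALSE, n, n)
  mesh[unique(mesh_idx)] <- TRUE
  mesh <- binary_dilate(mesh, vp$capillary_radius_px)

  # --- major vessel trees -------------------------------------------------
  level_masks <- rep(list(matrix(FALSE, n, n)), length(vp$major_radius_px))
  trace_tree <- function(p0, ang, level) {
    if (level > vp$branch_depth) return(invisible())
    len <- stats::runif(1, vp$segment_length_px[1], vp$segment_length_px[2])
    steps <- max(2L, ceiling(len))
    pts <- matrix(NA_real_, steps, 2L)
    p <- p0
    a <- ang
    for (s in seq_len(steps)) {
      a <- a + stats::rnorm(1, 0, 2 * pi / 180)
      p <- p + c(-sin(a), cos(a))
      pts[s, ] <- p
    }
    rr <- round(pts[, 1]); cc <- round(pts[, 2])
    ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
    if (any(ok)) {
      level_masks[[min(level, length(vp$major_radius_px))]][
        cbind(rr[ok], cc[ok])] <<- TRUE
    }
    if (all(!ok)) return(invisible())
    n_children <- sample(1:2, 1L, prob = c(0.35, 0.65))
    for (ch in seq_len(n_children)) {
      dang <- stats::rnorm(1, 0, vp$branch_angle_sd_deg * pi / 180)
      trace_tree(p, a + dang, level + 1L)
    }
  }
  for (k in seq_len(vp$n_major_trees)) {
    if (scan_type == "disc") {
      ang <- 2 * pi * (k - 1) / vp$n_major_trees + stats::rnorm(1, 0, 0.15)
      p0 <- ctr + 6 * c(-sin(ang), cos(ang))
    } else {
      side <- sample(1:4, 1L)
      t0 <- stats::runif(1, 0.15, 0.85) * n
      p0 <- switch(side, c(1, t0), c(n, t0), c(t0, 1), c(t0, n))
      ang <- atan2(ctr[2] - p0[2], -(ctr[1] - p0[1])) +
        stats::rnorm(1, 0, 0.3)
    }
    trace_tree(p0, ang, 1L)
  }
  tree <- matrix(FALSE, n, n)
  large <- matrix(FALSE, n, n)
  for (lv in seq_along(level_masks)) {
    dil <- binary_dilate(level_masks[[lv]], vp$major_radius_px[lv])
    tree <- tree | dil
    if (vp$major_radius_px[lv] >= 1L) large <- large | dil
  }

  # --- macular avascular zone + terminal capillary ring -------------------
  faz_mask <- NULL
  if (scan_type == "macula") {
    r_faz_px <- vp$faz_radius_mm * 1000 / um_per_px
    dr <- matrix(seq_len(n) - ctr[1], n, n)
    dc <- matrix(seq_len(n) - ctr[2], n, n, byrow = TRUE)
    d <- sqrt(dr^2 + dc^2)
    faz_mask <- d < r_faz_px
    ring <- d >= r_faz_px & d < r_faz_px + 2
    mesh <- (mesh & !faz_mask) | ring
    tree <- tree & !binary_dilate(faz_mask, 2)
    large <- large & !binary_dilate(faz_mask, 2)
  }

  vessel <- mesh | tree
  if (!any(vessel)) stop("vessel parameters yielded zero vessel pixels")

  # --- decorrelation image ------------------------------------------------
  img <- np$floor + abs(stats::rnorm(n * n, 0, np$sigma))
  img <- matrix(img, n, n)
  n_cap <- sum(vessel & !large)
  img[vessel & !large] <- stats::rnorm(n_cap, vp$vessel_mean, vp$vessel_sd)
  n_lrg <- sum(large)
  img[large] <- stats::rnorm(n_lrg, vp$large_vessel_mean, vp$large_vessel_sd)
  img <- pmin(pmax(img, 0), 1)

  image <- en_face_angiogram(img, field_width_mm = field_width_mm,
                             scan_type = scan_type, layer = layer,
                             quality = quality)

  roi <- if (scan_type == "macula") {
    make_annulus(image, 1.0, 3.0)
  } else {
    make_annulus(image, 2.0, 4.0)
  }
  true_vd <- 100 * sum(vessel & roi$mask) / roi$n_px
  true_afi <- mean(img[vessel & roi$mask])
  faz_area_mm2 <- if (is.null(faz_mask)) NA_real_ else {
    sum(faz_mask) * (um_per_px^2) / 1e6
  }
  skeleton_length_px <- if (truth_skeleton) {
    sum(skeletonize(vessel)$mask)
  } else NA_integer_

  truth <- structure(
    list(vessel_mask = vessel, large_vessel_mask = large,
         faz_mask = faz_mask, faz_area_mm2 = faz_area_mm2,
         roi = roi, true_vd_percent = true_vd, true_afi = true_afi,
         skeleton_length_px = skeleton_length_px,
         params = list(vessel = vp, noise = np, size_px = n,
                       field_width_mm = field_width_mm,
                       scan_type = scan_type),
         seed = seed),
    class = "angiogram_truth")
  list(image = image, truth = truth)
}

#' @export
print.angiogram_truth <- function(x, ...) {
  cat(sprintf(
    "<angiogram_truth> %s seed %d: true VD %.1f%%, true AFI %.3f%s\n",
    x$params$scan_type, x$seed, x$true_vd_percent, x$true_afi,
    if (!is.na(x$faz_area_mm2))
      sprintf(", FAZ %.3f mm^2", x$faz_area_mm2) else ""))
  invisible(x)
}
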