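# Binarization of en face angiograms.
#
# Three routes, matching standard OCTA practice:
#   * Phansalkar local thresholding (15x15 px window) for disc scans,
#   * Shanbhag global entropy thresholding inside the large-vessel-mask
#     pipeline,
#   * the FAZ background threshold for macular scans, where the avascular
#     foveal zone provides an in-image noise floor.
# All thresholds are strict ("above threshold" = vessel; ties go to
# background).

binary_vessel_map <- function(mask, provenance, threshold_params) {
  structure(list(mask = mask, provenance = provenance,
                 threshold_params = threshold_params),
            class = "binary_vessel_map")
}

#' @export
print.binary_vessel_map <- function(x, ...) {
  cat(sprintf("<binary_vessel_map> %dx%d, %s, %.1f%% foreground\n",
              nrow(x$mask), ncol(x$mask), x$provenance,
              100 * mean(x$mask)))
  invisible(x)
}

#' Phansalkar local thresholding
#'
#' Binarizes a `[0, 1]` image with the Phansalkar local threshold
#' `t = m * (1 + p * exp(-q * m) + k * ((s / r) - 1))`, where `m` and `s`
#' are the local mean and (population) standard deviation over a square
#' window centred on each pixel. Window edges are handled by mirror
#' padding. A pixel is foreground iff its value is strictly above `t`.
#' The defaults are the canonical constants for images scaled to
#' `[0, 1]`, with the 15 px window used for peripapillary OCTA scans.
#'
#' @param image An `en_face_angiogram` or a numeric matrix in `[0, 1]`.
#' @param window_px Odd window side length (>= 3).
#' @param p,q,k,r Phansalkar constants.
#' @return A `binary_vessel_map` with provenance `"phansalkar"`.
#' @export
phansalkar_binarize <- function(image, window_px = 15L, p = 2.0, q = 10.0,
                                k = 0.25, r = 0.5) {
  px <- image_pixels(image)
  if (window_px < 3L || window_px %% 2L == 0L) {
    stop("window_px must be an odd integer >= 3")
  }
  stats <- local_mean_sd(px, window_px)
  t <- stats$mean * (1 + p * exp(-q * stats$mean) +
                       k * ((stats$sd / r) - 1))
  binary_vessel_map(px > t, "phansalkar",
                    list(window_px = window_px, p = p, q = q, k = k, r = r))
}

# Local mean and population SD over a w x w window with mirror
# (symmetric, edge-repeating) padding, via integral images.
local_mean_sd <- function(px, w) {
  pad <- (w - 1L) %/% 2L
  padded <- mirror_pad(px, pad)
  s1 <- window_sum(padded, w)
  s2 <- window_sum(padded^2, w)
  m <- s1 / (w * w)
  v <- pmax(s2 / (w * w) - m^2, 0)
  list(mean = m, sd = sqrt(v))
}

mirror_pad <- function(px, pad) {
  n <- nrow(px); m <- ncol(px)
  ri <- c(pad:1, 1:n, n:(n - pad + 1L))
  ci <- c(pad:1, 1:m, m:(m - pad + 1L))
  px[ri, ci, drop = FALSE]
}

# Sum over all w x w windows of `padded`; output has dims reduced by w - 1.
window_sum <- function(padded, w) {
  cs <- apply(padded, 2L, cumsum)
  rowsum_strip <- rbind(cs[w, , drop = FALSE],
                        cs[(w + 1L):nrow(cs), , drop = FALSE] -
                          cs[1:(nrow(cs) - w), , drop = FALSE])
  cs2 <- t(apply(rowsum_strip, 1L, cumsum))
  cbind(cs2[, w, drop = FALSE],
        cs2[, (w + 1L):ncol(cs2), drop = FALSE] -
          cs2[, 1:(ncol(cs2) - w), drop = FALSE])
}

image_pixels <- function(image) {
  if (inherits(image, "en_face_angiogram")) return(image$pixels)
  if (is.matrix(image) && is.numeric(image)) return(image)
  stop("expected an en_face_angiogram or a numeric matrix")
}

#' Shanbhag global thresholding
#'
#' Chooses a global threshold on the `n_bins`-level histogram by
#' Shanbhag's fuzzy-entropy criterion (the information measure used by the
#' standard auto-threshold family): for each candidate bin the fuzzy
#' entropies of the background and object classes are computed from the
#' cumulative histogram and the bin minimizing their absolute difference
#' is selected (first minimum on ties). Pixels are quantized to levels
#' `round(v * (n_bins - 1))`; foreground = level strictly above the
#' threshold bin.
#'
#' @param image An `en_face_angiogram` or numeric matrix in `[0, 1]`.
#' @param n_bins Number of histogram bins (256 = 8-bit convention).
#' @return A `binary_vessel_map` with provenance `"shanbhag"`;
#'   `threshold_params` records the selected bin (0-based level) and its
#'   `[0, 1]`-scale value. A constant image (single occupied bin) falls
#'   back to all-background with a warning.
#' @export
shanbhag_binarize <- function(image, n_bins = 256L) {
  px <- image_pixels(image)
  levels <- pmin(pmax(as.integer(round(px * (n_bins - 1L))), 0L),
                 n_bins - 1L)
  counts <- tabulate(levels + 1L, nbins = n_bins)
  occupied <- which(counts > 0L)
  if (length(occupied) <= 1L) {
    warning("constant image: Shanbhag threshold undefined, ",
            "returning all background")
    return(binary_vessel_map(
      matrix(FALSE, nrow(px), ncol(px)), "shanbhag",
      list(n_bins = n_bins, threshold_bin = NA_integer_,
           threshold_value = NA_real_, degenerate = TRUE)))
  }
  t_bin <- shanbhag_threshold_bin(counts)
  mask <- matrix(levels > t_bin, nrow(px), ncol(px))
  binary_vessel_map(mask, "shanbhag",
                    list(n_bins = n_bins, threshold_bin = t_bin,
                         threshold_value = t_bin / (n_bins - 1L),
                         degenerate = FALSE))
}

#' Shanbhag criterion scan
#'
#' Evaluates the Shanbhag information measure at every candidate bin of a
#' histogram and returns the 0-based bin index of the first minimum.
#' Exposed so the selection can be audited bin by bin.
#'
#' @param counts Integer histogram counts (length = number of bins).
#' @return 0-based threshold bin index.
#' @export
shanbhag_threshold_bin <- function(counts) {
  n_bins <- length(counts)
  norm <- counts / sum(counts)
  P1 <- cumsum(norm)
  P2 <- 1 - P1
  eps <- .Machine$double.eps
  first_bin <- which(P1 >= eps)[1L]
  last_bin <- max(which(abs(P2) >= eps))
  min_ent <- Inf
  threshold <- first_bin
  for (it in first_bin:last_bin) {
    # fuzzy entropy of background class (bins <= it)
    term_b <- 0.5 / P1[it]
    ih <- 2:it
    ent_back <- if (it >= 2L) {
      -sum(norm[ih] * log(1 - term_b * P1[ih - 1L])) * term_b
    } else 0
    # fuzzy entropy of object class (bins > it)
    term_o <- 0.5 / P2[it]
    ih <- (it + 1L):n_bins
    ent_obj <- -sum(norm[ih] * log(pmax(1 - term_o * P2[ih], eps))) * term_o
    tot_ent <- abs(ent_back - ent_obj)
    if (tot_ent < min_ent) {
      min_ent <- tot_ent
      threshold <- it
    }
  }
  threshold - 1L  # 0-based level
}

#' Percentile contrast stretch
#'
#' Linear rescale mapping the `low_percentile` of the pixel distribution
#' to 0 and the `high_percentile` to 1, clipping outside. Pixel ordering
#' is preserved. A degenerate image (low == high) is returned unchanged
#' with a warning.
#'
#' @param image An `en_face_angiogram` or numeric matrix in `[0, 1]`.
#' @param low_percentile,high_percentile Percentiles in `[0, 100]`.
#' @return Same type as the input, with stretched pixels.
#' @export
contrast_stretch <- function(image, low_percentile = 0.5,
                             high_percentile = 99.5) {
  px <- image_pixels(image)
  qs <- stats::quantile(px, c(low_percentile, high_percentile) / 100,
                        names = FALSE)
  if (diff(qs) <= 0) {
    warning("degenerate intensity range; image returned unchanged")
    return(image)
  }
  stretched <- pmin(pmax((px - qs[1]) / (qs[2] - qs[1]), 0), 1)
  if (inherits(image, "en_face_angiogram")) {
    image$pixels <- stretched
    image
  } else {
    stretched
  }
}

#' FAZ background thresholding of a macular angiogram
#'
#' Uses the foveal avascular zone (FAZ) as an in-image noise reference.
#' The FAZ is delineated by region growing from a seed assumed to lie in
#' the avascular centre: pixels at most `grow_multiplier` SDs above the
#' mean of a small disc around the seed are "low signal", and the FAZ is
#' the 8-connected low-signal component containing the seed (interior
#' holes filled). The global binarization threshold is then
#' `T = mean + threshold_multiplier * SD` of the pixel values inside the
#' FAZ; foreground = value strictly above `T`.
#'
#' @param image A macular `en_face_angiogram`.
#' @param faz_seed_px `(row, col)` seed inside the avascular zone;
#'   defaults to the image centre landmark.
#' @param seed_disc_diameter_mm Diameter of the disc around the seed used
#'   for the initial noise estimate (0.3 mm).
#' @param grow_multiplier SD multiplier for region-growing membership.
#' @param threshold_multiplier SD multiplier for the binarization
#'   threshold. The default 3 suppresses ~99.5% of a folded-normal noise
#'   floor; see the methods vignette for why this is preferred over 2.
#' @param fill_holes Fill enclosed holes in the grown FAZ region.
#' @return List with `map` (a `binary_vessel_map`, provenance
#'   `"faz_background"`) and `faz` (list: `mask`, `area_mm2`, `seed_px`,
#'   `threshold`).
#' @export
faz_background_binarize <- function(image, faz_seed_px = NULL,
                                    seed_disc_diameter_mm = 0.3,
                                    grow_multiplier = 2,
                                    threshold_multiplier = 3,
                                    fill_holes = TRUE) {
  stopifnot(inherits(image, "en_face_angiogram"))
  if (image$scan_type != "macula") {
    stop("FAZ background thresholding applies to macular scans")
  }
  px <- image$pixels
  n <- nrow(px)
  if (is.null(faz_seed_px)) faz_seed_px <- round(image$center_px)
  seed <- as.integer(round(faz_seed_px))
  if (any(seed < 1L) || any(seed > n)) stop("FAZ seed outside image")

  # a seed on a perfused pixel inflates the local noise estimate, so the
  # high-signal check is against the global intensity distribution
  global_cut <- stats::median(px) + 2 * stats::sd(px)
  if (px[seed[1], seed[2]] > global_cut) {
    stop("FAZ seed lies on a high-signal pixel (value ",
         signif(px[seed[1], seed[2]], 3), " > median + 2 SD = ",
         signif(global_cut, 3),
         "); pick a seed inside the avascular zone")
  }
  um <- scale_info(image)$um_per_px
  r_seed_px <- seed_disc_diameter_mm / 2 * 1000 / um
  dr <- matrix(seq_len(n) - seed[1], n, n)
  dc <- matrix(seq_len(n) - seed[2], n, n, byrow = TRUE)
  seed_disc <- sqrt(dr^2 + dc^2) <= r_seed_px
  m0 <- mean(px[seed_disc])
  s0 <- stats::sd(px[seed_disc])
  grow_cut <- m0 + grow_multiplier * s0
  low <- px <= grow_cut
  if (!low[seed[1], seed[2]]) {
    # the seed itself may be a mild noise outlier: snap to the darkest
    # pixel of the seed disc (a vessel seed was already rejected above)
    disc_idx <- which(seed_disc)
    snap <- disc_idx[which.min(px[disc_idx])]
    seed <- c((snap - 1L) %% n + 1L, (snap - 1L) %/% n + 1L)
    if (!low[seed[1], seed[2]]) {
      stop("no low-signal pixel near the FAZ seed; ",
           "pick a seed inside the avascular zone")
    }
  }
  labels <- label_components(low)
  faz_mask <- labels == labels[seed[1], seed[2]]
  if (fill_holes) faz_mask <- fill_mask_holes(faz_mask)

  faz_vals <- px[faz_mask]
  threshold <- mean(faz_vals) + threshold_multiplier * stats::sd(faz_vals)
  if (is.na(threshold)) threshold <- mean(faz_vals)
  area_mm2 <- sum(faz_mask) * scale_info(image)$px_area_um2 / 1e6
  map <- binary_vessel_map(
    px > threshold, "faz_background",
    list(threshold = threshold, grow_multiplier = grow_multiplier,
         threshold_multiplier = threshold_multiplier,
         seed_px = seed, faz_mean = mean(faz_vals),
         faz_sd = stats::sd(faz_vals)))
  list(map = map,
       faz = list(mask = faz_mask, area_mm2 = area_mm2, seed_px = seed,
                  threshold = threshold))
}

#' FAZ area in mm^2
#'
#' @param faz The `faz` element returned by [faz_background_binarize()],
#'   or a logical mask together with an `image` for scale.
#' @param image Optional `en_face_angiogram` (required when `faz` is a
#'   plain mask).
#' @return Area in mm^2.
#' @export
faz_area <- function(faz, image = NULL) {
  if (is.list(faz) && !is.null(faz$area_mm2)) return(faz$area_mm2)
  stopifnot(is.matrix(faz), is.logical(faz),
            inherits(image, "en_face_angiogram"))
  sum(faz) * scale_info(image)$px_area_um2 / 1e6
}
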