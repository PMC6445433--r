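# Binary morphology: connected components, small-component removal, hole
# filling, dilation, and topology-preserving thinning.

#' Label connected components of a binary mask
#'
#' 8-connected labelling via an adjacency graph (igraph components).
#' Background pixels get label 0; foreground components are numbered from
#' 1 in first-encounter (column-major) order.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of labels, same shape as `mask`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask),
            connectivity %in% c(4L, 8L))
  n <- nrow(mask); m <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, n, m)
  if (!length(idx)) return(out)
  # directed neighbour offsets covering each undirected adjacency once:
  # down (+1), right (+n), down-right (+n+1), up-right (+n-1)
  offsets <- c(1L, n, if (connectivity == 8L) c(n + 1L, n - 1L))
  row_of <- ((idx - 1L) %% n) + 1L
  edges <- integer(0)
  for (off in offsets) {
    to <- idx + off
    ok <- to >= 1L & to <= n * m
    # forbid wraparound across matrix rows
    drow <- if (off == 1L) 1L else if (off == n) 0L
            else if (off == n + 1L) 1L else -1L
    ok <- ok & (row_of + drow >= 1L) & (row_of + drow <= n)
    ok[ok] <- mask[to[ok]]
    if (any(ok)) edges <- c(edges, rbind(idx[ok], to[ok]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  vmap <- integer(n * m)
  vmap[idx] <- seq_along(idx)
  if (length(edges)) {
    g <- igraph::add_edges(g, vmap[edges])
  }
  membership <- igraph::components(g)$membership
  # renumber in first-encounter order
  first <- !duplicated(membership)
  renum <- integer(max(membership))
  renum[membership[first]] <- seq_len(sum(first))
  out[idx] <- renum[membership]
  out
}

#' Remove small connected components
#'
#' Drops 8-connected foreground components whose pixel count is below
#' `min_px`.
#'
#' @param mask Logical matrix.
#' @param min_px Minimum component size in pixels to keep.
#' @return Logical matrix.
#' @export
remove_small_components <- function(mask, min_px) {
  labels <- label_components(mask)
  if (max(labels) == 0L) return(mask)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= min_px)
  labels %in% keep & mask
}

# Fill enclosed holes: background components not reachable from the image
# border become foreground.
fill_mask_holes <- function(mask) {
  bg <- label_components(!mask)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0L]
  mask | (bg > 0L & !(bg %in% border_labels))
}

# Binary dilation with a disc structuring element of the given pixel
# radius (radius 0 = identity). Used by the synthetic vessel renderer.
binary_dilate <- function(mask, radius_px) {
  if (radius_px <= 0) return(mask)
  n <- nrow(mask); m <- ncol(mask)
  out <- matrix(FALSE, n, m)
  r <- ceiling(radius_px)
  for (dr in -r:r) {
    for (dc in -r:r) {
      if (dr^2 + dc^2 > radius_px^2 + 1e-9) next
      rs <- max(1L, 1L + dr):min(n, n + dr)
      rt <- rs - dr
      cs <- max(1L, 1L + dc):min(m, m + dc)
      ct <- cs - dc
      out[rs, cs] <- out[rs, cs] | mask[rt, ct]
    }
  }
  out
}

skeleton_map <- function(mask) {
  structure(list(mask = mask), class = "skeleton_map")
}

#' @export
print.skeleton_map <- function(x, ...) {
  cat(sprintf("<skeleton_map> %dx%d, %d skeleton px\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

#' Skeletonize a binary vessel map
#'
#' Topology-preserving iterative thinning (Zhang-Suen) to 1-pixel-wide,
#' 8-connected centrelines. Deletion is simultaneous within each
#' sub-iteration; a retention guard keeps one pixel whenever a whole
#' component would otherwise vanish in a single sub-iteration (plain
#' Zhang-Suen deletes an isolated 2x2 block entirely), so the
#' connected-component count is preserved for components larger than one
#' pixel. The result is idempotent: skeletonizing a skeleton changes
#' nothing.
#'
#' @param binary A `binary_vessel_map` or logical matrix.
#' @return A `skeleton_map` whose mask is a subset of the input mask.
#' @export
skeletonize <- function(binary) {
  mask <- binary_mask(binary)
  comp <- label_components(mask)
  n_comp <- max(comp)
  img <- mask
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      del <- zs_deletable(img, step)
      if (!any(del)) next
      # retention guard: never delete the last pixels of a component
      del_labels <- comp[del]
      remaining <- tabulate(comp[img], nbins = n_comp) -
        tabulate(del_labels, nbins = n_comp)
      dying <- which(remaining == 0L)
      if (length(dying)) {
        del_idx <- which(del)
        for (lab in dying) {
          keep_one <- del_idx[comp[del_idx] == lab][1L]
          del[keep_one] <- FALSE
        }
      }
      if (any(del)) {
        img[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  skeleton_map(img)
}

# Zhang-Suen deletability for one sub-iteration, computed simultaneously
# for all pixels via shifted neighbourhoods (zero padding at the border).
zs_deletable <- function(img, step) {
  n <- nrow(img); m <- ncol(img)
  pad <- matrix(FALSE, n + 2L, m + 2L)
  pad[2:(n + 1L), 2:(m + 1L)] <- img
  shift <- function(dr, dc) pad[(2:(n + 1L)) + dr, (2:(m + 1L)) + dc]
  p2 <- shift(-1L, 0L); p3 <- shift(-1L, 1L); p4 <- shift(0L, 1L)
  p5 <- shift(1L, 1L);  p6 <- shift(1L, 0L);  p7 <- shift(1L, -1L)
  p8 <- shift(0L, -1L); p9 <- shift(-1L, -1L)
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
       (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
  cond <- img & b >= 2L & b <= 6L & a == 1L
  if (step == 1L) {
    cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
  } else {
    cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
  }
}
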