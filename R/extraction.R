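#' Extraction parameters
#'
#' Tunable parameters of the per-slice lung-diaphragm intersection
#' extraction.
#'
#' @param band_fraction width fraction of each costophrenic search band
#'   (first and last part of the outline's x-extent). Default 0.25.
#' @param ascent_check_length number of voxels over which the fallback trace
#'   checks that the outline ascends past a candidate edge. Default 5.
#' @param filter2_min_distance_fraction minimum distance between the arc's
#'   midpoint and its most caudal voxel, as a fraction of the arc's x-extent;
#'   shorter arcs are discarded as inward-curving. Default 0.25.
#' @param lower_fraction fraction of the lung's z-extent retained as the
#'   "lower third". Default 1/3.
#' @return An object of class `extraction_params`.
#' @export
extraction_params <- function(band_fraction = 0.25,
                              ascent_check_length = 5L,
                              filter2_min_distance_fraction = 0.25,
                              lower_fraction = 1 / 3) {
  stopifnot(band_fraction > 0, band_fraction < 1,
            filter2_min_distance_fraction > 0, filter2_min_distance_fraction < 1,
            lower_fraction > 0, lower_fraction < 1,
            ascent_check_length >= 1)
  structure(list(band_fraction = band_fraction,
                 ascent_check_length = as.integer(ascent_check_length),
                 filter2_min_distance_fraction = filter2_min_distance_fraction,
                 lower_fraction = lower_fraction),
            class = "extraction_params")
}

#' Retain the lower (caudal) part of a lung mask
#'
#' Keeps voxels with z below `z_min + round(lower_fraction * z_extent)`,
#' where z_min/z_max bound the mask's occupied z range; a minimum slab of
#' one slice is guaranteed for degenerate masks.
#'
#' @param mask a [binary_mask()].
#' @param lower_fraction fraction of the z-extent to keep (default 1/3).
#' @return A [binary_mask()] of the same shape.
#' @export
lower_third <- function(mask, lower_fraction = 1 / 3) {
  if (!any(mask$grid))
    dct_error("empty lung mask", "diaphragmct_empty_segmentation")
  zs <- which(apply(mask$grid, 3, any))
  z_min <- min(zs); z_max <- max(zs)
  n_keep <- max(1L, as.integer(round(lower_fraction * (z_max - z_min + 1L))))
  grid <- mask$grid
  cut <- z_min + n_keep          # first excluded slice
  if (cut <= dim(grid)[3]) grid[, , cut:dim(grid)[3]] <- FALSE
  binary_mask(grid, mask$spacing, mask$origin, side = mask$side)
}

#' Keep the largest 8-connected component of a coronal slice
#'
#' Ties are broken in favour of the component containing the first voxel in
#' (z, x) scan order.
#'
#' @param slice logical matrix indexed (x, z).
#' @return A logical matrix with at most one component.
#' @export
largest_component_2d <- function(slice) {
  lab <- label_components_2d(slice, connectivity = 8L)
  k <- max(lab)
  if (k <= 1L) return(slice)
  sizes <- tabulate(lab, k)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    idx <- which(slice, arr.ind = TRUE)
    sk <- scan_key(idx, nrow(slice))
    first <- vapply(best, function(g) min(sk[lab[idx] == g]), numeric(1))
    best <- best[which.min(first)]
  }
  lab == best
}

#' Outline of a slice region
#'
#' Morphological dilation by a 3x3 square structuring element minus the
#' region itself: a one-layer 8-connected ring around the segmentation.
#'
#' @param slice logical matrix indexed (x, z).
#' @return A logical matrix holding the outline (disjoint from `slice`).
#' @export
outline_2d <- function(slice) {
  dilate_3x3(slice) & !slice
}

# Most caudal voxel within a set of (x, z) coords; ties at equal z resolved
# to the outermost x (away from the slice centre when outer_sign is +/-1).
most_caudal <- function(coords, outer_sign) {
  zmin <- min(coords[, 2])
  cand <- coords[coords[, 2] == zmin, , drop = FALSE]
  if (nrow(cand) > 1L) {
    xpick <- if (outer_sign < 0) min(cand[, 1]) else max(cand[, 1])
    cand <- cand[cand[, 1] == xpick, , drop = FALSE]
  }
  cand[1, ]
}

#' Cut an outline at the costophrenic recesses
#'
#' In each of the two search bands (the first and last `band_fraction` of
#' the outline's x-extent) the most caudal voxel is removed (outermost x on
#' ties). If the removal splits the closed outline into exactly two
#' components the smaller one is returned as the diaphragm arc; otherwise
#' the slice needs the fallback trace.
#'
#' The split is assessed with 4-connectivity: the box-dilation outline is a
#' simple 4-connected cycle, so removing one voxel per band separates it
#' into exactly two arcs, whereas its staircase corners carry diagonal
#' shortcuts that would keep an 8-connected ring in one piece. The returned
#' arc is still an 8-connected (indeed 4-connected) voxel path.
#'
#' @param outline logical matrix indexed (x, z), the closed outline ring.
#' @param params an [extraction_params()].
#' @return A list with `needs_fallback` (logical) and, when successful,
#'   `arc`: a `diaphragm_arc` whose `path` is an ordered n x 2 (x, z) matrix.
#' @export
cut_costophrenic <- function(outline, params = extraction_params()) {
  coords <- which(outline, arr.ind = TRUE)
  if (nrow(coords) == 0L) return(list(needs_fallback = TRUE))
  x_min <- min(coords[, 1]); x_max <- max(coords[, 1])
  width <- x_max - x_min + 1L
  if (width < 4L) return(list(needs_fallback = TRUE))
  bw <- max(1L, as.integer(floor(params$band_fraction * width)))
  in_left <- coords[, 1] <= x_min + bw - 1L
  in_right <- coords[, 1] >= x_max - bw + 1L
  rm1 <- most_caudal(coords[in_left, , drop = FALSE], outer_sign = -1)
  rm2 <- most_caudal(coords[in_right, , drop = FALSE], outer_sign = +1)
  cut <- outline
  cut[rm1[1], rm1[2]] <- FALSE
  cut[rm2[1], rm2[2]] <- FALSE
  lab <- label_components_2d(cut, connectivity = 4L)
  k <- max(lab)
  if (k != 2L) return(list(needs_fallback = TRUE))
  sizes <- tabulate(lab, 2L)
  pick <- if (sizes[1] != sizes[2]) which.min(sizes) else {
    # tie: the half containing the cut outline's most caudal voxel
    ccoords <- which(cut, arr.ind = TRUE)
    caud <- most_caudal(ccoords, outer_sign = -1)
    lab[caud[1], caud[2]]
  }
  acoords <- which(lab == pick, arr.ind = TRUE)
  path <- trace_path(acoords, nx = nrow(outline))
  list(needs_fallback = FALSE,
       arc = new_arc(path, provenance = "cut"))
}

#' Construct a per-slice diaphragm arc
#'
#' An ordered open path of (x, z) voxels in one coronal slice: the
#' lung-diaphragm intersection for that slice. Normally produced by
#' [cut_costophrenic()] or [fallback_trace()]; the constructor is exported
#' so arcs can be built directly for [filter_arc()] and [stitch_slices()].
#'
#' @param path n x 2 integer matrix of (x, z) voxels, consecutive rows
#'   8-adjacent.
#' @param y_index coronal slice position, if known.
#' @param provenance `"cut"` or `"fallback"`.
#' @return An object of class `diaphragm_arc`.
#' @export
diaphragm_arc <- function(path, y_index = NA_integer_, provenance = "cut") {
  path <- matrix(as.integer(path), ncol = 2,
                 dimnames = NULL)
  structure(list(path = path, y_index = as.integer(y_index),
                 provenance = provenance, status = "pending"),
            class = "diaphragm_arc")
}

new_arc <- diaphragm_arc

#' @export
print.diaphragm_arc <- function(x, ...) {
  cat("diaphragm_arc:", nrow(x$path), "voxels, provenance", x$provenance,
      if (!is.na(x$y_index)) paste("at y =", x$y_index) else "", "\n")
  invisible(x)
}

#' Fallback arc trace along the outline
#'
#' Used when removing the costophrenic voxels fails to split the outline.
#' The ring is traced outward in both directions from the most caudal voxel
#' at the outline's x-midpoint. On each side the candidate edge is that
#' side's most caudal voxel; it is accepted if the outline ascends (net z
#' increase) over the next `ascent_check_length` voxels beyond it, otherwise
#' the side's outermost voxel becomes the edge. The arc spans the caudal
#' portion between the two edges.
#'
#' @param outline logical matrix indexed (x, z).
#' @param params an [extraction_params()].
#' @return A `diaphragm_arc`, or `NULL` when the outline is too small to
#'   trace (fewer than `2 * ascent_check_length` voxels).
#' @export
fallback_trace <- function(outline, params = extraction_params()) {
  coords <- which(outline, arr.ind = TRUE)
  L <- params$ascent_check_length
  if (nrow(coords) < 2L * L) return(NULL)
  ring <- trace_path(coords, nx = nrow(outline))
  n <- nrow(ring)
  if (n < 2L * L) return(NULL)
  x_mid <- (min(ring[, 1]) + max(ring[, 1])) / 2
  # start: nearest the x-midpoint, most caudal on ties
  d <- abs(ring[, 1] - x_mid)
  cand <- which(d == min(d))
  cand <- cand[ring[cand, 2] == min(ring[cand, 2])]
  start <- cand[which.min(ring[cand, 1])]
  ring <- ring[c(start:n, seq_len(start - 1L)), , drop = FALSE]  # start at 1
  half <- (n - 1L) %/% 2L
  sideA <- ring[1L + seq_len(half), , drop = FALSE]
  sideB <- ring[n + 1L - seq_len(n - 1L - half), , drop = FALSE]
  pick_edge <- function(side) {
    m <- nrow(side)
    zmin <- min(side[, 2])
    ci <- which(side[, 2] == zmin)
    # outermost candidate on ties: farthest along the walk
    ci <- ci[length(ci)]
    ahead <- min(m, ci + params$ascent_check_length)
    ascends <- ahead > ci && side[ahead, 2] > side[ci, 2]
    if (ascends) return(ci)
    which.max(abs(side[, 1] - ring[1, 1]))   # outermost x of this side
  }
  eA <- pick_edge(sideA)
  eB <- pick_edge(sideB)
  path <- rbind(sideB[rev(seq_len(eB)), , drop = FALSE],
                ring[1, , drop = FALSE],
                sideA[seq_len(eA), , drop = FALSE])
  new_arc(path, provenance = "fallback")
}

#' Filter a per-slice arc
#'
#' Filter 1 removes arcs that curve caudally at the midpoint (valley
#' shapes): discard when the path-length midpoint lies caudal to both
#' endpoints. Filter 2 removes inward-curving arcs: discard when the
#' distance between the midpoint and the arc's most caudal voxel is below
#' `filter2_min_distance_fraction` of the arc's x-extent. Arcs shorter than
#' 3 voxels are discarded as degenerate.
#'
#' @param arc a `diaphragm_arc`.
#' @param params an [extraction_params()].
#' @return `"kept"`, `"discarded_filter1"` or `"discarded_filter2"`.
#' @export
filter_arc <- function(arc, params = extraction_params()) {
  path <- arc$path
  n <- nrow(path)
  if (n < 3L) return("discarded_filter2")
  m <- path[ceiling(n / 2), ]
  if (m[2] < min(path[1, 2], path[n, 2])) return("discarded_filter1")
  zmin <- min(path[, 2])
  caud <- path[path[, 2] == zmin, , drop = FALSE]
  # on ties (e.g. a perfectly flat arc) the caudal extreme farthest from the
  # midpoint is used, so flat arcs are kept and inward-curving hooks are not
  dist_mid <- sqrt(max((caud[, 1] - m[1])^2 + (caud[, 2] - m[2])^2))
  x_extent <- max(path[, 1]) - min(path[, 1]) + 1L
  if (dist_mid < params$filter2_min_distance_fraction * x_extent)
    return("discarded_filter2")
  "kept"
}

#' Stitch the current arc to the previously kept arc
#'
#' The previous slice's arc is overlaid into the current (x, z) plane, each
#' of its endpoints is joined to the nearer endpoint of the current arc by a
#' digital straight segment, and the interior of the resulting closed curve
#' is filled. The filled region guarantees 26-connectivity of consecutive
#' slice regions in 3D.
#'
#' @param prev a `diaphragm_arc` or `NULL` (first kept slice).
#' @param cur the current slice's kept `diaphragm_arc`.
#' @param dims integer length-2: the (x, z) slice dimensions.
#' @return A logical matrix: the filled region for the current slice.
#' @export
stitch_slices <- function(prev, cur, dims) {
  region <- matrix(FALSE, dims[1], dims[2])
  region[cur$path] <- TRUE
  if (is.null(prev)) return(region)
  region[prev$path] <- TRUE
  p_ends <- prev$path[c(1L, nrow(prev$path)), , drop = FALSE]
  c_ends <- cur$path[c(1L, nrow(cur$path)), , drop = FALSE]
  d <- function(a, b) sum((a - b)^2)
  straight <- d(p_ends[1, ], c_ends[1, ]) + d(p_ends[2, ], c_ends[2, ])
  crossed <- d(p_ends[1, ], c_ends[2, ]) + d(p_ends[2, ], c_ends[1, ])
  pairing <- if (straight <= crossed) cbind(1:2, 1:2) else cbind(1:2, 2:1)
  for (k in 1:2) {
    seg <- line_voxels(p_ends[pairing[k, 1], ], c_ends[pairing[k, 2], ])
    seg <- seg[seg[, 1] >= 1 & seg[, 1] <= dims[1] &
               seg[, 2] >= 1 & seg[, 2] <= dims[2], , drop = FALSE]
    region[seg] <- TRUE
  }
  fill_holes_2d(region)
}

#' Extract the lung-diaphragm intersection surface of one lung
#'
#' Orchestrates the full per-lung pipeline: restrict to the lower third,
#' then per coronal slice keep the largest component, outline it, cut at the
#' costophrenic recesses (falling back to the midpoint trace when the cut
#' fails), filter out non-diaphragm arcs, and stitch kept arcs to the
#' previous one. Finally only the largest 26-connected 3D component is
#' retained, which resolves gaps left by filtered slices.
#'
#' @param lung a [binary_mask()] for one lung (isotropically resampled).
#' @param params an [extraction_params()].
#' @return An object of class `diaphragm_surface`: a list with the logical
#'   3D `grid`, `spacing`, `origin`, `side` and a per-slice `slice_log`
#'   data frame (`y`, `provenance`, `status`).
#' @export
extract_diaphragm <- function(lung, params = extraction_params()) {
  stopifnot(inherits(lung, "binary_mask"))
  if (!any(lung$grid))
    dct_error("empty lung mask", "diaphragmct_empty_segmentation")
  lt <- lower_third(lung, params$lower_fraction)
  dims <- dim(lt$grid)
  surface <- array(FALSE, dims)
  log_y <- integer(0); log_prov <- character(0); log_status <- character(0)
  prev <- NULL
  for (y in seq_len(dims[2])) {
    slice <- lt$grid[, y, ]
    if (!any(slice)) next
    slice <- largest_component_2d(slice)
    outline <- outline_2d(slice)
    res <- cut_costophrenic(outline, params)
    if (res$needs_fallback) {
      arc <- fallback_trace(outline, params)
      if (is.null(arc)) {
        log_y <- c(log_y, y); log_prov <- c(log_prov, "fallback")
        log_status <- c(log_status, "skipped_untraceable")
        next
      }
    } else {
      arc <- res$arc
    }
    arc$y_index <- y
    status <- filter_arc(arc, params)
    arc$status <- status
    log_y <- c(log_y, y); log_prov <- c(log_prov, arc$provenance)
    log_status <- c(log_status, status)
    if (status != "kept") next
    surface[, y, ] <- stitch_slices(prev, arc, dims[c(1, 3)])
    prev <- arc
  }
  slice_log <- data.frame(y = log_y, provenance = log_prov,
                          status = log_status, stringsAsFactors = FALSE)
  if (!any(surface)) {
    stop(errorCondition(
      paste0("diaphragm extraction failed for ", lung$side,
             " lung: no coronal slice produced a kept arc"),
      slice_log = slice_log,
      class = c("diaphragmct_extraction_failure", "diaphragmct_error")))
  }
  surface <- largest_component_3d(surface)
  structure(list(grid = surface, spacing = lung$spacing, origin = lung$origin,
                 side = lung$side, slice_log = slice_log),
            class = "diaphragm_surface")
}

#' @export
print.diaphragm_surface <- function(x, ...) {
  kept <- sum(x$slice_log$status == "kept")
  cat("diaphragm_surface (", x$side, "): ", sum(x$grid), " voxels over ",
      kept, " kept coronal slices (", nrow(x$slice_log),
      " processed)\n", sep = "")
  invisible(x)
}
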