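#' Height map of a diaphragm surface
#'
#' Collapses the (possibly multi-voxel-thick) surface sheet to one height
#' per occupied (x, y) column: the mean z of that column's surface voxels,
#' in mm, measured relative to the surface's own most caudal voxel. Using
#' the mean makes the height robust to the fill thickness left by
#' stitching; the relative datum makes all downstream areas independent of
#' the absolute scanner z position.
#'
#' @param surface a `diaphragm_surface` from [extract_diaphragm()], or any
#'   list with a logical 3D `grid` and `spacing`.
#' @return An object of class `height_map`: list with `height` (nx x ny
#'   matrix in mm, `NA` outside the footprint) and `spacing` (x, y mm).
#' @export
to_height_map <- function(surface) {
  grid <- surface$grid
  if (!any(grid))
    dct_error("empty diaphragm surface", "diaphragmct_empty_surface")
  dims <- dim(grid)
  idx <- which(grid, arr.ind = TRUE)
  z0 <- min(idx[, 3])
  col <- (idx[, 2] - 1L) * dims[1] + idx[, 1]
  zsum <- rowsum(as.numeric(idx[, 3] - z0), col)
  zn <- rowsum(rep(1, nrow(idx)), col)
  height <- matrix(NA_real_, dims[1], dims[2])
  height[as.integer(rownames(zsum))] <- (zsum / zn) * surface$spacing[3]
  structure(list(height = height, spacing = surface$spacing[1:2]),
            class = "height_map")
}

# Per-cell corner matrices of a height map: corners 00, 10, 01, 11 of each
# (nx-1) x (ny-1) unit cell.
cell_corners <- function(hm) {
  H <- hm$height
  nx <- nrow(H); ny <- ncol(H)
  if (nx < 2L || ny < 2L)
    dct_error("height map has no complete cell", "diaphragmct_degenerate_surface")
  list(
    A = H[-nx, -ny], B = H[-1, -ny],   # z at (0,0) and (sx,0)
    C = H[-nx, -1],  D = H[-1, -1]     # z at (0,sy) and (sx,sy)
  )
}

#' Triangulated surface area of a height map
#'
#' Every complete unit cell (all four corner columns occupied) is split
#' into four triangles meeting at the cell centroid (height = mean of the
#' four corners) and the 3D triangle areas are summed. Cells with any
#' absent corner contribute nothing. The fan construction is exactly
#' invariant under left-right mirroring and integer translation of the
#' surface; per-cell areas are summed in sorted order so the total is too.
#'
#' @param hm a [to_height_map()] result.
#' @return Surface area in mm^2.
#' @export
surface_area <- function(hm) {
  cc <- cell_corners(hm)
  ok <- !(is.na(cc$A) | is.na(cc$B) | is.na(cc$C) | is.na(cc$D))
  if (!any(ok))
    dct_error("height map has no complete cell", "diaphragmct_degenerate_surface")
  A <- cc$A[ok]; B <- cc$B[ok]; C <- cc$C[ok]; D <- cc$D[ok]
  # canonicalise over the x-mirror symmetry (A<->B, C<->D) so mirrored
  # inputs take bit-identical float paths
  sw <- (B < A) | (B == A & D < C)
  tmp <- A[sw]; A[sw] <- B[sw]; B[sw] <- tmp
  tmp <- C[sw]; C[sw] <- D[sw]; D[sw] <- tmp
  sx <- hm$spacing[1]; sy <- hm$spacing[2]
  M <- ((A + B) + (C + D)) / 4
  # triangle over one cell edge (heights h1 -> h2 along an edge of length
  # `len`, apex at centroid): cross-product area, vectorised
  tri <- function(h1, h2, len, other) {
    dz <- h2 - h1
    zc <- M - (h1 + h2) / 2
    0.5 * sqrt((dz * other / 2)^2 + (zc * len)^2 + (len * other / 2)^2)
  }
  areas <- tri(A, B, sx, sy) +   # caudal edge (y = 0)
           tri(C, D, sx, sy) +   # cranial edge (y = sy)
           tri(A, C, sy, sx) +   # left edge   (x = 0)
           tri(B, D, sy, sx)     # right edge  (x = sx)
  sum(sort(areas))
}

#' Axially projected area of a height map
#'
#' The number of complete unit cells times the cell area, on the same cell
#' grid as [surface_area()], so a perfectly flat surface has index exactly 1.
#'
#' @param hm a [to_height_map()] result.
#' @return Projected area in mm^2.
#' @export
projected_area <- function(hm) {
  cc <- cell_corners(hm)
  ok <- !(is.na(cc$A) | is.na(cc$B) | is.na(cc$C) | is.na(cc$D))
  if (!any(ok))
    dct_error("height map has no complete cell", "diaphragmct_degenerate_surface")
  sum(ok) * hm$spacing[1] * hm$spacing[2]
}

#' Diaphragm index of one or two lung surfaces
#'
#' The diaphragm index is the ratio of diaphragm surface area to its
#' axially projected area: 1 for a perfectly flat diaphragm, 2 for a
#' hemispherical dome. The combined index pools areas across sides:
#' (SA_L + SA_R) / (PA_L + PA_R).
#'
#' @param left,right `diaphragm_surface` objects (either may be `NULL`).
#' @return An object of class `diaphragm_index_result`: a data frame with
#'   one row per side plus a combined row, columns `side`, `surface_area`,
#'   `projected_area`, `diaphragm_index`.
#' @export
diaphragm_index <- function(left = NULL, right = NULL) {
  if (is.null(left) && is.null(right))
    dct_error("at least one lung surface is required", "diaphragmct_parameter_error")
  rows <- list()
  for (side in c("left", "right")) {
    s <- if (side == "left") left else right
    if (is.null(s)) next
    hm <- to_height_map(s)
    sa <- surface_area(hm)
    pa <- projected_area(hm)
    if (pa <= 0)
      dct_error(paste0("degenerate ", side, " surface: projected area is 0"),
                "diaphragmct_degenerate_surface")
    rows[[side]] <- data.frame(side = side, surface_area = sa,
                               projected_area = pa,
                               diaphragm_index = sa / pa,
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res <- rbind(res, data.frame(
    side = "combined",
    surface_area = sum(res$surface_area),
    projected_area = sum(res$projected_area),
    diaphragm_index = sum(res$surface_area) / sum(res$projected_area),
    stringsAsFactors = FALSE))
  rownames(res) <- NULL
  class(res) <- c("diaphragm_index_result", "data.frame")
  res
}

#' @export
print.diaphragm_index_result <- function(x, digits = 4, ...) {
  cat("Diaphragm index (surface area / projected area)\n")
  df <- as.data.frame(x)
  df$surface_area <- round(df$surface_area, 1)
  df$projected_area <- round(df$projected_area, 1)
  df$diaphragm_index <- round(df$diaphragm_index, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Emphysema score (%LAA-950)
#'
#' Percentage of lung-mask voxels whose attenuation lies below the
#' threshold (default -950 HU), the standard CT emphysema densitometry.
#'
#' @param ct 3D numeric array of Hounsfield units (or a list with a `grid`
#'   element), co-registered with the lung mask.
#' @param lung a [binary_mask()] (or logical array) on the same grid.
#' @param threshold HU threshold, default -950.
#' @return A list with `percent` (in [0, 100]), `threshold` and
#'   `n_lung_voxels`.
#' @export
emphysema_score <- function(ct, lung, threshold = -950) {
  ct_grid <- if (is.list(ct)) ct$grid else ct
  lung_grid <- if (is.list(lung)) lung$grid else lung
  if (!identical(dim(ct_grid), dim(lung_grid)))
    dct_error("CT and lung mask grids do not align", "diaphragmct_alignment_error")
  n <- sum(lung_grid)
  if (n == 0L)
    dct_error("empty lung mask", "diaphragmct_empty_segmentation")
  pct <- 100 * sum(ct_grid[lung_grid] < threshold) / n
  list(percent = pct, threshold = threshold, n_lung_voxels = n)
}
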