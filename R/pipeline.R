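#' Measure the diaphragm index of a chest-CT lung segmentation
#'
#' The end-to-end pipeline: resample the label volume to an isotropic grid,
#' merge lobe labels into left/right lung masks, extract each lung's
#' lung-diaphragm intersection surface, and compute per-side and pooled
#' diaphragm indices.
#'
#' @param vol a [label_volume()] (lobe or lung segmentation).
#' @param map a [label_map()] assigning labels to sides.
#' @param params an [extraction_params()].
#' @param target_spacing isotropic voxel size in mm for processing
#'   (default 1).
#' @return An object of class `diaphragm_measurement`: list with `index`
#'   (a [diaphragm_index()] result), `surfaces` (per-side
#'   `diaphragm_surface` or `NULL`), `params` and `target_spacing`.
#' @examples
#' spec <- cap_phantom_spec(a = 30, h = 15, lung_height = 50)
#' vol <- make_cap_phantom(spec)
#' res <- measure_diaphragm(vol)
#' res$index
#' analytic_cap_index(30, 15)
#' @export
measure_diaphragm <- function(vol, map = label_map(),
                              params = extraction_params(),
                              target_spacing = 1.0) {
  stopifnot(inherits(vol, "label_volume"))
  vol <- resample_isotropic(vol, target_spacing)
  lungs <- split_lungs(vol, map)
  surfaces <- list(left = NULL, right = NULL)
  for (side in c("left", "right")) {
    if (any(lungs[[side]]$grid))
      surfaces[[side]] <- extract_diaphragm(lungs[[side]], params)
  }
  idx <- diaphragm_index(left = surfaces$left, right = surfaces$right)
  structure(list(index = idx, surfaces = surfaces, params = params,
                 target_spacing = target_spacing),
            class = "diaphragm_measurement")
}

#' @export
print.diaphragm_measurement <- function(x, ...) {
  print(x$index, ...)
  for (side in c("left", "right")) {
    s <- x$surfaces[[side]]
    if (!is.null(s)) {
      kept <- sum(s$slice_log$status == "kept")
      cat(sprintf("  %s lung: %d surface voxels, %d/%d slices kept\n",
                  side, sum(s$grid), kept, nrow(s$slice_log)))
    }
  }
  invisible(x)
}

#' @export
summary.diaphragm_measurement <- function(object, ...) {
  logd <- lapply(c("left", "right"), function(side) {
    s <- object$surfaces[[side]]
    if (is.null(s)) return(NULL)
    tab <- table(s$slice_log$status)
    data.frame(side = side, status = names(tab), n = as.integer(tab),
               stringsAsFactors = FALSE)
  })
  out <- list(index = object$index, slice_status = do.call(rbind, logd))
  class(out) <- "summary.diaphragm_measurement"
  out
}

#' @export
print.summary.diaphragm_measurement <- function(x, ...) {
  print(x$index)
  cat("\nPer-slice extraction status:\n")
  print(x$slice_status, row.names = FALSE)
  invisible(x)
}
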