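#' Label volume container
#'
#' A `label_volume` holds a 3D grid of non-negative integer labels together
#' with per-axis voxel spacing (mm) and an origin (mm). The canonical axis
#' convention is x = left-to-right, y = posterior-to-anterior,
#' z = caudal-to-cranial (RAS); volumes read from disk are reoriented to this
#' frame when the header carries orientation information.
#'
#' @param grid 3D array of non-negative integers (0 = background).
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3, position of the first voxel centre in mm.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L) stop("grid must be a 3D array")
  if (any(dim(grid) < 1L)) stop("grid dimensions must all be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm)")
  if (any(grid < 0, na.rm = TRUE)) stop("labels must be non-negative")
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, spacing = spacing, origin = as.numeric(origin)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", paste(dim(x$grid), collapse = " x "), "voxels,",
      paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  labs <- sort(unique(as.vector(x$grid)))
  cat("  labels:", paste(labs, collapse = ", "), "\n")
  invisible(x)
}

#' Binary mask container
#'
#' Same grid contract as [label_volume()] but with a logical grid and a
#' `side` tag (`"left"`, `"right"` or `"n/a"`).
#'
#' @param grid 3D logical array.
#' @param spacing,origin as in [label_volume()].
#' @param side which lung the mask represents.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        side = c("n/a", "left", "right")) {
  side <- match.arg(side)
  if (length(dim(grid)) != 3L) stop("grid must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be positive")
  storage.mode(grid) <- "logical"
  structure(list(grid = grid, spacing = spacing, origin = as.numeric(origin),
                 side = side),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("binary_mask (", x$side, "): ", paste(dim(x$grid), collapse = " x "),
      " voxels, ", sum(x$grid), " foreground\n", sep = "")
  invisible(x)
}

dct_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "diaphragmct_error")))
}

has_ext <- function(path, exts) {
  any(vapply(exts, function(e) grepl(paste0("\\.", e, "$"), path,
                                     ignore.case = TRUE), logical(1)))
}

#' Read a label volume from NIfTI or MetaImage
#'
#' Integer labels are preserved exactly; spacing is taken from the header.
#' NIfTI volumes carrying a qform/sform are reoriented to the canonical RAS
#' frame; MetaImage volumes with an axis-aligned TransformMatrix are
#' permuted/flipped accordingly.
#'
#' @param path file path ending in `.nii`, `.nii.gz`, `.mha` or `.mhd`.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path))
    dct_error(paste0("cannot read '", path, "': file does not exist"),
              "diaphragmct_io_error")
  if (has_ext(path, c("nii", "nii\\.gz"))) {
    img <- RNifti::readNifti(path)
    suppressWarnings(RNifti::orientation(img) <- "RAS")
    grid <- array(as.vector(img), dim(img))   # plain array, no image attributes
    if (length(dim(grid)) == 4L && dim(grid)[4] == 1L)
      grid <- grid[, , , 1, drop = TRUE]
    if (any(grid != round(grid)))
      dct_error("volume has non-integer voxel values; expected a label map",
                "diaphragmct_type_error")
    sp <- RNifti::pixdim(img)[1:3]
    label_volume(grid, spacing = sp, origin = c(0, 0, 0))
  } else if (has_ext(path, c("mha", "mhd"))) {
    read_metaimage(path)
  } else {
    dct_error(paste0("unsupported volume format: '", path,
                     "' (expected .nii, .nii.gz, .mha or .mhd)"),
              "diaphragmct_format_error")
  }
}

#' Write a label volume or binary mask
#'
#' @param vol a [label_volume()] or [binary_mask()].
#' @param path output path; format chosen by extension (`.nii`, `.nii.gz`,
#'   `.mha`, `.mhd`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  grid <- vol$grid
  storage.mode(grid) <- "integer"
  if (has_ext(path, c("nii", "nii\\.gz"))) {
    img <- RNifti::asNifti(grid)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  } else if (has_ext(path, c("mha", "mhd"))) {
    write_metaimage(grid, vol$spacing, vol$origin, path)
  } else {
    dct_error(paste0("unsupported output format: '", path, "'"),
              "diaphragmct_format_error")
  }
  invisible(path)
}

# --- MetaImage (.mha single-file, .mhd + .raw) ------------------------------
# Minimal reader/writer for the uncompressed 3D integer case used here.

metaimage_types <- c(
  MET_UCHAR = 1L, MET_CHAR = 1L, MET_USHORT = 2L, MET_SHORT = 2L,
  MET_UINT = 4L, MET_INT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L
)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list(); data_offset <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) dct_error("truncated MetaImage header",
                                 "diaphragmct_io_error")
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) dct_error(paste("bad MetaImage header line:", line),
                                    "diaphragmct_io_error")
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3L)
    dct_error("only 3D MetaImage volumes are supported", "diaphragmct_format_error")
  type <- hdr$ElementType
  if (!type %in% names(metaimage_types))
    dct_error(paste("unsupported MetaImage ElementType:", type),
              "diaphragmct_type_error")
  if (type %in% c("MET_FLOAT", "MET_DOUBLE"))
    dct_error("volume has floating-point voxel type; expected a label map",
              "diaphragmct_type_error")
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  compressed <- identical(toupper(hdr$CompressedData %||% "FALSE"), "TRUE")
  msb <- identical(toupper(hdr$ElementByteOrderMSB %||%
                           hdr$BinaryDataByteOrderMSB %||% "FALSE"), "TRUE")
  size <- metaimage_types[[type]]
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, "raw", n = file.size(path))
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawpath))
      dct_error(paste0("cannot read MetaImage data file '", rawpath, "'"),
                "diaphragmct_io_error")
    raw <- readBin(rawpath, "raw", n = file.size(rawpath))
  }
  if (compressed) raw <- memDecompress(raw, type = "gzip")
  signed <- type %in% c("MET_CHAR", "MET_SHORT", "MET_INT")
  vals <- readBin(raw, "integer", n = n, size = size, signed = signed || size == 4L,
                  endian = if (msb) "big" else "little")
  grid <- array(vals, dim = dims)
  tm <- hdr$TransformMatrix
  if (!is.null(tm)) {
    M <- matrix(as.numeric(strsplit(tm, "\\s+")[[1]]), 3L, 3L, byrow = TRUE)
    grid <- reorient_axis_aligned(grid, M)
    spacing <- abs(as.numeric(M %*% spacing))
  }
  label_volume(grid, spacing = spacing, origin = origin)
}

# Apply an axis-aligned direction matrix (signed permutation) to the grid.
reorient_axis_aligned <- function(grid, M) {
  if (all(M == diag(3))) return(grid)
  if (any(abs(M) != 0 & abs(M) != 1) || any(colSums(abs(M)) != 1) ||
      any(rowSums(abs(M)) != 1))
    dct_error("oblique MetaImage TransformMatrix is not supported",
              "diaphragmct_format_error")
  perm <- apply(abs(M), 2, which.max)
  grid <- aperm(grid, order(perm))
  for (ax in 1:3) {
    if (M[ax, perm == ax] < 0) {
      idx <- rev(seq_len(dim(grid)[ax]))
      grid <- switch(ax, grid[idx, , , drop = FALSE],
                     grid[, idx, , drop = FALSE],
                     grid[, , idx, drop = FALSE])
    }
  }
  grid
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_metaimage <- function(grid, spacing, origin, path) {
  dims <- dim(grid)
  mhd <- has_ext(path, "mhd")
  datafile <- if (mhd) paste0(sub("\\.mhd$", "", basename(path),
                                  ignore.case = TRUE), ".raw") else "LOCAL"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(origin, collapse = " ")),
    paste("ElementSpacing =", paste(spacing, collapse = " ")),
    paste("DimSize =", paste(dims, collapse = " ")),
    "ElementType = MET_INT",
    paste("ElementDataFile =", datafile)
  )
  con <- file(path, "wb")
  writeLines(hdr, con)
  if (!mhd) {
    writeBin(as.integer(grid), con, size = 4L, endian = "little")
    close(con)
  } else {
    close(con)
    rcon <- file(file.path(dirname(path), datafile), "wb")
    writeBin(as.integer(grid), rcon, size = 4L, endian = "little")
    close(rcon)
  }
  invisible(path)
}

# --- Resampling -------------------------------------------------------------

#' Resample a label volume to an isotropic grid
#'
#' Nearest-neighbour label assignment: no new label values are created. The
#' output grid has `ceiling(extent / target)` voxels per axis so the input's
#' physical extent is never cropped.
#'
#' @param vol a [label_volume()] or [binary_mask()].
#' @param target isotropic voxel size in mm (default 1).
#' @return A resampled object of the same class as `vol`.
#' @export
resample_isotropic <- function(vol, target = 1.0) {
  if (!is.numeric(target) || length(target) != 1L || !is.finite(target) ||
      target <= 0)
    dct_error("target spacing must be a single positive number",
              "diaphragmct_parameter_error")
  sp <- vol$spacing
  dims <- dim(vol$grid)
  if (all(sp == target)) return(vol)
  out_dims <- pmax(1L, as.integer(ceiling(dims * sp / target)))
  idx <- lapply(1:3, function(ax) {
    centres <- (seq_len(out_dims[ax]) - 1) * target   # mm from first voxel
    pmin(dims[ax], pmax(1L, as.integer(round(centres / sp[ax])) + 1L))
  })
  grid <- vol$grid[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  if (inherits(vol, "binary_mask"))
    binary_mask(grid, spacing = rep(target, 3), origin = vol$origin,
                side = vol$side)
  else
    label_volume(grid, spacing = rep(target, 3), origin = vol$origin)
}

# --- Lung splitting ---------------------------------------------------------

#' Lobe-label to lung-side mapping
#'
#' The default follows the common 5-lobe convention: labels 1-2 form the
#' left lung (upper/lower lobes), labels 3-5 the right (upper/middle/lower).
#'
#' @param left,right integer vectors of lobe labels; must be disjoint.
#' @return An object of class `label_map`.
#' @export
label_map <- function(left = c(1L, 2L), right = c(3L, 4L, 5L)) {
  left <- as.integer(left); right <- as.integer(right)
  if (length(intersect(left, right)))
    stop("a label cannot map to both sides")
  if (!length(left) && !length(right)) stop("label map is empty")
  structure(list(left = left, right = right), class = "label_map")
}

#' Read a label map from a JSON config file
#'
#' The file holds an object with `left` and `right` integer arrays, e.g.
#' `{"left": [1, 2], "right": [3, 4, 5]}`.
#'
#' @param path JSON file path.
#' @return A [label_map()].
#' @export
read_label_map <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  label_map(left = cfg$left %||% integer(0), right = cfg$right %||% integer(0))
}

#' Split a lobe/lung label volume into left and right lung masks
#'
#' @param vol a [label_volume()].
#' @param map a [label_map()] assigning lobe labels to sides.
#' @return A list with elements `left` and `right`, each a [binary_mask()].
#' @export
split_lungs <- function(vol, map = label_map()) {
  stopifnot(inherits(vol, "label_volume"), inherits(map, "label_map"))
  lgrid <- array(vol$grid %in% map$left, dim(vol$grid))
  rgrid <- array(vol$grid %in% map$right, dim(vol$grid))
  if (!any(lgrid) && !any(rgrid))
    dct_error("no voxels map to either lung: empty segmentation",
              "diaphragmct_empty_segmentation")
  list(
    left = binary_mask(lgrid, vol$spacing, vol$origin, side = "left"),
    right = binary_mask(rgrid, vol$spacing, vol$origin, side = "right")
  )
}
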