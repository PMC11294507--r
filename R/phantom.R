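#' Analytic diaphragm index of a spherical cap
#'
#' A spherical cap of base radius `a` and height `h` has lateral area
#' pi * (a^2 + h^2) and base (projected) area pi * a^2, so its diaphragm
#' index is exactly 1 + (h/a)^2: 1 in the flat limit, 2 for a hemisphere.
#'
#' @param a cap base radius in mm (> 0).
#' @param h cap height in mm (0 <= h <= a).
#' @return The dimensionless analytic index.
#' @export
analytic_cap_index <- function(a, h) {
  if (!is.numeric(a) || a <= 0)
    dct_error("cap base radius a must be positive", "diaphragmct_parameter_error")
  if (!is.numeric(h) || h < 0 || h > a)
    dct_error("cap height h must satisfy 0 <= h <= a",
              "diaphragmct_parameter_error")
  1 + (h / a)^2
}

#' Specification of a spherical-cap lung phantom
#'
#' Describes a synthetic lung label volume whose caudal boundary is a
#' spherical cap (the idealised diaphragm dome) under a cylindrical lung
#' body with a flat top. Only the lower third of the lung matters to the
#' extraction algorithm, so the simple body keeps the analytic base area
#' exact while the dome provides ground truth with index 1 + (h/a)^2.
#'
#' The lung height defaults to `max(3.5 * h, 40)` mm so the dome always
#' lies inside the lower third of the lung, mirroring real anatomy where
#' the dome is small relative to lung height.
#'
#' @param a cap base radius mm (> 0).
#' @param h cap (dome) height mm for the generated lung, `0 <= h <= a`.
#' @param side `"right"` (default) or `"left"`; ignored when `h_right` is
#'   given.
#' @param h_right if non-`NULL`, generate two lungs: the left with height
#'   `h`, the right with `h_right`.
#' @param spacing isotropic voxel size mm (default 1).
#' @param lung_height lung body height mm; must be >= 3.2 * max dome
#'   height. Default `max(3.5 * h, 40)`.
#' @param margin empty margin around the phantom, in voxels (default 3).
#' @param roughen_sd if > 0, the dome surface is roughened by adding
#'   N(0, roughen_sd) mm column-wise noise (clipped to +/- 2 voxels) to the
#'   analytic dome height; requires `seed`.
#' @param seed integer seed for the roughening noise (ignored when
#'   `roughen_sd == 0`); generation is fully deterministic given the spec.
#' @return An object of class `cap_phantom_spec`.
#' @export
cap_phantom_spec <- function(a = 60, h = 30, side = c("right", "left"),
                             h_right = NULL, spacing = 1,
                             lung_height = NULL, margin = 3L,
                             roughen_sd = 0, seed = 1L) {
  side <- match.arg(side)
  h_all <- c(h, h_right)
  if (a <= 0) dct_error("a must be positive", "diaphragmct_parameter_error")
  if (any(h_all < 0) || any(h_all > a))
    dct_error("dome heights must satisfy 0 <= h <= a",
              "diaphragmct_parameter_error")
  if (spacing <= 0) dct_error("spacing must be positive",
                              "diaphragmct_parameter_error")
  if (is.null(lung_height)) lung_height <- max(3.5 * max(h_all), 40)
  if (lung_height < 3.2 * max(h_all))
    dct_error("lung_height must be at least 3.2 times the dome height",
              "diaphragmct_parameter_error")
  structure(list(a = a, h = h, h_right = h_right, side = side,
                 spacing = spacing, lung_height = lung_height,
                 margin = as.integer(margin), roughen_sd = roughen_sd,
                 seed = as.integer(seed)),
            class = "cap_phantom_spec")
}

# Sphere radius of the cap: R = (a^2 + h^2) / (2h).
cap_sphere_radius <- function(a, h) (a^2 + h^2) / (2 * h)

# Analytic dome height above the rim plane at lateral distance rho <= a.
cap_dome_z <- function(a, h, rho) {
  if (h == 0) return(rep(0, length(rho)))
  R <- cap_sphere_radius(a, h)
  sqrt(pmax(0, R^2 - rho^2)) - (R - h)
}

# Internal geometry shared by the generator and the analytic oracle.
phantom_geometry <- function(spec) {
  m <- spec$margin * spec$spacing
  two <- !is.null(spec$h_right)
  gap <- 10                                   # mm between the two lungs
  lungs <- if (two) {
    list(list(side = "left", h = spec$h, cx = m + spec$a),
         list(side = "right", h = spec$h_right, cx = m + 3 * spec$a + gap))
  } else {
    list(list(side = spec$side, h = spec$h, cx = m + spec$a))
  }
  width <- if (two) 4 * spec$a + gap + 2 * m else 2 * spec$a + 2 * m
  z_base <- m
  list(lungs = lungs, cy = m + spec$a, z_base = z_base,
       extent = c(width, 2 * spec$a + 2 * m,
                  z_base + spec$lung_height + m))
}

#' Generate a spherical-cap lung phantom
#'
#' Voxels belong to a lung when their lateral distance to the lung centre
#' is at most `a` and their z lies between the dome surface and the flat
#' lung top. Left-lung voxels carry lobe labels 1-2 (split at mid-height),
#' right-lung voxels labels 3-5 (thirds), so the lobe-to-lung merge is
#' exercised downstream.
#'
#' @param spec a [cap_phantom_spec()].
#' @return A [label_volume()].
#' @export
make_cap_phantom <- function(spec) {
  stopifnot(inherits(spec, "cap_phantom_spec"))
  geo <- phantom_geometry(spec)
  sp <- spec$spacing
  dims <- as.integer(ceiling(geo$extent / sp)) + 1L
  xs <- (seq_len(dims[1]) - 1) * sp
  ys <- (seq_len(dims[2]) - 1) * sp
  zs <- (seq_len(dims[3]) - 1) * sp
  grid <- array(0L, dims)
  z_top <- geo$z_base + spec$lung_height
  for (lung in geo$lungs) {
    rho <- sqrt(outer((xs - lung$cx)^2, (ys - geo$cy)^2, "+"))
    inside <- rho <= spec$a
    dome <- matrix(0, dims[1], dims[2])
    dome[inside] <- geo$z_base + cap_dome_z(spec$a, lung$h, rho[inside])
    if (spec$roughen_sd > 0) {
      # self-seeded, and the caller's RNG stream is left untouched
      old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(spec$seed)
      rng <- matrix(stats::rnorm(prod(dims[1:2]), sd = spec$roughen_sd),
                    dims[1], dims[2])
      if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv())
      rng <- pmin(pmax(rng, -2 * sp), 2 * sp)
      dome[inside] <- pmax(geo$z_base, dome[inside] + rng[inside])
    }
    labels <- if (lung$side == "left") c(1L, 2L) else c(3L, 4L, 5L)
    nl <- length(labels)
    for (k in seq_len(dims[3])) {
      z <- zs[k]
      if (z > z_top) next
      sel <- inside & (z >= dome)
      if (!any(sel)) next
      band <- min(nl, 1L + floor(nl * (z - geo$z_base) /
                                   (spec$lung_height + 1e-9)))
      band <- max(1L, band)
      slice <- grid[, , k]
      slice[sel] <- labels[band]
      grid[, , k] <- slice
    }
  }
  label_volume(grid, spacing = rep(sp, 3), origin = c(0, 0, 0))
}

#' Analytic dome height map of a phantom
#'
#' Ground-truth dome height (mm above the rim plane) per (x, y) voxel
#' column for one lung of the phantom, for surface-fidelity checks.
#'
#' @param spec a [cap_phantom_spec()].
#' @param side which lung (`"left"`/`"right"`); defaults to the only one.
#' @return A matrix matching the phantom (x, y) grid; `NA` outside the
#'   lung footprint. Attribute `z_base_vox` gives the rim plane position
#'   in voxel units (1-based).
#' @export
cap_dome_height <- function(spec, side = NULL) {
  geo <- phantom_geometry(spec)
  sides <- vapply(geo$lungs, `[[`, character(1), "side")
  if (is.null(side)) side <- sides[1]
  lung <- geo$lungs[[match(side, sides)]]
  sp <- spec$spacing
  dims <- as.integer(ceiling(geo$extent / sp)) + 1L
  xs <- (seq_len(dims[1]) - 1) * sp
  ys <- (seq_len(dims[2]) - 1) * sp
  rho <- sqrt(outer((xs - lung$cx)^2, (ys - geo$cy)^2, "+"))
  dome <- matrix(NA_real_, dims[1], dims[2])
  inside <- rho <= spec$a
  dome[inside] <- cap_dome_z(spec$a, lung$h, rho[inside])
  attr(dome, "z_base_vox") <- geo$z_base / sp + 1
  dome
}
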