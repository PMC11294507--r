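# A small coronal test shape: slab with a domed caudal boundary, the kind of
# cross-section the per-slice pipeline sees.
dome_slice <- function(nx = 41, nz = 32, a = 18, h = 10, z0 = 4) {
  m <- matrix(FALSE, nx, nz)
  cx <- (nx + 1) / 2
  R <- (a^2 + h^2) / (2 * h)
  for (i in seq_len(nx)) {
    rho <- abs(i - cx)
    if (rho > a) next
    zlow <- z0 + sqrt(R^2 - rho^2) - (R - h)
    m[i, ceiling(zlow):(nz - 3L)] <- TRUE   # flat top inside the grid
  }
  m
}

test_that("lower_third keeps the caudal third of the occupied z range", {
  grid <- array(FALSE, c(5, 5, 40))
  grid[2:4, 2:4, 1:30] <- TRUE                    # z extent 30
  mask <- binary_mask(grid, side = "right")
  lt <- lower_third(mask)
  zs <- which(apply(lt$grid, 3, any))
  expect_identical(range(zs), c(1L, 10L))         # round(30 / 3) = 10 slices
})

test_that("lower_third guards a one-slice slab and rejects empty masks", {
  grid <- array(FALSE, c(4, 4, 8)); grid[2, 2, 5] <- TRUE
  lt <- lower_third(binary_mask(grid))
  expect_identical(lt$grid, grid)
  expect_error(lower_third(binary_mask(array(FALSE, c(3, 3, 3)))),
               class = "diaphragmct_empty_segmentation")
})

test_that("largest_component_2d keeps the most-voxel component", {
  m <- matrix(FALSE, 20, 20)
  m[2:6, 2:3] <- TRUE           # 10 voxels
  m[12:16, 12] <- TRUE          # 5 voxels
  out <- largest_component_2d(m)
  expect_identical(sum(out), 10L)
  expect_true(all(out[2:6, 2:3]))
  single <- matrix(FALSE, 5, 5); single[2:3, 2:3] <- TRUE
  expect_identical(largest_component_2d(single), single)
})

test_that("equal-size components resolve to the first in (z, x) scan order", {
  m <- matrix(FALSE, 20, 20)
  m[10:12, 8] <- TRUE     # starts at z = 8
  m[2:4, 12] <- TRUE      # starts at z = 12
  out <- largest_component_2d(m)
  expect_true(all(out[10:12, 8]))
  expect_false(any(out[2:4, 12]))
})

test_that("largest_component_2d matches the brute-force oracle on random blobs", {
  set.seed(101)
  for (rep in 1:25) {
    m <- rand_blob(40, 40, ndisc = sample(2:4, 1))
    expect_identical(unname(largest_component_2d(m)), unname(bf_largest2d(m)))
  }
})

test_that("outline_2d gives the dilation ring: 8 around a voxel, 16 around a 3x3", {
  m1 <- matrix(FALSE, 7, 7); m1[4, 4] <- TRUE
  o1 <- outline_2d(m1)
  expect_identical(sum(o1), 8L)
  m2 <- matrix(FALSE, 9, 9); m2[4:6, 4:6] <- TRUE
  o2 <- outline_2d(m2)
  expect_identical(sum(o2), 16L)
  expect_false(any(o2 & m2))
})

test_that("outline_2d matches the brute-force dilation oracle on random blobs", {
  set.seed(202)
  for (rep in 1:25) {
    m <- rand_blob(36, 36)
    expect_identical(outline_2d(m), bf_outline(m))
  }
})

test_that("cutting a circle outline retains the caudal arc, under half the ring", {
  m <- matrix(FALSE, 31, 31)
  for (i in 1:31) for (j in 1:31)
    if ((i - 16)^2 + (j - 16)^2 <= 100) m[i, j] <- TRUE
  outline <- outline_2d(m)
  res <- cut_costophrenic(outline)
  expect_false(res$needs_fallback)
  arc <- res$arc$path
  expect_lt(nrow(arc), sum(outline) / 2)
  expect_lt(max(arc[, 2]), 16)              # caudal portion only
  # the arc is one 8-connected piece
  arcmat <- matrix(FALSE, 31, 31); arcmat[arc] <- TRUE
  expect_identical(max(bf_label2d(arcmat, 8L)), 1L)
})

test_that("cutting a dome-slice outline retains the dome curve", {
  m <- dome_slice()
  outline <- outline_2d(m)
  res <- cut_costophrenic(outline)
  expect_false(res$needs_fallback)
  # every arc voxel must hug the analytic dome boundary, not the flat top
  expect_lt(max(res$arc$path[, 2]), 15)
})

test_that("cuts that cannot split the outline report NeedsFallback", {
  # an open curve (not a closed ring): removing its band extremes cannot
  # leave two components
  open_line <- matrix(FALSE, 20, 12); open_line[4:16, 6] <- TRUE
  expect_true(cut_costophrenic(open_line)$needs_fallback)
  # degenerate width < 4
  m2 <- matrix(FALSE, 8, 8); m2[4, 3:6] <- TRUE
  expect_true(cut_costophrenic(outline_2d(m2))$needs_fallback)
})

test_that("cut_costophrenic matches the brute-force oracle on random blobs", {
  set.seed(303)
  n_agree_arc <- 0L
  for (rep in 1:60) {
    outline <- bf_outline(bf_largest2d(rand_blob(48, 48, ndisc = sample(1:3, 1))))
    res <- cut_costophrenic(outline)
    ref <- bf_cut(outline)
    if (is.null(ref)) {
      expect_true(res$needs_fallback)
    } else {
      expect_false(res$needs_fallback)
      got <- matrix(FALSE, nrow(outline), ncol(outline))
      got[res$arc$path] <- TRUE
      expect_identical(got, ref)
      n_agree_arc <- n_agree_arc + 1L
    }
  }
  expect_gt(n_agree_arc, 10L)   # the fixtures must actually exercise the cut
})

test_that("fallback_trace agrees with the cut on a dome-shaped outline", {
  m <- dome_slice()
  outline <- outline_2d(m)
  cut_arc <- cut_costophrenic(outline)$arc$path
  fb_arc <- fallback_trace(outline)$path
  cut_set <- paste(cut_arc[, 1], cut_arc[, 2])
  fb_set <- paste(fb_arc[, 1], fb_arc[, 2])
  # same arc up to a few voxels at the endpoints
  expect_lte(length(setdiff(cut_set, fb_set)), 4L)
  expect_lte(length(setdiff(fb_set, cut_set)), 4L)
})

test_that("a flat outline sends the fallback edges to the outermost points", {
  m <- matrix(FALSE, 30, 14); m[5:26, 4:10] <- TRUE     # rectangle
  arc <- fallback_trace(outline_2d(m))
  expect_identical(arc$provenance, "fallback")
  expect_identical(sort(range(arc$path[, 1])), c(4L, 27L))  # full outline width
  expect_true(all(arc$path[, 2] <= 4))                      # caudal edge only
})

test_that("outlines too small for the ascent check are skipped", {
  m <- matrix(FALSE, 6, 6); m[3, 3] <- TRUE
  expect_null(fallback_trace(outline_2d(m)))   # 8 voxels < 2 * 5
})

test_that("filter_arc keeps domes and rejects valleys and hooks", {
  # dome: midpoint cranial to the endpoints
  xs <- 1:21
  dome <- cbind(xs, c(1:10, 11, 10:1) + 3L)
  expect_identical(filter_arc(diaphragm_arc(dome)), "kept")
  # valley: midpoint 5 voxels caudal of both ends -> filter 1
  valley <- cbind(1:11, c(8:4, 3, 4:8))
  expect_identical(filter_arc(diaphragm_arc(valley)), "discarded_filter1")
  # hook: flat arc with a dip close to the midpoint -> filter 2
  hook <- cbind(1:21, c(rep(5L, 8), 4L, rep(5L, 12)))
  expect_identical(filter_arc(diaphragm_arc(hook)), "discarded_filter2")
  # degenerate
  expect_identical(filter_arc(diaphragm_arc(cbind(1:2, c(1L, 1L)))),
                   "discarded_filter2")
})

test_that("a flat arc passes both filters", {
  flat <- cbind(1:20, rep(5L, 20))
  expect_identical(filter_arc(diaphragm_arc(flat)), "kept")
})

test_that("stitching identical arcs degenerates to the arc itself", {
  arc <- diaphragm_arc(cbind(3:12, rep(4L, 10)))
  region <- stitch_slices(arc, arc, c(16, 10))
  expect_identical(sum(region), 10L)
  expect_true(all(region[arc$path]))
})

test_that("stitching a cranially shifted copy fills a 2-thick band", {
  path <- cbind(3:14, rep(4L, 12))
  prev <- diaphragm_arc(path)
  cur <- diaphragm_arc(cbind(path[, 1], path[, 2] + 1L))
  region <- stitch_slices(prev, cur, c(18, 10))
  expect_identical(sum(region), 24L)
  expect_true(all(region[3:14, 4:5]))
})

test_that("the first slice stitches to exactly its own arc", {
  path <- cbind(2:9, c(5L, 4L, 3L, 3L, 3L, 3L, 4L, 5L))
  region <- stitch_slices(NULL, diaphragm_arc(path), c(12, 8))
  expect_identical(sum(region), nrow(path))
  expect_true(all(region[path]))
})

test_that("stitch_slices matches the brute-force pair-join-fill oracle", {
  set.seed(404)
  for (rep in 1:40) {
    prev <- if (rep %% 8 == 0) NULL else rand_arc()
    cur <- rand_arc()
    dims <- c(44L, 44L)
    got <- stitch_slices(if (is.null(prev)) NULL else diaphragm_arc(prev),
                         diaphragm_arc(cur), dims)
    ref <- bf_stitch(prev, cur, dims)
    expect_identical(got, ref)
  }
})

test_that("extraction fails informatively on a speck mask", {
  grid <- array(FALSE, c(10, 10, 10)); grid[5, 5, 5] <- TRUE; grid[6, 5, 5] <- TRUE
  err <- tryCatch(extract_diaphragm(binary_mask(grid, side = "right")),
                  error = identity)
  expect_s3_class(err, "diaphragmct_extraction_failure")
  expect_true(is.data.frame(err$slice_log))
})

test_that("extracted phantom surfaces are a single 26-connected component", {
  spec <- cap_phantom_spec(a = 24, h = 12, lung_height = 42)
  lungs <- split_lungs(make_cap_phantom(spec))
  surf <- extract_diaphragm(lungs$right)
  lab <- diaphragmCT:::label_components_3d(surf$grid)
  expect_identical(max(lab$membership), 1L)
  # filters discard few slices on a clean dome
  frac_disc <- mean(grepl("discarded", surf$slice_log$status))
  expect_lte(frac_disc, 0.10)
})

test_that("extraction is deterministic and equivariant under shift and mirror", {
  spec <- cap_phantom_spec(a = 20, h = 10, lung_height = 36)
  vol <- make_cap_phantom(spec)
  mask <- split_lungs(vol)$right
  s1 <- extract_diaphragm(mask)
  s2 <- extract_diaphragm(mask)
  expect_identical(s1$grid, s2$grid)
  # integer translation
  g <- mask$grid
  gt <- array(FALSE, dim(g) + c(3L, 2L, 4L))
  gt[4:(dim(g)[1] + 3), 3:(dim(g)[2] + 2), 5:(dim(g)[3] + 4)] <- g
  st <- extract_diaphragm(binary_mask(gt, side = "right"))
  shifted <- sweep(which(st$grid, arr.ind = TRUE), 2, c(3L, 2L, 4L))
  expect_identical(unname(shifted), unname(which(s1$grid, arr.ind = TRUE)))
  # x-mirror
  gm <- g[rev(seq_len(dim(g)[1])), , , drop = FALSE]
  sm <- extract_diaphragm(binary_mask(gm, side = "right"))
  expect_identical(sm$grid[rev(seq_len(dim(gm)[1])), , , drop = FALSE], s1$grid)
})
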