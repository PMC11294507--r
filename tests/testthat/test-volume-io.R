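make_random_label_grid <- function(dims = c(9, 8, 7), labels = 0:5) {
  array(sample(labels, prod(dims), replace = TRUE), dims)
}

test_that("NIfTI and MetaImage round trips preserve grid, labels and spacing", {
  set.seed(42)
  vol <- label_volume(make_random_label_grid(), spacing = c(0.7, 0.7, 0.5))
  for (ext in c("nii", "nii.gz", "mha", "mhd")) {
    path <- file.path(tempdir(), paste0("rt.", ext))
    write_label_volume(vol, path)
    back <- read_label_volume(path)
    expect_identical(back$grid, vol$grid, label = ext)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  }
})

test_that("unsupported extensions and missing files raise typed errors", {
  bad <- file.path(tempdir(), "vol.txt")
  writeLines("not a volume", bad)
  expect_error(read_label_volume(bad), class = "diaphragmct_format_error")
  expect_error(read_label_volume(file.path(tempdir(), "nope.nii")),
               class = "diaphragmct_io_error")
  vol <- label_volume(array(1L, c(2, 2, 2)))
  expect_error(write_label_volume(vol, file.path(tempdir(), "out.xyz")),
               class = "diaphragmct_format_error")
})

test_that("floating-point voxel data is rejected as a label map", {
  path <- file.path(tempdir(), "float.nii")
  img <- RNifti::asNifti(array(runif(8), c(2, 2, 2)))
  RNifti::writeNifti(img, path)
  expect_error(read_label_volume(path), class = "diaphragmct_type_error")
})

test_that("resampling to the native spacing is the identity", {
  set.seed(7)
  vol <- label_volume(make_random_label_grid(), spacing = c(1, 1, 1))
  expect_identical(resample_isotropic(vol, 1.0)$grid, vol$grid)
})

test_that("resampling a 2 mm grid to 1 mm doubles the shape (ceil policy)", {
  vol <- label_volume(array(1L, c(10, 10, 10)), spacing = c(2, 2, 2))
  out <- resample_isotropic(vol, 1.0)
  expect_identical(dim(out$grid), c(20L, 20L, 20L))
  expect_equal(out$spacing, c(1, 1, 1))
})

test_that("nearest-neighbour resampling never invents label values", {
  set.seed(11)
  for (rep in 1:10) {
    dims <- sample(4:12, 3, replace = TRUE)
    sp <- runif(3, 0.4, 2.5)
    vol <- label_volume(make_random_label_grid(dims), spacing = sp)
    out <- resample_isotropic(vol, runif(1, 0.5, 2))
    expect_true(all(unique(as.vector(out$grid)) %in%
                    unique(as.vector(vol$grid))))
  }
})

test_that("resampling rejects non-positive targets", {
  vol <- label_volume(array(1L, c(2, 2, 2)))
  expect_error(resample_isotropic(vol, 0), class = "diaphragmct_parameter_error")
  expect_error(resample_isotropic(vol, -1), class = "diaphragmct_parameter_error")
})

test_that("split_lungs separates two labelled blobs onto their sides", {
  grid <- array(0L, c(20, 10, 10))
  grid[2:8, 3:8, 2:9] <- 1L
  grid[3:5, 4:6, 3:5] <- 2L
  grid[12:18, 3:8, 2:9] <- 4L
  vol <- label_volume(grid)
  lungs <- split_lungs(vol, label_map())
  expect_identical(sum(lungs$left$grid), sum(grid %in% 1:2))
  expect_identical(sum(lungs$right$grid), sum(grid == 4L))
  expect_false(any(lungs$left$grid & lungs$right$grid))
  expect_identical(lungs$left$grid | lungs$right$grid, array(grid %in% 1:5, dim(grid)))
})

test_that("a right-only volume gives an empty left mask without error", {
  grid <- array(0L, c(6, 6, 6)); grid[2:4, 2:4, 2:4] <- 5L
  lungs <- split_lungs(label_volume(grid))
  expect_false(any(lungs$left$grid))
  expect_true(any(lungs$right$grid))
})

test_that("an all-background volume is an empty-segmentation error", {
  expect_error(split_lungs(label_volume(array(0L, c(4, 4, 4)))),
               class = "diaphragmct_empty_segmentation")
})

test_that("label maps reject overlapping sides and read from JSON", {
  expect_error(label_map(left = 1:3, right = 3:5))
  cfg <- file.path(tempdir(), "map.json")
  writeLines('{"left": [10], "right": [20, 30]}', cfg)
  map <- read_label_map(cfg)
  expect_identical(map$left, 10L)
  expect_identical(map$right, c(20L, 30L))
})
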