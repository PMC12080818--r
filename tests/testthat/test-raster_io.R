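test_that("band exclusion drops exactly the listed ranges and keeps labels", {
  cube <- hypercube(array(seq_len(2 * 2 * 242), dim = c(2, 2, 242)))
  slim <- exclude_bands(cube, c("B001-B007", "58-76", "225-242"))
  expect_equal(dim(slim)[3], 198)
  labels <- attr(slim, "band_labels")
  expect_length(labels, 198)
  expect_false(any(labels %in% c(1:7, 58:76, 225:242)))
  # surviving planes are untouched, original order preserved
  expect_identical(slim[, , 1], cube[, , 8], ignore_attr = TRUE)
  expect_identical(slim[, , 198], cube[, , 224], ignore_attr = TRUE)

  # idempotence: re-applying the same (label-space) ranges changes nothing
  expect_identical(exclude_bands(slim, c("1-7", "58-76", "225-242")), slim)

  # empty exclusion is the identity
  expect_identical(exclude_bands(cube, NULL), cube)
  expect_identical(exclude_bands(cube, list()), cube)
})

test_that("band exclusion rejects degenerate and out-of-range requests", {
  cube <- array(1, dim = c(2, 2, 10))
  expect_error(exclude_bands(cube, "1-10"), "no bands remain")
  expect_error(exclude_bands(cube, list(c(5, 12))), "out of range")
  expect_error(exclude_bands(cube, "7-3"), "exceeds end")
  # overlapping ranges are fine
  expect_equal(dim(exclude_bands(cube, c("1-5", "3-6")))[3], 4)
})

test_that("cube validation rejects non-finite values and bad shapes", {
  expect_error(hypercube(array(c(1, NaN), dim = c(1, 1, 2))), "non-finite")
  expect_error(hypercube(array(c(1, Inf), dim = c(1, 1, 2))), "non-finite")
  expect_error(hypercube(1:10), "3-D array")
  expect_error(hypercube(array(1, dim = c(2, 2, 2, 2))), "3-D array")
  expect_error(hypercube(array(1, dim = c(1, 1, 3)), band_labels = c(3, 2, 1)),
               "strictly increasing")
})

test_that("ENVI read/write round-trips bit-exactly for every interleave", {
  cube <- rand_cube(7, 5, 6, seed = 42)
  for (il in c("bsq", "bil", "bip")) {
    path <- file.path(tempdir(), paste0("rt_", il))
    write_envi(cube, path, interleave = il)
    expect_identical(read_envi(path), hypercube(cube), label = il)
    # header path and data path are interchangeable entries
    expect_identical(read_envi(paste0(path, ".hdr")), hypercube(cube))
  }
})

test_that("ENVI BSQ/BIL/BIP encodings of one scene load identically", {
  cube <- rand_cube(6, 9, 4, seed = 7)
  loaded <- lapply(c("bsq", "bil", "bip"), function(il) {
    path <- file.path(tempdir(), paste0("axis_", il))
    write_envi(cube, path, interleave = il)
    read_envi(path)
  })
  expect_identical(loaded[[1]], loaded[[2]])
  expect_identical(loaded[[1]], loaded[[3]])
})

test_that("ENVI reader honors integer data types and byte order", {
  # hand-written int16 big-endian BIL file
  rows <- 3L; cols <- 4L; bands <- 2L
  vals <- array(sample.int(3000, rows * cols * bands) - 1500L,
                dim = c(rows, cols, bands))
  path <- file.path(tempdir(), "int16be")
  con <- file(path, "wb")
  writeBin(as.integer(aperm(vals, c(2, 3, 1))), con, size = 2L,
           endian = "big")
  close(con)
  writeLines(c("ENVI", "samples = 4", "lines = 3", "bands = 2",
               "header offset = 0", "data type = 2", "interleave = bil",
               "byte order = 1"), paste0(path, ".hdr"))
  expect_identical(read_envi(path), hypercube(vals))
})

test_that("ENVI reader reports missing files and malformed headers", {
  expect_error(read_envi(file.path(tempdir(), "nope.hdr")),
               "file not found.*nope")
  bad <- file.path(tempdir(), "notenvi")
  writeLines("hello", bad)
  writeLines("hello", paste0(bad, ".hdr"))
  expect_error(read_envi(bad), "not an ENVI header")
})

test_that("MAT v5 read/write round-trips bit-exactly", {
  cube <- rand_cube(4, 5, 3, seed = 3)
  mask <- matrix(rbinom(12, 1, 0.5), 3, 4)
  path <- file.path(tempdir(), "rt.mat")
  write_mat(list(cube = cube, mask = mask, v = c(1.5, -2)), path)
  got <- read_mat(path)
  expect_identical(got$cube, cube)
  expect_identical(got$mask, mask + 0)   # stored as double
  expect_identical(as.vector(got$v), c(1.5, -2))
  # shape pass-through: 4 x 5 x 3 array -> rows 4, cols 5, bands 3
  expect_equal(dim(read_cube(path, mat_variable = "cube")), c(4, 5, 3))
})

test_that("MAT cube selection disambiguates 3-D variables", {
  path <- file.path(tempdir(), "two.mat")
  write_mat(list(a = rand_cube(2, 2, 2, 1), b = rand_cube(3, 2, 2, 2),
                 flat = matrix(1, 2, 2)), path)
  expect_error(read_cube(path), "ambiguous.*a, b")
  expect_equal(dim(read_cube(path, mat_variable = "b")), c(3, 2, 2))
  expect_error(read_cube(path, mat_variable = "zzz"), "not found")
  expect_error(read_cube(path, mat_variable = "flat"), "2 dimensions")
  only2d <- file.path(tempdir(), "only2d.mat")
  write_mat(list(flat = matrix(1, 2, 2)), only2d)
  expect_error(read_cube(only2d), "no 3-D variable")
})

test_that("TIFF cubes load with (row, col, band) order and unscaled DNs", {
  skip_if_not_installed("tiff")
  # 16-bit grid values k/65535 survive the integer TIFF round trip exactly
  dn <- array(sample.int(65536, 6 * 5 * 7) - 1L, dim = c(6, 5, 7))
  path <- file.path(tempdir(), "cube.tif")
  tiff::writeTIFF(lapply(1:7, function(b) dn[, , b] / 65535), path,
                  bits.per.sample = 16L)
  got <- read_cube(path)
  expect_equal(dim(got), c(6, 5, 7))
  expect_identical(got, hypercube(dn))
})

test_that("masks binarize on load from PNG, ENVI and MAT", {
  truth <- matrix(rbinom(30, 1, 0.4), 5, 6)
  p_png <- file.path(tempdir(), "m.png")
  write_mask(truth, p_png)
  expect_identical(read_mask(p_png), truth)

  # nonzero values other than 1 also map to 1
  p_envi <- file.path(tempdir(), "m255")
  write_envi(array(truth * 255, dim = c(5, 6, 1)), p_envi)
  expect_identical(read_mask(p_envi), truth)

  p_mat <- file.path(tempdir(), "m.mat")
  write_mat(list(gt = truth * 7), p_mat)
  expect_identical(read_mask(p_mat), truth)

  # all-zero raster stays all zero
  p0 <- file.path(tempdir(), "zeros")
  write_envi(array(0, dim = c(3, 3, 1)), p0)
  expect_true(all(read_mask(p0) == 0))
})

test_that("mask positive counts are preserved through raster I/O", {
  # benchmark-style labelling: fixed positive count on a larger grid
  set.seed(99)
  m <- matrix(0L, 130, 100)
  m[sample.int(13000, 998)] <- 1L
  path <- file.path(tempdir(), "bigmask")
  write_envi(array(as.numeric(m), dim = c(130, 100, 1)), path)
  got <- read_mask(path)
  expect_equal(sum(got), 998)
  expect_equal(sum(got == 0), 13000 - 998)
})
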