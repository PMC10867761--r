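test_that("load_mask binarizes PNG rasters and preserves dimensions", {
  d <- withr::local_tempdir()
  p0 <- file.path(d, "empty.png")
  png::writePNG(matrix(0, 64, 64), p0)
  m0 <- load_mask(p0)
  expect_s3_class(m0, "binary_mask")
  expect_identical(dim(m0$pixels), c(64L, 64L))
  expect_equal(sum(m0$pixels), 0)

  img <- matrix(0, 64, 64); img[10, ] <- 1
  p1 <- file.path(d, "row.png")
  png::writePNG(img, p1)
  m1 <- load_mask(p1)
  expect_equal(sum(m1$pixels), 64)
  expect_equal(m1$image_id, "row")
})

test_that("load_mask handles multi-channel rasters", {
  d <- withr::local_tempdir()
  gray <- matrix(0, 32, 32)
  gray[cbind(sample.int(32, 10), sample.int(32, 10))] <- 1
  gray[1:5, 1] <- 1
  n_true <- sum(gray != 0)
  rgb <- array(rep(gray, 3), dim = c(32, 32, 3))
  p <- file.path(d, "rgb.png")
  png::writePNG(rgb, p)
  expect_equal(sum(load_mask(p)$pixels), n_true)

  bad <- rgb; bad[1, 1, 2] <- 1 - bad[1, 1, 2]
  pb <- file.path(d, "bad.png")
  png::writePNG(bad, pb)
  expect_error(load_mask(pb), "differing channels")
  expect_error(load_mask(file.path(d, "nope.png")), "does not exist")
})

test_that("load_mask respects the intensity threshold and round-trips", {
  d <- withr::local_tempdir()
  img <- matrix(0, 16, 16)
  img[3, 3] <- 10 / 255; img[4, 4] <- 200 / 255
  p <- file.path(d, "gray.png")
  png::writePNG(img, p)
  expect_equal(sum(load_mask(p, threshold = 1)$pixels), 2)
  expect_equal(sum(load_mask(p, threshold = 100)$pixels), 1)
  expect_error(load_mask(p, threshold = 0), "threshold")

  # idempotence through a lossless write/read cycle
  m <- load_mask(p)
  p2 <- file.path(d, "rt.png")
  write_mask(m, p2)
  expect_identical(load_mask(p2)$pixels, m$pixels)
})

test_that("TIFF masks load like PNG masks", {
  d <- withr::local_tempdir()
  img <- matrix(0, 20, 20); img[5:8, 5:8] <- 1
  p <- file.path(d, "m.tif")
  tiff::writeTIFF(img, p)
  expect_equal(sum(load_mask(p)$pixels), 16)
})

test_that("disc centers load from CSV and JSON with validation", {
  d <- withr::local_tempdir()
  p <- file.path(d, "discs.csv")
  writeLines(c("image_id,row,col", "img1,100,200", "img2,3.5,4.5"), p)
  dc <- load_disc_centers(p)
  expect_equal(nrow(dc), 2)
  expect_equal(dc$row[dc$image_id == "img1"], 100)
  expect_equal(dc$col[dc$image_id == "img1"], 200)

  # empty (header-only) file -> zero rows
  pe <- file.path(d, "empty.csv")
  writeLines("image_id,row,col", pe)
  expect_equal(nrow(load_disc_centers(pe)), 0)

  # duplicates named in the error
  pd <- file.path(d, "dup.csv")
  writeLines(c("image_id,row,col", "img1,1,2", "img1,3,4"), pd)
  expect_error(load_disc_centers(pd), "img1")

  # missing column named in the error
  pm <- file.path(d, "m.csv")
  writeLines(c("image_id,row", "img1,1"), pm)
  expect_error(load_disc_centers(pm), "col")

  # JSON variant
  pj <- file.path(d, "discs.json")
  writeLines('[{"image_id":"a","row":7,"col":9}]', pj)
  dj <- load_disc_centers(pj)
  expect_equal(dj$row, 7)

  # (x, y) order swap
  ds <- load_disc_centers(p, xy_order = TRUE)
  expect_equal(ds$row[ds$image_id == "img1"], 200)
  expect_equal(ds$col[ds$image_id == "img1"], 100)
})

test_that("results tables write with image_id first and round-trip", {
  d <- withr::local_tempdir()
  p <- file.path(d, "out.csv")
  recs <- list(list(cti = 1.05, image_id = "a", n = 3L),
               list(cti = 1.10, image_id = "b", n = 5L))
  write_results_table(recs, p)
  back <- utils::read.csv(p, stringsAsFactors = FALSE)
  expect_identical(names(back)[1], "image_id")
  expect_equal(back$cti, c(1.05, 1.10))

  expect_error(write_results_table(list(), p), "empty")
  expect_error(write_results_table(data.frame(), p), "empty")
  expect_error(
    write_results_table(list(list(a = 1), list(a = 1, extra = 2)), p),
    "extra")
})

test_that("coordinate convention is shared: disc pairs with mask pixels", {
  # one vessel pixel at 0-based (3, 7); a disc center written at the same
  # place must coincide after both pass through their loaders
  d <- withr::local_tempdir()
  img <- matrix(0, 10, 12); img[4, 8] <- 1   # 1-based (4, 8) = 0-based (3, 7)
  pm <- file.path(d, "m.png"); png::writePNG(img, pm)
  pc <- file.path(d, "c.csv"); writeLines(c("image_id,row,col", "m,3,7"), pc)
  mk <- load_mask(pm)
  dc <- load_disc_centers(pc)
  expect_true(mk$pixels[dc$row + 1, dc$col + 1])
})
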