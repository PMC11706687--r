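# OME-TIFF / metadata-table input and output.

test_that("write_image / read_image roundtrip is lossless", {
  s <- generate_sample(synthetic_config(image_size = 48), "Col-0", "mock")
  img <- multichannel_image(round(s$image$pixels), pixel_size_um = 0.415133)
  p <- withr::local_tempfile(fileext = ".ome.tif")
  write_image(img, p)
  img2 <- read_image(p)
  expect_equal(img2$pixels, img$pixels)
  expect_identical(img2$channel_roles, img$channel_roles)
  expect_equal(img2$pixel_size_um, 0.415133)
})

test_that("files with fewer than four channels are rejected", {
  p <- withr::local_tempfile(fileext = ".tif")
  rootzones:::write_tiff(p, list(matrix(1, 8, 8), matrix(2, 8, 8),
                                 matrix(3, 8, 8)), type = "uint16")
  expect_error(read_image(p), "4 channels")
  expect_error(read_image(file.path(tempdir(), "does-not-exist.tif")))
})

test_that("result images carry derived layers with exact label roundtrip", {
  s <- generate_sample(synthetic_config(image_size = 48, seed = 4), "Col-0", "mock")
  ratio <- compute_ratio_image(s$image)
  p <- withr::local_tempfile(fileext = ".ome.tif")
  write_result_image(s$image,
                     list(segmentation = matrix(as.double(s$mask), 48, 48),
                          ratio = ratio$X), p)
  layers <- rootzones:::read_result_layers(p)
  expect_identical(names(layers),
                   c("fl405", "bf405", "fl458", "bf458", "segmentation", "ratio"))
  expect_identical(layers$segmentation, matrix(as.double(s$mask), 48, 48))
  # float32 storage: ~7 significant digits
  keep <- ratio$valid
  expect_lt(max(abs(layers$ratio[keep] - ratio$X[keep]) / ratio$X[keep]), 1e-6)
  # empty extra layers: pixel content identical to input (float32-exact here)
  p2 <- withr::local_tempfile(fileext = ".ome.tif")
  img <- multichannel_image(round(s$image$pixels))
  write_result_image(img, list(), p2)
  expect_equal(rootzones:::read_result_layers(p2)$bf405, img$pixels[, , 2])
  # shape mismatch is an error
  expect_error(write_result_image(s$image, list(x = matrix(0, 3, 3)), p2),
               "mismatch")
})

test_that("TIFF interchange agrees with an independent implementation", {
  td <- withr::local_tempdir()
  s <- generate_sample(synthetic_config(image_size = 48, seed = 7), "Col-0", "BL")
  img <- multichannel_image(round(s$image$pixels))
  ours <- file.path(td, "ours.ome.tif")
  write_image(img, ours)
  script <- file.path(td, "check.py")
  theirs <- file.path(td, "theirs.tif")
  writeLines(c(
    "import sys, tifffile, numpy as np",
    sprintf("a = tifffile.imread('%s')", ours),
    "print('SUM', int(a.sum()), a.shape[0])",
    sprintf("with tifffile.TiffFile('%s') as tf:", ours),
    "    print('OME', int(tf.ome_metadata is not None))",
    "rng = np.random.default_rng(0)",
    "b = rng.integers(0, 65535, size=(4, 20, 24), dtype=np.uint16)",
    sprintf("tifffile.imwrite('%s', b, photometric='minisblack')", theirs),
    "print('BSUM', int(b.sum()))"), script)
  out <- system2("python", script, stdout = TRUE)
  expect_equal(as.numeric(strsplit(grep("^SUM", out, value = TRUE), " ")[[1]][2]),
               sum(img$pixels))
  expect_equal(strsplit(grep("^OME", out, value = TRUE), " ")[[1]][2], "1")
  back <- rootzones:::read_tiff(theirs)
  expect_length(back$planes, 4)
  expect_equal(sum(vapply(back$planes, sum, numeric(1))),
               as.numeric(strsplit(grep("^BSUM", out, value = TRUE), " ")[[1]][2]))
})

test_that("metadata tables are parsed and validated", {
  td <- withr::local_tempdir()
  tab <- data.frame(sample_id = sprintf("s%02d", 1:20),
                    line = rep(c("Col-0", "bri1-301"), 10),
                    treatment = rep(c("mock", "BL"), each = 10),
                    file = sprintf("s%02d.ome.tif", 1:20))
  tsv <- file.path(td, "meta.tsv")
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_metadata_table(tsv)
  expect_identical(nrow(rec), 20L)
  csv <- file.path(td, "meta.csv")
  write.csv(tab, csv, row.names = FALSE)
  expect_identical(nrow(read_metadata_table(csv)), 20L)

  bad <- tab[, setdiff(names(tab), "treatment")]
  write.table(bad, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_metadata_table(tsv), "treatment")

  dup <- tab; dup$sample_id[2] <- dup$sample_id[1]
  write.table(dup, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_metadata_table(tsv), "duplicate")

  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_metadata_table(tsv, check_files = TRUE), "missing image")
})
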