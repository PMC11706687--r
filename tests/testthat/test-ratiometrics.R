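# Ratio images, masked zone means, and Welch's t statistics.

mk_image <- function(fl405, fl458) {
  d <- dim(fl405)
  px <- array(0, dim = c(d[1], d[2], 4))
  px[, , 1] <- fl405
  px[, , 2] <- 1000
  px[, , 3] <- fl458
  px[, , 4] <- 1000
  multichannel_image(px)
}

test_that("the ratio image is fl458/fl405 with a validity mask", {
  fl405 <- matrix(c(2, 4, 0, 8), 2, 2)
  img <- mk_image(fl405, 2 * fl405)
  r <- compute_ratio_image(img)
  expect_equal(r$X[r$valid], rep(2, 3))
  expect_identical(r$valid, fl405 > 0)
  expect_true(is.na(r$X[!r$valid]))
  # noise-free synthetic sample with zone ratio 1.5 gives X = 1.5 on that zone
  s <- generate_sample(synthetic_config(image_size = 64, noise_sd = 0), "Col-0", "mock")
  rs <- compute_ratio_image(s$image)
  expect_equal(unique(rs$X[unclass(s$mask) == 4]), 1.5, tolerance = 1e-12)
})

test_that("zone means follow the masked-mean rule", {
  X405 <- matrix(1, 2, 2)
  img <- mk_image(X405, matrix(2.37, 2, 2))
  m_all <- seg_mask(matrix(2L, 2, 2))
  expect_equal(zone_mean_ratio(compute_ratio_image(img), m_all, "EEZ")$mean_ratio, 2.37)
  # zone pixels {1, 2, 3, 6} average to 3
  img2 <- mk_image(matrix(1, 2, 2), matrix(c(1, 2, 3, 6), 2, 2))
  expect_equal(zone_mean_ratio(compute_ratio_image(img2), m_all, 2)$mean_ratio, 3.0)
  # invalid pixel excluded: X = [[1,2],[3,4]], zone = first column,
  # denominator 0 at (1,1): mean over the single remaining zone pixel = 2
  fl405 <- matrix(c(0, 1, 1, 1), 2, 2)
  fl458 <- matrix(c(1, 2, 3, 4), 2, 2)
  mask <- seg_mask(matrix(c(2, 2, 0, 0), 2, 2))
  zm <- zone_mean_ratio(compute_ratio_image(mk_image(fl405, fl458)), mask, "EEZ")
  expect_equal(zm$mean_ratio, 2.0)
  expect_identical(zm$n_pixels, 1L)
  # zone with no valid pixel is flagged missing
  zm0 <- zone_mean_ratio(compute_ratio_image(img), m_all, "MZ")
  expect_true(is.na(zm0$mean_ratio))
  expect_identical(zm0$n_pixels, 0L)
  expect_error(zone_mean_ratio(compute_ratio_image(img),
                               seg_mask(matrix(0L, 3, 3)), "EEZ"), "mismatch")
})

test_that("zone means lie within the zone value range regardless of pixel order", {
  set.seed(8)
  for (i in 1:20) {
    fl405 <- matrix(runif(36, 0.5, 2), 6, 6)
    fl458 <- matrix(runif(36, 0.5, 4), 6, 6)
    mask <- seg_mask(matrix(sample(0:4, 36, TRUE), 6, 6))
    r <- compute_ratio_image(mk_image(fl405, fl458))
    zm <- zone_mean_ratio(r, mask, "LEZ")
    sel <- unclass(mask) == 3
    if (zm$n_pixels > 0) {
      expect_gte(zm$mean_ratio, min(r$X[sel]))
      expect_lte(zm$mean_ratio, max(r$X[sel]))
    }
  }
})

test_that("Welch's t-test matches the textbook formulas and its symmetries", {
  a <- c(1, 2, 3)
  b <- c(2, 4, 6)
  got <- welch_t_test(a, b)
  ora <- welch_oracle(a, b)
  expect_equal(got$t_statistic, ora$t, tolerance = 1e-10)
  expect_equal(got$df, ora$df, tolerance = 1e-10)
  expect_equal(got$p_value, ora$p, tolerance = 1e-10)
  # identical groups: t = 0, p = 1
  same <- welch_t_test(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  # swapping groups negates t and keeps p
  sw <- welch_t_test(b, a)
  expect_equal(sw$t_statistic, -got$t_statistic)
  expect_equal(sw$p_value, got$p_value)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  expect_error(welch_t_test(c(1, 1, 1), c(2, 2, 2)), "zero variance")
  # quartiles use the linear-interpolation convention
  expect_equal(got$q1_a, 1.5)
  expect_equal(got$median_b, 4)
})

test_that("group statistics join measures to records and run the default contrasts", {
  meta <- expand.grid(line = c("Col-0", "bri1-301"),
                      treatment = c("mock", "BL"),
                      rep = 1:4, stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("s%02d", seq_len(nrow(meta)))
  set.seed(9)
  measures <- do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
    eff <- if (meta$line[i] == "Col-0" && meta$treatment[i] == "BL") 0.8 else 1
    data.frame(sample_id = meta$sample_id[i], zone = "MZ",
               mean_ratio = 1.5 * eff + rnorm(1, sd = 0.01), n_pixels = 100L)
  }))
  gs <- group_statistics(measures, meta)
  expect_true(all(c("zone", "group_a", "group_b", "t_statistic", "df",
                    "p_value", "median_a", "q3_b") %in% names(gs)))
  colbl <- gs[gs$group_a == "Col-0:mock" & gs$group_b == "Col-0:BL", ]
  expect_identical(nrow(colbl), 1L)
  expect_lt(colbl$p_value, 0.05)
  mut <- gs[gs$group_a == "bri1-301:mock" & gs$group_b == "bri1-301:BL", ]
  expect_gt(mut$p_value, 0.05)
  # orphan measures and unknown comparison labels are errors
  bad <- measures; bad$sample_id[1] <- "ghost"
  expect_error(group_statistics(bad, meta), "without a metadata record")
  expect_error(group_statistics(measures, meta,
                                comparisons = list(list(a = c("nope", "mock"),
                                                        b = c("Col-0", "BL")))),
               "unknown comparison")
})
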