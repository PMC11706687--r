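# Synthetic root-tip generator: ground-truth construction and determinism.

test_that("noise-free samples encode the configured zone ratios exactly", {
  cfg <- synthetic_config(image_size = 64, noise_sd = 0,
                          true_zone_ratio = c(root = 1.8, EEZ = 2.0,
                                              LEZ = 2.5, MZ = 1.5))
  s <- generate_sample(cfg, "Col-0", "mock")
  r <- compute_ratio_image(s$image)
  for (z in c("MZ", "EEZ", "LEZ", "root")) {
    zm <- zone_mean_ratio(r, s$mask, z)
    expect_equal(zm$mean_ratio, unname(cfg$true_zone_ratio[[z]]),
                 tolerance = 1e-12, info = z)
    expect_gt(zm$n_pixels, 0)
  }
})

test_that("treatment effect multiplies ratios only for wildtype + BL", {
  cfg <- synthetic_config(image_size = 64, noise_sd = 0, treatment_effect = 0.8)
  s_bl <- generate_sample(cfg, "Col-0", "BL")
  r_bl <- compute_ratio_image(s_bl$image)
  # effective LEZ ratio 2.5 * 0.8 = 2.0 recovered from the noise-free image
  expect_equal(zone_mean_ratio(r_bl, s_bl$mask, "LEZ")$mean_ratio, 2.0,
               tolerance = 1e-12)
  expect_equal(unname(s_bl$truth[["MZ"]]), 1.5 * 0.8)
  # mutant line and mock treatment are unaffected
  for (g in list(c("bri1-301", "BL"), c("Col-0", "mock"), c("bri1-301", "mock"))) {
    s <- generate_sample(cfg, g[1], g[2])
    r <- compute_ratio_image(s$image)
    expect_equal(zone_mean_ratio(r, s$mask, "LEZ")$mean_ratio, 2.5,
                 tolerance = 1e-12, info = paste(g, collapse = "/"))
  }
})

test_that("generation is bit-exact reproducible and seed-sensitive", {
  cfg <- synthetic_config(image_size = 64, seed = 9)
  s1 <- generate_sample(cfg, "Col-0", "mock")
  s2 <- generate_sample(cfg, "Col-0", "mock")
  expect_identical(s1, s2)
  cfg2 <- cfg; cfg2$seed <- 10L
  s3 <- generate_sample(cfg2, "Col-0", "mock")
  expect_false(identical(s1$image$pixels, s3$image$pixels))
})

test_that("masks carry all five classes with valid labels and channel layout", {
  s <- generate_sample(synthetic_config(image_size = 96), "Col-0", "mock")
  expect_setequal(sort(unique(as.vector(unclass(s$mask)))), 0:4)
  expect_identical(dim(s$image$pixels)[3], 4L)
  expect_identical(s$image$channel_roles, c("fl405", "bf405", "fl458", "bf458"))
  # cell geometry rules are enforced at configuration time
  expect_error(synthetic_config(
    image_size = 64,
    cell_geometry = list(MZ = list(length = c(10, 12), width = c(4, 6)),
                         EEZ = list(length = c(8, 10), width = c(6, 8)),
                         LEZ = list(length = c(20, 24), width = c(6, 8)),
                         root = list(length = c(8, 10), width = c(6, 8)))),
    "length/width")
})

test_that("degenerate zone layouts are rejected", {
  expect_error(synthetic_config(zone_layout = c(MZ = 0.5, EEZ = 0.4, LEZ = 0.2)))
  cfg <- synthetic_config(image_size = 64,
                          zone_layout = c(MZ = 0.93, EEZ = 0.001, LEZ = 0.06))
  expect_error(generate_sample(cfg), "zone")
})

test_that("datasets have the requested group structure and derived seeds", {
  cfg <- synthetic_config(image_size = 64, seed = 3)
  groups <- list(c("Col-0", "mock"), c("Col-0", "BL"),
                 c("bri1-301", "mock"), c("bri1-301", "BL"))
  ds <- generate_dataset(cfg, 5, groups)
  expect_length(ds$samples, 20)
  expect_identical(nrow(ds$metadata), 20L)
  expect_setequal(unique(ds$metadata$line), c("bri1-301", "Col-0"))
  # deterministic as a whole, samples mutually distinct
  ds2 <- generate_dataset(cfg, 5, groups)
  expect_identical(ds, ds2)
  expect_false(identical(ds$samples[[1]]$image$pixels,
                         ds$samples[[2]]$image$pixels))
  expect_error(generate_dataset(cfg, 0), "n_per_group")
  expect_error(generate_dataset(cfg, 2, list()), "groups")
})

test_that("group mean ratios differ only where the effect is applied (noise-free)", {
  cfg <- synthetic_config(image_size = 64, noise_sd = 0, seed = 11)
  ds <- generate_dataset(cfg, 2)
  mr <- function(sid) {
    s <- ds$samples[[sid]]
    zone_mean_ratio(compute_ratio_image(s$image), s$mask, "MZ")$mean_ratio
  }
  meta <- ds$metadata
  by_group <- tapply(vapply(meta$sample_id, mr, numeric(1)),
                     paste(meta$line, meta$treatment), mean)
  expect_lt(by_group[["Col-0 BL"]], by_group[["Col-0 mock"]])
  expect_equal(by_group[["bri1-301 BL"]], by_group[["bri1-301 mock"]],
               tolerance = 1e-12)
})
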