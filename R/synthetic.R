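#' Configuration for the synthetic root-tip image generator
#'
#' The generator renders a curved root band entering the frame from the left,
#' with a rounded tip cap and developmental zones laid out along the root
#' axis: the meristematic zone (MZ) at the tip, then the early elongation
#' zone (EEZ), then the late elongation zone (LEZ); remaining band pixels
#' (tip cap and shank) are plain root tissue. Each zone is tiled with "cells"
#' whose length/width ratios obey the morphological rules used to define the
#' zones (MZ < 1, EEZ in [1, 2], LEZ > 2). Cell walls are dark lines on a
#' bright interior in the two brightfield channels, and carry most of the
#' fluorescence signal (the dye stains the apoplast).
#'
#' The fluorescence channels encode a known ground truth: fl458 =
#' fl405 * R(zone) * (1 + noise), where R is the per-zone 458/405 ratio,
#' multiplied by `treatment_effect` for every zone when the sample is from
#' the wildtype line under BL treatment. With `noise_sd = 0` the pixel-wise
#' ratio over any zone equals the configured value to machine precision
#' (in-memory; 16-bit quantization on disk adds ~1e-4 relative error).
#'
#' @param image_size pixels per side (512 for real data; tests use 64-128).
#' @param root_width band width in pixels (default 0.3 * image_size).
#' @param zone_layout named fractions of the root length from the tip for
#'   MZ, EEZ, LEZ (must sum to < 1; the rest is plain root tissue).
#' @param cell_geometry per-zone cell length/width ranges in pixels; default
#'   derived from `root_width` so that the zone aspect-ratio rules hold.
#' @param true_zone_ratio named per-zone target 458/405 ratios (> 0),
#'   for classes root, EEZ, LEZ, MZ.
#' @param treatment_effect multiplicative shift of the zone ratios applied
#'   when `line == wildtype_line` and `treatment == effect_treatment`.
#' @param wildtype_line,effect_treatment labels selecting the affected group.
#' @param noise_sd multiplicative intensity noise scale.
#' @param seed integer seed.
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(image_size = 512L,
                             root_width = NULL,
                             zone_layout = c(MZ = 0.25, EEZ = 0.20, LEZ = 0.45),
                             cell_geometry = NULL,
                             true_zone_ratio = c(root = 1.8, EEZ = 2.0,
                                                 LEZ = 2.5, MZ = 1.5),
                             treatment_effect = 0.8,
                             wildtype_line = "Col-0",
                             effect_treatment = "BL",
                             noise_sd = 0.05,
                             seed = 1L) {
  image_size <- as.integer(image_size)
  stopifnot(image_size >= 32)
  root_width <- as.integer(root_width %||% round(0.3 * image_size))
  stopifnot(all(c("MZ", "EEZ", "LEZ") %in% names(zone_layout)),
            sum(zone_layout) < 1, all(zone_layout > 0))
  stopifnot(all(c("root", "EEZ", "LEZ", "MZ") %in% names(true_zone_ratio)),
            all(true_zone_ratio > 0))
  stopifnot(treatment_effect > 0, noise_sd >= 0)
  if (is.null(cell_geometry)) {
    cw <- max(4, round(root_width / 6))       # transverse cell width
    # ranges are chosen so every length/width combination obeys the zone rule
    cell_geometry <- list(
      MZ = list(length = c(max(2, round(0.5 * cw)), cw - 1),
                width = c(cw, cw + 2)),
      EEZ = list(length = c(cw + 2, 2 * cw),
                 width = c(cw, cw + 2)),
      LEZ = list(length = c(2 * (cw + 2) + 1, 3 * (cw + 2)),
                 width = c(cw, cw + 2)),
      root = list(length = c(cw, 2 * cw),
                  width = c(cw, cw + 2)))
  }
  check_lw <- function(zone, lo, hi) {
    g <- cell_geometry[[zone]]
    r <- range(outer(g$length, g$width, "/"))
    if (r[1] < lo || r[2] > hi) {
      stop(sprintf("cell geometry of %s violates its length/width rule", zone))
    }
  }
  check_lw("MZ", 0, 1 - 1e-9)
  check_lw("EEZ", 1, 2)
  check_lw("LEZ", 2 + 1e-9, Inf)
  structure(list(image_size = image_size, root_width = root_width,
                 zone_layout = zone_layout, cell_geometry = cell_geometry,
                 true_zone_ratio = true_zone_ratio,
                 treatment_effect = treatment_effect,
                 wildtype_line = wildtype_line,
                 effect_treatment = effect_treatment,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate one synthetic labeled sample
#'
#' Deterministic in (config, line, treatment): the same call is bit-identical.
#'
#' @param config a [synthetic_config()].
#' @param line plant line label (e.g. "Col-0", "bri1-301").
#' @param treatment treatment label (e.g. "mock", "BL").
#' @return a `synthetic_sample`: list with `image` (a [multichannel_image()]),
#'   `mask` (a [seg_mask()]), `truth` (named effective per-zone ratios),
#'   `line`, `treatment`.
#' @export
generate_sample <- function(config, line = "Col-0", treatment = "mock") {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$image_size
  rw <- config$root_width
  with_seed(derive_seed(config$seed, paste("sample", line, treatment)), {
    # curved centerline: low-order polynomial in the column coordinate
    xc <- (n + 1) / 2
    a1 <- runif(1, -0.08, 0.08) * n
    a2 <- runif(1, -0.10, 0.10) * n
    xx <- matrix(rep(seq_len(n), each = n), n, n)   # column index
    yy <- matrix(rep(seq_len(n), times = n), n, n)  # row index
    u <- (xx - xc) / n
    ycl <- xc + a1 * u + a2 * (u^2 - 1 / 12)
    x_tip <- round(0.12 * n)
    dy <- yy - ycl
    band <- abs(dy) <= rw / 2 & xx >= x_tip
    y_tip <- xc + a1 * (x_tip - xc) / n + a2 * (((x_tip - xc) / n)^2 - 1 / 12)
    cap <- (xx - x_tip)^2 + (yy - y_tip)^2 <= (rw / 2)^2 & xx < x_tip
    root_px <- band | cap

    # axial zone layout from the tip
    s <- xx - x_tip
    len <- n - x_tip
    b1 <- config$zone_layout[["MZ"]] * len
    b2 <- b1 + config$zone_layout[["EEZ"]] * len
    b3 <- b2 + config$zone_layout[["LEZ"]] * len
    lab <- matrix(0L, n, n)
    lab[root_px] <- 1L
    lab[band & s >= 0 & s < b1] <- ZONE_CLASSES[["MZ"]]
    lab[band & s >= b1 & s < b2] <- ZONE_CLASSES[["EEZ"]]
    lab[band & s >= b2 & s < b3] <- ZONE_CLASSES[["LEZ"]]
    for (z in c("MZ", "EEZ", "LEZ")) {
      if (!any(lab == ZONE_CLASSES[[z]])) {
        stop("zone ", z, " received no pixels; zone spans exceed the usable root length")
      }
    }

    # per-zone cell grids: walls where axial or transverse phase is small
    cellgeom <- lapply(config$cell_geometry, function(g) {
      c(len = round(runif(1, g$length[1], g$length[2])),
        wid = round(runif(1, g$width[1], g$width[2])))
    })
    tcoord <- dy + rw / 2
    wall <- matrix(FALSE, n, n)
    zone_of_s <- function(sv) {
      ifelse(sv < 0 | sv >= b3, "root",
             ifelse(sv < b1, "MZ", ifelse(sv < b2, "EEZ", "LEZ")))
    }
    zname <- zone_of_s(s)
    for (z in names(cellgeom)) {
      gi <- cellgeom[[z]]
      sel <- root_px & zname == z
      wall[sel] <- (s[sel] %% gi[["len"]]) < 1.5 | (tcoord[sel] %% gi[["wid"]]) < 1.5
    }
    # band rim counts as wall (outer cell file boundary)
    wall[root_px & abs(abs(dy) - rw / 2) < 1.5] <- TRUE

    # effective per-zone ratios (treatment effect on wildtype + BL)
    eff <- config$true_zone_ratio
    if (identical(line, config$wildtype_line) &&
        identical(treatment, config$effect_treatment)) {
      eff <- eff * config$treatment_effect
    }
    ratio_map <- matrix(1.0, n, n)
    for (z in names(eff)) ratio_map[lab == ZONE_CLASSES[[z]]] <- eff[[z]]

    # brightfield channels: bright field, dark walls
    bf_base <- matrix(52000, n, n)
    bf_base[root_px] <- 45000
    bf_base[wall] <- 18000
    bf405 <- bf_base + matrix(rnorm(n * n, sd = 400), n, n)
    bf458 <- bf_base + matrix(rnorm(n * n, sd = 400), n, n)

    # fluorescence: apoplastic (wall-concentrated) dye signal
    base <- matrix(150, n, n)
    base[root_px] <- 6000
    base[wall & root_px] <- 12000
    e1 <- if (config$noise_sd > 0) matrix(rnorm(n * n, sd = config$noise_sd), n, n) else 0
    e2 <- if (config$noise_sd > 0) matrix(rnorm(n * n, sd = config$noise_sd), n, n) else 0
    fl405 <- base * pmax(1 + e1, 0.05)
    fl458 <- fl405 * ratio_map * pmax(1 + e2, 0.05)

    px <- array(0, dim = c(n, n, 4))
    px[, , 1] <- fl405
    px[, , 2] <- pmax(bf405, 0)
    px[, , 3] <- fl458
    px[, , 4] <- pmax(bf458, 0)
    px <- pmin(px, 65535)
    structure(list(image = multichannel_image(px),
                   mask = seg_mask(lab),
                   truth = eff, line = line, treatment = treatment),
              class = "synthetic_sample")
  })
}

#' Generate a labeled synthetic dataset with group structure
#'
#' Mirrors a two-line by two-treatment experimental design. Per-sample seeds
#' are `config$seed + sample index`, so the dataset is deterministic as a
#' whole while samples differ.
#'
#' @param config a [synthetic_config()].
#' @param n_per_group samples per (line, treatment) group (>= 1).
#' @param groups list of `c(line, treatment)` pairs.
#' @return list with `samples` (named list of `synthetic_sample`) and
#'   `metadata` (data.frame: sample_id, line, treatment, file [NA until
#'   written to disk]).
#' @export
generate_dataset <- function(config, n_per_group,
                             groups = list(c("Col-0", "mock"), c("Col-0", "BL"),
                                           c("bri1-301", "mock"), c("bri1-301", "BL"))) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(groups) == 0) stop("no groups given")
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  samples <- list()
  meta <- list()
  idx <- 0L
  for (g in groups) {
    line <- g[[1]]; treatment <- g[[2]]
    for (i in seq_len(n_per_group)) {
      idx <- idx + 1L
      cfg_i <- config
      cfg_i$seed <- config$seed + idx
      sid <- sprintf("%s_%s_%03d", gsub("[^A-Za-z0-9.-]", "-", line),
                     gsub("[^A-Za-z0-9.-]", "-", treatment), i)
      samples[[sid]] <- generate_sample(cfg_i, line, treatment)
      meta[[idx]] <- data.frame(sample_id = sid, line = line,
                                treatment = treatment, file = NA_character_,
                                stringsAsFactors = FALSE)
    }
  }
  list(samples = samples, metadata = do.call(rbind, meta))
}
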