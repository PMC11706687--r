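#' Pixel-wise 458/405 ratio image
#'
#' The relative abundance of protonated (405 nm-excited) and deprotonated
#' (458 nm-excited) HPTS is reflected by the pixel-wise 458/405 intensity
#' ratio, which tracks apoplastic pH. Pixels whose 405 nm denominator is not
#' strictly above `eps` are flagged invalid and excluded downstream
#' (invalidity is data, not an error).
#'
#' @param image a [multichannel_image()].
#' @param eps denominator validity threshold (default 0: any strictly
#'   positive fl405 intensity is valid).
#' @return a `ratio_image`: list with `X` (H x W ratio matrix, `NA` at
#'   invalid pixels) and `valid` (logical H x W).
#' @export
compute_ratio_image <- function(image, eps = 0) {
  stopifnot(inherits(image, "mc_image"))
  fl405 <- channel(image, "fl405")
  fl458 <- channel(image, "fl458")
  valid <- fl405 > eps
  X <- matrix(NA_real_, nrow(fl405), ncol(fl405))
  X[valid] <- fl458[valid] / fl405[valid]
  structure(list(X = X, valid = valid), class = "ratio_image")
}

#' Mean 458/405 ratio over one zone
#'
#' The zone mean is sum(X * Y) / sum(Y) with Y the one-hot mask of the zone,
#' restricted to valid ratio pixels (invalid pixels are excluded from both
#' sums rather than counted as zero, which would bias the mean downward).
#'
#' @param ratio a [compute_ratio_image()] result.
#' @param mask a [seg_mask()] on the same grid.
#' @param zone zone name ("root", "EEZ", "LEZ", "MZ") or class id.
#' @param sample_id optional sample id carried into the result.
#' @return one-row data.frame: sample_id, zone, mean_ratio, n_pixels;
#'   `mean_ratio` is `NA` (measure missing) when the zone has no valid pixel.
#' @export
zone_mean_ratio <- function(ratio, mask, zone, sample_id = NA_character_) {
  stopifnot(inherits(ratio, "ratio_image"))
  if (!all(dim(ratio$X) == dim(mask))) stop("ratio/mask shape mismatch")
  cid <- if (is.character(zone)) {
    if (!zone %in% names(ZONE_CLASSES)) stop("unknown zone: ", zone)
    ZONE_CLASSES[[zone]]
  } else as.integer(zone)
  zname <- names(ZONE_CLASSES)[match(cid, ZONE_CLASSES)]
  sel <- unclass(mask) == cid & ratio$valid
  n <- sum(sel)
  data.frame(sample_id = sample_id, zone = zname,
             mean_ratio = if (n > 0) mean(ratio$X[sel]) else NA_real_,
             n_pixels = n, stringsAsFactors = FALSE)
}

#' Zone mean ratios for the standard set of zones of one sample
#'
#' @inheritParams zone_mean_ratio
#' @param zones zone names to measure.
#' @return data.frame with one [zone_mean_ratio()] row per zone.
#' @export
zone_measures <- function(ratio, mask, sample_id,
                          zones = c("root", "EEZ", "LEZ", "MZ")) {
  do.call(rbind, lapply(zones, function(z) {
    zone_mean_ratio(ratio, mask, z, sample_id)
  }))
}

#' Welch's two-sample t-test with group summaries
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value, plus per-group n, mean, median and quartiles
#' (linear-interpolation convention).
#'
#' @param values_a,values_b numeric vectors (>= 2 finite values each, and at
#'   least one group with nonzero variance).
#' @return a one-row data.frame: t_statistic, df, p_value, and per-group
#'   summaries.
#' @export
welch_t_test <- function(values_a, values_b) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 finite values")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("both groups have zero variance; Welch's t-test is undefined")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  qa <- qs(a); qb <- qs(b)
  data.frame(t_statistic = unname(ht$statistic), df = unname(ht$parameter),
             p_value = ht$p.value,
             n_a = length(a), mean_a = mean(a), q1_a = qa[1], median_a = qa[2], q3_a = qa[3],
             n_b = length(b), mean_b = mean(b), q1_b = qb[1], median_b = qb[2], q3_b = qb[3])
}

#' Group comparisons of zone mean ratios
#'
#' Joins per-sample zone measures to sample records and runs Welch's t-test
#' for each configured comparison in each zone. By default, treatments are
#' compared within each line (reference treatment vs every other), and lines
#' are compared against the wildtype within each treatment. Raw p values are
#' reported (no multiple-testing correction), as is conventional for this
#' assay; the HTML report flags the multiplicity.
#'
#' @param measures data.frame from [zone_mean_ratio()] rows.
#' @param records data.frame with sample_id, line, treatment.
#' @param comparisons optional list of comparisons, each a list with
#'   elements `a` and `b`, both `c(line, treatment)` pairs.
#' @param wildtype_line reference line (default "Col-0" if present).
#' @param reference_treatment reference treatment (default "mock" if present).
#' @return data.frame with one row per (zone, comparison).
#' @export
group_statistics <- function(measures, records, comparisons = NULL,
                             wildtype_line = NULL, reference_treatment = NULL) {
  if (!all(measures$sample_id %in% records$sample_id)) {
    orphan <- setdiff(measures$sample_id, records$sample_id)
    stop("measures without a metadata record: ", paste(orphan, collapse = ", "))
  }
  df <- merge(measures, records[, c("sample_id", "line", "treatment")],
              by = "sample_id")
  lines <- sort(unique(df$line))
  treatments <- sort(unique(df$treatment))
  wildtype_line <- wildtype_line %||%
    (if ("Col-0" %in% lines) "Col-0" else lines[1])
  reference_treatment <- reference_treatment %||%
    (if ("mock" %in% treatments) "mock" else treatments[1])
  if (is.null(comparisons)) {
    comparisons <- list()
    for (ln in lines) {
      for (tr in setdiff(treatments, reference_treatment)) {
        comparisons <- c(comparisons,
                         list(list(a = c(ln, reference_treatment), b = c(ln, tr))))
      }
    }
    for (tr in treatments) {
      for (ln in setdiff(lines, wildtype_line)) {
        comparisons <- c(comparisons,
                         list(list(a = c(wildtype_line, tr), b = c(ln, tr))))
      }
    }
  }
  known <- function(g) g[1] %in% df$line && g[2] %in% df$treatment
  out <- list()
  for (zone in sort(unique(df$zone))) {
    dz <- df[df$zone == zone & is.finite(df$mean_ratio), ]
    for (cmp in comparisons) {
      if (!known(cmp$a) || !known(cmp$b)) {
        stop(sprintf("unknown comparison labels: (%s,%s) vs (%s,%s)",
                     cmp$a[1], cmp$a[2], cmp$b[1], cmp$b[2]))
      }
      va <- dz$mean_ratio[dz$line == cmp$a[1] & dz$treatment == cmp$a[2]]
      vb <- dz$mean_ratio[dz$line == cmp$b[1] & dz$treatment == cmp$b[2]]
      if (length(va) < 2 || length(vb) < 2) next
      wt <- welch_t_test(va, vb)
      out[[length(out) + 1]] <- cbind(
        data.frame(zone = zone,
                   group_a = paste(cmp$a, collapse = ":"),
                   group_b = paste(cmp$b, collapse = ":"),
                   stringsAsFactors = FALSE),
        wt)
    }
  }
  if (length(out) == 0) {
    return(data.frame())
  }
  do.call(rbind, out)
}
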