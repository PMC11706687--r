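#' Pipeline configuration
#'
#' @param input_table path to the sample metadata table (sample_id, line,
#'   treatment, file).
#' @param model_checkpoint path to a trained model checkpoint.
#' @param output_dir output directory (created if needed).
#' @param mc_dropout an [mc_dropout_config()].
#' @param attribution compute Guided Grad-CAM maps per sample.
#' @param attribution_top_k number of most frequently predicted
#'   non-background classes to attribute per sample.
#' @param comparisons optional explicit comparisons (see [group_statistics()]).
#' @param seed integer top-level seed; all pipeline randomness (dropout
#'   sampling) derives from it and is recorded in the manifest.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(input_table, model_checkpoint, output_dir,
                            mc_dropout = mc_dropout_config(),
                            attribution = TRUE, attribution_top_k = 3L,
                            comparisons = NULL, seed = 1L) {
  structure(list(input_table = input_table,
                 model_checkpoint = model_checkpoint,
                 output_dir = output_dir, mc_dropout = mc_dropout,
                 attribution = isTRUE(attribution),
                 attribution_top_k = as.integer(attribution_top_k),
                 comparisons = comparisons, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end analysis pipeline
#'
#' For every sample in the metadata table: reads the 4-channel image,
#' computes the pixel-wise 458/405 ratio image, segments the bf-405nm
#' channel, computes Monte Carlo Dropout uncertainty maps and (optionally)
#' Guided Grad-CAM attribution maps for the most frequently predicted
#' non-background classes, writes all derived layers into a per-sample
#' result OME-TIFF, and collects per-zone mean ratios. Group statistics
#' (Welch's t-tests) are computed across samples, CSV tables and an HTML
#' report are written, and a JSON run manifest records seeds, versions and
#' per-sample status. Per-sample failures are logged and skipped; the run
#' fails only if every sample fails. Two runs with identical inputs, config
#' and seed produce byte-identical CSV tables and masks.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `measures`, `comparisons`, `manifest`, and
#'   output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  records <- read_metadata_table(config$input_table)
  model <- load_checkpoint(config$model_checkpoint)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  img_dir <- file.path(out, "images")
  dir.create(img_dir, showWarnings = FALSE)

  measures <- list()
  panels <- list()
  manifest <- list(package_version = as.character(utils::packageVersion("rootzones")),
                   seed = config$seed,
                   mc_dropout = unclass(config$mc_dropout),
                   model_checkpoint = config$model_checkpoint,
                   samples = list())
  n_ok <- 0L
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    t0 <- Sys.time()
    res <- tryCatch({
      image <- read_image(rec$path_resolved)
      bf <- channel(image, "bf405")
      pred <- predict(model, bf)
      ratio <- compute_ratio_image(image)
      mc_cfg <- config$mc_dropout
      mc_cfg$seed <- derive_seed(config$seed, paste0("mc_", rec$sample_id))
      unc <- mc_dropout_predict(model, bf, mc_cfg)
      layers <- list(segmentation = matrix(as.double(pred$mask),
                                           nrow(bf), ncol(bf)),
                     ratio = ratio$X)
      for (cn in names(ZONE_CLASSES)) {
        layers[[paste0("uncertainty_", cn)]] <-
          unc$per_class_std[, , ZONE_CLASSES[[cn]] + 1]
      }
      layers$uncertainty <- unc$scalar_map
      panel <- list(bf405 = render_gray_png(bf),
                    segmentation = render_mask_png(pred$mask),
                    ratio = render_heatmap(ratio$X),
                    uncertainty = render_heatmap(unc$scalar_map))
      if (config$attribution) {
        freq <- table(factor(unclass(pred$mask), levels = ZONE_CLASSES))
        freq <- freq[names(freq) != "0"]
        top <- names(sort(freq[freq > 0], decreasing = TRUE))
        top <- utils::head(top, config$attribution_top_k)
        for (cls in as.integer(top)) {
          am <- guided_grad_cam(model, bf, cls)
          cn <- names(ZONE_CLASSES)[cls + 1]
          layers[[paste0("attribution_", cn)]] <- am$values
          panel[[paste0("attribution_", cn)]] <-
            render_heatmap(am$values, palette = pal_orange)
        }
      }
      res_path <- file.path(img_dir, paste0(rec$sample_id, "_result.ome.tif"))
      write_result_image(image, layers, res_path)
      measures[[rec$sample_id]] <- zone_measures(ratio, pred$mask, rec$sample_id)
      panels[[rec$sample_id]] <- list(sample_id = rec$sample_id,
                                      line = rec$line,
                                      treatment = rec$treatment,
                                      panels = panel)
      n_ok <- n_ok + 1L
      list(status = "ok", result_image = basename(res_path))
    }, error = function(e) list(status = "failed", error = conditionMessage(e)))
    res$seconds <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    manifest$samples[[rec$sample_id]] <- res
  }
  manifest_path <- file.path(out, "manifest.json")
  if (n_ok == 0L) {
    # the manifest is written even when the whole run fails
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    stop("all samples failed; see manifest for details: ",
         manifest$samples[[1]]$error)
  }

  measures_df <- do.call(rbind, measures)
  rownames(measures_df) <- NULL
  comparisons_df <- group_statistics(measures_df, records,
                                     comparisons = config$comparisons)
  measures_csv <- file.path(out, "zone_measures.csv")
  comparisons_csv <- file.path(out, "group_comparisons.csv")
  write.csv(measures_df, measures_csv, row.names = FALSE)
  write.csv(comparisons_df, comparisons_csv, row.names = FALSE)
  report_path <- file.path(out, "report.html")
  render_report(report_path, panels, measures_df, comparisons_df, manifest)
  manifest$total_seconds <- round(as.numeric(difftime(Sys.time(), t_start,
                                                      units = "secs")), 3)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(measures = measures_df, comparisons = comparisons_df,
                 manifest = manifest,
                 paths = list(measures = measures_csv,
                              comparisons = comparisons_csv,
                              report = report_path, manifest = manifest_path)))
}

#' Train a model from a dataset directory
#'
#' Reads a dataset written by [simulate_command()] (metadata table, OME-TIFF
#' images, `<id>_mask.tif` label masks), splits it per the configured
#' fractions, trains, and writes the checkpoint (+ JSON sidecar) and a
#' per-epoch metrics CSV.
#'
#' @param config a [train_config()].
#' @param dataset_dir dataset directory.
#' @param out_checkpoint checkpoint output path.
#' @param arch an [arch_config()] (default tiny preset).
#' @return invisibly, list with `model`, `metrics`, `split`, `test_report`.
#' @export
train_command <- function(config, dataset_dir, out_checkpoint,
                          arch = arch_config("tiny")) {
  if (!dir.exists(dataset_dir)) stop("dataset directory not found: ", dataset_dir)
  tab <- read_metadata_table(file.path(dataset_dir, "metadata.tsv"),
                             check_files = TRUE)
  dataset <- list()
  for (i in seq_len(nrow(tab))) {
    sid <- tab$sample_id[i]
    img <- read_image(tab$path_resolved[i])
    mask_path <- file.path(dataset_dir, paste0(sid, "_mask.tif"))
    if (!file.exists(mask_path)) stop("missing mask for sample ", sid)
    m <- read_tiff(mask_path)$planes[[1]]
    dataset[[sid]] <- list(x = channel(img, "bf405"), y = seg_mask(m))
  }
  sp <- split_dataset(names(dataset), config$split, seed = config$seed)
  model <- build_model(arch, seed = if (config$deterministic) config$seed else
    sample.int(2^30, 1))
  fit <- train(model, dataset[sp$train], config, val_dataset = dataset[sp$val])
  save_checkpoint(fit$model, out_checkpoint)
  metrics_csv <- paste0(tools::file_path_sans_ext(out_checkpoint), "_metrics.csv")
  write.csv(fit$metrics, metrics_csv, row.names = FALSE)
  test_report <- evaluate(fit$model, dataset[sp$test])
  invisible(list(model = fit$model, metrics = fit$metrics, split = sp,
                 test_report = test_report, checkpoint = out_checkpoint))
}

#' Generate a synthetic dataset on disk
#'
#' @param config a [synthetic_config()].
#' @param groups list of `c(line, treatment)` pairs.
#' @param n_per_group samples per group.
#' @param out_dir output directory.
#' @return invisibly, the metadata table path.
#' @export
simulate_command <- function(config, groups, n_per_group, out_dir) {
  ds <- generate_dataset(config, n_per_group, groups)
  write_dataset(ds$samples, ds$metadata, out_dir)
}
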