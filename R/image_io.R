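#' Multichannel microscopy image
#'
#' A 4-channel 2-D image in the fixed acquisition channel order:
#' (1) fluorescence 405 nm, (2) brightfield 405 nm, (3) fluorescence 458 nm,
#' (4) brightfield 458 nm. Pixels are stored as a (H, W, 4) double array;
#' intensities are non-negative.
#'
#' @param pixels (H, W, 4) numeric array.
#' @param pixel_size_um physical pixel size in micrometres (the acquisition
#'   target pixel size, 0.415133 um, by default).
#' @return an object of class `mc_image`.
#' @export
multichannel_image <- function(pixels, pixel_size_um = 0.415133) {
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 4) stop("pixels must be an (H, W, 4) array")
  if (min(pixels) < 0) stop("intensities must be non-negative")
  structure(list(pixels = pixels, channel_roles = CHANNEL_ROLES,
                 pixel_size_um = pixel_size_um),
            class = "mc_image")
}

#' @export
print.mc_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<mc_image> %d x %d px, channels: %s, pixel size %.6f um\n",
              d[1], d[2], paste(x$channel_roles, collapse = ","),
              x$pixel_size_um))
  invisible(x)
}

#' Extract one channel of a multichannel image by role
#'
#' @param image a [multichannel_image()].
#' @param role one of "fl405", "bf405", "fl458", "bf458".
#' @return H x W numeric matrix.
#' @export
channel <- function(image, role) {
  i <- match(role, image$channel_roles)
  if (is.na(i)) stop("no channel with role ", role)
  image$pixels[, , i]
}

#' Read a multichannel image from (OME-)TIFF
#'
#' Accepts OME-TIFF or bare multi-page TIFF with at least 4 planes; a bare
#' TIFF is assumed to follow the acquisition channel order. OME channel
#' metadata (channel names, PhysicalSizeX) is honoured when present;
#' intensities are preserved losslessly.
#'
#' @param path file path.
#' @return a [multichannel_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  tf <- read_tiff(path)
  if (length(tf$planes) < 4) {
    stop(sprintf("expected >= 4 channels, found %d in %s", length(tf$planes), path))
  }
  ome <- parse_ome_xml(tf$description)
  px_size <- ome$pixel_size_um %||% 0.415133
  d <- dim(tf$planes[[1]])
  arr <- array(0, dim = c(d[1], d[2], 4))
  for (i in 1:4) arr[, , i] <- tf$planes[[i]]
  multichannel_image(arr, pixel_size_um = px_size)
}

#' Write a multichannel image as OME-TIFF (uint16)
#'
#' @param image a [multichannel_image()].
#' @param path output path.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "mc_image"))
  d <- dim(image$pixels)
  planes <- lapply(1:4, function(i) image$pixels[, , i])
  write_tiff(path, planes, type = "uint16",
             description = ome_xml(image$channel_roles, d[1], d[2], "uint16",
                                   image$pixel_size_um))
  invisible(path)
}

#' Write a result OME-TIFF with derived layers
#'
#' The output contains the original four channels followed by the named
#' derived layers (e.g. segmentation, ratio, uncertainty, attribution), each
#' as an extra channel; channel names are recorded in the OME metadata. All
#' planes are written as 32-bit float for OME type consistency: integer
#' label layers survive exactly (small integers are exact in float32).
#'
#' @param image a [multichannel_image()].
#' @param extra_layers named list of H x W matrices (possibly empty).
#' @param path output path.
#' @export
write_result_image <- function(image, extra_layers = list(), path) {
  stopifnot(inherits(image, "mc_image"))
  d <- dim(image$pixels)
  if (length(extra_layers) && is.null(names(extra_layers))) {
    stop("extra layers must be named")
  }
  for (nm in names(extra_layers)) {
    l <- extra_layers[[nm]]
    if (!all(dim(l)[1:2] == d[1:2])) {
      stop(sprintf("layer '%s' shape mismatch: %dx%d vs %dx%d",
                   nm, dim(l)[1], dim(l)[2], d[1], d[2]))
    }
  }
  planes <- c(lapply(1:4, function(i) image$pixels[, , i]),
              lapply(extra_layers, function(l) {
                m <- as.matrix(unclass(l))
                m[!is.finite(m)] <- 0
                m
              }))
  names(planes) <- NULL
  ch_names <- c(image$channel_roles, names(extra_layers))
  write_tiff(path, planes, type = "float32",
             description = ome_xml(ch_names, d[1], d[2], "float",
                                   image$pixel_size_um))
  invisible(path)
}

# Read back a result OME-TIFF as a named list of layers.
read_result_layers <- function(path) {
  tf <- read_tiff(path)
  ome <- parse_ome_xml(tf$description)
  nms <- ome$channel_names %||% paste0("channel", seq_along(tf$planes))
  setNames(tf$planes, nms[seq_along(tf$planes)])
}

#' Read and validate the sample metadata table
#'
#' A tab- or comma-separated table with required columns
#' `sample_id`, `line`, `treatment`, `file`. Sample ids must be unique.
#'
#' @param path table path.
#' @param check_files verify that referenced image files exist (relative
#'   paths are resolved against the table's directory).
#' @return a data.frame of sample records; a `path_resolved` column holds
#'   absolute file paths.
#' @export
read_metadata_table <- function(path, check_files = FALSE) {
  if (!file.exists(path)) stop("metadata table not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  tb <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                   quote = "\"", comment.char = "")
  req <- c("sample_id", "line", "treatment", "file")
  missing_cols <- setdiff(req, names(tb))
  if (length(missing_cols)) {
    stop("metadata table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tb$sample_id)) {
    stop("duplicate sample_id in metadata table: ",
         paste(unique(tb$sample_id[duplicated(tb$sample_id)]), collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  tb$path_resolved <- ifelse(grepl("^(/|[A-Za-z]:)", tb$file), tb$file,
                             file.path(base, tb$file))
  if (check_files) {
    missing_f <- tb$path_resolved[!file.exists(tb$path_resolved)]
    if (length(missing_f)) {
      stop("missing image file(s): ", paste(missing_f, collapse = ", "))
    }
  }
  tb
}

# Write a dataset (images + masks + metadata table) to a directory.
write_dataset <- function(samples, metadata, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)
  metadata$file <- paste0(metadata$sample_id, ".ome.tif")
  for (i in seq_len(nrow(metadata))) {
    sid <- metadata$sample_id[i]
    s <- samples[[sid]]
    write_image(s$image, file.path(out_dir, metadata$file[i]))
    write_tiff(file.path(out_dir, paste0(sid, "_mask.tif")),
               list(matrix(as.double(s$mask), nrow(s$mask), ncol(s$mask))),
               type = "uint8")
  }
  tab_path <- file.path(out_dir, "metadata.tsv")
  write.table(metadata[, c("sample_id", "line", "treatment", "file")],
              tab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab_path)
}
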