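# Minimal baseline TIFF reader/writer (uncompressed, single-sample-per-pixel,
# multi-page), sufficient for OME-TIFF interchange of microscopy planes.
# No TIFF package ships with this R installation, so the subset of the format
# the pipeline needs is implemented here and cross-validated in the tests
# against an independent TIFF implementation.
#
# Supported on read: little/big endian classic TIFF; bits 8/16/32; sample
# formats uint and IEEE float; any strip layout; tags beyond the needed set
# are ignored. Supported on write: little endian; uint8/uint16/float32; one
# strip per page; ImageDescription on the first page.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, ImageDescription = 270L,
               StripOffsets = 273L, SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

# --- writer ----------------------------------------------------------------

# planes: list of numeric matrices; type: "uint8", "uint16" or "float32"
# (recycled over planes); description: character scalar or NULL.
write_tiff <- function(path, planes, type = "uint16", description = NULL) {
  stopifnot(length(planes) >= 1)
  type <- rep(type, length.out = length(planes))
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  desc_raw <- if (!is.null(description)) {
    c(charToRaw(enc2utf8(description)), as.raw(0))
  } else NULL

  # layout: header(8) | desc | pixel data per page | IFDs
  offset <- 8L
  desc_off <- 0L
  if (!is.null(desc_raw)) {
    desc_off <- offset
    offset <- offset + length(desc_raw)
    if (offset %% 2L == 1L) offset <- offset + 1L
  }
  np <- length(planes)
  data_off <- integer(np)
  nbytes <- integer(np)
  for (i in seq_len(np)) {
    bps <- switch(type[i], uint8 = 1L, uint16 = 2L, float32 = 4L,
                  stop("unsupported type: ", type[i]))
    nbytes[i] <- length(planes[[i]]) * bps
    data_off[i] <- offset
    offset <- offset + nbytes[i]
    if (offset %% 2L == 1L) offset <- offset + 1L
  }
  ifd_off <- offset

  # header
  writeBin(charToRaw("II"), con)
  w(42L, 2)
  w(ifd_off, 4)
  if (!is.null(desc_raw)) {
    writeBin(desc_raw, con)
    if ((8L + length(desc_raw)) %% 2L == 1L) writeBin(as.raw(0), con)
  }
  # pixel data (row-major)
  for (i in seq_len(np)) {
    m <- planes[[i]]
    v <- as.vector(t(m))
    if (type[i] == "float32") {
      w(as.double(v), 4)
    } else if (type[i] == "uint16") {
      iv <- as.integer(round(pmin(pmax(v, 0), 65535)))
      iv[iv > 32767L] <- iv[iv > 32767L] - 65536L
      w(iv, 2)
    } else {
      writeBin(as.raw(as.integer(round(pmin(pmax(v, 0), 255)))), con)
    }
    if (nbytes[i] %% 2L == 1L) writeBin(as.raw(0), con)
  }
  # IFDs
  ifd_sizes <- integer(np)
  for (i in seq_len(np)) {
    n_entries <- 10L + as.integer(i == 1L && !is.null(desc_raw))
    ifd_sizes[i] <- 2L + n_entries * 12L + 4L
  }
  for (i in seq_len(np)) {
    m <- planes[[i]]
    bits <- switch(type[i], uint8 = 8L, uint16 = 16L, float32 = 32L)
    sfmt <- if (type[i] == "float32") 3L else 1L
    entries <- list(
      list(TIFF_TAGS[["ImageWidth"]], 3L, 1L, ncol(m)),
      list(TIFF_TAGS[["ImageLength"]], 3L, 1L, nrow(m)),
      list(TIFF_TAGS[["BitsPerSample"]], 3L, 1L, bits),
      list(TIFF_TAGS[["Compression"]], 3L, 1L, 1L),
      list(TIFF_TAGS[["Photometric"]], 3L, 1L, 1L))
    if (i == 1L && !is.null(desc_raw)) {
      entries <- c(entries, list(list(TIFF_TAGS[["ImageDescription"]], 2L,
                                      length(desc_raw), desc_off)))
    }
    entries <- c(entries, list(
      list(TIFF_TAGS[["StripOffsets"]], 4L, 1L, data_off[i]),
      list(TIFF_TAGS[["SamplesPerPixel"]], 3L, 1L, 1L),
      list(TIFF_TAGS[["RowsPerStrip"]], 3L, 1L, nrow(m)),
      list(TIFF_TAGS[["StripByteCounts"]], 4L, 1L, nbytes[i]),
      list(TIFF_TAGS[["SampleFormat"]], 3L, 1L, sfmt)))
    ord <- order(vapply(entries, function(e) e[[1]], numeric(1)))
    entries <- entries[ord]
    w(length(entries), 2)
    for (e in entries) {
      w(as.integer(e[[1]]), 2)              # tag
      w(as.integer(e[[2]]), 2)              # type (2 ascii, 3 short, 4 long)
      w(as.integer(e[[3]]), 4)              # count
      if (e[[2]] == 3L && e[[3]] == 1L) {
        w(as.integer(e[[4]]), 2); w(0L, 2)  # short packed into 4 bytes
      } else {
        w(as.integer(e[[4]]), 4)
      }
    }
    next_off <- if (i < np) ifd_off + sum(ifd_sizes[seq_len(i)]) else 0L
    w(next_off, 4)
  }
  invisible(path)
}

# --- reader ----------------------------------------------------------------

# Returns list(planes = list of matrices, description = chr or NULL).
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  endian <- if (rawToChar(raw[1:2]) == "II") "little" else
    if (rawToChar(raw[1:2]) == "MM") "big" else stop("not a TIFF file: ", path)
  rint <- function(off, size, n = 1L, signed = FALSE) {
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            signed = signed || size == 4L, endian = endian)
  }
  if (rint(2, 2) != 42L) stop("not a classic TIFF file: ", path)
  ifd_off <- rint(4, 4)
  planes <- list()
  description <- NULL
  while (ifd_off != 0) {
    nent <- rint(ifd_off, 2)
    tags <- list()
    for (j in seq_len(nent)) {
      e <- ifd_off + 2 + (j - 1) * 12
      tag <- rint(e, 2)
      typ <- rint(e + 2, 2)
      cnt <- rint(e + 4, 4)
      tsize <- switch(as.character(typ), "1" = 1L, "2" = 1L, "3" = 2L,
                      "4" = 4L, "6" = 1L, "8" = 2L, "9" = 4L, NA_integer_)
      if (is.na(tsize)) next
      total <- tsize * cnt
      voff <- if (total <= 4) e + 8 else rint(e + 8, 4)
      vals <- if (typ == 2L) {
        rawToChar(raw[(voff + 1):(voff + cnt)][raw[(voff + 1):(voff + cnt)] != as.raw(0)])
      } else {
        v <- rint(voff, tsize, cnt, signed = FALSE)
        if (tsize == 2L) v[v < 0] <- v[v < 0] + 65536
        v
      }
      tags[[as.character(tag)]] <- vals
    }
    g <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    Wd <- g(256); Ht <- g(257)
    if (is.null(Wd) || is.null(Ht)) stop("TIFF page missing dimensions")
    if (g(259, 1L)[1] != 1L) stop("compressed TIFF not supported")
    bits <- g(258, 1L)[1]
    sfmt <- g(339, 1L)[1]
    spp <- g(277, 1L)[1]
    if (spp != 1L) stop("only single-sample TIFF pages are supported")
    offs <- g(273); cnts <- g(279)
    if (is.null(offs)) stop("TIFF page missing strip offsets")
    buf <- raw(0)
    if (is.null(cnts)) cnts <- Wd * Ht * bits / 8
    for (si in seq_along(offs)) {
      buf <- c(buf, raw[(offs[si] + 1):(offs[si] + cnts[si])])
    }
    npx <- Wd * Ht
    v <- if (sfmt == 3L) {
      if (bits != 32L) stop("only 32-bit float TIFF supported")
      readBin(buf, "double", n = npx, size = 4, endian = endian)
    } else if (bits == 8L) {
      as.double(readBin(buf, "integer", n = npx, size = 1, signed = FALSE,
                        endian = endian))
    } else if (bits == 16L) {
      x <- readBin(buf, "integer", n = npx, size = 2, signed = FALSE,
                   endian = endian)
      as.double(x)
    } else if (bits == 32L) {
      as.double(readBin(buf, "integer", n = npx, size = 4, endian = endian))
    } else stop("unsupported bit depth: ", bits)
    planes[[length(planes) + 1]] <- t(matrix(v, nrow = Wd, ncol = Ht))
    if (is.null(description) && !is.null(g(270))) description <- g(270)
    ifd_off <- rint(ifd_off + 2 + nent * 12, 4)
  }
  list(planes = planes, description = description)
}

# --- OME-XML ---------------------------------------------------------------

ome_xml <- function(channel_names, H, W, type, pixel_size_um = NULL) {
  ch <- paste0(sprintf('<Channel ID="Channel:0:%d" Name="%s" SamplesPerPixel="1"/>',
                       seq_along(channel_names) - 1L, channel_names),
               collapse = "")
  ps <- if (!is.null(pixel_size_um)) {
    sprintf(' PhysicalSizeX="%.10g" PhysicalSizeXUnit="µm" PhysicalSizeY="%.10g" PhysicalSizeYUnit="µm"',
            pixel_size_um, pixel_size_um)
  } else ""
  paste0('<?xml version="1.0" encoding="UTF-8"?>',
         '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
         '<Image ID="Image:0" Name="rootzones">',
         sprintf('<Pixels ID="Pixels:0" DimensionOrder="XYCZT" Type="%s" SizeX="%d" SizeY="%d" SizeC="%d" SizeZ="1" SizeT="1"%s>',
                 type, W, H, length(channel_names), ps),
         ch,
         paste0(sprintf('<TiffData FirstC="%d" FirstT="0" FirstZ="0" IFD="%d" PlaneCount="1"/>',
                        seq_along(channel_names) - 1L, seq_along(channel_names) - 1L),
                collapse = ""),
         '</Pixels></Image></OME>')
}

parse_ome_xml <- function(description) {
  if (is.null(description) || !grepl("<OME", description, fixed = TRUE)) {
    return(NULL)
  }
  doc <- tryCatch(xml2::read_xml(description), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  if (inherits(px, "xml_missing")) return(NULL)
  psx <- xml2::xml_attr(px, "PhysicalSizeX")
  chn <- xml2::xml_attr(xml2::xml_find_all(doc, ".//Channel"), "Name")
  list(pixel_size_um = if (!is.na(psx)) as.numeric(psx) else NULL,
       channel_names = if (length(chn) && !all(is.na(chn))) chn else NULL)
}
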