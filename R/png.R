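# Dependency-free PNG writing for report figures. Uses base R memCompress
# for the deflate stream (rewrapped from gzip to zlib framing) plus
# hand-rolled CRC-32/Adler-32, so report rendering needs no graphics device
# and is bit-reproducible.

.png_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (is.null(.png_env$tab)) {
    tab <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L) != 0L) {
          bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320
        } else bitwShiftR(c, 1L)
      }
      tab[n + 1] <- c
    }
    .png_env$tab <- tab
  }
  .png_env$tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  c <- -1L  # 0xFFFFFFFF
  v <- as.integer(bytes)
  for (b in v) {
    c <- bitwXor(bitwShiftR(c, 8L), tab[bitwAnd(bitwXor(c, b), 255L) + 1L])
  }
  bitwXor(c, -1L)
}

int_be <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

adler32 <- function(bytes) {
  a <- 1; b <- 0
  v <- as.integer(bytes)
  # process in blocks to keep the modulo cheap
  for (i in seq(1, length(v), by = 4096)) {
    blk <- v[i:min(i + 4095, length(v))]
    ca <- cumsum(blk)
    b <- (b + length(blk) * a + sum(ca %% 65521)) %% 65521
    a <- (a + ca[length(ca)]) %% 65521
  }
  a + b * 65536
}

zlib_wrap <- function(bytes) {
  gz <- memCompress(bytes, type = "gzip")
  if (as.integer(gz[1]) == 0x78) {
    return(gz)                               # already zlib-framed
  }
  # gzip framing: strip 10-byte header / 8-byte trailer, add zlib wrapper
  if (as.integer(gz[4]) != 0L) stop("unexpected gzip flags")
  deflate <- gz[11:(length(gz) - 8)]
  c(as.raw(c(0x78, 0x9c)), deflate, int_be(adler32(bytes)))
}

# img: (H, W, 3) array with values in [0, 1]. Returns raw PNG bytes.
png_bytes <- function(img) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  px <- round(pmin(pmax(img, 0), 1) * 255)
  # interleave to RGBRGB... per row, filter byte 0 per scanline
  arr <- aperm(px, c(3, 2, 1))               # (C, W, H)
  rows <- matrix(as.raw(as.integer(arr)), nrow = 3L * W, ncol = H)
  scan <- rbind(matrix(as.raw(0L), 1, H), rows)
  idat <- zlib_wrap(as.vector(scan))
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(int_be(length(data)), body, int_be(crc32(body)))
  }
  ihdr <- c(int_be(W), int_be(H), as.raw(c(8L, 2L, 0L, 0L, 0L)))
  c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
    chunk("IHDR", ihdr), chunk("IDAT", idat), chunk("IEND", raw(0)))
}

# Nearest-neighbour downsample of a matrix to at most `max_px` per side.
shrink_matrix <- function(m, max_px = 192L) {
  d <- dim(m)
  if (max(d) <= max_px) return(m)
  f <- ceiling(max(d) / max_px)
  m[seq(1, d[1], by = f), seq(1, d[2], by = f), drop = FALSE]
}

ramp_palette <- function(anchors) {
  function(v) {
    v <- pmin(pmax(v, 0), 1)
    n <- nrow(anchors)
    pos <- v * (n - 1)
    lo <- pmin(floor(pos) + 1, n)
    hi <- pmin(lo + 1, n)
    f <- pos - (lo - 1)
    out <- array(0, dim = c(dim(v), 3))
    for (c in 1:3) {
      out[, , c] <- anchors[lo, c] * (1 - f) + anchors[hi, c] * f
    }
    out
  }
}

# viridis-style ramp (dark blue = low, bright yellow = high)
pal_viridis <- ramp_palette(matrix(c(
  0.267, 0.005, 0.329,  0.283, 0.141, 0.458,  0.254, 0.265, 0.530,
  0.207, 0.372, 0.553,  0.164, 0.471, 0.558,  0.128, 0.567, 0.551,
  0.135, 0.659, 0.518,  0.267, 0.749, 0.441,  0.478, 0.821, 0.318,
  0.741, 0.873, 0.150,  0.993, 0.906, 0.144), ncol = 3, byrow = TRUE))

# attribution ramp (dark gray = low, bright orange = high)
pal_orange <- ramp_palette(matrix(c(
  0.20, 0.20, 0.20,  0.45, 0.35, 0.25,  0.80, 0.50, 0.10,
  1.00, 0.65, 0.05,  1.00, 0.85, 0.40), ncol = 3, byrow = TRUE))

# qualitative zone colors: background blue, root yellow, EEZ green,
# LEZ brown, MZ purple
MASK_COLORS <- matrix(c(
  0.19, 0.31, 0.97,   # background
  0.95, 0.87, 0.24,   # root
  0.30, 0.69, 0.29,   # EEZ
  0.55, 0.34, 0.16,   # LEZ
  0.60, 0.31, 0.64),  # MZ
  ncol = 3, byrow = TRUE)

render_heatmap <- function(m, palette = pal_viridis, normalize = TRUE) {
  m <- shrink_matrix(as.matrix(m))
  if (normalize) {
    r <- range(m, finite = TRUE)
    m <- if (r[2] > r[1]) (m - r[1]) / (r[2] - r[1]) else m * 0
  }
  m[!is.finite(m)] <- 0
  png_bytes(palette(m))
}

render_mask_png <- function(mask) {
  m <- shrink_matrix(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  out <- array(0, dim = c(dim(m), 3))
  for (c in 1:3) out[, , c] <- matrix(MASK_COLORS[m + 1L, c], nrow(m), ncol(m))
  png_bytes(out)
}

render_gray_png <- function(m) {
  m <- shrink_matrix(as.matrix(m))
  v <- normalize01(m)
  png_bytes(array(rep(v, 3), dim = c(dim(v), 3)))
}
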