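# Forward and backward passes through the nested residual-U-block network.
#
# The backward pass is hand-derived and verified against central finite
# differences in the test suite. A forward "ctx" carries runtime switches:
#   drop_p  dropout probability applied before every convolution (MC mode),
#   guided  use the guided-backpropagation rule at ReLUs during backward.

nn_ctx <- function(drop_p = 0, guided = FALSE) list(drop_p = drop_p, guided = guided)

# Channel-wise concatenation of two (H, W, C) arrays.
abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), dim = c(da[1], da[2], da[3] + db[3]))
}

# --- conv (+ optional pre-dropout, + optional ReLU) ------------------------

reb_fw <- function(pr, x, dil, ctx, relu = TRUE) {
  mask <- NULL
  if (ctx$drop_p > 0) {
    mask <- array(runif(length(x)) >= ctx$drop_p, dim = dim(x))
    x <- x * mask / (1 - ctx$drop_p)
  }
  z <- .conv2d_fw(x, pr$w, pr$b, dil)
  y <- if (relu) z * (z > 0) else z
  list(y = y,
       cache = list(x = x, y = y, mask = mask, relu = relu, dil = dil,
                    drop_p = ctx$drop_p))
}

reb_bw <- function(pr, cache, gy, ctx) {
  if (cache$relu) {
    gy <- gy * (cache$y > 0)
    if (ctx$guided) gy <- gy * (gy > 0)
  }
  bw <- .conv2d_bw(cache$x, pr$w, gy, cache$dil)
  gx <- bw$gx
  if (!is.null(cache$mask)) gx <- gx * cache$mask / (1 - cache$drop_p)
  list(gx = gx, g = list(w = bw$gw, b = bw$gb))
}

# --- residual U-block with internal pooling (RSU-L) ------------------------

rsu_fw <- function(p, L, x, ctx) {
  rin <- reb_fw(p$convin, x, 1L, ctx)
  hs <- vector("list", L - 1)
  cs <- vector("list", L - 1)
  pools <- vector("list", L - 2)
  pdims <- vector("list", L - 2)
  h <- rin$y
  for (j in seq_len(L - 1)) {
    r <- reb_fw(p[[paste0("conv", j)]], h, 1L, ctx)
    hs[[j]] <- r$y
    cs[[j]] <- r$cache
    if (j < L - 1) {
      pl <- .maxpool2_fw(r$y)
      pools[[j]] <- pl$idx
      pdims[[j]] <- dim(r$y)
      h <- pl$y
    }
  }
  rl <- reb_fw(p[[paste0("conv", L)]], hs[[L - 1]], 2L, ctx)
  d <- rl$y
  dcs <- vector("list", L - 1)
  updims <- vector("list", L - 1)
  for (j in rev(seq_len(L - 1))) {
    r <- reb_fw(p[[paste0("conv", j, "d")]], abind3(d, hs[[j]]), 1L, ctx)
    dcs[[j]] <- r$cache
    if (j > 1) {
      updims[[j]] <- dim(r$y)
      tgt <- dim(hs[[j - 1]])
      d <- .resize_bilinear_fw(r$y, tgt[1], tgt[2])
    } else {
      d <- r$y
    }
  }
  list(y = d + rin$y,
       cache = list(rin = rin$cache, cs = cs, pools = pools, pdims = pdims,
                    rl = rl$cache, dcs = dcs, updims = updims, L = L,
                    hdims = lapply(hs, dim)))
}

rsu_bw <- function(p, cache, gy, ctx) {
  L <- cache$L
  g <- list()
  ghs <- vector("list", L - 1)
  gcur <- gy                       # grad wrt conv1d output (residual branch)
  for (j in seq_len(L - 1)) {
    bw <- reb_bw(p[[paste0("conv", j, "d")]], cache$dcs[[j]], gcur, ctx)
    g[[paste0("conv", j, "d")]] <- bw$g
    cin <- dim(bw$gx)[3]
    ch <- cache$hdims[[j]][3]
    gd_part <- bw$gx[, , seq_len(cin - ch), drop = FALSE]
    ghx <- bw$gx[, , cin - ch + seq_len(ch), drop = FALSE]
    ghs[[j]] <- if (is.null(ghs[[j]])) ghx else ghs[[j]] + ghx
    if (j < L - 1) {
      ud <- cache$updims[[j + 1]]
      gcur <- .resize_bilinear_bw(gd_part, ud[1], ud[2])
    } else {
      bwl <- reb_bw(p[[paste0("conv", L)]], cache$rl, gd_part, ctx)
      g[[paste0("conv", L)]] <- bwl$g
      ghs[[L - 1]] <- ghs[[L - 1]] + bwl$gx
    }
  }
  gpool <- NULL
  for (j in rev(seq_len(L - 1))) {
    gj <- ghs[[j]]
    if (!is.null(gpool)) gj <- gj + gpool
    bw <- reb_bw(p[[paste0("conv", j)]], cache$cs[[j]], gj, ctx)
    g[[paste0("conv", j)]] <- bw$g
    if (j > 1) {
      pd <- cache$pdims[[j - 1]]
      gpool <- .maxpool2_bw(cache$pools[[j - 1]], bw$gx, pd[1], pd[2], pd[3])
    } else {
      ghxin <- bw$gx
    }
  }
  ghxin <- ghxin + gy              # residual connection
  bwin <- reb_bw(p$convin, cache$rin, ghxin, ctx)
  g$convin <- bwin$g
  list(gx = bwin$gx, g = g)
}

# Fully dilated block (constant resolution, no pooling).
rsu4f_fw <- function(p, x, ctx) {
  rin <- reb_fw(p$convin, x, 1L, ctx)
  r1 <- reb_fw(p$conv1, rin$y, 1L, ctx)
  r2 <- reb_fw(p$conv2, r1$y, 2L, ctx)
  r3 <- reb_fw(p$conv3, r2$y, 4L, ctx)
  r4 <- reb_fw(p$conv4, r3$y, 8L, ctx)
  r3d <- reb_fw(p$conv3d, abind3(r4$y, r3$y), 4L, ctx)
  r2d <- reb_fw(p$conv2d, abind3(r3d$y, r2$y), 2L, ctx)
  r1d <- reb_fw(p$conv1d, abind3(r2d$y, r1$y), 1L, ctx)
  list(y = r1d$y + rin$y,
       cache = list(rin = rin$cache, r1 = r1$cache, r2 = r2$cache,
                    r3 = r3$cache, r4 = r4$cache, r3d = r3d$cache,
                    r2d = r2d$cache, r1d = r1d$cache))
}

rsu4f_bw <- function(p, cache, gy, ctx) {
  g <- list()
  split2 <- function(gx, ch) {
    cin <- dim(gx)[3]
    list(a = gx[, , seq_len(cin - ch), drop = FALSE],
         b = gx[, , cin - ch + seq_len(ch), drop = FALSE])
  }
  b1d <- reb_bw(p$conv1d, cache$r1d, gy, ctx); g$conv1d <- b1d$g
  s <- split2(b1d$gx, dim(cache$r1$y)[3]); g2d_out <- s$a; g1 <- s$b
  b2d <- reb_bw(p$conv2d, cache$r2d, g2d_out, ctx); g$conv2d <- b2d$g
  s <- split2(b2d$gx, dim(cache$r2$y)[3]); g3d_out <- s$a; g2 <- s$b
  b3d <- reb_bw(p$conv3d, cache$r3d, g3d_out, ctx); g$conv3d <- b3d$g
  s <- split2(b3d$gx, dim(cache$r3$y)[3]); g4_out <- s$a; g3 <- s$b
  b4 <- reb_bw(p$conv4, cache$r4, g4_out, ctx); g$conv4 <- b4$g
  g3 <- g3 + b4$gx
  b3 <- reb_bw(p$conv3, cache$r3, g3, ctx); g$conv3 <- b3$g
  g2 <- g2 + b3$gx
  b2 <- reb_bw(p$conv2, cache$r2, g2, ctx); g$conv2 <- b2$g
  g1 <- g1 + b2$gx
  b1 <- reb_bw(p$conv1, cache$r1, g1, ctx); g$conv1 <- b1$g
  ghxin <- b1$gx + gy
  bin <- reb_bw(p$convin, cache$rin, ghxin, ctx); g$convin <- bin$g
  list(gx = bin$gx, g = g)
}

stage_fw <- function(p, spec, x, ctx) {
  if (spec$type == "rsu4f") rsu4f_fw(p, x, ctx) else rsu_fw(p, spec$L, x, ctx)
}

stage_bw <- function(p, spec, cache, gy, ctx) {
  if (spec$type == "rsu4f") rsu4f_bw(p, cache, gy, ctx) else rsu_bw(p, cache, gy, ctx)
}

# --- whole network ---------------------------------------------------------

# x: (H, W, in_channels). Returns logits d0 (H, W, n_classes) plus caches.
u2net_fw <- function(model, x, ctx = nn_ctx()) {
  spec <- model$spec
  p <- model$params
  if (spec$linear) {
    r <- reb_fw(p$out$conv, x, 1L, ctx, relu = FALSE)
    return(list(d0 = r$y, cache = list(linear = r$cache),
                stage_out = list()))
  }
  n <- length(spec$enc)
  enc <- vector("list", n)
  encc <- vector("list", n)
  pools <- vector("list", n - 1)
  pdims <- vector("list", n - 1)
  h <- x
  for (k in seq_len(n)) {
    if (k > 1) {
      pl <- .maxpool2_fw(h)
      pools[[k - 1]] <- pl$idx
      pdims[[k - 1]] <- dim(h)
      h <- pl$y
    }
    r <- stage_fw(p[[paste0("en", k)]], spec$enc[[k]], h, ctx)
    enc[[k]] <- r$y
    encc[[k]] <- r$cache
    h <- r$y
  }
  dec <- vector("list", n - 1)
  decc <- vector("list", n - 1)
  ddims <- vector("list", n)      # dims of deeper map feeding each concat
  d <- enc[[n]]
  for (k in rev(seq_len(n - 1))) {
    ddims[[k]] <- dim(d)
    tgt <- dim(enc[[k]])
    dup <- .resize_bilinear_fw(d, tgt[1], tgt[2])
    r <- stage_fw(p[[paste0("de", k)]], spec$dec[[k]], abind3(dup, enc[[k]]), ctx)
    dec[[k]] <- r$y
    decc[[k]] <- r$cache
    d <- r$y
  }
  H <- dim(x)[1]; W <- dim(x)[2]
  ns <- n
  sides <- vector("list", ns)
  sidec <- vector("list", ns)
  sdims <- vector("list", ns)
  for (k in seq_len(ns)) {
    src <- if (k <= n - 1) dec[[k]] else enc[[n]]
    r <- reb_fw(p[[paste0("side", k)]]$conv, src, 1L, ctx, relu = FALSE)
    sidec[[k]] <- r$cache
    sdims[[k]] <- dim(r$y)
    sides[[k]] <- if (k == 1) r$y else .resize_bilinear_fw(r$y, H, W)
  }
  cat_sides <- sides[[1]]
  for (k in seq_len(ns)[-1]) cat_sides <- abind3(cat_sides, sides[[k]])
  rout <- reb_fw(p$out$conv, cat_sides, 1L, ctx, relu = FALSE)
  list(d0 = rout$y,
       cache = list(linear = NULL, encc = encc, decc = decc, pools = pools,
                    pdims = pdims, ddims = ddims, sidec = sidec, sdims = sdims,
                    outc = rout$cache, n = n, xdim = dim(x),
                    enc_dims = lapply(enc, dim), dec_dims = lapply(dec, dim)),
       stage_out = c(setNames(dec, paste0("de", seq_len(n - 1))),
                     setNames(enc, paste0("en", seq_len(n)))))
}

# Backward from a gradient on the logits. Returns the gradient with respect
# to the input image, parameter gradients, and (optionally) the gradient at
# one named stage output (for Grad-CAM).
u2net_bw <- function(model, fw, g_d0, ctx = nn_ctx(), cam_layer = NULL) {
  spec <- model$spec
  p <- model$params
  cache <- fw$cache
  if (spec$linear) {
    bw <- reb_bw(p$out$conv, cache$linear, g_d0, ctx)
    return(list(gx = bw$gx, g = list(out = list(conv = bw$g)), cam = NULL))
  }
  n <- cache$n
  nc <- spec$n_classes
  g <- list()
  cam <- NULL
  addg <- function(a, b) if (is.null(a)) b else a + b

  bout <- reb_bw(p$out$conv, cache$outc, g_d0, ctx)
  g$out <- list(conv = bout$g)

  gd <- vector("list", n - 1)      # grads on decoder stage outputs
  gh <- vector("list", n)          # grads on encoder stage outputs
  for (k in seq_len(n)) {
    gs <- bout$gx[, , (k - 1) * nc + seq_len(nc), drop = FALSE]
    if (k > 1) {
      sd <- cache$sdims[[k]]
      gs <- .resize_bilinear_bw(gs, sd[1], sd[2])
    }
    bs <- reb_bw(p[[paste0("side", k)]]$conv, cache$sidec[[k]], gs, ctx)
    g[[paste0("side", k)]] <- list(conv = bs$g)
    if (k <= n - 1) gd[[k]] <- addg(gd[[k]], bs$gx) else gh[[n]] <- addg(gh[[n]], bs$gx)
  }

  for (k in seq_len(n - 1)) {      # shallow -> deep: gd[[k]] complete here
    if (identical(cam_layer, paste0("de", k))) cam <- gd[[k]]
    bw <- stage_bw(p[[paste0("de", k)]], spec$dec[[k]], cache$decc[[k]], gd[[k]], ctx)
    g[[paste0("de", k)]] <- bw$g
    cin <- dim(bw$gx)[3]
    ch <- cache$enc_dims[[k]][3]
    gdup <- bw$gx[, , seq_len(cin - ch), drop = FALSE]
    genc <- bw$gx[, , cin - ch + seq_len(ch), drop = FALSE]
    gh[[k]] <- addg(gh[[k]], genc)
    dd <- cache$ddims[[k]]
    gdeep <- .resize_bilinear_bw(gdup, dd[1], dd[2])
    if (k < n - 1) gd[[k + 1]] <- addg(gd[[k + 1]], gdeep)
    else gh[[n]] <- addg(gh[[n]], gdeep)
  }

  gx <- NULL
  for (k in rev(seq_len(n))) {     # deep -> shallow: gh[[k]] complete here
    if (identical(cam_layer, paste0("en", k))) cam <- gh[[k]]
    bw <- stage_bw(p[[paste0("en", k)]], spec$enc[[k]], cache$encc[[k]], gh[[k]], ctx)
    g[[paste0("en", k)]] <- bw$g
    if (k > 1) {
      pd <- cache$pdims[[k - 1]]
      gprev <- .maxpool2_bw(cache$pools[[k - 1]], bw$gx, pd[1], pd[2], pd[3])
      gh[[k - 1]] <- addg(gh[[k - 1]], gprev)
    } else {
      gx <- bw$gx
    }
  }
  list(gx = gx, g = g, cam = cam)
}
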