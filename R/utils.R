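`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named sub-seed from a top-level seed
#'
#' All randomness in the package flows from one integer seed through named
#' substreams, so that independent stages (weight init, data order, dropout
#' sampling, ...) are decoupled but jointly reproducible.
#'
#' @param seed integer top-level seed.
#' @param name character stream name.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147480009
  as.integer((abs(seed) %% 2147480009 * 7919 + h) %% 2147480009)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Row-wise softmax over the channel (3rd) dimension of an (H, W, C) array.
softmax_hwc <- function(z) {
  d <- dim(z)
  m <- array(apply(z, c(1, 2), max), dim = c(d[1], d[2], 1))
  e <- exp(z - m[, , rep(1, d[3]), drop = FALSE])
  s <- array(rowSums(matrix(e, ncol = d[3])), dim = d[1:2])
  e / array(s, dim = d)
}

# Per-pixel argmax over channels; ties broken toward the lowest class index.
argmax_hwc <- function(z) {
  d <- dim(z)
  m <- matrix(z, ncol = d[3])
  array(max.col(m, ties.method = "first") - 1L, dim = d[1:2])
}

# Min-max normalization of a single-channel image to [0, 1].
normalize01 <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
}

# Flatten a nested list of numeric arrays into a named flat list ("a.b.c").
flatten_params <- function(p, prefix = NULL) {
  out <- list()
  for (nm in names(p)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    if (is.list(p[[nm]])) {
      out <- c(out, flatten_params(p[[nm]], key))
    } else {
      out[[key]] <- p[[nm]]
    }
  }
  out
}

# Inverse of flatten_params, relying on a template for the nesting.
unflatten_params <- function(flat, template) {
  walk <- function(tpl, prefix) {
    out <- tpl
    for (nm in names(tpl)) {
      key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
      if (is.list(tpl[[nm]])) {
        out[[nm]] <- walk(tpl[[nm]], key)
      } else {
        out[[nm]] <- flat[[key]]
      }
    }
    out
  }
  walk(template, NULL)
}

# Elementwise combination of two identically shaped nested lists of arrays.
combine_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- combine_params(a[[nm]], b[[nm]], f)
    out
  } else {
    f(a, b)
  }
}
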