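# Named color gradients for heat-map rendering. Each gradient is an ordered
# set of 2-5 RGB anchors at evenly spaced positions in [0, 1]; cell colors are
# piecewise-linear interpolations between the bracketing anchors. The
# registry ships more than 28 gradients and accepts user-defined ones.

rgb_anchors <- function(...) {
  m <- do.call(rbind, list(...))
  storage.mode(m) <- "integer"
  colnames(m) <- c("r", "g", "b")
  m
}

BUILTIN_GRADIENTS <- list(
  grayscale        = rgb_anchors(c(0, 0, 0), c(255, 255, 255)),
  inverted_gray    = rgb_anchors(c(255, 255, 255), c(0, 0, 0)),
  fire             = rgb_anchors(c(0, 0, 0), c(180, 0, 0), c(255, 160, 0), c(255, 255, 255)),
  heat             = rgb_anchors(c(255, 255, 224), c(255, 165, 0), c(178, 0, 0)),
  viridis_like     = rgb_anchors(c(68, 1, 84), c(59, 82, 139), c(33, 145, 140), c(94, 201, 98), c(253, 231, 37)),
  magma_like       = rgb_anchors(c(0, 0, 4), c(81, 18, 124), c(183, 55, 121), c(252, 137, 97), c(252, 253, 191)),
  inferno_like     = rgb_anchors(c(0, 0, 4), c(87, 16, 110), c(188, 55, 84), c(249, 142, 9), c(252, 255, 164)),
  plasma_like      = rgb_anchors(c(13, 8, 135), c(126, 3, 168), c(204, 71, 120), c(248, 149, 64), c(240, 249, 33)),
  cividis_like     = rgb_anchors(c(0, 32, 77), c(87, 92, 109), c(170, 156, 117), c(255, 234, 70)),
  blue_white_red   = rgb_anchors(c(0, 0, 255), c(255, 255, 255), c(255, 0, 0)),
  red_white_blue   = rgb_anchors(c(255, 0, 0), c(255, 255, 255), c(0, 0, 255)),
  green_black_red  = rgb_anchors(c(0, 255, 0), c(0, 0, 0), c(255, 0, 0)),
  red_black_green  = rgb_anchors(c(255, 0, 0), c(0, 0, 0), c(0, 255, 0)),
  blue_yellow      = rgb_anchors(c(0, 0, 160), c(255, 255, 0)),
  purple_orange    = rgb_anchors(c(94, 60, 153), c(247, 247, 247), c(230, 97, 1)),
  teal_magenta     = rgb_anchors(c(0, 128, 128), c(255, 255, 255), c(199, 21, 133)),
  ocean            = rgb_anchors(c(3, 5, 40), c(10, 60, 120), c(60, 160, 190), c(220, 245, 250)),
  sunset           = rgb_anchors(c(40, 0, 70), c(200, 50, 80), c(255, 160, 60), c(255, 230, 180)),
  forest           = rgb_anchors(c(10, 30, 10), c(30, 110, 50), c(150, 200, 110), c(245, 250, 220)),
  spectral_like    = rgb_anchors(c(158, 1, 66), c(253, 174, 97), c(255, 255, 191), c(171, 221, 164), c(94, 79, 162)),
  coolwarm         = rgb_anchors(c(59, 76, 192), c(221, 221, 221), c(180, 4, 38)),
  blues            = rgb_anchors(c(247, 251, 255), c(107, 174, 214), c(8, 48, 107)),
  reds             = rgb_anchors(c(255, 245, 240), c(251, 106, 74), c(103, 0, 13)),
  greens           = rgb_anchors(c(247, 252, 245), c(116, 196, 118), c(0, 68, 27)),
  purples          = rgb_anchors(c(252, 251, 253), c(158, 154, 200), c(63, 0, 125)),
  oranges          = rgb_anchors(c(255, 245, 235), c(253, 141, 60), c(127, 39, 4)),
  ice              = rgb_anchors(c(255, 255, 255), c(150, 200, 255), c(0, 60, 130)),
  earth            = rgb_anchors(c(120, 63, 4), c(246, 232, 195), c(0, 60, 48)),
  rainbow          = rgb_anchors(c(120, 0, 180), c(0, 80, 255), c(0, 200, 80), c(255, 220, 0), c(230, 30, 30)),
  candy            = rgb_anchors(c(255, 240, 245), c(255, 105, 180), c(139, 0, 79))
)

gradient_registry <- new.env(parent = emptyenv())

init_gradient_registry <- function() {
  for (nm in names(BUILTIN_GRADIENTS)) {
    assign(nm, BUILTIN_GRADIENTS[[nm]], envir = gradient_registry)
  }
}

#' List registered gradient names
#'
#' The package ships more than 28 built-in gradients; [register_gradient()]
#' adds user-defined ones.
#'
#' @return Sorted character vector of gradient names.
#' @export
list_gradients <- function() {
  sort(ls(gradient_registry), method = "radix")
}

#' Look up a gradient by name
#'
#' @param name Gradient name (see [list_gradients()]).
#' @return A `gx_gradient`: list with `name` and `anchors` (n x 3 integer
#'   matrix, channels 0-255, anchors at evenly spaced positions in `[0, 1]`).
#' @export
get_gradient <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !exists(name, envir = gradient_registry, inherits = FALSE)) {
    gx_validation_error(sprintf(
      "unknown gradient %s; see list_gradients()", sQuote(as.character(name)[1])
    ))
  }
  structure(
    list(name = name, anchors = get(name, envir = gradient_registry)),
    class = "gx_gradient"
  )
}

#' Register a user-defined gradient
#'
#' @param name Gradient name.
#' @param anchors Matrix (or list of length-3 vectors) of 2 or more RGB
#'   anchors with integer channels in 0-255, evenly spaced over `[0, 1]`.
#' @return The registered `gx_gradient`, invisibly.
#' @export
register_gradient <- function(name, anchors) {
  if (is.list(anchors)) anchors <- do.call(rbind, anchors)
  anchors <- as.matrix(anchors)
  if (nrow(anchors) < 2L || ncol(anchors) != 3L ||
      any(anchors < 0) || any(anchors > 255) ||
      any(anchors != round(anchors))) {
    gx_validation_error(
      "anchors must be >= 2 RGB triples with integer channels in [0, 255]"
    )
  }
  storage.mode(anchors) <- "integer"
  colnames(anchors) <- c("r", "g", "b")
  assign(name, anchors, envir = gradient_registry)
  invisible(get_gradient(name))
}

#' Map values to gradient colors
#'
#' Each value is rescaled to `t = clamp((value - vmin) / (vmax - vmin), 0, 1)`
#' and colored by piecewise-linear interpolation between the two bracketing
#' anchors. Channels are rounded half-up to integers, so renders are
#' bit-reproducible.
#'
#' @param value Numeric vector of values.
#' @param vmin,vmax Value range; `vmin < vmax` required.
#' @param gradient A `gx_gradient` (or a name passed to [get_gradient()]).
#' @return Integer matrix, `length(value)` x 3 (columns r, g, b).
#' @export
map_value_to_color <- function(value, vmin, vmax, gradient) {
  if (is.character(gradient)) gradient <- get_gradient(gradient)
  stopifnot(inherits(gradient, "gx_gradient"))
  if (!is.finite(vmin) || !is.finite(vmax) || vmin >= vmax) {
    gx_validation_error(sprintf(
      "vmin (%g) must be strictly less than vmax (%g)", vmin, vmax
    ))
  }
  a <- gradient$anchors
  n <- nrow(a)
  t <- pmin(pmax((value - vmin) / (vmax - vmin), 0), 1)
  pos <- t * (n - 1L)
  i <- pmin(floor(pos), n - 2L)
  u <- pos - i
  lo <- a[i + 1L, , drop = FALSE]
  hi <- a[i + 2L, , drop = FALSE]
  col <- lo * (1 - u) + hi * u
  col <- matrix(as.integer(floor(col + 0.5)), ncol = 3L,
                dimnames = list(NULL, c("r", "g", "b")))
  col
}
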