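LABEL_FIELDS <- c("gene_symbol", "ensembl_id", "diseases", "none")
TRANSFORMS <- c("linear", "log10_plus1")

#' Describe a heat-map rendering
#'
#' Captures every customization the renderer supports: the four titles
#' (header, x axis, left and right y axes), the color gradient, which field
#' labels each side of the rows, the value transform and an optional fixed
#' color range.
#'
#' @param title_header,title_x,title_y_left,title_y_right Title texts
#'   (empty string suppresses the title and its margin space).
#' @param gradient Name of a registered gradient (see [list_gradients()]).
#' @param left_label_field,right_label_field What to print beside each row:
#'   `"gene_symbol"`, `"ensembl_id"`, `"diseases"` (terms joined with
#'   `"; "`) or `"none"`.
#' @param transform `"linear"` (default) or `"log10_plus1"`
#'   (`log10(value + 1)`; useful because TPM spans orders of magnitude).
#'   The transform changes cell colors only, never the retained gene set or
#'   row order.
#' @param vmin,vmax Color range on the transformed scale; `NULL` (default)
#'   auto-ranges to the matrix minimum/maximum after transform. When both are
#'   given, `vmin < vmax` is required.
#' @param na_color RGB triple for missing cells (fill policy
#'   `exclude_missing`).
#' @return An object of class `gx_heatmap_spec`.
#' @export
heatmap_spec <- function(title_header = "", title_x = "",
                         title_y_left = "", title_y_right = "",
                         gradient = "viridis_like",
                         left_label_field = "gene_symbol",
                         right_label_field = "diseases",
                         transform = "linear",
                         vmin = NULL, vmax = NULL,
                         na_color = c(200L, 200L, 200L)) {
  left_label_field <- gx_match_arg(left_label_field, LABEL_FIELDS,
                                   "left_label_field")
  right_label_field <- gx_match_arg(right_label_field, LABEL_FIELDS,
                                    "right_label_field")
  transform <- gx_match_arg(transform, TRANSFORMS, "transform")
  grad <- get_gradient(gradient)  # validates the name
  if (!is.null(vmin) && !is.null(vmax) && vmin >= vmax) {
    gx_validation_error(sprintf(
      "vmin (%g) must be strictly less than vmax (%g)", vmin, vmax
    ))
  }
  structure(
    list(title_header = title_header, title_x = title_x,
         title_y_left = title_y_left, title_y_right = title_y_right,
         gradient = grad$name,
         left_label_field = left_label_field,
         right_label_field = right_label_field,
         transform = transform, vmin = vmin, vmax = vmax,
         na_color = as.integer(na_color)),
    class = "gx_heatmap_spec"
  )
}

result_values <- function(table) {
  samples <- attr(table, "samples")
  if (is.null(samples)) {
    fixed <- c("gene_symbol", "ensembl_id", "mean_transcript_length",
               "diseases")
    samples <- setdiff(names(table), fixed)
  }
  v <- as.matrix(table[, samples, drop = FALSE])
  rownames(v) <- table$ensembl_id
  v
}

row_labels_for <- function(table, field) {
  switch(field,
    gene_symbol = table$gene_symbol,
    ensembl_id = table$ensembl_id,
    diseases = vapply(table$diseases, paste, character(1L), collapse = "; "),
    none = rep("", nrow(table))
  )
}

apply_transform <- function(v, transform) {
  if (transform == "log10_plus1") log10(pmax(v, 0) + 1) else v
}

#' Lay out an annotated result table as a colored grid
#'
#' Applies the spec's transform, resolves the color range (auto-ranging to
#' the transformed matrix extremes unless fixed), maps every cell through the
#' gradient and attaches row/column labels and titles. Rows keep the result
#' table's deterministic ordering. An empty table yields an empty grid that
#' [render_image()] turns into an annotated "no genes" canvas.
#'
#' @param table A `gx_result` from [annotate_result()].
#' @param spec A `gx_heatmap_spec`.
#' @return An object of class `gx_heatmap_grid`: `cell_colors` (rows x cols
#'   x 3 integer array), `row_labels_left`, `row_labels_right`, `col_labels`,
#'   `titles`, `vmin`, `vmax`, `gradient`.
#' @export
layout_heatmap <- function(table, spec) {
  stopifnot(inherits(spec, "gx_heatmap_spec"))
  v <- apply_transform(result_values(table), spec$transform)
  nr <- nrow(v); nc <- ncol(v)

  finite <- v[is.finite(v)]
  vmin <- spec$vmin %||% if (length(finite)) min(finite) else 0
  vmax <- spec$vmax %||% if (length(finite)) max(finite) else 1
  if (vmin >= vmax) vmax <- vmin + 1  # constant matrix: degenerate auto-range

  grad <- get_gradient(spec$gradient)
  cols <- array(0L, dim = c(nr, nc, 3L))
  if (nr > 0L && nc > 0L) {
    flat <- as.vector(v)
    rgb <- matrix(rep(spec$na_color, each = length(flat)), ncol = 3L)
    ok <- is.finite(flat)
    if (any(ok)) rgb[ok, ] <- map_value_to_color(flat[ok], vmin, vmax, grad)
    for (k in 1:3) cols[, , k] <- matrix(rgb[, k], nrow = nr, ncol = nc)
  }

  structure(
    list(
      cell_colors = cols,
      row_labels_left = row_labels_for(table, spec$left_label_field),
      row_labels_right = row_labels_for(table, spec$right_label_field),
      col_labels = colnames(v) %||% character(0),
      titles = list(header = spec$title_header, x = spec$title_x,
                    y_left = spec$title_y_left, y_right = spec$title_y_right),
      vmin = vmin, vmax = vmax, gradient = spec$gradient
    ),
    class = "gx_heatmap_grid"
  )
}

#' @export
print.gx_heatmap_grid <- function(x, ...) {
  d <- dim(x$cell_colors)
  cat(sprintf("<gx_heatmap_grid> %d x %d cells, gradient %s, range [%g, %g]\n",
              d[[1L]], d[[2L]], x$gradient, x$vmin, x$vmax))
  invisible(x)
}

# Auto margins sized from label/title pixel extents (7 px text + 4 px pad).
auto_margins <- function(grid) {
  pad <- 4L
  text_h <- 7L
  w_left <- max(c(0L, vapply(grid$row_labels_left, text_pixel_width,
                             integer(1L))))
  w_right <- max(c(0L, vapply(grid$row_labels_right, text_pixel_width,
                              integer(1L))))
  h_cols <- max(c(0L, vapply(grid$col_labels, text_pixel_width, integer(1L))))
  list(
    top = if (nzchar(grid$titles$header)) text_h + 2L * pad else pad,
    bottom = pad + (if (h_cols > 0L) h_cols + pad else 0L) +
      (if (nzchar(grid$titles$x)) text_h + pad else 0L),
    left = pad + (if (w_left > 0L) w_left + pad else 0L) +
      (if (nzchar(grid$titles$y_left)) text_h + pad else 0L),
    right = pad + (if (w_right > 0L) w_right + pad else 0L) +
      (if (nzchar(grid$titles$y_right)) text_h + pad else 0L)
  )
}

#' Render a heat-map grid to a raster file
#'
#' Composes the pixel raster directly (cells, labels and titles drawn with an
#' embedded bitmap font) and writes it as PNG (fixed compression settings) or
#' uncompressed TIFF. Rendering is fully deterministic: identical inputs give
#' byte-identical PNG output. The raster's data region is exactly
#' `rows x cell_size` by `cols x cell_size` pixels, placed inside the
#' label/title margins.
#'
#' @param grid A `gx_heatmap_grid`.
#' @param path Output file path.
#' @param format `"png"` or `"tiff"`.
#' @param cell_size Cell edge length in pixels (default 12).
#' @param dpi Raster resolution metadata (default 72).
#' @param margins `NULL` (default) sizes margins automatically from labels
#'   and titles; or a list with `top`, `bottom`, `left`, `right` pixel counts
#'   (zeros give a bare data region).
#' @return `path`, invisibly.
#' @export
render_image <- function(grid, path, format = "png", cell_size = 12L,
                         dpi = 72, margins = NULL) {
  stopifnot(inherits(grid, "gx_heatmap_grid"))
  format <- gx_match_arg(format, c("png", "tiff"), "format")
  d <- dim(grid$cell_colors)
  nr <- d[[1L]]; nc <- d[[2L]]

  if (nr == 0L || nc == 0L) {
    canvas <- array(255, dim = c(24L, 120L, 3L))
    canvas <- draw_text(canvas, "NO GENES RETAINED", 9L, 8L)
    return(write_raster(canvas, path, format, dpi))
  }

  m <- margins %||% auto_margins(grid)
  for (side in c("top", "bottom", "left", "right")) {
    if (is.null(m[[side]]) || m[[side]] < 0) {
      gx_validation_error("margins must provide non-negative top/bottom/left/right")
    }
  }
  h <- nr * cell_size + m$top + m$bottom
  w <- nc * cell_size + m$left + m$right
  canvas <- array(255, dim = c(h, w, 3L))

  # cell blocks
  for (k in 1:3) {
    block <- grid$cell_colors[, , k, drop = FALSE]
    dim(block) <- c(nr, nc)
    expanded <- block[rep(seq_len(nr), each = cell_size),
                      rep(seq_len(nc), each = cell_size), drop = FALSE]
    canvas[(m$top + 1L):(m$top + nr * cell_size),
           (m$left + 1L):(m$left + nc * cell_size), k] <- expanded
  }

  pad <- 4L
  if (nzchar(grid$titles$header) && m$top >= 7L) {
    canvas <- draw_text(canvas, grid$titles$header,
                        row = max(1L, (m$top - 7L) %/% 2L + 1L), col = m$left + 1L)
  }
  if (m$left > 10L || m$right > 10L) {
    for (i in seq_len(nr)) {
      yc <- m$top + (i - 1L) * cell_size + max(1L, (cell_size - 7L) %/% 2L + 1L)
      lab <- grid$row_labels_left[[i]]
      if (nzchar(lab)) {
        x0 <- m$left - pad - text_pixel_width(lab) + 1L
        canvas <- draw_text(canvas, lab, yc, max(1L, x0))
      }
      lab <- grid$row_labels_right[[i]]
      if (nzchar(lab)) {
        canvas <- draw_text(canvas, lab, yc, m$left + nc * cell_size + pad + 1L)
      }
    }
  }
  if (m$bottom > 10L) {
    for (j in seq_len(nc)) {
      lab <- grid$col_labels[[j]]
      if (nzchar(lab)) {
        xc <- m$left + (j - 1L) * cell_size + max(1L, (cell_size - 7L) %/% 2L + 1L)
        canvas <- draw_text(canvas, lab, m$top + nr * cell_size + pad + 1L, xc,
                            rotate = TRUE)
      }
    }
    if (nzchar(grid$titles$x)) {
      canvas <- draw_text(canvas, grid$titles$x, h - 7L - pad + 1L, m$left + 1L)
    }
  }
  if (nzchar(grid$titles$y_left) && m$left >= 7L + pad) {
    canvas <- draw_text(canvas, grid$titles$y_left, m$top + 1L, pad %/% 2L + 1L,
                        rotate = TRUE)
  }
  if (nzchar(grid$titles$y_right) && m$right >= 7L + pad) {
    canvas <- draw_text(canvas, grid$titles$y_right, m$top + 1L,
                        w - 7L - pad %/% 2L, rotate = TRUE)
  }

  write_raster(canvas, path, format, dpi)
}

write_raster <- function(canvas, path, format, dpi) {
  img <- canvas / 255
  if (format == "png") {
    png::writePNG(img, target = path, dpi = dpi)
  } else {
    tiff::writeTIFF(img, where = path, compression = "none")
  }
  invisible(path)
}

#' Export an annotated result table to CSV
#'
#' Writes `gene_symbol,ensembl_id,<one column per sample>,
#' mean_transcript_length,diseases` (RFC 4180 quoting; disease terms joined
#' with `"; "`), preserving the table's row order. [read_result_csv()]
#' reproduces all values at the full written precision.
#'
#' @param table A `gx_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(table, path) {
  flat <- tibble::as_tibble(table)
  flat$diseases <- vapply(table$diseases, paste, character(1L),
                          collapse = "; ")
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' Re-import a result CSV written by [export_csv()]
#'
#' @param path CSV path.
#' @return A `gx_result` tibble (diseases split back into sorted character
#'   vectors).
#' @export
read_result_csv <- function(path) {
  if (!file.exists(path)) gx_io_error(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    gene_symbol = "c", ensembl_id = "c", diseases = "c", .default = "d"
  ), progress = FALSE)
  fixed <- c("gene_symbol", "ensembl_id", "mean_transcript_length", "diseases")
  missing <- setdiff(fixed, names(raw))
  if (length(missing) > 0L) {
    gx_format_error(sprintf(
      "missing required column%s %s in %s",
      if (length(missing) > 1L) "s" else "",
      paste(sQuote(missing), collapse = ", "), path
    ))
  }
  samples <- setdiff(names(raw), fixed)
  raw$diseases <- lapply(raw$diseases, function(x) {
    if (is.na(x) || !nzchar(x)) character(0)
    else strsplit(x, "; ", fixed = TRUE)[[1L]]
  })
  structure(raw, class = c("gx_result", class(raw)), samples = samples)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
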