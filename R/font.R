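# Minimal embedded 5x7 bitmap font (classic LCD glyph shapes) for titles and
# axis labels on rendered heat maps. Each glyph is 5 column bytes; bit k of a
# column byte is row k from the top. Lowercase letters render as uppercase;
# unmapped characters render as a hollow box. Using an embedded font (rather
# than a graphics device) keeps raster output byte-identical across runs and
# platforms.

FONT5X7 <- list(
  " " = c(0x00, 0x00, 0x00, 0x00, 0x00),
  "!" = c(0x00, 0x00, 0x5F, 0x00, 0x00),
  "'" = c(0x00, 0x05, 0x03, 0x00, 0x00),
  "(" = c(0x00, 0x1C, 0x22, 0x41, 0x00),
  ")" = c(0x00, 0x41, 0x22, 0x1C, 0x00),
  "+" = c(0x08, 0x08, 0x3E, 0x08, 0x08),
  "," = c(0x00, 0x50, 0x30, 0x00, 0x00),
  "-" = c(0x08, 0x08, 0x08, 0x08, 0x08),
  "." = c(0x00, 0x60, 0x60, 0x00, 0x00),
  "/" = c(0x20, 0x10, 0x08, 0x04, 0x02),
  "0" = c(0x3E, 0x51, 0x49, 0x45, 0x3E),
  "1" = c(0x00, 0x42, 0x7F, 0x40, 0x00),
  "2" = c(0x42, 0x61, 0x51, 0x49, 0x46),
  "3" = c(0x21, 0x41, 0x45, 0x4B, 0x31),
  "4" = c(0x18, 0x14, 0x12, 0x7F, 0x10),
  "5" = c(0x27, 0x45, 0x45, 0x45, 0x39),
  "6" = c(0x3C, 0x4A, 0x49, 0x49, 0x30),
  "7" = c(0x01, 0x71, 0x09, 0x05, 0x03),
  "8" = c(0x36, 0x49, 0x49, 0x49, 0x36),
  "9" = c(0x06, 0x49, 0x49, 0x29, 0x1E),
  ":" = c(0x00, 0x36, 0x36, 0x00, 0x00),
  ";" = c(0x00, 0x56, 0x36, 0x00, 0x00),
  "=" = c(0x14, 0x14, 0x14, 0x14, 0x14),
  "?" = c(0x02, 0x01, 0x51, 0x09, 0x06),
  "%" = c(0x23, 0x13, 0x08, 0x64, 0x62),
  "_" = c(0x40, 0x40, 0x40, 0x40, 0x40),
  "A" = c(0x7E, 0x11, 0x11, 0x11, 0x7E),
  "B" = c(0x7F, 0x49, 0x49, 0x49, 0x36),
  "C" = c(0x3E, 0x41, 0x41, 0x41, 0x22),
  "D" = c(0x7F, 0x41, 0x41, 0x22, 0x1C),
  "E" = c(0x7F, 0x49, 0x49, 0x49, 0x41),
  "F" = c(0x7F, 0x09, 0x09, 0x09, 0x01),
  "G" = c(0x3E, 0x41, 0x49, 0x49, 0x7A),
  "H" = c(0x7F, 0x08, 0x08, 0x08, 0x7F),
  "I" = c(0x00, 0x41, 0x7F, 0x41, 0x00),
  "J" = c(0x20, 0x40, 0x41, 0x3F, 0x01),
  "K" = c(0x7F, 0x08, 0x14, 0x22, 0x41),
  "L" = c(0x7F, 0x40, 0x40, 0x40, 0x40),
  "M" = c(0x7F, 0x02, 0x0C, 0x02, 0x7F),
  "N" = c(0x7F, 0x04, 0x08, 0x10, 0x7F),
  "O" = c(0x3E, 0x41, 0x41, 0x41, 0x3E),
  "P" = c(0x7F, 0x09, 0x09, 0x09, 0x06),
  "Q" = c(0x3E, 0x41, 0x51, 0x21, 0x5E),
  "R" = c(0x7F, 0x09, 0x19, 0x29, 0x46),
  "S" = c(0x46, 0x49, 0x49, 0x49, 0x31),
  "T" = c(0x01, 0x01, 0x7F, 0x01, 0x01),
  "U" = c(0x3F, 0x40, 0x40, 0x40, 0x3F),
  "V" = c(0x1F, 0x20, 0x40, 0x20, 0x1F),
  "W" = c(0x3F, 0x40, 0x38, 0x40, 0x3F),
  "X" = c(0x63, 0x14, 0x08, 0x14, 0x63),
  "Y" = c(0x07, 0x08, 0x70, 0x08, 0x07),
  "Z" = c(0x61, 0x51, 0x49, 0x45, 0x43)
)

FONT_FALLBACK <- c(0x7F, 0x41, 0x41, 0x41, 0x7F)

glyph_matrix <- function(ch) {
  cols <- FONT5X7[[toupper(ch)]]
  if (is.null(cols)) cols <- FONT_FALLBACK
  m <- matrix(0L, nrow = 7L, ncol = 5L)
  for (j in 1:5) {
    m[, j] <- as.integer(bitwAnd(cols[[j]], bitwShiftL(1L, 0:6)) > 0L)
  }
  m
}

# Binary pixel matrix for a text string: 7 rows, 6 columns per character
# (5 glyph columns + 1 spacing column, no trailing space).
text_bitmap <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) return(matrix(0L, nrow = 7L, ncol = 0L))
  parts <- lapply(chars, function(ch) {
    cbind(glyph_matrix(ch), matrix(0L, nrow = 7L, ncol = 1L))
  })
  m <- do.call(cbind, parts)
  m[, seq_len(ncol(m) - 1L), drop = FALSE]
}

text_pixel_width <- function(text) {
  n <- nchar(text)
  if (n == 0L) 0L else 6L * n - 1L
}

# Blit a binary bitmap onto an h x w x 3 canvas (values 0-255) at (row, col),
# 1-indexed top-left, in the given RGB color. Out-of-canvas pixels clipped.
blit_bitmap <- function(canvas, bitmap, row, col, color) {
  if (ncol(bitmap) == 0L) return(canvas)
  h <- dim(canvas)[[1L]]; w <- dim(canvas)[[2L]]
  px <- which(bitmap == 1L, arr.ind = TRUE)
  if (nrow(px) == 0L) return(canvas)
  rr <- row + px[, 1L] - 1L
  cc <- col + px[, 2L] - 1L
  ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
  rr <- rr[ok]; cc <- cc[ok]
  for (k in 1:3) canvas[cbind(rr, cc, k)] <- color[[k]]
  canvas
}

draw_text <- function(canvas, text, row, col, color = c(0L, 0L, 0L),
                      rotate = FALSE) {
  bm <- text_bitmap(text)
  if (rotate) {
    # rotate 90 degrees counter-clockwise: text reads bottom-to-top
    bm <- t(bm)[rev(seq_len(ncol(bm))), , drop = FALSE]
  }
  blit_bitmap(canvas, bm, row, col, color)
}
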