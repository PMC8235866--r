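test_that("gradient registry ships at least 28 validated gradients", {
  nms <- list_gradients()
  expect_gte(length(nms), 28L)
  for (nm in nms) {
    g <- get_gradient(nm)
    expect_gte(nrow(g$anchors), 2L)
    expect_true(all(g$anchors >= 0L & g$anchors <= 255L))
  }
  expect_error(get_gradient("no_such_gradient"),
               class = "gx_validation_error")
})

test_that("user gradients register and validate", {
  g <- register_gradient("test_two_tone", rbind(c(10, 20, 30), c(200, 100, 0)))
  expect_true("test_two_tone" %in% list_gradients())
  expect_equal(unname(g$anchors[1L, ]), c(10L, 20L, 30L))
  expect_error(register_gradient("bad", rbind(c(-1, 0, 0), c(0, 0, 0))),
               class = "gx_validation_error")
  expect_error(register_gradient("bad", rbind(c(1, 2, 3))),
               class = "gx_validation_error")
})

test_that("value-to-color mapping hits anchors exactly and rounds half-up", {
  grad <- get_gradient("grayscale")
  expect_equal(unname(map_value_to_color(0, 0, 1, grad)[1L, ]), c(0L, 0L, 0L))
  expect_equal(unname(map_value_to_color(1, 0, 1, grad)[1L, ]),
               c(255L, 255L, 255L))
  # midpoint: 0.5 * 255 = 127.5 rounds half-up to 128
  expect_equal(unname(map_value_to_color(0.5, 0, 1, grad)[1L, ]),
               c(128L, 128L, 128L))
  # out-of-range values clamp to the endpoints
  expect_equal(map_value_to_color(-10, 0, 1, grad),
               map_value_to_color(0, 0, 1, grad))
  expect_equal(map_value_to_color(99, 0, 1, grad),
               map_value_to_color(1, 0, 1, grad))
  # multi-anchor endpoints
  fire <- get_gradient("fire")
  expect_equal(unname(map_value_to_color(c(0, 1), 0, 1, fire)),
               rbind(unname(fire$anchors[1L, ]),
                     unname(fire$anchors[nrow(fire$anchors), ])))
  expect_error(map_value_to_color(0.5, 1, 1, grad),
               class = "gx_validation_error")
})

test_that("monotone gradients give per-channel monotone colors", {
  withr::local_seed(41)
  grad <- get_gradient("grayscale")
  vals <- sort(stats::runif(50L, 0, 100))
  cols <- map_value_to_color(vals, 0, 100, grad)
  for (k in 1:3) expect_true(all(diff(cols[, k]) >= 0L))
})

small_result <- function() {
  ds <- tiny_dataset()
  ann <- tiny_annotation()
  m <- build_matrix(ds, query_spec(samples = c("A", "B")))
  annotate_result(m, ann, ds)
}

test_that("layout maps transformed values and populates labels", {
  tab <- small_result()
  spec <- heatmap_spec(gradient = "grayscale")
  grid <- layout_heatmap(tab, spec)
  expect_equal(dim(grid$cell_colors), c(3L, 2L, 3L))
  # auto range: max cell (120) gets the last anchor color
  expect_equal(grid$cell_colors[1L, 1L, ], c(255L, 255L, 255L))
  expect_equal(grid$row_labels_left, tab$gene_symbol)
  expect_equal(grid$col_labels, c("A", "B"))

  # log10_plus1 with fixed range: value 99 -> log10(100)/2 = 1 -> last color
  spec_log <- heatmap_spec(gradient = "grayscale", transform = "log10_plus1",
                           vmin = 0, vmax = 2)
  v <- tab
  v$A <- c(99, 0, 0); v$B <- c(99, 0, 0)
  grid_log <- layout_heatmap(v, spec_log)
  expect_equal(grid_log$cell_colors[1L, 1L, ], c(255L, 255L, 255L))
  expect_equal(grid_log$cell_colors[2L, 1L, ], c(0L, 0L, 0L))
})

test_that("swapping label fields changes labels, never colors", {
  tab <- small_result()
  g1 <- layout_heatmap(tab, heatmap_spec(left_label_field = "gene_symbol",
                                         right_label_field = "diseases"))
  g2 <- layout_heatmap(tab, heatmap_spec(left_label_field = "diseases",
                                         right_label_field = "gene_symbol"))
  expect_identical(g1$cell_colors, g2$cell_colors)
  expect_equal(g1$row_labels_left, g2$row_labels_right)
  expect_equal(g1$row_labels_right, g2$row_labels_left)
  expect_equal(g1$row_labels_right[[1L]], "Alzheimer's disease; arthritis")
})

test_that("log transform changes colors but never membership or order", {
  tab <- small_result()
  lin <- layout_heatmap(tab, heatmap_spec())
  log <- layout_heatmap(tab, heatmap_spec(transform = "log10_plus1"))
  expect_equal(dim(lin$cell_colors), dim(log$cell_colors))
  expect_equal(lin$row_labels_left, log$row_labels_left)
})

test_that("rendered rasters have the contracted dimensions", {
  tab <- small_result()
  grid <- layout_heatmap(tab, heatmap_spec())
  p <- withr::local_tempfile(fileext = ".png")
  zero <- list(top = 0L, bottom = 0L, left = 0L, right = 0L)
  render_image(grid, p, format = "png", cell_size = 10L, margins = zero)
  img <- png::readPNG(p)
  expect_equal(dim(img)[1:2], c(3L * 10L, 2L * 10L))

  m <- list(top = 20L, bottom = 30L, left = 40L, right = 50L)
  render_image(grid, p, format = "png", cell_size = 8L, margins = m)
  img <- png::readPNG(p)
  expect_equal(dim(img)[1:2], c(3L * 8L + 50L, 2L * 8L + 90L))

  expect_error(render_image(grid, p, format = "bmp"),
               class = "gx_validation_error")
})

test_that("PNG rendering is byte-stable and TIFF agrees pixel-for-pixel", {
  tab <- small_result()
  grid <- layout_heatmap(tab, heatmap_spec(title_header = "Cohort TPM"))
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  render_image(grid, p1)
  render_image(grid, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  pt <- withr::local_tempfile(fileext = ".tiff")
  render_image(grid, pt, format = "tiff")
  expect_equal(round(tiff::readTIFF(pt) * 255),
               round(png::readPNG(p1) * 255))
})

test_that("cell-center pixels read back as the grid colors", {
  withr::local_seed(47)
  for (rep in 1:10) {
    m <- random_matrix(sample(2:8, 1L), sample(2:6, 1L))
    tab <- annotate_result(m, gexmap:::new_gx_annotation(tibble::tibble(
      gene_symbol = character(), ensembl_id = character(),
      category = character(), disease = character()
    )), gexmap:::new_gx_dataset(
      samples = colnames(m$values), genes = rownames(m$values),
      records = tibble::tibble(
        sample_id = character(), gene_id = character(), length = double(),
        effective_length = double(), expected_count = double(),
        tpm = double(), fpkm = double()
      )
    ))
    grad <- sample(list_gradients(), 1L)
    grid <- layout_heatmap(tab, heatmap_spec(gradient = grad))
    p <- withr::local_tempfile(fileext = ".png")
    cs <- 9L
    zero <- list(top = 0L, bottom = 0L, left = 0L, right = 0L)
    render_image(grid, p, cell_size = cs, margins = zero)
    img <- round(png::readPNG(p) * 255)
    nr <- dim(grid$cell_colors)[[1L]]; nc <- dim(grid$cell_colors)[[2L]]
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        px <- img[(i - 1L) * cs + 5L, (j - 1L) * cs + 5L, ]
        expect_equal(unname(px), grid$cell_colors[i, j, ])
      }
    }
  }
})

test_that("empty tables render an annotated placeholder canvas", {
  ds <- tiny_dataset()
  ann <- tiny_annotation()
  m <- apply_threshold(build_matrix(ds, query_spec(samples = c("A", "B"))),
                       1e9)
  tab <- annotate_result(m, ann, ds)
  grid <- layout_heatmap(tab, heatmap_spec())
  p <- withr::local_tempfile(fileext = ".png")
  render_image(grid, p)
  expect_true(file.exists(p) && file.size(p) > 0)
})

test_that("result CSV export round-trips values, order and diseases", {
  tab <- small_result()
  p <- withr::local_tempfile(fileext = ".csv")
  export_csv(tab, p)
  lines <- readLines(p)
  expect_equal(lines[[1L]],
               "gene_symbol,ensembl_id,A,B,mean_transcript_length,diseases")
  expect_equal(length(lines), 4L)

  t2 <- read_result_csv(p)
  expect_equal(t2$ensembl_id, tab$ensembl_id)
  expect_equal(t2$gene_symbol, tab$gene_symbol)
  expect_equal(as.matrix(t2[, c("A", "B")]), as.matrix(tab[, c("A", "B")]))
  expect_true(all(mapply(identical, t2$diseases, tab$diseases)))

  # empty table -> header-only file
  empty <- tab[0, ]
  attr(empty, "samples") <- attr(tab, "samples")
  export_csv(empty, p)
  expect_equal(length(readLines(p)), 1L)
})
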