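align_toy <- function(nr, nc, keep = NULL, seed = 1) {
  cat <- load_template(write_toy_catalog(nr, nc))
  ids <- cat$variables$variable_id
  keep <- keep %||% ids
  al <- suppressWarnings(align_results(cat, toy_results(keep, seed = seed)))
  list(cat = cat, al = al)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("one circle per unmasked cell, none per masked cell", {
  tc <- align_toy(2, 3)
  sc <- make_scales(c(-1, 1), c(1, 10), cap = 35)
  pan <- render_bubble_grid(tc$al$grids[[1]], sc)
  expect_identical(nrow(pan$circles), 6L)

  ids <- tc$cat$variables$variable_id
  tc2 <- align_toy(2, 3, keep = ids[1:4])
  pan2 <- render_bubble_grid(tc2$al$grids[[1]], sc)
  expect_identical(nrow(pan2$circles), 4L)
  # masked cells can optionally show a small grey dot
  pan3 <- render_bubble_grid(tc2$al$grids[[1]], sc,
                             style = bubble_style(na_dot = TRUE))
  expect_identical(nrow(pan3$circles), 6L)
})

test_that("a zero score still draws a visible bubble of radius rmin", {
  tc <- align_toy(1, 1)
  al <- tc$al
  al$grids[[1]]$size[1, 1] <- 0
  sc <- make_scales(1, 10, cap = 35, rmin = 0.1, rmax = 0.4)
  pan <- render_bubble_grid(al$grids[[1]], sc)
  expect_equal(pan$circles$r, 0.1)
})

test_that("degenerate grids and overlapping bubbles are rejected", {
  g <- structure(list(name = "empty", row_labels = character(),
                      col_labels = character(),
                      cells = matrix(character(), 0, 0)),
                 class = "template_grid")
  empty <- structure(list(grid = g, color = matrix(numeric(), 0, 0),
                          size = matrix(numeric(), 0, 0),
                          mask = matrix(logical(), 0, 0)),
                     class = "aligned_grid")
  sc <- make_scales(1, 1, cap = 10)
  expect_error(render_bubble_grid(empty, sc), "zero-dimension")
  tc <- align_toy(2, 2)
  expect_error(render_bubble_grid(tc$al$grids[[1]], sc,
                                  style = bubble_style(pitch = 0.5)),
               "overlap")
})

test_that("rendering is deterministic for identical inputs", {
  tc <- align_toy(3, 4)
  sc <- make_scales(c(-1, 1), c(1, 20), cap = 35)
  expect_identical(render_bubble_grid(tc$al$grids[[1]], sc),
                   render_bubble_grid(tc$al$grids[[1]], sc))
})

test_that("brackets add one polyline and a label outside the data region", {
  tc <- align_toy(4, 12)
  sc <- make_scales(c(-1, 1), c(1, 20), cap = 35)
  pan <- render_bubble_grid(tc$al$grids[[1]], sc)
  n_poly <- length(pan$polylines); n_text <- nrow(pan$texts)
  b <- add_bracket(pan, cols = c(1, 5), label = "exposure block")
  expect_identical(length(b$polylines), n_poly + 1L)
  expect_identical(nrow(b$texts), n_text + 1L)
  # original primitives untouched
  expect_identical(b$circles, pan$circles)
  expect_identical(b$texts[seq_len(n_text), ], pan$texts)

  # left-side row bracket: label sits left of the row labels
  bl <- add_bracket(pan, rows = c(2, 3), label = "rows", side = "left")
  lab <- bl$texts[nrow(bl$texts), ]
  rowlab_x <- min(pan$texts$x[pan$texts$anchor == "end"])
  expect_lt(lab$x, rowlab_x)

  expect_error(add_bracket(pan, cols = c(1, 100), label = "x"),
               "outside grid extent")
  expect_error(add_bracket(pan, rows = c(1, 2), cols = c(1, 2), label = "x"),
               "exactly one")
})

test_that("legends show the cap annotation and symmetric colour ticks", {
  sc <- make_scales(c(-2, 2), c(1, 60), cap = 35)
  leg <- render_legends(sc)
  expect_true(any(grepl("35 \\(capped\\)", leg$texts$label)))
  expect_true(any(leg$texts$label == "0"))      # midpoint swatch tick
  expect_gt(nrow(leg$rects), 10)                # colour ramp swatches
  expect_identical(nrow(leg$circles),
                   length(legend_ticks(sc$size, 4)))

  # no cap: reference bubbles span up to the observed maximum
  sc2 <- make_scales(1, c(0.5, 7.3))
  leg2 <- render_legends(sc2)
  expect_true(any(grepl("^7\\.3$", leg2$texts$label)))
  expect_false(any(grepl("capped", leg2$texts$label)))
})

test_that("compose_figure translates panels and rejects overlaps", {
  tc <- align_toy(2, 2)
  sc <- make_scales(c(-1, 1), c(1, 20), cap = 35)
  pan <- render_bubble_grid(tc$al$grids[[1]], sc)
  w <- pan$bbox[3] - pan$bbox[1]; h <- pan$bbox[4] - pan$bbox[2]

  fig <- compose_figure(list(pan), data.frame(x = 0, y = 0))
  expect_equal(fig$bbox[3:4], c(w + 0.5, h + 0.5))
  expect_identical(nrow(fig$circles), nrow(pan$circles))

  fig2 <- compose_figure(list(pan, pan),
                         data.frame(x = c(0, w + 1), y = c(0, 0)))
  expect_identical(nrow(fig2$circles), 2L * nrow(pan$circles))
  expect_error(compose_figure(list(pan, pan),
                              data.frame(x = c(0, 0.5), y = c(0, 0.5))),
               "overlap")
})

test_that("the one-step NH figure contains all panels and the footnote", {
  res <- generate_results("nh225", seed = 1)
  fig <- metab_figure(res, "nh225", cap = 35)
  expect_identical(fig$meta$n_panels, 11L)  # 10 grids + legend
  expect_equal(nrow(fig$circles),
               225 + length(legend_ticks(make_scales(1, 1, cap = 35)$size, 4)))
  expect_true(any(grepl("Ratios are to total fatty acids",
                        fig$texts$label)))
  rep <- attr(fig, "report")
  expect_equal(rep$n_matched, 225)
  expect_error(metab_figure(res[0, ], "nh225"), "non-empty")
})

test_that("the main block is the largest panel region", {
  cat <- load_template("nh251")
  lay <- cat$layout
  sizes <- vapply(cat$grids, function(g)
    prod(dim(g$cells)), 0)[lay$placements$grid]
  expect_identical(names(which.max(sizes)), "Lipoprotein subclasses")
})

test_that("write_figure produces deterministic SVG and honors formats", {
  res <- generate_results("nh225", seed = 1)
  fig <- metab_figure(res, "nh225", cap = 35)
  f1 <- tempfile(fileext = ".svg"); f2 <- tempfile(fileext = ".svg")
  write_figure(fig, f1)
  write_figure(fig, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_error(write_figure(fig, tempfile(fileext = ".tiff")),
               "unknown format")

  fp <- tempfile(fileext = ".pdf")
  write_figure(fig, fp)
  expect_gt(file.size(fp), 0)

  p72 <- tempfile(fileext = ".png"); p144 <- tempfile(fileext = ".png")
  write_figure(fig, p72, dpi = 72)
  write_figure(fig, p144, dpi = 144)
  d72 <- dim(png::readPNG(p72)); d144 <- dim(png::readPNG(p144))
  # doubling dpi doubles pixel dimensions (up to device rounding)
  expect_true(all(abs(d144[1:2] - 2L * d72[1:2]) <= 1L))
})
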