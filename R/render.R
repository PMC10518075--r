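#' Style options for panel rendering
#'
#' Geometry and typography knobs shared by every panel of a figure. All
#' lengths are in abstract canvas units; one unit is one grid cell pitch
#' by default and maps to `unit_px` pixels in SVG output (at the 96 dpi
#' reference used for PDF/PNG sizing).
#'
#' @param pitch Cell-centre spacing. Must be at least twice the size
#'   scale's `rmax` so bubbles never overlap neighbouring cells (checked
#'   at render time).
#' @param font,title_font Label and title font sizes (units).
#' @param char_w Estimated glyph width as a fraction of the font size;
#'   used to size label margins deterministically without font metrics.
#' @param label_gap Gap between labels and the data region.
#' @param max_label Labels longer than this many characters are
#'   ellipsized rather than shrinking the cell pitch.
#' @param unit_px Pixels per unit in SVG output.
#' @param na_dot Draw a small grey dot in masked (missing) cells instead
#'   of leaving them blank.
#' @param na_dot_col Colour of that dot.
#' @return A list of class `bubble_style`.
#' @export
bubble_style <- function(pitch = 1, font = 0.32, title_font = 0.38,
                         char_w = 0.52, label_gap = 0.25, max_label = 38,
                         unit_px = 24, na_dot = FALSE,
                         na_dot_col = "#C8C8C8") {
  structure(list(pitch = pitch, font = font, title_font = title_font,
                 char_w = char_w, label_gap = label_gap,
                 max_label = max_label, unit_px = unit_px,
                 na_dot = na_dot, na_dot_col = na_dot_col),
            class = "bubble_style")
}

ellipsize <- function(x, n) {
  long <- !is.na(x) & nchar(x) > n
  x[long] <- paste0(substr(x[long], 1, n - 3), "...")
  x
}

text_w <- function(labels, style, font = style$font) {
  if (!length(labels)) return(0)
  max(nchar(ellipsize(labels, style$max_label))) * style$char_w * font
}

empty_panel <- function() {
  structure(list(
    circles = data.frame(x = numeric(), y = numeric(), r = numeric(),
                         fill = character(), stringsAsFactors = FALSE),
    rects = data.frame(x = numeric(), y = numeric(), w = numeric(),
                       h = numeric(), fill = character(),
                       stringsAsFactors = FALSE),
    texts = data.frame(x = numeric(), y = numeric(), label = character(),
                       size = numeric(), angle = numeric(),
                       anchor = character(), stringsAsFactors = FALSE),
    polylines = list(),
    bbox = c(0, 0, 0, 0), meta = list()), class = "bubble_panel")
}

#' @export
print.bubble_panel <- function(x, ...) {
  cat(sprintf("<bubble_panel: %d circles, %d texts, %d polylines, %d rects; bbox [%.1f, %.1f] - [%.1f, %.1f]>\n",
              nrow(x$circles), nrow(x$texts), length(x$polylines),
              nrow(x$rects), x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4]))
  invisible(x)
}

## Footprint of a rendered grid panel without rendering it; used both by
## render_bubble_grid() and by layout authoring so placements stay valid.
panel_extent <- function(grid, style = bubble_style(), title = grid$name) {
  left <- style$label_gap + text_w(grid$row_labels, style) + 0.1
  top <- style$label_gap + text_w(grid$col_labels, style) +
    (if (nzchar(title %||% "")) style$title_font * 1.8 else 0.2)
  title_w <- text_w(title %||% "", style, style$title_font) + 0.2
  c(width = max(left + length(grid$col_labels) * style$pitch + 0.15,
                title_w),
    height = top + length(grid$row_labels) * style$pitch + 0.15,
    left = left, top = top)
}

#' Render one aligned grid as a bubble panel
#'
#' Draws one filled circle per unmasked cell, centred on the cell, with
#' radius from the size scale and fill from the colour scale; row labels
#' sit to the left and column labels (rotated vertical) on top. Output is
#' a plain list of drawing primitives, deterministic for identical
#' inputs.
#'
#' @param data An `aligned_grid` (one element of
#'   `align_results()$grids`).
#' @param scales A `bubble_scales` pair from [make_scales()].
#' @param style A [bubble_style()].
#' @param title Panel title; defaults to the grid name. `""` suppresses.
#' @return A `bubble_panel`.
#' @export
render_bubble_grid <- function(data, scales, style = bubble_style(),
                               title = NULL) {
  stopifnot(inherits(data, "aligned_grid"),
            inherits(scales, "bubble_scales"))
  g <- data$grid
  nr <- nrow(g$cells); nc <- ncol(g$cells)
  if (nr == 0 || nc == 0) bg_stop("cannot render a zero-dimension grid")
  if (style$pitch < 2 * scales$size$rmax)
    bg_stop(sprintf("cell pitch %.3g < 2 * rmax %.3g: bubbles would overlap",
                    style$pitch, scales$size$rmax))
  title <- title %||% g$name
  ext <- panel_extent(g, style, title)
  left <- ext[["left"]]; top <- ext[["top"]]
  p <- style$pitch
  pan <- empty_panel()

  idx <- which(!data$mask, arr.ind = TRUE)
  if (nrow(idx)) {
    vals_c <- data$color[idx]
    vals_s <- data$size[idx]
    pan$circles <- data.frame(
      x = left + (idx[, 2] - 0.5) * p,
      y = top + (idx[, 1] - 0.5) * p,
      r = map_radius(scales$size, vals_s),
      fill = map_color(scales$color, vals_c),
      stringsAsFactors = FALSE)
  }
  if (style$na_dot) {
    midx <- which(data$mask & nzchar(g$cells), arr.ind = TRUE)
    if (nrow(midx)) {
      pan$circles <- rbind(pan$circles, data.frame(
        x = left + (midx[, 2] - 0.5) * p,
        y = top + (midx[, 1] - 0.5) * p,
        r = 0.04, fill = style$na_dot_col, stringsAsFactors = FALSE))
    }
  }
  rl <- ellipsize(g$row_labels, style$max_label)
  cl <- ellipsize(g$col_labels, style$max_label)
  pan$texts <- rbind(
    data.frame(x = left - style$label_gap,
               y = top + (seq_len(nr) - 0.5) * p,
               label = rl, size = style$font, angle = 0, anchor = "end",
               stringsAsFactors = FALSE),
    data.frame(x = left + (seq_len(nc) - 0.5) * p,
               y = top - style$label_gap,
               label = cl, size = style$font, angle = -90, anchor = "start",
               stringsAsFactors = FALSE))
  if (nzchar(title)) {
    pan$texts <- rbind(pan$texts, data.frame(
      x = 0, y = style$title_font, label = title,
      size = style$title_font, angle = 0, anchor = "start",
      stringsAsFactors = FALSE))
  }
  pan$bbox <- c(0, 0, ext[["width"]], ext[["height"]])
  pan$meta <- list(grid_name = g$name, nrow = nr, ncol = nc,
                   left = left, top = top, pitch = p,
                   footnote = any(nzchar(g$cells) & !data$mask &
                                    cell_footnotes(data)))
  pan
}

## footnote flags are carried on the aligned grid when built through
## align_results on a catalog with footnote-flagged variables
cell_footnotes <- function(data) {
  fn <- attr(data, "footnote_cells")
  if (is.null(fn)) matrix(FALSE, nrow(data$mask), ncol(data$mask)) else fn
}

#' Add a labelled bracket to a panel
#'
#' Draws a square bracket spanning a contiguous run of rows or columns,
#' outside the panel's current contents, with a centred label -- the
#' usual way to flag a subset of a heatmap (e.g. the columns belonging to
#' one exposure). Existing primitives are untouched; the bounding box
#' grows to fit.
#'
#' @param panel A `bubble_panel` produced by [render_bubble_grid()].
#' @param rows,cols Inclusive 1-based index range (length-2 integer
#'   vector) of rows or columns to span; give exactly one of the two.
#' @param label Bracket label text.
#' @param side `"top"`, `"bottom"`, `"left"` or `"right"`; defaults to
#'   `"top"` for column brackets and `"left"` for row brackets.
#' @return The augmented `bubble_panel`.
#' @export
add_bracket <- function(panel, rows = NULL, cols = NULL, label = "",
                        side = NULL) {
  stopifnot(inherits(panel, "bubble_panel"))
  m <- panel$meta
  if (is.null(m$pitch)) bg_stop("panel lacks grid metadata")
  if (is.null(rows) == is.null(cols))
    bg_stop("give exactly one of `rows` or `cols`")
  rng <- sort(as.integer(if (is.null(rows)) cols else rows))
  lim <- if (is.null(rows)) m$ncol else m$nrow
  if (length(rng) != 2 || rng[1] < 1 || rng[2] > lim)
    bg_stop(sprintf("bracket range [%s] outside grid extent 1..%d",
                    paste(rng, collapse = ", "), lim))
  side <- side %||% if (is.null(rows)) "top" else "left"
  side <- match.arg(side, c("top", "bottom", "left", "right"))
  p <- m$pitch; tick <- 0.18; off <- 0.2
  fsize <- 0.3
  if (is.null(rows)) {  # column bracket (horizontal span)
    x0 <- m$left + (rng[1] - 1) * p + 0.08
    x1 <- m$left + rng[2] * p - 0.08
    if (side == "top") {
      y <- panel$bbox[2] - off
      poly <- list(x = c(x0, x0, x1, x1), y = c(y + tick, y, y, y + tick))
      ly <- y - 0.12
    } else {
      y <- panel$bbox[4] + off
      poly <- list(x = c(x0, x0, x1, x1), y = c(y - tick, y, y, y - tick))
      ly <- y + 0.12 + fsize
    }
    lab <- data.frame(x = (x0 + x1) / 2, y = ly, label = label,
                      size = fsize, angle = 0, anchor = "middle",
                      stringsAsFactors = FALSE)
  } else {              # row bracket (vertical span)
    y0 <- m$top + (rng[1] - 1) * p + 0.08
    y1 <- m$top + rng[2] * p - 0.08
    if (side == "left") {
      x <- panel$bbox[1] - off
      poly <- list(x = c(x + tick, x, x, x + tick), y = c(y0, y0, y1, y1))
      lx <- x - 0.12
      ang <- -90
    } else {
      x <- panel$bbox[3] + off
      poly <- list(x = c(x - tick, x, x, x - tick), y = c(y0, y0, y1, y1))
      lx <- x + 0.12
      ang <- 90
    }
    lab <- data.frame(x = lx, y = (y0 + y1) / 2, label = label,
                      size = fsize, angle = ang, anchor = "middle",
                      stringsAsFactors = FALSE)
  }
  panel$polylines <- c(panel$polylines, list(poly))
  if (nzchar(label)) panel$texts <- rbind(panel$texts, lab)
  pad <- off + tick + (if (nzchar(label)) 0.55 else 0.1)
  panel$bbox <- switch(side,
    top = panel$bbox + c(0, -pad, 0, 0),
    bottom = panel$bbox + c(0, 0, 0, pad),
    left = panel$bbox + c(-pad, 0, 0, 0),
    right = panel$bbox + c(0, 0, pad, 0))
  panel
}

#' Render the colour and size legend panel
#'
#' Produces the figure key: a discrete colour-swatch ramp with tick
#' labels for the effect-estimate scale, and a row of reference bubbles
#' at [legend_ticks()] scores for the size scale, the top bubble
#' annotated `"(capped)"` when a cap is active.
#'
#' @param scales A `bubble_scales` pair.
#' @param style A [bubble_style()].
#' @param color_title,size_title Legend headings.
#' @return A `bubble_panel`.
#' @export
render_legends <- function(scales, style = bubble_style(),
                           color_title = "Effect estimate",
                           size_title = "-log10(P)") {
  stopifnot(inherits(scales, "bubble_scales"))
  pan <- empty_panel()
  fs <- style$font
  n_sw <- 48; ramp_w <- 6; sw <- ramp_w / n_sw; ramp_h <- 0.45
  y0 <- style$title_font * 1.6
  vmax <- scales$color$vmax
  mid <- (seq_len(n_sw) - 0.5) / n_sw
  pan$rects <- data.frame(
    x = (seq_len(n_sw) - 1) * sw, y = y0, w = sw * 1.02, h = ramp_h,
    fill = map_color(scales$color, (mid * 2 - 1) * vmax),
    stringsAsFactors = FALSE)
  ct <- legend_ticks(scales$color, 5)
  pan$texts <- rbind(
    data.frame(x = 0, y = style$title_font, label = color_title,
               size = style$title_font, angle = 0, anchor = "start",
               stringsAsFactors = FALSE),
    data.frame(x = (ct / vmax + 1) / 2 * ramp_w, y = y0 + ramp_h + fs + 0.12,
               label = vapply(ct, format, "", trim = TRUE, digits = 3),
               size = fs, angle = 0, anchor = "middle",
               stringsAsFactors = FALSE))

  st <- legend_ticks(scales$size, 4)
  gap <- max(2.6 * scales$size$rmax, 1.6)
  cy <- y0 + ramp_h + fs + 1.2 + scales$size$rmax
  cx <- scales$size$rmax + (seq_along(st) - 1) * gap
  pan$circles <- data.frame(
    x = cx, y = cy, r = map_radius(scales$size, st),
    fill = map_color(scales$color, rep(NA_real_, length(st))),
    stringsAsFactors = FALSE)
  lab <- vapply(st, format, "", trim = TRUE, digits = 3)
  if (scales$size$cap_active)
    lab[length(lab)] <- paste0(">=", lab[length(lab)], " (capped)")
  pan$texts <- rbind(pan$texts,
    data.frame(x = 0, y = y0 + ramp_h + fs + 0.9, label = size_title,
               size = style$title_font, angle = 0, anchor = "start",
               stringsAsFactors = FALSE),
    data.frame(x = cx, y = cy + scales$size$rmax + fs + 0.12, label = lab,
               size = fs, angle = 0, anchor = "middle",
               stringsAsFactors = FALSE))
  h <- cy + scales$size$rmax + fs + 0.3
  w <- max(ramp_w + 0.5, max(cx) + scales$size$rmax + 1.4)
  pan$bbox <- c(0, 0, w, h)
  pan$meta <- list(grid_name = ".legend")
  pan
}

translate_panel <- function(panel, dx, dy) {
  if (nrow(panel$circles)) {
    panel$circles$x <- panel$circles$x + dx
    panel$circles$y <- panel$circles$y + dy
  }
  if (nrow(panel$rects)) {
    panel$rects$x <- panel$rects$x + dx
    panel$rects$y <- panel$rects$y + dy
  }
  if (nrow(panel$texts)) {
    panel$texts$x <- panel$texts$x + dx
    panel$texts$y <- panel$texts$y + dy
  }
  panel$polylines <- lapply(panel$polylines, function(pl)
    list(x = pl$x + dx, y = pl$y + dy))
  panel$bbox <- panel$bbox + c(dx, dy, dx, dy)
  panel
}

#' Compose panels into a single figure
#'
#' Places each panel with its bounding-box corner at the given anchor,
#' translating (never rescaling) panel-local coordinates, and returns one
#' figure object holding all primitives. Overlapping panel regions are an
#' error naming the colliding pair.
#'
#' @param panels List of `bubble_panel` objects.
#' @param placements Data frame (or list of lists) with columns/fields
#'   `x`, `y` giving each panel's top-left anchor in canvas units, one
#'   row per panel, in panel order.
#' @param canvas Optional `c(width, height)`; defaults to the union of
#'   placed panels plus a margin.
#' @param footnote Optional footnote text drawn at the bottom left.
#' @param style A [bubble_style()] (used for the footnote and for the
#'   SVG pixel scale recorded on the figure).
#' @return An object of class `bubble_figure` (same primitive structure
#'   as a panel, bbox = full canvas).
#' @export
compose_figure <- function(panels, placements, canvas = NULL,
                           footnote = NULL, style = bubble_style()) {
  if (!length(panels)) bg_stop("no panels to compose")
  if (is.list(placements) && !is.data.frame(placements))
    placements <- do.call(rbind, lapply(placements, as.data.frame))
  if (nrow(placements) != length(panels))
    bg_stop("one placement per panel required")
  placed <- vector("list", length(panels))
  regions <- matrix(0, length(panels), 4)
  for (i in seq_along(panels)) {
    p <- panels[[i]]
    placed[[i]] <- translate_panel(p, placements$x[i] - p$bbox[1],
                                   placements$y[i] - p$bbox[2])
    regions[i, ] <- placed[[i]]$bbox
  }
  nm <- vapply(placed, function(p) p$meta$grid_name %||% "?", "")
  for (i in seq_along(panels)) for (j in seq_len(i - 1L)) {
    if (regions[i, 1] < regions[j, 3] && regions[j, 1] < regions[i, 3] &&
        regions[i, 2] < regions[j, 4] && regions[j, 2] < regions[i, 4]) {
      bg_stop(sprintf("panel regions overlap: '%s' and '%s'", nm[j], nm[i]))
    }
  }
  fig <- empty_panel()
  fig$circles <- do.call(rbind, lapply(placed, `[[`, "circles"))
  fig$rects <- do.call(rbind, lapply(placed, `[[`, "rects"))
  fig$texts <- do.call(rbind, lapply(placed, `[[`, "texts"))
  fig$polylines <- do.call(c, lapply(placed, `[[`, "polylines"))
  xmax <- max(regions[, 3]); ymax <- max(regions[, 4])
  if (!is.null(footnote) && nzchar(footnote)) {
    ymax <- ymax + 0.8
    fig$texts <- rbind(fig$texts, data.frame(
      x = 0.2, y = ymax, label = footnote, size = style$font, angle = 0,
      anchor = "start", stringsAsFactors = FALSE))
  }
  canvas <- canvas %||% c(xmax + 0.5, ymax + 0.5)
  fig$bbox <- c(0, 0, canvas[1], canvas[2])
  fig$meta <- list(unit_px = style$unit_px, n_panels = length(panels))
  class(fig) <- c("bubble_figure", class(fig))
  fig
}

#' @export
print.bubble_figure <- function(x, ...) {
  cat(sprintf("<bubble_figure: %d panels, %d circles, canvas %.1f x %.1f units>\n",
              x$meta$n_panels %||% NA, nrow(x$circles),
              x$bbox[3], x$bbox[4]))
  invisible(x)
}

## Fallback layout for catalogs without one: stack panels into columns,
## filling down to roughly the height of the tallest panel.
auto_placements <- function(panels, gap = 0.6) {
  h <- vapply(panels, function(p) p$bbox[4] - p$bbox[2], 0)
  w <- vapply(panels, function(p) p$bbox[3] - p$bbox[1], 0)
  target <- max(h) * 1.6
  x <- 0.3; y <- 0.3; colw <- 0; out <- matrix(0, length(panels), 2)
  for (i in seq_along(panels)) {
    if (y > 0.3 && y + h[i] > target) {
      x <- x + colw + gap; y <- 0.3; colw <- 0
    }
    out[i, ] <- c(x, y)
    y <- y + h[i] + gap
    colw <- max(colw, w[i])
  }
  data.frame(x = out[, 1], y = out[, 2])
}

mark_footnotes <- function(aligned, cat) {
  fn <- cat$variables$variable_id[cat$variables$footnote]
  for (g in names(aligned$grids)) {
    cells <- aligned$grids[[g]]$grid$cells
    attr(aligned$grids[[g]], "footnote_cells") <-
      matrix(cells %in% fn, nrow(cells))
  }
  aligned
}

#' One-step figure for a Nightingale-style template
#'
#' Runs the full pipeline -- load the catalog, align the results, build
#' shared scales, render every grid panel plus the legend, and compose
#' them on the catalog's layout -- in one call. The result is identical
#' to running the four steps yourself with the same options.
#'
#' When any footnote-flagged variable (a ratio-to-total-fatty-acids
#' measure in the packaged catalogs) receives a result, the catalog's
#' footnote line is added beneath the figure automatically.
#'
#' @param results A `bubble_results` data frame (see [read_results()],
#'   [generate_results()]).
#' @param template Template id or catalog path, as in [load_template()],
#'   or a ready `bubble_catalog`.
#' @param keyspace,mapping Identifier resolution, as in [resolve_ids()].
#' @param cap,vmax Scale options, as in [make_scales()].
#' @param style A [bubble_style()].
#' @param ... Further arguments passed to [make_scales()].
#' @return A `bubble_figure`; the alignment report is attached as
#'   `attr(, "report")`.
#' @examples
#' fig <- metab_figure(generate_results("nh225", seed = 1), "nh225", cap = 35)
#' fig
#' @export
metab_figure <- function(results, template = "nh251", keyspace = "nh_name",
                         mapping = NULL, cap = NULL, vmax = NULL,
                         style = bubble_style(), ...) {
  cat <- if (inherits(template, "bubble_catalog")) template
         else load_template(template)
  aligned <- align_results(cat, results, keyspace, mapping)
  aligned <- mark_footnotes(aligned, cat)
  est <- unlist(lapply(aligned$grids, function(g) g$color[!g$mask]))
  sco <- unlist(lapply(aligned$grids, function(g) g$size[!g$mask]))
  scales <- make_scales(est, sco, vmax = vmax, cap = cap, ...)
  panels <- lapply(aligned$grids, render_bubble_grid, scales = scales,
                   style = style)
  legend <- render_legends(scales, style)

  lay <- cat$layout
  if (!is.null(lay)) {
    pl <- lay$placements
    ord <- match(pl$grid, names(panels))
    if (anyNA(ord)) bg_stop(paste("layout places unknown grid(s):",
                                  paste(pl$grid[is.na(ord)], collapse = ", ")))
    panels <- panels[ord]
    placements <- data.frame(x = pl$x, y = pl$y)
    if (!is.null(lay$legend)) {
      panels <- c(panels, list(legend))
      placements <- rbind(placements,
                          data.frame(x = lay$legend$x, y = lay$legend$y))
    }
    canvas <- if (!is.null(lay$canvas)) unlist(lay$canvas) else NULL
  } else {
    panels <- c(panels, list(legend))
    placements <- auto_placements(panels)
    canvas <- NULL
  }
  any_fn <- any(vapply(panels, function(p) isTRUE(p$meta$footnote), TRUE))
  footnote <- if (any_fn) (lay$footnote %||% NULL) else NULL
  fig <- compose_figure(panels, placements, canvas = canvas,
                        footnote = footnote, style = style)
  attr(fig, "report") <- aligned$report
  fig
}
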