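## Native SVG serialisation. The dialect is deliberately boring so output
## is byte-stable: no timestamps, no generated ids, all coordinates fixed
## at three decimals, primitives emitted in insertion order.

fmt <- function(x) {
  out <- sprintf("%.3f", x)
  out[out == "-0.000"] <- "0.000"
  out
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_lines <- function(fig, unit_px) {
  k <- unit_px
  w <- (fig$bbox[3] - fig$bbox[1]) * k
  h <- (fig$bbox[4] - fig$bbox[2]) * k
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt(w), fmt(h), fmt(w), fmt(h)),
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="#FFFFFF"/>',
            fmt(w), fmt(h)),
    '<g font-family="Helvetica, Arial, sans-serif" fill="#000000">')
  r <- fig$rects
  if (nrow(r)) {
    out <- c(out, sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="none"/>',
      fmt(r$x * k), fmt(r$y * k), fmt(r$w * k), fmt(r$h * k), r$fill))
  }
  ci <- fig$circles
  if (nrow(ci)) {
    out <- c(out, sprintf(
      '<circle cx="%s" cy="%s" r="%s" fill="%s"/>',
      fmt(ci$x * k), fmt(ci$y * k), fmt(ci$r * k), ci$fill))
  }
  for (pl in fig$polylines) {
    pts <- paste(fmt(pl$x * k), fmt(pl$y * k), sep = ",", collapse = " ")
    out <- c(out, sprintf(
      '<polyline points="%s" fill="none" stroke="#000000" stroke-width="%s"/>',
      pts, fmt(0.035 * k)))
  }
  tx <- fig$texts
  if (nrow(tx)) {
    anchor <- c(start = "start", middle = "middle", end = "end")[tx$anchor]
    rot <- ifelse(tx$angle != 0,
                  sprintf(' transform="rotate(%s %s %s)"',
                          fmt(tx$angle), fmt(tx$x * k), fmt(tx$y * k)), "")
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="%s" text-anchor="%s"%s>%s</text>',
      fmt(tx$x * k), fmt(tx$y * k), fmt(tx$size * k), anchor, rot,
      xml_escape(tx$label)))
  }
  c(out, "</g>", "</svg>")
}

## Draw primitives on the active grid graphics device. Uses absolute inch
## coordinates from the top-left so x and y units stay isotropic.
draw_figure_grid <- function(fig, unit_in) {
  H <- (fig$bbox[4] - fig$bbox[2]) * unit_in
  ix <- function(x) grid::unit(x * unit_in, "in")
  iy <- function(y) grid::unit(H - y * unit_in, "in")
  grid::grid.newpage()
  r <- fig$rects
  if (nrow(r)) {
    grid::grid.rect(x = ix(r$x), y = iy(r$y), width = grid::unit(r$w * unit_in, "in"),
                    height = grid::unit(r$h * unit_in, "in"),
                    just = c("left", "top"),
                    gp = grid::gpar(fill = r$fill, col = NA))
  }
  ci <- fig$circles
  if (nrow(ci)) {
    grid::grid.circle(x = ix(ci$x), y = iy(ci$y),
                      r = grid::unit(ci$r * unit_in, "in"),
                      gp = grid::gpar(fill = ci$fill, col = NA))
  }
  for (pl in fig$polylines) {
    grid::grid.lines(x = ix(pl$x), y = iy(pl$y),
                     gp = grid::gpar(col = "black",
                                     lwd = 0.035 * unit_in * 72))
  }
  tx <- fig$texts
  for (i in seq_len(nrow(tx))) {
    just <- switch(tx$anchor[i], start = "left", middle = "centre",
                   end = "right")
    grid::grid.text(tx$label[i], x = ix(tx$x[i]), y = iy(tx$y[i]),
                    just = c(just, "bottom"), rot = -tx$angle[i],
                    gp = grid::gpar(fontsize = tx$size[i] * unit_in * 72))
  }
}

#' Write a figure to SVG, PDF or PNG
#'
#' SVG is serialised natively and deterministically: identical inputs
#' give byte-identical files (fixed three-decimal coordinates, no
#' timestamps or generated ids). PDF and PNG are drawn through the grid
#' graphics system; PNG pixel dimensions scale with `dpi` (the figure's
#' abstract size is referenced to 96 dpi, so `dpi = 192` doubles the
#' pixel dimensions).
#'
#' @param fig A `bubble_figure` (or single `bubble_panel`).
#' @param path Output file path.
#' @param format `"svg"`, `"pdf"` or `"png"`; default guessed from the
#'   file extension.
#' @param dpi Resolution for PNG output.
#' @return `path`, invisibly.
#' @export
write_figure <- function(fig, path, format = NULL, dpi = 96) {
  stopifnot(inherits(fig, "bubble_panel") || inherits(fig, "bubble_figure"))
  if (!dir.exists(dirname(path)))
    bg_stop(paste("no such directory:", dirname(path)), "bg_io_error")
  format <- tolower(format %||% tools::file_ext(path))
  if (!format %in% c("svg", "pdf", "png"))
    bg_stop(paste0("unknown format '", format,
                   "': use one of svg, pdf, png"))
  unit_px <- fig$meta$unit_px %||% bubble_style()$unit_px
  if (identical(format, "svg")) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(svg_lines(fig, unit_px), con, sep = "\n", useBytes = TRUE)
    return(invisible(path))
  }
  unit_in <- unit_px / 96
  w_in <- (fig$bbox[3] - fig$bbox[1]) * unit_in
  h_in <- (fig$bbox[4] - fig$bbox[2]) * unit_in
  if (identical(format, "pdf")) {
    grDevices::pdf(path, width = w_in, height = h_in, useDingbats = FALSE)
  } else {
    grDevices::png(path, width = w_in, height = h_in, units = "in",
                   res = dpi, type = "cairo")
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  draw_figure_grid(fig, unit_in)
  invisible(path)
}
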