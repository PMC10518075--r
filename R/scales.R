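#' Convert a P-value to a -log10 score
#'
#' `neglog10()` maps a P-value in `[0, 1]` onto the significance score used
#' for bubble sizing. A P-value of exactly zero (or one small enough to
#' underflow past the ceiling) returns `ceiling`, a finite stand-in that
#' exceeds any plausible display cap.
#'
#' @param p Numeric vector of P-values in `[0, 1]`. `NA` passes through.
#' @param ceiling Score returned for `p = 0` (default 300).
#' @return Numeric vector of scores, `-log10(p)` clamped to `[0, ceiling]`.
#' @examples
#' neglog10(c(1, 0.05, 1e-10, 0))
#' @export
neglog10 <- function(p, ceiling = 300) {
  if (!is.numeric(p)) bg_stop("`p` must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    bg_stop(sprintf("P-values outside [0, 1]: %s",
                    paste(format(p[bad]), collapse = ", ")))
  }
  s <- -log10(p)
  pmin(s, ceiling)
}

#' Cap a -log10 P-value score
#'
#' Saturates significance scores at `cap` so that a handful of extreme
#' P-values (e.g. below 1e-35) do not dominate the bubble-size scale.
#' With `cap = NULL` the score is returned unchanged. Idempotent.
#'
#' @param s Numeric vector of nonnegative scores.
#' @param cap Positive cap, or `NULL` for no capping.
#' @return `pmin(s, cap)`.
#' @examples
#' cap_score(c(3, 40), cap = 35)
#' @export
cap_score <- function(s, cap = NULL) {
  if (any(!is.na(s) & s < 0)) bg_stop("scores must be nonnegative")
  if (is.null(cap)) return(s)
  if (!is.numeric(cap) || length(cap) != 1L || is.na(cap) || cap <= 0)
    bg_stop("`cap` must be a single positive number or NULL")
  pmin(s, cap)
}

default_palette <- function() c("#2166AC", "#F7F7F7", "#B2182B")

#' Build the colour and size scales for one figure
#'
#' Constructs the pair of encodings shared by every panel of a figure: a
#' symmetric diverging colour scale for signed effect estimates (zero is
#' always the palette midpoint) and a monotone size scale for -log10
#' P-values. The colour range defaults to plus/minus the largest absolute
#' estimate; the size domain runs from 0 to `cap`, or to the largest
#' observed score when no cap is requested.
#'
#' @param estimates Numeric vector of signed effect estimates (used for the
#'   default colour range; `NA` ignored).
#' @param scores Numeric vector of -log10 P scores (used for the fallback
#'   size domain; `NA` ignored).
#' @param vmax Override for the colour half-range (must be positive).
#' @param cap Size cap in -log10 P units, or `NULL` for no cap (the
#'   observed maximum then bounds the size domain).
#' @param rmin,rmax Bubble radii (abstract canvas units) at score 0 and at
#'   the top of the size domain.
#' @param transform `"area"` (default; perceived area proportional to the
#'   capped score) or `"radius"` (radius proportional to the capped score).
#' @param palette Character vector of 3+ colours, low to high, middle
#'   entry the zero colour.
#' @param na_col Fill used for cells whose estimate is missing.
#' @return An object of class `bubble_scales`: list with elements `color`
#'   (class `color_scale`) and `size` (class `size_scale`).
#' @examples
#' sc <- make_scales(c(-2, 1, 0.5), c(10, 50), cap = 35)
#' sc$color$vmax
#' sc$size$cap
#' @export
make_scales <- function(estimates, scores, vmax = NULL, cap = NULL,
                        rmin = 0.08, rmax = 0.42,
                        transform = c("area", "radius"),
                        palette = default_palette(), na_col = "#BDBDBD") {
  transform <- match.arg(transform)
  est <- estimates[is.finite(estimates)]
  sco <- scores[is.finite(scores)]
  if (is.null(vmax)) {
    if (!length(est))
      bg_stop("no finite estimates; supply `vmax` explicitly")
    vmax <- max(abs(est))
    if (vmax == 0) vmax <- 1
  }
  if (vmax <= 0) bg_stop("`vmax` must be positive")
  cap_active <- !is.null(cap)
  if (cap_active) {
    cap_eff <- cap_score(Inf, cap)  # validates cap
  } else {
    if (!length(sco))
      bg_stop("no finite scores; supply `cap` explicitly")
    cap_eff <- max(sco)
    if (cap_eff == 0) cap_eff <- 1
  }
  if (!(rmin > 0 && rmin < rmax))
    bg_stop("need 0 < rmin < rmax")
  if (length(palette) < 3 || length(palette) %% 2 == 0)
    bg_stop("`palette` must hold an odd number (>= 3) of colours")
  color <- structure(list(vmax = vmax, palette = palette, na_col = na_col),
                     class = "color_scale")
  size <- structure(list(cap = cap_eff, cap_active = cap_active,
                         rmin = rmin, rmax = rmax, transform = transform),
                    class = "size_scale")
  structure(list(color = color, size = size), class = "bubble_scales")
}

#' Position of a value on the unit colour ramp
#'
#' Maps a signed estimate to `[0, 1]`: 0 for `-vmax`, 0.5 for zero, 1 for
#' `+vmax`, clamped outside that range. Exposed so the symmetry of the
#' encoding (`pos(v) + pos(-v) = 1`) can be inspected directly.
#'
#' @param scale A `color_scale` (see [make_scales()]).
#' @param v Numeric vector of estimates.
#' @return Numeric vector in `[0, 1]` (`NA` for missing input).
#' @export
color_position <- function(scale, v) {
  stopifnot(inherits(scale, "color_scale"))
  pos <- (pmax(pmin(v, scale$vmax), -scale$vmax) / scale$vmax + 1) / 2
  pos
}

#' Map estimates to fill colours
#'
#' Evaluates the diverging ramp of a colour scale. Values are clamped to
#' `[-vmax, vmax]`; missing values get the scale's `na_col`.
#'
#' @inheritParams color_position
#' @return Character vector of `#RRGGBB` colours.
#' @examples
#' sc <- make_scales(c(-1, 1), 5, cap = 10)
#' map_color(sc$color, c(-1, 0, 1, NA))
#' @export
map_color <- function(scale, v) {
  stopifnot(inherits(scale, "color_scale"))
  pos <- color_position(scale, v)
  out <- rep(scale$na_col, length(v))
  ok <- !is.na(pos)
  if (any(ok)) {
    m <- grDevices::colorRamp(scale$palette)(pos[ok])
    out[ok] <- grDevices::rgb(round(m[, 1]), round(m[, 2]), round(m[, 3]),
                              maxColorValue = 255)
  }
  out
}

#' Map -log10 P scores to bubble radii
#'
#' Monotone mapping from the score domain `[0, cap]` to radii
#' `[rmin, rmax]`; scores above the cap saturate at `rmax`. Under the
#' default area transform the circle area grows linearly with the capped
#' score: `r(s) = sqrt(rmin^2 + (rmax^2 - rmin^2) * min(s, cap) / cap)`.
#' The radius transform interpolates the radius itself linearly.
#'
#' @param scale A `size_scale` (see [make_scales()]).
#' @param s Numeric vector of nonnegative scores.
#' @return Numeric vector of radii in abstract canvas units.
#' @examples
#' sc <- make_scales(1, 35, cap = 35, rmin = 1, rmax = 3)
#' map_radius(sc$size, c(0, 17.5, 35, 100))
#' @export
map_radius <- function(scale, s) {
  stopifnot(inherits(scale, "size_scale"))
  if (any(!is.na(s) & s < 0)) bg_stop("scores must be nonnegative")
  f <- cap_score(s, scale$cap) / scale$cap
  if (scale$transform == "area") {
    sqrt(scale$rmin^2 + (scale$rmax^2 - scale$rmin^2) * f)
  } else {
    scale$rmin + (scale$rmax - scale$rmin) * f
  }
}

#' Reference tick values for a legend
#'
#' Chooses round, strictly increasing values spanning a scale's domain,
#' always including both endpoints; colour scales get ticks symmetric
#' about zero. A degenerate (zero-width) domain yields a single tick.
#'
#' @param scale A `size_scale` or `color_scale`.
#' @param n Target number of ticks (at least 2).
#' @return Numeric vector of tick values.
#' @export
legend_ticks <- function(scale, n = 5) {
  if (n < 2) bg_stop("`n` must be at least 2")
  if (inherits(scale, "size_scale")) {
    lo <- 0
    hi <- scale$cap
    if (hi <= lo) return(lo)
    inner <- pretty(c(lo, hi), n = n)
    inner <- inner[inner > lo & inner < hi * 0.85]
    ticks <- unique(c(lo, inner, hi))
    # thin interior ticks crowding the endpoints
    if (length(ticks) > n) {
      keep <- unique(round(seq(1, length(ticks), length.out = n)))
      ticks <- ticks[keep]
      ticks[length(ticks)] <- hi
    }
    return(ticks)
  }
  if (inherits(scale, "color_scale")) {
    hi <- scale$vmax
    if (hi <= 0) return(0)
    half <- pretty(c(0, hi), n = max(2, ceiling(n / 2)))
    half <- half[half > 0 & half < hi * 0.75]
    return(unique(c(-hi, -rev(half), 0, half, hi)))
  }
  bg_stop("`scale` must be a size_scale or color_scale")
}
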