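# Internal rasterization helpers for the scheme generator.
#
# Everything draws into a logical ink mask [height x width] (TRUE = ink),
# using the package-wide 0-based (x, y) convention. Strokes are rasterized
# by marking every pixel whose center lies within half the stroke thickness
# of the ideal segment, which keeps thin strokes 8-connected at any angle.

# Mark pixels within distance t/2 of segment (x0,y0)-(x1,y1). Coordinates are
# continuous; pixel (i, j) has center (i + 0.5, j + 0.5).
draw_segment <- function(mask, x0, y0, x1, y1, thickness = 2) {
  h <- nrow(mask); w <- ncol(mask)
  r <- thickness / 2
  xmin <- max(0L, floor(min(x0, x1) - r - 1)); xmax <- min(w - 1L, ceiling(max(x0, x1) + r + 1))
  ymin <- max(0L, floor(min(y0, y1) - r - 1)); ymax <- min(h - 1L, ceiling(max(y0, y1) + r + 1))
  if (xmin > xmax || ymin > ymax) return(mask)
  xs <- xmin:xmax; ys <- ymin:ymax
  px <- rep(xs + 0.5, each = length(ys))
  py <- rep(ys + 0.5, times = length(xs))
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx^2 + dy^2
  if (len2 == 0) {
    d2 <- (px - x0)^2 + (py - y0)^2
  } else {
    t <- pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / len2))
    d2 <- (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2
  }
  hit <- d2 <= r^2
  if (any(hit)) {
    idx <- (px[hit] - 0.5) * h + (py[hit] - 0.5) + 1L
    mask[idx] <- TRUE
  }
  mask
}

draw_polyline <- function(mask, pts, thickness = 2, closed = FALSE) {
  n <- nrow(pts)
  if (closed && n >= 2) pts <- rbind(pts, pts[1, , drop = FALSE])
  for (i in seq_len(nrow(pts) - 1L)) {
    mask <- draw_segment(mask, pts[i, 1], pts[i, 2],
                         pts[i + 1, 1], pts[i + 1, 2], thickness)
  }
  mask
}

# Filled triangle (solid arrowhead): pixels whose centers fall inside.
draw_triangle <- function(mask, p1, p2, p3) {
  h <- nrow(mask); w <- ncol(mask)
  xs <- max(0L, floor(min(p1[1], p2[1], p3[1]))):min(w - 1L, ceiling(max(p1[1], p2[1], p3[1])))
  ys <- max(0L, floor(min(p1[2], p2[2], p3[2]))):min(h - 1L, ceiling(max(p1[2], p2[2], p3[2])))
  if (length(xs) == 0L || length(ys) == 0L) return(mask)
  px <- rep(xs + 0.5, each = length(ys))
  py <- rep(ys + 0.5, times = length(xs))
  sgn <- function(a, b) (px - b[1]) * (a[2] - b[2]) - (a[1] - b[1]) * (py - b[2])
  d1 <- sgn(p1, p2); d2 <- sgn(p2, p3); d3 <- sgn(p3, p1)
  inside <- !((d1 < 0 | d2 < 0 | d3 < 0) & (d1 > 0 | d2 > 0 | d3 > 0))
  if (any(inside)) {
    idx <- (px[inside] - 0.5) * h + (py[inside] - 0.5) + 1L
    mask[idx] <- TRUE
  }
  mask
}

# Quadratic Bezier arc sampled densely enough to stay connected.
draw_bezier <- function(mask, p0, p1, p2, thickness = 2, n = 48) {
  tt <- seq(0, 1, length.out = n)
  bx <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1]
  by <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2]
  draw_polyline(mask, cbind(bx, by), thickness)
}

# Crop a mask to its tight ink bbox; NULL for an empty mask.
crop_tight <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  mask[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]), drop = FALSE]
}

# Stamp a glyph mask onto a canvas with its top-left pixel at (x, y) 0-based.
# Returns the canvas; ink accumulates with logical OR.
stamp <- function(canvas, glyph_mask, x, y) {
  gh <- nrow(glyph_mask); gw <- ncol(glyph_mask)
  h <- nrow(canvas); w <- ncol(canvas)
  stopifnot(x >= 0, y >= 0, x + gw <= w, y + gh <= h)
  rows <- (y + 1):(y + gh); cols <- (x + 1):(x + gw)
  canvas[rows, cols] <- canvas[rows, cols] | glyph_mask
  canvas
}

# Tiny procedural "character": random short strokes in a cell, vaguely
# letter-like. Used for labels, conditions text and superatom clusters.
draw_char_cell <- function(rng_unused = NULL, cw = 9, ch = 13, thickness = 1.6) {
  m <- matrix(FALSE, ch, cw)
  n_strokes <- sample(2:4, 1)
  anchors <- cbind(runif(n_strokes + 1, 1, cw - 1), runif(n_strokes + 1, 1, ch - 1))
  # bias anchors toward cell corners/edges for a skeletal look
  anchors[, 1] <- round(anchors[, 1] / (cw - 2) * 2) / 2 * (cw - 2) + 1
  anchors[, 2] <- round(anchors[, 2] / (ch - 2) * 2) / 2 * (ch - 2) + 1
  draw_polyline(m, anchors, thickness)
}

# A text block: `rows` lines of `n_chars` characters. Returns a tight mask.
draw_text_block <- function(n_chars, rows = 1, cw = 9, ch = 13, gap = 2) {
  w <- n_chars * cw + (n_chars - 1) * gap
  h <- rows * ch + (rows - 1) * 3
  m <- matrix(FALSE, h, w)
  for (r in seq_len(rows)) {
    for (k in seq_len(n_chars)) {
      cell <- draw_char_cell(cw = cw, ch = ch)
      m <- stamp(m, cell, (k - 1) * (cw + gap), (r - 1) * (ch + 3))
    }
  }
  out <- crop_tight(m)
  if (is.null(out)) matrix(TRUE, 2, 2) else out
}
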