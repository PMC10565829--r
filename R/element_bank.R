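# Element bank: the procedurally rendered glyphs from which artificial
# reaction schemes are composed. Diagram glyphs are polyline "skeletons"
# (rings, bond-like spokes, optional detached superatom text clusters) rather
# than renders of real molecules: what matters for training and testing the
# detection stages is that the imagery carries the right classes of visual
# features (line drawings with discontinuities, small text blocks, arrows of
# all four types, decoy symbols), not chemical meaning.

new_glyph <- function(mask, type, subtype = NULL, ...) {
  stopifnot(is.matrix(mask), is.logical(mask), any(mask))
  structure(mask, class = "glyph", type = type, subtype = subtype, ...)
}

#' @export
print.glyph <- function(x, ...) {
  cat(sprintf("<glyph %s%s %dx%d, %d ink px>\n", attr(x, "type"),
              if (!is.null(attr(x, "subtype"))) paste0("/", attr(x, "subtype")) else "",
              ncol(x), nrow(x), sum(x)))
  invisible(x)
}

glyph_mask <- function(g) {
  m <- unclass(g)
  attributes(m) <- list(dim = dim(g))
  m
}

# ---- arrow rendering ---------------------------------------------------

# Render an arrow of a given subtype at an arbitrary angle. Geometry is laid
# out in continuous coordinates along the +x axis (tail at origin, tip at
# (len, 0)), rotated, then rasterized. Returns a glyph whose attributes carry
# the tail/tip positions in glyph-local 0-based pixel coordinates, which the
# composer records as ground truth for arrow direction.
render_arrow <- function(subtype = c("solid", "curly", "equilibrium", "resonance"),
                         len = 80, thickness = 2.4, angle = 0,
                         head_len = 11, head_w = 5.5) {
  subtype <- match.arg(subtype)
  segs <- list()   # each: list(p, q, t) straight stroke
  tris <- list()   # filled triangles
  bez <- NULL
  tail_pt <- c(0, 0); tip_pt <- c(len, 0)
  if (subtype == "solid") {
    segs <- list(list(p = c(0, 0), q = c(len - head_len * 0.6, 0), t = thickness))
    tris <- list(list(a = c(len, 0), b = c(len - head_len, -head_w),
                      c = c(len - head_len, head_w)))
  } else if (subtype == "resonance") {
    segs <- list(list(p = c(head_len * 0.6, 0), q = c(len - head_len * 0.6, 0),
                      t = thickness))
    tris <- list(list(a = c(len, 0), b = c(len - head_len, -head_w),
                      c = c(len - head_len, head_w)),
                 list(a = c(0, 0), b = c(head_len, -head_w),
                      c = c(head_len, head_w)))
  } else if (subtype == "equilibrium") {
    # two harpoons; the half-heads slant toward the other shaft so the arrow
    # stays one 8-connected component
    off <- 2.6
    segs <- list(
      list(p = c(0, -off), q = c(len, -off), t = thickness),
      list(p = c(len, -off), q = c(len - head_len, -off + head_w + off), t = thickness),
      list(p = c(0, off), q = c(len, off), t = thickness),
      list(p = c(0, off), q = c(head_len, off - head_w - off), t = thickness))
  } else { # curly
    bez <- list(p0 = c(0, 0), p1 = c(len / 2, -0.55 * len), p2 = c(len, 0))
    # hook at the tip: two short strokes backward from the tip relative to
    # the tangent direction at t = 1
    tang <- c(bez$p2[1] - bez$p1[1], bez$p2[2] - bez$p1[2])
    tang <- tang / sqrt(sum(tang^2))
    for (s in c(-1, 1)) {
      th <- s * 28 * pi / 180
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      d <- as.vector(R %*% tang)
      segs <- c(segs, list(list(p = c(len, 0),
                                q = c(len, 0) - d * head_len, t = thickness)))
    }
  }
  rot <- function(p) as.vector(rotate_points(matrix(p, 1, 2), angle))
  segs <- lapply(segs, function(s) list(p = rot(s$p), q = rot(s$q), t = s$t))
  tris <- lapply(tris, function(t3) list(a = rot(t3$a), b = rot(t3$b), c = rot(t3$c)))
  if (!is.null(bez)) bez <- lapply(bez, rot)
  tail_pt <- rot(tail_pt); tip_pt <- rot(tip_pt)

  allx <- c(unlist(lapply(segs, function(s) c(s$p[1], s$q[1]))),
            unlist(lapply(tris, function(t3) c(t3$a[1], t3$b[1], t3$c[1]))),
            if (!is.null(bez)) c(bez$p0[1], bez$p1[1], bez$p2[1]),
            tail_pt[1], tip_pt[1])
  ally <- c(unlist(lapply(segs, function(s) c(s$p[2], s$q[2]))),
            unlist(lapply(tris, function(t3) c(t3$a[2], t3$b[2], t3$c[2]))),
            if (!is.null(bez)) c(bez$p0[2], bez$p1[2], bez$p2[2]),
            tail_pt[2], tip_pt[2])
  pad <- thickness + 2
  ox <- -min(allx) + pad; oy <- -min(ally) + pad
  w <- ceiling(max(allx) - min(allx) + 2 * pad)
  h <- ceiling(max(ally) - min(ally) + 2 * pad)
  m <- matrix(FALSE, h, w)
  for (s in segs) {
    m <- draw_segment(m, s$p[1] + ox, s$p[2] + oy, s$q[1] + ox, s$q[2] + oy, s$t)
  }
  for (t3 in tris) {
    m <- draw_triangle(m, t3$a + c(ox, oy), t3$b + c(ox, oy), t3$c + c(ox, oy))
  }
  if (!is.null(bez)) {
    m <- draw_bezier(m, bez$p0 + c(ox, oy), bez$p1 + c(ox, oy),
                     bez$p2 + c(ox, oy), thickness)
  }
  # tight crop, tracking the offset so tail/tip stay correct
  idx <- which(m, arr.ind = TRUE)
  r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
  m <- m[r0:max(idx[, 1]), c0:max(idx[, 2]), drop = FALSE]
  shift <- c(-(c0 - 1), -(r0 - 1))
  new_glyph(m, "arrow", subtype,
            tail = tail_pt + c(ox, oy) + shift,
            tip = tip_pt + c(ox, oy) + shift,
            spec = list(subtype = subtype, len = len, thickness = thickness,
                        head_len = head_len, head_w = head_w))
}

# ---- other glyph classes -----------------------------------------------

render_diagram_glyph <- function(size = 70, with_superatom = FALSE) {
  # ring skeleton with bond-like spokes
  k <- sample(5:7, 1)
  rad <- size * runif1(0.28, 0.38)
  cx <- size * 0.5; cy <- size * 0.55
  ang <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)] + runif1(0, 2 * pi / k)
  ring <- cbind(cx + rad * cos(ang) * runif(k, 0.9, 1.1),
                cy + rad * sin(ang) * runif(k, 0.9, 1.1))
  m <- matrix(FALSE, ceiling(size * 1.1), ceiling(size * 1.1))
  m <- draw_polyline(m, ring, thickness = 2, closed = TRUE)
  n_spokes <- sample(1:3, 1)
  spoke_ends <- list()
  for (s in seq_len(n_spokes)) {
    v <- sample(k, 1)
    dirv <- ring[v, ] - c(cx, cy)
    dirv <- dirv / sqrt(sum(dirv^2))
    end <- ring[v, ] + dirv * rad * runif1(0.5, 0.8)
    end <- pmin(pmax(end, 2), ncol(m) - 3)
    m <- draw_segment(m, ring[v, 1], ring[v, 2], end[1], end[2], 2)
    spoke_ends[[s]] <- list(end = end, dir = dirv)
  }
  if (with_superatom) {
    # detached text cluster near a spoke end, separated by a small gap so the
    # glyph binarizes to >= 2 connected components (exercises dilation
    # completion downstream)
    txt <- draw_text_block(sample(2:3, 1))
    se <- spoke_ends[[sample(length(spoke_ends), 1)]]
    gap <- runif1(4, 7)
    pos <- se$end + se$dir * (gap + 4)
    # grow canvas to fit the text block wherever it lands
    grow_r <- nrow(txt) + 20; grow_c <- ncol(txt) + 20
    big <- matrix(FALSE, nrow(m) + 2 * grow_r, ncol(m) + 2 * grow_c)
    big[grow_r + seq_len(nrow(m)), grow_c + seq_len(ncol(m))] <- m
    x0 <- round(pos[1] - ncol(txt) / 2) + grow_c
    y0 <- round(pos[2] - nrow(txt) / 2) + grow_r
    big <- stamp(big, txt, x0, y0)
    m <- big
  }
  m <- crop_tight(m)
  new_glyph(m, "diagram", has_superatom = with_superatom)
}

render_negative_glyph <- function(kind = c("plus", "bracket")) {
  kind <- match.arg(kind)
  if (kind == "plus") {
    s <- round(runif1(10, 16))
    m <- matrix(FALSE, s, s)
    m <- draw_segment(m, 1, s / 2, s - 1, s / 2, 2)
    m <- draw_segment(m, s / 2, 1, s / 2, s - 1, 2)
  } else {
    h <- round(runif1(26, 44)); w <- round(h * 0.28)
    m <- matrix(FALSE, h, w)
    m <- draw_segment(m, w - 2, 1, 2, 1, 2)
    m <- draw_segment(m, 2, 1, 2, h - 2, 2)
    m <- draw_segment(m, 2, h - 2, w - 2, h - 2, 2)
  }
  new_glyph(crop_tight(m), "negative", kind = kind)
}

#' Build an element bank of procedural glyphs
#'
#' Creates the visual components from which artificial reaction schemes are
#' composed: chemical-diagram skeleton glyphs (some with detached superatom
#' text clusters), reaction arrows of all four subtypes (solid, curly,
#' equilibrium, resonance), chemical-label and conditions text blocks, and
#' negative decoy symbols (plus signs, brackets). Deterministic for a fixed
#' `(config, seed)` pair.
#'
#' @param config Named list of counts and options; see
#'   [element_bank_config()] for the defaults.
#' @param seed Integer seed controlling every random draw.
#' @return An object of class `element_bank`: a list with components
#'   `diagram`, `label`, `conditions`, `negative` (lists of glyphs) and
#'   `arrow` (a list of glyph lists keyed by subtype).
#' @examples
#' bank <- build_element_bank(seed = 1)
#' length(bank$diagram)
#' @export
build_element_bank <- function(config = element_bank_config(), seed = 1) {
  config <- utils::modifyList(element_bank_config(), config)
  counts <- c(diagram = config$n_diagram, label = config$n_label,
              conditions = config$n_conditions, arrow = config$n_arrow_per_type)
  if (any(counts < 1)) {
    stop("mandatory glyph class requested with count 0: ",
         paste(names(counts)[counts < 1], collapse = ", "))
  }
  with_seed(seed, {
    diagrams <- lapply(seq_len(config$n_diagram), function(i) {
      render_diagram_glyph(size = runif1(config$diagram_size[1], config$diagram_size[2]),
                           with_superatom = stats::runif(1) < config$p_superatom)
    })
    labels <- lapply(seq_len(config$n_label), function(i)
      new_glyph(draw_text_block(sample(2:3, 1)), "label"))
    conditions <- lapply(seq_len(config$n_conditions), function(i)
      new_glyph(draw_text_block(sample(4:7, 1), rows = sample(1:2, 1)), "conditions"))
    negatives <- if (config$n_negative > 0) {
      lapply(seq_len(config$n_negative), function(i)
        render_negative_glyph(sample(c("plus", "bracket"), 1)))
    } else list()
    arrows <- lapply(stats::setNames(nm = c("solid", "curly", "equilibrium", "resonance")),
                     function(st) {
      lapply(seq_len(config$n_arrow_per_type), function(i)
        render_arrow(st, len = runif1(config$arrow_len[1], config$arrow_len[2])))
    })
    structure(list(diagram = diagrams, label = labels, conditions = conditions,
                   negative = negatives, arrow = arrows),
              class = "element_bank", seed = seed, config = config)
  })
}

#' Default element-bank configuration
#'
#' @return Named list: glyph counts per class, diagram size range (px),
#'   arrow length range (px), probability that a diagram glyph carries a
#'   detached superatom text cluster.
#' @export
element_bank_config <- function() {
  list(n_diagram = 8, n_label = 6, n_conditions = 6, n_negative = 4,
       n_arrow_per_type = 2, diagram_size = c(55, 90), arrow_len = c(65, 100),
       p_superatom = 0.5)
}

#' @export
print.element_bank <- function(x, ...) {
  cat(sprintf(paste0("<element_bank: %d diagrams, %d labels, %d conditions, ",
                     "%d negatives, %d arrows/type x 4 types (seed %s)>\n"),
              length(x$diagram), length(x$label), length(x$conditions),
              length(x$negative), length(x$arrow$solid),
              format(attr(x, "seed"))))
  invisible(x)
}

# ---- augmentation ------------------------------------------------------

#' Randomly augment a glyph
#'
#' Applies an affine jitter (isotropic scaling and rotation within the given
#' bounds) and, optionally, a small Gaussian blur, mirroring the augmentation
#' applied to scheme elements before placement so that detectors become
#' robust to low-resolution renderings. The result is re-thresholded to a
#' binary mask and tight-cropped. Augmentations that would shrink the glyph
#' below 3 px in either dimension are rejected and resampled (bounded
#' retries). With identity bounds (`scale = c(1, 1)`, `rotate = c(0, 0)`,
#' `p_blur = 0`) the glyph is returned pixel-identical.
#'
#' @param glyph A glyph from [build_element_bank()].
#' @param seed Integer seed; fixed seed gives identical output.
#' @param scale Length-2 scaling-factor bounds.
#' @param rotate Length-2 rotation bounds in degrees.
#' @param p_blur Probability of applying a Gaussian blur.
#' @param blur_sigma Length-2 bounds of the blur standard deviation (px).
#' @return An augmented glyph (same `type`/`subtype` attributes).
#' @export
augment_glyph <- function(glyph, seed = NULL, scale = c(0.85, 1.2),
                          rotate = c(-4, 4), p_blur = 0.25,
                          blur_sigma = c(0.5, 0.9)) {
  stopifnot(inherits(glyph, "glyph"))
  with_seed(seed, {
    for (attempt in 1:10) {
      s <- runif1(scale[1], scale[2])
      a <- runif1(rotate[1], rotate[2])
      do_blur <- stats::runif(1) < p_blur
      m <- glyph_mask(glyph)
      img <- EBImage::Image(t(m * 1))
      if (s != 1) {
        img <- EBImage::resize(img, w = max(3, round(dim(img)[1] * s)))
      }
      if (a != 0) {
        img <- EBImage::rotate(img, a, bg.col = 0)
      }
      if (do_blur && min(dim(img)) >= 9) {  # gblur kernel needs room
        img <- EBImage::gblur(img, sigma = runif1(blur_sigma[1], blur_sigma[2]))
      }
      out <- t(EBImage::imageData(img)) >= 0.4
      out <- crop_tight(out)
      if (!is.null(out) && nrow(out) >= 3 && ncol(out) >= 3) {
        keep <- attributes(glyph)[setdiff(names(attributes(glyph)),
                                          c("dim", "class"))]
        return(do.call(new_glyph, c(list(mask = out, type = attr(glyph, "type"),
                                         subtype = attr(glyph, "subtype")),
                                    keep[setdiff(names(keep),
                                                 c("type", "subtype", "tail", "tip"))])))
      }
    }
    stop("augmentation repeatedly produced a degenerate glyph (< 3 px)")
  })
}
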