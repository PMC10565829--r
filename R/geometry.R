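# Geometry primitives shared by every stage of the pipeline.
#
# Coordinate convention (fixed package-wide): 0-based pixel coordinates with
# origin at the top-left corner, x growing rightward and y growing downward.
# A bounding box is half-open, [x0, x1) x [y0, y1); the pixel at integer
# coordinates (x, y) occupies the unit box [x, x+1) x [y, y+1). Image rasters
# are stored as numeric matrices indexed [y + 1, x + 1].

#' Bounding box constructor
#'
#' Boxes are half-open pixel rectangles `[x0, x1) x [y0, y1)` in a 0-based
#' coordinate frame with the origin at the top-left of the image, x rightward
#' and y downward. The convention is shared by every function in the package
#' and by the COCO-style annotation files it writes.
#'
#' @param x0,y0 Top-left corner (inclusive).
#' @param x1,y1 Bottom-right corner (exclusive); must exceed `x0`/`y0`.
#' @return An object of class `bbox`: a named numeric vector
#'   `c(x0, y0, x1, y1)`.
#' @examples
#' b <- bbox(0, 0, 10, 10)
#' bbox_area(b)
#' @export
bbox <- function(x0, y0, x1, y1) {
  stopifnot(is.numeric(x0), is.numeric(y0), is.numeric(x1), is.numeric(y1))
  if (!(x0 < x1 && y0 < y1)) {
    stop("invalid bbox: need x0 < x1 and y0 < y1 (got [",
         x0, ",", y0, ",", x1, ",", y1, "])")
  }
  structure(c(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox [%g,%g) x [%g,%g), area %g>\n",
              x[["x0"]], x[["x1"]], x[["y0"]], x[["y1"]], bbox_area(x)))
  invisible(x)
}

#' Box area, width, height and center
#' @param b A [bbox()].
#' @return A scalar (`bbox_area`, `bbox_width`, `bbox_height`) or length-2
#'   numeric `c(x, y)` (`bbox_center`).
#' @export
bbox_area <- function(b) (b[["x1"]] - b[["x0"]]) * (b[["y1"]] - b[["y0"]])

#' @rdname bbox_area
#' @export
bbox_width <- function(b) b[["x1"]] - b[["x0"]]

#' @rdname bbox_area
#' @export
bbox_height <- function(b) b[["y1"]] - b[["y0"]]

#' @rdname bbox_area
#' @export
bbox_center <- function(b) {
  c(x = (b[["x0"]] + b[["x1"]]) / 2, y = (b[["y0"]] + b[["y1"]]) / 2)
}

#' Union of bounding boxes
#' @param ... [bbox()] objects (or a single list of them).
#' @return The tightest [bbox()] containing all inputs.
#' @export
bbox_union <- function(...) {
  bs <- list(...)
  if (length(bs) == 1L && is.list(bs[[1]]) && !inherits(bs[[1]], "bbox")) {
    bs <- bs[[1]]
  }
  stopifnot(length(bs) >= 1L)
  m <- do.call(rbind, lapply(bs, unclass))
  bbox(min(m[, "x0"]), min(m[, "y0"]), max(m[, "x1"]), max(m[, "y1"]))
}

#' Do two boxes intersect?
#' @param a,b [bbox()] objects.
#' @return Logical scalar; `TRUE` when the half-open boxes share interior.
#' @export
bbox_intersects <- function(a, b) {
  a[["x0"]] < b[["x1"]] && b[["x0"]] < a[["x1"]] &&
    a[["y0"]] < b[["y1"]] && b[["y0"]] < a[["y1"]]
}

#' Intersection-over-union of two boxes
#' @param a,b [bbox()] objects.
#' @return IoU in `[0, 1]`.
#' @export
bbox_iou <- function(a, b) {
  iw <- min(a[["x1"]], b[["x1"]]) - max(a[["x0"]], b[["x0"]])
  ih <- min(a[["y1"]], b[["y1"]]) - max(a[["y0"]], b[["y0"]])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (bbox_area(a) + bbox_area(b) - inter)
}

#' Minimal distance between two boxes
#'
#' The smallest Euclidean distance between any point of box `a` and any point
#' of box `b`, treating each half-open box as the solid rectangle it bounds.
#' Zero when the boxes overlap or touch; symmetric in its arguments. This is
#' the "closest element" primitive used when text regions are matched to their
#' nearest diagram or arrow.
#'
#' @param a,b [bbox()] objects.
#' @return Non-negative distance in pixels.
#' @examples
#' separation(bbox(0, 0, 10, 10), bbox(20, 0, 30, 10))   # 10
#' separation(bbox(0, 0, 10, 10), bbox(20, 20, 30, 30))  # sqrt(200)
#' @export
separation <- function(a, b) {
  dx <- max(0, b[["x0"]] - a[["x1"]], a[["x0"]] - b[["x1"]])
  dy <- max(0, b[["y0"]] - a[["y1"]], a[["y0"]] - b[["y1"]])
  sqrt(dx^2 + dy^2)
}

#' Binary (ink) image
#'
#' A logical foreground mask over an image raster; `TRUE` marks ink.
#'
#' @param mask Logical matrix, rows indexed by y and columns by x.
#' @return An object of class `binary_image` with fields `width`, `height`
#'   and `mask`.
#' @export
binary_image <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask), length(mask) >= 1L)
  structure(list(width = ncol(mask), height = nrow(mask), mask = mask),
            class = "binary_image")
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image %d x %d, %d foreground px (%.2f%%)>\n",
              x$width, x$height, sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Binarize a grayscale raster
#'
#' Schemes are high-contrast line art, so a global Otsu threshold on the
#' grayscale intensities is used; pixels darker than the threshold become
#' foreground (ink). A perfectly uniform image has no ink and yields an empty
#' mask with a warning.
#'
#' @param image Numeric matrix in `[0, 1]` (0 = black, 1 = white), or an
#'   H x W x C array whose channels are averaged first.
#' @return A [binary_image()].
#' @examples
#' img <- matrix(1, 64, 64); img[10:12, 10:12] <- 0
#' sum(binarize(img)$mask)  # 9
#' @export
binarize <- function(image) {
  if (is.array(image) && length(dim(image)) == 3L) {
    image <- apply(image, c(1, 2), mean)
  }
  stopifnot(is.matrix(image), is.numeric(image))
  if (length(image) == 0L) stop("empty image")
  rng <- range(image)
  if (rng[1] == rng[2]) {
    warning("uniform image: no foreground found")
    return(binary_image(matrix(FALSE, nrow(image), ncol(image))))
  }
  thr <- EBImage::otsu(EBImage::Image(t(image)), range = rng)
  binary_image(image < thr)
}

#' Connected component of foreground pixels
#'
#' @param pixels Integer matrix with columns `x`, `y` (0-based pixel
#'   coordinates) holding the component's foreground pixels.
#' @return An object of class `conncomp` with fields `pixels`, `bbox`
#'   (tight [bbox()]), `area` (pixel count) and `centroid` (mean of pixel
#'   centers, `c(x, y)`).
#' @export
conncomp <- function(pixels) {
  stopifnot(is.matrix(pixels), ncol(pixels) == 2L, nrow(pixels) >= 1L)
  colnames(pixels) <- c("x", "y")
  b <- bbox(min(pixels[, "x"]), min(pixels[, "y"]),
            max(pixels[, "x"]) + 1, max(pixels[, "y"]) + 1)
  structure(list(pixels = pixels, bbox = b, area = nrow(pixels),
                 centroid = c(x = mean(pixels[, "x"]) + 0.5,
                              y = mean(pixels[, "y"]) + 0.5)),
            class = "conncomp")
}

#' @export
print.conncomp <- function(x, ...) {
  cat(sprintf("<conncomp area %d, bbox [%g,%g)x[%g,%g)>\n", x$area,
              x$bbox[["x0"]], x$bbox[["x1"]], x$bbox[["y0"]], x$bbox[["y1"]]))
  invisible(x)
}

# 8-connected labeling of a logical mask. Returns an integer matrix of the
# same shape: 0 = background, k = component id. Adjacency edges between
# foreground pixels are enumerated vectorially and the components resolved
# with igraph (EBImage::bwlabel is 4-connected, which would split shapes
# that touch only at corners, e.g. arrowheads meeting shafts diagonally).
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  lab[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  neigh <- function(dr, dc) {
    ok <- r + dr >= 1L & r + dr <= nr & cc + dc >= 1L & cc + dc <= nc
    j <- (cc[ok] + dc - 1L) * nr + (r[ok] + dr)
    keep <- mask[j]
    cbind(lab[idx[ok][keep]], lab[j[keep]])
  }
  edges <- rbind(neigh(0L, 1L), neigh(1L, 0L), neigh(1L, 1L), neigh(-1L, 1L))
  if (nrow(edges) == 0L) {
    memb <- seq_along(idx)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(g) < length(idx)) {
      g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
    }
    memb <- igraph::components(g)$membership
  }
  lab[idx] <- memb
  lab
}

#' Find 8-connected components
#'
#' Decomposes the foreground of a binary image into maximal 8-connected
#' components (diagonal adjacency counts, so arrowheads that touch shafts
#' corner-to-corner stay in one piece). Components are returned in reading
#' order (by bbox `y0`, then `x0`, then area) so that downstream tie-breaks
#' are reproducible.
#'
#' @param bin A [binary_image()].
#' @return A list of [conncomp()] objects; empty for a blank image.
#' @export
find_connected_components <- function(bin) {
  stopifnot(inherits(bin, "binary_image"))
  lab <- label_components8(bin$mask)
  k <- max(lab)
  if (k == 0L) return(list())
  idx <- which(lab > 0L)
  memb <- lab[idx]
  nr <- nrow(lab)
  xs <- ((idx - 1L) %/% nr)       # 0-based x
  ys <- ((idx - 1L) %% nr)        # 0-based y
  comps <- vector("list", k)
  ord <- order(memb)
  memb_s <- memb[ord]; xs_s <- xs[ord]; ys_s <- ys[ord]
  bounds <- c(0L, cumsum(tabulate(memb_s, nbins = k)))
  for (i in seq_len(k)) {
    sel <- (bounds[i] + 1L):bounds[i + 1L]
    comps[[i]] <- conncomp(cbind(x = xs_s[sel], y = ys_s[sel]))
  }
  key <- vapply(comps, function(cc)
    c(cc$bbox[["y0"]], cc$bbox[["x0"]], -cc$area), numeric(3))
  comps[order(key[1, ], key[2, ], key[3, ])]
}

# Paint a list of components into a fresh logical mask of given dims.
# Matrix is [height x width], column-major: pixel (x, y) -> x*height + y + 1.
mask_from_components <- function(comps, width, height) {
  m <- matrix(FALSE, height, width)
  for (cc in comps) {
    m[cc$pixels[, "x"] * height + cc$pixels[, "y"] + 1L] <- TRUE
  }
  m
}
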