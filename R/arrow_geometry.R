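# Arrow geometry: orientation, center of mass, curly-arrow endpoints and
# hook/end classification. These quantities decide which side of an arrow
# holds the reactants and which the products, and in which directions the
# step scan proceeds.

#' Fit an oriented frame to an arrow
#'
#' Fits a minimal rotated bounding rectangle to the arrow's pixels by a
#' least-squares (principal-axis) fit and computes the center of mass (COM)
#' of the foreground pixels. For solid, equilibrium and resonance arrows the
#' COM's offset from the rectangle center along the long axis marks the head
#' side: ink accumulates in the arrowhead, so the COM leans toward the
#' products. The returned unit `direction` points toward the head; when the
#' offset is negligible (symmetric arrow, no head) `head_side` is 0 (head
#' undetermined, direction sign arbitrary), otherwise 1 (the head lies along
#' `direction`). Equilibrium and resonance arrows are additionally flagged
#' `bidirectional`.
#'
#' @param arrow An [arrow_obj()] (needs >= 2 pixels).
#' @return Object of class `arrow_frame`: fields `id`, `center` (rotated
#'   rectangle center), `com`, `direction` (unit vector), `angle` (degrees in
#'   `[0, 180)`), `length`, `width`, `head_side` (+1 head along `direction`,
#'   0 undetermined), `bidirectional`, `bbox`, `subtype`, and (for curly
#'   arrows, after [classify_endpoints()]) `endpoints`, `ref_hook`,
#'   `ref_end`.
#' @export
fit_arrow_frame <- function(arrow) {
  stopifnot(inherits(arrow, "arrow"))
  P <- arrow$cc$pixels + 0.5   # pixel centers
  if (nrow(P) < 2) stop("degenerate arrow: fewer than 2 pixels")
  com <- colMeans(P)
  C <- stats::cov(P)
  e <- eigen(C, symmetric = TRUE)
  d1 <- e$vectors[, 1]
  d2 <- e$vectors[, 2]
  pd <- as.vector(P %*% d1)
  pn <- as.vector(P %*% d2)
  cd <- (max(pd) + min(pd)) / 2
  cn <- (max(pn) + min(pn)) / 2
  center <- cd * d1 + cn * d2
  len <- max(pd) - min(pd)
  wid <- max(pn) - min(pn)
  offset <- sum(com * d1) - cd
  tol <- 0.005 * max(len, 1)
  head_side <- if (abs(offset) <= tol) 0L else 1L
  dirv <- if (head_side == 0L) d1 else d1 * sign(offset)
  ang <- atan2(dirv[2], dirv[1]) * 180 / pi
  ang <- ang %% 180
  structure(list(id = arrow$id %||% NA_integer_,
                 center = c(x = unname(center[1]), y = unname(center[2])),
                 com = c(x = unname(com[1]), y = unname(com[2])),
                 direction = c(x = unname(dirv[1]), y = unname(dirv[2])),
                 angle = ang, length = len, width = wid,
                 head_side = head_side,
                 bidirectional = isTRUE(arrow$subtype %in%
                                          c("equilibrium", "resonance")),
                 bbox = arrow$cc$bbox, subtype = arrow$subtype,
                 endpoints = NULL, ref_hook = NULL, ref_end = NULL),
            class = "arrow_frame")
}

#' @export
print.arrow_frame <- function(x, ...) {
  cat(sprintf("<arrow_frame %s: angle %.1f deg, length %.1f, head_side %d%s>\n",
              x$subtype %||% "?", x$angle, x$length, x$head_side,
              if (x$bidirectional) ", bidirectional" else ""))
  invisible(x)
}

# probe rectangles along the four bbox sides; depth = f * other dimension
probe_regions <- function(b, f) {
  w <- bbox_width(b); h <- bbox_height(b)
  list(left = bbox(b[["x0"]], b[["y0"]], b[["x0"]] + f * w, b[["y1"]]),
       right = bbox(b[["x1"]] - f * w, b[["y0"]], b[["x1"]], b[["y1"]]),
       top = bbox(b[["x0"]], b[["y0"]], b[["x1"]], b[["y0"]] + f * h),
       bottom = bbox(b[["x0"]], b[["y0"]] + (1 - f) * h, b[["x1"]], b[["y1"]]))
}

pixels_in_box <- function(P, b) {
  P[, 1] >= b[["x0"]] & P[, 1] < b[["x1"]] &
    P[, 2] >= b[["y0"]] & P[, 2] < b[["y1"]]
}

count_components_of <- function(P, min_area = 1L) {
  if (nrow(P) == 0) return(0L)
  x <- P[, 1] - min(P[, 1]); y <- P[, 2] - min(P[, 2])
  m <- matrix(FALSE, max(y) + 1L, max(x) + 1L)
  m[x * nrow(m) + y + 1L] <- TRUE
  lab <- label_components8(m)
  sizes <- tabulate(lab[lab > 0L])
  sum(sizes >= min_area)
}

#' Locate the endpoints of a (curly) arrow
#'
#' Probes four shallow rectangles, one along each side of the arrow's
#' unrotated bounding box, with depth a fraction `f` of the perpendicular
#' box dimension; within each probe the arrow pixel closest to the probed
#' boundary is picked. Two filters follow. Stage 1 merges picks closer than
#' a merge radius (one physical arrow end can span two probes, e.g. in a
#' corner). Stage 2 removes picks that sit mid-arc rather than at a
#' terminus: the probe region's pixels are erased and if the arrow then
#' splits into two or more connected components, the pick was not an
#' endpoint (erasing around a true end never breaks the stroke).
#'
#' @param arrow An [arrow_obj()].
#' @param f Probe depth fraction of the perpendicular bbox dimension.
#' @param merge_radius Stage-1 merge radius; default
#'   `max(5, 0.2 * bbox diagonal)`.
#' @return Integer matrix of endpoint pixel coordinates (columns `x`, `y`),
#'   2 to 4 rows. Fewer than 2 survivors raises an error (unparseable
#'   arrow).
#' @export
find_arrow_endpoints <- function(arrow, f = 0.2, merge_radius = NULL) {
  stopifnot(inherits(arrow, "arrow"))
  P <- arrow$cc$pixels
  b <- arrow$cc$bbox
  diag_len <- sqrt(bbox_width(b)^2 + bbox_height(b)^2)
  # two probes picking the same strongly curved terminus can land up to
  # ~0.2 diagonals apart, so the merge radius must reach that far; distinct
  # termini sit about a full arrow length apart and stay separate
  merge_radius <- merge_radius %||% max(5, 0.2 * diag_len)
  probes <- probe_regions(b, f)
  picks <- list()
  for (side in names(probes)) {
    sel <- pixels_in_box(P, probes[[side]])
    if (!any(sel)) next
    Q <- P[sel, , drop = FALSE]
    o <- switch(side,
      left = order(Q[, 1], Q[, 2]),
      right = order(-Q[, 1], Q[, 2]),
      top = order(Q[, 2], Q[, 1]),
      bottom = order(-Q[, 2], Q[, 1]))
    p <- Q[o[1], ]
    extremality <- switch(side,
      left = p[1] - b[["x0"]], right = b[["x1"]] - 1 - p[1],
      top = p[2] - b[["y0"]], bottom = b[["y1"]] - 1 - p[2])
    picks[[side]] <- list(pt = p, side = side, ext = extremality)
  }
  if (length(picks) < 2) stop("unparseable arrow: fewer than 2 endpoint picks")
  # stage 1: merge near-coincident picks, keeping the most extremal one
  pts <- do.call(rbind, lapply(picks, function(p) p$pt))
  keep <- rep(TRUE, length(picks))
  ord <- order(vapply(picks, function(p) p$ext, numeric(1)))
  for (i in seq_along(ord)) {
    if (!keep[ord[i]]) next
    for (j in seq_along(ord)) {
      if (j <= i) next
      if (!keep[ord[j]]) next
      if (sqrt(sum((pts[ord[i], ] - pts[ord[j], ])^2)) < merge_radius) {
        keep[ord[j]] <- FALSE
      }
    }
  }
  picks <- picks[keep]
  # stage 2: erase the probed neighbourhood of each pick; removing pixels
  # around a true terminus leaves the arrow in one piece, removing a
  # mid-arc (or corner) region splits it in two. The window must swallow a
  # whole arrowhead (barbs included), hence the diagonal scaling; fragments
  # below 3 px are erasure crumbs, not components.
  r_erase <- max(merge_radius, 0.15 * diag_len)
  is_end <- vapply(picks, function(p) {
    inside <- abs(P[, 1] - p$pt[1]) <= r_erase &
      abs(P[, 2] - p$pt[2]) <= r_erase
    rest <- P[!inside, , drop = FALSE]
    if (nrow(rest) == 0) return(TRUE)
    n_comp <- count_components_of(rest, min_area = 3L)
    n_comp <= 1L
  }, logical(1))
  picks <- picks[is_end]
  if (length(picks) < 2) stop("unparseable arrow: fewer than 2 endpoints survive filtering")
  if (length(picks) > 4) picks <- picks[1:4]
  out <- do.call(rbind, lapply(picks, function(p) p$pt))
  colnames(out) <- c("x", "y")
  rownames(out) <- vapply(picks, function(p) p$side, character(1))
  out
}

#' Classify arrow endpoints as hooks or ends and pick the reference pair
#'
#' At each endpoint a straight line is fitted (least squares / principal
#' axis) to the arrow pixels within 15% of the arrow length, and the pixel
#' count per scan line perpendicular to that fit is recorded while moving
#' inward along the stroke over that fitted stretch. A near-constant count
#' (coefficient of variation below `cv_max`) marks a plain stroke terminus
#' (an "end"); a varying count marks an arrowhead (a "hook"). Among the
#' classified endpoints, the reference (hook, end) pair is the one with the
#' largest chemical diagrams nearby, encoding the assumption that each step
#' has a main reactant and product. Hooks point toward products.
#'
#' @param arrow An [arrow_obj()].
#' @param endpoints Matrix from [find_arrow_endpoints()].
#' @param diagrams Region data.frame of (completed) diagram regions; may be
#'   empty.
#' @param frame Optional [fit_arrow_frame()] result to update.
#' @param cv_max Coefficient-of-variation threshold for "approximately
#'   constant" scan-line counts.
#' @return The updated `arrow_frame` with fields `endpoints` (matrix),
#'   `endpoint_tags` (`"hook"`/`"end"`), `ref_hook`, `ref_end`. When all
#'   endpoints classify identically, frame-axis assignment is used as a
#'   fallback with a warning.
#' @export
classify_endpoints <- function(arrow, endpoints, diagrams = NULL,
                               frame = NULL, cv_max = 0.25) {
  stopifnot(inherits(arrow, "arrow"))
  if (is.null(frame)) frame <- fit_arrow_frame(arrow)
  P <- arrow$cc$pixels + 0.5
  L <- max(frame$length, 8)
  r_loc <- max(8, 0.15 * L)   # local enough that a curved stroke is straight
  tag_one <- function(e) {
    d2 <- (P[, 1] - e[1])^2 + (P[, 2] - e[2])^2
    local <- P[d2 <= r_loc^2, , drop = FALSE]
    if (nrow(local) < 4) return("end")
    ctr <- colMeans(local)
    u <- eigen(stats::cov(local), symmetric = TRUE)$vectors[, 1]
    if (sum((ctr - e) * u) < 0) u <- -u   # inward along the stroke
    proj <- as.vector(sweep(local, 2, e) %*% u)
    bw <- 2   # 2 px scan bins damp rasterization flicker on diagonal strokes
    S <- max(4, round(r_loc / bw))
    counts <- vapply(seq_len(S), function(s)
      sum(proj >= (s - 1) * bw & proj < s * bw), numeric(1))
    counts <- counts[counts > 0]
    if (length(counts) < 3) return("end")
    cv <- stats::sd(counts) / mean(counts)
    if (cv < cv_max) "end" else "hook"
  }
  tags <- apply(endpoints, 1, function(e) tag_one(as.numeric(e) + 0.5))
  frame$endpoints <- endpoints
  frame$endpoint_tags <- tags
  if (all(tags == "hook") || all(tags == "end")) {
    warning("all endpoints classified identically (", tags[1],
            "); falling back to frame-axis assignment")
    pd <- as.vector(sweep(endpoints + 0.5, 2, frame$center) %*% frame$direction)
    frame$ref_hook <- endpoints[which.max(pd), ]
    frame$ref_end <- endpoints[which.min(pd), ]
    return(frame)
  }
  nearby_area <- function(e) {
    if (is.null(diagrams) || nrow(diagrams) == 0) return(0)
    e <- unname(e)
    pb <- bbox(e[1], e[2], e[1] + 1, e[2] + 1)
    areas <- vapply(seq_len(nrow(diagrams)), function(j) {
      db <- bbox(diagrams$x0[j], diagrams$y0[j], diagrams$x1[j], diagrams$y1[j])
      if (separation(pb, db) < 1.5 * L) bbox_area(db) else 0
    }, numeric(1))
    max(areas, 0)
  }
  hooks <- which(tags == "hook")
  ends <- which(tags == "end")
  hk_area <- vapply(hooks, function(i) nearby_area(endpoints[i, ]), numeric(1))
  en_area <- vapply(ends, function(i) nearby_area(endpoints[i, ]), numeric(1))
  frame$ref_hook <- endpoints[hooks[which.max(hk_area)], ]
  frame$ref_end <- endpoints[ends[which.max(en_area)], ]
  frame
}

# Scan directions for a step: products toward the head/hook, reactants
# toward the tail/end.
scan_directions <- function(frame) {
  if (identical(frame$subtype, "curly") && !is.null(frame$ref_hook)) {
    mid <- bbox_center(frame$bbox)
    dp <- c(frame$ref_hook[1] - mid[["x"]], frame$ref_hook[2] - mid[["y"]])
    dr <- c(frame$ref_end[1] - mid[["x"]], frame$ref_end[2] - mid[["y"]])
    list(product = dp / sqrt(sum(dp^2)), reactant = dr / sqrt(sum(dr^2)))
  } else {
    d <- c(frame$direction[1], frame$direction[2])
    list(product = d, reactant = -d)
  }
}
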