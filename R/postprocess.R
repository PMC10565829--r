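# Symbolic postprocessing of raw detections: dilation-based diagram
# completion, text-region reclassification, and pairing of labels with
# diagrams and conditions with arrows.

#' Parameters of the conditions directionality criterion
#'
#' A text region counts as conditions (arrow-annotation) text when it lies
#' along the line normal to the arrow through the arrow's center: its offset
#' along the normal must be at most `max_normal` arrow lengths (how far
#' above/below a horizontal arrow the text may sit) and its offset along the
#' arrow axis at most `lateral_tol` arrow lengths (how far it may slide off
#' the arrow's midpoint).
#'
#' @param max_normal Maximum normal offset, in units of arrow length.
#' @param lateral_tol Maximum along-axis offset, in units of arrow length.
#' @return Named list of class `directionality_params`.
#' @export
directionality_params <- function(max_normal = 1.0, lateral_tol = 0.6) {
  stopifnot(max_normal > 0, lateral_tol > 0)
  structure(list(max_normal = max_normal, lateral_tol = lateral_tol),
            class = "directionality_params")
}

#' Complete a diagram detection by local dilation
#'
#' Chemical diagrams contain signal discontinuities (detached superatom
#' groups, charges); a raw detection box may clip them or include spurious
#' margin. Completion takes the largest connected component overlapping the
#' raw box, dilates it with a disk kernel whose radius is computed locally
#' (a multiple `c` of the median nearest-neighbour gap between the
#' components inside the raw box, clamped to `[r_min, 0.05 * image
#' diagonal]`), assigns every component intersecting the dilated mask to
#' the diagram, and refits the box to the union. Regions already marked
#' `postprocessed` are returned unchanged, which makes the operation
#' idempotent.
#'
#' @param region One-row region data.frame (class `diagram`).
#' @param bin The scheme's [binary_image()].
#' @param ccs Components from [find_connected_components()].
#' @param c_gap Kernel multiplier on the median component gap.
#' @param r_min Minimum kernel radius (px).
#' @return The region row with a refitted box and provenance
#'   `"postprocessed"`; unchanged (with a warning) when no component
#'   overlaps the box.
#' @export
complete_diagram <- function(region, bin, ccs, c_gap = 1.2, r_min = 3) {
  stopifnot(nrow(region) == 1, region$class == "diagram")
  if (identical(region$provenance, "postprocessed")) return(region)
  rb <- bbox(region$x0, region$y0, region$x1, region$y1)
  inside <- Filter(function(cc) bbox_intersects(cc$bbox, rb), ccs)
  if (length(inside) == 0) {
    warning("no connected component overlaps diagram region ", region$id)
    return(region)
  }
  areas <- vapply(inside, function(cc) cc$area, numeric(1))
  seedcc <- inside[[which.max(areas)]]
  # local kernel radius from the gaps between components in the raw box
  r_max <- 0.05 * sqrt(bin$width^2 + bin$height^2)
  if (length(inside) >= 2) {
    gaps <- vapply(seq_along(inside), function(i) {
      min(vapply(seq_along(inside)[-i], function(j)
        separation(inside[[i]]$bbox, inside[[j]]$bbox), numeric(1)))
    }, numeric(1))
    r <- c_gap * stats::median(gaps)
  } else {
    r <- r_min
  }
  r <- max(r_min, min(r, r_max))
  # dilate the seed component in a local window and collect what it touches
  win <- bbox(max(0, seedcc$bbox[["x0"]] - 2 * r - 2),
              max(0, seedcc$bbox[["y0"]] - 2 * r - 2),
              min(bin$width, seedcc$bbox[["x1"]] + 2 * r + 2),
              min(bin$height, seedcc$bbox[["y1"]] + 2 * r + 2))
  ww <- as.integer(win[["x1"]] - win[["x0"]])
  wh <- as.integer(win[["y1"]] - win[["y0"]])
  local <- matrix(FALSE, wh, ww)
  px <- seedcc$pixels[, "x"] - as.integer(win[["x0"]])
  py <- seedcc$pixels[, "y"] - as.integer(win[["y0"]])
  local[px * wh + py + 1L] <- TRUE
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(r)) + 1L, "disc")
  dil <- t(EBImage::imageData(EBImage::dilate(EBImage::Image(t(local * 1)),
                                              brush))) > 0.5
  touches <- function(cc) {
    sel <- cc$pixels[, "x"] >= win[["x0"]] & cc$pixels[, "x"] < win[["x1"]] &
      cc$pixels[, "y"] >= win[["y0"]] & cc$pixels[, "y"] < win[["y1"]]
    if (!any(sel)) return(FALSE)
    qx <- cc$pixels[sel, "x"] - as.integer(win[["x0"]])
    qy <- cc$pixels[sel, "y"] - as.integer(win[["y0"]])
    any(dil[qx * wh + qy + 1L])
  }
  members <- Filter(touches, ccs)
  newb <- bbox_union(lapply(members, function(cc) cc$bbox))
  region$x0 <- newb[["x0"]]; region$y0 <- newb[["y0"]]
  region$x1 <- newb[["x1"]]; region$y1 <- newb[["y1"]]
  region$provenance <- "postprocessed"
  region
}

# "below this diagram": region center below the diagram's bottom edge and
# horizontal overlap of at least 25% of the narrower box.
is_below_diagram <- function(region_box, diagram_box) {
  ctr <- bbox_center(region_box)
  if (ctr[["y"]] <= diagram_box[["y1"]]) return(FALSE)
  overlap <- min(region_box[["x1"]], diagram_box[["x1"]]) -
    max(region_box[["x0"]], diagram_box[["x0"]])
  narrower <- min(bbox_width(region_box), bbox_width(diagram_box))
  overlap >= 0.25 * narrower
}

# distance from a box to an arrow: minimal distance between the arrow's
# axis segment and the box (a diagonal arrow's axis-aligned bounding box
# would grossly understate this). Falls back to box separation when no
# frame geometry is available.
arrow_separation <- function(region_box, fr, k = 48) {
  if (is.null(fr$center) || is.null(fr$direction)) {
    return(separation(region_box, fr$bbox))
  }
  d <- c(fr$direction[1], fr$direction[2])
  m <- c(fr$center[1], fr$center[2])
  tt <- seq(-fr$length / 2, fr$length / 2, length.out = k)
  px <- m[1] + tt * d[1]
  py <- m[2] + tt * d[2]
  dx <- pmax(0, region_box[["x0"]] - px, px - region_box[["x1"]])
  dy <- pmax(0, region_box[["y0"]] - py, py - region_box[["y1"]])
  min(sqrt(dx^2 + dy^2))
}

# directionality criterion of a region w.r.t. an arrow frame
satisfies_directionality <- function(region_box, frame, params) {
  ctr <- bbox_center(region_box)
  m <- frame$center
  d <- c(frame$direction[1], frame$direction[2])
  nv <- c(-d[2], d[1])
  v <- c(ctr[["x"]] - m[["x"]], ctr[["y"]] - m[["y"]])
  L <- max(frame$length, 1)
  abs(sum(v * nv)) <= params$max_normal * L &&
    abs(sum(v * d)) <= params$lateral_tol * L
}

#' Reclassify a text region as label or conditions
#'
#' Finds the closest chemical diagram and the closest reaction arrow (by
#' box [separation()]). If the diagram is closer and the region lies below
#' that diagram, the class becomes `label`; if the arrow is closer and the
#' region satisfies the directionality criterion with respect to it, the
#' class becomes `conditions`; otherwise the prior class is kept. At exactly
#' equal separations the diagram wins (documented tie-break). Regions are
#' never created or deleted: only `class` and `provenance` change.
#'
#' @param region One-row region data.frame with class `label` or
#'   `conditions`.
#' @param diagrams Region data.frame of diagrams (completed where
#'   possible).
#' @param arrows List of `arrow_frame` objects (or a data.frame of arrow
#'   boxes plus a parallel list of frames).
#' @param params [directionality_params()].
#' @return The region row, possibly with updated class and provenance
#'   `"postprocessed"`.
#' @export
reclassify_text_region <- function(region, diagrams, arrows,
                                   params = directionality_params()) {
  stopifnot(nrow(region) == 1, region$class %in% c("label", "conditions"))
  rb <- bbox(region$x0, region$y0, region$x1, region$y1)
  if ((is.null(diagrams) || nrow(diagrams) == 0) && length(arrows) == 0) {
    warning("no diagrams and no arrows present; keeping prior class")
    return(region)
  }
  d_diag <- Inf; nearest_diag <- NULL
  if (!is.null(diagrams) && nrow(diagrams)) {
    ds <- vapply(seq_len(nrow(diagrams)), function(i)
      separation(rb, bbox(diagrams$x0[i], diagrams$y0[i],
                          diagrams$x1[i], diagrams$y1[i])), numeric(1))
    d_diag <- min(ds)
    i <- order(ds, diagrams$y0, diagrams$x0)[1]   # reading-order tie-break
    nearest_diag <- bbox(diagrams$x0[i], diagrams$y0[i],
                         diagrams$x1[i], diagrams$y1[i])
  }
  d_arr <- Inf; nearest_frame <- NULL
  if (length(arrows)) {
    ds <- vapply(arrows, function(fr) arrow_separation(rb, fr), numeric(1))
    d_arr <- min(ds)
    nearest_frame <- arrows[[which.min(ds)]]
  }
  new_class <- region$class
  if (d_diag <= d_arr && !is.null(nearest_diag)) {      # tie: diagram wins
    if (is_below_diagram(rb, nearest_diag)) new_class <- "label"
  } else if (!is.null(nearest_frame)) {
    if (satisfies_directionality(rb, nearest_frame, params)) {
      new_class <- "conditions"
    }
  }
  if (!identical(new_class, region$class)) {
    region$class <- new_class
    region$provenance <- "postprocessed"
  }
  region
}

#' Pair labels with diagrams and conditions with arrows
#'
#' Each label is paired with its nearest diagram and each conditions region
#' with its nearest arrow (minimum [separation()]; reading-order tie-break;
#' many-to-one pairings are permitted). Diagrams whose completed box lies
#' inside a conditions region are additionally attached to that conditions
#' record (chemical diagrams can appear above an arrow as reagents).
#'
#' @param regions Region data.frame containing final classes.
#' @param arrows List of `arrow_frame`s or a data.frame with arrow `id` and
#'   box columns.
#' @return List with named integer vectors `label_of` (label id ->
#'   diagram id), `conditions_of` (conditions id -> arrow id) and
#'   `diagrams_of_conditions` (diagram id -> conditions id).
#' @export
pair_regions <- function(regions, arrows) {
  diagrams <- regions[regions$class == "diagram", , drop = FALSE]
  labels <- regions[regions$class == "label", , drop = FALSE]
  conds <- regions[regions$class == "conditions", , drop = FALSE]
  arrow_boxes <- if (is.data.frame(arrows)) {
    lapply(seq_len(nrow(arrows)), function(i)
      list(id = arrows$id[i],
           box = bbox(arrows$x0[i], arrows$y0[i], arrows$x1[i], arrows$y1[i])))
  } else {
    lapply(arrows, function(fr) list(id = fr$id, box = fr$bbox, frame = fr))
  }
  label_of <- integer(0)
  for (i in seq_len(nrow(labels))) {
    if (nrow(diagrams) == 0) break
    lb <- bbox(labels$x0[i], labels$y0[i], labels$x1[i], labels$y1[i])
    ds <- vapply(seq_len(nrow(diagrams)), function(j)
      separation(lb, bbox(diagrams$x0[j], diagrams$y0[j],
                          diagrams$x1[j], diagrams$y1[j])), numeric(1))
    j <- order(ds, diagrams$y0, diagrams$x0)[1]
    label_of[as.character(labels$id[i])] <- diagrams$id[j]
  }
  conditions_of <- integer(0)
  for (i in seq_len(nrow(conds))) {
    if (length(arrow_boxes) == 0) break
    cb <- bbox(conds$x0[i], conds$y0[i], conds$x1[i], conds$y1[i])
    ds <- vapply(arrow_boxes, function(ab) {
      if (!is.null(ab$frame)) arrow_separation(cb, ab$frame)
      else separation(cb, ab$box)
    }, numeric(1))
    conditions_of[as.character(conds$id[i])] <-
      arrow_boxes[[which.min(ds)]]$id
  }
  diagrams_of_conditions <- integer(0)
  for (j in seq_len(nrow(diagrams))) {
    for (i in seq_len(nrow(conds))) {
      cb <- bbox(conds$x0[i], conds$y0[i], conds$x1[i], conds$y1[i])
      db <- bbox(diagrams$x0[j], diagrams$y0[j], diagrams$x1[j], diagrams$y1[j])
      if (db[["x0"]] >= cb[["x0"]] && db[["x1"]] <= cb[["x1"]] &&
          db[["y0"]] >= cb[["y0"]] && db[["y1"]] <= cb[["y1"]]) {
        diagrams_of_conditions[as.character(diagrams$id[j])] <- conds$id[i]
      }
    }
  }
  list(label_of = label_of, conditions_of = conditions_of,
       diagrams_of_conditions = diagrams_of_conditions)
}
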