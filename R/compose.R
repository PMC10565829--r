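# Schema-driven composition of artificial reaction schemes.
#
# A schema fixes the global layout (linear chain of steps, or a cycle), the
# number of steps, how many diagrams appear per diagram group, and the
# probabilities that diagrams carry labels and arrows carry conditions text.
# Elements are drawn from an element bank, augmented, and placed on a blank
# canvas; the composer records a complete ground-truth annotation (region
# boxes and classes, label/conditions pairings, arrow tail/tip points, and
# the reaction graph) alongside the rendered image.

#' Schema for artificial scheme composition
#'
#' @param layout `"linear"` (steps along horizontal rows, reading order) or
#'   `"cyclic"` (steps arranged around a ring, as in a catalytic cycle).
#' @param n_steps Number of reaction steps (>= 1).
#' @param diagrams_per_step Length-2 integer range for the number of diagrams
#'   in each diagram group (side reactants/products beyond the first are
#'   separated by plus signs).
#' @param p_label Probability that a diagram receives a chemical label
#'   (placed below it).
#' @param p_conditions Probability that an arrow receives a conditions text
#'   block (placed above or below it, within 0.15-0.6 arrow lengths of the
#'   arrow midpoint so the directionality criterion holds by construction).
#' @param n_negatives Length-2 integer range of decoy symbols (plus signs,
#'   brackets) scattered in free space.
#' @param arrow_types Character vector of arrow subtypes to sample from
#'   (uniformly); default solid only.
#' @param canvas Optional `c(width, height)` in pixels. `NULL` (default)
#'   auto-sizes the canvas to the content; a fixed canvas is validated and a
#'   composition that cannot fit raises an error naming the constraint.
#' @param max_width Optional maximum content width; a linear chain longer
#'   than this wraps onto further rows (an arrow starts the continuation
#'   row, its reactants being the last diagram group of the previous row).
#' @param augment Named list of augmentation bounds forwarded to
#'   [augment_glyph()] for diagram/text glyphs.
#' @return An object of class `schema_spec`.
#' @export
schema_spec <- function(layout = c("linear", "cyclic"), n_steps = 2,
                        diagrams_per_step = c(1, 2), p_label = 0.5,
                        p_conditions = 0.5, n_negatives = c(0, 2),
                        arrow_types = "solid", canvas = NULL,
                        max_width = NULL,
                        augment = list(scale = c(0.9, 1.1), rotate = c(-2, 2),
                                       p_blur = 0.15)) {
  layout <- match.arg(layout)
  if (length(diagrams_per_step) == 1) diagrams_per_step <- rep(diagrams_per_step, 2)
  if (length(n_negatives) == 1) n_negatives <- rep(n_negatives, 2)
  stopifnot(n_steps >= 1, p_label >= 0, p_label <= 1,
            p_conditions >= 0, p_conditions <= 1,
            diagrams_per_step[1] >= 1, diagrams_per_step[2] >= diagrams_per_step[1],
            n_negatives[1] >= 0, n_negatives[2] >= n_negatives[1],
            all(arrow_types %in% c("solid", "curly", "equilibrium", "resonance")))
  structure(list(layout = layout, n_steps = n_steps,
                 diagrams_per_step = diagrams_per_step, p_label = p_label,
                 p_conditions = p_conditions, n_negatives = n_negatives,
                 arrow_types = arrow_types, canvas = canvas,
                 max_width = max_width, augment = augment),
            class = "schema_spec")
}

#' @export
print.schema_spec <- function(x, ...) {
  cat(sprintf("<schema_spec %s, %d step(s), %d-%d diagrams/group, p_label=%g, p_conditions=%g>\n",
              x$layout, x$n_steps, x$diagrams_per_step[1], x$diagrams_per_step[2],
              x$p_label, x$p_conditions))
  invisible(x)
}

# placement record collector used internally by the composer
new_placer <- function() {
  env <- new.env(parent = emptyenv())
  env$items <- list()   # list(glyph mask, x0, y0, class, subtype, extra)
  env$boxes <- list()   # placed bboxes for overlap checks
  env
}

placer_add <- function(pl, mask, x0, y0, class, subtype = NA_character_,
                       extra = list()) {
  x0 <- round(x0); y0 <- round(y0)
  b <- bbox(x0, y0, x0 + ncol(mask), y0 + nrow(mask))
  pl$items[[length(pl$items) + 1L]] <-
    list(mask = mask, x0 = x0, y0 = y0, class = class, subtype = subtype,
         box = b, extra = extra)
  pl$boxes[[length(pl$boxes) + 1L]] <- b
  length(pl$items)
}

placer_clear_of <- function(pl, x0, y0, w, h, margin = 4) {
  cand <- bbox(round(x0), round(y0), round(x0) + w, round(y0) + h)
  for (it in pl$items) {
    if (it$class == "arrow") {
      # a rotated arrow's axis-aligned box is much larger than its ink;
      # test clearance against the actual pixels instead
      if (separation(cand, it$box) >= margin) next
      px <- which(it$mask, arr.ind = TRUE)
      gx <- it$x0 + px[, 2] - 1L
      gy <- it$y0 + px[, 1] - 1L
      hit <- gx >= cand[["x0"]] - margin & gx < cand[["x1"]] + margin &
        gy >= cand[["y0"]] - margin & gy < cand[["y1"]] + margin
      if (any(hit)) return(FALSE)
    } else {
      if (separation(cand, it$box) < margin) return(FALSE)
    }
  }
  TRUE
}

pick_aug <- function(bank, class, schema) {
  g <- bank[[class]][[sample(length(bank[[class]]), 1)]]
  do.call(augment_glyph, c(list(glyph = g), schema$augment))
}

# Place one diagram group horizontally, top-aligned on centerline y_mid.
# Returns list(ids, x_end).
place_group <- function(pl, bank, schema, n_diag, x, y_mid, plus_glyphs) {
  ids <- integer(0)
  for (j in seq_len(n_diag)) {
    g <- pick_aug(bank, "diagram", schema)
    id <- placer_add(pl, glyph_mask(g), x, y_mid - nrow(g) / 2, "diagram")
    ids <- c(ids, id)
    x <- x + ncol(g)
    if (j < n_diag) {
      plus <- plus_glyphs[[sample(length(plus_glyphs), 1)]]
      x <- x + 10
      placer_add(pl, glyph_mask(plus), x, y_mid - nrow(plus) / 2, "negative")
      x <- x + ncol(plus) + 10
    }
  }
  list(ids = ids, x_end = x)
}

# Labels below diagrams; conditions near arrows. Shared by both layouts.
place_labels <- function(pl, bank, schema, diagram_ids, strict = TRUE) {
  label_of <- integer(0)
  for (id in diagram_ids) {
    if (stats::runif(1) >= schema$p_label) next
    g <- pick_aug(bank, "label", schema)
    db <- pl$items[[id]]$box
    placed <- NA_integer_
    gap0 <- runif1(4, 8); dx0 <- runif1(-3, 3)
    for (gap in c(gap0, 4, 6, 8, 11)) {
      for (dx in c(dx0, 0, -6, 6, -12, 12)) {
        x0 <- bbox_center(db)[["x"]] - ncol(g) / 2 + dx
        y0 <- db[["y1"]] + gap
        if (placer_clear_of(pl, x0, y0, ncol(g), nrow(g))) {
          placed <- placer_add(pl, glyph_mask(g), x0, y0, "label")
          break
        }
      }
      if (!is.na(placed)) break
    }
    if (is.na(placed)) {
      if (strict) {
        stop("canvas overflow: label placement collides below diagram ", id)
      }
      next   # ring layouts: a crowded diagram goes unlabelled
    }
    label_of[as.character(placed)] <- id
  }
  label_of
}

place_conditions_for <- function(pl, bank, schema, arrow_id) {
  item <- pl$items[[arrow_id]]
  L <- sqrt(sum((item$extra$tip - item$extra$tail)^2))
  mid <- (item$extra$tip + item$extra$tail) / 2
  d <- c(item$extra$tip - item$extra$tail) / L
  nrm <- c(-d[2], d[1])
  g <- pick_aug(bank, "conditions", schema)
  try_at <- function(side, dist) {
    ctr <- mid + side * dist * nrm
    x0 <- ctr[1] - ncol(g) / 2; y0 <- ctr[2] - nrow(g) / 2
    if (placer_clear_of(pl, x0, y0, ncol(g), nrow(g))) {
      placer_add(pl, glyph_mask(g), x0, y0, "conditions")
    } else NA_integer_
  }
  for (attempt in 1:20) {
    id <- try_at(if (stats::runif(1) < 0.5) -1 else 1, runif1(0.15, 0.6) * L)
    if (!is.na(id)) return(id)
  }
  # deterministic sweep over the allowed band before giving up
  for (side in c(1, -1)) {
    for (dist in seq(0.15, 0.6, by = 0.05) * L) {
      id <- try_at(side, dist)
      if (!is.na(id)) return(id)
    }
  }
  stop("canvas overflow: conditions placement collides near arrow ", arrow_id)
}

place_negatives <- function(pl, bank, schema) {
  if (length(bank$negative) == 0) return(invisible(NULL))
  n <- sample(schema$n_negatives[1]:schema$n_negatives[2], 1)
  if (n == 0) return(invisible(NULL))
  all_box <- bbox_union(pl$boxes)
  for (k in seq_len(n)) {
    g <- bank$negative[[sample(length(bank$negative), 1)]]
    ok <- FALSE
    for (attempt in 1:40) {
      x0 <- runif1(all_box[["x0"]], all_box[["x1"]] - ncol(g))
      y0 <- if (stats::runif(1) < 0.5) all_box[["y0"]] - nrow(g) - runif1(6, 20)
            else all_box[["y1"]] + runif1(6, 20)
      if (placer_clear_of(pl, x0, y0, ncol(g), nrow(g), margin = 6)) {
        placer_add(pl, glyph_mask(g), x0, y0, "negative")
        ok <- TRUE
        break
      }
    }
    if (!ok) next  # decoys are best-effort; skip rather than fail
  }
  invisible(NULL)
}

sample_arrow <- function(bank, schema, len = NULL, angle = 0) {
  st <- if (length(schema$arrow_types) == 1) schema$arrow_types
        else sample(schema$arrow_types, 1)
  base <- bank$arrow[[st]][[sample(length(bank$arrow[[st]]), 1)]]
  spec <- attr(base, "spec")
  render_arrow(st, len = len %||% (spec$len * runif1(0.95, 1.05)),
               thickness = spec$thickness, angle = angle,
               head_len = spec$head_len, head_w = spec$head_w)
}

compose_linear <- function(schema, bank) {
  pl <- new_placer()
  plus_glyphs <- Filter(function(g) identical(attr(g, "kind"), "plus"), bank$negative)
  if (length(plus_glyphs) == 0) plus_glyphs <- list(render_negative_glyph("plus"))
  n_groups <- schema$n_steps + 1L
  group_sizes <- sample(schema$diagrams_per_step[1]:schema$diagrams_per_step[2],
                        n_groups, replace = TRUE)
  wrap_w <- schema$max_width %||% (if (!is.null(schema$canvas)) schema$canvas[1] - 24 else Inf)
  row_h <- 195
  margin <- 16
  x <- margin; y_mid <- row_h / 2
  groups <- vector("list", n_groups)
  arrow_ids <- integer(schema$n_steps)
  g0 <- place_group(pl, bank, schema, group_sizes[1], x, y_mid, plus_glyphs)
  groups[[1]] <- g0$ids
  x <- g0$x_end
  for (s in seq_len(schema$n_steps)) {
    arr <- sample_arrow(bank, schema, angle = runif1(-2, 2))
    need <- 20 + ncol(arr) + 20 + 100   # arrow + gaps + minimal next group
    if (x + need > wrap_w) {            # wrap: arrow starts the next row
      y_mid <- y_mid + row_h
      x <- margin
    }
    x <- x + runif1(16, 26)
    tail_tip <- list(tail = c(attr(arr, "tail")[1], attr(arr, "tail")[2]),
                     tip = c(attr(arr, "tip")[1], attr(arr, "tip")[2]))
    ax0 <- x; ay0 <- y_mid - nrow(arr) / 2
    aid <- placer_add(pl, glyph_mask(arr), ax0, ay0, "arrow",
                      subtype = attr(arr, "subtype"),
                      extra = list(tail = tail_tip$tail + c(round(ax0), round(ay0)),
                                   tip = tail_tip$tip + c(round(ax0), round(ay0))))
    arrow_ids[s] <- aid
    x <- x + ncol(arr) + runif1(16, 26)
    gg <- place_group(pl, bank, schema, group_sizes[s + 1], x, y_mid, plus_glyphs)
    groups[[s + 1]] <- gg$ids
    x <- gg$x_end
  }
  steps <- lapply(seq_len(schema$n_steps), function(s) {
    list(arrow = arrow_ids[s], reactants = groups[[s]],
         products = groups[[s + 1]], conditions = integer(0))
  })
  list(pl = pl, steps = steps, diagram_ids = unlist(groups),
       arrow_ids = arrow_ids)
}

compose_cyclic <- function(schema, bank) {
  pl <- new_placer()
  n <- schema$n_steps
  stopifnot(n >= 3)
  diam <- mean(attr(bank, "config")$diagram_size)
  R <- max(180, n * (diam + 110) / (2 * pi) * 1.7)
  cx <- R + 140; cy <- R + 140
  th <- -pi / 2 + (seq_len(n) - 1) * 2 * pi / n
  centers <- cbind(cx + R * cos(th), cy + R * sin(th))
  diag_ids <- integer(n)
  half <- numeric(n)
  glyphs <- vector("list", n)
  for (k in seq_len(n)) {
    g <- pick_aug(bank, "diagram", schema)
    glyphs[[k]] <- g
    half[k] <- sqrt(ncol(g)^2 + nrow(g)^2) / 2
    diag_ids[k] <- placer_add(pl, glyph_mask(g),
                              centers[k, 1] - ncol(g) / 2,
                              centers[k, 2] - nrow(g) / 2, "diagram")
  }
  arrow_ids <- integer(n)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    chord <- centers[k2, ] - centers[k, ]
    clen <- sqrt(sum(chord^2))
    u <- chord / clen
    tail <- centers[k, ] + u * (half[k] + 14)
    tip <- centers[k2, ] - u * (half[k2] + 14)
    alen <- sqrt(sum((tip - tail)^2))
    if (alen < 28) stop("canvas overflow: cyclic ring too tight for arrows")
    ang <- atan2(u[2], u[1]) * 180 / pi
    arr <- sample_arrow(bank, schema, len = alen, angle = ang)
    # position the glyph so its recorded tail lands on the computed tail
    gx0 <- tail[1] - attr(arr, "tail")[1]
    gy0 <- tail[2] - attr(arr, "tail")[2]
    aid <- placer_add(pl, glyph_mask(arr), gx0, gy0, "arrow",
                      subtype = attr(arr, "subtype"),
                      extra = list(tail = attr(arr, "tail") + c(round(gx0), round(gy0)),
                                   tip = attr(arr, "tip") + c(round(gx0), round(gy0))))
    arrow_ids[k] <- aid
  }
  steps <- lapply(seq_len(n), function(k) {
    k2 <- if (k == n) 1L else k + 1L
    list(arrow = arrow_ids[k], reactants = diag_ids[k],
         products = diag_ids[k2], conditions = integer(0))
  })
  list(pl = pl, steps = steps, diagram_ids = diag_ids, arrow_ids = arrow_ids)
}

#' Compose one artificial reaction scheme
#'
#' Renders a scheme image following `schema` from the glyphs in `bank`, and
#' returns it together with its full ground-truth annotation: every element's
#' bounding box and class (diagram / label / conditions / arrow, plus
#' unclassed negative decoys), the label-to-diagram and conditions-to-arrow
#' pairings, the arrows' tail/tip points, and the reaction graph the scheme
#' depicts. Deterministic for fixed `(schema, bank, seed)`.
#'
#' @param schema A [schema_spec()].
#' @param bank An [build_element_bank()] element bank.
#' @param seed Integer seed.
#' @return A list with components `image` (numeric matrix, 1 = white paper,
#'   0 = ink) and `annotation` (class `scheme_annotation`; see Details).
#'
#' @details The `scheme_annotation` is a list with fields
#' \describe{
#'   \item{regions}{data.frame `id, class, subtype, x0, y0, x1, y1`.}
#'   \item{arrows}{data.frame of arrow ground truth: `id, subtype,
#'     tail_x, tail_y, tip_x, tip_y` (tail = reactant side, tip = product
#'     side).}
#'   \item{pairings}{list `label_of`, `conditions_of`: named integer vectors
#'     keyed by region id.}
#'   \item{graph}{the ground-truth [reaction_graph()].}
#' }
#' @export
compose_scheme <- function(schema, bank, seed = 1) {
  stopifnot(inherits(schema, "schema_spec"), inherits(bank, "element_bank"))
  if (schema$layout == "cyclic" && schema$n_steps < 3) {
    stop("cyclic layout needs n_steps >= 3")
  }
  with_seed(seed, {
    res <- if (schema$layout == "linear") compose_linear(schema, bank)
           else compose_cyclic(schema, bank)
    pl <- res$pl
    label_of <- place_labels(pl, bank, schema, res$diagram_ids,
                             strict = schema$layout == "linear")
    conditions_of <- integer(0)
    for (s in seq_along(res$steps)) {
      if (stats::runif(1) < schema$p_conditions) {
        cid <- place_conditions_for(pl, bank, schema, res$steps[[s]]$arrow)
        conditions_of[as.character(cid)] <- res$steps[[s]]$arrow
        res$steps[[s]]$conditions <- cid
      }
    }
    place_negatives(pl, bank, schema)

    # canvas: shift content to a margin, or validate the requested canvas
    content <- bbox_union(pl$boxes)
    pad <- 14
    if (is.null(schema$canvas)) {
      W <- ceiling(bbox_width(content)) + 2 * pad
      H <- ceiling(bbox_height(content)) + 2 * pad
      dx <- pad - content[["x0"]]; dy <- pad - content[["y0"]]
    } else {
      W <- schema$canvas[1]; H <- schema$canvas[2]
      if (bbox_width(content) + 2 * pad > W || bbox_height(content) + 2 * pad > H) {
        stop("canvas overflow: content ",
             ceiling(bbox_width(content)), "x", ceiling(bbox_height(content)),
             " does not fit canvas ", W, "x", H)
      }
      dx <- pad - content[["x0"]]; dy <- pad - content[["y0"]]
    }
    dx <- round(dx); dy <- round(dy)
    canvas <- matrix(1, H, W)
    rows <- list()
    arrows_df <- NULL
    for (i in seq_along(pl$items)) {
      it <- pl$items[[i]]
      x0 <- it$x0 + dx; y0 <- it$y0 + dy
      canvas[(y0 + 1):(y0 + nrow(it$mask)), (x0 + 1):(x0 + ncol(it$mask))] <-
        ifelse(it$mask, 0,
               canvas[(y0 + 1):(y0 + nrow(it$mask)), (x0 + 1):(x0 + ncol(it$mask))])
      rows[[i]] <- data.frame(id = i, class = it$class, subtype = it$subtype,
                              x0 = x0, y0 = y0, x1 = x0 + ncol(it$mask),
                              y1 = y0 + nrow(it$mask))
      if (it$class == "arrow") {
        arrows_df <- rbind(arrows_df, data.frame(
          id = i, subtype = it$subtype,
          tail_x = it$extra$tail[1] + dx, tail_y = it$extra$tail[2] + dy,
          tip_x = it$extra$tip[1] + dx, tip_y = it$extra$tip[2] + dy))
      }
    }
    regions <- do.call(rbind, rows)
    graph <- reaction_graph(
      nodes = regions[regions$class == "diagram",
                      c("id", "x0", "y0", "x1", "y1")],
      steps = res$steps)
    ann <- structure(list(regions = regions, arrows = arrows_df,
                          pairings = list(label_of = label_of,
                                          conditions_of = conditions_of),
                          graph = graph),
                     class = "scheme_annotation")
    list(image = canvas, annotation = ann)
  })
}

#' @export
print.scheme_annotation <- function(x, ...) {
  tab <- table(x$regions$class)
  cat("<scheme_annotation: ",
      paste(names(tab), tab, sep = "=", collapse = ", "),
      "; ", length(x$graph$steps), " step(s)>\n", sep = "")
  invisible(x)
}
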