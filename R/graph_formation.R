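# Reaction-graph container, step scanning around arrows, and step stitching.

#' Reaction graph container
#'
#' A reaction graph holds diagram nodes (with their boxes and optional
#' decoded text/structure fields) and reaction steps: directed edges from a
#' reactant diagram group to a product diagram group via one arrow, with
#' optional conditions regions attached. Catalytic cycles are legal graphs.
#'
#' @param nodes data.frame with columns `id, x0, y0, x1, y1` and optionally
#'   `label_text`, `smiles`.
#' @param steps List of steps; each a list with fields `arrow` (arrow region
#'   id), `reactants`, `products` (integer vectors of node ids) and
#'   `conditions` (integer vector, possibly empty).
#' @return An object of class `reaction_graph`.
#' @export
reaction_graph <- function(nodes = data.frame(id = integer(), x0 = numeric(),
                                              y0 = numeric(), x1 = numeric(),
                                              y1 = numeric()),
                           steps = list()) {
  stopifnot(is.data.frame(nodes),
            all(c("id", "x0", "y0", "x1", "y1") %in% names(nodes)))
  if (!"label_text" %in% names(nodes)) {
    nodes$label_text <- rep(NA_character_, nrow(nodes))
  }
  if (!"smiles" %in% names(nodes)) {
    nodes$smiles <- rep(NA_character_, nrow(nodes))
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  arrow_ids <- vapply(steps, function(s) as.integer(s$arrow[1]), integer(1))
  if (anyDuplicated(arrow_ids)) stop("duplicate arrow ids across steps")
  steps <- lapply(steps, function(s) {
    s$arrow <- as.integer(s$arrow)
    s$reactants <- sort(as.integer(s$reactants))
    s$products <- sort(as.integer(s$products))
    s$conditions <- sort(as.integer(s$conditions %||% integer(0)))
    if (length(intersect(s$reactants, s$products))) {
      stop("step ", s$arrow, ": reactant and product sets overlap")
    }
    ref <- c(s$reactants, s$products)
    if (!all(ref %in% nodes$id)) {
      stop("step ", s$arrow, " references unknown node id(s): ",
           paste(setdiff(ref, nodes$id), collapse = ", "))
    }
    s
  })
  structure(list(nodes = nodes, steps = steps), class = "reaction_graph")
}

#' @export
print.reaction_graph <- function(x, ...) {
  cat(sprintf("<reaction_graph: %d node(s), %d step(s)>\n",
              nrow(x$nodes), length(x$steps)))
  for (s in x$steps) {
    cat(sprintf("  [arrow %d] {%s} -> {%s}%s\n", s$arrow,
                paste(s$reactants, collapse = ","),
                paste(s$products, collapse = ","),
                if (length(s$conditions))
                  paste0("  (conditions ", paste(s$conditions, collapse = ","), ")")
                else ""))
  }
  invisible(x)
}

# node-level directed igraph (edges reactant -> product, edge attr step/arrow)
graph_as_igraph <- function(g) {
  stopifnot(inherits(g, "reaction_graph"))
  edges <- do.call(rbind, lapply(g$steps, function(s) {
    expand.grid(from = s$reactants, to = s$products)
  }))
  arrow_attr <- unlist(lapply(g$steps, function(s) {
    rep(s$arrow, length(s$reactants) * length(s$products))
  }))
  ig <- igraph::make_empty_graph(n = nrow(g$nodes), directed = TRUE)
  ig <- igraph::set_vertex_attr(ig, "name", value = as.character(g$nodes$id))
  for (a in c("x0", "y0", "x1", "y1")) {
    ig <- igraph::set_vertex_attr(ig, a, value = g$nodes[[a]])
  }
  if (!is.null(edges) && nrow(edges)) {
    el <- rbind(match(edges$from, g$nodes$id), match(edges$to, g$nodes$id))
    ig <- igraph::add_edges(ig, as.vector(el), arrow = arrow_attr)
  }
  ig
}

# ---- step scanning ------------------------------------------------------

# corners of an arrow's fitted rotated rectangle (slightly padded),
# in perimeter order
frame_corners <- function(fr, pad = 1) {
  d <- c(fr$direction[1], fr$direction[2])
  nv <- c(-d[2], d[1])
  hl <- fr$length / 2 + pad
  hw <- fr$width / 2 + pad
  m <- c(fr$center[1], fr$center[2])
  rbind(m + hl * d + hw * nv, m + hl * d - hw * nv,
        m - hl * d - hw * nv, m - hl * d + hw * nv)
}

# separating-axis test between two convex quadrilaterals (4 x 2 corner
# matrices in perimeter order); axes from both quads' edge directions
quads_intersect <- function(A, B) {
  axes <- rbind(A[2, ] - A[1, ], A[3, ] - A[2, ],
                B[2, ] - B[1, ], B[3, ] - B[2, ])
  for (k in seq_len(nrow(axes))) {
    ax <- axes[k, ]
    n2 <- sum(ax^2)
    if (n2 < 1e-12) next
    pa <- A %*% ax; pb <- B %*% ax
    if (max(pa) < min(pb) || max(pb) < min(pa)) return(FALSE)
  }
  TRUE
}

# smallest along-axis projection of the part of a quad (corner matrix, in
# perimeter order) that lies inside the scan corridor |lateral| <= hn;
# approximated by dense sampling of the quad's edges
corridor_entry <- function(Q, m, d, nv, hn, k = 32, min_pd = 0) {
  tt <- seq(0, 1, length.out = k)
  pts <- do.call(rbind, lapply(1:4, function(i) {
    j <- if (i == 4) 1L else i + 1L
    cbind(Q[i, 1] + tt * (Q[j, 1] - Q[i, 1]),
          Q[i, 2] + tt * (Q[j, 2] - Q[i, 2]))
  }))
  rel <- sweep(pts, 2, m)
  pd <- rel %*% d
  pn <- rel %*% nv
  inside <- abs(pn) <= hn & pd > min_pd   # forward part of the corridor only
  if (!any(inside)) return(Inf)
  min(pd[inside])
}

# axis-separating test: axis-aligned box vs oriented rectangle given by
# center m, unit axes d (along) and nv (normal), half-extents (hd, hn)
box_hits_strip <- function(b, m, d, nv, lo, hi, hn) {
  corners <- rbind(c(b[["x0"]], b[["y0"]]), c(b[["x1"]], b[["y0"]]),
                   c(b[["x0"]], b[["y1"]]), c(b[["x1"]], b[["y1"]]))
  rel <- sweep(corners, 2, m)
  pd <- rel %*% d
  pn <- rel %*% nv
  if (max(pd) < lo || min(pd) > hi) return(FALSE)
  if (max(pn) < -hn || min(pn) > hn) return(FALSE)
  # project the strip onto x and y axes and compare against the box
  ctr <- m + d * (lo + hi) / 2
  hd <- (hi - lo) / 2
  ex <- abs(d[1]) * hd + abs(nv[1]) * hn
  ey <- abs(d[2]) * hd + abs(nv[2]) * hn
  if (ctr[1] + ex < b[["x0"]] || ctr[1] - ex > b[["x1"]]) return(FALSE)
  if (ctr[2] + ey < b[["y0"]] || ctr[2] - ey > b[["y1"]]) return(FALSE)
  TRUE
}

# horizontal text lines: cluster diagram boxes into bands by y overlap
diagram_lines <- function(diagrams) {
  if (nrow(diagrams) == 0) return(list())
  ord <- order((diagrams$y0 + diagrams$y1) / 2)
  d <- diagrams[ord, , drop = FALSE]
  bands <- list()
  cur <- d[1, , drop = FALSE]
  for (i in seq_len(nrow(d))[-1]) {
    if (d$y0[i] <= max(cur$y1)) {
      cur <- rbind(cur, d[i, , drop = FALSE])
    } else {
      bands[[length(bands) + 1L]] <- cur
      cur <- d[i, , drop = FALSE]
    }
  }
  bands[[length(bands) + 1L]] <- cur
  bands
}

#' Scan outward from one arrow to assemble a reaction step
#'
#' From the arrow's geometry two scan directions are derived: toward the
#' products (the head / hook side) and toward the reactants (the tail / end
#' side). Scanning proceeds in equidistant strips of width `delta` moving
#' away from the arrow center, collecting every diagram whose box intersects
#' a strip; a scan stops when a strip meets another arrow's bounding box
#' (that arrow belongs to a different step) or leaves the image. If one side
#' collects nothing, the step is assumed to be spread over multiple text
#' lines and the previous or next line of diagrams is searched, the choice
#' depending on the arrow's position relative to the image height.
#'
#' @param frame An [fit_arrow_frame()] result (with curly-arrow reference
#'   endpoints resolved where applicable).
#' @param regions Region data.frame (completed diagrams among them).
#' @param arrows data.frame of all arrow boxes (`id, x0, y0, x1, y1`); used
#'   for the stop rule.
#' @param image_dim `c(width, height)` of the image.
#' @param params List: `delta` strip width as a fraction of arrow length
#'   (default 0.25), `half_width` lateral half-width of the scanned strip as
#'   a fraction of arrow length (default 0.75), `conditions_of` optional
#'   pairing map used to attach conditions regions to the step.
#' @return A list of class `reaction_step`: `arrow`, `reactants`,
#'   `products`, `conditions`, plus a `fallback` flag marking sides
#'   recovered by the multi-line search.
#' @export
scan_reaction_step <- function(frame, regions, arrows, image_dim,
                               params = list()) {
  delta_f <- params$delta %||% 0.25
  hw_f <- params$half_width %||% 0.2
  diagrams <- regions[regions$class == "diagram", , drop = FALSE]
  m <- frame$center
  L <- max(frame$length, 8)
  dirs <- scan_directions(frame)
  max_extent <- sqrt(sum(image_dim^2))
  delta <- delta_f * L
  hn <- max(hw_f * L, 20)   # floor keeps short arrows usable
  # stop rule uses the other arrows' rotated rectangles (an axis-aligned box
  # around a diagonal arrow would block scans far from its actual ink)
  other_quads <- if (is.data.frame(arrows)) {
    aa <- arrows[arrows$id != frame$id, , drop = FALSE]
    lapply(seq_len(nrow(aa)), function(j)
      rbind(c(aa$x0[j], aa$y0[j]), c(aa$x1[j], aa$y0[j]),
            c(aa$x1[j], aa$y1[j]), c(aa$x0[j], aa$y1[j])))
  } else {
    lapply(Filter(function(fr) !identical(fr$id, frame$id), arrows),
           frame_corners)
  }
  collect <- function(d) {
    nv <- c(-d[2], d[1])
    found <- integer(0)
    t0 <- L * 0.35   # start just beyond the arrow's own extent
    t <- t0
    while (t < max_extent) {
      strip <- rbind(m + t * d + hn * nv, m + t * d - hn * nv,
                     m + (t + delta) * d - hn * nv,
                     m + (t + delta) * d + hn * nv)
      block_at <- Inf   # where (along the axis) a blocking arrow enters
      for (q in other_quads) {
        if (quads_intersect(strip, q)) {
          block_at <- min(block_at, corridor_entry(q, m, d, nv, hn))
        }
      }
      if (is.finite(block_at)) {
        # stop: collect the diagrams that enter the corridor before the
        # blocking arrow does, with a grace margin of one arrowhead --
        # a neighbouring arrow's head abuts the shared diagram and may
        # graze the corridor a few pixels ahead of the diagram's box
        grace <- 0.15 * L
        for (j in seq_len(nrow(diagrams))) {
          db <- bbox(diagrams$x0[j], diagrams$y0[j],
                     diagrams$x1[j], diagrams$y1[j])
          corners <- rbind(c(db[["x0"]], db[["y0"]]), c(db[["x1"]], db[["y0"]]),
                           c(db[["x1"]], db[["y1"]]), c(db[["x0"]], db[["y1"]]))
          entry <- corridor_entry(corners, m, d, nv, hn)
          if (entry > 0 && entry < block_at + grace) {
            found <- union(found, diagrams$id[j])
          }
        }
        break
      }
      if (nrow(diagrams)) {
        for (j in seq_len(nrow(diagrams))) {
          db <- bbox(diagrams$x0[j], diagrams$y0[j],
                     diagrams$x1[j], diagrams$y1[j])
          if (box_hits_strip(db, m, d, nv, t, t + delta, hn)) {
            found <- union(found, diagrams$id[j])
          }
        }
      }
      t <- t + delta
    }
    found
  }
  products <- collect(dirs$product)
  reactants <- collect(dirs$reactant)
  # a diagram seen on both sides goes to the nearer side (tie -> reactants)
  both <- intersect(products, reactants)
  for (id in both) {
    db <- diagrams[diagrams$id == id, ]
    ctr <- c((db$x0 + db$x1) / 2, (db$y0 + db$y1) / 2)
    proj <- sum((ctr - m) * dirs$product)
    if (proj > 0) reactants <- setdiff(reactants, id)
    else products <- setdiff(products, id)
  }
  fallback <- character(0)
  if ((length(reactants) == 0 || length(products) == 0) && nrow(diagrams)) {
    bands <- diagram_lines(diagrams)
    band_of_arrow <- which(vapply(bands, function(b)
      any(b$y1 > m[2] - 1) && any(b$y0 < m[2] + 1) ||
        (min(b$y0) <= m[2] && max(b$y1) >= m[2]), logical(1)))
    # nearest band to the arrow center
    band_idx <- which.min(vapply(bands, function(b)
      abs((min(b$y0) + max(b$y1)) / 2 - m[2]), numeric(1)))
    lower_half <- m[2] > image_dim[2] / 2
    target <- if (lower_half) band_idx - 1L else band_idx + 1L
    if (target >= 1 && target <= length(bands)) {
      band <- bands[[target]]
      if (length(reactants) == 0) {
        reactants <- band$id[which.max(band$x1)]   # rightmost of that line
        fallback <- c(fallback, "reactants")
      } else if (length(products) == 0) {
        products <- band$id[which.min(band$x0)]    # leftmost of that line
        fallback <- c(fallback, "products")
      }
    }
  }
  conditions <- integer(0)
  if (!is.null(params$conditions_of) && length(params$conditions_of)) {
    conditions <- as.integer(names(params$conditions_of)[
      params$conditions_of == frame$id])
  }
  structure(list(arrow = frame$id, reactants = sort(reactants),
                 products = sort(setdiff(products, reactants)),
                 conditions = conditions, fallback = fallback),
            class = "reaction_step")
}

#' @export
print.reaction_step <- function(x, ...) {
  cat(sprintf("<reaction_step arrow %d: {%s} -> {%s}%s>\n", x$arrow,
              paste(x$reactants, collapse = ","),
              paste(x$products, collapse = ","),
              if (length(x$fallback))
                paste0(" [fallback: ", paste(x$fallback, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Stitch reaction steps into a reaction graph
#'
#' Creates one node per distinct diagram id referenced by any step and one
#' edge per step; steps are implicitly linked wherever one step's product
#' set intersects another's reactant set (shared diagram ids), which is how
#' multi-step sequences and catalytic cycles arise. Node ordering is
#' deterministic (sorted ids).
#'
#' @param steps List of `reaction_step` objects (or plain lists with the
#'   same fields).
#' @param regions Region data.frame supplying node boxes.
#' @return A [reaction_graph()].
#' @export
build_reaction_graph <- function(steps, regions) {
  used <- sort(unique(unlist(lapply(steps, function(s)
    c(s$reactants, s$products)))))
  nodes <- regions[regions$id %in% used,
                   c("id", "x0", "y0", "x1", "y1"), drop = FALSE]
  reaction_graph(nodes = nodes, steps = steps)
}

# ---- export / import ----------------------------------------------------

#' Export / import a reaction graph
#'
#' JSON export follows the bundled schema (`nodes` with ids, boxes and
#' optional decoded text; `steps` with arrow id, reactant/product node ids
#' and conditions ids). GraphML export goes through igraph with one edge per
#' (reactant, product) pair carrying the step's arrow id, so that
#' `import_graph(export_graph(g)) == g` for both formats.
#'
#' @param graph A [reaction_graph()].
#' @param path Output file path.
#' @param format `"json"` or `"graphml"`.
#' @return `path`, invisibly (`export_graph`); a [reaction_graph()]
#'   (`import_graph`).
#' @export
export_graph <- function(graph, path, format = c("json", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "reaction_graph"))
  if (format == "json") {
    payload <- list(
      nodes = lapply(seq_len(nrow(graph$nodes)), function(i) {
        n <- graph$nodes[i, ]
        list(id = n$id, bbox = c(n$x0, n$y0, n$x1 - n$x0, n$y1 - n$y0),
             label_text = n$label_text, smiles = n$smiles)
      }),
      steps = lapply(graph$steps, function(s) {
        list(arrow = s$arrow, reactants = s$reactants, products = s$products,
             conditions = s$conditions)
      }))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                         digits = NA, pretty = TRUE)
  } else {
    ig <- graph_as_igraph(graph)
    steps_json <- jsonlite::toJSON(graph$steps, auto_unbox = TRUE, digits = NA)
    ig <- igraph::set_graph_attr(ig, "steps", as.character(steps_json))
    ig <- igraph::set_vertex_attr(ig, "label_text",
                                  value = ifelse(is.na(graph$nodes$label_text),
                                                 "", graph$nodes$label_text))
    ig <- igraph::set_vertex_attr(ig, "smiles",
                                  value = ifelse(is.na(graph$nodes$smiles),
                                                 "", graph$nodes$smiles))
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("json", "graphml")) {
  format <- match.arg(format)
  if (format == "json") {
    js <- jsonlite::read_json(path)
    nodes <- if (length(js$nodes)) {
      do.call(rbind, lapply(js$nodes, function(n) {
        data.frame(id = as.integer(n$id),
                   x0 = n$bbox[[1]], y0 = n$bbox[[2]],
                   x1 = n$bbox[[1]] + n$bbox[[3]],
                   y1 = n$bbox[[2]] + n$bbox[[4]],
                   label_text = if (is.null(n$label_text)) NA_character_
                                else as.character(n$label_text),
                   smiles = if (is.null(n$smiles)) NA_character_
                            else as.character(n$smiles))
      }))
    } else {
      data.frame(id = integer(), x0 = numeric(), y0 = numeric(),
                 x1 = numeric(), y1 = numeric())
    }
    steps <- lapply(js$steps, function(s) {
      list(arrow = as.integer(s$arrow),
           reactants = as.integer(unlist(s$reactants)),
           products = as.integer(unlist(s$products)),
           conditions = as.integer(unlist(s$conditions)))
    })
    reaction_graph(nodes, steps)
  } else {
    ig <- igraph::read_graph(path, format = "graphml")
    ids <- as.integer(igraph::vertex_attr(ig, "name"))
    nodes <- data.frame(id = ids,
                        x0 = igraph::vertex_attr(ig, "x0"),
                        y0 = igraph::vertex_attr(ig, "y0"),
                        x1 = igraph::vertex_attr(ig, "x1"),
                        y1 = igraph::vertex_attr(ig, "y1"),
                        label_text = ifelse(igraph::vertex_attr(ig, "label_text") == "",
                                            NA_character_,
                                            igraph::vertex_attr(ig, "label_text")),
                        smiles = ifelse(igraph::vertex_attr(ig, "smiles") == "",
                                        NA_character_,
                                        igraph::vertex_attr(ig, "smiles")))
    steps_json <- igraph::graph_attr(ig, "steps")
    steps <- lapply(jsonlite::fromJSON(steps_json, simplifyVector = FALSE),
                    function(s) {
      list(arrow = as.integer(s$arrow),
           reactants = as.integer(unlist(s$reactants)),
           products = as.integer(unlist(s$products)),
           conditions = as.integer(unlist(s$conditions)))
    })
    reaction_graph(nodes, steps)
  }
}
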