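# End-to-end orchestration: image in, reaction graph out, with plugin seams
# for external OCR / OCSR engines.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one serializable list:
#' detection backend, model objects or paths, thresholds, scan parameters,
#' seed and debug flag.
#'
#' @param backend `"oracle"` (replay a ground-truth annotation; used for
#'   testing the symbolic stages in isolation) or `"learned"`.
#' @param arrow_model,region_model Model objects (or paths to `.rds` files)
#'   for the learned backend. With the oracle backend, arrows are taken
#'   from the annotation.
#' @param arrow_threshold Detector probability threshold.
#' @param directionality [directionality_params()].
#' @param scan List of step-scan parameters (`delta`, `half_width`; in
#'   units of arrow length).
#' @param oracle List of oracle perturbations (`jitter_sd`, `drop_rate`,
#'   `spurious_rate`).
#' @param seed Integer seed for any stochastic stage.
#' @param debug Keep per-stage intermediates in the result.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(backend = c("oracle", "learned"),
                            arrow_model = NULL, region_model = NULL,
                            arrow_threshold = 0.5,
                            directionality = directionality_params(),
                            scan = list(delta = 0.25, half_width = 0.2),
                            oracle = list(jitter_sd = 0, drop_rate = 0,
                                          spurious_rate = 0),
                            seed = 1, debug = FALSE) {
  backend <- match.arg(backend)
  stopifnot(arrow_threshold >= 0, arrow_threshold <= 1,
            scan$delta > 0, scan$half_width > 0)
  structure(list(backend = backend, arrow_model = arrow_model,
                 region_model = region_model,
                 arrow_threshold = arrow_threshold,
                 directionality = directionality, scan = scan,
                 oracle = oracle, seed = seed, debug = debug),
            class = "pipeline_config")
}

# ground-truth arrows for the oracle backend: the largest component inside
# each annotated arrow box
arrows_from_annotation <- function(annotation, ccs) {
  areg <- annotation$regions[annotation$regions$class == "arrow", ,
                             drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(areg))) {
    ab <- bbox(areg$x0[i] - 1, areg$y0[i] - 1, areg$x1[i] + 1, areg$y1[i] + 1)
    inside <- Filter(function(cc) {
      cb <- cc$bbox
      cb[["x0"]] >= ab[["x0"]] && cb[["x1"]] <= ab[["x1"]] &&
        cb[["y0"]] >= ab[["y0"]] && cb[["y1"]] <= ab[["y1"]]
    }, ccs)
    if (length(inside) == 0) next
    cc <- inside[[which.max(vapply(inside, function(x) x$area, numeric(1)))]]
    out[[length(out) + 1L]] <- arrow_obj(cc, subtype = areg$subtype[i],
                                         score = 1, id = areg$id[i])
  }
  out
}

#' Extract the reaction scheme from one image
#'
#' Runs the operational pipeline top to bottom: binarize, detect regions
#' and arrows (in parallel branches), complete diagram boxes by local
#' dilation, reclassify and pair text regions, recover arrow geometry, scan
#' each arrow for its reactants and products, and stitch the steps into a
#' reaction graph.
#'
#' @param image Path to a PNG/JPEG file, or a numeric grayscale matrix
#'   (1 = white).
#' @param config A [pipeline_config()].
#' @param annotation A `scheme_annotation`, required when
#'   `config$backend == "oracle"`.
#' @return List of class `scheme_extraction`: `graph`
#'   ([reaction_graph()]), `regions` (final region report), `arrows`
#'   (arrow frames), `pairings`, `log` (per-stage counts), and `debug`
#'   intermediates when requested.
#' @export
extract_scheme <- function(image, config = pipeline_config(),
                           annotation = NULL) {
  if (is.character(image)) {
    img <- png::readPNG(image)
    if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  } else {
    img <- image
  }
  stopifnot(is.matrix(img))
  log <- list()
  if (length(img) == 0 || nrow(img) == 0) stop("empty image")
  uniform <- length(unique(as.vector(img))) == 1L
  bin <- if (uniform) binary_image(matrix(FALSE, nrow(img), ncol(img)))
         else binarize(img)
  ccs <- find_connected_components(bin)
  log$n_components <- length(ccs)

  if (config$backend == "oracle") {
    if (is.null(annotation)) stop("oracle backend requires an annotation")
    regions <- detect_regions(img, "oracle", annotation = annotation,
                              jitter_sd = config$oracle$jitter_sd %||% 0,
                              drop_rate = config$oracle$drop_rate %||% 0,
                              spurious_rate = config$oracle$spurious_rate %||% 0,
                              seed = config$seed)
    arrows <- arrows_from_annotation(annotation, ccs)
  } else {
    rm_model <- config$region_model
    am_model <- config$arrow_model
    if (is.character(rm_model)) rm_model <- readRDS(rm_model)
    if (is.character(am_model)) am_model <- readRDS(am_model)
    if (is.null(rm_model) || is.null(am_model)) {
      stop("learned backend requires arrow_model and region_model")
    }
    regions <- detect_regions(img, "learned", model = rm_model)
    arrows <- detect_arrows(bin, am_model,
                            threshold = config$arrow_threshold, ccs = ccs)
  }
  log$n_regions_raw <- nrow(regions)
  log$n_arrows <- length(arrows)
  if (length(arrows) == 0) {
    warning("no arrows found; returning graph with isolated diagram nodes")
  }

  # diagram completion
  for (i in which(regions$class == "diagram")) {
    regions[i, ] <- complete_diagram(regions[i, ], bin, ccs)
  }

  # arrow geometry
  frames <- lapply(arrows, function(a) {
    fr <- fit_arrow_frame(a)
    if (identical(a$subtype, "curly")) {
      fr <- tryCatch({
        eps <- find_arrow_endpoints(a)
        classify_endpoints(a, eps,
                           regions[regions$class == "diagram", , drop = FALSE],
                           frame = fr)
      }, error = function(e) fr)
    }
    fr
  })

  # text postprocessing: reclassify, then pair
  for (i in which(regions$class %in% c("label", "conditions"))) {
    regions[i, ] <- reclassify_text_region(
      regions[i, ], regions[regions$class == "diagram", , drop = FALSE],
      frames, params = config$directionality)
  }
  pairings <- pair_regions(regions, frames)
  log$n_labels <- sum(regions$class == "label")
  log$n_conditions <- sum(regions$class == "conditions")

  # step scanning and graph formation
  scan_params <- c(config$scan, list(conditions_of = pairings$conditions_of))
  steps <- lapply(frames, function(fr)
    scan_reaction_step(fr, regions, frames,
                       c(bin$width, bin$height), scan_params))
  steps <- Filter(function(s) length(s$reactants) && length(s$products), steps)
  log$n_steps <- length(steps)
  graph <- if (length(steps)) {
    build_reaction_graph(steps, regions)
  } else {
    diag <- regions[regions$class == "diagram",
                    c("id", "x0", "y0", "x1", "y1"), drop = FALSE]
    reaction_graph(nodes = diag, steps = list())
  }
  out <- list(graph = graph, regions = regions, arrows = frames,
              pairings = pairings, log = log)
  if (config$debug) out$debug <- list(bin = bin, ccs = ccs)
  structure(out, class = "scheme_extraction")
}

#' @export
print.scheme_extraction <- function(x, ...) {
  cat(sprintf("<scheme_extraction: %d region(s), %d arrow(s), %d step(s)>\n",
              nrow(x$regions), length(x$arrows), length(x$graph$steps)))
  print(x$graph)
  invisible(x)
}

#' Extract schemes from a batch of images
#'
#' Per-image failures are caught and logged as skips rather than aborting
#' the batch; the output order matches the input order.
#'
#' @param paths Character vector of image paths.
#' @param config A [pipeline_config()].
#' @param annotations Optional list of annotations (oracle backend),
#'   parallel to `paths`.
#' @return List with `results` (named list of extractions, `NULL` where
#'   skipped) and `skipped` (named character vector of failure reasons).
#' @export
extract_batch <- function(paths, config = pipeline_config(),
                          annotations = NULL) {
  results <- stats::setNames(vector("list", length(paths)), paths)
  skipped <- character(0)
  for (i in seq_along(paths)) {
    ann <- if (!is.null(annotations)) annotations[[i]] else NULL
    res <- tryCatch(extract_scheme(paths[i], config, annotation = ann),
                    error = function(e) e)
    if (inherits(res, "error")) {
      skipped[paths[i]] <- conditionMessage(res)
    } else {
      results[[i]] <- res
    }
  }
  list(results = results, skipped = skipped)
}

#' Annotate an extracted graph via OCR / OCSR plugin adapters
#'
#' The core pipeline never performs optical character or structure
#' recognition; external engines plug in here. An adapter is a function
#' taking an image crop (numeric matrix) and returning a character scalar
#' (decoded text for labels/conditions, a structure line notation such as
#' SMILES for diagrams). Missing adapters leave the fields `NA`; an adapter
#' exception leaves that field `NA` and is logged, without affecting other
#' crops.
#'
#' @param extraction A [extract_scheme()] result.
#' @param image The source image (matrix or path).
#' @param adapters List with optional elements `ocr` (labels/conditions)
#'   and `ocsr` (diagrams).
#' @return The extraction with `graph$nodes$smiles`,
#'   `graph$nodes$label_text` filled where adapters succeeded, plus
#'   `plugin_log`.
#' @export
ocr_ocsr_plugins <- function(extraction, image, adapters = list()) {
  if (is.character(image)) {
    image <- png::readPNG(image)
    if (length(dim(image)) == 3L) image <- apply(image, c(1, 2), mean)
  }
  plugin_log <- character(0)
  crop <- function(x0, y0, x1, y1) {
    image[(max(0, floor(y0)) + 1):min(nrow(image), ceiling(y1)),
          (max(0, floor(x0)) + 1):min(ncol(image), ceiling(x1)),
          drop = FALSE]
  }
  apply_adapter <- function(fn, cp, what) {
    out <- tryCatch(fn(cp), error = function(e) {
      plugin_log[[length(plugin_log) + 1L]] <<-
        paste0(what, ": ", conditionMessage(e))
      NA_character_
    })
    if (is.null(out)) NA_character_ else as.character(out)[1]
  }
  if (!is.null(adapters$ocsr)) {
    for (i in seq_len(nrow(extraction$graph$nodes))) {
      n <- extraction$graph$nodes[i, ]
      extraction$graph$nodes$smiles[i] <-
        apply_adapter(adapters$ocsr, crop(n$x0, n$y0, n$x1, n$y1),
                      paste0("ocsr node ", n$id))
    }
  }
  if (!is.null(adapters$ocr)) {
    labs <- extraction$regions[extraction$regions$class == "label", ,
                               drop = FALSE]
    for (i in seq_len(nrow(labs))) {
      txt <- apply_adapter(adapters$ocr,
                           crop(labs$x0[i], labs$y0[i], labs$x1[i], labs$y1[i]),
                           paste0("ocr label ", labs$id[i]))
      target <- extraction$pairings$label_of[as.character(labs$id[i])]
      if (length(target) == 1 && !is.na(target)) {
        j <- which(extraction$graph$nodes$id == target)
        if (length(j)) extraction$graph$nodes$label_text[j] <- txt
      }
    }
  }
  extraction$plugin_log <- plugin_log
  extraction
}
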