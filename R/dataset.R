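# Dataset generation: batches of artificial schemes with COCO-style
# annotations and per-scheme ground-truth graphs, written to disk.

COCO_CATEGORIES <- data.frame(
  id = 1:4, name = c("diagram", "label", "conditions", "arrow"))

annotation_to_coco <- function(ann, image_id, start_ann_id = 1L) {
  reg <- ann$regions[ann$regions$class %in% COCO_CATEGORIES$name, ,
                     drop = FALSE]
  anns <- lapply(seq_len(nrow(reg)), function(i) {
    list(id = start_ann_id + i - 1L,
         image_id = image_id,
         category_id = COCO_CATEGORIES$id[match(reg$class[i],
                                                COCO_CATEGORIES$name)],
         bbox = c(reg$x0[i], reg$y0[i],
                  reg$x1[i] - reg$x0[i], reg$y1[i] - reg$y0[i]),
         area = (reg$x1[i] - reg$x0[i]) * (reg$y1[i] - reg$y0[i]),
         region_id = reg$id[i],
         iscrowd = 0L)
  })
  list(annotations = anns, next_id = start_ann_id + nrow(reg))
}

#' Generate a dataset of artificial reaction schemes
#'
#' Composes `n` schemes under one schema, writes one PNG per scheme, a
#' COCO-style annotation file (`annotations.json` with `images`,
#' `annotations`, `categories`; category ids 1 = diagram, 2 = label,
#' 3 = conditions, 4 = arrow; boxes as `[x, y, width, height]`), and a
#' ground-truth graph JSON per scheme. Per-scheme seeds are derived from
#' `seed`, so a rerun reproduces every file byte for byte.
#'
#' @param n Number of schemes (0 gives an empty manifest).
#' @param schema A [schema_spec()].
#' @param bank Optional [build_element_bank()]; derived from `seed` when
#'   absent.
#' @param seed Integer master seed.
#' @param outdir Output directory (created if needed).
#' @return Object of class `scheme_manifest`: data.frame of files and
#'   per-scheme seeds, with the output paths in attributes.
#' @export
generate_dataset <- function(n, schema, seed = 1, outdir,
                             bank = NULL) {
  stopifnot(n >= 0)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  if (is.null(bank)) bank <- build_element_bank(seed = child_seed(seed, 0))
  images <- list(); all_anns <- list(); next_id <- 1L
  rows <- list()
  for (i in seq_len(n)) {
    s_i <- child_seed(seed, i)
    sc <- compose_scheme(schema, bank, seed = s_i)
    img_name <- sprintf("scheme_%04d.png", i)
    graph_name <- sprintf("scheme_%04d_graph.json", i)
    png::writePNG(sc$image, file.path(outdir, img_name))
    export_graph(sc$annotation$graph, file.path(outdir, graph_name), "json")
    images[[i]] <- list(id = i, file_name = img_name,
                        width = ncol(sc$image), height = nrow(sc$image))
    cc <- annotation_to_coco(sc$annotation, i, next_id)
    all_anns <- c(all_anns, cc$annotations)
    next_id <- cc$next_id
    # sidecar with the full annotation (pairings + arrows), for the oracle
    side_name <- sprintf("scheme_%04d_annotation.json", i)
    write_annotation_json(sc$annotation, file.path(outdir, side_name))
    rows[[i]] <- data.frame(image = img_name, graph = graph_name,
                            annotation = side_name, seed = s_i)
  }
  coco <- list(images = images, annotations = all_anns,
               categories = lapply(seq_len(nrow(COCO_CATEGORIES)), function(i)
                 list(id = COCO_CATEGORIES$id[i],
                      name = COCO_CATEGORIES$name[i])))
  jsonlite::write_json(coco, file.path(outdir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- if (n > 0) do.call(rbind, rows) else {
    data.frame(image = character(), graph = character(),
               annotation = character(), seed = numeric())
  }
  manifest <- structure(manifest, class = c("scheme_manifest", "data.frame"),
                        outdir = outdir, master_seed = seed)
  jsonlite::write_json(list(master_seed = seed, n = n, files = manifest),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

write_annotation_json <- function(ann, path) {
  payload <- list(
    regions = ann$regions,
    arrows = ann$arrows,
    pairings = list(
      label_of = as.list(ann$pairings$label_of),
      conditions_of = as.list(ann$pairings$conditions_of)),
    graph = list(
      nodes = ann$graph$nodes[, c("id", "x0", "y0", "x1", "y1")],
      steps = ann$graph$steps))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
}

read_annotation_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  regions <- as.data.frame(js$regions)
  arrows <- if (!is.null(js$arrows) && length(js$arrows)) {
    as.data.frame(js$arrows)
  } else NULL
  to_named_int <- function(x) {
    if (is.null(x) || length(x) == 0) return(integer(0))
    stats::setNames(as.integer(unlist(x)), names(x))
  }
  steps <- js$graph$steps
  if (is.data.frame(steps)) {
    steps <- lapply(seq_len(nrow(steps)), function(i) {
      list(arrow = steps$arrow[i],
           reactants = as.integer(unlist(steps$reactants[i])),
           products = as.integer(unlist(steps$products[i])),
           conditions = as.integer(unlist(steps$conditions[i])))
    })
  } else {
    steps <- lapply(steps, function(s) {
      list(arrow = as.integer(s$arrow),
           reactants = as.integer(unlist(s$reactants)),
           products = as.integer(unlist(s$products)),
           conditions = as.integer(unlist(s$conditions)))
    })
  }
  graph <- reaction_graph(as.data.frame(js$graph$nodes), steps)
  structure(list(regions = regions, arrows = arrows,
                 pairings = list(
                   label_of = to_named_int(js$pairings$label_of),
                   conditions_of = to_named_int(js$pairings$conditions_of)),
                 graph = graph),
            class = "scheme_annotation")
}

#' Load a generated dataset back into memory
#'
#' @param manifest A `scheme_manifest` from [generate_dataset()], or the
#'   path of the dataset directory.
#' @return List of `list(image, annotation)` pairs.
#' @export
load_dataset <- function(manifest) {
  if (is.character(manifest)) {
    outdir <- manifest
    js <- jsonlite::read_json(file.path(outdir, "manifest.json"),
                              simplifyVector = TRUE)
    manifest <- structure(as.data.frame(js$files),
                          class = c("scheme_manifest", "data.frame"),
                          outdir = outdir)
  }
  outdir <- attr(manifest, "outdir")
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- png::readPNG(file.path(outdir, manifest$image[i]))
    if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
    ann <- read_annotation_json(file.path(outdir, manifest$annotation[i]))
    list(image = img, annotation = ann)
  })
}
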