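# The scheme engineer: element bank, augmentation, composition, datasets.

test_that("element bank is reproducible and covers all classes", {
  b1 <- build_element_bank(seed = 5)
  b2 <- build_element_bank(seed = 5)
  expect_identical(rxnscheme:::object_hash(b1), rxnscheme:::object_hash(b2))
  b3 <- build_element_bank(seed = 6)
  expect_false(identical(rxnscheme:::object_hash(b1),
                         rxnscheme:::object_hash(b3)))
  expect_setequal(names(b1$arrow),
                  c("solid", "curly", "equilibrium", "resonance"))
  expect_true(all(vapply(b1$arrow, length, integer(1)) >= 1))
  expect_error(build_element_bank(list(n_diagram = 0), seed = 1),
               "mandatory")
})

test_that("a diagram glyph with a detached superatom has >= 2 components", {
  bank <- build_element_bank(list(p_superatom = 1, n_diagram = 3), seed = 8)
  g <- bank$diagram[[1]]
  ccs <- find_connected_components(
    binary_image(rxnscheme:::glyph_mask(g)))
  expect_gte(length(ccs), 2)
})

test_that("augmentation is identity at identity bounds and tracks rotation", {
  g <- fx_bank()$diagram[[1]]
  same <- augment_glyph(g, seed = 3, scale = c(1, 1), rotate = c(0, 0),
                        p_blur = 0)
  expect_identical(unclass(same)[, ], unclass(g)[, ])

  rot <- augment_glyph(g, seed = 3, scale = c(1, 1), rotate = c(90, 90),
                       p_blur = 0)
  expect_equal(dim(rot), rev(dim(g)), tolerance = 0.02)
})

test_that("augmentation is seed-deterministic but varies across seeds", {
  g <- fx_bank()$label[[1]]
  a1 <- augment_glyph(g, seed = 77)
  a2 <- augment_glyph(g, seed = 77)
  expect_identical(rxnscheme:::object_hash(a1), rxnscheme:::object_hash(a2))
  # a larger glyph: small rasters quantize distinct draws onto one output
  d <- fx_bank()$diagram[[2]]
  hashes <- vapply(1:30, function(s)
    rxnscheme:::object_hash(augment_glyph(d, seed = 1000 + s)), character(1))
  expect_gt(length(unique(hashes)), 25)
})

test_that("minimal linear scheme composes exactly the expected elements", {
  sch <- schema_spec("linear", n_steps = 1, diagrams_per_step = c(1, 1),
                     p_label = 0, p_conditions = 0, n_negatives = c(0, 0))
  sc <- compose_scheme(sch, fx_bank(), seed = 2)
  reg <- sc$annotation$regions
  expect_identical(sum(reg$class == "diagram"), 2L)
  expect_identical(sum(reg$class == "arrow"), 1L)
  expect_identical(sum(reg$class %in% c("label", "conditions", "negative")), 0L)
  g <- sc$annotation$graph
  expect_length(g$steps, 1)
  expect_length(g$steps[[1]]$reactants, 1)
  expect_length(g$steps[[1]]$products, 1)
})

test_that("multi-step linear schemes chain products into reactants", {
  sch <- schema_spec("linear", n_steps = 3, diagrams_per_step = c(1, 2),
                     p_label = 0.5, p_conditions = 0.5)
  sc <- compose_scheme(sch, fx_bank(), seed = 14)
  g <- sc$annotation$graph
  expect_length(g$steps, 3)
  expect_identical(sum(sc$annotation$regions$class == "arrow"), 3L)
  for (i in 1:2) {
    expect_identical(g$steps[[i]]$products, g$steps[[i + 1]]$reactants)
  }
})

test_that("cyclic schemes close into a ring", {
  sch <- schema_spec("cyclic", n_steps = 4, diagrams_per_step = 1,
                     p_label = 0, p_conditions = 0)
  sc <- compose_scheme(sch, fx_bank(), seed = 5)
  g <- sc$annotation$graph
  expect_length(g$steps, 4)
  # walk: from any node, following steps returns to it after 4 steps
  start <- g$steps[[1]]$reactants
  node <- start
  for (k in 1:4) {
    s <- Filter(function(s) node %in% s$reactants, g$steps)
    expect_length(s, 1)
    node <- s[[1]]$products
  }
  expect_identical(node, start)
})

test_that("composition is byte-identical under a fixed seed", {
  sch <- schema_spec("linear", n_steps = 2)
  s1 <- compose_scheme(sch, fx_bank(), seed = 9)
  s2 <- compose_scheme(sch, fx_bank(), seed = 9)
  expect_identical(s1$image, s2$image)
  expect_identical(rxnscheme:::object_hash(s1$annotation),
                   rxnscheme:::object_hash(s2$annotation))
})

test_that("every ink component lies inside an annotated box", {
  for (seed in c(3, 17)) {
    sc <- fx_scheme(seed = seed, n_steps = 2, p_label = 0.8,
                    p_conditions = 0.8, n_negatives = c(1, 2))
    ccs <- find_connected_components(binarize(sc$image))
    reg <- sc$annotation$regions
    for (cc in ccs) {
      covered <- any(vapply(seq_len(nrow(reg)), function(i) {
        cc$bbox[["x0"]] >= reg$x0[i] - 1 && cc$bbox[["x1"]] <= reg$x1[i] + 1 &&
          cc$bbox[["y0"]] >= reg$y0[i] - 1 && cc$bbox[["y1"]] <= reg$y1[i] + 1
      }, logical(1)))
      expect_true(covered)
    }
  }
})

test_that("generate_dataset writes reproducible files and valid counts", {
  sch <- schema_spec("linear", n_steps = 2, p_conditions = 1, p_label = 0.5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(3, sch, seed = 7, outdir = d1)
  m2 <- generate_dataset(3, sch, seed = 7, outdir = d2)
  expect_identical(nrow(m1), 3L)
  h1 <- tools::md5sum(file.path(d1, sort(list.files(d1))))
  h2 <- tools::md5sum(file.path(d2, sort(list.files(d2))))
  expect_identical(unname(h1), unname(h2))

  coco <- jsonlite::read_json(file.path(d1, "annotations.json"),
                              simplifyVector = TRUE)
  expect_setequal(coco$categories$name,
                  c("diagram", "label", "conditions", "arrow"))
  # p_conditions = 1: one conditions box per arrow
  ann <- coco$annotations
  expect_identical(sum(ann$category_id == 3), sum(ann$category_id == 4))

  # boxes are COCO [x, y, w, h] with positive extents
  expect_true(all(vapply(ann$bbox, function(b) b[3] > 0 && b[4] > 0,
                         logical(1))))
})

test_that("generate_dataset with n = 0 yields an empty manifest", {
  d <- withr::local_tempdir()
  m <- generate_dataset(0, schema_spec("linear"), seed = 1, outdir = d)
  expect_identical(nrow(m), 0L)
})

test_that("a generated dataset round-trips through load_dataset", {
  d <- withr::local_tempdir()
  sch <- schema_spec("linear", n_steps = 1, p_label = 1, p_conditions = 1)
  generate_dataset(2, sch, seed = 3, outdir = d)
  back <- load_dataset(d)
  expect_length(back, 2)
  expect_true(is.matrix(back[[1]]$image))
  expect_s3_class(back[[1]]$annotation$graph, "reaction_graph")
  expect_gt(length(back[[1]]$annotation$pairings$label_of), 0)
})
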