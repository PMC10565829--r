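# Symbolic postprocessing: diagram completion, text reclassification,
# pairing.

make_region <- function(id, class, x0, y0, x1, y1, provenance = "oracle") {
  data.frame(id = id, class = class, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
             score = 1, provenance = provenance)
}

test_that("completion of an isolated diagram is a fixed point", {
  m <- matrix(FALSE, 60, 60)
  m[20:40, 15:45] <- TRUE
  bin <- binary_image(m)
  ccs <- find_connected_components(bin)
  reg <- make_region(1, "diagram", 10, 15, 50, 45)  # loose raw box
  out <- complete_diagram(reg, bin, ccs)
  expect_identical(unname(c(out$x0, out$y0, out$x1, out$y1)),
                   unname(c(ccs[[1]]$bbox)))
  expect_identical(out$provenance, "postprocessed")
})

test_that("completion absorbs a detached superatom across a 6 px gap", {
  m <- matrix(FALSE, 80, 120)
  m[20:60, 10:60] <- TRUE          # main skeleton blob
  m[35:45, 67:90] <- TRUE          # superatom cluster, 6 px gap
  bin <- binary_image(m)
  ccs <- find_connected_components(bin)
  expect_length(ccs, 2)
  reg <- make_region(1, "diagram", 8, 18, 64, 62)   # raw box covers both CCs
  # include the superatom's left edge so the local gap is measurable
  reg$x1 <- 70
  out <- complete_diagram(reg, bin, ccs)
  expect_lte(out$x0, 9)
  expect_gte(out$x1, 90)   # covers the superatom
  expect_gte(out$y1, 60)
})

test_that("completion never merges two distant diagrams", {
  m <- matrix(FALSE, 80, 220)
  m[20:60, 10:60] <- TRUE
  m[20:60, 160:210] <- TRUE        # second diagram 100 px away
  bin <- binary_image(m)
  ccs <- find_connected_components(bin)
  reg <- make_region(1, "diagram", 10, 20, 61, 61)
  out <- complete_diagram(reg, bin, ccs, c_gap = 1.2, r_min = 10)
  expect_lte(out$x1, 65)
})

test_that("completion is idempotent", {
  sc <- fx_scheme(seed = 47, n_steps = 2)
  bin <- binarize(sc$image)
  ccs <- find_connected_components(bin)
  reg <- sc$annotation$regions
  d <- reg[reg$class == "diagram", ][1, ]
  d$score <- 1; d$provenance <- "oracle"
  once <- complete_diagram(d, bin, ccs)
  twice <- complete_diagram(once, bin, ccs)
  expect_identical(once, twice)
})

test_that("canonical text placements reclassify as expected", {
  # horizontal arrow centered at (100, 50), length 80
  arrow_cc <- conncomp(cbind(x = 60:139, y = rep(50L, 80)))
  fr <- fit_arrow_frame(arrow_obj(arrow_cc, subtype = "solid", id = 9))
  diagrams_far <- make_region(1, "diagram", 300, 30, 360, 90)
  # text 10 px above the arrow midpoint: conditions
  r1 <- make_region(2, "label", 80, 25, 120, 40)
  out1 <- reclassify_text_region(r1, diagrams_far, list(fr))
  expect_identical(out1$class, "conditions")
  # text directly below a diagram, arrow far away: label
  diagrams_near <- make_region(1, "diagram", 70, 100, 130, 160)
  r2 <- make_region(3, "conditions", 85, 168, 115, 180)
  out2 <- reclassify_text_region(r2, diagrams_near, list(fr))
  expect_identical(out2$class, "label")
  # no diagrams, no arrows: prior kept with a warning
  expect_warning(out3 <- reclassify_text_region(r1, diagrams_far[0, ], list()),
                 "keeping prior")
  expect_identical(out3$class, r1$class)
})

test_that("reclassification matches a brute-force rule grid (ties -> diagram)", {
  arrow_cc <- conncomp(cbind(x = 100:179, y = rep(200L, 80)))
  fr <- fit_arrow_frame(arrow_obj(arrow_cc, subtype = "solid", id = 50))
  diag <- make_region(1, "diagram", 60, 40, 140, 120)
  params <- directionality_params()
  for (cx in seq(60, 260, by = 40)) {
    for (cy in seq(30, 260, by = 33)) {
      r <- make_region(7, "conditions", cx - 15, cy - 7, cx + 15, cy + 7)
      rb <- bbox(r$x0, r$y0, r$x1, r$y1)
      got <- reclassify_text_region(r, diag, list(fr), params)$class
      # independent re-evaluation of the written rule
      d_diag <- separation(rb, bbox(60, 40, 140, 120))
      d_arr <- rxnscheme:::arrow_separation(rb, fr)
      expected <- "conditions"  # prior
      if (d_diag <= d_arr) {
        below <- (cy > 120) &&
          (min(rb[["x1"]], 140) - max(rb[["x0"]], 60)) >=
            0.25 * min(bbox_width(rb), 80)
        if (below) expected <- "label"
      } else {
        v <- c(cx - 140, cy - 200.5)
        ok <- abs(v[2]) <= params$max_normal * fr$length &&
          abs(v[1]) <= params$lateral_tol * fr$length
        if (ok) expected <- "conditions"
      }
      expect_identical(got, expected)
    }
  }
})

test_that("pairing maps each text region to its nearest target", {
  diag <- make_region(1, "diagram", 10, 10, 60, 60)
  lab <- make_region(2, "label", 20, 66, 50, 80)
  regions <- rbind(diag, lab)
  arrow_cc <- conncomp(cbind(x = 100:179, y = rep(35L, 80)))
  fr <- fit_arrow_frame(arrow_obj(arrow_cc, subtype = "solid", id = 9))
  p <- pair_regions(regions, list(fr))
  expect_identical(p$label_of, c(`2` = 1))

  # two labels nearest the same diagram: many-to-one is permitted
  lab2 <- make_region(3, "label", 20, 84, 50, 96)
  p2 <- pair_regions(rbind(diag, lab, lab2), list(fr))
  expect_identical(unname(p2$label_of), c(1, 1))
})

test_that("oracle pairing recovers the generated ground truth", {
  sc <- fx_scheme(seed = 53, n_steps = 3, p_label = 1, p_conditions = 1)
  ex <- extract_scheme(sc$image, pipeline_config("oracle"),
                       annotation = sc$annotation)
  norm <- function(v) paste(sort(paste(names(v), v, sep = ">")), collapse = ";")
  expect_identical(norm(ex$pairings$label_of),
                   norm(sc$annotation$pairings$label_of))
  expect_identical(norm(ex$pairings$conditions_of),
                   norm(sc$annotation$pairings$conditions_of))
})

test_that("reclassification only ever changes class and provenance", {
  sc <- fx_scheme(seed = 59, n_steps = 2, p_label = 1, p_conditions = 1)
  ex <- extract_scheme(sc$image, pipeline_config("oracle"),
                       annotation = sc$annotation)
  gt <- sc$annotation$regions
  gt <- gt[gt$class %in% c("diagram", "label", "conditions"), ]
  expect_identical(sort(ex$regions$id), sort(gt$id))
  txt <- ex$regions[ex$regions$class %in% c("label", "conditions"), ]
  gt_txt <- gt[match(txt$id, gt$id), ]
  expect_identical(`rownames<-`(txt[, c("x0", "y0", "x1", "y1")], NULL),
                   `rownames<-`(gt_txt[, c("x0", "y0", "x1", "y1")], NULL))
})
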