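# Metrics, region matching, graph matching.

# Published evaluation counts with the metrics printed alongside them
# (recall %, precision %, F %); NA marks a value not printed or undefined.
published_rows <- list(
  list(id = "arrows/full pipeline",      tp = 1131, fn = 43,  fp = 51,  r = 96.3, p = 95.7, f = 96.0),
  list(id = "diagrams/full pipeline",    tp = 2292, fn = 237, fp = 84,  r = 90.6, p = 96.5, f = 93.5),
  list(id = "labels/full pipeline",      tp = 1439, fn = 464, fp = 504, r = 75.6, p = 74.1, f = 74.8),
  list(id = "conditions/full pipeline",  tp = 756,  fn = 299, fp = 167, r = 71.7, p = 81.9, f = 76.4),
  list(id = "reaction graphs",           tp = 878,  fn = 289, fp = 120, r = 75.2, p = 88.0, f = 81.1),
  list(id = "arrows/single model",       tp = 903,  fn = 326, fp = 129, r = 73.5, p = 87.5, f = 79.9),
  list(id = "diagrams/single model",     tp = 1996, fn = 99,  fp = 204, r = 95.3, p = 90.7, f = 92.9),
  list(id = "labels/single model",       tp = 1319, fn = 545, fp = 485, r = 70.8, p = 73.1, f = 71.9),
  list(id = "conditions/single model",   tp = 491,  fn = 333, fp = 384, r = 59.6, p = 56.1, f = 57.8),
  list(id = "solid arrow subtype",       tp = 1071, fn = 48,  fp = 38,  r = 95.7, p = 96.6, f = 96.1),
  list(id = "curly arrow subtype",       tp = 33,   fn = 5,   fp = 17,  r = 86.8, p = 66.0, f = 75.0),
  list(id = "equilibrium arrow subtype", tp = 12,   fn = 4,   fp = 5,   r = 75.0, p = 70.6, f = 72.7),
  list(id = "labels before postproc",    tp = 1254, fn = 649, fp = 454, r = 65.9, p = 73.4, f = 69.4),
  list(id = "conditions before postproc", tp = 698, fn = 359, fp = 439, r = 66.0, p = 61.4, f = 63.6),
  list(id = "arrows v1 benchmark",       tp = 370,  fn = 48,  fp = 59,  r = 88.5, p = 86.2, f = 87.4),
  list(id = "diagrams v1 benchmark",     tp = 722,  fn = 149, fp = 103, r = 82.9, p = 87.5, f = 85.1),
  list(id = "labels v1 benchmark",       tp = 375,  fn = 79,  fp = 143, r = 82.6, p = 72.4, f = 77.2))

test_that("prf_metrics reproduces the published worked examples", {
  for (row in published_rows) {
    m <- prf_metrics(confusion_counts(tp = row$tp, fn = row$fn, fp = row$fp))
    expect_equal(m$recall, row$r, tolerance = 0.06 / row$r * 100,
                 label = paste(row$id, "recall"))
    expect_equal(round(m$recall, 1), row$r, tolerance = 0.06,
                 label = paste(row$id, "recall"))
    expect_equal(round(m$precision, 1), row$p, tolerance = 0.06,
                 label = paste(row$id, "precision"))
    expect_equal(round(m$f, 1), row$f, tolerance = 0.06,
                 label = paste(row$id, "F"))
  }
})

test_that("diagram-label matching is scored by equivalent recall only", {
  m <- prf_metrics(confusion_counts(tp = 1255, fn = 235, fp = 0))
  expect_equal(round(m$recall, 1), 84.2)
})

test_that("undefined metrics are reported as NA, not numbers", {
  m <- prf_metrics(confusion_counts(tp = 0, fn = 5, fp = 0))
  expect_identical(m$recall, 0)
  expect_true(is.na(m$precision))
  expect_true(is.na(m$f))
  # no true instances and spurious predictions: recall undefined, precision 0
  m2 <- prf_metrics(confusion_counts(tp = 0, fn = 0, fp = 6))
  expect_true(is.na(m2$recall))
  expect_identical(m2$precision, 0)
})

test_that("metric bounds hold for arbitrary counts", {
  set.seed(8)
  for (k in 1:50) {
    m <- prf_metrics(confusion_counts(tp = rpois(1, 20) + 1,
                                      fn = rpois(1, 10), fp = rpois(1, 10)))
    expect_true(m$recall >= 0 && m$recall <= 100)
    expect_true(m$precision >= 0 && m$precision <= 100)
    expect_gte(m$f, min(m$recall, m$precision))
    expect_lte(m$f, max(m$recall, m$precision))
  }
})

test_that("region matching is greedy one-to-one by IoU", {
  gt <- data.frame(x0 = c(0, 100), y0 = 0, x1 = c(50, 150), y1 = 50)
  cm <- match_regions(gt, gt)
  expect_identical(c(cm$tp, cm$fn, cm$fp), c(2L, 0L, 0L))
  cm2 <- match_regions(gt[0, ], gt)
  expect_identical(c(cm2$tp, cm2$fn, cm2$fp), c(0L, 2L, 0L))

  # two predictions on one truth at IoU ~0.9 and ~0.6: one tp, one fp
  one_gt <- data.frame(x0 = 0, y0 = 0, x1 = 100, y1 = 100)
  pred <- data.frame(x0 = c(0, 0), y0 = c(5, 35), x1 = c(100, 100),
                     y1 = c(100, 100))
  cm3 <- match_regions(pred, one_gt, iou_threshold = 0.5)
  expect_identical(c(cm3$tp, cm3$fn, cm3$fp), c(1L, 0L, 1L))
  # brute force over both possible assignments confirms 1 is the maximum
  iou <- vapply(1:2, function(i)
    bbox_iou(bbox(pred$x0[i], pred$y0[i], pred$x1[i], pred$y1[i]),
             bbox(0, 0, 100, 100)), numeric(1))
  expect_identical(sum(iou >= 0.5) >= 1, TRUE)
  expect_identical(cm3$tp, 1L)  # one-to-one: the second match is forbidden
})

test_that("graph matching counts steps through traversal", {
  nodes <- data.frame(id = 1:4, x0 = c(0, 100, 200, 300), y0 = 0,
                      x1 = c(50, 150, 250, 350), y1 = 50)
  chain <- function(k) lapply(seq_len(k), function(i)
    list(arrow = 10 + i, reactants = i, products = i + 1,
         conditions = integer(0)))
  gt <- reaction_graph(nodes, chain(3))
  expect_identical(unclass(match_graphs(gt, gt))[c("tp", "fn", "fp")],
                   list(tp = 3L, fn = 0L, fp = 0L))

  miss <- reaction_graph(nodes, chain(3)[-2])
  cm <- match_graphs(miss, gt)
  expect_identical(c(cm$tp, cm$fn, cm$fp), c(2L, 1L, 0L))
})

test_that("cycle matching is invariant to the random start node", {
  nodes <- data.frame(id = 1:4, x0 = c(0, 100, 200, 300), y0 = 0,
                      x1 = c(50, 150, 250, 350), y1 = 50)
  ring <- lapply(1:4, function(i)
    list(arrow = 20 + i, reactants = i, products = if (i == 4) 1 else i + 1,
         conditions = integer(0)))
  g <- reaction_graph(nodes, ring)
  for (s in 1:8) {
    cm <- match_graphs(g, g, seed = s)
    expect_identical(c(cm$tp, cm$fn, cm$fp), c(4L, 0L, 0L))
  }
})

test_that("graph matching tolerates node relabeling via box correspondence", {
  nodes <- data.frame(id = 1:3, x0 = c(0, 100, 200), y0 = 0,
                      x1 = c(50, 150, 250), y1 = 50)
  gt <- reaction_graph(nodes, list(
    list(arrow = 5, reactants = 1, products = 2, conditions = integer(0)),
    list(arrow = 6, reactants = 2, products = 3, conditions = integer(0))))
  nodes2 <- nodes
  nodes2$id <- c(31, 17, 99)
  pred <- reaction_graph(nodes2, list(
    list(arrow = 50, reactants = 31, products = 17, conditions = integer(0)),
    list(arrow = 60, reactants = 17, products = 99, conditions = integer(0))))
  cm <- match_graphs(pred, gt)
  expect_identical(c(cm$tp, cm$fn, cm$fp), c(2L, 0L, 0L))
})

test_that("per-class evaluation accumulates counts", {
  gt <- data.frame(class = c("diagram", "arrow"),
                   x0 = c(0, 100), y0 = 0, x1 = c(50, 180), y1 = c(50, 20))
  pred <- gt
  rep <- evaluate_detections(pred, gt)
  expect_identical(rep$all$counts$tp, 2L)
  expect_equal(rep$diagram$recall, 100)
  expect_true(is.na(rep$label$precision))
})
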