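# Arrow branch: proposals, patches, the combined loss, training, detection.

test_that("combined loss reproduces hand-computed values", {
  # perfect prediction: zero loss
  expect_equal(combined_arrow_loss(1.0, c(1, 0, 0, 0), 1L), 0)
  expect_equal(combined_arrow_loss(0.0, rep(0.25, 4), 0L), 0)
  # uncertain detector on a negative: 10 * ln 2
  expect_equal(combined_arrow_loss(0.5, rep(0.25, 4), 0L), 10 * log(2),
               tolerance = 1e-9)
  # branch weights lambda1 = 10, lambda2 = 1 are the defaults
  expect_equal(combined_arrow_loss(0.5, c(0.5, 0.5, 0, 0), 1L),
               10 * log(2) + 1 * (-log(0.5)), tolerance = 1e-9)
  # the subtype term is masked for non-arrows
  expect_equal(combined_arrow_loss(0, c(0.1, 0.2, 0.3, 0.4), 0L), 0)
  expect_error(combined_arrow_loss(1.2, rep(0.25, 4), 0L), "probability")
  expect_error(combined_arrow_loss(0.5, c(2, 0, 0, 0), 1L), "probabilities")
})

test_that("proposal filtering keeps elongated strokes, drops dots", {
  line <- conncomp(cbind(x = 0:199, y = rep(5L, 200)))
  dot <- conncomp(as.matrix(expand.grid(x = 1:3, y = 1:3)))
  kept <- propose_arrow_candidates(list(line, dot), image_dim = c(400, 200))
  expect_length(kept, 1)
  expect_identical(kept[[1]]$area, 200L)
})

test_that("every ground-truth arrow survives the default proposal filter", {
  sc <- fx_scheme(seed = 19, n_steps = 3)
  bin <- binarize(sc$image)
  ccs <- find_connected_components(bin)
  cand <- propose_arrow_candidates(ccs, c(bin$width, bin$height))
  areg <- sc$annotation$regions[sc$annotation$regions$class == "arrow", ]
  for (i in seq_len(nrow(areg))) {
    ab <- bbox(areg$x0[i] - 1, areg$y0[i] - 1, areg$x1[i] + 1, areg$y1[i] + 1)
    hit <- any(vapply(cand, function(cc) {
      cb <- cc$bbox
      cb[["x0"]] >= ab[["x0"]] && cb[["x1"]] <= ab[["x1"]] &&
        cb[["y0"]] >= ab[["y0"]] && cb[["y1"]] <= ab[["y1"]]
    }, logical(1)))
    expect_true(hit)
  }
})

test_that("extract_patch centers, rescales, and isolates its component", {
  # a full 64 x 64 component passes through unchanged
  m <- matrix(TRUE, 64, 64)
  bin <- binary_image(m)
  cc <- find_connected_components(bin)[[1]]
  p <- extract_patch(bin, cc)
  expect_identical(dim(unclass(p)), c(64L, 64L))
  expect_true(all(unclass(p) > 0.5))

  # 128 x 32 solid block: aspect preserved -> 64 x 16 content, centered
  m2 <- matrix(FALSE, 40, 130)
  m2[5:36, 2:129] <- TRUE
  bin2 <- binary_image(m2)
  cc2 <- find_connected_components(bin2)[[1]]
  p2 <- extract_patch(bin2, cc2)
  rows_with_ink <- range(which(rowSums(unclass(p2)) > 0))
  expect_identical(diff(rows_with_ink) + 1L, 16L)
  expect_equal(mean(rows_with_ink), 32.5, tolerance = 1.5)

  # a neighbouring component inside the crop window is masked out
  m3 <- matrix(FALSE, 80, 80)
  m3[11:74, 11:14] <- TRUE   # component A: 64 x 64 bbox L-shape
  m3[71:74, 11:74] <- TRUE
  m3[30:40, 40:55] <- TRUE   # component B, strictly inside A's bbox
  bin3 <- binary_image(m3)
  ccs3 <- find_connected_components(bin3)
  expect_length(ccs3, 2)
  a_cc <- ccs3[[which.max(vapply(ccs3, function(x) x$area, numeric(1)))]]
  pa <- extract_patch(bin3, a_cc)      # bbox is 64 x 64: no resize
  expect_identical(sum(unclass(pa) > 0.5), a_cc$area)
  # B's pixels (relative to A's bbox) are absent from the patch
  expect_true(all(unclass(pa)[20:30, 30:45] < 0.5))
})

test_that("training rejects degenerate label sets", {
  ds <- fx_patch_data()
  arr_idx <- which(ds$labels > 0)[1:10]
  expect_error(train_arrow_model(ds$patches[arr_idx], ds$labels[arr_idx],
                                 epochs = 1), "both arrow and non-arrow")
})

test_that("zero-epoch training returns an untrained model without error", {
  ds <- fx_patch_data()
  m <- train_arrow_model(ds$patches[1:8], ds$labels[1:8], epochs = 0)
  expect_s3_class(m, "arrow_model")
  expect_length(m$history, 0)
  pred <- predict_arrow_model(m, ds$patches[1:2])
  expect_true(all(pred$det >= 0 & pred$det <= 1))
})

test_that("the trained model separates arrows from other glyphs", {
  model <- fx_arrow_model()
  sp <- fx_patch_split()
  ds <- fx_patch_data()
  pred <- predict_arrow_model(model, ds$patches[sp$test])
  acc <- mean((pred$det >= 0.5) == (ds$labels[sp$test] > 0))
  expect_gte(acc, 0.95)
  # training loss decreased over the run
  expect_lte(utils::tail(model$history, 1), model$history[1])
})

test_that("detection output is a subset of the proposals", {
  model <- fx_arrow_model()
  sc <- fx_scheme(seed = 23, n_steps = 2)
  bin <- binarize(sc$image)
  ccs <- find_connected_components(bin)
  cand <- propose_arrow_candidates(ccs, c(bin$width, bin$height))
  arrows <- detect_arrows(bin, model)
  cand_keys <- vapply(cand, function(cc) paste(cc$bbox, collapse = ","),
                      character(1))
  for (a in arrows) {
    expect_true(paste(a$cc$bbox, collapse = ",") %in% cand_keys)
  }
})

test_that("a minimal scheme yields exactly one solid arrow detection", {
  model <- fx_arrow_model()
  sch <- schema_spec("linear", n_steps = 1, diagrams_per_step = c(1, 1),
                     p_label = 0, p_conditions = 0, n_negatives = c(0, 0))
  sc <- compose_scheme(sch, fx_bank(), seed = 31)
  bin <- binarize(sc$image)
  arrows <- detect_arrows(bin, model)
  expect_length(arrows, 1)
  expect_identical(arrows[[1]]$subtype, "solid")
  expect_identical(detect_arrows(binary_image(matrix(FALSE, 40, 40)), model),
                   list())
})

test_that("an arrow fused to text can no longer be recovered", {
  model <- fx_arrow_model()
  g <- rxnscheme:::render_arrow("solid", len = 80)
  txt <- rxnscheme:::draw_text_block(5)
  m <- matrix(FALSE, 80, 140)
  m[40:(39 + nrow(g)), 10:(9 + ncol(g))] <- unclass(g)[, ]
  arrow_box <- bbox(9, 39, 9 + ncol(g), 39 + nrow(g))
  m[20:(19 + nrow(txt)), 25:(24 + ncol(txt))] <-
    m[20:(19 + nrow(txt)), 25:(24 + ncol(txt))] | txt
  # strokes gluing the text onto the shaft: arrow and text become one blob
  m <- rxnscheme:::draw_segment(m, 35, 25, 35, 46, 2)
  m <- rxnscheme:::draw_segment(m, 60, 25, 60, 46, 2)
  bin <- binary_image(m)
  ccs <- find_connected_components(bin)
  areas <- vapply(ccs, function(cc) cc$area, numeric(1))
  fused <- ccs[[which.max(areas)]]
  # the arrow is subsumed: no proposal corresponds to the arrow itself, so
  # no detection can recover the arrow's own box
  expect_gt(fused$area, 0.6 * sum(areas))
  arrows <- detect_arrows(bin, model)
  for (a in arrows) {
    expect_lt(bbox_iou(a$cc$bbox, arrow_box), 0.8)
  }
})

test_that("training is deterministic under a fixed seed", {
  ds <- fx_patch_data()
  idx <- c(which(ds$labels > 0)[1:12], which(ds$labels == 0)[1:12])
  m1 <- train_arrow_model(ds$patches[idx], ds$labels[idx], epochs = 2,
                          seed = 5)
  m2 <- train_arrow_model(ds$patches[idx], ds$labels[idx], epochs = 2,
                          seed = 5)
  expect_identical(rxnscheme:::object_hash(rxnscheme:::nn_params(m1$net)),
                   rxnscheme:::object_hash(rxnscheme:::nn_params(m2$net)))
})
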