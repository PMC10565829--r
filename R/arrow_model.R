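# Arrow detection: connected-component proposal filtering, 64 x 64 patch
# extraction, and a two-branch convolutional model (binary arrow detector +
# 4-way arrow-type classifier) trained under a combined loss.

ARROW_SUBTYPES <- c("solid", "curly", "equilibrium", "resonance")

#' Arrow object
#'
#' @param cc The arrow's [conncomp()].
#' @param subtype One of `"solid"`, `"curly"`, `"equilibrium"`,
#'   `"resonance"`, or `NA` when undetermined.
#' @param score Detection score in `[0, 1]`.
#' @param id Optional region id.
#' @return Object of class `arrow`.
#' @export
arrow_obj <- function(cc, subtype = NA_character_, score = 1, id = NA_integer_) {
  stopifnot(inherits(cc, "conncomp"), score >= 0, score <= 1)
  if (!is.na(subtype)) stopifnot(subtype %in% ARROW_SUBTYPES)
  structure(list(cc = cc, subtype = subtype, score = score, id = id),
            class = "arrow")
}

#' @export
print.arrow <- function(x, ...) {
  cat(sprintf("<arrow %s, score %.3f, area %d>\n",
              x$subtype %||% "?", x$score, x$cc$area))
  invisible(x)
}

#' Filter connected components to arrow candidates
#'
#' Keeps components passing simple, configurable bounds: area at least
#' `min_area` pixels and at most `max_area_frac` of the image, and either
#' elongated (bbox aspect at least `min_elongation`) or sparse (foreground
#' fill ratio of the bbox at most `max_fill`) -- arrows are thin, elongated
#' or arc-like strokes. Input order is preserved.
#'
#' @param ccs List of [conncomp()] from [find_connected_components()].
#' @param image_dim `c(width, height)` in pixels.
#' @param min_area,max_area_frac,min_elongation,max_fill Filter bounds.
#' @return The surviving subset of `ccs`.
#' @export
propose_arrow_candidates <- function(ccs, image_dim, min_area = 20,
                                     max_area_frac = 0.05,
                                     min_elongation = 2, max_fill = 0.2) {
  max_area <- max_area_frac * image_dim[1] * image_dim[2]
  Filter(function(cc) {
    if (cc$area < min_area || cc$area > max_area) return(FALSE)
    w <- bbox_width(cc$bbox); h <- bbox_height(cc$bbox)
    elong <- max(w, h) / min(w, h)
    fill <- cc$area / (w * h)
    elong >= min_elongation || fill <= max_fill
  }, ccs)
}

#' Extract a centered 64 x 64 patch for one connected component
#'
#' Crops the component's bounding box, masks out every pixel that does not
#' belong to the component itself (neighboring ink is removed, so the patch
#' contains a single, isolated connected component), pads to a square with
#' the content centered, and rescales to `size` x `size` preserving aspect.
#'
#' @param bin A [binary_image()] (used only for its dimensions; the pixels
#'   come from `cc`).
#' @param cc A [conncomp()].
#' @param size Patch side length (default 64).
#' @return Object of class `arrow_patch`: a `size` x `size` numeric matrix
#'   in `[0, 1]` with the source component attached as attribute `cc`.
#' @export
extract_patch <- function(bin, cc, size = 64L) {
  b <- cc$bbox
  w <- as.integer(bbox_width(b)); h <- as.integer(bbox_height(b))
  m <- matrix(0, h, w)
  m[(cc$pixels[, "x"] - b[["x0"]]) * h + (cc$pixels[, "y"] - b[["y0"]]) + 1L] <- 1
  s <- max(w, h)
  sq <- matrix(0, s, s)
  oy <- (s - h) %/% 2L; ox <- (s - w) %/% 2L
  sq[(oy + 1):(oy + h), (ox + 1):(ox + w)] <- m
  if (s != size) {
    img <- EBImage::resize(EBImage::Image(t(sq)), w = size, h = size,
                           filter = "none")
    sq <- t(EBImage::imageData(img))
  }
  structure(sq, class = "arrow_patch", cc = cc)
}

#' Combined two-branch arrow loss
#'
#' The detector branch emits the probability that a patch contains an arrow
#' and is scored with binary cross-entropy; the classifier branch emits a
#' distribution over the four arrow subtypes and is scored with categorical
#' cross-entropy. The total is `lambda1 * BCE + lambda2 * CE` with defaults
#' `lambda1 = 10`, `lambda2 = 1`; the CE term contributes only for true
#' arrows (`label > 0`), since a subtype is undefined for non-arrow patches.
#'
#' @param det_out Probability in `[0, 1]` that the patch is an arrow.
#' @param cls_out Numeric length-4 probability vector over subtypes
#'   (solid, curly, equilibrium, resonance).
#' @param label Integer in 0..4: 0 = non-arrow, 1-4 = subtype index.
#' @param lambda1,lambda2 Branch weights.
#' @return Non-negative scalar loss; zero iff the detector output matches
#'   the binary label exactly and (for arrows) the classifier is one-hot
#'   correct.
#' @examples
#' combined_arrow_loss(0.5, rep(0.25, 4), 0L)  # 10 * log(2)
#' @export
combined_arrow_loss <- function(det_out, cls_out, label,
                                lambda1 = 10, lambda2 = 1) {
  stopifnot(length(det_out) == 1, length(label) == 1, label %in% 0:4)
  if (det_out < 0 || det_out > 1) stop("det_out must be a probability in [0, 1]")
  if (any(cls_out < 0) || any(cls_out > 1)) {
    stop("cls_out must be probabilities in [0, 1]")
  }
  eps <- 1e-12
  y <- as.numeric(label > 0)
  bce <- -(y * log(max(det_out, eps)) + (1 - y) * log(max(1 - det_out, eps)))
  ce <- if (label > 0) -log(max(cls_out[label], eps)) else 0
  lambda1 * bce + lambda2 * ce
}

#' Train the two-branch arrow model
#'
#' Trains a small convolutional backbone (three 3x3 conv / max-pool stages
#' and a shared fully connected layer) with two heads end-to-end: a 1-unit
#' detector head under binary cross-entropy and a 4-unit subtype classifier
#' (two fully connected layers) under categorical cross-entropy masked on
#' non-arrow patches. Defaults follow the published recipe: 20 epochs, Adam,
#' learning rate 0.001, branch weights `lambda1 = 10`, `lambda2 = 1`.
#' Deterministic for fixed data and seed.
#'
#' @param patches List of [extract_patch()] patches (or 64 x 64 matrices).
#' @param labels Integer vector in 0..4 (0 = non-arrow).
#' @param epochs,lr,batch_size,lambda1,lambda2 Training hyperparameters.
#' @param seed Integer seed for initialization and shuffling.
#' @param verbose Print per-epoch mean loss.
#' @return Object of class `arrow_model`: the network, the hyperparameters,
#'   and `history` (mean training loss per epoch). `epochs = 0` returns the
#'   randomly initialized model.
#' @export
train_arrow_model <- function(patches, labels, epochs = 20, lr = 0.001,
                              batch_size = 32, lambda1 = 10, lambda2 = 1,
                              seed = 1, verbose = FALSE) {
  stopifnot(length(patches) == length(labels), all(labels %in% 0:4))
  if (epochs > 0 && (all(labels > 0) || all(labels == 0))) {
    stop("training set must contain both arrow and non-arrow patches")
  }
  net <- cnn_init(seed = seed, heads = list(det = 1L, cls = c(32L, 4L)))
  hist <- numeric(0)
  if (epochs > 0) {
    params <- nn_params(net)
    opt <- optimizer_init("adam", params, lr = lr)
    n <- length(patches)
    with_seed(child_seed(seed, 1), {
      for (ep in seq_len(epochs)) {
        ord <- sample(n)
        ep_loss <- 0
        for (start in seq(1, n, by = batch_size)) {
          ids <- ord[start:min(start + batch_size - 1, n)]
          gacc <- NULL
          bloss <- 0
          for (i in ids) {
            fw <- cnn_forward(net, as.numeric(patches[[i]]), train = TRUE)
            zd <- fw$out$det
            zc <- fw$out$cls
            y <- as.numeric(labels[i] > 0)
            p <- sigmoid(zd)
            bce <- log(1 + exp(-abs(zd))) + max(zd, 0) - y * zd
            dzd <- lambda1 * (p - y)
            if (labels[i] > 0) {
              sm <- softmax(zc)
              ce <- logsumexp(zc) - zc[labels[i]]
              dzc <- lambda2 * sm
              dzc[labels[i]] <- dzc[labels[i]] - lambda2
            } else {
              ce <- 0
              dzc <- numeric(4)
            }
            bloss <- bloss + lambda1 * bce + lambda2 * ce
            g <- grads_as_params(net, cnn_backward(net, fw$cache,
                                                   list(det = dzd, cls = dzc)))
            gacc <- if (is.null(gacc)) g
                    else Map(`+`, gacc, g)
          }
          gacc <- lapply(gacc, function(g) g / length(ids))
          st <- optimizer_step(opt, params, gacc)
          opt <- st$opt; params <- st$params
          net <- nn_set_params(net, params)
          ep_loss <- ep_loss + bloss
        }
        hist <- c(hist, ep_loss / n)
        if (verbose) message(sprintf("epoch %d: loss %.4f", ep, ep_loss / n))
      }
    })
  }
  structure(list(net = net,
                 config = list(epochs = epochs, lr = lr,
                               batch_size = batch_size, lambda1 = lambda1,
                               lambda2 = lambda2, seed = seed,
                               optimizer = "adam"),
                 history = hist, subtypes = ARROW_SUBTYPES),
            class = "arrow_model")
}

#' @export
print.arrow_model <- function(x, ...) {
  cat(sprintf("<arrow_model: %d epoch(s) trained, final loss %s>\n",
              x$config$epochs,
              if (length(x$history)) sprintf("%.4f", utils::tail(x$history, 1))
              else "n/a"))
  invisible(x)
}

#' Predict detector and classifier probabilities for patches
#'
#' @param model An [train_arrow_model()] model.
#' @param patches List of patches (or a single patch).
#' @return List with `det` (numeric vector of arrow probabilities) and
#'   `cls` (matrix, one row per patch, columns the four subtypes).
#' @export
predict_arrow_model <- function(model, patches) {
  stopifnot(inherits(model, "arrow_model"))
  if (!is.list(patches)) patches <- list(patches)
  det <- numeric(length(patches))
  cls <- matrix(0, length(patches), 4,
                dimnames = list(NULL, model$subtypes))
  for (i in seq_along(patches)) {
    out <- cnn_forward(model$net, as.numeric(patches[[i]]), train = FALSE)
    det[i] <- sigmoid(out$det)
    cls[i, ] <- softmax(out$cls)
  }
  list(det = det, cls = cls)
}

#' Detect arrows in a binary image
#'
#' Runs the full arrow branch: connected components, proposal filtering,
#' patch extraction, and the two-branch model. Components whose detector
#' probability reaches `threshold` are returned as arrows with the
#' classifier's argmax subtype. An arrow fused to other ink is not an
#' isolated connected component: only the merged blob exists as a proposal,
#' so the arrow itself cannot be recovered, by design.
#'
#' @param bin A [binary_image()].
#' @param model An [train_arrow_model()] model.
#' @param threshold Detector probability threshold (default 0.5).
#' @param proposal Optional named list of [propose_arrow_candidates()]
#'   bounds.
#' @param ccs Optional precomputed component list.
#' @return List of [arrow_obj()].
#' @export
detect_arrows <- function(bin, model, threshold = 0.5, proposal = list(),
                          ccs = NULL) {
  stopifnot(inherits(bin, "binary_image"))
  if (is.null(ccs)) ccs <- find_connected_components(bin)
  if (length(ccs) == 0) return(list())
  cand <- do.call(propose_arrow_candidates,
                  c(list(ccs = ccs, image_dim = c(bin$width, bin$height)),
                    proposal))
  if (length(cand) == 0) return(list())
  patches <- lapply(cand, function(cc) extract_patch(bin, cc))
  pred <- predict_arrow_model(model, patches)
  out <- list()
  for (i in seq_along(cand)) {
    if (pred$det[i] >= threshold) {
      out[[length(out) + 1L]] <-
        arrow_obj(cand[[i]],
                  subtype = model$subtypes[which.max(pred$cls[i, ])],
                  score = pred$det[i])
    }
  }
  out
}

#' Build a labelled 64 x 64 patch dataset from procedural glyphs
#'
#' Renders augmented arrow glyphs of all four subtypes as positives and
#' augmented diagram / label / conditions / decoy glyphs as negatives, each
#' reduced to its largest connected component and embedded in a centered
#' patch. This is the desk-scale training source for the arrow model.
#'
#' @param n_arrow,n_negative Patch counts (arrows are split evenly over the
#'   four subtypes).
#' @param bank Optional [build_element_bank()]; built from `seed` if absent.
#' @param seed Integer seed.
#' @return List with `patches` (list of patches) and `labels` (integer
#'   vector, 0 = non-arrow, 1-4 = subtype).
#' @export
make_arrow_patch_dataset <- function(n_arrow = 100, n_negative = 100,
                                     bank = NULL, seed = 1) {
  if (is.null(bank)) bank <- build_element_bank(seed = child_seed(seed, 99))
  patch_of_glyph <- function(g) {
    m <- glyph_mask(g)
    bin <- binary_image(m)
    ccs <- find_connected_components(bin)
    cc <- ccs[[which.max(vapply(ccs, function(x) x$area, numeric(1)))]]
    extract_patch(bin, cc)
  }
  patches <- list()
  labels <- integer(0)
  with_seed(seed, {
    for (i in seq_len(n_arrow)) {
      st <- ARROW_SUBTYPES[(i - 1L) %% 4L + 1L]
      base <- bank$arrow[[st]][[sample(length(bank$arrow[[st]]), 1)]]
      g <- augment_glyph(base, scale = c(0.8, 1.25), rotate = c(-10, 10),
                         p_blur = 0.3)
      patches[[length(patches) + 1L]] <- patch_of_glyph(g)
      labels <- c(labels, (i - 1L) %% 4L + 1L)
    }
    neg_classes <- c("diagram", "label", "conditions", "negative")
    neg_classes <- neg_classes[vapply(neg_classes, function(cl)
      length(bank[[cl]]) > 0, logical(1))]
    for (i in seq_len(n_negative)) {
      cl <- neg_classes[(i - 1L) %% length(neg_classes) + 1L]
      base <- bank[[cl]][[sample(length(bank[[cl]]), 1)]]
      g <- augment_glyph(base, scale = c(0.8, 1.25), rotate = c(-10, 10),
                         p_blur = 0.3)
      patches[[length(patches) + 1L]] <- patch_of_glyph(g)
      labels <- c(labels, 0L)
    }
  })
  list(patches = patches, labels = labels)
}
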