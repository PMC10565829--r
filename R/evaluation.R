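# Evaluation: precision / recall / F-score, prediction-to-ground-truth
# region matching, and graph-traversal comparison of full reaction schemes.

#' Confusion counts
#'
#' @param tp,fn,fp Non-negative integers: true positives (correctly
#'   extracted data), false negatives (missed data), false positives
#'   (spurious extractions).
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0, fn = 0, fp = 0) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0)
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts tp=%d fn=%d fp=%d>\n", x$tp, x$fn, x$fp))
  invisible(x)
}

#' Precision, recall and F-score (percent)
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`,
#' `F = 2 P R / (P + R)`, reported in percent. Metrics with a zero
#' denominator are undefined and reported as `NA` (printed "N/A"), e.g.
#' precision when nothing was predicted. Values are returned at full
#' precision; the print method rounds to one decimal for display.
#'
#' @param counts A [confusion_counts()] (or anything with `tp`, `fn`, `fp`).
#' @return Object of class `prf_metrics`: list with `recall`, `precision`,
#'   `f` in percent (`NA` where undefined) and the input counts.
#' @examples
#' m <- prf_metrics(confusion_counts(tp = 1131, fn = 43, fp = 51))
#' round(c(m$recall, m$precision, m$f), 1)  # 96.3 95.7 96.0
#' @export
prf_metrics <- function(counts) {
  tp <- counts$tp; fn <- counts$fn; fp <- counts$fp
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  f <- if (!is.na(recall) && !is.na(precision) && (recall + precision) > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(recall = recall, precision = precision, f = f,
                 counts = counts),
            class = "prf_metrics")
}

#' @export
print.prf_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "N/A" else sprintf("%.1f%%", v)
  cat(sprintf("recall %s  precision %s  F-score %s  (tp=%d fn=%d fp=%d)\n",
              fmt(x$recall), fmt(x$precision), fmt(x$f),
              x$counts$tp, x$counts$fn, x$counts$fp))
  invisible(x)
}

#' Match predicted regions to ground truth by IoU
#'
#' Greedy one-to-one matching: candidate (pred, gt) pairs are sorted by
#' descending IoU and accepted while both members are unmatched and the IoU
#' reaches the threshold. Matched pairs are true positives, unmatched
#' ground-truth boxes false negatives, unmatched predictions false
#' positives. Compare boxes of one class at a time.
#'
#' @param pred,gt data.frames with `x0, y0, x1, y1` columns.
#' @param iou_threshold IoU acceptance threshold in (0, 1); default 0.5.
#' @return A [confusion_counts()].
#' @export
match_regions <- function(pred, gt, iou_threshold = 0.5) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  np <- if (is.null(pred)) 0L else nrow(pred)
  ng <- if (is.null(gt)) 0L else nrow(gt)
  if (np == 0 || ng == 0) {
    return(confusion_counts(tp = 0, fn = ng, fp = np))
  }
  pairs <- expand.grid(p = seq_len(np), g = seq_len(ng))
  pairs$iou <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs$p[k]; j <- pairs$g[k]
    bbox_iou(bbox(pred$x0[i], pred$y0[i], pred$x1[i], pred$y1[i]),
             bbox(gt$x0[j], gt$y0[j], gt$x1[j], gt$y1[j]))
  }, numeric(1))
  pairs <- pairs[pairs$iou >= iou_threshold, , drop = FALSE]
  pairs <- pairs[order(-pairs$iou, pairs$p, pairs$g), , drop = FALSE]
  used_p <- logical(np); used_g <- logical(ng)
  tp <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$p[k]; j <- pairs$g[k]
    if (!used_p[i] && !used_g[j]) {
      used_p[i] <- TRUE; used_g[j] <- TRUE
      tp <- tp + 1L
    }
  }
  confusion_counts(tp = tp, fn = ng - tp, fp = np - tp)
}

# node correspondence between two graphs by diagram-box IoU (greedy by
# descending IoU; ambiguity resolved by highest IoU)
node_correspondence <- function(gt, pred, iou_threshold = 0.5) {
  if (nrow(gt$nodes) == 0 || nrow(pred$nodes) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  pairs <- expand.grid(g = seq_len(nrow(gt$nodes)),
                       p = seq_len(nrow(pred$nodes)))
  pairs$iou <- vapply(seq_len(nrow(pairs)), function(k) {
    g <- gt$nodes[pairs$g[k], ]; p <- pred$nodes[pairs$p[k], ]
    bbox_iou(bbox(g$x0, g$y0, g$x1, g$y1), bbox(p$x0, p$y0, p$x1, p$y1))
  }, numeric(1))
  pairs <- pairs[pairs$iou >= iou_threshold, , drop = FALSE]
  pairs <- pairs[order(-pairs$iou, pairs$g, pairs$p), , drop = FALSE]
  used_g <- logical(nrow(gt$nodes)); used_p <- logical(nrow(pred$nodes))
  map <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    gi <- pairs$g[k]; pi <- pairs$p[k]
    if (!used_g[gi] && !used_p[pi]) {
      used_g[gi] <- TRUE; used_p[pi] <- TRUE
      map[as.character(gt$nodes$id[gi])] <- as.integer(pred$nodes$id[pi])
    }
  }
  map
}

# order steps along a traversal from the graph's start nodes (in-degree 0);
# for cyclic graphs with no start node, start from a seeded random node and
# walk the cycle back to it.
traversal_order <- function(g, seed = 1) {
  if (length(g$steps) == 0) return(integer(0))
  reactant_sets <- lapply(g$steps, `[[`, "reactants")
  product_sets <- lapply(g$steps, `[[`, "products")
  all_products <- unique(unlist(product_sets))
  start_steps <- which(vapply(seq_along(g$steps), function(i)
    !any(reactant_sets[[i]] %in% all_products), logical(1)))
  order_out <- integer(0)
  visited <- logical(length(g$steps))
  frontier <- start_steps
  if (length(frontier) == 0) {
    # cyclic: seed a random node and begin at a step consuming it
    start_node <- with_seed(seed, sample(g$nodes$id, 1))
    frontier <- which(vapply(reactant_sets, function(r)
      start_node %in% r, logical(1)))[1]
  }
  while (length(frontier)) {
    i <- frontier[1]; frontier <- frontier[-1]
    if (is.na(i) || visited[i]) next
    visited[i] <- TRUE
    order_out <- c(order_out, i)
    nxt <- which(vapply(seq_along(g$steps), function(j)
      !visited[j] && any(reactant_sets[[j]] %in% product_sets[[i]]),
      logical(1)))
    frontier <- c(frontier, nxt)
  }
  c(order_out, which(!visited))   # disconnected steps appended
}

#' Compare two reaction graphs by traversal
#'
#' Establishes a node correspondence between ground truth and prediction by
#' diagram-box IoU, finds the starting nodes (steps whose reactants are not
#' produced by any step) in both graphs, and traverses each graph from its
#' starts, storing reaction steps. A ground-truth step counts as a true
#' positive when the prediction contains a step whose reactant and product
#' node sets correspond to it; unmatched ground-truth steps are false
#' negatives and unmatched predicted steps false positives. Cyclic schemes,
#' which have no starting node, are handled by seeding a random start node
#' and walking the circular path back to it; the counts are invariant to
#' that choice.
#'
#' @param pred,gt [reaction_graph()]s.
#' @param iou_threshold Node-correspondence IoU threshold (default 0.5, the
#'   same as region matching).
#' @param seed Seed for the cyclic start-node choice.
#' @return A [confusion_counts()] over reaction steps.
#' @export
match_graphs <- function(pred, gt, iou_threshold = 0.5, seed = 1) {
  stopifnot(inherits(pred, "reaction_graph"), inherits(gt, "reaction_graph"))
  map <- node_correspondence(gt, pred, iou_threshold)
  gt_order <- traversal_order(gt, seed = seed)
  pred_steps <- lapply(pred$steps, function(s)
    list(r = sort(s$reactants), p = sort(s$products)))
  used_pred <- logical(length(pred_steps))
  tp <- 0L
  for (i in gt_order) {
    s <- gt$steps[[i]]
    r_m <- map[as.character(s$reactants)]
    p_m <- map[as.character(s$products)]
    if (anyNA(r_m) || anyNA(p_m)) next   # unmatched node: step cannot match
    r_m <- sort(as.integer(unname(r_m))); p_m <- sort(as.integer(unname(p_m)))
    for (j in seq_along(pred_steps)) {
      if (used_pred[j]) next
      if (identical(pred_steps[[j]]$r, r_m) &&
          identical(pred_steps[[j]]$p, p_m)) {
        used_pred[j] <- TRUE
        tp <- tp + 1L
        break
      }
    }
  }
  confusion_counts(tp = tp, fn = length(gt$steps) - tp,
                   fp = sum(!used_pred))
}

#' Evaluate detections per class over a set of schemes
#'
#' Convenience wrapper: matches predictions to ground truth class by class
#' with [match_regions()], accumulates counts, and reports
#' [prf_metrics()] per class.
#'
#' @param pred,gt Region data.frames (with a `class` column).
#' @param classes Classes to evaluate.
#' @param iou_threshold IoU threshold.
#' @return Named list of `prf_metrics`, one per class, plus `"all"`.
#' @export
evaluate_detections <- function(pred, gt,
                                classes = c("diagram", "label",
                                            "conditions", "arrow"),
                                iou_threshold = 0.5) {
  out <- list()
  tot <- confusion_counts()
  for (cl in classes) {
    cc <- match_regions(pred[pred$class == cl, , drop = FALSE],
                        gt[gt$class == cl, , drop = FALSE],
                        iou_threshold)
    out[[cl]] <- prf_metrics(cc)
    tot <- confusion_counts(tot$tp + cc$tp, tot$fn + cc$fn, tot$fp + cc$fp)
  }
  out$all <- prf_metrics(tot)
  out
}
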