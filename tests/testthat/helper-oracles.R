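# Independent brute-force oracles used to verify the implementation.
# These deliberately avoid the package's own code paths.

# Otsu threshold by exhaustive sweep over 256 candidate thresholds,
# maximizing between-class variance.
oracle_otsu_threshold <- function(img) {
  vals <- as.vector(img)
  cand <- seq(min(vals), max(vals), length.out = 256)
  best <- -Inf
  best_thr <- cand[1]
  for (thr in cand) {
    lo <- vals[vals < thr]
    hi <- vals[vals >= thr]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(vals)
    w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best) {
      best <- v
      best_thr <- thr
    }
  }
  best_thr
}

# 8-connected component labeling by explicit stack-based flood fill.
oracle_flood_fill_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  k <- 0L
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      if (mask[i, j] && lab[i, j] == 0L) {
        k <- k + 1L
        stack <- list(c(i, j))
        while (length(stack)) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          if (p[1] < 1 || p[1] > h || p[2] < 1 || p[2] > w) next
          if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
          lab[p[1], p[2]] <- k
          for (di in -1:1) for (dj in -1:1) {
            if (di || dj) stack[[length(stack) + 1L]] <- c(p[1] + di, p[2] + dj)
          }
        }
      }
    }
  }
  lab
}

# Minimal distance between two boxes by dense sampling of integer points.
oracle_box_distance <- function(a, b, step = 0.5) {
  ax <- seq(a[["x0"]], a[["x1"]], by = step)
  ay <- seq(a[["y0"]], a[["y1"]], by = step)
  bx <- seq(b[["x0"]], b[["x1"]], by = step)
  by <- seq(b[["y0"]], b[["y1"]], by = step)
  best <- Inf
  for (x1 in ax) for (y1 in ay) {
    dx <- pmax(0, b[["x0"]] - x1, x1 - b[["x1"]])
    # nearest b point in y for each candidate: clamp
    yb <- pmin(pmax(y1, b[["y0"]]), b[["y1"]])
    xb <- pmin(pmax(x1, b[["x0"]]), b[["x1"]])
    best <- min(best, sqrt((x1 - xb)^2 + (y1 - yb)^2))
  }
  best
}

# Zhang-Suen thinning; returns a skeleton mask.
oracle_skeletonize <- function(mask) {
  m <- mask
  pad <- function(x) rbind(FALSE, cbind(FALSE, x, FALSE), FALSE)
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p <- pad(m)
      h <- nrow(m); w <- ncol(m)
      idx <- which(m, arr.ind = TRUE)
      if (nrow(idx) == 0) break
      del <- logical(nrow(idx))
      for (q in seq_len(nrow(idx))) {
        i <- idx[q, 1] + 1L; j <- idx[q, 2] + 1L
        nb <- c(p[i - 1, j], p[i - 1, j + 1], p[i, j + 1], p[i + 1, j + 1],
                p[i + 1, j], p[i + 1, j - 1], p[i, j - 1], p[i - 1, j - 1])
        B <- sum(nb)
        if (B < 2 || B > 6) next
        A <- sum(diff(c(nb, nb[1])) == 1)
        if (A != 1) next
        if (phase == 1) {
          if ((nb[1] && nb[3] && nb[5]) || (nb[3] && nb[5] && nb[7])) next
        } else {
          if ((nb[1] && nb[3] && nb[7]) || (nb[1] && nb[5] && nb[7])) next
        }
        del[q] <- TRUE
      }
      if (any(del)) {
        m[idx[del, , drop = FALSE]] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Skeleton endpoints: skeleton pixels with exactly one 8-neighbour,
# clustered with the given merge radius (one physical arrow end can leave
# several degree-1 pixels, e.g. the two barbs of a hook).
oracle_skeleton_endpoints <- function(mask, merge_radius) {
  sk <- oracle_skeletonize(mask)
  p <- rbind(FALSE, cbind(FALSE, sk, FALSE), FALSE)
  idx <- which(sk, arr.ind = TRUE)
  deg1 <- idx[vapply(seq_len(nrow(idx)), function(q) {
    i <- idx[q, 1] + 1L; j <- idx[q, 2] + 1L
    sum(p[(i - 1):(i + 1), (j - 1):(j + 1)]) - 1L == 1L
  }, logical(1)), , drop = FALSE]
  if (nrow(deg1) == 0) return(deg1)
  pts <- deg1[, c(2, 1), drop = FALSE] - 1L  # to (x, y) 0-based
  oracle_cluster_points(pts, merge_radius)
}

# transitive single-linkage clustering of 2-D points; returns cluster means
oracle_cluster_points <- function(pts, radius) {
  n <- nrow(pts)
  memb <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (memb[i] != memb[j] &&
          sqrt(sum((pts[i, ] - pts[j, ])^2)) <= radius) {
        memb[memb == memb[j]] <- memb[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  do.call(rbind, lapply(unique(memb), function(k)
    colMeans(pts[memb == k, , drop = FALSE])))
}

# endpoint-set agreement: cluster both point sets at the same radius; they
# agree when the cluster counts match and every detected cluster lies within
# the radius of a skeleton cluster
oracle_endpoints_agree <- function(detected, skeleton_pts, radius) {
  dc <- oracle_cluster_points(detected, radius)
  sc <- skeleton_pts
  if (nrow(dc) != nrow(sc)) return(FALSE)
  for (i in seq_len(nrow(dc))) {
    d <- sqrt((sc[, 1] - dc[i, 1])^2 + (sc[, 2] - dc[i, 2])^2)
    if (min(d) > radius) return(FALSE)
  }
  TRUE
}

# A random procedural curly arrow (quadratic arc + hook), returned as an
# arrow object, for the geometry test suite.
oracle_random_curly <- function(seed) {
  rxnscheme:::with_seed(seed, {
    len <- runif(1, 60, 110)
    g <- rxnscheme:::render_arrow("curly", len = len,
                                  thickness = runif(1, 2, 3),
                                  angle = runif(1, 0, 360))
    m <- matrix(FALSE, nrow(g) + 8, ncol(g) + 8)
    m[5:(4 + nrow(g)), 5:(4 + ncol(g))] <- unclass(g)[seq_len(nrow(g)),
                                                      seq_len(ncol(g))]
    bin <- binary_image(m)
    ccs <- find_connected_components(bin)
    cc <- ccs[[which.max(vapply(ccs, function(x) x$area, numeric(1)))]]
    arrow_obj(cc, subtype = "curly")
  })
}
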