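# A compact convolutional-network engine in base R matrix operations.
#
# The detection heads in this package are deliberately small (64 x 64 input
# patches, three 3x3 conv stages with 2x2 max pooling, one shared fully
# connected layer and one or two linear heads), so an im2col formulation --
# each convolution becomes a single matrix product -- is fast enough on one
# CPU for the desk-scale training runs the package performs. Backpropagation
# and the Adam / SGD update rules are implemented directly.

# im2col gather indices for a 3x3 convolution with pad 1 on an H x W x C
# input. Rows are output positions in R's column-major order (y fastest);
# columns iterate (dy, dx, c) with dy fastest, matching the weight layout.
make_im2col_idx <- function(H, W, C) {
  Hp <- H + 2L
  ys <- rep(seq_len(H), times = W)        # output y, column-major order
  xs <- rep(seq_len(W), each = H)         # output x
  cols <- vector("list", 9L * C)
  k <- 1L
  for (c in seq_len(C)) {
    base_c <- (c - 1L) * Hp * (W + 2L)
    for (dx in 0:2) {
      for (dy in 0:2) {
        cols[[k]] <- base_c + (xs + dx - 1L) * Hp + (ys + dy)
        k <- k + 1L
      }
    }
  }
  matrix(unlist(cols), nrow = H * W)
}

# 2x2 max-pool candidate indices for an H x W x C array (H, W even):
# one row per output cell (column-major over (ho, wo, c)), 4 candidate
# linear indices into the input array.
make_pool_idx <- function(H, W, C) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  yo <- rep(seq_len(Ho), times = Wo * C)
  xo <- rep(rep(seq_len(Wo), each = Ho), times = C)
  co <- rep(seq_len(C), each = Ho * Wo)
  base <- (co - 1L) * H * W
  tl <- base + (2L * xo - 2L) * H + (2L * yo - 1L)
  cbind(tl, tl + 1L, tl + H, tl + H + 1L)
}

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

# Initialize a network: conv channels (3 stages assumed even divisions of
# `in_size`), one shared fc layer, and named linear heads. A head given as
# c(hidden, nout) gets one extra hidden layer with ReLU.
cnn_init <- function(seed = 1, in_size = 64L, in_channels = 1L,
                     channels = c(8L, 16L, 32L), fc = 64L,
                     heads = list(det = 1L, cls = c(32L, 4L))) {
  with_seed(seed, {
    sizes <- in_size / c(1L, 2L, 4L)
    chans <- c(in_channels, channels)
    net <- list(channels = channels, in_size = in_size, fc_dim = fc,
                heads_spec = heads)
    net$conv <- lapply(1:3, function(k) {
      list(W = he_init(9L * chans[k], chans[k + 1L]),
           b = numeric(chans[k + 1L]),
           idx = make_im2col_idx(sizes[k], sizes[k], chans[k]),
           H = sizes[k], C = chans[k], Cout = chans[k + 1L],
           pool = make_pool_idx(sizes[k], sizes[k], chans[k + 1L]))
    })
    flat <- (in_size / 8L)^2 * channels[3]
    net$fc <- list(W = he_init(flat, fc), b = numeric(fc))
    net$heads <- lapply(heads, function(spec) {
      if (length(spec) == 1L) {
        list(list(W = he_init(fc, spec), b = numeric(spec)))
      } else {
        list(list(W = he_init(fc, spec[1]), b = numeric(spec[1])),
             list(W = he_init(spec[1], spec[2]), b = numeric(spec[2])))
      }
    })
    net
  })
}

# Forward pass for one image (matrix in_size x in_size). Returns head
# outputs (linear scores) and, when train = TRUE, the caches for backprop.
cnn_forward <- function(net, x, train = FALSE) {
  a <- array(x, c(net$in_size, net$in_size, 1L))
  caches <- vector("list", 3L)
  for (k in 1:3) {
    cv <- net$conv[[k]]
    H <- cv$H
    p <- array(0, c(H + 2L, H + 2L, cv$C))
    p[2:(H + 1L), 2:(H + 1L), ] <- a
    Xcol <- matrix(p[cv$idx], nrow = H * H)
    Z <- Xcol %*% cv$W
    Z <- sweep(Z, 2L, cv$b, "+")
    R <- Z * (Z > 0)
    ra <- array(R, c(H, H, cv$Cout))
    vals <- matrix(ra[cv$pool], ncol = 4L)
    amax <- max.col(vals, ties.method = "first")
    pooled <- vals[cbind(seq_len(nrow(vals)), amax)]
    a <- array(pooled, c(H %/% 2L, H %/% 2L, cv$Cout))
    if (train) {
      caches[[k]] <- list(Xcol = Xcol, relu_mask = (Z > 0),
                          chosen = cv$pool[cbind(seq_len(nrow(vals)), amax)],
                          in_len = H * H * cv$Cout)
    }
  }
  flat <- as.vector(a)
  hfc <- drop(flat %*% net$fc$W) + net$fc$b
  afc <- hfc * (hfc > 0)
  heads_out <- list()
  head_caches <- list()
  for (hn in names(net$heads)) {
    layers <- net$heads[[hn]]
    hin <- afc
    hcache <- list()
    for (li in seq_along(layers)) {
      z <- drop(hin %*% layers[[li]]$W) + layers[[li]]$b
      if (li < length(layers)) {
        hcache[[li]] <- list(input = hin, pre = z)
        hin <- z * (z > 0)
      } else {
        hcache[[li]] <- list(input = hin, pre = z)
        hin <- z
      }
    }
    heads_out[[hn]] <- hin
    head_caches[[hn]] <- hcache
  }
  if (!train) return(heads_out)
  list(out = heads_out,
       cache = list(conv = caches, flat = flat, fc_pre = hfc, fc_act = afc,
                    heads = head_caches))
}

# Backward pass given d(loss)/d(head scores). Returns gradients with the
# same shape as the network's weights.
cnn_backward <- function(net, cache, dheads) {
  grads <- list(conv = vector("list", 3L), fc = NULL, heads = list())
  dafc <- numeric(net$fc_dim)
  for (hn in names(net$heads)) {
    layers <- net$heads[[hn]]
    hcache <- cache$heads[[hn]]
    dz <- dheads[[hn]]
    glayers <- vector("list", length(layers))
    for (li in rev(seq_along(layers))) {
      if (li < length(layers)) dz <- dz * (hcache[[li]]$pre > 0)
      glayers[[li]] <- list(W = outer(hcache[[li]]$input, dz), b = dz)
      dz <- drop(layers[[li]]$W %*% dz)
    }
    grads$heads[[hn]] <- glayers
    dafc <- dafc + dz
  }
  dhfc <- dafc * (cache$fc_pre > 0)
  grads$fc <- list(W = outer(cache$flat, dhfc), b = dhfc)
  da <- drop(net$fc$W %*% dhfc)
  for (k in 3:1) {
    cv <- net$conv[[k]]
    cc <- cache$conv[[k]]
    H <- cv$H
    dR <- numeric(cc$in_len)
    dR[cc$chosen] <- da
    dZ <- matrix(dR, nrow = H * H)
    dZ <- dZ * cc$relu_mask
    gW <- crossprod(cc$Xcol, dZ)
    gb <- colSums(dZ)
    dXcol <- tcrossprod(dZ, cv$W)
    dpad <- numeric((H + 2L)^2 * cv$C)
    rs <- rowsum(as.vector(dXcol), group = as.vector(cv$idx))
    dpad[as.integer(rownames(rs))] <- rs
    dp <- array(dpad, c(H + 2L, H + 2L, cv$C))
    da <- as.vector(dp[2:(H + 1L), 2:(H + 1L), , drop = FALSE])
    grads$conv[[k]] <- list(W = gW, b = gb)
  }
  grads
}

# flatten weights <-> flat list, for the optimizers
nn_params <- function(net) {
  p <- list()
  for (k in 1:3) {
    p[[paste0("cW", k)]] <- net$conv[[k]]$W
    p[[paste0("cb", k)]] <- net$conv[[k]]$b
  }
  p$fW <- net$fc$W; p$fb <- net$fc$b
  for (hn in names(net$heads)) {
    for (li in seq_along(net$heads[[hn]])) {
      p[[paste0("h_", hn, "_W", li)]] <- net$heads[[hn]][[li]]$W
      p[[paste0("h_", hn, "_b", li)]] <- net$heads[[hn]][[li]]$b
    }
  }
  p
}

nn_set_params <- function(net, p) {
  for (k in 1:3) {
    net$conv[[k]]$W <- p[[paste0("cW", k)]]
    net$conv[[k]]$b <- p[[paste0("cb", k)]]
  }
  net$fc$W <- p$fW; net$fc$b <- p$fb
  for (hn in names(net$heads)) {
    for (li in seq_along(net$heads[[hn]])) {
      net$heads[[hn]][[li]]$W <- p[[paste0("h_", hn, "_W", li)]]
      net$heads[[hn]][[li]]$b <- p[[paste0("h_", hn, "_b", li)]]
    }
  }
  net
}

grads_as_params <- function(net, grads) {
  p <- list()
  for (k in 1:3) {
    p[[paste0("cW", k)]] <- grads$conv[[k]]$W
    p[[paste0("cb", k)]] <- grads$conv[[k]]$b
  }
  p$fW <- grads$fc$W; p$fb <- grads$fc$b
  for (hn in names(net$heads)) {
    for (li in seq_along(grads$heads[[hn]])) {
      p[[paste0("h_", hn, "_W", li)]] <- grads$heads[[hn]][[li]]$W
      p[[paste0("h_", hn, "_b", li)]] <- grads$heads[[hn]][[li]]$b
    }
  }
  p
}

optimizer_init <- function(kind = c("adam", "sgd"), params, lr = 0.001,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                           momentum = 0.9) {
  kind <- match.arg(kind)
  zero <- lapply(params, function(w) w * 0)
  list(kind = kind, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       momentum = momentum, m = zero, v = zero, t = 0L)
}

optimizer_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (opt$kind == "adam") {
      opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
      opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
      mhat <- opt$m[[nm]] / (1 - opt$beta1^opt$t)
      vhat <- opt$v[[nm]] / (1 - opt$beta2^opt$t)
      params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    } else {
      opt$m[[nm]] <- opt$momentum * opt$m[[nm]] + g
      params[[nm]] <- params[[nm]] - opt$lr * opt$m[[nm]]
    }
  }
  list(opt = opt, params = params)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

logsumexp <- function(z) {
  m <- max(z)
  m + log(sum(exp(z - m)))
}
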