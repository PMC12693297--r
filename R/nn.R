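# Internal neural-network primitives for the two-branch Siamese model.
# Plain-R implementation: convolution via im2col + GEMM, explicit backward
# passes, Adam updates. Everything is deterministic for a fixed seed because
# training is full-batch and sample order is fixed.

.idx_cache <- new.env(parent = emptyenv())

# Linear indices (into the zero-padded H+2p x W+2p plane) of every k x k
# patch, one row per output pixel (column-major pixel order), one column per
# patch element (di fastest, then dj). 'same' padding, odd k.
.im2col_idx <- function(h, w, k) {
  key <- paste(h, w, k, sep = "x")
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  p <- (k - 1L) %/% 2L
  hp <- h + 2L * p
  base <- (rep(seq_len(h), times = w) - 1L) +
    (rep(seq_len(w), each = h) - 1L) * hp
  off <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * hp, "+"))
  idx <- outer(base, off, "+") + 1L
  assign(key, idx, envir = .idx_cache)
  idx
}

.conv_fwd <- function(x, W, b) {
  d <- dim(x); h <- d[1]; w <- d[2]; cin <- d[3]
  k <- dim(W)[1]; cout <- dim(W)[4]
  p <- (k - 1L) %/% 2L
  idx <- .im2col_idx(h, w, k)
  kk <- k * k
  xp <- array(0, c(h + 2L * p, w + 2L * p, cin))
  xp[p + seq_len(h), p + seq_len(w), ] <- x
  cols <- matrix(0, h * w, kk * cin)
  for (c in seq_len(cin)) {
    plane <- xp[, , c]
    cols[, (c - 1L) * kk + seq_len(kk)] <- plane[idx]
  }
  Wm <- matrix(W, kk * cin, cout)
  out <- cols %*% Wm
  out <- sweep(out, 2L, b, "+")
  list(out = array(out, c(h, w, cout)),
       cache = list(cols = cols, Wm = Wm, dimx = d, k = k))
}

.conv_bwd <- function(dout, cache) {
  d <- cache$dimx; h <- d[1]; w <- d[2]; cin <- d[3]
  k <- cache$k; kk <- k * k
  p <- (k - 1L) %/% 2L
  dm <- matrix(dout, h * w)
  dW <- crossprod(cache$cols, dm)
  db <- colSums(dm)
  dcols <- dm %*% t(cache$Wm)
  idx <- .im2col_idx(h, w, k)
  hp <- h + 2L * p; wp <- w + 2L * p
  dx <- array(0, c(hp, wp, cin))
  for (c in seq_len(cin)) {
    plane <- numeric(hp * wp)
    for (m in seq_len(kk)) {
      ii <- idx[, m]
      plane[ii] <- plane[ii] + dcols[, (c - 1L) * kk + m]
    }
    dx[, , c] <- plane
  }
  list(dx = dx[p + seq_len(h), p + seq_len(w), , drop = FALSE],
       dW = array(dW, c(k, k, cin, ncol(dW))),
       db = db)
}

.pool2_fwd <- function(x) {
  d <- dim(x); h <- d[1]; w <- d[2]; ch <- d[3]
  ri <- seq(1L, h, 2L); ci <- seq(1L, w, 2L)
  a <- x[ri, ci, , drop = FALSE]
  b <- x[ri + 1L, ci, , drop = FALSE]
  cc <- x[ri, ci + 1L, , drop = FALSE]
  dd <- x[ri + 1L, ci + 1L, , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  # first-winner tie break, fixed order (top-left, bottom-left, top-right,
  # bottom-right) so runs are reproducible
  which4 <- 1L * (a == out) +
    2L * (a != out & b == out) +
    3L * (a != out & b != out & cc == out) +
    4L * (a != out & b != out & cc != out)
  list(out = out, cache = list(which4 = which4, dimx = d))
}

.pool2_bwd <- function(dout, cache) {
  d <- cache$dimx
  dx <- array(0, d)
  ri <- seq(1L, d[1], 2L); ci <- seq(1L, d[2], 2L)
  w4 <- cache$which4
  dx[ri, ci, ]           <- dout * (w4 == 1L)
  dx[ri + 1L, ci, ]      <- dout * (w4 == 2L)
  dx[ri, ci + 1L, ]      <- dout * (w4 == 3L)
  dx[ri + 1L, ci + 1L, ] <- dout * (w4 == 4L)
  dx
}

.dense_fwd <- function(x, W, b) drop(x %*% W) + b
.dense_bwd <- function(dout, x, W) {
  list(dW = outer(x, dout), db = dout, dx = drop(W %*% dout))
}

# Parameter initialization: He-scaled normal for ReLU layers, smaller
# Xavier-like scale for the final linear projection.
.init_params <- function(cfg) .with_seed(cfg$seed, {
  rn <- function(dims, fan_in) {
    array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
  }
  p <- list()
  cin <- 3L
  k <- cfg$kernel_size
  for (i in seq_along(cfg$conv_filters)) {
    co <- cfg$conv_filters[[i]]
    p[[paste0("conv", i, "_W")]] <- rn(c(k, k, cin, co), k * k * cin)
    p[[paste0("conv", i, "_b")]] <- numeric(co)
    cin <- co
  }
  sizes <- c(64L, cfg$mlp_hidden)
  for (i in seq_along(cfg$mlp_hidden)) {
    p[[paste0("mlp", i, "_W")]] <- rn(c(sizes[i], sizes[i + 1]), sizes[i])
    p[[paste0("mlp", i, "_b")]] <- numeric(sizes[i + 1])
  }
  fuse_in <- utils::tail(cfg$conv_filters, 1) + utils::tail(cfg$mlp_hidden, 1)
  p$proj1_W <- rn(c(fuse_in, cfg$projector_hidden), fuse_in)
  p$proj1_b <- numeric(cfg$projector_hidden)
  p$proj2_W <- array(
    stats::rnorm(cfg$projector_hidden * cfg$embedding_dim,
                 sd = sqrt(1 / cfg$projector_hidden)),
    c(cfg$projector_hidden, cfg$embedding_dim))
  p$proj2_b <- numeric(cfg$embedding_dim)
  p
})

# Full forward pass for one multimodal sample.
# mep: input_size x input_size x 3 in [0,1]; glcmv: length-64 vector.
.embed_fwd <- function(params, cfg, mep, glcmv) {
  cache <- list(convs = list(), pools = list(), relus = list())
  x <- mep
  nb <- length(cfg$conv_filters)
  for (i in seq_len(nb)) {
    cf <- .conv_fwd(x, params[[paste0("conv", i, "_W")]],
                    params[[paste0("conv", i, "_b")]])
    cache$convs[[i]] <- cf$cache
    r <- pmax(cf$out, 0)
    cache$relus[[i]] <- cf$out > 0
    if (i == nb) cache$last_relu <- r      # Grad-CAM target activation
    pf <- .pool2_fwd(r)
    cache$pools[[i]] <- pf$cache
    x <- pf$out
  }
  cache$gap_dim <- dim(x)
  visual <- colMeans(matrix(x, prod(dim(x)[1:2]), dim(x)[3]))
  h <- glcmv
  cache$mlp_in <- list()
  for (i in seq_along(cfg$mlp_hidden)) {
    cache$mlp_in[[i]] <- h
    z <- .dense_fwd(h, params[[paste0("mlp", i, "_W")]],
                    params[[paste0("mlp", i, "_b")]])
    cache[[paste0("mlp", i, "_mask")]] <- z > 0
    h <- pmax(z, 0)
  }
  texture <- h
  fused <- c(visual, texture)
  cache$fused <- fused
  z1 <- .dense_fwd(fused, params$proj1_W, params$proj1_b)
  cache$proj1_mask <- z1 > 0
  h1 <- pmax(z1, 0)
  cache$proj1_out <- h1
  e <- .dense_fwd(h1, params$proj2_W, params$proj2_b)
  if (isTRUE(cfg$normalize_embeddings)) {
    nrm <- sqrt(sum(e^2))
    cache$pre_norm <- e
    cache$norm <- nrm
    e <- if (nrm > 0) e / nrm else e
  }
  cache$visual_len <- length(visual)
  list(e = e, cache = cache)
}

# Backward pass: gradient of a scalar w.r.t. all parameters, the GLCM input
# vector, and the last conv ReLU activation (for Grad-CAM).
.embed_bwd <- function(params, cfg, cache, de) {
  g <- list()
  if (isTRUE(cfg$normalize_embeddings)) {
    nrm <- cache$norm
    if (nrm > 0) {
      y <- cache$pre_norm / nrm
      de <- (de - y * sum(de * y)) / nrm
    }
  }
  d2 <- .dense_bwd(de, cache$proj1_out, params$proj2_W)
  g$proj2_W <- d2$dW; g$proj2_b <- d2$db
  dh1 <- d2$dx * cache$proj1_mask
  d1 <- .dense_bwd(dh1, cache$fused, params$proj1_W)
  g$proj1_W <- d1$dW; g$proj1_b <- d1$db
  vl <- cache$visual_len
  dvisual <- d1$dx[seq_len(vl)]
  dtexture <- d1$dx[-seq_len(vl)]
  dh <- dtexture
  for (i in rev(seq_along(cfg$mlp_hidden))) {
    dz <- dh * cache[[paste0("mlp", i, "_mask")]]
    dd <- .dense_bwd(dz, cache$mlp_in[[i]], params[[paste0("mlp", i, "_W")]])
    g[[paste0("mlp", i, "_W")]] <- dd$dW
    g[[paste0("mlp", i, "_b")]] <- dd$db
    dh <- dd$dx
  }
  dglcm <- dh
  gd <- cache$gap_dim
  dx <- array(rep(dvisual, each = prod(gd[1:2])) / prod(gd[1:2]), gd)
  nb <- length(cfg$conv_filters)
  d_last_relu <- NULL
  for (i in rev(seq_len(nb))) {
    dr <- .pool2_bwd(dx, cache$pools[[i]])
    if (i == nb) d_last_relu <- dr
    dz <- dr * cache$relus[[i]]
    cb <- .conv_bwd(dz, cache$convs[[i]])
    g[[paste0("conv", i, "_W")]] <- cb$dW
    g[[paste0("conv", i, "_b")]] <- cb$db
    dx <- cb$dx
  }
  list(grads = g, dglcm = dglcm, d_last_relu = d_last_relu)
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    if (is.null(gnm)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Restore-on-exit seeded RNG scope so generators never disturb the caller's
# random stream.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
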