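## Minimal 3D convolutional-network engine.
##
## Activations are dense matrices of shape (batch * n_voxels) x channels,
## subjects stacked block-wise along the rows and voxels in the fixed
## lexicographic grid order. A 3x3x3 stride-1 convolution is computed
## against a zero-padded copy of the activations: for each of the 27 kernel
## offsets the padded buffer is gathered at a constant linear shift and
## multiplied by the corresponding channel-slice of the kernel, so the
## whole operation is 27 skinny BLAS multiplies with no boundary special
## cases. Average pooling (3x3x3, stride 2, zero padding counted in the
## denominator) reuses the same padded buffer at stride-2 centres. The
## transposed (up-) convolution is zero-stuffing followed by a stride-1
## convolution, the standard algebraic identity for stride 2. All gradients
## are analytic and validated against finite differences in the test suite.
## Everything is double precision.

conv_offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))
sigmoid <- function(x) 1 / (1 + exp(-x))

## Kernel weights are stored as a (27 * C_in) x C_out matrix with the
## offset index fastest: row = offset + 27 * (c_in - 1).
kernel_rows <- function(o, c_in) seq.int(o, 27L * c_in, by = 27L)

## Geometry of one grid (+1 voxel zero pad on each side) for a batch of B
## subject blocks:
##   pad_idx  - rows of the true voxels inside the padded batched buffer
##   shifts   - linear offset in the padded grid for each kernel offset
##   n_pad    - padded rows per subject
pad_geometry <- function(d, B) {
  dp <- d + 2L
  co <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  pidx0 <- (co[, 1] + 1L) + co[, 2] * dp[1] + co[, 3] * dp[1] * dp[2]
  n_pad <- prod(dp)
  list(pad_idx = as.integer(as.vector(
         outer(pidx0, (seq_len(B) - 1L) * n_pad, "+"))),
       shifts = as.integer(conv_offsets[, 1] + conv_offsets[, 2] * dp[1] +
                             conv_offsets[, 3] * dp[1] * dp[2]),
       n_pad = n_pad, n = prod(d), B = B)
}

## Stride-2 pooling/upsampling centres (2j - 1 in each dimension) of the
## fine grid d, as rows of the padded fine-grid buffer.
pool_centers <- function(d, B) {
  dc <- d %/% 2L
  dp <- d + 2L
  co <- as.matrix(expand.grid(2L * seq_len(dc[1]) - 1L,
                              2L * seq_len(dc[2]) - 1L,
                              2L * seq_len(dc[3]) - 1L))
  pidx0 <- (co[, 1] + 1L) + co[, 2] * dp[1] + co[, 3] * dp[1] * dp[2]
  as.integer(as.vector(outer(pidx0, (seq_len(B) - 1L) * prod(dp), "+")))
}

## Zero-stuffing positions: voxel (x,y,z) of the coarse grid d lands at
## (2x-1, 2y-1, 2z-1) of the fine grid 2d (the trailing plane of the fine
## grid stays zero - the output-padding convention for exact doubling).
stuff_positions <- function(d, B) {
  co <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  D <- 2L * d
  pos <- (2L * co[, 1] - 1L) + (2L * co[, 2] - 2L) * D[1] +
    (2L * co[, 3] - 2L) * D[1] * D[2]
  as.integer(as.vector(outer(pos, (seq_len(B) - 1L) * prod(D), "+")))
}

pad_activations <- function(X, geom) {
  Xpad <- matrix(0, geom$B * geom$n_pad, ncol(X))
  Xpad[geom$pad_idx, ] <- X
  Xpad
}

## ---- layer forward/backward primitives ----

conv_fwd <- function(X, W, b, geom, Xpad = NULL) {
  C_in <- ncol(X)
  C_out <- ncol(W)
  if (is.null(Xpad)) Xpad <- pad_activations(X, geom)
  rows <- geom$B * geom$n
  Y <- matrix(rep(b, each = rows), rows, C_out)
  for (o in seq_len(27L)) {
    src <- geom$pad_idx + geom$shifts[o]
    Y <- Y + Xpad[src, , drop = FALSE] %*%
      W[kernel_rows(o, C_in), , drop = FALSE]
  }
  list(Y = Y, Xpad = Xpad)
}

conv_bwd <- function(dY, Xpad, W, geom) {
  C_in <- ncol(Xpad)
  dW <- W * 0
  dXpad <- matrix(0, nrow(Xpad), C_in)
  for (o in seq_len(27L)) {
    src <- geom$pad_idx + geom$shifts[o]
    kr <- kernel_rows(o, C_in)
    dW[kr, ] <- crossprod(Xpad[src, , drop = FALSE], dY)
    dXpad[src, ] <- dXpad[src, ] +
      dY %*% t(W[kr, , drop = FALSE])
  }
  list(dX = dXpad[geom$pad_idx, , drop = FALSE], dW = dW, db = colSums(dY))
}

pool_fwd <- function(X, geom, centers) {
  Xpad <- pad_activations(X, geom)
  rows_out <- length(centers)
  Y <- matrix(0, rows_out, ncol(X))
  for (o in seq_len(27L))
    Y <- Y + Xpad[centers + geom$shifts[o], , drop = FALSE]
  Y / 27
}

pool_bwd <- function(dY, geom, centers) {
  dXpad <- matrix(0, geom$B * geom$n_pad, ncol(dY))
  dYs <- dY / 27
  for (o in seq_len(27L)) {
    idx <- centers + geom$shifts[o]
    dXpad[idx, ] <- dXpad[idx, ] + dYs
  }
  dXpad[geom$pad_idx, , drop = FALSE]
}

bn_fwd <- function(X, gamma, beta, state, training, momentum = 0.1,
                   eps = 1e-5) {
  N <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    xc <- X - rep(mu, each = N)
    va <- colMeans(xc * xc)
    sdv <- sqrt(va + eps)
    xh <- xc / rep(sdv, each = N)
    state$rm <- (1 - momentum) * state$rm + momentum * mu
    state$rv <- (1 - momentum) * state$rv + momentum * va
  } else {
    sdv <- sqrt(state$rv + eps)
    xh <- (X - rep(state$rm, each = N)) / rep(sdv, each = N)
  }
  list(Y = xh * rep(gamma, each = N) + rep(beta, each = N),
       xh = xh, sdv = sdv, state = state)
}

bn_bwd <- function(dY, xh, sdv, gamma, training) {
  N <- nrow(dY)
  dg <- colSums(dY * xh)
  db <- colSums(dY)
  dxh <- dY * rep(gamma, each = N)
  if (training) {
    dX <- (dxh - rep(colMeans(dxh), each = N) -
             xh * rep(colMeans(dxh * xh), each = N)) / rep(sdv, each = N)
  } else {
    dX <- dxh / rep(sdv, each = N)
  }
  list(dX = dX, dgamma = dg, dbeta = db)
}

relu_fwd <- function(X) X * (X > 0)
relu_bwd <- function(dY, X) dY * (X > 0)

## ---- Adam optimiser ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}
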