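#' U-Net configuration
#'
#' Describes the 3D U-Net: an encoder/decoder with `n_levels` resolution
#' levels. Each encoder level applies two 3x3x3 convolutions, each followed
#' by batch normalisation and a ReLU, and (except at the coarsest level) a
#' 3x3x3 average pooling with stride 2. Each decoder level applies a 3x3x3
#' up-convolution (transposed convolution with stride 2 by default),
#' concatenates the skip connection from the same resolution, and applies
#' two convolution + batch-norm + ReLU blocks. A final 1x1x1 convolution
#' maps to `out_channels`. Channel counts double at every level down and
#' halve on the way up. When several baseline modalities are stacked as
#' input channels, an optional positive per-modality weight vector is
#' multiplied into the channels before the first encoder block, so the
#' learned weights expose each modality's contribution to the prediction.
#'
#' @param input_shape cubic (or general) grid dimensions; every dimension
#'   must be divisible by `2^n_levels`.
#' @param n_levels number of resolution levels (4 at full scale; small
#'   synthetic runs use 2).
#' @param in_channels number of stacked baseline modalities K.
#' @param out_channels number of output channels.
#' @param base_channels channels at the first level.
#' @param modality_weighting learn positive per-modality input weights.
#' @param upsample `"transposed"` (default) or `"nearest"` (nearest-neighbour
#'   upsampling followed by the same 3x3x3 convolution).
#' @param share_sigma share the per-voxel loss scales across output channels.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(input_shape = c(16, 16, 16), n_levels = 2,
                        in_channels = 1, out_channels = 1,
                        base_channels = 8,
                        modality_weighting = in_channels > 1,
                        upsample = c("transposed", "nearest"),
                        share_sigma = FALSE) {
  upsample <- match.arg(upsample)
  input_shape <- as.integer(input_shape)
  if (length(input_shape) == 1L) input_shape <- rep(input_shape, 3L)
  if (any(input_shape %% (2L^n_levels) != 0L))
    stop("configuration error: input dimensions must be divisible by 2^n_levels")
  if (n_levels < 1 || base_channels < 1 || in_channels < 1 ||
      out_channels < 1)
    stop("configuration error: counts must be positive")
  structure(
    list(input_shape = input_shape, n_levels = n_levels,
         in_channels = in_channels, out_channels = out_channels,
         base_channels = base_channels,
         modality_weighting = modality_weighting,
         upsample = upsample, share_sigma = share_sigma),
    class = "unet_config")
}

level_channels <- function(config, l) config$base_channels * 2L^(l - 1L)

level_dims <- function(config, l) config$input_shape %/% (2L^(l - 1L))

#' Build an untrained U-Net predictor
#'
#' Initialises all convolution weights with Gaussian random numbers of mean
#' 0 and variance 1 (the full-scale training recipe), biases
#' at 0, batch-norm scale/shift at 1/0. Modality weights and per-voxel loss
#' scales are parameterised through a softplus so they stay positive, and
#' start at exactly 1.
#'
#' @param config a [unet_config()].
#' @param seed integer seed for the weight initialisation.
#' @param mask optional logical array (grid shape); sizes the per-voxel loss
#'   scales now rather than at the start of training.
#' @return An object of class `unet_model` with elements `config`, `params`
#'   (named list of weight matrices), `bn_state` (running statistics),
#'   `sigma_latent`, `history`, and a geometry cache.
#' @export
build_model <- function(config, seed = 1, mask = NULL) {
  stopifnot(inherits(config, "unet_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  L <- config$n_levels
  params <- list()
  bn_state <- list()
  gw <- function(nr, nc) matrix(stats::rnorm(nr * nc), nr, nc)
  add_conv <- function(nm, cin, cout) {
    params[[paste0(nm, "_W")]] <<- gw(27L * cin, cout)
    params[[paste0(nm, "_b")]] <<- rep(0, cout)
  }
  add_bn <- function(nm, ch) {
    params[[paste0(nm, "_g")]] <<- rep(1, ch)
    params[[paste0(nm, "_be")]] <<- rep(0, ch)
    bn_state[[nm]] <<- list(rm = rep(0, ch), rv = rep(1, ch))
  }
  cin <- config$in_channels
  for (l in seq_len(L)) {
    cl <- level_channels(config, l)
    add_conv(sprintf("e%dc1", l), cin, cl); add_bn(sprintf("e%dn1", l), cl)
    add_conv(sprintf("e%dc2", l), cl, cl); add_bn(sprintf("e%dn2", l), cl)
    cin <- cl
  }
  for (l in rev(seq_len(L - 1L))) {
    cl <- level_channels(config, l)
    cup <- level_channels(config, l + 1L)
    add_conv(sprintf("u%d", l), cup, cl)
    add_conv(sprintf("d%dc1", l), 2L * cl, cl); add_bn(sprintf("d%dn1", l), cl)
    add_conv(sprintf("d%dc2", l), cl, cl); add_bn(sprintf("d%dn2", l), cl)
  }
  params$fin_W <- gw(level_channels(config, 1L), config$out_channels)
  params$fin_b <- rep(0, config$out_channels)
  if (config$modality_weighting)
    params$mod_theta <- rep(softplus_inv(1), config$in_channels)
  model <- list(config = config, params = params, bn_state = bn_state,
                sigma_latent = NULL, mask = NULL, pop_mean = NULL,
                history = NULL, geom = new.env(parent = emptyenv()))
  if (!is.null(mask)) {
    model$mask <- mask
    model$sigma_latent <- init_sigma_latent(config, sum(mask))
  }
  class(model) <- "unet_model"
  model
}

init_sigma_latent <- function(config, v) {
  nc <- if (config$share_sigma) 1L else config$out_channels
  matrix(softplus_inv(1), v, nc)
}

#' @exportS3Method print unet_model
print.unet_model <- function(x, ...) {
  cfg <- x$config
  cat("<unet_model> ", paste(cfg$input_shape, collapse = "x"), " input, ",
      cfg$n_levels, " levels, base ", cfg$base_channels, " channels, K = ",
      cfg$in_channels, " -> ", cfg$out_channels, " channel(s); ",
      model_parameter_count(x), " learnable parameters",
      if (is.null(x$history)) " (untrained)" else " (trained)", "\n",
      sep = "")
  invisible(x)
}

#' Number of learnable parameters
#'
#' Counts convolution weights and biases, batch-norm scales and shifts,
#' modality-weight latents and per-voxel loss-scale latents. Batch-norm
#' running statistics are not learnable and are excluded.
#'
#' @param model a `unet_model`.
#' @return Integer parameter count.
#' @export
model_parameter_count <- function(model) {
  n <- sum(vapply(model$params, length, integer(1)))
  if (!is.null(model$sigma_latent)) n <- n + length(model$sigma_latent)
  n
}

#' Learned modality weights
#'
#' @param model a `unet_model` built with modality weighting.
#' @return Positive numeric vector of length K (softplus of the latent).
#' @export
modality_weights <- function(model) {
  if (is.null(model$params$mod_theta))
    stop("model was built without modality weighting")
  softplus(model$params$mod_theta)
}

#' Learned per-voxel loss scales
#'
#' @param model a trained `unet_model`.
#' @return Positive matrix (in-mask voxels x output channels).
#' @export
voxel_sigmas <- function(model) {
  if (is.null(model$sigma_latent))
    stop("loss scales are not initialised (train the model, or build with a mask)")
  softplus(model$sigma_latent)
}

## Geometry (padded-grid indices, pooling centres, stuffing positions) for
## one batch size, cached on the model's environment for reuse.
unet_geometry <- function(model, B) {
  key <- paste0("B", B)
  if (!is.null(model$geom[[key]])) return(model$geom[[key]])
  cfg <- model$config
  L <- cfg$n_levels
  g <- list(pad = vector("list", L), pool = vector("list", L),
            stuff = vector("list", L), nearest = vector("list", L),
            n = integer(L))
  for (l in seq_len(L)) {
    d <- level_dims(cfg, l)
    g$n[l] <- prod(d)
    g$pad[[l]] <- pad_geometry(d, B)
    if (l < L) {
      dn <- level_dims(cfg, l + 1L)
      g$pool[[l]] <- pool_centers(d, B)
      g$stuff[[l]] <- stuff_positions(dn, B)
      if (cfg$upsample == "nearest") {
        co <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]),
                                    seq_len(d[3])))
        par <- ((co[, 1] + 1L) %/% 2L) + ((co[, 2] + 1L) %/% 2L - 1L) * dn[1] +
          ((co[, 3] + 1L) %/% 2L - 1L) * dn[1] * dn[2]
        g$nearest[[l]] <- as.integer(as.vector(
          outer(par, (seq_len(B) - 1L) * prod(dn), "+")))
      }
    }
  }
  model$geom[[key]] <- g
  g
}

## Full forward pass. X: (B * n_level1) x K matrix. Returns output matrix
## and (optionally) the cache needed for the backward pass.
unet_forward <- function(model, X, B, training = FALSE, keep_cache = TRUE) {
  cfg <- model$config
  L <- cfg$n_levels
  g <- unet_geometry(model, B)
  p <- model$params
  cache <- list(B = B)
  if (cfg$modality_weighting) {
    w <- softplus(p$mod_theta)
    cache$X_raw <- X
    X <- X * rep(w, each = nrow(X))
  }
  conv_block <- function(X, nm_conv, nm_bn, geom) {
    cf <- conv_fwd(X, p[[paste0(nm_conv, "_W")]], p[[paste0(nm_conv, "_b")]],
                   geom)
    bn <- bn_fwd(cf$Y, p[[paste0(nm_bn, "_g")]], p[[paste0(nm_bn, "_be")]],
                 model$bn_state[[nm_bn]], training)
    if (training) model$bn_state[[nm_bn]] <<- bn$state
    out <- relu_fwd(bn$Y)
    if (keep_cache)
      cache[[nm_conv]] <<- list(Xpad = cf$Xpad, Ybn = bn$Y, xh = bn$xh,
                                sdv = bn$sdv)
    out
  }
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    X <- conv_block(X, sprintf("e%dc1", l), sprintf("e%dn1", l), g$pad[[l]])
    X <- conv_block(X, sprintf("e%dc2", l), sprintf("e%dn2", l), g$pad[[l]])
    if (l < L) {
      skips[[l]] <- X
      X <- pool_fwd(X, g$pad[[l]], g$pool[[l]])
    }
  }
  for (l in rev(seq_len(L - 1L))) {
    nm <- sprintf("u%d", l)
    if (cfg$upsample == "transposed") {
      Xup <- matrix(0, B * g$n[l], ncol(X))
      Xup[g$stuff[[l]], ] <- X
    } else {
      Xup <- X[g$nearest[[l]], , drop = FALSE]
    }
    cf <- conv_fwd(Xup, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]],
                   g$pad[[l]])
    if (keep_cache) cache[[nm]] <- list(Xpad = cf$Xpad)
    X <- cf$Y
    X <- cbind(X, skips[[l]])
    X <- conv_block(X, sprintf("d%dc1", l), sprintf("d%dn1", l), g$pad[[l]])
    X <- conv_block(X, sprintf("d%dc2", l), sprintf("d%dn2", l), g$pad[[l]])
  }
  if (keep_cache) cache$fin_in <- X
  out <- X %*% p$fin_W + rep(p$fin_b, each = nrow(X))
  list(out = out, cache = if (keep_cache) cache else NULL, model = model)
}

## Full backward pass. dOut: gradient of a scalar loss w.r.t. the output
## matrix. Returns named gradient list (matching model$params) and the
## gradient w.r.t. the input stack.
unet_backward <- function(model, cache, dOut, training = FALSE) {
  cfg <- model$config
  L <- cfg$n_levels
  B <- cache$B
  g <- unet_geometry(model, B)
  p <- model$params
  grads <- list()
  block_bwd <- function(dY, nm_conv, nm_bn, geom) {
    cc <- cache[[nm_conv]]
    dY <- relu_bwd(dY, cc$Ybn)
    bn <- bn_bwd(dY, cc$xh, cc$sdv, p[[paste0(nm_bn, "_g")]], training)
    grads[[paste0(nm_bn, "_g")]] <<- bn$dgamma
    grads[[paste0(nm_bn, "_be")]] <<- bn$dbeta
    cv <- conv_bwd(bn$dX, cc$Xpad, p[[paste0(nm_conv, "_W")]], geom)
    grads[[paste0(nm_conv, "_W")]] <<- cv$dW
    grads[[paste0(nm_conv, "_b")]] <<- cv$db
    cv$dX
  }
  grads$fin_W <- crossprod(cache$fin_in, dOut)
  grads$fin_b <- colSums(dOut)
  dX <- dOut %*% t(p$fin_W)
  dSkip <- vector("list", L)
  for (l in seq_len(L - 1L)) {
    dX <- block_bwd(dX, sprintf("d%dc2", l), sprintf("d%dn2", l), g$pad[[l]])
    dX <- block_bwd(dX, sprintf("d%dc1", l), sprintf("d%dn1", l), g$pad[[l]])
    cl <- level_channels(cfg, l)
    dSkip[[l]] <- dX[, (cl + 1L):(2L * cl), drop = FALSE]
    dUp <- dX[, seq_len(cl), drop = FALSE]
    nm <- sprintf("u%d", l)
    cv <- conv_bwd(dUp, cache[[nm]]$Xpad, p[[paste0(nm, "_W")]], g$pad[[l]])
    grads[[paste0(nm, "_W")]] <- cv$dW
    grads[[paste0(nm, "_b")]] <- cv$db
    if (cfg$upsample == "transposed") {
      dX <- cv$dX[g$stuff[[l]], , drop = FALSE]
    } else {
      rs <- rowsum(cv$dX, g$nearest[[l]])
      ids <- as.integer(rownames(rs))
      dX <- matrix(0, B * g$n[l + 1L], ncol(cv$dX))
      dX[ids, ] <- rs
    }
  }
  for (l in rev(seq_len(L))) {
    if (l < L) {
      dX <- pool_bwd(dX, g$pad[[l]], g$pool[[l]]) + dSkip[[l]]
    }
    dX <- block_bwd(dX, sprintf("e%dc2", l), sprintf("e%dn2", l), g$pad[[l]])
    dX <- block_bwd(dX, sprintf("e%dc1", l), sprintf("e%dn1", l), g$pad[[l]])
  }
  if (cfg$modality_weighting) {
    w <- softplus(p$mod_theta)
    grads$mod_theta <- colSums(dX * cache$X_raw) * sigmoid(p$mod_theta)
    dX <- dX * rep(w, each = nrow(dX))
  }
  list(grads = grads, dInput = dX)
}
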