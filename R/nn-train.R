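#' Min-max normalise a volume
#'
#' Rescales in-mask intensities affinely to the interval \[0, 1\]. Applied to
#' network inputs only; targets stay on their original scale so predictions
#' are directly comparable with the true images.
#'
#' @param vol an `image_volume`.
#' @return An `image_volume` with in-mask range exactly \[0, 1\] (voxels
#'   outside the mask are set to 0).
#' @export
minmax_normalise <- function(vol) {
  x <- mask_values(vol)
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("degenerate input: image is constant inside the mask")
  with_mask_values(vol, (x - rng[1]) / (rng[2] - rng[1]))
}

#' Uncertainty-weighted voxel-wise loss
#'
#' The training objective treats the prediction at every in-mask voxel as
#' its own task with a learnable scale `sigma_i > 0`:
#' \deqn{L = \sum_{i=1}^{v}\left(\frac{l_i}{2\sigma_i^2} +
#'   \log(\sigma_i + 1)\right)}
#' where `l_i` is the squared error at voxel i. Voxels with persistently
#' large error receive a larger `sigma_i` and hence a smaller weight, while
#' the `log(sigma_i + 1)` term (regularised so it is exactly 0 at the
#' plain-MSE-like point `sigma = 0`) prevents the scales from growing
#' unboundedly. With all scales frozen at 1 the loss reduces to half the
#' masked sum of squared errors plus the constant `v log 2`.
#'
#' @param pred,target numeric vectors of in-mask predictions and targets.
#' @param sigmas positive vector of per-voxel scales (recycled if length 1).
#' @param gradient also return analytic gradients.
#' @return The scalar loss, or (with `gradient = TRUE`) a list with `loss`,
#'   `dpred` and `dsigma`.
#' @export
uncertainty_weighted_loss <- function(pred, target, sigmas,
                                      gradient = FALSE) {
  if (length(pred) != length(target))
    stop("pred and target must have equal length")
  if (length(sigmas) == 1L) sigmas <- rep(sigmas, length(pred))
  if (length(sigmas) != length(pred))
    stop("sigmas must match pred in length")
  if (any(sigmas <= 0)) stop("all sigma_i must be strictly positive")
  d <- pred - target
  l <- d * d
  loss <- sum(l / (2 * sigmas^2) + log(sigmas + 1))
  if (!gradient) return(loss)
  list(loss = loss,
       dpred = d / sigmas^2,
       dsigma = -l / sigmas^3 + 1 / (sigmas + 1))
}

#' Training configuration
#'
#' Defaults follow the full-scale training recipe: Adam with
#' learning rate 0.001, mini-batches of 16 subjects, 40 epochs, cosine
#' learning-rate decay, no data augmentation.
#'
#' @param learning_rate initial Adam learning rate (> 0).
#' @param batch_size subjects per mini-batch.
#' @param epochs passes over the training data (>= 1).
#' @param lr_schedule `"cosine"` or `"constant"`.
#' @param loss_mode `"uncertainty"` (learnable per-voxel scales) or `"mse"`
#'   (plain masked mean squared error, for ablation).
#' @param seed integer seed controlling initial shuffling and all other
#'   training randomness.
#' @param shuffle reshuffle subjects every epoch.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 16,
                         epochs = 40, lr_schedule = c("cosine", "constant"),
                         loss_mode = c("uncertainty", "mse"), seed = 1,
                         shuffle = TRUE) {
  lr_schedule <- match.arg(lr_schedule)
  loss_mode <- match.arg(loss_mode)
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, lr_schedule = lr_schedule,
                 loss_mode = loss_mode, seed = seed, shuffle = shuffle),
            class = "train_config")
}

#' Assemble network training data from residualised pairs
#'
#' Builds per-subject input/target arrays for [train_model()]. Inputs are
#' the min-max normalised residualised baselines (one channel per modality);
#' the target is taken from the first modality and is NOT normalised. Target
#' modes: `"followup"` predicts ResB, `"temporal_difference"` predicts
#' ResB - ResA, and `"residual_temporal_difference"` predicts ResB\\ResA.
#'
#' @param residuals list of `residual_set` objects (one modality), or a list
#'   of such lists (multiple modalities, aligned by subject).
#' @param target_mode one of `"followup"`, `"temporal_difference"`,
#'   `"residual_temporal_difference"`.
#' @param normalise min-max normalise the input channels (default TRUE).
#' @return List of class `unet_dataset`: per-subject elements with `input`
#'   (grid-voxels x K matrix), `target` (grid-voxels vector), `subject_id`,
#'   plus attributes `mask` and `target_mode`.
#' @export
prepare_training_data <- function(residuals,
                                  target_mode = c("followup",
                                                  "temporal_difference",
                                                  "residual_temporal_difference"),
                                  normalise = TRUE) {
  target_mode <- match.arg(target_mode)
  if (inherits(residuals[[1]], "residual_set"))
    residuals <- list(residuals)
  n_mod <- length(residuals)
  n_sub <- length(residuals[[1]])
  if (n_sub == 0) stop("empty cohort")
  mask <- residuals[[1]][[1]]$res_a$mask
  n <- length(mask)
  data <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    X <- matrix(0, n, n_mod)
    for (m in seq_len(n_mod)) {
      ra <- residuals[[m]][[s]]$res_a
      if (!identical(ra$mask, mask)) stop("mask mismatch across modalities")
      X[, m] <- if (normalise) minmax_normalise(ra)$data else ra$data
    }
    r1 <- residuals[[1]][[s]]
    target <- switch(target_mode,
      followup = r1$res_b$data,
      temporal_difference = r1$res_b$data - r1$res_a$data,
      residual_temporal_difference = {
        if (is.null(r1$res_b_given_a))
          r1 <- residual_temporal_difference(r1)
        r1$res_b_given_a$data
      })
    data[[s]] <- list(input = X, target = as.numeric(target),
                      subject_id = r1$subject_id)
  }
  structure(data, mask = mask, target_mode = target_mode,
            class = "unet_dataset")
}

## One mini-batch forward/backward/update. Returns the batch loss.
train_step <- function(model_env, data, idx, mask_rows, v, tcfg, lr) {
  model <- model_env$model
  B <- length(idx)
  n <- nrow(data[[idx[1]]]$input)
  K <- ncol(data[[idx[1]]]$input)
  X <- matrix(0, B * n, K)
  Tg <- matrix(0, B * v, 1)
  for (j in seq_len(B)) {
    X[(j - 1L) * n + seq_len(n), ] <- data[[idx[j]]]$input
    Tg[(j - 1L) * v + seq_len(v), 1] <- data[[idx[j]]]$target[mask_rows]
  }
  fw <- unet_forward(model, X, B, training = TRUE, keep_cache = TRUE)
  model <- fw$model
  rows <- rep((seq_len(B) - 1L) * n, each = v) + mask_rows
  P <- fw$out[rows, 1, drop = FALSE]
  D <- P - Tg
  l2 <- D * D
  dOut <- matrix(0, B * n, ncol(fw$out))
  if (tcfg$loss_mode == "uncertainty") {
    sig <- softplus(model$sigma_latent[, 1])
    sigR <- rep(sig, B)
    loss <- sum(l2 / (2 * sigR^2)) / B + sum(log(sig + 1))
    dOut[rows, 1] <- D / sigR^2 / B
    lsum <- rowSums(matrix(l2, v, B))
    dsig <- -lsum / sig^3 / B + 1 / (sig + 1)
    dsl <- dsig * sigmoid(model$sigma_latent[, 1])
  } else {
    loss <- sum(l2) / (2 * B)
    dOut[rows, 1] <- D / B
    dsl <- NULL
  }
  bw <- unet_backward(model, fw$cache, dOut, training = TRUE)
  grads <- bw$grads
  st <- adam_step(model$params, grads, model_env$opt, lr)
  model$params <- st$params
  model_env$opt <- st$opt
  if (!is.null(dsl)) {
    so <- model_env$sopt
    so$t <- so$t + 1L
    so$m <- 0.9 * so$m + 0.1 * dsl
    so$v <- 0.999 * so$v + 0.001 * dsl * dsl
    model$sigma_latent[, 1] <- model$sigma_latent[, 1] -
      lr * (so$m / (1 - 0.9^so$t)) / (sqrt(so$v / (1 - 0.999^so$t)) + 1e-8)
    model_env$sopt <- so
  }
  model_env$model <- model
  loss
}

#' Train a U-Net predictor
#'
#' Runs mini-batch Adam over a residualised cohort with the configured loss
#' (uncertainty-weighted by default), cosine learning-rate decay and a fixed
#' seed for all randomness, so repeated runs are bit-identical. The loss is
#' computed over in-mask voxels only and averaged over the subjects of each
#' batch.
#'
#' @param model an untrained (or previously trained) `unet_model`.
#' @param data a `unet_dataset` from [prepare_training_data()], built from
#'   pairs residualised with the TRAINING-set population mean.
#' @param tcfg a [train_config()].
#' @param pop_mean optional training-set population mean `image_volume`,
#'   stored on the model so follow-up images can be reconstructed at
#'   prediction time.
#' @return The trained `unet_model`, with `history` (data.frame of per-epoch
#'   mean training loss) attached.
#' @export
train_model <- function(model, data, tcfg = train_config(),
                        pop_mean = NULL) {
  stopifnot(inherits(model, "unet_model"), inherits(data, "unet_dataset"))
  if (length(data) == 0) stop("empty cohort")
  mask <- attr(data, "mask")
  if (!identical(as.integer(dim(mask)), model$config$input_shape))
    stop("mask mismatch: dataset grid does not match model input shape")
  if (model$config$out_channels != 1L)
    stop("training is implemented for single-channel targets")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(tcfg$seed)
  if (is.null(model$sigma_latent))
    model$sigma_latent <- init_sigma_latent(model$config, sum(mask))
  model$mask <- mask
  if (!is.null(pop_mean)) model$pop_mean <- pop_mean
  mask_rows <- which(as.vector(mask))
  v <- length(mask_rows)
  model_env <- new.env(parent = emptyenv())
  model_env$model <- model
  model_env$opt <- adam_init(model$params)
  model_env$sopt <- list(m = numeric(v), v = numeric(v), t = 0L)
  n_sub <- length(data)
  history <- data.frame(epoch = seq_len(tcfg$epochs), loss = NA_real_,
                        lr = NA_real_)
  for (ep in seq_len(tcfg$epochs)) {
    lr <- if (tcfg$lr_schedule == "cosine") {
      tcfg$learning_rate * 0.5 * (1 + cos(pi * (ep - 1) / tcfg$epochs))
    } else tcfg$learning_rate
    ord <- if (tcfg$shuffle) sample.int(n_sub) else seq_len(n_sub)
    losses <- c()
    for (start in seq(1L, n_sub, by = tcfg$batch_size)) {
      idx <- ord[start:min(start + tcfg$batch_size - 1L, n_sub)]
      losses <- c(losses,
                  train_step(model_env, data, idx, mask_rows, v, tcfg, lr))
    }
    history$loss[ep] <- mean(losses)
    history$lr[ep] <- lr
  }
  model <- model_env$model
  model$history <- history
  model
}

#' Predict a follow-up (or change) map from a baseline stack
#'
#' Runs the network in evaluation mode (batch-norm running statistics) on
#' one subject's baseline stack. Inputs are min-max normalised internally by
#' default, mirroring training; the prediction is returned on the
#' un-normalised output scale. If `reconstruct` is `TRUE` and the model
#' carries a training-set population mean, the population component
#' `pop_mean * beta_pop` is added back, turning a predicted ResB into an
#' estimate of the original follow-up image.
#'
#' @param model a trained `unet_model`.
#' @param stack an `image_volume`, or a list of K volumes (stacked baseline
#'   modalities), or a grid-voxels x K matrix.
#' @param normalise min-max normalise input channels (default TRUE).
#' @param reconstruct add back the population-mean component.
#' @param beta_pop subject coefficient used when `reconstruct = TRUE`.
#' @return An `image_volume` (first output channel).
#' @export
predict_volume <- function(model, stack, normalise = TRUE,
                           reconstruct = FALSE, beta_pop = 1) {
  stopifnot(inherits(model, "unet_model"))
  X <- stack_to_matrix(model, stack, normalise)
  fw <- unet_forward(model, X, B = 1L, training = FALSE, keep_cache = FALSE)
  mask <- model$mask
  if (is.null(mask)) mask <- array(TRUE, model$config$input_shape)
  template <- image_volume(array(0, model$config$input_shape), mask)
  out <- with_mask_values(template, fw$out[which(as.vector(mask)), 1])
  if (reconstruct) {
    if (is.null(model$pop_mean))
      stop("model carries no population mean; train with pop_mean = ...")
    out <- reconstruct_followup(out, model$pop_mean, beta_pop)
  }
  out
}

stack_to_matrix <- function(model, stack, normalise = TRUE) {
  K <- model$config$in_channels
  if (inherits(stack, "image_volume")) stack <- list(stack)
  if (is.list(stack)) {
    if (length(stack) != K)
      stop("channel mismatch: model expects K = ", K, " input modalities")
    X <- vapply(stack, function(vol) {
      if (normalise) vol <- minmax_normalise(vol)
      as.numeric(vol$data)
    }, numeric(prod(model$config$input_shape)))
    matrix(X, ncol = K)
  } else {
    if (ncol(stack) != K)
      stop("channel mismatch: model expects K = ", K, " input channels")
    stack
  }
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive holding the configuration, all
#' learned parameters, batch-norm running statistics, per-voxel loss scales,
#' the mask, the training history and the training-set population mean
#' (needed for residualisation and reconstruction at prediction time).
#'
#' @param model a `unet_model`.
#' @param path checkpoint file path.
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   restored `unet_model`.
#' @export
save_model <- function(model, path) {
  keep <- model[setdiff(names(model), "geom")]
  saveRDS(keep, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  model$geom <- new.env(parent = emptyenv())
  class(model) <- "unet_model"
  model
}
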