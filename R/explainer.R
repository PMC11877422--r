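#' Saliency of one output voxel with respect to the input
#'
#' Computes the derivative of the predicted value at a single output voxel
#' with respect to every voxel of the input stack, by one backward pass
#' through the network with batch normalisation in evaluation mode (running
#' statistics), so the map is deterministic for a fixed model. The magnitude
#' of the derivative indicates which input voxels need to change least to
#' affect that output most.
#'
#' Also supports plain linear predictors built with [linear_model()] (where
#' the saliency of output voxel i is exactly row i of the coefficient
#' matrix), which serve as analytic references.
#'
#' @param model a trained `unet_model` or a [linear_model()].
#' @param stack input stack (see [predict_volume()]).
#' @param output_voxel in-mask voxel index (position within the vectorised
#'   in-mask order) whose prediction is differentiated.
#' @param normalise min-max normalise the stack first (as in prediction).
#' @return A list of K `image_volume`s (one per input channel) holding the
#'   derivative map.
#' @export
voxel_saliency <- function(model, stack, output_voxel, normalise = TRUE) {
  UseMethod("voxel_saliency")
}

#' @export
voxel_saliency.unet_model <- function(model, stack, output_voxel,
                                      normalise = TRUE) {
  mask <- model_mask(model)
  mask_rows <- which(as.vector(mask))
  if (output_voxel < 1 || output_voxel > length(mask_rows))
    stop("output_voxel outside the mask (1..", length(mask_rows), ")")
  X <- stack_to_matrix(model, stack, normalise)
  fw <- unet_forward(model, X, B = 1L, training = FALSE, keep_cache = TRUE)
  dOut <- matrix(0, nrow(fw$out), ncol(fw$out))
  dOut[mask_rows[output_voxel], 1] <- 1
  bw <- unet_backward(model, fw$cache, dOut, training = FALSE)
  grad_to_volumes(bw$dInput, mask, model$config$input_shape)
}

#' @export
voxel_saliency.linear_model <- function(model, stack, output_voxel,
                                        normalise = TRUE) {
  v <- sum(model$mask)
  if (output_voxel < 1 || output_voxel > v)
    stop("output_voxel outside the mask (1..", v, ")")
  template <- image_volume(array(0, dim(model$mask)), model$mask)
  list(with_mask_values(template, model$M[output_voxel, ]))
}

model_mask <- function(model) {
  mask <- model$mask
  if (is.null(mask)) array(TRUE, model$config$input_shape) else mask
}

grad_to_volumes <- function(dInput, mask, shape) {
  template <- image_volume(array(0, shape), mask)
  lapply(seq_len(ncol(dInput)), function(k)
    with_mask_values(template, dInput[which(as.vector(mask)), k]))
}

#' Weighted saliency explanation map
#'
#' Explains which baseline voxels drive the predicted change for one
#' subject: the predicted image is thresholded to its top `k_fraction` of
#' in-mask voxels by absolute value (ties broken by ascending voxel index),
#' and the absolute saliency maps of those output voxels are summed,
#' `E = sum_i |E_i|`. The result is non-negative everywhere and zero outside
#' the mask. The sum over selected voxels is accumulated voxel by voxel
#' (one backward pass each); a single backward pass through a signed sum of
#' outputs would not equal the sum of absolute maps and is not used.
#'
#' @param model a trained `unet_model` or [linear_model()].
#' @param stack input stack for one subject.
#' @param k_fraction fraction of in-mask output voxels to explain
#'   (default 0.05).
#' @param normalise min-max normalise the stack (as in prediction).
#' @param subject_id optional id stored on the result.
#' @return An object of class `saliency_map`: list with `E` (list of K
#'   `image_volume`s, one per input channel), `selected` (in-mask indices of
#'   the explained output voxels), `k_fraction`, `subject_id`.
#' @export
explanation_map <- function(model, stack, k_fraction = 0.05,
                            normalise = TRUE, subject_id = NA_character_) {
  if (k_fraction <= 0 || k_fraction > 1)
    stop("k_fraction must lie in (0, 1]")
  pred <- predict_explained(model, stack, normalise)
  v <- length(pred)
  k <- floor(k_fraction * v)
  if (k < 1)
    stop("degenerate input: k_fraction selects no voxels (v = ", v, ")")
  ord <- order(-abs(pred), seq_len(v))
  selected <- sort(ord[seq_len(k)])
  acc <- NULL
  for (i in selected) {
    Ei <- voxel_saliency(model, stack, i, normalise = normalise)
    if (is.null(acc)) {
      acc <- lapply(Ei, function(e) abs(e$data))
    } else {
      for (kch in seq_along(Ei)) acc[[kch]] <- acc[[kch]] + abs(Ei[[kch]]$data)
    }
  }
  mask <- if (inherits(model, "linear_model")) model$mask else
    model_mask(model)
  E <- lapply(acc, function(a) image_volume(a * mask, mask))
  structure(list(E = E, selected = selected, k_fraction = k_fraction,
                 subject_id = subject_id),
            class = "saliency_map")
}

predict_explained <- function(model, stack, normalise) {
  if (inherits(model, "linear_model")) {
    x <- if (inherits(stack, "image_volume")) mask_values(stack) else
      stack
    as.numeric(model$M %*% x)
  } else {
    mask_values(predict_volume(model, stack, normalise = normalise))
  }
}

#' @exportS3Method print saliency_map
print.saliency_map <- function(x, ...) {
  cat("<saliency_map> subject ", x$subject_id, ", ", length(x$selected),
      " output voxels explained (k = ", x$k_fraction, "), ",
      length(x$E), " input channel(s)\n", sep = "")
  invisible(x)
}

#' Group-level explanation map
#'
#' Voxel-wise mean of individual explanation maps across subjects (first
#' input channel).
#'
#' @param maps list of `saliency_map` objects sharing one mask.
#' @param channel input channel to average (default 1).
#' @return An `image_volume`.
#' @export
group_explanation <- function(maps, channel = 1) {
  if (length(maps) == 0) stop("empty list of saliency maps")
  first <- maps[[1]]$E[[channel]]
  acc <- array(0, dim(first$data))
  for (m in maps) {
    e <- m$E[[channel]]
    stop_if_grid_mismatch(first, e, "saliency maps")
    acc <- acc + e$data
  }
  image_volume(acc / length(maps), first$mask, first$spacing,
               first$orientation)
}

#' Linear reference predictor
#'
#' A transparent linear map `pred = M x` over in-mask voxels, used as an
#' analytic reference for the saliency machinery and as a configurable
#' oracle in evaluation tests.
#'
#' @param M v x v coefficient matrix (v = in-mask voxels).
#' @param mask logical 3D array.
#' @return An object of class `linear_model`.
#' @export
linear_model <- function(M, mask) {
  mask <- array(as.logical(mask), dim(as.array(mask)))
  v <- sum(mask)
  if (!identical(dim(M), c(v, v)))
    stop("M must be v x v with v = ", v)
  structure(list(M = M, mask = mask), class = "linear_model")
}

#' Save a saliency map with its JSON sidecar
#'
#' @param map a `saliency_map`.
#' @param path output NIfTI path (channel 1; extra channels get a suffix).
#' @return Invisibly, `path`.
#' @export
save_saliency <- function(map, path) {
  for (k in seq_along(map$E)) {
    p <- if (k == 1) path else sub("(\\.nii(\\.gz)?)$",
                                   sprintf("_ch%d\\1", k), path)
    save_volume(map$E[[k]], p)
  }
  side <- sub("(\\.nii(\\.gz)?)$", ".json", path)
  jsonlite::write_json(
    list(k_fraction = map$k_fraction, n_selected = length(map$selected),
         subject_id = map$subject_id),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
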