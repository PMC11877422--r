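#' Construct an image volume
#'
#' An `image_volume` is one 3D scalar field together with a binary brain mask
#' of identical shape and minimal voxel-grid metadata. All statistics in the
#' package are computed over the in-mask voxels only, vectorised in a fixed
#' lexicographic order (the first array index varies fastest), which is stable
#' across save/load round trips.
#'
#' @param data 3D numeric array.
#' @param mask 3D logical (or 0/1 numeric) array of the same shape. Defaults
#'   to all voxels in the grid.
#' @param spacing numeric length-3 voxel spacing in millimetres.
#' @param orientation character orientation descriptor (metadata only).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, mask = NULL, spacing = c(1, 1, 1),
                         orientation = "RAS") {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("image_volume: `data` must be a 3D array")
  if (is.null(mask)) {
    mask <- array(TRUE, dim(data))
  } else {
    mask <- array(as.logical(mask), dim(as.array(mask)))
  }
  if (!identical(dim(mask), dim(data)))
    stop("image_volume: mask shape ", paste(dim(mask), collapse = "x"),
         " does not match data shape ", paste(dim(data), collapse = "x"))
  if (!any(mask))
    stop("image_volume: mask must contain at least one TRUE voxel")
  if (any(!is.finite(data[mask])))
    stop("image_volume: data contains non-finite values inside the mask")
  structure(
    list(data = data, mask = mask,
         spacing = as.numeric(spacing), orientation = orientation),
    class = "image_volume")
}

#' @exportS3Method print image_volume
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = "x"),
      " grid, v = ", sum(x$mask), " in-mask voxels, spacing ",
      paste(signif(x$spacing, 3), collapse = "x"), " mm\n", sep = "")
  invisible(x)
}

#' In-mask values of a volume
#'
#' Returns the length-v vector of voxel values inside the mask, in the fixed
#' lexicographic vectorisation order.
#'
#' @param vol an `image_volume`.
#' @return numeric vector of length `sum(vol$mask)`.
#' @export
mask_values <- function(vol) {
  stopifnot(inherits(vol, "image_volume"))
  vol$data[vol$mask]
}

#' Rebuild a volume from in-mask values
#'
#' Inverse of [mask_values()]: places a length-v vector back on the grid of a
#' template volume, setting voxels outside the mask to `fill`.
#'
#' @param template an `image_volume` providing mask and metadata.
#' @param values numeric vector of length `sum(template$mask)`.
#' @param fill value used outside the mask.
#' @return An `image_volume`.
#' @export
with_mask_values <- function(template, values, fill = 0) {
  stopifnot(inherits(template, "image_volume"))
  v <- sum(template$mask)
  if (length(values) != v)
    stop("with_mask_values: expected ", v, " values, got ", length(values))
  arr <- array(fill, dim(template$data))
  arr[template$mask] <- values
  image_volume(arr, template$mask, template$spacing, template$orientation)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) && identical(a$mask, b$mask)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop("mask/grid mismatch between ", what)
  invisible(TRUE)
}

#' Construct a longitudinal baseline/follow-up pair
#'
#' Holds one subject's co-registered baseline image A and follow-up image B
#' for a single modality. Both volumes must share an identical mask and grid.
#'
#' @param subject_id opaque subject identifier.
#' @param baseline baseline `image_volume` (A).
#' @param followup follow-up `image_volume` (B).
#' @param interval_years non-negative scan interval in years.
#' @return An object of class `longitudinal_pair`.
#' @export
longitudinal_pair <- function(subject_id, baseline, followup,
                              interval_years = 2) {
  stopifnot(inherits(baseline, "image_volume"),
            inherits(followup, "image_volume"))
  stop_if_grid_mismatch(baseline, followup, "baseline and follow-up")
  if (interval_years < 0) stop("interval_years must be non-negative")
  structure(
    list(subject_id = as.character(subject_id), baseline = baseline,
         followup = followup, interval_years = interval_years),
    class = "longitudinal_pair")
}

#' @exportS3Method print longitudinal_pair
print.longitudinal_pair <- function(x, ...) {
  cat("<longitudinal_pair> subject ", x$subject_id, ", interval ",
      x$interval_years, " y, ", paste(dim(x$baseline$data), collapse = "x"),
      " grid\n", sep = "")
  invisible(x)
}

#' Ground-truth parameters of the longitudinal generative model
#'
#' Describes the generative model used throughout the package: the baseline
#' image is `A = A0 + E_A` and the follow-up is `B = A0 + Delta + E_B`, where
#' `A0` is a spatially smooth signal with unit variance, `E_A` and `E_B` are
#' i.i.d. Gaussian noise fields with standard deviation `sigma`, and the true
#' change decomposes into a linear and a nonlinear part,
#' `Delta = W A0 + f(A0)`.
#'
#' Supported linear operators `W` (see [w_scalar()], [w_diagonal()],
#' [w_blur()]): a scalar multiple of the identity, a diagonal (voxel-wise
#' gain) operator, and a Gaussian-blur kernel scaled by a constant. Supported
#' nonlinear parts `f` (see [f_none()], [f_poly()], [f_region()]): none, an
#' elementwise polynomial re-centred to zero mean, and a region-gated
#' function of the baseline signal.
#'
#' @param sigma noise standard deviation (same for both time points), >= 0.
#' @param w_spec linear change descriptor, e.g. `w_scalar(-0.3)`.
#' @param f_spec nonlinear change descriptor, e.g. `f_none()`.
#' @param smoothness_fwhm Gaussian smoothing scale of A0, in voxels FWHM.
#' @return An object of class `generative_params`. The signal variance is
#'   fixed at 1 by convention.
#' @export
generative_params <- function(sigma = 1, w_spec = w_scalar(0),
                              f_spec = f_none(), smoothness_fwhm = 3) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (!inherits(w_spec, "w_spec")) stop("w_spec must be built with w_*()")
  if (!inherits(f_spec, "f_spec")) stop("f_spec must be built with f_*()")
  structure(
    list(sigma = sigma, w_spec = w_spec, f_spec = f_spec,
         smoothness_fwhm = smoothness_fwhm, signal_variance = 1),
    class = "generative_params")
}

#' Linear change operators
#'
#' Constructors for the linear part `W` of the true change `Delta = W A0 +
#' f(A0)`. `w_scalar(c)` is `c` times the identity; `w_diagonal(gain)` applies
#' a voxel-wise gain (an array matching the grid, or a function of voxel
#' coordinates); `w_blur(scale, fwhm)` applies a Gaussian blur at the given
#' FWHM (voxels) scaled by `scale`.
#'
#' @param value scalar multiplier for `w_scalar`.
#' @param gain array or function for `w_diagonal`.
#' @param scale,fwhm blur amplitude and width for `w_blur`.
#' @return A `w_spec` descriptor.
#' @export
w_scalar <- function(value) {
  structure(list(type = "scalar", value = value), class = "w_spec")
}

#' @rdname w_scalar
#' @export
w_diagonal <- function(gain) {
  structure(list(type = "diagonal", gain = gain), class = "w_spec")
}

#' @rdname w_scalar
#' @export
w_blur <- function(scale, fwhm = 3) {
  structure(list(type = "blur", scale = scale, fwhm = fwhm), class = "w_spec")
}

#' Nonlinear change components
#'
#' Constructors for the nonlinear part `f(A0)` of the true change. `f_none()`
#' disables it. `f_poly(coef)` applies an elementwise polynomial
#' `sum_k coef[k] * A0^k` (k starting at 1), re-centred to zero in-mask mean;
#' an even polynomial such as `f_poly(c(0, 1))` (a centred square) is also
#' linearly uncorrelated with A0 under its symmetric distribution. `f_region`
#' gates a function of A0 (default identity) by a spatial region, re-centred.
#'
#' @param coef polynomial coefficients for powers 1, 2, ... of A0.
#' @param region logical array (grid shape) marking the gated region.
#' @param amplitude multiplier for the gated component.
#' @param fun elementwise function of A0 applied inside the region.
#' @return An `f_spec` descriptor.
#' @export
f_none <- function() structure(list(type = "none"), class = "f_spec")

#' @rdname f_none
#' @export
f_poly <- function(coef) {
  structure(list(type = "poly", coef = coef), class = "f_spec")
}

#' @rdname f_none
#' @export
f_region <- function(region, amplitude = 1, fun = identity) {
  structure(list(type = "region", region = region, amplitude = amplitude,
                 fun = fun), class = "f_spec")
}
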