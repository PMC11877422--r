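#' Null correlation between the temporal difference and the baseline
#'
#' In the absence of any true change (`Delta = 0`), the spatial Pearson
#' correlation between the observed temporal difference `B - A` and the
#' baseline `A` is not zero: both are dominated by the shared baseline noise
#' term. With `A = A0 + E_A`, `B = A0 + E_B` and unit signal variance,
#' `cov(B - A, A) = -sigma^2`, `var(B - A) = 2 sigma^2` and
#' `var(A) = 1 + sigma^2`, so
#' \deqn{r(B - A, A) = \frac{-\sigma^2}{\sqrt{2\sigma^2 (1 + \sigma^2)}}
#'   = -\frac{1}{\sqrt{2 + 2/\sigma^2}}.}
#' The value lies in \eqn{(-1/\sqrt{2}, 0)} for any positive noise level and
#' decreases monotonically with `sigma`: simply predicting the change as
#' `-A` can look deceptively good, and observed change correlations must be
#' judged against this null.
#'
#' @param sigma noise standard deviation, >= 0.
#' @return The null Pearson correlation (0 when `sigma = 0`).
#' @seealso [expected_change_correlation()] for the general closed form,
#'   which reduces to this null when all change terms vanish.
#' @export
#' @examples
#' null_change_correlation(1)  # -0.5
null_change_correlation <- function(sigma) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  ifelse(sigma == 0, 0, -1 / sqrt(2 + 2 / sigma^2))
}

#' Expected correlation between temporal difference and baseline
#'
#' Closed form for the population spatial correlation `r(B - A, A)` under the
#' generative model `A = A0 + E_A`, `B = A0 + W A0 + f(A0) + E_B`:
#' \deqn{r = \frac{\mathrm{cov}(W A_0, A_0) - \sigma^2}
#'   {\sqrt{(\mathrm{var}(W A_0) + \mathrm{var}(f) + 2\sigma^2)(1 + \sigma^2)}}}
#' With all change moments zero this reduces to
#' [null_change_correlation()]. A negative `cov(W A0, A0)` (change that
#' shrinks the baseline pattern) pushes the correlation below the null.
#'
#' @param params a [generative_params()] object (supplies `sigma`).
#' @param cov_wa0_a0 `cov(W A0, A0)` under the A0 distribution.
#' @param var_wa0 `var(W A0)`, >= 0.
#' @param var_f `var(f(A0))`, >= 0.
#' @return Expected Pearson correlation.
#' @export
expected_change_correlation <- function(params, cov_wa0_a0 = 0,
                                        var_wa0 = 0, var_f = 0) {
  stopifnot(inherits(params, "generative_params"))
  if (var_wa0 < 0 || var_f < 0) stop("variance arguments must be >= 0")
  s2 <- params$sigma^2
  denom <- sqrt((var_wa0 + var_f + 2 * s2) * (1 + s2))
  if (denom == 0) return(0)  # sigma = 0 and no change: B - A is identically 0
  (cov_wa0_a0 - s2) / denom
}

#' Expected correlation between follow-up and baseline images
#'
#' Closed form for the population spatial correlation `r(B, A)` under the
#' same generative model:
#' \deqn{r = \frac{\mathrm{cov}((I+W) A_0, A_0)}
#'   {\sqrt{(\mathrm{var}((I+W) A_0) + \mathrm{var}(f) + \sigma^2)(1 + \sigma^2)}}}
#' With no true change this reduces to the data reproducibility
#' `1 / (1 + sigma^2)`, i.e. the test-retest correlation implied by the noise
#' level. An observed `r(B, A)` below the measured reproducibility is
#' therefore evidence that true change exists.
#'
#' @inheritParams expected_change_correlation
#' @param cov_ipw `cov((I + W) A0, A0)`.
#' @param var_ipw `var((I + W) A0)`, >= 0.
#' @return Expected Pearson correlation.
#' @export
expected_followup_correlation <- function(params, cov_ipw = 1,
                                          var_ipw = 1, var_f = 0) {
  stopifnot(inherits(params, "generative_params"))
  if (var_ipw < 0 || var_f < 0) stop("variance arguments must be >= 0")
  s2 <- params$sigma^2
  denom <- sqrt((var_ipw + var_f + s2) * (1 + s2))
  if (denom == 0) return(0)
  cov_ipw / denom
}

#' Noise level implied by a test-retest reproducibility
#'
#' Inverts the no-change reduction of [expected_followup_correlation()],
#' `rho = 1 / (1 + sigma^2)`, to recover the noise standard deviation under
#' the unit-signal-variance convention: `sigma = sqrt(1/rho - 1)`. Because
#' any true change also depresses the baseline/follow-up correlation, using
#' an observed correlation here yields a lower-bound-style approximation of
#' the reproducibility-implied noise; split-half reproducibility of a single
#' scan is the intended input.
#'
#' @param rho test-retest (reproducibility) correlation, in (0, 1).
#' @return Noise standard deviation `sigma`.
#' @export
#' @examples
#' sigma_from_reproducibility(0.5)  # 1
sigma_from_reproducibility <- function(rho) {
  if (any(rho <= 0 | rho >= 1))
    stop("rho must lie strictly between 0 and 1")
  sqrt(1 / rho - 1)
}

#' Descriptive test for the existence of longitudinal change
#'
#' Compares observed cohort-level spatial correlations with their no-change
#' references: the observed baseline/follow-up correlation `r(B, A)` against
#' the measured data reproducibility, and the observed change correlation
#' `r(B - A, A)` against the closed-form null [null_change_correlation()].
#' Either observed value falling below (or away from) its reference is
#' evidence that true temporal change exists. The verdict is descriptive; no
#' sampling distribution is attached. If per-subject correlation vectors are
#' supplied, seeded percentile bootstrap confidence intervals for the two
#' gaps are added.
#'
#' @param observed_r_ab observed cohort-mean `r(B, A)`, in `[-1, 1]`.
#' @param reproducibility measured test-retest correlation, in `[-1, 1]`.
#' @param observed_r_diff_a observed cohort-mean `r(B - A, A)`, in `[-1, 1]`.
#' @param sigma noise standard deviation used for the null change
#'   correlation, >= 0.
#' @param tol absolute tolerance below which a gap is not flagged.
#' @param r_ab_subjects,r_diff_a_subjects optional per-subject correlation
#'   vectors; when given, percentile bootstrap intervals are computed.
#' @param n_boot,conf,seed bootstrap resamples, level and seed.
#' @return A list of class `change_existence_verdict` with elements
#'   `flag_followup`, `flag_diff`, `change_evidence`, `gap_followup`
#'   (observed minus reproducibility), `gap_diff` (observed minus null),
#'   `null_diff`, and optionally `ci_followup` / `ci_diff`.
#' @export
change_existence_test <- function(observed_r_ab, reproducibility,
                                  observed_r_diff_a, sigma,
                                  tol = 0,
                                  r_ab_subjects = NULL,
                                  r_diff_a_subjects = NULL,
                                  n_boot = 1000, conf = 0.95, seed = 1) {
  vals <- c(observed_r_ab, reproducibility, observed_r_diff_a)
  if (any(abs(vals) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  if (sigma < 0) stop("sigma must be non-negative")
  null_diff <- null_change_correlation(sigma)
  gap_followup <- observed_r_ab - reproducibility
  gap_diff <- observed_r_diff_a - null_diff
  out <- list(
    flag_followup = gap_followup < -tol,
    flag_diff = abs(gap_diff) > tol,
    gap_followup = gap_followup,
    gap_diff = gap_diff,
    null_diff = null_diff,
    reproducibility = reproducibility,
    tol = tol)
  out$change_evidence <- out$flag_followup || out$flag_diff
  boot_ci <- function(x, shift) {
    n <- length(x)
    stat <- vapply(seq_len(n_boot), function(i)
      mean(x[sample.int(n, n, replace = TRUE)]) - shift, numeric(1))
    stats::quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  }
  if (!is.null(r_ab_subjects) || !is.null(r_diff_a_subjects)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    if (!is.null(r_ab_subjects))
      out$ci_followup <- boot_ci(r_ab_subjects, reproducibility)
    if (!is.null(r_diff_a_subjects))
      out$ci_diff <- boot_ci(r_diff_a_subjects, null_diff)
  }
  class(out) <- "change_existence_verdict"
  out
}

#' @exportS3Method print change_existence_verdict
print.change_existence_verdict <- function(x, ...) {
  cat("<change_existence_verdict>\n")
  cat(sprintf("  r(B,A) vs reproducibility: gap %+0.4f (flag: %s)\n",
              x$gap_followup, x$flag_followup))
  cat(sprintf("  r(B-A,A) vs null %0.4f:    gap %+0.4f (flag: %s)\n",
              x$null_diff, x$gap_diff, x$flag_diff))
  cat("  change evidence:", x$change_evidence, "\n")
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Residualise a baseline/follow-up pair against the population mean
#'
#' For all modalities there is a population-average pattern that can dominate
#' each subject's image, biasing a predictor towards reproducing the cohort
#' mean. Residualisation removes it by a per-subject scalar regression over
#' in-mask voxels: the coefficient `beta_pop` is the least-squares fit of the
#' baseline A on the population mean, and the SAME coefficient is applied to
#' both time points:
#' \deqn{ResA = A - \bar{A}\hat\beta, \qquad ResB = B - \bar{A}\hat\beta.}
#' Using the baseline-fitted coefficient for both images means the original
#' follow-up can later be reconstructed from a predicted ResB without knowing
#' the true B (see [reconstruct_followup()]). By default the regression has
#' no intercept (a single scalar coefficient); set `intercept = TRUE` to also
#' remove a fitted constant.
#'
#' @param pair a [longitudinal_pair()].
#' @param pop_mean population-average baseline `image_volume` computed on the
#'   training subjects (see [population_mean()]).
#' @param intercept include an intercept in the fit (default `FALSE`).
#' @return An object of class `residual_set` with `res_a`, `res_b`
#'   (image volumes), `beta_pop`, and the pair's subject id; `res_b_given_a`
#'   and `beta_within` are filled by [residual_temporal_difference()].
#' @export
residualise_pair <- function(pair, pop_mean, intercept = FALSE) {
  stopifnot(inherits(pair, "longitudinal_pair"),
            inherits(pop_mean, "image_volume"))
  stop_if_grid_mismatch(pair$baseline, pop_mean, "pair and population mean")
  p <- mask_values(pop_mean)
  a <- mask_values(pair$baseline)
  b <- mask_values(pair$followup)
  if (length(p) > 1 && stats::var(p) == 0)
    stop("singular fit: population mean has zero in-mask variance")
  if (intercept) {
    den <- sum((p - mean(p))^2)
    if (den == 0) stop("singular fit: population mean is constant in the mask")
    beta <- sum((p - mean(p)) * (a - mean(a))) / den
    alpha <- mean(a) - beta * mean(p)
    fit <- alpha + beta * p
  } else {
    den <- sum(p * p)
    if (den == 0) stop("singular fit: population mean is zero in the mask")
    beta <- sum(p * a) / den
    fit <- beta * p
  }
  res <- list(
    subject_id = pair$subject_id,
    res_a = with_mask_values(pair$baseline, a - fit),
    res_b = with_mask_values(pair$followup, b - fit),
    beta_pop = beta,
    intercept = intercept,
    res_b_given_a = NULL,
    beta_within = NULL)
  class(res) <- "residual_set"
  res
}

#' Residual temporal difference ResB\\ResA
#'
#' The naive temporal difference `ResB - ResA` carries a non-zero null
#' correlation with the baseline because both share the baseline noise. The
#' residual temporal difference instead regresses ResA out of ResB,
#' \deqn{ResB\backslash ResA = ResB - ResA\,\hat\beta,}
#' leaving a change map that is exactly uncorrelated with ResA by
#' construction: in the no-change null its correlation with the baseline is
#' zero. It isolates the part of the follow-up that cannot be linearly
#' represented by the baseline — with the caveat that when ResA is noisy,
#' regression dilution (attenuation of the fitted coefficient) can leave
#' residual baseline signal in the map; no correction is applied.
#'
#' The fit is centred (equivalently, includes an intercept) so the Pearson
#' orthogonality holds exactly rather than only when the in-mask means happen
#' to vanish; `center = FALSE` gives the raw single-coefficient projection.
#'
#' @param res a `residual_set` from [residualise_pair()].
#' @param center centre the regression (default `TRUE`).
#' @return The input `residual_set` with `res_b_given_a` and `beta_within`
#'   filled in.
#' @export
residual_temporal_difference <- function(res, center = TRUE) {
  stopifnot(inherits(res, "residual_set"))
  ra <- mask_values(res$res_a)
  rb <- mask_values(res$res_b)
  if (center) {
    rac <- ra - mean(ra)
    den <- sum(rac^2)
    if (den == 0) stop("singular fit: ResA has zero in-mask variance")
    beta <- sum(rac * (rb - mean(rb))) / den
    resid <- rb - mean(rb) - beta * rac
  } else {
    den <- sum(ra^2)
    if (den == 0) stop("singular fit: ResA is identically zero in the mask")
    beta <- sum(ra * rb) / den
    resid <- rb - beta * ra
  }
  res$res_b_given_a <- with_mask_values(res$res_b, resid)
  res$beta_within <- beta
  res
}

#' Population mean image
#'
#' Voxel-wise mean of the baseline images of a set of pairs. In a train/test
#' workflow this must be computed on the training subjects only and reused
#' for every subject at prediction time.
#'
#' @param pairs list of [longitudinal_pair()] objects.
#' @param which `"baseline"` (default) or `"followup"`.
#' @return An `image_volume`.
#' @export
population_mean <- function(pairs, which = c("baseline", "followup")) {
  which <- match.arg(which)
  stopifnot(length(pairs) >= 1)
  acc <- array(0, dim(pairs[[1]][[which]]$data))
  for (p in pairs) {
    stop_if_grid_mismatch(pairs[[1]][[which]], p[[which]], "cohort volumes")
    acc <- acc + p[[which]]$data
  }
  template <- pairs[[1]][[which]]
  image_volume(acc / length(pairs), template$mask, template$spacing,
               template$orientation)
}

#' Residualise every pair in a cohort
#'
#' Applies [residualise_pair()] and [residual_temporal_difference()] to each
#' pair using a common population mean.
#'
#' @param pairs list of [longitudinal_pair()] objects (or a cohort from
#'   [generate_cohort()], whose pairs are used).
#' @param pop_mean population mean `image_volume`; defaults to the baseline
#'   mean of `pairs` (use the training-set mean in split workflows).
#' @param intercept passed to [residualise_pair()].
#' @return List of `residual_set` objects with the residual temporal
#'   difference filled in.
#' @export
residualise_cohort <- function(pairs, pop_mean = NULL, intercept = FALSE) {
  if (inherits(pairs, "synthetic_cohort")) {
    if (is.null(pop_mean)) pop_mean <- pairs$pop_mean
    pairs <- pairs$pairs
  }
  if (is.null(pop_mean)) pop_mean <- population_mean(pairs)
  lapply(pairs, function(p)
    residual_temporal_difference(residualise_pair(p, pop_mean, intercept)))
}

#' Reconstruct a follow-up image from a predicted residual
#'
#' Adds the population-mean component `pop_mean * beta_pop` back onto a
#' predicted ResB, recovering an estimate of the original follow-up image.
#' This is possible because residualisation used the coefficient fitted on
#' the baseline image only.
#'
#' @param pred_res_b predicted ResB `image_volume`.
#' @param pop_mean training-set population mean.
#' @param beta_pop the subject's `beta_pop` from [residualise_pair()].
#' @return An `image_volume` on the original follow-up scale.
#' @export
reconstruct_followup <- function(pred_res_b, pop_mean, beta_pop) {
  stop_if_grid_mismatch(pred_res_b, pop_mean, "prediction and population mean")
  with_mask_values(pred_res_b,
                   mask_values(pred_res_b) + beta_pop * mask_values(pop_mean))
}
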