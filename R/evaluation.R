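#' Pearson correlation over in-mask voxels
#'
#' The package's core similarity metric: the spatial Pearson correlation of
#' two volumes, computed over the shared in-mask voxels in double precision.
#'
#' @param x,y `image_volume`s with identical masks.
#' @return Pearson r.
#' @export
masked_correlation <- function(x, y) {
  stop_if_grid_mismatch(x, y, "correlation inputs")
  xv <- mask_values(x)
  yv <- mask_values(y)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("degenerate input: constant image inside the mask")
  stats::cor(xv, yv)
}

#' Evaluate predictions against true maps
#'
#' Per-subject spatial correlation and mean absolute error of predictions
#' against the true maps, with a copy-baseline comparison: for follow-up
#' targets the baseline prediction is the (residualised) baseline image
#' itself (`copyA`); for difference targets it is its negative (`copyNegA`),
#' which is what a no-skill model that exploits the shared-noise null would
#' produce. Percent improvement is `100 * (r_model - r_baseline) /
#' |r_baseline|`, so positive values mean the model beats copying.
#'
#' @param preds,truths aligned lists of `image_volume`s.
#' @param baselines aligned list of baseline `image_volume`s (ResA).
#' @param baseline_mode `"copyA"` or `"copyNegA"`.
#' @param subject_ids optional ids for the per-subject table.
#' @return An object of class `prediction_report`: list with `per_subject`
#'   (data.frame: subject, r, mae, r_baseline, mae_baseline), `mean_r`,
#'   `mean_mae`, `mean_r_baseline`, `percent_improvement_r`.
#' @export
evaluate_predictions <- function(preds, truths, baselines,
                                 baseline_mode = c("copyA", "copyNegA"),
                                 subject_ids = NULL) {
  baseline_mode <- match.arg(baseline_mode)
  if (length(preds) != length(truths) || length(preds) != length(baselines))
    stop("subject mismatch: preds, truths and baselines differ in length")
  n <- length(preds)
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%04d", seq_len(n))
  sgn <- if (baseline_mode == "copyA") 1 else -1
  rows <- lapply(seq_len(n), function(s) {
    tv <- mask_values(truths[[s]])
    pv <- mask_values(preds[[s]])
    bv <- sgn * mask_values(baselines[[s]])
    data.frame(
      subject_id = subject_ids[s],
      r = stats::cor(pv, tv),
      mae = mean(abs(pv - tv)),
      r_baseline = stats::cor(bv, tv),
      mae_baseline = mean(abs(bv - tv)),
      stringsAsFactors = FALSE)
  })
  per_subject <- do.call(rbind, rows)
  if (any(!is.finite(per_subject$r)))
    stop("non-finite per-subject correlation (constant map?)")
  mean_r <- mean(per_subject$r)
  mean_rb <- mean(per_subject$r_baseline)
  structure(list(
    per_subject = per_subject,
    mean_r = mean_r,
    mean_mae = mean(per_subject$mae),
    mean_r_baseline = mean_rb,
    mean_mae_baseline = mean(per_subject$mae_baseline),
    percent_improvement_r = 100 * (mean_r - mean_rb) / abs(mean_rb),
    baseline_mode = baseline_mode),
    class = "prediction_report")
}

#' @exportS3Method print prediction_report
print.prediction_report <- function(x, ...) {
  cat("<prediction_report> n =", nrow(x$per_subject), "subjects\n")
  cat(sprintf("  mean r:    %0.4f (baseline %s: %0.4f, improvement %+0.1f%%)\n",
              x$mean_r, x$baseline_mode, x$mean_r_baseline,
              x$percent_improvement_r))
  cat(sprintf("  mean MAE:  %0.4f (baseline: %0.4f)\n",
              x$mean_mae, x$mean_mae_baseline))
  invisible(x)
}

## Normalise the many ways a "model" can be supplied to the diagnostic:
## a unet_model, a linear_model, or a plain function image_volume -> image_volume.
as_predict_fun <- function(model, normalise = TRUE) {
  if (inherits(model, "unet_model")) {
    if (is.null(model$history))
      stop("untrained model: train it before running the diagnostic")
    function(vol) predict_volume(model, vol, normalise = normalise)
  } else if (inherits(model, "linear_model")) {
    function(vol) with_mask_values(vol, as.numeric(model$M %*% mask_values(vol)))
  } else if (is.function(model)) {
    model
  } else {
    stop("model must be a unet_model, linear_model, or function")
  }
}

#' Change-prediction versus denoising diagnostic
#'
#' A model that merely denoises the baseline can score a deceptively high
#' follow-up prediction correlation. The diagnostic feeds the residualised
#' baseline ResA and the residualised follow-up ResB through the SAME model
#' separately and compares the cohort-mean forward correlation
#' `r(g(ResA), ResB)` with the backward correlation `r(g(ResB), ResA)`. For
#' a pure denoiser the two are matched (denoising either time point helps
#' the cross-correlation equally in the no-change case), whereas a model
#' that genuinely predicts change moves its output towards the *next* time
#' point, inflating the forward and deflating the backward correlation. A
#' residual-temporal-difference variant compares
#' `r(g(ResA) \\ ResA, ResB \\ ResA)` with the time-reversed analogue.
#'
#' @param model a trained `unet_model`, a [linear_model()], or a function
#'   mapping an `image_volume` to an `image_volume`.
#' @param residuals list of `residual_set`s from [residualise_cohort()].
#' @param margin cohort-mean correlation gap above which the verdict is
#'   `"change-prediction"` (default 0.02, chosen to exceed Monte-Carlo
#'   noise at a few hundred subjects).
#' @param rtd_variant also compute the residual-temporal-difference variant.
#' @param normalise passed to the model's prediction path.
#' @return An object of class `diagnostic_report`: `r_forward`,
#'   `r_backward`, `gap`, per-subject vectors, `verdict` (one of
#'   `"change-prediction"`, `"denoising-only"`, `"indeterminate"`), the
#'   copy-baseline reference `r_copy` = mean r(ResA, ResB), and (optionally)
#'   `r_forward_rtd` / `r_backward_rtd` / `gap_rtd`.
#' @export
denoising_diagnostic <- function(model, residuals, margin = 0.02,
                                 rtd_variant = TRUE, normalise = TRUE) {
  g <- as_predict_fun(model, normalise)
  n <- length(residuals)
  if (n < 1) stop("empty cohort")
  fwd <- bwd <- copy <- numeric(n)
  fwd_rtd <- bwd_rtd <- rep(NA_real_, n)
  for (s in seq_len(n)) {
    res <- residuals[[s]]
    pred_b <- g(res$res_a)   # feed baseline, expect follow-up-like output
    pred_a <- g(res$res_b)   # feed follow-up into the same model
    fwd[s] <- masked_correlation(pred_b, res$res_b)
    bwd[s] <- masked_correlation(pred_a, res$res_a)
    copy[s] <- masked_correlation(res$res_a, res$res_b)
    if (rtd_variant) {
      ## regress the fed image out of both prediction and target, mirroring
      ## the residual-temporal-difference metric in each direction
      rtd_f <- project_out(pred_b, res$res_a)
      tgt_f <- project_out(res$res_b, res$res_a)
      rtd_b <- project_out(pred_a, res$res_b)
      tgt_b <- project_out(res$res_a, res$res_b)
      fwd_rtd[s] <- masked_correlation(rtd_f, tgt_f)
      bwd_rtd[s] <- masked_correlation(rtd_b, tgt_b)
    }
  }
  gap <- mean(fwd) - mean(bwd)
  verdict <- if (gap > margin) "change-prediction"
  else if (abs(gap) <= margin) "denoising-only"
  else "indeterminate"
  structure(list(
    r_forward = mean(fwd), r_backward = mean(bwd), gap = gap,
    r_forward_subjects = fwd, r_backward_subjects = bwd,
    r_copy = mean(copy), margin = margin, verdict = verdict,
    r_forward_rtd = if (rtd_variant) mean(fwd_rtd) else NA_real_,
    r_backward_rtd = if (rtd_variant) mean(bwd_rtd) else NA_real_,
    gap_rtd = if (rtd_variant) mean(fwd_rtd) - mean(bwd_rtd) else NA_real_),
    class = "diagnostic_report")
}

## Residual of y after centred scalar regression on x (in-mask).
project_out <- function(y, x) {
  yv <- mask_values(y)
  xv <- mask_values(x)
  xc <- xv - mean(xv)
  den <- sum(xc^2)
  if (den == 0) stop("singular fit: regressor constant in mask")
  beta <- sum(xc * (yv - mean(yv))) / den
  with_mask_values(y, yv - mean(yv) - beta * xc)
}

#' @exportS3Method print diagnostic_report
print.diagnostic_report <- function(x, ...) {
  cat("<diagnostic_report>\n")
  cat(sprintf("  forward  r(g(ResA), ResB): %0.4f\n", x$r_forward))
  cat(sprintf("  backward r(g(ResB), ResA): %0.4f\n", x$r_backward))
  cat(sprintf("  gap: %+0.4f (margin %0.3f) -> %s\n", x$gap, x$margin,
              x$verdict))
  if (!is.na(x$gap_rtd))
    cat(sprintf("  residual-difference variant gap: %+0.4f\n", x$gap_rtd))
  cat(sprintf("  copy-baseline reference r(ResA, ResB): %0.4f\n", x$r_copy))
  invisible(x)
}

#' Fingerprint identification rate
#'
#' Treats each predicted map as a candidate fingerprint: a subject is
#' identified when the correlation of their predicted map with their own
#' true map strictly exceeds its correlation with every other subject's
#' true map. Ties count as failures. The rate is the fraction of identified
#' subjects; it is invariant to any common positive affine rescaling of the
#' maps because Pearson correlation is.
#'
#' @param pred_maps,true_maps aligned lists (>= 2 subjects) of
#'   `image_volume`s.
#' @return Identification rate in \[0, 1\].
#' @export
identification_rate <- function(pred_maps, true_maps) {
  n <- length(pred_maps)
  if (n < 2 || length(true_maps) != n)
    stop("need >= 2 aligned subjects")
  P <- vapply(pred_maps, mask_values, numeric(sum(pred_maps[[1]]$mask)))
  Tm <- vapply(true_maps, mask_values, numeric(sum(true_maps[[1]]$mask)))
  R <- stats::cor(P, Tm)  # R[s, t] = r(pred_s, true_t)
  hits <- vapply(seq_len(n), function(s) {
    R[s, s] > max(R[s, -s])
  }, logical(1))
  mean(hits)
}

#' Predict non-imaging phenotypes from change maps
#'
#' The downstream utility test: reduce subjects-by-voxels change maps (the
#' residual temporal difference, predicted or true) to principal components
#' and predict each phenotype with elastic-net regression, reporting the
#' out-of-fold correlation between predicted and true phenotype values.
#' Components are fitted on the training folds only and test subjects are
#' projected onto them, so no test information leaks into the fit; the
#' regularisation path is selected by inner cross-validation within the
#' training folds. Phenotypes are z-scored across subjects; a phenotype
#' that is constant in any training fold is excluded and flagged.
#'
#' @param change_maps list of `image_volume`s (one per subject), or a
#'   subjects x voxels matrix.
#' @param nidp a [generate_nidp_table()] result or a data.frame whose first
#'   column is `subject_id`.
#' @param n_components number of principal components (must be `<
#'   n_subjects`); the source protocol uses 500 at biobank scale.
#' @param folds number of outer cross-validation folds.
#' @param seed integer seed for fold assignment and the elastic net.
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param nlambda length of the regularisation path.
#' @param rule penalty selection rule from the inner cross-validation:
#'   `"lambda.1se"` (default, conservative: the largest penalty within one
#'   standard error of the minimum, which shrinks null associations to the
#'   intercept) or `"lambda.min"`. A phenotype whose out-of-fold predictions
#'   are constant is scored r = 0 (no detectable association).
#' @return An object of class `nidp_report`: data.frame `results` with
#'   columns `phenotype`, `r`, `n_used`, `excluded`, plus the out-of-fold
#'   predictions in `predictions`.
#' @export
nidp_prediction <- function(change_maps, nidp, n_components = 20,
                            folds = 5, seed = 1, alpha = 0.5,
                            nlambda = 10,
                            rule = c("lambda.1se", "lambda.min")) {
  rule <- match.arg(rule)
  X <- if (is.matrix(change_maps)) change_maps else
    t(vapply(change_maps, mask_values,
             numeric(sum(change_maps[[1]]$mask))))
  tab <- if (inherits(nidp, "nidp_table")) nidp$table else nidp
  stopifnot(is.data.frame(tab), names(tab)[1] == "subject_id")
  n <- nrow(X)
  if (nrow(tab) != n) stop("subject mismatch between maps and phenotypes")
  if (n_components > n - 1)
    stop("configuration error: n_components must be < n_subjects")
  phen_names <- names(tab)[-1]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  preds <- matrix(NA_real_, n, length(phen_names),
                  dimnames = list(NULL, phen_names))
  excluded <- logical(length(phen_names))
  ## z-score phenotypes across subjects
  Y <- as.matrix(tab[, -1, drop = FALSE])
  Y <- scale(Y)
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    mu <- colMeans(X[tr, , drop = FALSE])
    Xc <- X[tr, , drop = FALSE] - rep(mu, each = length(tr))
    sv <- svd(Xc, nu = 0, nv = min(n_components, length(tr) - 1L))
    V <- sv$v
    S_tr <- Xc %*% V
    S_te <- (X[te, , drop = FALSE] - rep(mu, each = length(te))) %*% V
    for (j in seq_along(phen_names)) {
      y_tr <- Y[tr, j]
      ok <- !is.na(y_tr)
      if (sum(ok) < 10 || stats::sd(y_tr[ok]) == 0) {
        excluded[j] <- TRUE
        next
      }
      cv <- glmnet::cv.glmnet(S_tr[ok, , drop = FALSE], y_tr[ok],
                              alpha = alpha, nlambda = nlambda,
                              nfolds = 5, standardize = TRUE)
      preds[te, j] <- as.numeric(stats::predict(cv, newx = S_te, s = rule))
    }
  }
  results <- data.frame(
    phenotype = phen_names,
    r = vapply(seq_along(phen_names), function(j) {
      if (excluded[j]) return(NA_real_)
      ## correlation within each fold, averaged: pooling out-of-fold
      ## predictions would let per-fold intercept differences masquerade
      ## as predictive variance for null phenotypes
      rs <- vapply(seq_len(folds), function(f) {
        ok <- fold_id == f & !is.na(preds[, j]) & !is.na(Y[, j])
        if (sum(ok) < 3) return(NA_real_)
        if (stats::sd(preds[ok, j]) == 0) return(0)
        stats::cor(preds[ok, j], Y[ok, j])
      }, numeric(1))
      mean(rs, na.rm = TRUE)
    }, numeric(1)),
    n_used = vapply(seq_along(phen_names), function(j)
      sum(!is.na(preds[, j]) & !is.na(Y[, j])), numeric(1)),
    excluded = excluded,
    stringsAsFactors = FALSE)
  structure(list(results = results, predictions = preds,
                 n_components = n_components, folds = folds, seed = seed),
            class = "nidp_report")
}

#' @exportS3Method print nidp_report
print.nidp_report <- function(x, ...) {
  cat("<nidp_report>", x$n_components, "components,", x$folds, "folds\n")
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Write a diagnostic or prediction report to TSV + JSON
#'
#' @param report a `prediction_report`, `diagnostic_report` or
#'   `nidp_report`.
#' @param prefix output path prefix (writes `<prefix>.tsv` and
#'   `<prefix>.json`).
#' @return Invisibly, the prefix.
#' @export
write_report <- function(report, prefix) {
  if (inherits(report, "prediction_report")) {
    write_report_tsv(report$per_subject, paste0(prefix, ".tsv"))
    summ <- report[c("mean_r", "mean_mae", "mean_r_baseline",
                     "mean_mae_baseline", "percent_improvement_r",
                     "baseline_mode")]
  } else if (inherits(report, "diagnostic_report")) {
    write_report_tsv(
      data.frame(subject = seq_along(report$r_forward_subjects),
                 r_forward = report$r_forward_subjects,
                 r_backward = report$r_backward_subjects),
      paste0(prefix, ".tsv"))
    summ <- report[c("r_forward", "r_backward", "gap", "gap_rtd", "r_copy",
                     "margin", "verdict")]
  } else if (inherits(report, "nidp_report")) {
    write_report_tsv(report$results, paste0(prefix, ".tsv"))
    summ <- list(n_components = report$n_components, folds = report$folds,
                 mean_abs_r = mean(abs(report$results$r), na.rm = TRUE))
  } else stop("unknown report type")
  jsonlite::write_json(summ, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(prefix)
}
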