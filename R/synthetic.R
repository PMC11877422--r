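## Separable Gaussian smoothing on a 3D array.
## Builds one dense d x d band matrix per axis (grids are small, <= ~128);
## rows are renormalised so a constant field is preserved at the edges.
gaussian_smooth_3d <- function(arr, fwhm) {
  if (fwhm <= 0) return(arr)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  d <- dim(arr)
  smooth_mat <- function(n) {
    half <- max(1L, ceiling(3 * sigma))
    offs <- (-half):half
    k <- exp(-offs^2 / (2 * sigma^2))
    S <- matrix(0, n, n)
    for (j in seq_along(offs)) {
      o <- offs[j]
      idx <- seq_len(n)
      src <- idx + o
      ok <- src >= 1 & src <= n
      S[cbind(idx[ok], src[ok])] <- S[cbind(idx[ok], src[ok])] + k[j]
    }
    S / rowSums(S)
  }
  ## axis 1
  m <- matrix(arr, d[1], d[2] * d[3])
  arr <- array(smooth_mat(d[1]) %*% m, d)
  ## axis 2
  a <- aperm(arr, c(2, 1, 3))
  m <- matrix(a, d[2], d[1] * d[3])
  a <- array(smooth_mat(d[2]) %*% m, c(d[2], d[1], d[3]))
  arr <- aperm(a, c(2, 1, 3))
  ## axis 3
  a <- aperm(arr, c(3, 1, 2))
  m <- matrix(a, d[3], d[1] * d[2])
  a <- array(smooth_mat(d[3]) %*% m, c(d[3], d[1], d[2]))
  aperm(a, c(2, 3, 1))
}

## Deterministic per-subject substream: one cohort seed spawns independent
## per-subject seeds, so subject s is reproducible regardless of cohort size.
## Kept below 2^31 - 1.
subject_seed <- function(seed, s, stream = 0L) {
  (as.numeric(seed) * 48271 + s * 7919 + stream * 104729) %% 2147483647
}

#' Generate a smooth unit-variance random signal
#'
#' Realises the latent baseline signal A0 of the generative model: a Gaussian
#' white-noise field smoothed by a separable Gaussian kernel, then
#' standardised to in-mask mean 0 and (sample) variance exactly 1, matching
#' the model convention `var(A0) = 1`.
#'
#' @param shape integer length-3 grid dimensions (each >= 8).
#' @param smoothness_fwhm smoothing scale in voxels FWHM (0 = white noise).
#' @param seed integer seed; the same seed reproduces the field exactly.
#' @param mask optional logical array; defaults to the full grid.
#' @return An `image_volume` with standardised in-mask values.
#' @export
make_smooth_signal <- function(shape, smoothness_fwhm = 3, seed = 1,
                               mask = NULL) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  if (any(shape < 8L)) stop("each grid dimension must be >= 8")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  arr <- array(stats::rnorm(prod(shape)), shape)
  arr <- gaussian_smooth_3d(arr, smoothness_fwhm)
  vol <- image_volume(arr, mask)
  x <- mask_values(vol)
  x <- (x - mean(x)) / stats::sd(x)
  with_mask_values(vol, x)
}

#' Apply the true change model to a baseline signal
#'
#' Computes `Delta = W A0 + f(A0)` for a standardised baseline signal. The
#' nonlinear component is re-centred to zero in-mask mean before being added.
#' The linear and nonlinear parts are returned separately alongside their
#' sum, so ground truth can be retained by cohort generators.
#'
#' @param a0 standardised baseline signal `image_volume`.
#' @param params a [generative_params()] object.
#' @return List with `delta`, `linear`, `nonlinear` (image volumes).
#' @export
apply_change <- function(a0, params) {
  stopifnot(inherits(a0, "image_volume"),
            inherits(params, "generative_params"))
  w <- params$w_spec
  lin <- switch(w$type,
    scalar = w$value * a0$data,
    diagonal = {
      g <- w$gain
      if (is.function(g)) {
        d <- dim(a0$data)
        co <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                    z = seq_len(d[3])))
        array(g(co), d) * a0$data
      } else {
        if (!identical(dim(as.array(g)), dim(a0$data)))
          stop("configuration error: diagonal gain shape mismatch")
        as.array(g) * a0$data
      }
    },
    blur = w$scale * gaussian_smooth_3d(a0$data, w$fwhm),
    stop("configuration error: unsupported w_spec type '", w$type, "'"))
  f <- params$f_spec
  nl <- switch(f$type,
    none = array(0, dim(a0$data)),
    poly = {
      acc <- array(0, dim(a0$data))
      for (k in seq_along(f$coef))
        if (f$coef[k] != 0) acc <- acc + f$coef[k] * a0$data^k
      acc
    },
    region = {
      if (!identical(dim(as.array(f$region)), dim(a0$data)))
        stop("configuration error: region shape mismatch")
      f$amplitude * as.array(f$region) * f$fun(a0$data)
    },
    stop("configuration error: unsupported f_spec type '", f$type, "'"))
  ## re-centre the nonlinear part: the model assumes mean(f(A0)) = 0
  if (f$type != "none") nl[] <- nl - mean(nl[a0$mask])
  lin_v <- image_volume(lin, a0$mask, a0$spacing, a0$orientation)
  nl_v <- image_volume(nl, a0$mask, a0$spacing, a0$orientation)
  list(delta = image_volume(lin + nl, a0$mask, a0$spacing, a0$orientation),
       linear = lin_v, nonlinear = nl_v)
}

#' Generate a synthetic longitudinal cohort with known ground truth
#'
#' Draws `n_subjects` independent subjects from the generative model:
#' `A = A0 + E_A`, `B = A0 + Delta + E_B` with `Delta = W A0 + f(A0)`,
#' smooth unit-variance A0 and i.i.d. Gaussian noise of standard deviation
#' `params$sigma` at both time points. A shared population-mean pattern
#' (a smooth field scaled to `pop_mean_amplitude` times the subject-level
#' standard deviation `sqrt(1 + sigma^2)`) is added to every baseline and
#' follow-up, emulating the dominant cohort-average pattern that
#' residualisation is designed to remove. All randomness flows from one seed
#' through deterministic per-subject substreams, so regenerating with the
#' same seed reproduces the cohort bit-identically.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param params a [generative_params()] object.
#' @param shape grid dimensions (scalar or length 3).
#' @param seed integer master seed.
#' @param mask optional logical array mask.
#' @param pop_mean_amplitude amplitude of the shared population pattern, as a
#'   multiple of the subject-level standard deviation; 0 disables it.
#' @param interval_years scan interval stored on each pair.
#' @param keep_truth retain per-subject ground truth (`a0`, `delta`,
#'   `linear`, `nonlinear`, `e_a`, `e_b` as in-mask vectors).
#' @return An object of class `synthetic_cohort`: list with `pairs`, `truth`,
#'   `params`, `pop_mean` (`image_volume` of the added pattern), `mask`,
#'   `shape`, `seed`.
#' @export
generate_cohort <- function(n_subjects, params = generative_params(),
                            shape = c(16, 16, 16), seed = 1, mask = NULL,
                            pop_mean_amplitude = 3, interval_years = 2,
                            keep_truth = TRUE) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  template <- image_volume(array(0, shape), mask)
  msk <- template$mask
  subj_sd <- sqrt(1 + params$sigma^2)
  pop <- make_smooth_signal(shape, params$smoothness_fwhm,
                            seed = subject_seed(seed, 0, 9L), mask = msk)
  pop <- with_mask_values(pop,
                          mask_values(pop) * pop_mean_amplitude * subj_sd)
  pairs <- vector("list", n_subjects)
  truth <- if (keep_truth) vector("list", n_subjects) else NULL
  for (s in seq_len(n_subjects)) {
    a0 <- make_smooth_signal(shape, params$smoothness_fwhm,
                             seed = subject_seed(seed, s, 1L), mask = msk)
    chg <- apply_change(a0, params)
    old <- .Random.seed_save()
    set.seed(subject_seed(seed, s, 2L))
    e_a <- array(stats::rnorm(prod(shape), sd = params$sigma), shape)
    e_b <- array(stats::rnorm(prod(shape), sd = params$sigma), shape)
    .Random.seed_restore(old)
    base <- a0$data + e_a + pop$data
    foll <- a0$data + chg$delta$data + e_b + pop$data
    pairs[[s]] <- longitudinal_pair(
      sprintf("sub-%04d", s),
      image_volume(base, msk), image_volume(foll, msk), interval_years)
    if (keep_truth)
      truth[[s]] <- list(a0 = a0$data[msk], delta = chg$delta$data[msk],
                         linear = chg$linear$data[msk],
                         nonlinear = chg$nonlinear$data[msk],
                         e_a = e_a[msk], e_b = e_b[msk])
  }
  structure(
    list(pairs = pairs, truth = truth, params = params, pop_mean = pop,
         mask = msk, shape = shape, seed = seed,
         pop_mean_amplitude = pop_mean_amplitude),
    class = "synthetic_cohort")
}

#' @exportS3Method print synthetic_cohort
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> n =", length(x$pairs), "subjects,",
      paste(x$shape, collapse = "x"), "grid, sigma =", x$params$sigma,
      ", seed =", x$seed, "\n")
  invisible(x)
}

## Subject-level summaries of the ground-truth change, used as building
## blocks for synthetic phenotypes.
cohort_truth_summaries <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$truth))
    stop("cohort was generated with keep_truth = FALSE")
  n <- length(cohort$pairs)
  delta_mat <- do.call(rbind, lapply(cohort$truth, `[[`, "delta"))
  rtd <- residualise_cohort(cohort)
  rtd_mat <- do.call(rbind, lapply(rtd, function(r)
    mask_values(r$res_b_given_a)))
  pc1 <- function(m) {
    mc <- sweep(m, 2, colMeans(m))
    if (all(mc == 0)) return(rep(0, nrow(m)))
    sv <- svd(mc, nu = 1, nv = 0)
    as.numeric(sv$u[, 1] * sv$d[1])
  }
  list(delta_mean = rowMeans(delta_mat),
       delta_sd = apply(delta_mat, 1, stats::sd),
       delta_pc1 = pc1(delta_mat),
       rtd_pc1 = pc1(rtd_mat),
       delta_mat = delta_mat)
}

#' Generate a synthetic non-imaging phenotype table
#'
#' Builds a subjects-by-phenotypes table in which each phenotype is a stated
#' linear combination of subject-level ground-truth change summaries plus
#' Gaussian noise, so that downstream phenotype-prediction machinery can be
#' validated against planted associations.
#'
#' Available summary components: `delta_mean` (in-mask mean of the true
#' change), `delta_sd` (its spatial SD), `delta_pc1` (subject score on the
#' leading principal component of the true change maps), `rtd_pc1` (leading
#' principal component of the residual temporal difference maps), and
#' `delta_region_mean` (mean of the true change inside a region supplied in
#' the recipe as `region`).
#'
#' @param cohort a [generate_cohort()] result with truth retained.
#' @param recipes named list; each element is
#'   `list(weights = c(component = w, ...), noise_sd = s, region = <array>)`
#'   (`region` only when `delta_region_mean` is used). Empty/zero weights
#'   give a pure-noise phenotype.
#' @param seed integer seed for the phenotype noise.
#' @param missing_frac fraction of entries set missing at random (default 0).
#' @return An object of class `nidp_table`: list with `table` (data.frame,
#'   first column `subject_id`), `recipes`, `seed`.
#' @export
generate_nidp_table <- function(cohort, recipes, seed = 1,
                                missing_frac = 0) {
  summ <- cohort_truth_summaries(cohort)
  n <- length(cohort$pairs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cols <- list(subject_id = vapply(cohort$pairs, `[[`, "", "subject_id"))
  for (nm in names(recipes)) {
    rc <- recipes[[nm]]
    y <- rep(0, n)
    w <- rc$weights
    for (comp in names(w)) {
      if (w[[comp]] == 0) next
      val <- if (comp == "delta_region_mean") {
        if (is.null(rc$region))
          stop("configuration error: recipe '", nm,
               "' uses delta_region_mean but supplies no region")
        reg <- as.array(rc$region)[cohort$mask]
        as.numeric(summ$delta_mat %*% reg) / sum(reg)
      } else if (comp %in% names(summ)) {
        summ[[comp]]
      } else {
        stop("configuration error: unknown truth component '", comp, "'")
      }
      y <- y + w[[comp]] * val
    }
    noise_sd <- if (is.null(rc$noise_sd)) 0 else rc$noise_sd
    y <- y + stats::rnorm(n, sd = noise_sd)
    if (missing_frac > 0)
      y[stats::runif(n) < missing_frac] <- NA
    if (stats::sd(y, na.rm = TRUE) == 0 && noise_sd == 0 &&
        all(unlist(rc$weights) == 0))
      y <- y + stats::rnorm(n, sd = 1)  # avoid a constant column
    cols[[nm]] <- y
  }
  structure(list(table = as.data.frame(cols, stringsAsFactors = FALSE),
                 recipes = recipes, seed = seed),
            class = "nidp_table")
}

#' Train/validation/test split
#'
#' Random split of subject indices, defaulting to the 2500/200/852
#' proportions of a biobank-scale protocol, scaled to the cohort size.
#'
#' @param n number of subjects.
#' @param fractions length-3 non-negative weights for train/validation/test.
#' @param seed integer seed.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
split_cohort <- function(n, fractions = c(2500, 200, 852), seed = 1) {
  fractions <- fractions / sum(fractions)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- max(1L, round(n * fractions[1]))
  n_val <- max(1L, round(n * fractions[2]))
  n_train <- min(n_train, n - 2L)
  list(train = sort(idx[seq_len(n_train)]),
       val = sort(idx[n_train + seq_len(min(n_val, n - n_train - 1L))]),
       test = sort(idx[(n_train + min(n_val, n - n_train - 1L) + 1L):n]))
}

#' Write a cohort to disk as a fixture dataset
#'
#' Emits per-subject baseline/follow-up NIfTI files, the mask, a TSV subject
#' manifest (columns `subject_id`, `modality`, `timepoint`, `path`), an
#' optional phenotype TSV, and a JSON sidecar recording the generative
#' parameters and seed.
#'
#' @param cohort a [generate_cohort()] result.
#' @param path output directory (created if needed).
#' @param nidp optional [generate_nidp_table()] result.
#' @param modality modality label used in the manifest.
#' @return Invisibly, the manifest data.frame.
#' @export
write_fixture_dataset <- function(cohort, path, nidp = NULL,
                                  modality = "synthetic") {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  mask_vol <- image_volume(array(as.numeric(cohort$mask), cohort$shape))
  save_volume(mask_vol, file.path(path, "mask.nii.gz"))
  save_volume(cohort$pop_mean, file.path(path, "population_mean.nii.gz"))
  rows <- list()
  for (p in cohort$pairs) {
    for (tp in c("baseline", "followup")) {
      fn <- sprintf("%s_%s.nii.gz", p$subject_id, tp)
      save_volume(p[[tp]], file.path(path, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = p$subject_id, modality = modality, timepoint = tp,
        path = fn, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(path, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(nidp))
    utils::write.table(nidp$table, file.path(path, "nidp.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(
    seed = cohort$seed, n_subjects = length(cohort$pairs),
    shape = cohort$shape, sigma = cohort$params$sigma,
    smoothness_fwhm = cohort$params$smoothness_fwhm,
    w_spec = cohort$params$w_spec[names(cohort$params$w_spec) != "gain"],
    f_type = cohort$params$f_spec$type,
    pop_mean_amplitude = cohort$pop_mean_amplitude)
  jsonlite::write_json(sidecar, file.path(path, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
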