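## Small in-code fixtures shared across the suite. Everything is generated
## programmatically under fixed seeds; nothing is read from disk.

`%||%` <- function(a, b) if (is.null(a)) b else a

## A random in-mask volume on a small grid.
rand_volume <- function(n_side = 8, seed = 1, mask = NULL) {
  set.seed(seed)
  image_volume(array(rnorm(n_side^3), rep(n_side, 3)), mask)
}

## A pair of random volumes sharing a grid, as a longitudinal pair.
rand_pair <- function(n_side = 8, seed = 1, subject_id = "s1") {
  set.seed(seed)
  a <- array(rnorm(n_side^3), rep(n_side, 3))
  b <- array(rnorm(n_side^3), rep(n_side, 3))
  longitudinal_pair(subject_id, image_volume(a), image_volume(b))
}

## Quick small cohort for network tests.
quick_cohort <- function(n = 8, sigma = 0.5, w = -0.3, shape = 8, seed = 1,
                         f_spec = f_none()) {
  generate_cohort(n, generative_params(sigma = sigma, w_spec = w_scalar(w),
                                       f_spec = f_spec),
                  shape = shape, seed = seed)
}

## Independent normal-equations least-squares slope (with optional centring),
## used as the regression oracle.
ls_slope_oracle <- function(y, x, center = FALSE) {
  if (center) {
    X <- cbind(1, x)
    solve(t(X) %*% X, t(X) %*% y)[2]
  } else {
    sum(x * y) / sum(x * x)
  }
}
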