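test_that("null change correlation has the correct closed form and limits", {
  ## direct covariance algebra: r = -sigma^2 / sqrt(2 sigma^2 (1 + sigma^2))
  for (sg in c(0.3, 0.5, 1, 2, 7)) {
    expect_equal(null_change_correlation(sg),
                 -sg^2 / sqrt(2 * sg^2 * (1 + sg^2)), tolerance = 1e-12)
  }
  expect_equal(null_change_correlation(0), 0)
  expect_equal(null_change_correlation(1), -0.5)
  ## bounded in (-1/sqrt(2), 0) and monotone decreasing in sigma
  grid <- seq(0.05, 50, length.out = 200)
  vals <- null_change_correlation(grid)
  expect_true(all(vals < 0 & vals > -1 / sqrt(2)))
  expect_true(all(diff(vals) < 0))
  expect_error(null_change_correlation(-1), "non-negative")
})

test_that("expected change correlation matches Monte-Carlo and reduces to the null", {
  p1 <- generative_params(sigma = 1)
  ## with no change terms the general form reduces to the null case
  for (sg in c(0.5, 1, 3)) {
    p <- generative_params(sigma = sg)
    expect_equal(expected_change_correlation(p, 0, 0, 0),
                 null_change_correlation(sg), tolerance = 1e-12)
  }
  ## Monte-Carlo oracle at 1e6 voxels, W = -0.2 I
  set.seed(101)
  a0 <- rnorm(1e6); ea <- rnorm(1e6); eb <- rnorm(1e6)
  emp <- cor(-0.2 * a0 + eb - ea, a0 + ea)
  th <- expected_change_correlation(generative_params(sigma = 1, w_spec = w_scalar(-0.2)),
                                    cov_wa0_a0 = -0.2, var_wa0 = 0.04)
  expect_lt(abs(emp - th), 0.005)
  ## shrinking change pushes the correlation below the null
  expect_lt(th, null_change_correlation(1))
  expect_error(expected_change_correlation(p1, 0, -1, 0), ">= 0")
})

test_that("expected follow-up correlation matches Monte-Carlo and the reproducibility limit", {
  ## Delta = 0: reduces to data reproducibility 1/(1+sigma^2)
  expect_equal(expected_followup_correlation(generative_params(sigma = 1)), 0.5)
  expect_equal(expected_followup_correlation(generative_params(sigma = 1e-8)),
               1, tolerance = 1e-6)
  ## Monte-Carlo oracle: W = -0.3 I plus a centred-square nonlinearity of
  ## variance 0.1
  set.seed(102)
  a0 <- rnorm(1e6); ea <- rnorm(1e6); eb <- rnorm(1e6)
  fa <- sqrt(0.1 / 2) * (a0^2 - 1)  # var = 0.1, uncorrelated with a0
  emp <- cor(0.7 * a0 + fa + eb, a0 + ea)
  th <- expected_followup_correlation(
    generative_params(sigma = 1, w_spec = w_scalar(-0.3)),
    cov_ipw = 0.7, var_ipw = 0.49, var_f = 0.1)
  expect_lt(abs(emp - th), 0.005)
})

test_that("sigma from reproducibility inverts the no-change follow-up correlation", {
  expect_equal(sigma_from_reproducibility(0.5), 1)
  expect_lt(sigma_from_reproducibility(0.999), 0.04)
  for (rho in seq(0.1, 0.9, by = 0.1)) {
    sg <- sigma_from_reproducibility(rho)
    expect_equal(expected_followup_correlation(generative_params(sigma = sg)),
                 rho, tolerance = 1e-12)
  }
  expect_error(sigma_from_reproducibility(0), "between 0 and 1")
  expect_error(sigma_from_reproducibility(1.2), "between 0 and 1")
})

test_that("change existence test flags gaps against both references", {
  ## follow-up correlation below the measured reproducibility flags change
  v1 <- change_existence_test(observed_r_ab = 0.23, reproducibility = 0.34,
                              observed_r_diff_a = -0.5, sigma = 1)
  expect_true(v1$flag_followup)
  expect_equal(v1$gap_followup, -0.11)
  ## change correlation away from the null flags change; at sigma = 0.9611
  ## the null is about -0.49, so an observed -0.63 leaves a gap near -0.14
  v2 <- change_existence_test(observed_r_ab = 0.5, reproducibility = 0.5,
                              observed_r_diff_a = -0.63, sigma = 0.9611)
  expect_true(v2$flag_diff)
  expect_equal(v2$null_diff, -0.49, tolerance = 0.001)
  expect_equal(v2$gap_diff, -0.14, tolerance = 0.001)
  ## observations exactly at their references: no flags
  v3 <- change_existence_test(observed_r_ab = 0.5, reproducibility = 0.5,
                              observed_r_diff_a = null_change_correlation(1),
                              sigma = 1)
  expect_false(v3$flag_followup)
  expect_false(v3$flag_diff)
  expect_false(v3$change_evidence)
  ## bootstrap intervals are reproducible and bracket the point gap
  set.seed(9)
  rs <- rnorm(40, mean = 0.3, sd = 0.05)
  v4 <- change_existence_test(mean(rs), 0.34, -0.5, 1,
                              r_ab_subjects = rs, seed = 11)
  v5 <- change_existence_test(mean(rs), 0.34, -0.5, 1,
                              r_ab_subjects = rs, seed = 11)
  expect_identical(v4$ci_followup, v5$ci_followup)
  expect_true(v4$ci_followup[1] <= v4$gap_followup &&
                v4$gap_followup <= v4$ci_followup[2])
})

test_that("residualise_pair removes the population mean with one baseline-fitted slope", {
  pm <- rand_volume(8, seed = 5)
  ## subject equal to the population mean: zero residual, beta 1
  pair1 <- longitudinal_pair("s1", pm, rand_volume(8, seed = 6))
  r1 <- residualise_pair(pair1, pm)
  expect_equal(r1$beta_pop, 1)
  expect_equal(max(abs(mask_values(r1$res_a))), 0)
  ## baseline orthogonal to the population mean: beta 0, residual = A
  pv <- mask_values(pm)
  a_orth <- pv * 0; a_orth[1] <- pv[2]; a_orth[2] <- -pv[1]
  vol_orth <- with_mask_values(pm, a_orth)
  r2 <- residualise_pair(longitudinal_pair("s2", vol_orth, vol_orth), pm)
  expect_equal(r2$beta_pop, 0, tolerance = 1e-14)
  expect_equal(mask_values(r2$res_a), a_orth)
  ## random 200-voxel fixture against the normal-equations oracle
  set.seed(7)
  mask <- array(FALSE, c(8, 8, 8)); mask[seq_len(200)] <- TRUE
  A <- array(rnorm(512), c(8, 8, 8)); B <- array(rnorm(512), c(8, 8, 8))
  P <- array(rnorm(512), c(8, 8, 8))
  pairx <- longitudinal_pair("s3", image_volume(A, mask),
                             image_volume(B, mask))
  pmx <- image_volume(P, mask)
  rx <- residualise_pair(pairx, pmx)
  beta_oracle <- ls_slope_oracle(A[mask], P[mask])
  expect_equal(rx$beta_pop, beta_oracle, tolerance = 1e-10)
  expect_equal(mask_values(rx$res_a), A[mask] - beta_oracle * P[mask],
               tolerance = 1e-10)
  ## the SAME slope is applied to the follow-up
  expect_equal(mask_values(rx$res_b), B[mask] - beta_oracle * P[mask],
               tolerance = 1e-10)
  ## reconstruction: pop_mean * beta + ResA reproduces A bit-consistently
  rec <- mask_values(pmx) * rx$beta_pop + mask_values(rx$res_a)
  expect_equal(rec, A[mask], tolerance = 1e-12)
  ## contract violations
  expect_error(residualise_pair(pairx, rand_volume(8, seed = 1)), "mismatch")
  pm0 <- image_volume(array(0, c(8, 8, 8)) + 2, mask)  # constant mean
  expect_error(residualise_pair(pairx, pm0), "singular")
})

test_that("residual temporal difference is exactly orthogonal to ResA", {
  ## exact linear dependence: ResB = 3 ResA -> zero residual, beta 3
  pm <- rand_volume(8, seed = 20)
  a <- rand_volume(8, seed = 21)
  pair <- longitudinal_pair("s1", a, with_mask_values(a, 3 * mask_values(a)))
  r <- residualise_pair(pair, pm)
  ## overwrite with exact multiples to isolate the within-subject step
  r$res_a <- a
  r$res_b <- with_mask_values(a, 3 * mask_values(a))
  r <- residual_temporal_difference(r)
  expect_equal(r$beta_within, 3, tolerance = 1e-12)
  expect_lt(max(abs(mask_values(r$res_b_given_a))), 1e-12)
  ## random 500-voxel pair: beta matches the centred oracle and the
  ## residual is Pearson-orthogonal to ResA
  set.seed(22)
  mask <- array(FALSE, c(8, 8, 8)); mask[seq_len(500)] <- TRUE
  ra <- array(rnorm(512), c(8, 8, 8)); rb <- array(rnorm(512), c(8, 8, 8))
  r2 <- structure(list(subject_id = "s2",
                       res_a = image_volume(ra, mask),
                       res_b = image_volume(rb, mask),
                       beta_pop = 0), class = "residual_set")
  r2 <- residual_temporal_difference(r2)
  expect_equal(r2$beta_within, ls_slope_oracle(rb[mask], ra[mask],
                                               center = TRUE),
               tolerance = 1e-10)
  expect_lt(abs(cor(mask_values(r2$res_b_given_a), ra[mask])), 1e-10)
  ## uncorrelated inputs: beta near zero, residual close to centred ResB
  expect_lt(abs(r2$beta_within), 0.1)
  ## degenerate input
  r3 <- r2; r3$res_a <- with_mask_values(r2$res_a, rep(1, 500))
  expect_error(residual_temporal_difference(r3), "singular")
})

test_that("orthogonality holds on repeated random fixtures", {
  set.seed(33)
  for (k in 1:25) {
    v <- 50 + k * 7
    mask <- array(FALSE, c(8, 8, 8)); mask[seq_len(v)] <- TRUE
    r <- structure(list(
      subject_id = "s", beta_pop = 0,
      res_a = image_volume(array(rnorm(512), c(8, 8, 8)), mask),
      res_b = image_volume(array(rnorm(512), c(8, 8, 8)), mask)),
      class = "residual_set")
    r <- residual_temporal_difference(r)
    expect_lt(abs(cor(mask_values(r$res_b_given_a),
                      mask_values(r$res_a))), 1e-10)
  }
})

test_that("population mean and cohort residualisation are consistent", {
  co <- quick_cohort(n = 6, sigma = 1, w = 0, shape = 8, seed = 44)
  res <- residualise_cohort(co)
  expect_length(res, 6)
  ## the residual sets carry both betas and the rtd map
  expect_true(all(vapply(res, function(r) !is.null(r$beta_within),
                         logical(1))))
  ## residualising against the cohort's own baseline mean
  pm <- population_mean(co$pairs)
  res2 <- residualise_cohort(co$pairs, pm)
  expect_equal(mask_values(res2[[1]]$res_a),
               mask_values(residualise_pair(co$pairs[[1]], pm)$res_a))
})
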