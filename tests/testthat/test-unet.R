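test_that("configuration invariants are enforced", {
  expect_error(unet_config(input_shape = c(12, 12, 12), n_levels = 3),
               "divisible")
  expect_error(unet_config(base_channels = 0), "positive")
  cfg <- unet_config(input_shape = c(16, 8, 8), n_levels = 1)
  expect_equal(cfg$input_shape, c(16L, 8L, 8L))
})

test_that("forward pass preserves spatial shape and channel contract", {
  for (shape in list(c(16, 16, 16), c(16, 8, 8))) {
    cfg <- unet_config(input_shape = shape, n_levels = 2, in_channels = 1,
                       base_channels = 2)
    m <- build_model(cfg, seed = 1)
    X <- matrix(rnorm(prod(shape)), ncol = 1)
    out <- longipred:::unet_forward(m, X, B = 1, training = FALSE, keep_cache = FALSE)$out
    expect_equal(dim(out), c(prod(shape), 1L))
  }
  ## K = 2 input channels consumed; channel mismatch rejected at predict
  cfg2 <- unet_config(input_shape = c(8, 8, 8), n_levels = 2,
                      in_channels = 2, base_channels = 2)
  m2 <- build_model(cfg2, seed = 2, mask = array(TRUE, c(8, 8, 8)))
  expect_error(predict_volume(m2, rand_volume(8, 1)), "channel mismatch")
})

test_that("parameter count matches layer-by-layer arithmetic", {
  cfg <- unet_config(input_shape = c(16, 16, 16), n_levels = 2,
                     in_channels = 1, base_channels = 4)
  m <- build_model(cfg, seed = 1, mask = array(TRUE, c(16, 16, 16)))
  ## independent hand count: conv W + b, bn gamma + beta per block,
  ## upconv, final 1x1x1, per-voxel loss scales (no modality weights, K=1)
  conv <- function(cin, cout) 27 * cin * cout + cout
  bn <- function(ch) 2 * ch
  expected <- conv(1, 4) + bn(4) + conv(4, 4) + bn(4) +      # encoder L1
    conv(4, 8) + bn(8) + conv(8, 8) + bn(8) +                # encoder L2
    conv(8, 4) +                                             # upconv
    conv(8, 4) + bn(4) + conv(4, 4) + bn(4) +                # decoder L1
    (4 * 1 + 1) +                                            # final 1x1x1
    16^3                                                     # voxel sigmas
  expect_equal(model_parameter_count(m), expected)
})

test_that("min-max normalisation maps the mask range onto [0, 1]", {
  v <- rand_volume(8, seed = 3)
  x <- mask_values(v)
  nm <- minmax_normalise(v)
  expect_equal(range(mask_values(nm)), c(0, 1))
  ## affine: in-mask range [-2, 6] maps through (x + 2) / 8
  v2 <- with_mask_values(v, c(-2, 6, runif(length(x) - 2, -2, 6)))
  expect_equal(mask_values(minmax_normalise(v2)),
               (mask_values(v2) + 2) / 8, tolerance = 1e-12)
  ## idempotent up to float error
  expect_equal(mask_values(minmax_normalise(nm)), mask_values(nm),
               tolerance = 1e-12)
  expect_error(minmax_normalise(with_mask_values(v, rep(1, length(x)))),
               "degenerate")
})

test_that("uncertainty-weighted loss has the stated values and exact gradients", {
  ## zero-error loss with unit scales is v log 2
  v <- 37
  expect_equal(uncertainty_weighted_loss(rep(1, v), rep(1, v), rep(1, v)),
               v * log(2))
  ## single voxel, squared error 2, sigma 1 -> 1 + log 2
  expect_equal(uncertainty_weighted_loss(sqrt(2), 0, 1), 1 + log(2))
  ## frozen sigma = 1 reduces to masked SSE/2 plus the constant
  set.seed(4)
  p <- rnorm(50); t <- rnorm(50)
  expect_equal(uncertainty_weighted_loss(p, t, rep(1, 50)),
               sum((p - t)^2) / 2 + 50 * log(2), tolerance = 1e-12)
  ## analytic gradients match central finite differences to 1e-5
  sg <- exp(rnorm(50) * 0.3)
  g <- uncertainty_weighted_loss(p, t, sg, gradient = TRUE)
  eps <- 1e-6
  for (i in c(1, 17, 50)) {
    pp <- p; pp[i] <- p[i] + eps
    pm <- p; pm[i] <- p[i] - eps
    num <- (uncertainty_weighted_loss(pp, t, sg) -
              uncertainty_weighted_loss(pm, t, sg)) / (2 * eps)
    expect_equal(g$dpred[i], num, tolerance = 1e-5)
    sp <- sg; sp[i] <- sg[i] + eps
    sm <- sg; sm[i] <- sg[i] - eps
    num_s <- (uncertainty_weighted_loss(p, t, sp) -
                uncertainty_weighted_loss(p, t, sm)) / (2 * eps)
    expect_equal(g$dsigma[i], num_s, tolerance = 1e-5)
  }
  expect_error(uncertainty_weighted_loss(1, 1, -0.1), "positive")
})

test_that("network gradients match finite differences in both modes", {
  cfg <- unet_config(input_shape = c(8, 8, 8), n_levels = 2,
                     in_channels = 2, base_channels = 2,
                     modality_weighting = TRUE)
  m <- build_model(cfg, seed = 5, mask = array(TRUE, c(8, 8, 8)))
  set.seed(6)
  B <- 2
  X <- matrix(rnorm(512 * B * 2), 512 * B, 2)
  loss_of <- function(mp, Xp, training) {
    o <- longipred:::unet_forward(mp, Xp, B, training = training, keep_cache = FALSE)$out
    sum(o^2) / 2
  }
  for (training in c(FALSE, TRUE)) {
    fw <- longipred:::unet_forward(m, X, B, training = training, keep_cache = TRUE)
    bw <- longipred:::unet_backward(m, fw$cache, fw$out, training = training)
    eps <- 1e-5
    for (nm in names(m$params)) {
      i <- sample(length(m$params[[nm]]), 1)
      mp <- m
      mp$params[[nm]][i] <- m$params[[nm]][i] + eps
      fp <- loss_of(mp, X, training)
      mp$params[[nm]][i] <- m$params[[nm]][i] - eps
      fm <- loss_of(mp, X, training)
      num <- (fp - fm) / (2 * eps)
      expect_equal(bw$grads[[nm]][i], num,
                   tolerance = 1e-4 * max(1, abs(num)),
                   label = sprintf("grad %s (training=%s)", nm, training))
    }
    i <- sample(512 * B, 1)
    Xp <- X; Xp[i, 1] <- X[i, 1] + eps
    fp <- loss_of(m, Xp, training)
    Xp[i, 1] <- X[i, 1] - eps
    fm <- loss_of(m, Xp, training)
    expect_equal(bw$dInput[i, 1], (fp - fm) / (2 * eps),
                 tolerance = 1e-4 * max(1, abs((fp - fm) / (2 * eps))))
  }
})

test_that("training decreases the loss, is deterministic, and keeps scales positive", {
  co <- quick_cohort(n = 8, sigma = 0.5, w = -0.3, shape = 8, seed = 8)
  res <- residualise_cohort(co)
  ds <- prepare_training_data(res, target_mode = "followup")
  cfg <- unet_config(input_shape = c(8, 8, 8), n_levels = 2,
                     base_channels = 2)
  tcfg <- train_config(learning_rate = 0.01, batch_size = 4, epochs = 4,
                       seed = 3)
  m1 <- train_model(build_model(cfg, seed = 1), ds, tcfg,
                    pop_mean = co$pop_mean)
  expect_lt(m1$history$loss[4], m1$history$loss[1])
  ## bitwise-identical history for the same seed
  m2 <- train_model(build_model(cfg, seed = 1), ds, tcfg,
                    pop_mean = co$pop_mean)
  expect_identical(m1$history, m2$history)
  ## distinct objectives: plain MSE history differs
  m3 <- train_model(build_model(cfg, seed = 1), ds,
                    train_config(learning_rate = 0.01, batch_size = 4,
                                 epochs = 4, seed = 3, loss_mode = "mse"),
                    pop_mean = co$pop_mean)
  expect_false(identical(m1$history$loss, m3$history$loss))
  ## positivity of learned scales and deterministic prediction
  expect_true(all(voxel_sigmas(m1) > 0))
  p1 <- predict_volume(m1, res[[1]]$res_a)
  p2 <- predict_volume(m1, res[[1]]$res_a)
  expect_identical(p1$data, p2$data)
  ## reconstruction helper adds the population component back
  rec <- predict_volume(m1, res[[1]]$res_a, reconstruct = TRUE,
                        beta_pop = res[[1]]$beta_pop)
  expect_equal(mask_values(rec),
               mask_values(p1) + res[[1]]$beta_pop * mask_values(co$pop_mean),
               tolerance = 1e-12)
})

test_that("modality weights recover a planted relevant channel", {
  ## channel 1 carries the baseline signal, channel 2 is pure noise
  co <- quick_cohort(n = 16, sigma = 0.2, w = -0.5, shape = 8, seed = 11)
  res <- residualise_cohort(co)
  res_noise <- lapply(seq_along(res), function(s) {
    r <- res[[s]]
    set.seed(100 + s)
    r$res_a <- with_mask_values(r$res_a, rnorm(sum(r$res_a$mask)))
    r
  })
  ds <- prepare_training_data(list(res, res_noise), target_mode = "followup")
  cfg <- unet_config(input_shape = c(8, 8, 8), n_levels = 2,
                     in_channels = 2, base_channels = 2,
                     modality_weighting = TRUE)
  m <- train_model(build_model(cfg, seed = 2), ds,
                   train_config(learning_rate = 0.02, batch_size = 4,
                                epochs = 30, seed = 4))
  w <- modality_weights(m)
  expect_true(all(w > 0))
  expect_gt(w[1], w[2])
})

test_that("model checkpoints round-trip through disk", {
  co <- quick_cohort(n = 4, sigma = 0.5, shape = 8, seed = 12)
  res <- residualise_cohort(co)
  ds <- prepare_training_data(res)
  m <- train_model(build_model(unet_config(input_shape = c(8, 8, 8),
                                           n_levels = 2, base_channels = 2),
                               seed = 1),
                   ds, train_config(epochs = 1, batch_size = 4, seed = 1),
                   pop_mean = co$pop_mean)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m$params, m2$params)
  expect_identical(predict_volume(m, res[[1]]$res_a)$data,
                   predict_volume(m2, res[[1]]$res_a)$data)
})
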