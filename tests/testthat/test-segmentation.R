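# Network construction, training mechanics, classical segmentation and
# Dice evaluation.

test_that("dice matches its definition and is symmetric", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[11:20, 11:20] <- TRUE
  expect_equal(dice(a, b), 0)
  # |A| = |B| = 100 with overlap 50
  c1 <- matrix(FALSE, 20, 20); c1[1:10, 1:10] <- TRUE
  c2 <- matrix(FALSE, 20, 20); c2[6:15, 1:10] <- TRUE
  expect_equal(dice(c1, c2), 0.5)
  expect_equal(dice(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5)), 1)
  expect_error(dice(a, matrix(FALSE, 5, 5)), "shapes differ")
  set.seed(4)
  for (i in 1:10) {
    x <- matrix(runif(100) < 0.4, 10, 10)
    y <- matrix(runif(100) < 0.4, 10, 10)
    d <- dice(x, y)
    expect_identical(d, dice(y, x))
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("the network honors layer count, residual span and seeding", {
  cfg <- seg_model_config()
  m <- build_model(cfg)
  expect_length(m$blocks, 10)                  # 20 layers, span 2
  expect_identical(cfg$n_conv_layers / cfg$residual_span, 10)
  expect_gt(m$n_params, 0)
  # identical seeds give identical initializations
  m2 <- build_model(cfg)
  expect_identical(m$blocks, m2$blocks)
  expect_identical(m$head, m2$head)
  m3 <- build_model(seg_model_config(seed = 43))
  expect_false(identical(m$blocks[[1]]$W1, m3$blocks[[1]]$W1))
  # config validation
  expect_error(seg_model_config(n_conv_layers = 19), "even")
  expect_error(seg_model_config(dilations = c(1, 2)), "length")
})

test_that("a forward pass on a zero image yields finite probabilities in [0,1]", {
  m <- build_model(seg_model_config())
  p <- projection2d(matrix(0, 64, 64), "AP", c(0.5, 1),
                    normalization = list(method = "minmax", min = 0, max = 1))
  prob <- predict_prob(m, p)
  expect_true(all(is.finite(prob)))
  expect_true(all(prob >= 0 & prob <= 1))
})

test_that("analytic gradients agree with numeric differentiation", {
  ns <- asNamespace("scoutrange")
  cfg <- seg_model_config(n_conv_layers = 4, residual_span = 2,
                          dilations = c(1, 2), channels = c(3, 4),
                          input_size = 32, seed = 7)
  model <- build_model(cfg)
  set.seed(1)
  S <- 32; B <- 2
  X <- matrix(runif(B * S * S), ncol = 1)
  G <- as.numeric(runif(B * S * S) > 0.7)
  fwd <- ns$.net_forward(model, X, B, keep_cache = TRUE)
  ld <- ns$.loss_and_dlogit(fwd$prob, G, B, "sum")
  gl <- ns$.grad_list(ns$.net_backward(model, fwd$cache, ld$dlogit, B))
  ps <- ns$.param_list(model)
  loss_at <- function(ps2) {
    m2 <- ns$.set_params(model, ps2)
    ns$.loss_and_dlogit(ns$.net_forward(m2, X, B)$prob, G, B, "sum")$loss
  }
  eps <- 1e-5
  set.seed(2)
  for (nm in names(ps)) {
    for (j in sample(length(ps[[nm]]), min(2, length(ps[[nm]])))) {
      p1 <- ps; p1[[nm]][j] <- p1[[nm]][j] + eps
      p2 <- ps; p2[[nm]][j] <- p2[[nm]][j] - eps
      num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
      ana <- gl[[nm]][j]
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-5)
    }
  }
})

test_that("raising the probability threshold never grows the predicted mask", {
  m <- build_model(seg_model_config(seed = 9))
  set.seed(10)
  p <- projection2d(matrix(runif(64 * 64), 64, 64), "AP", c(0.5, 1),
                    normalization = list(method = "minmax", min = 0, max = 1))
  areas <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th)
    sum(predict_mask(m, p, th)$pixels), numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("training for zero epochs leaves the model untouched", {
  ds <- make_projection_dataset(20, size = 64, seed = 5)
  m <- build_model(seg_model_config(epochs = 0))
  res <- train(m, ds)
  expect_identical(res$model$blocks, m$blocks)
  expect_identical(res$model$head, m$head)
  expect_length(res$report$epoch_loss, 0)
  expect_true(is.finite(res$report$final_val_dice))
})

test_that("training is reproducible for a fixed seed", {
  ds <- make_projection_dataset(24, size = 64, seed = 6)
  cfg <- seg_model_config(channels = rep(4, 10), epochs = 2, seed = 17)
  r1 <- train(build_model(cfg), ds)
  r2 <- train(build_model(cfg), ds)
  expect_identical(r1$report$epoch_loss, r2$report$epoch_loss)
  expect_identical(r1$model$head$W, r2$model$head$W)
})

test_that("classical segmentation is accurate on clean phantoms and robust to noise", {
  ph <- generate_phantom(quiet_config(), seed = 31)
  noisy <- generate_phantom(phantom_config(noise_sd = 20, pathology_fraction = 0),
                            seed = 31)
  for (v in c("AP", "LAT")) {
    pm <- normalize_resize(project_volume(ph$volume, v),
                           project_mask(ph$mask, v), 256)
    d_clean <- dice(classical_segment(pm$projection), pm$mask)
    expect_gte(d_clean, 0.95)
    pn <- normalize_resize(project_volume(noisy$volume, v),
                           project_mask(noisy$mask, v), 256)
    d_noisy <- dice(classical_segment(pn$projection), pn$mask)
    expect_lt(d_clean - d_noisy, 0.05)
  }
  expect_error(
    classical_segment(projection2d(matrix(1, 64, 64), "AP", c(0.5, 1),
                                   normalization = list(method = "minmax"))),
    "no body")
})

test_that("the trained network generalizes and agrees with the classical oracle", {
  fit <- get_training_fixture()
  ds <- fit$dataset
  te <- fit$report$test_indices
  d <- vapply(te, function(i)
    dice(predict_mask(fit$model, ds[[i]]$image), ds[[i]]$mask), numeric(1))
  expect_gte(mean(d), 0.90)

  # on a clean phantom the learned and classical range limits are close
  ph <- generate_phantom(quiet_config(), seed = 77)
  pm <- normalize_resize(project_volume(ph$volume, "AP"),
                         project_mask(ph$mask, "AP"), 64)
  m_net <- postprocess_mask(predict_mask(fit$model, pm$projection), 10)
  m_cls <- postprocess_mask(classical_segment(pm$projection), 10)
  rows_net <- range(which(rowSums(m_net$pixels) > 0))
  rows_cls <- range(which(rowSums(m_cls$pixels) > 0))
  expect_lte(max(abs(rows_net - rows_cls)), 2)
})

test_that("fine-tuning transfers the projection model to magnified scout views", {
  fit <- get_training_fixture()
  scout <- make_projection_dataset(50, size = 64, seed = 23, scout = TRUE)
  cfg <- seg_model_config(epochs = 5, lr = 5e-4, seed = 29)
  ft <- train(fit$model, scout, cfg)
  te <- ft$report$test_indices
  d <- vapply(te, function(i)
    dice(predict_mask(ft$model, scout[[i]]$image), scout[[i]]$mask), numeric(1))
  expect_gte(mean(d), 0.85)
})
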