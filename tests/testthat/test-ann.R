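probe_grid <- function(n = 5) {
  tidyr::expand_grid(aed_w_per_l = seq(41.1, 111.2, length.out = n),
                     temp_c = seq(20, 40, length.out = n),
                     time_min = seq(0, 60, length.out = n))
}

test_that("the forward pass matches hand evaluation", {
  zero <- ann_model(matrix(0, 4, 3), rep(0, 4), rep(0, 4), 0)
  out <- ann_predict(tibble::tibble(aed_w_per_l = 50, temp_c = 30,
                                    time_min = 10), zero)
  expect_equal(out$yield_pred, 0)

  one <- ann_model(matrix(c(1, 0, 0), 1, 3), 0, 1, 0)
  out1 <- ann_predict(tibble::tibble(aed_w_per_l = 1, temp_c = -4,
                                     time_min = 99), one)
  expect_equal(out1$yield_pred, tanh(1), tolerance = 1e-12)

  # with scaling: x maps to [-1, 1] before the hidden layer
  scaled <- ann_model(matrix(c(1, 0, 0), 1, 3), 0, 1, 0,
                      input_scaling = list(c(0, 2), c(0, 1), c(0, 1)),
                      output_scaling = c(0, 2))
  out2 <- ann_predict(tibble::tibble(aed_w_per_l = 2, temp_c = 0.5,
                                     time_min = 0.5), scaled)
  expect_equal(out2$yield_pred, (tanh(1) + 1) / 2 * 2, tolerance = 1e-12)
})

test_that("model construction enforces dimensional consistency", {
  expect_error(ann_model(matrix(0, 2, 2), rep(0, 2), rep(0, 2), 0),
               class = "uatpe_shape_error")
  expect_error(ann_model(matrix(0, 2, 3), rep(0, 3), rep(0, 2), 0),
               class = "uatpe_shape_error")
  expect_error(ann_model(matrix(0, 2, 3), rep(0, 2), rep(0, 2), 0,
                         input_scaling = list(c(1, 0), c(0, 1), c(0, 1))),
               class = "uatpe_domain_error")
  expect_error(ann_model(matrix(0, 2, 3), rep(0, 2), rep(0, 2), 0,
                         hidden_transfer = "relu"),
               class = "uatpe_domain_error")
})

test_that("min-max scaling round-trips to numerical identity", {
  withr::with_seed(51, {
    x <- runif(50, -3, 17)
    s <- uatpe:::scale_fit(x)
    expect_equal(uatpe:::scale_invert(uatpe:::scale_apply(x, s), s), x,
                 tolerance = 1e-12)
    expect_equal(range(uatpe:::scale_apply(x, s)), c(-1, 1))
  })
})

test_that("the published-weight fixture loads with the expected shape and predicts", {
  m <- reference_ann_model()
  expect_equal(dim(m$input_weights), c(8L, 3L))
  expect_length(m$hidden_bias, 8)
  expect_length(m$layer_weights, 8)
  expect_equal(m$output_bias, -1.0773)
  expect_equal(m$hidden_transfer, "tansig")
  out <- ann_predict(probe_grid(3), m)
  expect_true(all(is.finite(out$yield_pred)))
})

test_that("training on the noiseless factorial grid reaches R2 >= 0.99 and is deterministic", {
  kin <- gen_kinetics_grid(synth_config(seed = 7))
  fit <- ann_train(kin, n_hidden = 8, seed = 7)
  overall <- fit$metrics[fit$metrics$split == "overall", ]
  expect_gte(overall$r_squared, 0.99)
  fit2 <- ann_train(kin, n_hidden = 8, seed = 7)
  expect_identical(fit$model$input_weights, fit2$model$input_weights)
  expect_identical(fit$model$layer_weights, fit2$model$layer_weights)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_equal(glance(fit)$n_hidden, 8)
})

test_that("a constant-yield dataset is flagged and predicted as the constant", {
  const <- probe_grid(4)
  const$yield_mg_per_g <- 7.5
  expect_warning(fit <- ann_train(const, n_hidden = 3, seed = 2,
                                  max_iter = 200),
                 "zero variance")
  expect_true(fit$constant_target)
  overall <- fit$metrics[fit$metrics$split == "overall", ]
  expect_true(is.na(overall$r_squared))
  expect_lt(overall$rmse, 1e-3)
})

test_that("training recovers the function of a frozen random network on held-out points", {
  withr::with_seed(53, {
    truth <- ann_model(matrix(rnorm(24, 0, 0.8), 8, 3), rnorm(8, 0, 0.5),
                       rnorm(8, 0, 0.8), 0.3,
                       input_scaling = list(c(41.1, 111.2), c(20, 40),
                                            c(0, 60)))
    train_x <- tibble::tibble(aed_w_per_l = runif(300, 41.1, 111.2),
                              temp_c = runif(300, 20, 40),
                              time_min = runif(300, 0, 60))
    hold_x <- tibble::tibble(aed_w_per_l = runif(80, 41.1, 111.2),
                             temp_c = runif(80, 20, 40),
                             time_min = runif(80, 0, 60))
  })
  train <- ann_predict(train_x, truth)
  train$yield_mg_per_g <- train$yield_pred - min(train$yield_pred)
  fit <- ann_train(train[, c(ann_inputs <- c("aed_w_per_l", "temp_c",
                                             "time_min"),
                             "yield_mg_per_g")],
                   n_hidden = 8, seed = 4, max_iter = 4000)
  held <- ann_predict(hold_x, fit)
  truth_held <- ann_predict(hold_x, truth)
  truth_held$y <- truth_held$yield_pred - min(train$yield_pred)
  m <- fit_metrics(truth_held$y, held$yield_pred)
  expect_gte(m$r_squared, 0.999)
})

test_that("predictions are continuous with bounded slope on a probe grid", {
  m <- reference_ann_model()
  base <- tibble::tibble(aed_w_per_l = 70, temp_c = 30, time_min = 30)
  eps <- 1e-4
  for (col in c("aed_w_per_l", "temp_c", "time_min")) {
    lo <- hi <- base
    hi[[col]] <- hi[[col]] + eps
    slope <- abs(ann_predict(hi, m)$yield_pred -
                   ann_predict(lo, m)$yield_pred) / eps
    # |d tanh| <= 1 bounds the network slope by sum(|LW| * |IW|) / range
    expect_lt(slope, 10)
  }
})

test_that("hidden-size selection scans candidates and honours ties and failures", {
  kin <- gen_kinetics_grid(synth_config(seed = 7,
                                        aed_levels = c(41.1, 96.1),
                                        temperatures = c(20, 40)))
  # 36 rows is deliberately sparse for 5 hidden units; the sample-size
  # advisory is part of the contract
  expect_warning(
    sel <- ann_select_hidden(kin, candidate_sizes = c(3, 5), seed = 9,
                             max_iter = 300),
    "recommended")
  expect_true(sel$best_size %in% c(3, 5))
  expect_equal(nrow(sel$results), 2)
  single <- suppressWarnings(
    ann_select_hidden(kin, candidate_sizes = 8, seed = 9, max_iter = 200))
  expect_equal(single$best_size, 8)
  expect_error(ann_select_hidden(kin, candidate_sizes = integer(0)),
               class = "uatpe_domain_error")
})

test_that("model JSON round-trips bit-exactly and names missing fields", {
  kin <- gen_kinetics_grid(synth_config(seed = 7,
                                        aed_levels = c(41.1, 96.1),
                                        temperatures = c(20, 40)))
  fit <- suppressWarnings(ann_train(kin, n_hidden = 4, seed = 3,
                                    max_iter = 300))
  path <- withr::local_tempfile(fileext = ".json")
  ann_save(fit, path)
  loaded <- ann_load(path)
  probe <- probe_grid(4)
  expect_identical(ann_predict(probe, fit$model)$yield_pred,
                   ann_predict(probe, loaded)$yield_pred)

  broken <- jsonlite::read_json(path)
  broken$output_bias <- NULL
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(broken, path2, auto_unbox = TRUE, digits = NA)
  expect_error(ann_load(path2), "output_bias", class = "uatpe_parse_error")
  expect_error(ann_load("no-such-file.json"), class = "uatpe_io_error")
})
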