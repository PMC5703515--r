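make_toy_model <- function(w_in, b_h, w_out, b_out, d, h,
                           center = rep(0, d), scale = rep(1, d)) {
  structure(list(d = d, n_hidden = h, nu = 0, g_t = "tanh",
                 w_in = matrix(w_in, d, h), b_h = rep(b_h, length.out = h),
                 w_out = rep(w_out, length.out = h),
                 b_out = b_out, scaler = list(center = center, scale = scale),
                 features = paste0("x", seq_len(d))),
            class = "mlp_model")
}

test_that("forward pass follows the closed form and floors at zero", {
  m0 <- make_toy_model(0, 0, 0, 0, d = 2, h = 3)
  expect_equal(mlp_forward(m0, c(1, 2)), 0)

  m7 <- make_toy_model(rep(0.3, 6), rep(0.1, 3), rep(0, 3), 7, d = 2, h = 3)
  expect_equal(mlp_forward(m7, c(-4, 9)), 7)
  expect_equal(mlp_forward(m7, c(100, -100)), 7)

  # 1-hidden-unit tanh net: y(0) = b_out; saturates to w_out + b_out
  m1 <- make_toy_model(1, 0, 1, 0.5, d = 1, h = 1)
  expect_equal(mlp_forward(m1, 0), 0.5)
  expect_equal(mlp_forward(m1, 50), 1.5, tolerance = 1e-10)
  expect_equal(mlp_forward(m1, 2), tanh(2) + 0.5)

  # negative raw output is floored: the AHI is a nonnegative rate
  mneg <- make_toy_model(0, 0, 0, -5, d = 1, h = 1)
  expect_equal(mlp_forward(mneg, 3), 0)
  expect_error(mlp_forward(m1, c(1, 2)), "features")
})

test_that("training fits a noiseless linear map and is seed-deterministic", {
  set.seed(30)
  X <- matrix(runif(60, -1, 1), ncol = 1, dimnames = list(NULL, "x1"))
  y <- 2 * X[, 1] + 1
  m <- mlp_train(X, y, n_hidden = 4, nu = 0, seed = 3)
  rmse <- sqrt(mean((mlp_forward(m, X) - pmax(y, 0))^2))
  expect_lt(rmse, 0.1)
  m2 <- mlp_train(X, y, n_hidden = 4, nu = 0, seed = 3)
  expect_identical(m$w_in, m2$w_in)
  expect_identical(m$b_out, m2$b_out)
  m3 <- mlp_train(X, y, n_hidden = 4, nu = 0, seed = 4)
  expect_false(identical(m$w_in, m3$w_in))
})

test_that("heavy weight decay shrinks weights and predictions toward mean(y)", {
  set.seed(31)
  X <- matrix(rnorm(80), ncol = 2, dimnames = list(NULL, c("x1", "x2")))
  y <- 10 + 5 * X[, 1] - 3 * X[, 2]
  m <- mlp_train(X, y, n_hidden = 6, nu = 1e7, seed = 5)
  expect_lt(max(abs(m$w_in)), 1e-2)
  expect_lt(max(abs(m$w_out)), 1e-2)
  preds <- mlp_forward(m, X)
  expect_equal(unname(preds), rep(mean(y), nrow(X)), tolerance = 0.05)
})

test_that("training agrees with an independent weight-decay MLP fit", {
  skip_if_not_installed("nnet")
  set.seed(32)
  X <- matrix(runif(200, -2, 2), ncol = 2, dimnames = list(NULL, c("x1", "x2")))
  y <- pmax(0, 20 + 8 * tanh(X[, 1]) - 5 * X[, 2] + rnorm(100, 0, 0.5))
  m <- mlp_train(X, y, n_hidden = 6, nu = 0.01, seed = 6)
  rmse_own <- sqrt(mean((mlp_forward(m, X) - y)^2))
  nn <- nnet::nnet(scale(X), y, size = 6, linout = TRUE, decay = 0.01,
                   maxit = 500, trace = FALSE)
  rmse_ref <- sqrt(mean((pmax(predict(nn, scale(X)), 0) - y)^2))
  # both optimizers should reach comparable penalized-LS fits
  expect_lt(rmse_own, 2 * rmse_ref + 0.5)
  expect_lt(rmse_own, 2)
})

test_that("model selection picks the single offered cell and is deterministic", {
  set.seed(33)
  X <- matrix(runif(40, 0, 1), ncol = 1, dimnames = list(NULL, "x1"))
  y <- 30 * X[, 1] + rnorm(40, 0, 2)
  g <- select_model(X, y, n_hidden_grid = 4L, nu_grid = 1, reps = 2L, seed = 7)
  expect_identical(g$chosen$n_hidden, 4L)
  expect_identical(g$chosen$nu, 1)
  g2 <- select_model(X, y, n_hidden_grid = 4L, nu_grid = 1, reps = 2L, seed = 7)
  expect_identical(g$scores, g2$scores)
  expect_error(select_model(X, rep(5, 40), n_hidden_grid = 4L, nu_grid = 1,
                            reps = 1L), "degenerate")
})

test_that("cross-validation prefers parsimonious nets on a smooth map", {
  set.seed(34)
  X <- matrix(runif(50, 0, 60), ncol = 1, dimnames = list(NULL, "x1"))
  y <- X[, 1] + rnorm(50, 0, 6)
  # without weight decay the large net interpolates noise and loses held-out
  # agreement; the small one generalizes
  g <- select_model(X, y, n_hidden_grid = c(2L, 24L), nu_grid = 0,
                    reps = 3L, seed = 8)
  expect_lte(g$chosen$n_hidden, 8L)
})

test_that("model JSON round-trip preserves predictions exactly", {
  set.seed(35)
  X <- matrix(runif(60, 0, 1), ncol = 2, dimnames = list(NULL, c("x1", "x2")))
  y <- 15 * X[, 1] + 5 * X[, 2]
  m <- mlp_train(X, y, n_hidden = 3, nu = 0.1, seed = 9)
  p <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, p)
  m2 <- read_model_json(p)
  expect_equal(mlp_forward(m2, X), mlp_forward(m, X), tolerance = 1e-12)
})

test_that("published presets carry the validated architectures", {
  pr <- osas_presets()
  expect_identical(pr$lab$n_hidden, 12L)
  expect_identical(pr$lab$nu, 1)
  expect_length(pr$lab$features, 9L)
  expect_identical(pr$home$n_hidden, 12L)
  expect_identical(pr$home$nu, 4)
  expect_length(pr$home$features, 8L)
  expect_true(all(c("M1t", "M3t", "M4t", "PR", "SampEn", "CTM", "LZC") %in%
                    intersect(pr$lab$features, pr$home$features)))
  expect_true(all(pr$lab$features %in% feature_names()))
  expect_true(all(pr$home$features %in% feature_names()))
})

test_that("end-to-end AHI prediction separates severe from event-free recordings", {
  co <- simulate_cohort(25, ahi_range = c(0, 60), duration_hours = 1,
                        noise_sd = 0.4, seed = 36)
  X <- cohort_features(co$recordings)
  sel <- fcbf_select(X, co$ahi_true)
  m <- mlp_train(X[, sel$selected, drop = FALSE], co$ahi_true,
                 n_hidden = 12, nu = 1, seed = 10)
  quiet <- simulate_recording(sim_config(duration_hours = 1, event_rate = 0,
                                         noise_sd = 0.4, seed = 37))
  severe <- simulate_recording(sim_config(duration_hours = 1, event_rate = 45,
                                          noise_sd = 0.4, seed = 38))
  ahi_q <- predict_ahi(m, quiet$rec)
  ahi_s <- predict_ahi(m, severe$rec)
  expect_lt(ahi_q, 10)
  expect_gt(ahi_s, 30)
  expect_identical(predict_ahi(m, severe$rec), ahi_s)  # purity
})
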