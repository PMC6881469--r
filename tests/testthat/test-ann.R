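test_that("forward pass matches the layer equations and stays in (0,1)", {
  cfg <- ann_config(seed = 4)
  w <- rep(0, inhibisense:::n_params(cfg))
  out <- ann_forward(w, matrix(rnorm(9), 3, 3), cfg)
  expect_equal(out$output, matrix(0.5, 3, 6))   # logistic(0) everywhere
  # dead output layer: any hidden activity still yields 0.5
  wl <- inhibisense:::unpack_weights(inhibisense:::init_weights(cfg), cfg)
  wl$W2[] <- 0; wl$b2[] <- 0
  out2 <- ann_forward(inhibisense:::pack_weights(wl), matrix(rnorm(9), 3, 3), cfg)
  expect_equal(out2$output, matrix(0.5, 3, 6))
  # general bounds
  w3 <- inhibisense:::init_weights(ann_config(seed = 9))
  o3 <- ann_forward(w3, matrix(rnorm(30), 10, 3), ann_config(seed = 9))$output
  expect_true(all(o3 > 0 & o3 < 1))
  expect_error(ann_forward(w3, matrix(1, 1, 4), ann_config()), "expects")
})

test_that("backpropagated Jacobian matches central finite differences", {
  for (s in c(2, 7)) {
    cfg <- ann_config(n_input = 3, n_hidden = 12, n_output = 6, seed = s)
    set.seed(s)
    X <- matrix(rnorm(12), 4, 3)
    w <- inhibisense:::init_weights(cfg)
    J <- inhibisense:::ann_jacobian(w, X, cfg)$J
    Jfd <- fd_jacobian(w, X, cfg)
    expect_lt(max(abs(J - Jfd)) / max(abs(Jfd)), 1e-6)
  }
  # and on a non-square toy architecture
  cfg <- ann_config(n_input = 2, n_hidden = 3, n_output = 2, seed = 5)
  set.seed(5)
  X <- matrix(rnorm(10), 5, 2)
  w <- inhibisense:::init_weights(cfg)
  expect_lt(max(abs(inhibisense:::ann_jacobian(w, X, cfg)$J - fd_jacobian(w, X, cfg))),
            1e-8)
})

test_that("Levenberg-Marquardt solves XOR and its history decreases strictly", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  Y <- matrix(c(0, 1, 1, 0), ncol = 1)
  fit <- train_lm(X, Y, ann_config(n_input = 2, n_hidden = 2, n_output = 1,
                                   max_epochs = 200, mse_goal = 1e-10, seed = 1))
  expect_lt(fit$mse, 1e-6)
  expect_equal(fit$stop_reason, "mse_goal")
  expect_lte(fit$epochs, 200)
  expect_true(all(diff(fit$history) < 0))
  expect_equal(fit$mse, min(fit$history))
})

test_that("the MSE-goal stopping rule triggers at reduced epoch budgets", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  Y <- matrix(c(0, 1, 1, 0), ncol = 1)
  # loose goal: reached almost immediately, well inside the epoch budget
  fit <- train_lm(X, Y, ann_config(n_input = 2, n_hidden = 2, n_output = 1,
                                   max_epochs = 1000, mse_goal = 1e-2, seed = 1))
  expect_equal(fit$stop_reason, "mse_goal")
  expect_lt(fit$epochs, 100)
  expect_lte(fit$mse, 1e-2)
  # epoch cap binds when the budget is tiny
  fit2 <- train_lm(X, Y, ann_config(n_input = 2, n_hidden = 2, n_output = 1,
                                    max_epochs = 3, mse_goal = 1e-10, seed = 1))
  expect_equal(fit2$stop_reason, "max_epochs")
  expect_equal(fit2$epochs, 3L)
})

test_that("the full-scale 250,000-epoch configuration is representable", {
  cfg <- ann_config(max_epochs = 250000, mse_goal = 1e-10)
  expect_equal(cfg$max_epochs, 250000L)
  expect_equal(cfg$mse_goal, 1e-10)
})

test_that("training never increases the best MSE and is seed-reproducible", {
  d <- generate_dataset(n_per_class = 2, noise_cv = 0.1, seed = 21)
  cfg <- ann_config(max_epochs = 40, seed = 2)
  f1 <- ann_fit(d, cfg)
  f2 <- ann_fit(d, cfg)
  expect_identical(f1$weights, f2$weights)
  expect_true(all(diff(f1$history) < 0))
  w0 <- inhibisense:::init_weights(cfg)
  X <- inhibisense:::response_matrix(d)
  Y <- inhibisense:::codeword_bits(
    encode_class(d$pollutant, d$level_uM))
  mse0 <- mean((Y - ann_forward(w0, X, cfg)$output)^2)
  expect_lt(f1$mse, mse0)
})

test_that("a noise-free anchor-trained network nearly memorizes its classes", {
  # one sample per anchored class (levels 1/10/100 uM): the clamped 0.1 and
  # 1000 uM levels duplicate anchored inputs and are therefore excluded —
  # identical inputs with different target codewords cannot be separated
  train <- anchor_training_frame()
  net <- ann_fit(train, ann_config(seed = 1))
  calls <- predict(net, train)
  id_acc <- mean(calls$pollutant == train$pollutant)
  exact <- mean(calls$pollutant == train$pollutant &
                calls$level_uM == train$level_uM)
  expect_gte(id_acc, 0.90)
  # pinned seeded regression values (33/36 identities, 32/36 exact classes)
  expect_equal(id_acc, 33 / 36, tolerance = 1e-8)
  expect_equal(exact, 32 / 36, tolerance = 1e-8)
})

test_that("predict decodes a trained network's outputs deterministically", {
  train <- anchor_training_frame()
  net <- ann_fit(train, ann_config(seed = 1))
  p1 <- predict(net, train)
  p2 <- predict(net, train)
  expect_identical(p1, p2)
  expect_true(all(p1$codeword %in% codebook()$codeword))
  # strictly inside (0,1) in exact arithmetic; saturated sigmoids may round
  # to the bounds in floating point
  raw <- as.matrix(p1[, paste0("raw_", 1:6)])
  expect_true(all(raw >= 0 & raw <= 1))
  # the atrazine 1 uM anchor triple is called as atrazine
  atr <- train[train$pollutant == "atrazine" & train$level_uM == 1, ]
  expect_equal(predict(net, atr)$pollutant, "atrazine")
  # the Hg2+ 1 uM-level triple is called as a heavy metal class member
  hg <- train[train$pollutant == "Hg2+" & train$level_uM == 1, ]
  expect_equal(predict(net, hg)$pollutant, "Hg2+")
})

test_that("model accessors expose coefficients, residuals and history", {
  d <- generate_dataset(n_per_class = 1, noise_cv = 0.05, seed = 13)
  net <- ann_fit(d, ann_config(max_epochs = 30, seed = 3))
  co <- coef(net)
  expect_equal(dim(co$W1), c(12L, 3L))
  expect_equal(dim(co$W2), c(6L, 12L))
  expect_equal(length(co$b1), 12L)
  expect_equal(length(co$b2), 6L)
  r <- residuals(net)
  expect_equal(dim(r), c(nrow(d), 6L))
  expect_equal(mean(r^2), net$mse)
  s <- summary(net)
  expect_s3_class(s, "summary.sensor_ann")
  expect_true(s$training_pollutant_accuracy >= 0 &&
              s$training_pollutant_accuracy <= 1)
  expect_output(print(net), "Sensor-array pollutant network")
})
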