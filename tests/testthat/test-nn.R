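test_that("the adaptive kernel size maps channel counts to odd sizes", {
  expect_identical(adaptive_kernel_size(64), 3L)
  expect_identical(adaptive_kernel_size(256), 5L)   # tie 4.5 rounds up
  expect_identical(adaptive_kernel_size(2), 1L)
  expect_identical(adaptive_kernel_size(1), 1L)     # floored at 1
  expect_true(all(vapply(2^(1:10), adaptive_kernel_size,
                         integer(1)) %% 2 == 1))
  expect_error(adaptive_kernel_size(0), "positive")
})

test_that("the attention module squashes weights into (0, 1)", {
  set.seed(8)
  fm <- matrix(rnorm(30 * 64), 30, 64)
  att0 <- eca_attention(fm, kernel = numeric(3))
  expect_equal(att0$weights, rep(0.5, 64))

  att_id <- eca_attention(fm, kernel = c(0, 1, 0))
  expect_equal(att_id$weights, 1 / (1 + exp(-colMeans(fm))))

  att <- eca_attention(fm, kernel = rnorm(5))
  expect_true(all(att$weights > 0 & att$weights < 1))
  expect_equal(att$k, 5)
  expect_error(eca_attention(fm, kernel = numeric(4)), "odd")
})

test_that("applying attention rescales exactly the matching channels", {
  fm <- matrix(1, 10, 8)
  att <- structure(list(pooled = rep(1, 8), weights = rep(1, 8), k = 3),
                   class = "thz_attention")
  expect_equal(apply_attention(fm, att), fm)
  att$weights <- rep(0.5, 8)
  expect_equal(apply_attention(fm, att), fm / 2)
  att$weights <- c(0, rep(1, 7))
  out <- apply_attention(fm, att)
  expect_equal(out[, 1], numeric(10))
  expect_equal(out[, 2:8], fm[, 2:8])
  att$weights <- rep(1, 5)
  expect_error(apply_attention(fm, att), "mismatch")
})

test_that("a forward pass yields a normalized probability vector", {
  model <- build_network(network_config(), seed = 1)
  x <- array(rnorm(240 * 2), c(1, 240, 2))
  pr <- predict(model, x)
  expect_equal(dim(pr$prob), c(1, 20))
  expect_equal(sum(pr$prob), 1, tolerance = 1e-6)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
})

test_that("the plain CNN has strictly fewer parameters than the ECA net", {
  eca <- build_network(network_config(use_eca = TRUE), seed = 1)
  plain <- build_network(network_config(use_eca = FALSE), seed = 1)
  expect_lt(n_parameters(plain), n_parameters(eca))
  expect_identical(eca$eca_k, 3L)     # 64 channels from Conv4
})

test_that("prediction is deterministic, shape-checked and batch-safe", {
  model <- build_network(network_config(), seed = 2)
  x1 <- array(rnorm(240 * 2), c(1, 240, 2))
  xx <- array(0, c(2, 240, 2))
  xx[1, , ] <- x1[1, , ]; xx[2, , ] <- x1[1, , ]
  pr <- predict(model, xx)
  expect_equal(pr$prob[1, ], pr$prob[2, ])
  expect_equal(pr$class[1], pr$class[2])

  empty <- predict(model, array(0, c(0, 240, 2)))
  expect_equal(nrow(empty$prob), 0)
  expect_length(empty$class, 0)

  expect_error(predict(model, array(0, c(1, 120, 2))), "shape")
})

test_that("the input block produces a length-by-filters feature map", {
  model <- build_network(network_config(), seed = 3)
  item <- matrix(rnorm(240 * 2), 240, 2)
  fm <- input_block_feature_map(model, item)
  expect_equal(dim(fm), c(240, 32))
  expect_identical(fm, input_block_feature_map(model, item))
  zero_map <- input_block_feature_map(model, matrix(0, 240, 2))
  expect_equal(max(abs(zero_map)), 0)
})

test_that("a zero learning rate leaves the parameters unchanged", {
  set.seed(1)
  toy <- toy_separable_set(10)
  model <- build_network(small_net_config(), seed = 4)
  before <- model$params
  tr <- nn_train(model, toy, toy,
                 training_config(epochs = 1, fine_tune_epochs = 0, lr = 0,
                                 lr_decay = 0, batch_size = 20),
                 seed = 1)
  expect_identical(tr$model$params, before)
})

test_that("training solves a linearly separable two-class problem", {
  toy <- toy_separable_set(40)
  val <- toy_separable_set(10, seed = 3)
  tr <- nn_train(build_network(small_net_config(), seed = 5), toy, val,
                 training_config(epochs = 20, fine_tune_epochs = 0,
                                 lr = 1e-2, batch_size = 32),
                 seed = 5)
  expect_equal(utils::tail(tr$history$val_acc, 1), 1.0)
  expect_true(all(c("phase", "epoch", "train_loss", "train_acc",
                    "val_loss", "val_acc") %in% names(tr$history)))
})

test_that("a validation-loss plateau triggers early stopping", {
  toy <- toy_separable_set(10)
  tr <- nn_train(build_network(small_net_config(), seed = 6), toy, toy,
                 training_config(epochs = 100, fine_tune_epochs = 0, lr = 0,
                                 lr_decay = 0, batch_size = 20,
                                 patience = 3),
                 seed = 2)
  # batch-norm running statistics keep the validation loss moving for a
  # few epochs even with frozen weights; the plateau must still stop
  # training long before the epoch budget
  expect_lt(nrow(tr$history), 40)
})

test_that("an oversized batch is reduced with a warning", {
  toy <- toy_separable_set(5)
  expect_warning(
    nn_train(build_network(small_net_config(), seed = 7), toy, toy,
             training_config(epochs = 1, fine_tune_epochs = 0,
                             batch_size = 4096),
             seed = 1),
    "reduced")
})

test_that("training is reproducible under a fixed seed", {
  toy <- toy_separable_set(20)
  run <- function() nn_train(build_network(small_net_config(), seed = 8),
                             toy, toy,
                             training_config(epochs = 3,
                                             fine_tune_epochs = 1,
                                             batch_size = 16),
                             seed = 11)
  t1 <- run(); t2 <- run()
  expect_identical(t1$model$params, t2$model$params)
  expect_identical(t1$history, t2$history)
})
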