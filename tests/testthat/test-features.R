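test_that("the hybrid spectrum stacks absorption before refractive index", {
  a <- runif(240); n <- runif(240)
  h <- hybrid_spectrum(a, n)
  expect_equal(dim(h$matrix), c(240, 2))
  expect_equal(unname(h$matrix[, 1]), a)
  expect_equal(unname(h$matrix[, 2]), n)
  h2 <- hybrid_spectrum(a, a)
  expect_equal(h2$matrix[, 1], h2$matrix[, 2])
  expect_error(hybrid_spectrum(a, n[-1]), "equal length")
  expect_error(hybrid_spectrum(a, n, standardize = TRUE), "stats")
})

test_that("dataset assembly splits each class at the requested fraction", {
  feats <- toy_features(n_classes = 4, n_per_class = 10)
  ds <- assemble_datasets(feats, "hybrid", val_frac = 0.2, seed = 9)
  expect_equal(as.integer(table(ds$train$y)), rep(8L, 4))
  expect_equal(as.integer(table(ds$val$y)), rep(2L, 4))
  expect_equal(dim(ds$train$x)[3], 2)
  # partition: together they cover every record exactly once
  expect_equal(dim(ds$train$x)[1] + dim(ds$val$x)[1], 40)
})

test_that("single-metric modes produce one input channel", {
  feats <- toy_features()
  for (mode in c("absorption", "refractive")) {
    ds <- assemble_datasets(feats, mode, seed = 9)
    expect_equal(dim(ds$train$x)[3], 1)
  }
})

test_that("splits are deterministic under the seed", {
  feats <- toy_features()
  d1 <- assemble_datasets(feats, "hybrid", seed = 7)
  d2 <- assemble_datasets(feats, "hybrid", seed = 7)
  expect_identical(d1$train$y, d2$train$y)
  expect_identical(d1$train$x, d2$train$x)
})

test_that("standardization statistics come from the training split only", {
  feats <- toy_features()
  ds <- assemble_datasets(feats, "hybrid", seed = 9)
  for (ch in 1:2) {
    expect_equal(mean(ds$train$x[, , ch]), 0, tolerance = 1e-6)
    expect_equal(stats::sd(as.vector(ds$train$x[, , ch])), 1,
                 tolerance = 1e-2)
  }
  # test split transformed with the train stats, not its own
  raw <- feats$groups[["20"]]$alpha
  expect_equal(ds$test20$x[, , 1],
               (raw - ds$stats$mean[1]) / ds$stats$sd[1],
               ignore_attr = TRUE)
})

test_that("a missing averaging group is an error", {
  feats <- toy_features()
  expect_error(assemble_datasets(feats, "hybrid", train_group = "999"),
               "missing")
})

test_that("first principal component scores behave like a projection", {
  v1 <- c(1, 2, 3, 4); v2 <- c(4, 3, 2, 1)
  sc <- first_principal_component(list(v1, v2))
  expect_equal(sum(sc), 0, tolerance = 1e-12)
  expect_equal(abs(sc[1]), abs(sc[2]))

  sc2 <- first_principal_component(list(v1, v2, v1, v2))
  expect_equal(sc2[1], sc2[3])
  expect_equal(sc2[2], sc2[4])

  expect_error(first_principal_component(list(v1)), "at least 2")
  expect_error(first_principal_component(list(v1, v1)), "rank-0")
})

test_that("hybrid matrices are flattened frequency-major for PCA", {
  m1 <- hybrid_spectrum(c(1, 0), c(0, 0))
  m2 <- hybrid_spectrum(c(0, 0), c(0, 1))
  m3 <- hybrid_spectrum(c(1, 0), c(0, 1))
  sc <- first_principal_component(list(m1, m2, m3, m1, m2, m3))
  expect_length(sc, 6)
  expect_equal(sc[1:3], sc[4:6])
})
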