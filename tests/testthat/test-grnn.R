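test_that("GRNN prediction matches the kernel-regression formula", {
  # single pattern neuron: weights normalize to the lone target
  m1 <- raw_grnn(matrix(c(0.2, 0.4), 1), 5.0, sigma = 0.7)
  expect_equal(grnn_predict(m1, c(x1 = 100, x2 = -3)), 5.0)

  # two equidistant patterns average their targets
  m2 <- raw_grnn(matrix(c(-1, 1), 2, 1), c(2, 4), sigma = 0.3)
  expect_equal(grnn_predict(m2, c(x1 = 0)), 3.0)

  # brute-force double-loop oracle on random instances
  for (case in 1:25) {
    set.seed(case)
    n <- sample(2:12, 1)
    d <- sample(1:4, 1)
    P <- matrix(rnorm(n * d), n, d)
    t <- rnorm(n)
    Q <- matrix(rnorm(3 * d), 3, d)
    m <- raw_grnn(P, t, sigma = 0.2)
    colnames(Q) <- m$descriptor_names
    expect_equal(grnn_predict(m, Q), grnn_oracle(P, t, 0.2, Q),
                 tolerance = 1e-12)
  }
})

test_that("GRNN fit stores patterns verbatim and honours sigma limits", {
  train <- random_dataset(7, p = 2, seed = 3)
  m <- grnn_fit(train, c("dft_nci", "x1"), sigma = 0.2)
  expect_equal(nrow(m$patterns), 7)

  # sigma -> 0: interpolates every training target (normalized scale)
  m_small <- grnn_fit(train, c("dft_nci", "x1"), sigma = 1e-4)
  pred <- grnn_predict(m_small, train)
  expect_equal(unname(pred), m_small$targets, tolerance = 1e-9)

  # sigma -> Inf: every prediction is the target mean
  m_big <- grnn_fit(train, c("dft_nci", "x1"), sigma = 1e6)
  expect_equal(unname(grnn_predict(m_big, train)),
               rep(mean(m_big$targets), 7), tolerance = 1e-9)

  expect_error(grnn_fit(train, c("dft_nci", "x1"), sigma = 0),
               class = "grnncorr_argument_error")
  expect_error(grnn_fit(train, c("x1"), sigma = 0.2),
               class = "grnncorr_argument_error")
})

test_that("predictions stay within the training-target range", {
  for (case in 1:10) {
    set.seed(40 + case)
    P <- matrix(rnorm(30), 10, 3)
    t <- rnorm(10)
    m <- raw_grnn(P, t, sigma = runif(1, 0.05, 3))
    Q <- matrix(rnorm(60, sd = 3), 20, 3,
                dimnames = list(NULL, m$descriptor_names))
    pred <- grnn_predict(m, Q)
    expect_true(all(pred >= min(t) - 1e-12 & pred <= max(t) + 1e-12))
  }
})

test_that("distant queries return the nearest pattern's target, not 0/0", {
  set.seed(8)
  P <- matrix(rnorm(12), 4, 3)
  t <- c(1.5, -2, 0.25, 4)
  m <- raw_grnn(P, t, sigma = 0.2)
  far <- matrix(P[3, ] + 1e3, 1, dimnames = list(NULL, m$descriptor_names))
  pred <- grnn_predict(m, far)
  expect_true(is.finite(pred))
  nearest <- which.min(colSums((t(P) - drop(far))^2))
  expect_equal(pred, t[nearest])
})

test_that("prediction is invariant under pattern permutation", {
  set.seed(9)
  P <- matrix(rnorm(24), 8, 3)
  t <- rnorm(8)
  perm <- sample(8)
  m1 <- raw_grnn(P, t, sigma = 0.4)
  m2 <- raw_grnn(P[perm, ], t[perm], sigma = 0.4)
  Q <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, m1$descriptor_names))
  expect_equal(grnn_predict(m1, Q), grnn_predict(m2, Q), tolerance = 1e-12)
})

test_that("queries missing a model descriptor raise a schema error", {
  train <- random_dataset(5, p = 3, seed = 10)
  m <- grnn_fit(train, c("dft_nci", "x1", "x2"), sigma = 0.2)
  expect_error(grnn_predict(m, c(dft_nci = 0, x1 = 1)), "x2",
               class = "grnncorr_schema_error")
})

test_that("K-fold partition shuffles deterministically with balanced sizes", {
  folds <- kfold_partition(sprintf("s%02d", 1:10), cv_config(5, 1))
  expect_length(folds, 5)
  expect_true(all(lengths(folds) == 2))
  expect_setequal(unlist(folds), sprintf("s%02d", 1:10))

  folds91 <- kfold_partition(seq_len(91), cv_config(10, 3))
  expect_equal(unname(sort(lengths(folds91), decreasing = TRUE)),
               c(10, rep(9, 9)))

  expect_identical(kfold_partition(1:20, cv_config(4, 5)),
                   kfold_partition(1:20, cv_config(4, 5)))
  expect_false(identical(kfold_partition(1:20, cv_config(4, 5)),
                         kfold_partition(1:20, cv_config(4, 6))))
  expect_error(kfold_partition(1:3, cv_config(5, 1)),
               class = "grnncorr_argument_error")
})

test_that("cross-validated RMSE equals a hand-rolled leave-one-out loop", {
  ds <- random_dataset(6, p = 2, seed = 12)
  sub <- c("dft_nci", "x1")
  got <- cv_rmse(ds, sub, sigma = 0.35, cv_config(K = 6, seed = 2))

  ids <- ds$records$id
  obs <- reference_nci(ds)
  pred <- numeric(length(ids))
  names(pred) <- ids
  for (i in seq_along(ids)) {
    fit_set <- subset_records(ds, ids[-i])
    sub_set <- select_descriptors(fit_set, sub)
    map <- fit_normalization(sub_set, include_target = TRUE)
    m <- grnn_fit(fit_set, sub, sigma = 0.35, map = map)
    pred[ids[i]] <- grnn_predict(m, subset_records(ds, ids[i]),
                                 denormalize = TRUE)
  }
  expect_equal(as.numeric(got), sqrt(mean((pred - obs)^2)),
               tolerance = 1e-12)
  expect_equal(attr(got, "oof_pred")[ids], pred, tolerance = 1e-12)
})

test_that("noiseless smooth responses are recovered below 1e-3", {
  n <- 201
  x <- seq(-1, 1, length.out = n)
  df <- data.frame(id = sprintf("s%03d", 1:n), class = "unknown",
                   dft_nci = x, ref_nci = cos(pi * x))
  ds <- nci_dataset(df, "dft_nci")
  r <- cv_rmse(ds, "dft_nci", sigma = 0.005, cv_config(K = n, seed = 1))
  expect_lt(as.numeric(r), 1e-3)
})

test_that("pure-noise targets at the grid-max sigma give the mean-predictor error", {
  set.seed(42)
  df <- data.frame(id = sprintf("s%03d", 1:100), class = "unknown",
                   dft_nci = rnorm(100), ref_nci = rnorm(100))
  ds <- nci_dataset(df, "dft_nci")
  r <- as.numeric(cv_rmse(ds, "dft_nci", 2.0, cv_config(10, 1)))
  expect_lt(abs(r - sd(df$ref_nci)) / sd(df$ref_nci), 0.25)
})

test_that("sigma grid search returns the CV argmin with ties to larger sigma", {
  expect_length(sigma_grid_points(c(0.1, 2, 0.1)), 20)
  expect_equal(sigma_grid_points(0.7), 0.7)
  expect_error(sigma_grid_points(c(-1, 0)), class = "grnncorr_argument_error")

  ds <- random_dataset(30, p = 2, seed = 13)
  cv <- cv_config(5, 4)
  grid <- c(0.1, 1, 0.1)
  opt <- optimize_sigma(ds, c("dft_nci", "x1"), grid, cv)
  # independent per-sigma table via separate cv_rmse calls
  table_ref <- vapply(sigma_grid_points(grid), function(s) {
    as.numeric(cv_rmse(ds, c("dft_nci", "x1"), s, cv))
  }, numeric(1))
  expect_equal(opt$table$cv_rmse, table_ref, tolerance = 1e-12)
  best <- which(table_ref == min(table_ref))
  expect_equal(opt$sigma, sigma_grid_points(grid)[max(best)])

  opt1 <- optimize_sigma(ds, c("dft_nci", "x1"), 0.5, cv)
  expect_equal(opt1$sigma, 0.5)
})
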