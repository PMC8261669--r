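test_that("splitting gives floor-sized disjoint partitions, reproducibly", {
  sp <- split_dataset(724, seed = 1)
  expect_length(sp$test, 72)
  expect_length(sp$val, floor(0.10 * (724 - 72)))
  expect_length(sp$train, 724 - 72 - floor(0.10 * 652))
  all_ids <- sort(c(sp$train, sp$val, sp$test))
  expect_identical(all_ids, 1:724)
  expect_identical(split_dataset(724, seed = 1), sp)
  expect_false(identical(split_dataset(724, seed = 2), sp))
  expect_length(split_dataset(10, seed = 1)$test, 1)
  expect_error(split_dataset(9), "at least 10")
})

test_that("min-max scaling maps the training span to [-1,1] and inverts", {
  X <- cbind(a = c(39, 40, 41), b = c(0, 5, 10))
  sc <- floodscore:::.fit_scaler(X)
  Xs <- floodscore:::.apply_scaler(X, sc)
  expect_equal(Xs[, "a"], c(-1, 0, 1))
  expect_equal(Xs[, "b"], c(-1, 0, 1))
  # beyond-training values extend outside [-1,1] (no clipping)
  Xnew <- cbind(a = 42, b = -5)
  expect_equal(floodscore:::.apply_scaler(Xnew, sc)[1, ], c(a = 2, b = -2))
  back <- floodscore:::.invert_scaler(Xs, sc)
  expect_equal(back, X, tolerance = 1e-12)
  expect_warning(floodscore:::.fit_scaler(cbind(k = c(1, 1, 1))), "constant")
})

test_that("the residual Jacobian matches finite differences", {
  set.seed(20)
  for (rep in 1:3) {
    p <- sample(2:4, 1); h <- sample(2:5, 1); n <- 7
    X <- matrix(rnorm(n * p), n, p)
    theta <- rnorm(p * h + 2 * h + 1, sd = 0.5)
    fw <- floodscore:::.fnn_forward(theta, X, h)
    J <- floodscore:::.fnn_jacobian(fw, X)
    eps <- 1e-6
    J_fd <- sapply(seq_along(theta), function(k) {
      tp <- theta; tp[k] <- tp[k] + eps
      tm <- theta; tm[k] <- tm[k] - eps
      (floodscore:::.fnn_forward(tp, X, h)$yhat -
         floodscore:::.fnn_forward(tm, X, h)$yhat) / (2 * eps)
    })
    expect_lt(max(abs(J - J_fd)) / max(abs(J)), 1e-6)
  }
})

test_that("LM drives a noiseless linear target below 1e-6 quickly", {
  set.seed(21)
  X <- matrix(runif(200 * 3, -1, 1), 200, 3)
  y <- X[, 1]
  fit <- floodscore:::.lm_train(X, y, config = fnn_config(epochs_max = 100),
                                seed = 4)
  expect_lt(fit$mse, 1e-6)
  expect_lte(fit$epochs, 100)
  # accepted steps only: the training-loss trace never increases
  expect_true(all(diff(fit$trace$mse) <= 1e-12))
})

test_that("LM reaches the same least-squares basin as an independent solver", {
  set.seed(22)
  X <- matrix(runif(60 * 2, -1, 1), 60, 2)
  y <- tanh(X[, 1]) - 0.5 * X[, 2] + rnorm(60, sd = 0.01)
  h <- 3
  theta0 <- floodscore:::.fnn_init(2, h, seed = 5)
  ours <- floodscore:::.lm_train(X, y, config = fnn_config(hidden = h),
                                 seed = 5, theta0 = theta0)
  res_fn <- function(th) floodscore:::.fnn_forward(th, X, h)$yhat - y
  ref <- minpack.lm::nls.lm(par = theta0, fn = res_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, maxfev = 100000))
  expect_lt(ours$mse, 2 * mean(residuals(ref)^2) + 1e-8)
})

test_that("a pre-satisfied goal stops training at zero epochs", {
  set.seed(23)
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)
  fit <- floodscore:::.lm_train(X, y, config = fnn_config(goal = 1e6), seed = 1)
  expect_equal(fit$epochs, 0)
  expect_equal(fit$stop_reason, "goal")
})

test_that("forward pass matches hand evaluation and is batch-invariant", {
  # 1 input, 1 hidden unit: y = w2 * tanh(w1 x + b1) + b2
  theta <- c(0.7, -0.2, 1.5, 0.3)  # W1, b1, w2, b2
  x <- matrix(c(-1, 0, 2), 3, 1)
  got <- floodscore:::.fnn_forward(theta, x, 1)$yhat
  expect_equal(got, 1.5 * tanh(0.7 * x[, 1] - 0.2) + 0.3, tolerance = 1e-12)
  # zero weights, bias b2: constant output
  theta0 <- c(0, 0, 0, 0.42)
  expect_equal(floodscore:::.fnn_forward(theta0, x, 1)$yhat, rep(0.42, 3))
  # batch prediction equals per-record prediction
  set.seed(24)
  theta2 <- rnorm(3 * 4 + 2 * 4 + 1, sd = 0.3)
  X <- matrix(rnorm(15), 5, 3)
  batch <- floodscore:::.fnn_forward(theta2, X, 4)$yhat
  single <- sapply(1:5, function(i)
    floodscore:::.fnn_forward(theta2, X[i, , drop = FALSE], 4)$yhat)
  expect_equal(batch, single, tolerance = 1e-12)
})

test_that("output binning reproduces the categorization table", {
  expect_identical(bin_fis(c(0, 1.49, 1.5, 2.49, 2.5, 3.49, 3.5, 4.49, 4.5, 9)),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L))
  expect_identical(bin_fis(-0.2), 1L)          # negative outputs clip to 1
  expect_identical(bin_fis(as.numeric(1:5)), 1:5)  # idempotent on levels
  x <- sort(runif(50, -1, 6))
  expect_true(all(diff(bin_fis(x)) >= 0))      # monotone
  expect_error(bin_fis(c(1, NaN)), "non-finite")
})

test_that("accuracy is the correct-fraction percentage", {
  expect_equal(fis_accuracy(1:5, 1:5), 100)
  expect_equal(fis_accuracy(c(rep(1, 65), rep(2, 7)),
                            c(rep(1, 65), rep(3, 7))), 100 * 65 / 72)
  expect_equal(round(fis_accuracy(c(rep(1, 65), rep(2, 7)),
                                  c(rep(1, 65), rep(3, 7))), 2), 90.28)
  expect_equal(fis_accuracy(rep(1, 4), rep(2, 4)), 0)
  expect_error(fis_accuracy(integer(0), integer(0)), "non-empty")
})

test_that("confusion tables count pairs and tie out with accuracy", {
  ct <- confusion_table(c(1, 2, 2), c(1, 2, 3))
  expect_equal(ct["1", "1"], 1L)
  expect_equal(ct["2", "2"], 1L)
  expect_equal(ct["2", "3"], 1L)
  expect_equal(sum(ct), 3L)
  set.seed(25)
  pred <- sample(1:5, 40, TRUE); truth <- sample(1:5, 40, TRUE)
  ct2 <- confusion_table(pred, truth)
  expect_equal(unname(colSums(ct2)), unname(tabulate(truth, 5)))
  expect_equal(unname(rowSums(ct2)), unname(tabulate(pred, 5)))
  expect_equal(100 * sum(diag(ct2)) / 40, attr(ct2, "accuracy"))
  expect_error(confusion_table(c(0, 1), c(1, 1)), "1..5")
})

test_that("top-fraction selection ranks ascending with ceiling counts", {
  set.seed(26)
  raw <- runif(72, 0.5, 5.5)
  expect_length(select_top_fraction(raw, 0.10), 8)
  expect_length(select_top_fraction(raw, 0.20), 15)
  expect_length(select_top_fraction(raw, 1.0), 72)
  sel <- select_top_fraction(raw, 0.10)
  expect_true(all(raw[sel] <= sort(raw)[9]))
  # ties broken by id
  expect_identical(select_top_fraction(c(1, 1, 1), 0.5, c("b", "a", "c")),
                   c("a", "b"))
})

test_that("the fitted model object supports the standard methods", {
  fld <- small_field()
  ft <- pipeline_features(fld)
  m <- fis_fnn(fis ~ canopy_temp_c + ndvi_mean + area_px + width_px +
                 length_px, data = ft, seed = 2)
  expect_s3_class(m, "fis_fnn")
  expect_length(coef(m), 5 * 10 + 10 + 10 + 1)
  expect_equal(m$stop_reason %in%
                 c("max_fail", "min_grad", "epochs_max", "goal", "mu_max"),
               TRUE)
  # predictions on the stored test rows agree with predict(newdata)
  test_rows <- ft[ft$valid, ][m$split$test, ]
  expect_equal(predict(m, test_rows, type = "raw"), m$predictions$raw,
               tolerance = 1e-12)
  expect_identical(predict(m, test_rows, type = "fis"), m$predictions$fis_pred)
  expect_length(residuals(m), length(m$split$train))
  expect_equal(attr(m$confusion, "accuracy"), m$accuracy)
  # determinism: same seed, same fit
  m2 <- fis_fnn(fis ~ canopy_temp_c + ndvi_mean + area_px + width_px +
                  length_px, data = ft, seed = 2)
  expect_identical(coef(m), coef(m2))
  expect_error(predict(m, ft[, c("fis", "canopy_temp_c")]),
               "do not match|object")
})
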