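#' Training configuration of the FIS feedforward network
#'
#' Hyperparameters of the Levenberg-Marquardt (LM) trainer, with the
#' package defaults: one hidden layer of 10 tanh neurons, a
#' linear output, at most 1000 epochs, performance goal 0, early stopping
#' after 6 consecutive validation failures, minimum gradient 1e-7, and the
#' LM damping parameter mu starting at 0.001 (divided by 10 on accepted
#' steps, multiplied by 10 on rejected ones, capped at 1e10).
#'
#' @param hidden hidden-layer size.
#' @param epochs_max maximum number of epochs.
#' @param goal stop when the training MSE reaches this value.
#' @param max_fail consecutive validation failures tolerated before early
#'   stopping (best-validation weights are restored).
#' @param min_grad stop when the MSE gradient norm falls below this.
#' @param mu0 initial LM damping; `mu_dec`/`mu_inc` its per-step factors;
#'   `mu_max` the upper bound (training stops if exceeded).
#' @return Object of class `fnn_config`.
#' @export
fnn_config <- function(hidden = 10L, epochs_max = 1000L, goal = 0,
                       max_fail = 6L, min_grad = 1e-7,
                       mu0 = 0.001, mu_dec = 0.1, mu_inc = 10, mu_max = 1e10) {
  stopifnot(hidden >= 1, epochs_max >= 0, mu0 > 0, mu0 < mu_max,
            mu_dec < 1, mu_inc > 1)
  structure(list(hidden = as.integer(hidden),
                 epochs_max = as.integer(epochs_max), goal = goal,
                 max_fail = as.integer(max_fail), min_grad = min_grad,
                 mu0 = mu0, mu_dec = mu_dec, mu_inc = mu_inc, mu_max = mu_max),
            class = "fnn_config")
}

#' Random train/validation/test split
#'
#' Splits `n` records uniformly at random without replacement into a test
#' set of `floor(test_frac * n)` records, a validation set of
#' `floor(val_frac * remaining)` records (carved from the training
#' partition, used for early stopping) and the training remainder. With the
#' default fractions, 724 records give a 72-record test set.
#'
#' @param n number of records (or a data frame, whose rows are counted).
#' @param test_frac,val_frac split fractions.
#' @param seed integer seed; identical seeds give identical splits.
#' @return List of class `fis_split` with integer index vectors `train`,
#'   `val`, `test`.
#' @export
split_dataset <- function(n, test_frac = 0.10, val_frac = 0.10, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  n <- as.integer(n)
  if (n < 10L) stop("need at least 10 records to split")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  perm <- sample.int(n)
  n_test <- floor(test_frac * n)
  test <- sort(perm[seq_len(n_test)])
  rest <- perm[-seq_len(n_test)]
  n_val <- floor(val_frac * length(rest))
  val <- sort(rest[seq_len(n_val)])
  train <- sort(rest[-seq_len(n_val)])
  structure(list(train = train, val = val, test = test), class = "fis_split")
}

# ---- min-max feature scaling to [-1, 1] ----

.fit_scaler <- function(X) {
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  half <- (hi - lo) / 2
  if (any(half == 0))
    warning("constant feature(s) in training data mapped to 0: ",
            paste(colnames(X)[half == 0], collapse = ", "))
  list(center = (hi + lo) / 2, half = half)
}

.apply_scaler <- function(X, sc) {
  out <- sweep(X, 2, sc$center, `-`)
  half <- ifelse(sc$half == 0, 1, sc$half)
  sweep(out, 2, half, `/`)
}

.invert_scaler <- function(Xs, sc) {
  half <- ifelse(sc$half == 0, 1, sc$half)
  sweep(sweep(Xs, 2, half, `*`), 2, sc$center, `+`)
}

# ---- network forward pass and residual Jacobian ----

.fnn_unpack <- function(theta, p, h) {
  list(W1 = matrix(theta[seq_len(h * p)], h, p),
       b1 = theta[h * p + seq_len(h)],
       w2 = theta[h * p + h + seq_len(h)],
       b2 = theta[h * p + 2 * h + 1])
}

.fnn_forward <- function(theta, X, h) {
  p <- ncol(X)
  w <- .fnn_unpack(theta, p, h)
  H <- tanh(X %*% t(w$W1) + matrix(w$b1, nrow(X), h, byrow = TRUE))
  list(yhat = as.vector(H %*% w$w2 + w$b2), H = H, w = w)
}

# Jacobian of predictions w.r.t. theta (n x n_par); parameter order matches
# .fnn_unpack (W1 column-major, then b1, w2, b2)
.fnn_jacobian <- function(fw, X) {
  h <- length(fw$w$w2); p <- ncol(X); n <- nrow(X)
  D <- (1 - fw$H^2) * matrix(fw$w$w2, n, h, byrow = TRUE)
  J_W1 <- D[, rep(seq_len(h), p), drop = FALSE] *
    X[, rep(seq_len(p), each = h), drop = FALSE]
  cbind(J_W1, D, fw$H, rep(1, n))
}

.fnn_init <- function(p, h, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  c(stats::runif(h * p, -0.5, 0.5) / sqrt(p),
    stats::runif(h, -0.5, 0.5),
    stats::runif(h, -0.5, 0.5) / sqrt(h),
    stats::runif(1, -0.5, 0.5))
}

# Levenberg-Marquardt least-squares training of the 1-hidden-layer network.
# Each epoch solves (J'J + mu I) delta = J'r; accepted steps (SSE decreases)
# divide mu by 10, rejected ones multiply it by 10 and retry.
.lm_train <- function(X, y, Xval = NULL, yval = NULL, config = fnn_config(),
                      seed = 1L, theta0 = NULL) {
  h <- config$hidden
  n <- nrow(X)
  theta <- if (is.null(theta0)) .fnn_init(ncol(X), h, seed) else theta0
  mse <- function(th, Xm, ym) mean((.fnn_forward(th, Xm, h)$yhat - ym)^2)

  loss <- mse(theta, X, y)
  mu <- config$mu0
  has_val <- !is.null(Xval) && nrow(Xval) > 0
  best_val <- if (has_val) mse(theta, Xval, yval) else Inf
  best_theta <- theta
  fails <- 0L
  trace <- list()
  stop_reason <- "epochs_max"
  epoch <- 0L

  if (loss <= config$goal) stop_reason <- "goal"
  else while (epoch < config$epochs_max) {
    epoch <- epoch + 1L
    fw <- .fnn_forward(theta, X, h)
    r <- fw$yhat - y
    J <- .fnn_jacobian(fw, X)
    g <- crossprod(J, r)                      # gradient of SSE/2
    if (sqrt(sum((2 * g / n)^2)) < config$min_grad) {
      stop_reason <- "min_grad"; epoch <- epoch - 1L; break
    }
    JtJ <- crossprod(J)
    accepted <- FALSE
    while (!accepted && mu <= config$mu_max) {
      delta <- tryCatch(solve(JtJ + mu * diag(ncol(J)), g),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta - as.vector(delta)
        cand_loss <- mse(cand, X, y)
        if (is.finite(cand_loss) && cand_loss < loss) {
          theta <- cand; loss <- cand_loss
          mu <- mu * config$mu_dec
          accepted <- TRUE
          break
        }
      }
      mu <- mu * config$mu_inc
    }
    if (!accepted) { stop_reason <- "mu_max"; break }

    val_loss <- if (has_val) mse(theta, Xval, yval) else NA_real_
    trace[[epoch]] <- c(epoch = epoch, mse = loss, val_mse = val_loss, mu = mu)
    if (has_val) {
      if (val_loss < best_val) {
        best_val <- val_loss; best_theta <- theta; fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails >= config$max_fail) { stop_reason <- "max_fail"; break }
      }
    }
    if (loss <= config$goal) { stop_reason <- "goal"; break }
  }

  if (has_val && stop_reason == "max_fail") theta <- best_theta
  trace <- if (length(trace)) as.data.frame(do.call(rbind, trace)) else
    data.frame(epoch = numeric(0), mse = numeric(0), val_mse = numeric(0),
               mu = numeric(0))
  list(theta = theta, mse = mse(theta, X, y),
       val_mse = if (has_val) mse(theta, Xval, yval) else NA_real_,
       epochs = epoch, stop_reason = stop_reason, trace = trace)
}

#' Fit the FIS feedforward network
#'
#' Trains the package's 5-10-1 feedforward network (tanh hidden layer, linear
#' output) by Levenberg-Marquardt least squares, regressing the flooding
#' injury score (treated as a real number 1-5) on the plot-level image
#' features. The data are split 90/10 into training and test sets (with a
#' validation subset carved from training for early stopping), features are
#' min-max scaled to `[-1,1]` on the training set, and the continuous
#' network output is binned to the five FIS levels for classification.
#' Records flagged `valid == FALSE` are dropped before splitting.
#'
#' @param formula model formula, e.g.
#'   `fis ~ canopy_temp_c + ndvi_mean + area_px + width_px + length_px`.
#' @param data feature table (see [pipeline_features()]).
#' @param test_frac,val_frac split fractions (see [split_dataset()]).
#' @param config an [fnn_config()].
#' @param seed integer seed driving the split and the weight initialisation.
#' @return Object of class `fis_fnn` with components `theta` (71 parameters
#'   for the default architecture), `scaler`, `split`, `trace`,
#'   `stop_reason`, and test-set `predictions`, `accuracy` (percent) and
#'   `confusion`. Methods: [predict.fis_fnn()], `print`, `summary`, `coef`,
#'   `residuals`, `plot`.
#' @export
fis_fnn <- function(formula, data, test_frac = 0.10, val_frac = 0.10,
                    config = fnn_config(), seed = 1L) {
  if ("valid" %in% names(data)) data <- data[data$valid, , drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]

  split <- split_dataset(nrow(X), test_frac, val_frac, seed)
  scaler <- .fit_scaler(X[split$train, , drop = FALSE])
  Xs <- .apply_scaler(X, scaler)

  fit <- .lm_train(Xs[split$train, , drop = FALSE], y[split$train],
                   Xs[split$val, , drop = FALSE], y[split$val],
                   config, seed = seed)

  raw_test <- .fnn_forward(fit$theta, Xs[split$test, , drop = FALSE],
                           config$hidden)$yhat
  pred_test <- bin_fis(raw_test)
  obj <- structure(list(
    call = match.call(), formula = formula, config = config, seed = seed,
    features = colnames(X), theta = fit$theta, scaler = scaler,
    split = split, trace = fit$trace, stop_reason = fit$stop_reason,
    epochs = fit$epochs, mse = fit$mse, val_mse = fit$val_mse,
    train_y = y[split$train],
    train_fitted = .fnn_forward(fit$theta,
                                Xs[split$train, , drop = FALSE],
                                config$hidden)$yhat,
    predictions = data.frame(id = split$test, raw = raw_test,
                             fis_pred = pred_test, fis_true = y[split$test]),
    accuracy = fis_accuracy(pred_test, y[split$test]),
    confusion = confusion_table(pred_test, y[split$test])
  ), class = "fis_fnn")
  obj
}

#' Predict from a fitted FIS network
#'
#' @param object a [fis_fnn()] fit.
#' @param newdata data frame with the model's feature columns; defaults to
#'   returning the stored test-set predictions.
#' @param type `"raw"` for the continuous network output (no clipping),
#'   `"fis"` for the binned five-level score.
#' @param ... unused.
#' @return Numeric (raw) or integer (fis) vector.
#' @export
predict.fis_fnn <- function(object, newdata = NULL,
                            type = c("raw", "fis"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    raw <- object$predictions$raw
  } else {
    tt <- stats::delete.response(stats::terms(object$formula))
    mf <- stats::model.frame(tt, newdata)
    X <- stats::model.matrix(tt, mf)
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
    if (!identical(colnames(X), object$features))
      stop("newdata features do not match the fitted model: expected ",
           paste(object$features, collapse = ", "))
    raw <- .fnn_forward(object$theta, .apply_scaler(X, object$scaler),
                        object$config$hidden)$yhat
  }
  if (type == "raw") raw else bin_fis(raw)
}

#' @export
print.fis_fnn <- function(x, ...) {
  cat(sprintf("FIS feedforward network: %d-%d-1 (tanh/linear), %d parameters\n",
              length(x$features), x$config$hidden, length(x$theta)))
  cat(sprintf("  trained %d epochs by Levenberg-Marquardt (stop: %s)\n",
              x$epochs, x$stop_reason))
  cat(sprintf("  train MSE %.4g | validation MSE %.4g\n", x$mse, x$val_mse))
  cat(sprintf("  test set: n = %d, five-level accuracy %.2f%%\n",
              nrow(x$predictions), x$accuracy))
  invisible(x)
}

#' @export
summary.fis_fnn <- function(object, ...) {
  print(object)
  cat("\nConfusion table (rows = predicted, cols = observed):\n")
  print(object$confusion)
  invisible(object)
}

#' @export
coef.fis_fnn <- function(object, ...) {
  h <- object$config$hidden; p <- length(object$features)
  nm <- c(paste0("W1[", rep(seq_len(h), p), ",", rep(seq_len(p), each = h), "]"),
          paste0("b1[", seq_len(h), "]"),
          paste0("w2[", seq_len(h), "]"), "b2")
  stats::setNames(object$theta, nm)
}

#' @export
residuals.fis_fnn <- function(object, ...) {
  object$train_fitted - object$train_y
}

#' @export
plot.fis_fnn <- function(x, ...) {
  tr <- x$trace
  if (!nrow(tr)) { warning("no training trace to plot"); return(invisible(x)) }
  graphics::plot(tr$epoch, tr$mse, type = "l", log = "y", xlab = "epoch",
                 ylab = "MSE", main = "Levenberg-Marquardt training", ...)
  if (any(is.finite(tr$val_mse))) {
    graphics::lines(tr$epoch, tr$val_mse, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2,
                     bty = "n")
  }
  invisible(x)
}

#' Bin continuous network outputs to FIS levels
#'
#' Output categorization: `[0,1.5) -> 1`, `[1.5,2.5) -> 2`, `[2.5,3.5) -> 3`,
#' `[3.5,4.5) -> 4`, `[4.5,Inf) -> 5`. Negative outputs (possible from the
#' linear output layer) are clipped to level 1.
#'
#' @param x numeric vector of raw network outputs (must be finite).
#' @return Integer vector of FIS levels 1-5.
#' @export
bin_fis <- function(x) {
  if (any(!is.finite(x))) stop("non-finite network output")
  findInterval(x, c(1.5, 2.5, 3.5, 4.5)) + 1L
}

#' Classification accuracy in percent
#'
#' `100 * (number classified correctly) / (total number)` over a test set.
#'
#' @param predicted,truth equal-length label vectors (non-empty).
#' @return Accuracy in percent.
#' @export
fis_accuracy <- function(predicted, truth) {
  if (length(predicted) == 0L || length(predicted) != length(truth))
    stop("need non-empty label vectors of equal length")
  100 * mean(predicted == truth)
}

#' Five-level confusion table
#'
#' @param predicted,truth FIS label vectors with values in 1-5.
#' @return 5x5 integer matrix of class `confusion_table`
#'   (`counts[predicted, observed]`) with an `accuracy` attribute.
#' @export
confusion_table <- function(predicted, truth) {
  if (!all(predicted %in% 1:5) || !all(truth %in% 1:5))
    stop("FIS labels must be in 1..5")
  tab <- table(factor(predicted, levels = 1:5), factor(truth, levels = 1:5))
  out <- matrix(as.integer(tab), 5, 5,
                dimnames = list(predicted = 1:5, observed = 1:5))
  structure(out, accuracy = fis_accuracy(predicted, truth),
            class = c("confusion_table", "matrix"))
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(as.integer(x), 5, 5, dimnames = dimnames(x))
  print(m)
  cat(sprintf("accuracy: %.2f%%\n", attr(x, "accuracy")))
  invisible(x)
}

#' Select the most flood-tolerant fraction by predicted score
#'
#' Ranks plots ascending by raw network output (lower predicted FIS = more
#' tolerant) and selects the `ceiling(fraction * n)` best, breaking ties by
#' plot id. With a 72-plot test set, fractions 0.10 and 0.20 select 8 and
#' 15 plots.
#'
#' @param raw numeric vector of raw network outputs.
#' @param fraction fraction to select, in (0, 1].
#' @param ids plot identifiers (default positional indices).
#' @return The selected ids, in rank order.
#' @export
select_top_fraction <- function(raw, fraction, ids = seq_along(raw)) {
  stopifnot(fraction > 0, fraction <= 1, length(ids) == length(raw))
  n_sel <- ceiling(fraction * length(raw))
  ids[order(raw, ids)][seq_len(n_sel)]
}
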