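#' AdaBoost.R2 regression with tree base learners
#'
#' Drucker's AdaBoost.R2: at each stage a regression tree is fitted on a
#' weighted bootstrap of the training data, losses are rescaled by the
#' largest absolute error (linear loss by default), and sample weights are
#' multiplied by beta^(1 - loss) with beta = err/(1 - err). Boosting stops
#' early when the weighted error reaches 0 (perfect fit) or exceeds 0.5.
#' Predictions are the weighted median of the stage predictions under the
#' stage weights log(1/beta).
#'
#' @param Z numeric feature matrix.
#' @param y numeric response.
#' @param n_estimators maximum number of boosting stages (default 50).
#' @param loss "linear", "square" or "exponential" rescaled loss.
#' @param max_depth depth cap of the rpart base learner (default 3).
#' @return an \code{adaboost_r2} fit (list of trees and stage weights).
#' @export
adaboost_r2 <- function(Z, y, n_estimators = 50L, loss = "linear",
                        max_depth = 3L) {
  n <- length(y)
  df <- as.data.frame(Z)
  colnames(df) <- paste0("m", seq_len(ncol(Z)))
  df$..y <- y
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 2L,
                               minbucket = 1L, xval = 0L)
  w <- rep(1 / n, n)
  trees <- list(); betas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    fit <- rpart::rpart(..y ~ ., data = df[idx, , drop = FALSE],
                        method = "anova", control = ctrl)
    pred <- stats::predict(fit, df)
    abs_err <- abs(y - pred)
    D <- max(abs_err)
    if (D <= 0) { # perfect stage: keep with near-zero beta and stop
      trees[[length(trees) + 1L]] <- fit
      betas <- c(betas, 1e-10)
      break
    }
    L <- switch(loss,
                linear = abs_err / D,
                square = (abs_err / D)^2,
                exponential = 1 - exp(-abs_err / D),
                stop("unknown loss: ", loss))
    err <- sum(w * L)
    if (err >= 0.5) {
      if (length(trees) == 0L) { trees[[1L]] <- fit; betas <- 0.5 / (1 - 0.5) }
      break
    }
    beta <- err / (1 - err)
    trees[[length(trees) + 1L]] <- fit
    betas <- c(betas, max(beta, 1e-10))
    w <- w * beta^(1 - L)
    w <- w / sum(w)
  }
  structure(list(trees = trees, betas = betas,
                 feature_names = colnames(df)[colnames(df) != "..y"]),
            class = "adaboost_r2")
}

#' @rdname adaboost_r2
#' @param fit an \code{adaboost_r2} object.
#' @param Z_new feature matrix to predict.
#' @return numeric predictions (weighted median over stages).
#' @export
predict_adaboost_r2 <- function(fit, Z_new) {
  df <- as.data.frame(Z_new)
  colnames(df) <- fit$feature_names
  P <- vapply(fit$trees, function(t) stats::predict(t, df),
              numeric(nrow(df)))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  wts <- log(1 / fit$betas)
  if (!any(is.finite(wts)) || sum(wts) <= 0) wts <- rep(1, length(fit$betas))
  apply(P, 1L, weighted_median, w = wts)
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}
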