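#' Gaussian kernel of a genotype matrix
#'
#' K_ij = exp(-d2_ij / q) with d2 the squared Euclidean distance between
#' rows. \code{bandwidth = "median"} uses the median off-diagonal squared
#' distance, a scale-free default.
#'
#' @param Z samples x markers matrix, no missing entries.
#' @param bandwidth positive scalar q, or \code{"median"}.
#' @return symmetric positive semidefinite kernel matrix with unit diagonal.
#' @export
gaussian_kernel <- function(Z, bandwidth = "median") {
  if (anyNA(Z)) stop("kernel input must not contain missing values")
  d2 <- as.matrix(stats::dist(Z))^2
  if (identical(bandwidth, "median")) {
    q <- median(d2[upper.tri(d2)])
    if (!is.finite(q) || q <= 0) q <- mean(d2[upper.tri(d2)]) + 1e-8
  } else {
    q <- as.numeric(bandwidth)
  }
  if (q <= 0) stop("bandwidth must be positive")
  K <- exp(-d2 / q)
  attr(K, "bandwidth") <- q
  K
}

#' Radial-basis gamma for support vector regression
#'
#' gamma = 1 / (p * var(Z)) with p the number of loci and var(Z) the variance
#' of all entries of the genotype matrix.
#'
#' @param Z genotype matrix.
#' @return positive scalar.
#' @export
svm_gamma <- function(Z) {
  v <- var(as.vector(Z))
  if (!is.finite(v) || v <= 0) stop("constant genotype matrix: gamma undefined")
  1 / (ncol(Z) * v)
}

#' Model specification with study-default hyperparameters
#'
#' Returns the hyperparameter set of one of the six prediction engines, with
#' every default at the study value: RKHS and BRR run 20,000 MCMC iterations
#' with burn-in 2,000 and thinning 5; SVM uses a radial kernel with
#' gamma = 1/(p var(Z)); RF uses 100 trees, variance splitting, bootstrap,
#' minimum split size 2 and leaf size 1, no depth limit; AB is AdaBoost.R2
#' with a depth-3 tree base learner, linear loss and at most 50 estimators;
#' MLP has one hidden layer of 100 rectified-linear units trained by a
#' quasi-Newton optimizer with L2 strength 0.001. Any field can be
#' overridden through \code{...}.
#'
#' @param name one of "RKHS", "BRR", "SVM", "RF", "AB", "MLP".
#' @param ... overrides for individual hyperparameters.
#' @return a \code{model_spec} list.
#' @export
model_spec <- function(name = c("RKHS", "BRR", "SVM", "RF", "AB", "MLP"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    RKHS = list(n_iter = 20000L, burn_in = 2000L, thin = 5L,
                bandwidth = "median", df = 5, R2 = 0.5,
                fix_variances = FALSE, sigma2_u = NA, sigma2_e = NA,
                include_mu = TRUE),
    BRR = list(n_iter = 20000L, burn_in = 2000L, thin = 5L,
               df = 5, R2 = 0.5,
               fix_variances = FALSE, sigma2_b = NA, sigma2_e = NA,
               include_mu = TRUE),
    SVM = list(kernel = "radial", cost = 1, epsilon = 0.1, gamma = NULL),
    RF = list(num_trees = 100L, min_node_split = 2L, min_bucket = 1L,
              mtry = NULL, bootstrap = TRUE),
    AB = list(n_estimators = 50L, loss = "linear", max_depth = 3L),
    MLP = list(hidden = 100L, l2 = 0.001, maxit = 200L))
  ov <- list(...)
  bad <- setdiff(names(ov), names(defaults))
  if (length(bad)) stop("unknown hyperparameter(s) for ", name, ": ",
                        paste(bad, collapse = ", "))
  spec <- utils::modifyList(defaults, ov)
  spec$name <- name
  class(spec) <- "model_spec"
  spec
}

#' Fit one model and predict held-out families
#'
#' RKHS and BRR are fitted by Gibbs sampling (posterior means over
#' post-burn-in thinned draws); SVM, RF, AB and MLP are deterministic given
#' the seed. Train and test marker columns must be aligned.
#'
#' @param spec a \code{\link{model_spec}}.
#' @param Z_train,Z_test genotype matrices (test may have 0 rows).
#' @param y_train numeric response.
#' @param seed integer seed fixing all stochastic elements.
#' @return numeric vector of predictions for \code{Z_test} rows.
#' @export
fit_predict <- function(spec, Z_train, y_train, Z_test, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"),
            ncol(Z_train) == ncol(Z_test))
  if (sd(y_train) == 0) stop("degenerate response: y_train is constant")
  if (nrow(Z_train) < 3L) stop("need at least 3 training samples")
  set.seed(seed)
  switch(spec$name,
         BRR = predict_brr(spec, Z_train, y_train, Z_test),
         RKHS = predict_rkhs(spec, Z_train, y_train, Z_test),
         SVM = predict_svm(spec, Z_train, y_train, Z_test),
         RF = predict_rf(spec, Z_train, y_train, Z_test, seed),
         AB = predict_ab(spec, Z_train, y_train, Z_test),
         MLP = predict_mlp(spec, Z_train, y_train, Z_test, seed))
}

# hyperprior scales matched to a fraction R2 of the response variance, the
# convention of the standard Bayesian regression packages
brr_scales <- function(y, Z, df, R2) {
  vy <- var(y)
  msx <- sum(apply(Z, 2, var))
  if (msx <= 0) msx <- 1e-8
  list(S_b = vy * R2 / msx * (df + 2) / df,
       S_e = vy * (1 - R2) * (df + 2) / df)
}

predict_brr <- function(spec, Z_train, y_train, Z_test) {
  sc <- brr_scales(y_train, Z_train, spec$df, spec$R2)
  fit <- .brr_gibbs(y_train, Z_train, spec$n_iter, spec$burn_in, spec$thin,
                    spec$df, sc$S_b, spec$df, sc$S_e,
                    isTRUE(spec$fix_variances),
                    ifelse(is.na(spec$sigma2_b), 1, spec$sigma2_b),
                    ifelse(is.na(spec$sigma2_e), 1, spec$sigma2_e),
                    isTRUE(spec$include_mu))
  drop(fit$mu + Z_test %*% fit$beta)
}

#' BRR posterior summaries, for oracle checks
#' @inheritParams fit_predict
#' @return list with posterior-mean beta, mu and variance components.
#' @export
brr_posterior <- function(spec, Z_train, y_train, seed = 1L) {
  set.seed(seed)
  sc <- brr_scales(y_train, Z_train, spec$df, spec$R2)
  .brr_gibbs(y_train, Z_train, spec$n_iter, spec$burn_in, spec$thin,
             spec$df, sc$S_b, spec$df, sc$S_e,
             isTRUE(spec$fix_variances),
             ifelse(is.na(spec$sigma2_b), 1, spec$sigma2_b),
             ifelse(is.na(spec$sigma2_e), 1, spec$sigma2_e),
             isTRUE(spec$include_mu))
}

# RKHS Gibbs in the eigenbasis of K: y = mu + u + e, u ~ N(0, s2u K).
# With K = U D U', the rotated data decouple and every update is O(n).
rkhs_gibbs <- function(y, K, n_iter, burn_in, thin, df, R2,
                       fix_variances = FALSE, s2u0 = NA, s2e0 = NA,
                       include_mu = TRUE) {
  n <- length(y)
  eg <- eigen(K, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-10
  U <- eg$vectors[, keep, drop = FALSE]
  d <- eg$values[keep]
  m <- length(d)
  vy <- var(y)
  S_u <- vy * R2 / mean(diag(K)) * (df + 2) / df
  S_e <- vy * (1 - R2) * (df + 2) / df
  s2u <- if (fix_variances) s2u0 else S_u
  s2e <- if (fix_variances) s2e0 else S_e
  Uty <- drop(crossprod(U, y))
  Ut1 <- drop(crossprod(U, rep(1, n)))
  a <- colMeans(U)
  mu <- if (include_mu) mean(y) else 0
  w <- numeric(m)
  w_mean <- 0; mu_mean <- 0; s2u_mean <- 0; s2e_mean <- 0; kept <- 0L
  for (it in seq_len(n_iter)) {
    yt <- Uty - mu * Ut1
    pv <- 1 / (1 / (s2u * d) + 1 / s2e)
    w <- rnorm(m, pv * yt / s2e, sqrt(pv))
    if (include_mu) mu <- rnorm(1, mean(y) - sum(a * w), sqrt(s2e / n))
    if (!fix_variances) {
      s2u <- (S_u * df + sum(w^2 / d)) / rchisq(1, df + m)
      yc <- y - mu
      ee <- sum(yc^2) - 2 * sum((Uty - mu * Ut1) * w) + sum(w^2)
      s2e <- (S_e * df + max(ee, 0)) / rchisq(1, df + n)
    }
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      w_mean <- w_mean + w; mu_mean <- mu_mean + mu
      s2u_mean <- s2u_mean + s2u; s2e_mean <- s2e_mean + s2e
      kept <- kept + 1L
    }
  }
  w_mean <- w_mean / kept
  list(u = drop(U %*% w_mean), alpha = drop(U %*% (w_mean / d)),
       mu = mu_mean / kept, sigma2_u = s2u_mean / kept,
       sigma2_e = s2e_mean / kept)
}

predict_rkhs <- function(spec, Z_train, y_train, Z_test) {
  Zall <- rbind(Z_train, Z_test)
  K <- gaussian_kernel(Zall, spec$bandwidth)
  ntr <- nrow(Z_train)
  Ktt <- K[seq_len(ntr), seq_len(ntr), drop = FALSE]
  fit <- rkhs_gibbs(y_train, Ktt, spec$n_iter, spec$burn_in, spec$thin,
                    spec$df, spec$R2, isTRUE(spec$fix_variances),
                    spec$sigma2_u, spec$sigma2_e,
                    isTRUE(spec$include_mu))
  if (nrow(Z_test) == 0L) return(numeric(0))
  Kst <- K[ntr + seq_len(nrow(Z_test)), seq_len(ntr), drop = FALSE]
  drop(fit$mu + Kst %*% fit$alpha)
}

#' RKHS posterior on the training kernel, for oracle checks
#' @inheritParams fit_predict
#' @param K precomputed kernel on the training samples.
#' @export
rkhs_posterior <- function(spec, K, y_train, seed = 1L) {
  set.seed(seed)
  rkhs_gibbs(y_train, K, spec$n_iter, spec$burn_in, spec$thin,
             spec$df, spec$R2, isTRUE(spec$fix_variances),
             spec$sigma2_u, spec$sigma2_e, isTRUE(spec$include_mu))
}

predict_svm <- function(spec, Z_train, y_train, Z_test) {
  g <- if (is.null(spec$gamma)) svm_gamma(Z_train) else spec$gamma
  fit <- e1071::svm(x = Z_train, y = y_train, type = "eps-regression",
                    kernel = spec$kernel, gamma = g, cost = spec$cost,
                    epsilon = spec$epsilon, scale = FALSE)
  if (nrow(Z_test) == 0L) return(numeric(0))
  unname(stats::predict(fit, Z_test))
}

predict_rf <- function(spec, Z_train, y_train, Z_test, seed) {
  fit <- ranger_fit(Z_train, y_train, spec, seed, importance = "none",
                    splitrule = "variance", replace = spec$bootstrap)
  if (nrow(Z_test) == 0L) return(numeric(0))
  df_test <- as.data.frame(Z_test)
  colnames(df_test) <- paste0("m", seq_len(ncol(Z_test)))
  stats::predict(fit, data = df_test)$predictions
}

ranger_fit <- function(Z, y, spec, seed, importance, splitrule,
                       replace = TRUE, num_random_splits = 1L) {
  df <- as.data.frame(Z)
  colnames(df) <- paste0("m", seq_len(ncol(Z)))
  df$..y <- y
  ranger::ranger(dependent.variable.name = "..y", data = df,
                 num.trees = spec$num_trees,
                 mtry = if (is.null(spec$mtry)) ncol(Z) else spec$mtry,
                 min.node.size = spec$min_node_split,
                 min.bucket = spec$min_bucket,
                 splitrule = splitrule,
                 num.random.splits = num_random_splits,
                 replace = replace,
                 sample.fraction = 1,
                 importance = importance,
                 num.threads = 1L, seed = seed)
}

predict_ab <- function(spec, Z_train, y_train, Z_test) {
  fit <- adaboost_r2(Z_train, y_train, n_estimators = spec$n_estimators,
                     loss = spec$loss, max_depth = spec$max_depth)
  if (nrow(Z_test) == 0L) return(numeric(0))
  predict_adaboost_r2(fit, Z_test)
}

predict_mlp <- function(spec, Z_train, y_train, Z_test, seed) {
  fit <- mlp_fit(Z_train, y_train, hidden = spec$hidden, l2 = spec$l2,
                 maxit = spec$maxit, seed = seed)
  if (nrow(Z_test) == 0L) return(numeric(0))
  mlp_predict(fit, Z_test)
}

#' Predictive ability and mean squared error
#'
#' PA is the Pearson correlation between observation and prediction; MSE is
#' the mean squared error. A constant prediction (or observation) vector has
#' no defined correlation; PA is then recorded as 0 and flagged, keeping
#' repetition counts balanced for downstream ANOVA.
#'
#' @param y_true,y_pred equal-length numeric vectors (length >= 3).
#' @return list with \code{pa}, \code{mse}, \code{degenerate} flag.
#' @export
prediction_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 3L)
  mse <- mean((y_true - y_pred)^2)
  degenerate <- sd(y_true) == 0 || sd(y_pred) == 0
  pa <- if (degenerate) {
    warning("constant vector: predictive ability recorded as 0")
    0
  } else cor(y_true, y_pred)
  list(pa = pa, mse = mse, degenerate = degenerate)
}

#' Repeated k-fold cross-validation of one model
#'
#' Every repetition draws a fresh random partition into k near-equal folds;
#' each sample is predicted exactly once per repetition from the model
#' trained on the other folds. Per repetition, PA and MSE are computed on
#' the pooled out-of-fold predictions (\code{pa_mode = "pooled"}, the
#' default; \code{"per_fold_mean"} instead averages fold-level metrics).
#'
#' @param spec a \code{\link{model_spec}}.
#' @param Z families x markers matrix.
#' @param y response vector.
#' @param k folds (default 5).
#' @param repetitions number of repeats (default 100).
#' @param seed master seed; repetition r uses a stream derived from it.
#' @param pa_mode "pooled" or "per_fold_mean".
#' @return data.frame with one row per repetition: repetition, pa, mse,
#'   degenerate.
#' @export
cross_validate <- function(spec, Z, y, k = 5L, repetitions = 100L,
                           seed = 1L, pa_mode = c("pooled", "per_fold_mean")) {
  pa_mode <- match.arg(pa_mode)
  n <- length(y)
  if (k > n) stop("k = ", k, " exceeds the number of samples (", n, ")")
  out <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    rep_seed <- (seed + 7919L * r) %% .Machine$integer.max
    set.seed(rep_seed)
    folds <- sample(rep_len(seq_len(k), n))
    pred <- numeric(n)
    fold_pa <- fold_mse <- numeric(k)
    fold_deg <- logical(k)
    for (f in seq_len(k)) {
      te <- folds == f
      p <- fit_predict(spec, Z[!te, , drop = FALSE], y[!te],
                       Z[te, , drop = FALSE],
                       seed = (rep_seed + f) %% .Machine$integer.max)
      pred[te] <- p
      if (pa_mode == "per_fold_mean") {
        m <- suppressWarnings(prediction_metrics(y[te], p))
        fold_pa[f] <- m$pa; fold_mse[f] <- m$mse; fold_deg[f] <- m$degenerate
      }
    }
    if (pa_mode == "pooled") {
      m <- suppressWarnings(prediction_metrics(y, pred))
      out[[r]] <- data.frame(repetition = r, pa = m$pa, mse = m$mse,
                             degenerate = m$degenerate)
    } else {
      out[[r]] <- data.frame(repetition = r, pa = mean(fold_pa),
                             mse = mean(fold_mse),
                             degenerate = any(fold_deg))
    }
  }
  do.call(rbind, out)
}
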