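#' REML variance components for the family mixed model
#'
#' Fits y = Xr + Zg + e, with fixed block (repetition) effects r, random
#' family effects g ~ N(0, sigma2_g I) and residuals e ~ N(0, sigma2_e I),
#' by EM-REML on the mixed-model equations. EM is used because its REML
#' log-likelihood is nondecreasing at every step, which the test suite
#' asserts. Convergence is declared when both variance components change by
#' less than \code{tol} (relative); the fit errors after \code{max_iter}
#' iterations, carrying the last iterate in the condition.
#'
#' Family-mean heritability is h2 = sigma2_g / (sigma2_g + sigma2_e / n~)
#' with n~ the harmonic mean family size. A narrow-sense value is also
#' reported by treating the family variance as \code{wright_coefficient} x
#' additive variance (0.25 is the diploid half-sib coefficient; the
#' autotetraploid value is not settled, so the divisor is a parameter):
#' h2_narrow = (sigma2_g / wright) / (sigma2_g + sigma2_e).
#'
#' @param y numeric response vector.
#' @param family family labels (coercible to factor), >= 2 levels.
#' @param block optional block labels for the fixed repetition effects.
#' @param wright_coefficient relationship coefficient dividing the family
#'   variance for the narrow-sense report (default 0.25).
#' @param tol relative convergence tolerance on the variance components.
#' @param max_iter iteration cap.
#' @return list with sigma2_g, sigma2_e, h2_family, h2_narrow,
#'   wright_coefficient, n_iter, loglik (REML log-likelihood trace) and blup
#'   (family effects).
#' @export
reml_variance_components <- function(y, family, block = NULL,
                                     wright_coefficient = 0.25,
                                     tol = 1e-8, max_iter = 10000L) {
  family <- factor(family)
  if (nlevels(family) < 2L) stop("need at least 2 families")
  n <- length(y)
  if (max(table(family)) < 2L)
    stop("need at least one family with 2 or more observations")
  X <- if (is.null(block)) matrix(1, n, 1L)
       else stats::model.matrix(~ factor(block))
  Z <- stats::model.matrix(~ family - 1L)
  q <- ncol(Z)
  p <- qr(X)$rank
  XtX <- crossprod(X); XtZ <- crossprod(X, Z); ZtZ <- crossprod(Z)
  Xty <- crossprod(X, y); Zty <- crossprod(Z, y)
  yty <- sum(y^2)

  vtot <- var(y)
  sg <- se <- max(vtot / 2, 1e-8)
  ll_trace <- numeric(0)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    lambda <- se / sg
    M <- rbind(cbind(XtX, XtZ), cbind(t(XtZ), ZtZ + diag(lambda, q)))
    Minv <- solve(M)
    sol <- Minv %*% rbind(Xty, Zty)
    b <- sol[seq_len(ncol(X)), , drop = FALSE]
    g <- sol[-seq_len(ncol(X)), , drop = FALSE]
    Cgg <- Minv[-seq_len(ncol(X)), -seq_len(ncol(X)), drop = FALSE]
    se_new <- drop(yty - crossprod(b, Xty) - crossprod(g, Zty)) / (n - p)
    sg_new <- drop(crossprod(g) + se_new * sum(diag(Cgg))) / q
    sg_new <- max(sg_new, 1e-12); se_new <- max(se_new, 1e-12)
    ll_trace <- c(ll_trace, reml_loglik(y, X, family, sg_new, se_new))
    ll_flat <- it > 1L &&
      abs(ll_trace[it] - ll_trace[it - 1L]) < 1e-10 * (abs(ll_trace[it]) + 1)
    if ((abs(sg_new - sg) < tol * (sg + tol) &&
         abs(se_new - se) < tol * (se + tol)) || ll_flat) {
      # component tolerance, or the REML likelihood has reached its fixed
      # point (EM creeps near a zero-variance boundary)
      sg <- sg_new; se <- se_new; conv <- TRUE
      break
    }
    sg <- sg_new; se <- se_new
  }
  if (!conv) {
    cond <- simpleError(sprintf(
      "EM-REML did not converge in %d iterations (last sigma2_g=%.6g, sigma2_e=%.6g)",
      max_iter, sg, se))
    cond$last <- list(sigma2_g = sg, sigma2_e = se)
    stop(cond)
  }
  sizes <- as.numeric(table(family))
  n_harm <- length(sizes) / sum(1 / sizes)
  h2 <- sg / (sg + se / n_harm)
  list(sigma2_g = sg, sigma2_e = se,
       h2_family = min(max(h2, 0), 1),
       h2_narrow = (sg / wright_coefficient) / (sg + se),
       wright_coefficient = wright_coefficient,
       n_iter = it, loglik = ll_trace,
       blup = setNames(drop(g), levels(family)))
}

# REML log-likelihood of the one-random-effect model via the family-block
# structure of V = se I + sg ZZ' (Z'Z diagonal), avoiding any n x n solve.
reml_loglik <- function(y, X, family, sg, se) {
  sizes <- as.numeric(table(family))
  q <- length(sizes)
  n <- length(y)
  d <- sg / (se + sizes * sg)          # per-family shrinkage
  # V^{-1} x = (x - Z diag(d) Z' x) / se
  Vinv <- function(A) {
    ZtA <- rowsum(A, family)
    (A - (d * ZtA)[as.integer(family), , drop = FALSE]) / se
  }
  ViX <- Vinv(X); Viy <- Vinv(matrix(y))
  XtViX <- crossprod(X, ViX)
  XtViy <- crossprod(X, Viy)
  beta <- solve(XtViX, XtViy)
  yPy <- drop(crossprod(y, Viy) - crossprod(XtViy, beta))
  logdetV <- (n - q) * log(se) + sum(log(se + sizes * sg))
  -0.5 * (logdetV + determinant(XtViX, logarithm = TRUE)$modulus + yPy)
}
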