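#' Single-hidden-layer ReLU network for regression
#'
#' One hidden layer of rectified-linear units trained by a limited-memory
#' quasi-Newton optimizer (L-BFGS-B) on the squared-error objective
#' 0.5 * mean((f(x) - y)^2) + 0.5 * l2 * ||W||^2 / n, with Glorot-uniform
#' weight initialization. Gradients are analytic.
#'
#' @param Z features matrix (samples x p).
#' @param y numeric response.
#' @param hidden hidden units (default 100).
#' @param l2 L2 penalty strength on the weight matrices (default 0.001).
#' @param maxit optimizer iteration cap (default 200).
#' @param seed integer seed for the weight initialization.
#' @return an \code{mlp_fit} list (weights and dimensions).
#' @export
mlp_fit <- function(Z, y, hidden = 100L, l2 = 0.001, maxit = 200L,
                    seed = 1L) {
  p <- ncol(Z); h <- hidden; n <- nrow(Z)
  set.seed(seed)
  init <- function(fan_in, fan_out, m) {
    b <- sqrt(6 / (fan_in + fan_out))
    runif(m, -b, b)
  }
  theta0 <- c(init(p, h, p * h), rep(0, h), init(h, 1, h), 0)
  unpack <- function(theta) {
    W1 <- matrix(theta[seq_len(p * h)], p, h)
    b1 <- theta[p * h + seq_len(h)]
    W2 <- theta[p * h + h + seq_len(h)]
    b2 <- theta[length(theta)]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  fwd <- function(par, X) {
    A <- sweep(X %*% par$W1, 2, par$b1, `+`)
    H <- pmax(A, 0)
    list(A = A, H = H, pred = drop(H %*% par$W2) + par$b2)
  }
  obj <- function(theta) {
    par <- unpack(theta)
    f <- fwd(par, Z)
    r <- f$pred - y
    0.5 * mean(r^2) + 0.5 * l2 * (sum(par$W1^2) + sum(par$W2^2)) / n
  }
  grad <- function(theta) {
    par <- unpack(theta)
    f <- fwd(par, Z)
    r <- (f$pred - y) / n
    gW2 <- drop(crossprod(f$H, r)) + l2 * par$W2 / n
    gb2 <- sum(r)
    dH <- outer(r, par$W2) * (f$A > 0)
    gW1 <- crossprod(Z, dH) + l2 * par$W1 / n
    gb1 <- colSums(dH)
    c(as.vector(gW1), gb1, gW2, gb2)
  }
  opt <- stats::optim(theta0, obj, grad, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  structure(c(unpack(opt$par), list(p = p, hidden = h, value = opt$value)),
            class = "mlp_fit")
}

#' @rdname mlp_fit
#' @param fit an \code{mlp_fit} object.
#' @param Z_new feature matrix to predict.
#' @export
mlp_predict <- function(fit, Z_new) {
  H <- pmax(sweep(Z_new %*% fit$W1, 2, fit$b1, `+`), 0)
  drop(H %*% fit$W2) + fit$b2
}
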