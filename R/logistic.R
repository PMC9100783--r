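# L2-regularized logistic regression.
#
# Minimizes sum_i log(1 + exp(-y_i * w'x_i)) + lambda * w'w with y coded
# +/-1, via L-BFGS-B on the smooth convex objective with analytic
# gradient. The intercept is included and unpenalized by default (standard
# practice; the objective as published shows no intercept, so a switch is
# provided). lambda = 1 is the analysis default throughout.

logit_loss <- function(t) {
  # stable log(1 + exp(-t))
  ifelse(t > 0, log1p(exp(-t)), -t + log1p(exp(t)))
}

#' Fit L2-regularized logistic regression
#'
#' @param X numeric matrix, samples x features.
#' @param y labels; 0/1 or -1/+1 (recoded to -1/+1 internally).
#' @param lambda L2 penalty weight on the coefficient vector (default 1).
#' @param intercept include an unpenalized intercept (default `TRUE`).
#' @param maxit L-BFGS-B iteration cap.
#' @param tol relative convergence tolerance (passed as `factr * eps`).
#' @return An `l2logit` object with `coefficients` (intercept first when
#'   present), `lambda`, `objective`, `converged`.
#' @examples
#' X <- matrix(c(-1, -1, 1, 1), ncol = 1)
#' fit <- fit_logistic_l2(X, c(0, 0, 1, 1))
#' coef(fit)
#' @export
fit_logistic_l2 <- function(X, y, lambda = 1, intercept = TRUE,
                            maxit = 200L, tol = 1e-10) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite values in X")
  if (all(y %in% c(0, 1))) y <- 2 * y - 1
  if (!all(y %in% c(-1, 1))) stop("labels must be 0/1 or -1/+1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  stopifnot(lambda > 0, nrow(X) == length(y))
  n <- nrow(X); p <- ncol(X)

  obj <- function(par) {
    b0 <- if (intercept) par[1] else 0
    w <- if (intercept) par[-1] else par
    eta <- drop(X %*% w) + b0
    sum(logit_loss(y * eta)) + lambda * sum(w * w)
  }
  grad <- function(par) {
    b0 <- if (intercept) par[1] else 0
    w <- if (intercept) par[-1] else par
    eta <- drop(X %*% w) + b0
    # d/dt log(1+exp(-t)) = -sigma(-t)
    s <- -stats::plogis(-y * eta) * y
    gw <- drop(crossprod(X, s)) + 2 * lambda * w
    if (intercept) c(sum(s), gw) else gw
  }
  par0 <- numeric(p + intercept)
  fit <- optim(par0, fn = obj, gr = grad, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = tol / .Machine$double.eps))
  coefs <- fit$par
  names(coefs) <- c(if (intercept) "(Intercept)",
                    colnames(X) %||% paste0("x", seq_len(p)))
  structure(list(coefficients = coefs, lambda = lambda,
                 intercept = intercept, objective = fit$value,
                 converged = fit$convergence == 0, n = n, p = p),
            class = "l2logit")
}

#' @export
print.l2logit <- function(x, ...) {
  cat(sprintf(
    "L2 logistic regression: %d features, lambda = %g, objective = %.4f\n",
    x$p, x$lambda, x$objective))
  invisible(x)
}

#' @export
coef.l2logit <- function(object, ...) object$coefficients

#' Predict from an L2 logistic fit
#' @param object an `l2logit` fit.
#' @param newdata matrix of features.
#' @param type `"class"` (0/1), `"prob"` (P(y = 1)) or `"link"`.
#' @param ... unused.
#' @export
predict.l2logit <- function(object, newdata,
                            type = c("class", "prob", "link"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  w <- object$coefficients
  b0 <- if (object$intercept) w[1] else 0
  beta <- if (object$intercept) w[-1] else w
  eta <- drop(newdata %*% beta) + b0
  switch(type,
         link = eta,
         prob = stats::plogis(eta),
         class = as.integer(eta > 0))
}
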