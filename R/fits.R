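#' Fit the extinction surface (binomial GLM)
#'
#' Models per-replicate extinction (0/1) as a logistic function of the
#' sampled epidemiological parameters, `extinct ~ gamma + S + theta`.
#' Predictors that were held fixed in the experiment (zero variance) are
#' dropped from the formula. If every replicate (or none) went extinct the
#' fit is degenerate and only the overall rate is reported. If the GLM shows
#' complete separation (fitted probabilities collapsing to 0/1), the model is
#' refitted with a small ridge penalty and flagged `penalized`.
#'
#' @param rows Data frame with logical/0-1 column `extinct` and numeric
#'   predictor columns (any of `gamma`, `S`, `theta`).
#' @param ranges Named list of `c(lo, hi)` per predictor, used for the
#'   prediction curves; defaults to the standard sampling ranges.
#' @param n_curve Number of grid points per prediction curve.
#' @return An `srdm_fit` object: coefficients with standard errors,
#'   per-parameter prediction curves (focal parameter varied over its range,
#'   the others held at their range midpoints), and `degenerate`,
#'   `separation`, `penalized` flags.
#' @export
fit_extinction_model <- function(rows, ranges = param_ranges(),
                                 n_curve = 101) {
  y <- as.integer(rows$extinct)
  vars <- intersect(c("gamma", "S", "theta"), names(rows))
  vars <- vars[vapply(vars, function(v) stats::var(rows[[v]]) > 0, logical(1))]
  out <- list(kind = "extinction", n = length(y), rate = mean(y),
              vars = vars, ranges = ranges[names(ranges) %in% vars],
              degenerate = FALSE, separation = FALSE, penalized = FALSE)
  if (length(unique(y)) < 2 || length(vars) == 0) {
    out$degenerate <- TRUE
    out$coefficients <- data.frame(term = character(), estimate = numeric(),
                                   std_error = numeric())
    out$curves <- list()
    return(structure(out, class = "srdm_fit"))
  }
  dat <- rows[vars]
  dat$.y <- y
  form <- stats::as.formula(paste(".y ~", paste(vars, collapse = " + ")))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged || any(abs(stats::coef(fit)) > 20)) {
    out$separation <- TRUE
    out$penalized <- TRUE
    rf <- ridge_logistic(cbind(1, as.matrix(dat[vars])), y)
    beta <- rf$beta
    se <- rf$se
  } else {
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
  }
  names(beta) <- names(se) <- c("(Intercept)", vars)
  out$coefficients <- data.frame(term = names(beta), estimate = unname(beta),
                                 std_error = unname(se))
  out$curves <- prediction_curves(beta, vars, out$ranges, n_curve,
                                  link_inv = stats::plogis)
  structure(out, class = "srdm_fit")
}

# Ridge-penalised logistic regression by IRLS; a plain, always-finite
# fallback for separated data. X includes the intercept column; the penalty
# is applied to the slope terms only.
ridge_logistic <- function(X, y, lambda = 1, maxit = 100, tol = 1e-9) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, se = sqrt(diag(solve(H))))
}

#' Fit the mean-prevalence surface (linear model)
#'
#' Ordinary least squares of per-replicate mean infection prevalence on the
#' sampled parameters, `mean_prevalence ~ gamma + S + theta`, with
#' per-parameter prediction curves.
#'
#' @inheritParams fit_extinction_model
#' @return An `srdm_fit` object.
#' @export
fit_prevalence_model <- function(rows, ranges = param_ranges(),
                                 n_curve = 101) {
  vars <- intersect(c("gamma", "S", "theta"), names(rows))
  vars <- vars[vapply(vars, function(v) stats::var(rows[[v]]) > 0, logical(1))]
  out <- list(kind = "prevalence", n = nrow(rows),
              rate = mean(rows$mean_prevalence), vars = vars,
              ranges = ranges[names(ranges) %in% vars],
              degenerate = length(vars) == 0, separation = FALSE,
              penalized = FALSE)
  if (out$degenerate) {
    out$coefficients <- data.frame(term = character(), estimate = numeric(),
                                   std_error = numeric())
    out$curves <- list()
    return(structure(out, class = "srdm_fit"))
  }
  form <- stats::as.formula(
    paste("mean_prevalence ~", paste(vars, collapse = " + ")))
  fit <- stats::lm(form, data = rows)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  out$coefficients <- data.frame(term = names(beta), estimate = unname(beta),
                                 std_error = unname(se))
  out$curves <- prediction_curves(beta, vars, out$ranges, n_curve,
                                  link_inv = identity)
  structure(out, class = "srdm_fit")
}

# Model-predicted curves: vary the focal parameter over its range, hold the
# others at their range midpoints.
prediction_curves <- function(beta, vars, ranges, n_curve, link_inv) {
  mids <- vapply(ranges, mean, numeric(1))
  curves <- list()
  for (v in vars) {
    grid <- seq(ranges[[v]][1], ranges[[v]][2], length.out = n_curve)
    newdat <- as.data.frame(lapply(mids, rep, n_curve))
    newdat[[v]] <- grid
    X <- cbind(1, as.matrix(newdat[vars]))
    curves[[v]] <- data.frame(value = grid,
                              predicted = link_inv(drop(X %*% beta)))
  }
  curves
}

#' @export
print.srdm_fit <- function(x, ...) {
  cat(sprintf("srdm_fit [%s], n = %d, mean response = %.4f\n",
              x$kind, x$n, x$rate))
  if (x$degenerate) {
    cat("  degenerate response (no variation); no coefficients fitted\n")
  } else {
    if (x$penalized) cat("  separation detected: ridge-penalised fit\n")
    print(x$coefficients, row.names = FALSE)
  }
  invisible(x)
}

#' Fourth-degree polynomial smoother
#'
#' Least-squares fit of `y` on a 4th-degree polynomial in `x`, used to
#' summarise growth-rate relationships graphically. The predictor is centred
#' and scaled internally for numerical stability; predictions and derivatives
#' are reported on the original scale.
#'
#' @param x,y Numeric vectors of equal length (>= 6 points).
#' @return An object of class `srdm_poly`.
#' @seealso [poly_predict()], [poly_slope()]
#' @export
fit_growth_polynomial <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 6) stop("need at least 6 finite points", call. = FALSE)
  mu <- mean(x)
  sc <- stats::sd(x)
  if (sc == 0) stop("'x' is constant; cannot fit a polynomial", call. = FALSE)
  z <- (x - mu) / sc
  fit <- stats::lm(y ~ z + I(z^2) + I(z^3) + I(z^4))
  structure(list(fit = fit, mu = mu, sc = sc, n = length(x),
                 xrange = range(x)),
            class = "srdm_poly")
}

#' Evaluate a fitted polynomial smoother
#' @param object An `srdm_poly` from [fit_growth_polynomial()].
#' @param x Points (original scale) at which to evaluate the fitted curve.
#' @return Numeric vector of fitted values.
#' @export
poly_predict <- function(object, x) {
  z <- (x - object$mu) / object$sc
  unname(stats::predict(object$fit, newdata = data.frame(z = z)))
}

#' Slope (and standard error) of a fitted polynomial smoother
#'
#' Analytic first derivative of the fitted 4th-degree polynomial, with a
#' delta-method standard error from the coefficient covariance matrix. Used
#' to test for negative growth-rate relationships and for the absence of a
#' positive-slope (Allee-type) region at low abundance.
#'
#' @param object An `srdm_poly` from [fit_growth_polynomial()].
#' @param x Points (original scale) at which to evaluate the derivative.
#' @return Data frame with columns `x`, `slope` and `se`.
#' @export
poly_slope <- function(object, x) {
  z <- (x - object$mu) / object$sc
  b <- stats::coef(object$fit)
  V <- stats::vcov(object$fit)
  # d/dx = (b1 + 2 b2 z + 3 b3 z^2 + 4 b4 z^3) / sc
  G <- cbind(0, 1, 2 * z, 3 * z^2, 4 * z^3) / object$sc
  slope <- drop(G %*% b)
  se <- sqrt(rowSums((G %*% V) * G))
  data.frame(x = x, slope = slope, se = se)
}
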