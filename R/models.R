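# Fraction-versus-optical-property curve models: a two-parameter logistic for
# the monotone stroma and adipose responses and a three-parameter Gaussian for
# the peaked epithelium response, fitted by bounded multi-start nonlinear
# least squares.

#' Two-parameter logistic curve
#'
#' `1 / (1 + exp((x - c) / w))`. With `w > 0` the curve decreases in `x`, with
#' `w < 0` it increases; output is in (0, 1) with value 0.5 at `x = c`.
#'
#' @param x Property value(s).
#' @param c Center (half-maximum location).
#' @param w Width; nonzero. Sign sets direction.
#' @return Fraction value(s) in (0, 1).
#' @export
logistic2 <- function(x, c, w) {
  if (w == 0) stop("logistic width w must be nonzero")
  1 / (1 + exp((x - c) / w))
}

#' Three-parameter Gaussian curve
#'
#' `a * exp(-(x - c)^2 / (2 w^2))`: a peak of height `a` at `x = c`, symmetric,
#' with scale `w`. Models the epithelium volume fraction, which is diminished
#' for both fat and fibroglandular tissue but at opposite property extremes.
#'
#' @param x Property value(s).
#' @param a Peak height (> 0).
#' @param c Peak location.
#' @param w Width (> 0).
#' @return Fraction value(s) in (0, a].
#' @export
gaussian3 <- function(x, a, c, w) {
  if (w <= 0) stop("gaussian width w must be positive")
  if (a <= 0) stop("gaussian amplitude a must be positive")
  a * exp(-(x - c)^2 / (2 * w^2))
}

# Curve value and per-parameter gradient for a parameter vector, without the
# argument checks (used inside the optimizer where bounds enforce validity).
model_eval <- function(family, x, par) {
  if (family == "logistic2") {
    z <- (x - par[1]) / par[2]
    1 / (1 + exp(z))
  } else {
    z <- (x - par[2]) / par[3]
    par[1] * exp(-z^2 / 2)
  }
}

model_grad <- function(family, x, par) {
  if (family == "logistic2") {
    z <- (x - par[1]) / par[2]
    f <- 1 / (1 + exp(z))
    g <- f * (1 - f)
    cbind(c = g / par[2], w = g * z / par[2])
  } else {
    z <- (x - par[2]) / par[3]
    e <- exp(-z^2 / 2)
    f <- par[1] * e
    cbind(a = e, c = f * z / par[3], w = f * z^2 / par[3])
  }
}

# Multi-start grid per the fixed scheme: c over 5 quantiles of x, |w| over
# {0.05, 0.2, 1} * range(x) (both signs for the logistic), a over
# {0.25, 0.5, 1}. Fixed order; ties broken by the first minimum.
model_starts <- function(family, x) {
  cs <- stats::quantile(x, probs = c(0.1, 0.3, 0.5, 0.7, 0.9), names = FALSE)
  r <- max(diff(range(x)), 1e-3)
  ws <- c(0.05, 0.2, 1) * r
  starts <- list()
  if (family == "logistic2") {
    for (s in c(1, -1)) for (c0 in cs) for (w0 in ws)
      starts[[length(starts) + 1L]] <- c(c = c0, w = s * w0)
  } else {
    for (a0 in c(0.25, 0.5, 1)) for (c0 in cs) for (w0 in ws)
      starts[[length(starts) + 1L]] <- c(a = a0, c = c0, w = w0)
  }
  starts
}

#' Fit a fraction-versus-property curve
#'
#' Bounded nonlinear least squares over specimen ROI means (one point per
#' specimen): minimizes the residual sum of squares with `optim(method =
#' "L-BFGS-B")` and analytic gradients, restarted over a fixed grid of
#' initializations; the lowest-SSE solution wins (first minimum on ties).
#' Bounds: `a` in (0, 1.5], `|w|` in `[1e-4, 10 * range(x)]`, `c` within the
#' data range extended by one range on each side.
#'
#' @param x Specimen property means (finite, length > number of parameters).
#' @param y Specimen fraction means in `[0, 1]`.
#' @param family `"logistic2"` (stroma, adipose) or `"gaussian3"` (epithelium).
#' @param property_name,fraction_name Optional labels stored in the model.
#' @return A `scatter_model`: `family`, labels, `params`, `param_cov`, `rmse`
#'   (`sqrt(SSE / n)`), `r2_adj`, `sse`, `n_fit`, and the fitted `x_range`.
#' @export
fit_scatter_model <- function(x, y, family = c("logistic2", "gaussian3"),
                              property_name = NA_character_,
                              fraction_name = NA_character_) {
  family <- match.arg(family)
  x <- as.numeric(x); y <- as.numeric(y)
  p <- if (family == "logistic2") 2L else 3L
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)))
    stop("x and y must be finite")
  if (any(y < 0 | y > 1)) stop("y must be fractions in [0, 1]")
  n <- length(x)
  if (n <= p) stop("need more points than parameters")
  if (stats::sd(y) == 0) stop("no curvature: y is constant")

  r <- max(diff(range(x)), 1e-3)
  c_lo <- min(x) - r; c_hi <- max(x) + r
  w_lo <- 1e-4; w_hi <- 10 * r
  sse_fn <- function(par) {
    res <- y - model_eval(family, x, par)
    sum(res^2)
  }
  sse_gr <- function(par) {
    res <- y - model_eval(family, x, par)
    -2 * colSums(res * model_grad(family, x, par))
  }

  best <- NULL
  for (st in model_starts(family, x)) {
    if (family == "logistic2") {
      sgn <- sign(st["w"])
      lower <- c(c_lo, if (sgn > 0) w_lo else -w_hi)
      upper <- c(c_hi, if (sgn > 0) w_hi else -w_lo)
    } else {
      lower <- c(1e-6, c_lo, w_lo)
      upper <- c(1.5, c_hi, w_hi)
    }
    fit <- tryCatch(
      stats::optim(st, sse_fn, sse_gr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("fit failed: no start converged")

  par <- best$par
  sse <- best$value
  sst <- sum((y - mean(y))^2)
  rmse <- sqrt(sse / n)
  r2_adj <- 1 - (sse / (n - p)) / (sst / (n - 1))
  J <- model_grad(family, x, par)
  jtj <- crossprod(J)
  cov <- tryCatch(solve(jtj) * sse / (n - p), error = function(e) {
    matrix(NA_real_, p, p)
  })
  dimnames(cov) <- list(names(par), names(par))
  structure(
    list(family = family, property_name = property_name,
         fraction_name = fraction_name, params = par, param_cov = cov,
         rmse = rmse, r2_adj = r2_adj, sse = sse, n_fit = n,
         x_range = range(x)),
    class = "scatter_model")
}

#' @export
print.scatter_model <- function(x, ...) {
  cat(sprintf("scatter_model %s: %s ~ %s\n", x$family,
              x$fraction_name, x$property_name))
  cat("  params:", paste(sprintf("%s = %.4g", names(x$params), x$params),
                         collapse = ", "), "\n")
  cat(sprintf("  rmse = %.4g, adj R^2 = %.4g, n = %d\n",
              x$rmse, x$r2_adj, x$n_fit))
  invisible(x)
}

#' @export
predict.scatter_model <- function(object, newdata, ...) {
  model_eval(object$family, as.numeric(newdata), object$params)
}

#' Pointwise prediction interval for a fitted curve
#'
#' Linearized (delta-method) interval: `f(x) +/- t_{n-p} * sqrt(sigma^2 + g'
#' Cov g)` with `sigma^2 = SSE / (n - p)` and `g` the parameter gradient of the
#' curve at `x`. Endpoints are clipped to `[0, 1]`; points outside the fitted
#' property range are flagged as extrapolation but still returned.
#'
#' @param model A fitted `scatter_model`.
#' @param x Property value(s).
#' @param level Coverage in (0, 1); default 0.95.
#' @return `data.frame` with `x`, `fit`, `lower`, `upper`, `extrapolated`.
#' @export
prediction_interval <- function(model, x, level = 0.95) {
  stopifnot(inherits(model, "scatter_model"))
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  x <- as.numeric(x)
  p <- length(model$params)
  dfres <- model$n_fit - p
  sigma2 <- model$sse / dfres
  g <- model_grad(model$family, x, model$params)
  var_fit <- if (anyNA(model$param_cov)) 0 else
    rowSums((g %*% model$param_cov) * g)
  se <- sqrt(pmax(sigma2 + var_fit, 0))
  tq <- stats::qt((1 + level) / 2, df = dfres)
  fit <- model_eval(model$family, x, model$params)
  data.frame(
    x = x, fit = fit,
    lower = pmax(0, fit - tq * se),
    upper = pmin(1, fit + tq * se),
    extrapolated = x < model$x_range[1] | x > model$x_range[2])
}

#' Goodness of fit of a curve on given data
#'
#' @param model A fitted `scatter_model`.
#' @param x,y Data to evaluate on (need not be the fitting data).
#' @return List with `rmse = sqrt(SSE / n)` and degree-of-freedom adjusted
#'   `r2_adj = 1 - (SSE / (n - p)) / (SST / (n - 1))`.
#' @export
evaluate_fit <- function(model, x, y) {
  stopifnot(inherits(model, "scatter_model"))
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  p <- length(model$params)
  if (n <= p) stop("need more points than parameters")
  res <- y - model_eval(model$family, x, model$params)
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  list(rmse = sqrt(sse / n),
       r2_adj = 1 - (sse / (n - p)) / (sst / (n - 1)))
}
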