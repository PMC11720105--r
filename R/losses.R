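#' Wing loss hyperparameters
#'
#' The Wing loss is logarithmic for small errors and linear beyond a width
#' `omega`, joined continuously by the constant
#' C = omega - omega * log(1 + omega / epsilon). The log region keeps the
#' loss sensitive to small element errors (critical for sub-degree
#' orientation accuracy) while the linear tail is robust to outliers.
#'
#' @param omega Width of the nonlinear region (> 0), in matrix-element
#'   units; default 10.
#' @param epsilon Curvature parameter (> 0); default 3.
#' @return List of class `WingParams` with `omega`, `epsilon` and the cached
#'   continuity constant `C`.
#' @export
wingParams <- function(omega = 10, epsilon = 3) {
  if (omega <= 0 || epsilon <= 0)
    stop("wingParams: omega and epsilon must be > 0")
  structure(list(omega = omega, epsilon = epsilon,
                 C = omega - omega * log(1 + omega / epsilon)),
            class = "WingParams")
}

.wingElem <- function(d, p) {
  ifelse(d < p$omega, p$omega * log1p(d / p$epsilon), d - p$C)
}

#' Wing loss between a raw matrix and a target rotation
#'
#' Applied elementwise to the nine matrix entries with d = |x - y|:
#' omega * log(1 + d / epsilon) when d < omega, and d - C otherwise; the
#' mean over the nine elements is returned, keeping the hyperparameters
#' scale-free in the matrix size.
#'
#' @param x Predicted 3 x 3 matrix (raw network output).
#' @param y Ground-truth 3 x 3 rotation matrix.
#' @param params A [wingParams()] list.
#' @return Scalar loss.
#' @export
wingLoss <- function(x, y, params = wingParams()) {
  stopifnot(inherits(params, "WingParams"),
            all(dim(x) == c(3, 3)), all(dim(y) == c(3, 3)))
  mean(.wingElem(abs(x - y), params))
}

#' Comparison losses: MAE, MSE and Huber
#'
#' Elementwise mean over the nine matrix entries of |d|, d^2, or the Huber
#' form (quadratic d^2/2 below `delta`, linear delta * (|d| - delta/2)
#' above).
#'
#' @param x,y Predicted and ground-truth 3 x 3 matrices.
#' @param kind One of `"mae"`, `"mse"`, `"huber"`.
#' @param delta Huber threshold (default 1).
#' @return Scalar loss.
#' @export
comparisonLoss <- function(x, y, kind = c("mae", "mse", "huber"), delta = 1) {
  kind <- match.arg(kind)
  d <- abs(x - y)
  switch(kind,
         mae = mean(d),
         mse = mean(d^2),
         huber = mean(ifelse(d <= delta, d^2 / 2, delta * (d - delta / 2))))
}

# Loss value and gradient wrt x, dispatched on a loss config list
# (kind, omega, epsilon, delta); used by the training loop.
.lossValueGrad <- function(x, y, lossCfg) {
  diff <- x - y
  d <- abs(diff)
  sgn <- sign(diff)
  if (lossCfg$kind == "wing") {
    p <- wingParams(lossCfg$omega, lossCfg$epsilon)
    value <- mean(.wingElem(d, p))
    grad <- ifelse(d < p$omega, p$omega / (p$epsilon + d), 1) * sgn / 9
  } else if (lossCfg$kind == "mae") {
    value <- mean(d)
    grad <- sgn / 9
  } else if (lossCfg$kind == "mse") {
    value <- mean(d^2)
    grad <- 2 * diff / 9
  } else if (lossCfg$kind == "huber") {
    dl <- lossCfg$delta
    value <- mean(ifelse(d <= dl, d^2 / 2, dl * (d - dl / 2)))
    grad <- ifelse(d <= dl, diff, dl * sgn) / 9
  } else stop("unknown loss kind: ", lossCfg$kind)
  list(value = value, grad = grad)
}
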