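## Platt scaling: map SVM decision values to posterior probabilities via
## the sigmoid P(y=1 | f) = 1/(1 + exp(A f + B)), with (A, B) fitted by
## minimizing cross-entropy against smoothed target probabilities
## t+ = (N+ + 1)/(N+ + 2) and t- = 1/(N- + 2).

#' Smoothed Platt target probabilities
#'
#' @param nPos,nNeg Numbers of positive and negative training samples.
#' @return Named numeric vector `c(tPlus, tMinus)` with
#'   `tPlus = (nPos + 1)/(nPos + 2)` and `tMinus = 1/(nNeg + 2)`.
#' @export
#' @examples
#' plattTargets(8, 8) # 0.9, 0.1
plattTargets <- function(nPos, nNeg) {
  mgsAssert(nPos >= 0 && nNeg >= 0, "counts must be non-negative")
  c(tPlus = (nPos + 1) / (nPos + 2), tMinus = 1 / (nNeg + 2))
}

log1pexp <- function(z) {
  # numerically stable log(1 + exp(z))
  out <- z
  small <- z < 35
  out[small] <- log1p(exp(z[small]))
  out
}

#' Fit a Platt sigmoid to decision values
#'
#' Minimizes the cross-entropy between the sigmoid posterior
#' `1/(1 + exp(A f + B))` and the smoothed targets derived from the class
#' counts ([plattTargets()]).  Optimization is quasi-Newton (BFGS) with
#' analytic gradients from the standard initialization
#' `A = 0, B = log((N- + 1)/(N+ + 1))`.
#'
#' @param f Numeric vector of decision values.
#' @param labels Binary vector; the positive class is the larger of the two
#'   values (use 0/1).
#' @return A [PlattModel-class].
#' @export
fitPlatt <- function(f, labels) {
  lev <- sort(unique(labels))
  mgsAssert(length(lev) == 2L, "both classes must be present")
  pos <- labels == lev[2L]
  nPos <- sum(pos); nNeg <- sum(!pos)
  tg <- plattTargets(nPos, nNeg)
  t <- ifelse(pos, tg["tPlus"], tg["tMinus"])
  obj <- function(par) {
    z <- par[1L] * f + par[2L]
    sum(log1pexp(z) - (1 - t) * z)
  }
  grad <- function(par) {
    z <- par[1L] * f + par[2L]
    d <- t - plogis(-z) # t_i - p_i
    c(sum(d * f), sum(d))
  }
  init <- c(0, log((nNeg + 1) / (nPos + 1)))
  fit <- optim(init, obj, grad, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-12))
  new("PlattModel", A = fit$par[1L], B = fit$par[2L])
}

#' Posterior probability from a Platt sigmoid
#'
#' @param model A [PlattModel-class].
#' @param f Numeric vector of decision values.
#' @return Probabilities strictly inside `(0, 1)`.
#' @export
plattPosterior <- function(model, f) {
  p <- plogis(-(model@A * f + model@B))
  pmin(pmax(p, .Machine$double.eps), 1 - .Machine$double.eps)
}
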