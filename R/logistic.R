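# Binomial logistic regression used for propensity scoring.

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit of a binary outcome on a covariate
#' matrix (an intercept is added automatically), computed by IRLS through
#' \code{stats::glm.fit} with a deviance convergence tolerance of 1e-8 and
#' at most 100 iterations.  Complete or quasi-complete separation is
#' detected from fitted probabilities degenerating to 0/1; a warning is
#' raised and coefficients are capped at +/- 15 on the logit scale so that
#' downstream scores stay usable.
#'
#' @param covariate_matrix Numeric matrix or data.frame of covariates,
#'   one row per observation (no intercept column).
#' @param binary_outcome Vector of 0/1 outcomes, one per row.
#' @param tol Convergence tolerance on the relative deviance change.
#' @param max_iter Maximum IRLS iterations.
#' @return List with \code{coefficients} (named, intercept first),
#'   \code{fitted} probabilities in (0, 1), \code{iterations},
#'   \code{converged} and \code{separation} flags.
#' @examples
#' set.seed(1)
#' x <- rnorm(500)
#' y <- rbinom(500, 1, plogis(-1 + 2 * x))
#' logistic_fit(cbind(x = x), y)$coefficients
#' @export
logistic_fit <- function(covariate_matrix, binary_outcome,
                         tol = 1e-8, max_iter = 100) {
  x <- as.matrix(covariate_matrix)
  if (!is.numeric(x)) stop("covariates must be numeric")
  y <- as.numeric(binary_outcome)
  if (nrow(x) != length(y)) stop("covariate rows must match outcome length")
  if (!all(y %in% base::c(0, 1))) stop("outcome must be binary 0/1")
  if (any(apply(x, 2, function(col) all(col == 0)))) {
    stop("constant-zero covariate column")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  xm <- cbind("(Intercept)" = 1, x)

  fit <- suppressWarnings(
    stats::glm.fit(xm, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = tol,
                                                maxit = max_iter))
  )
  if (!fit$converged) {
    stop(sprintf("IRLS did not converge in %d iterations", fit$iter))
  }
  coefs <- fit$coefficients
  fitted <- fit$fitted.values
  separation <- any(fitted > 1 - 1e-7) || any(fitted < 1e-7) ||
    any(abs(coefs) > 15)
  if (separation) {
    warning("complete or quasi-complete separation detected; ",
            "coefficients capped at +/- 15")
    coefs <- pmin(pmax(coefs, -15), 15)
    fitted <- stats::plogis(drop(xm %*% coefs))
  }
  eps <- .Machine$double.eps
  fitted <- pmin(pmax(fitted, eps), 1 - eps)
  list(coefficients = coefs, fitted = fitted,
       iterations = fit$iter, converged = fit$converged,
       separation = separation)
}
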