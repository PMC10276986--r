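# Step-up multiple testing procedures and the covariate weight family.

# Step-up count on (possibly weighted) p-values.  `q` may exceed 1 or be Inf
# (zero-weight markers); `m` is the number of hypotheses used in the
# threshold i * alpha / m, which may differ from length(q) only never here.
stepup_rejected <- function(q, alpha, m = length(q)) {
  qs <- sort(q)
  k <- max(0L, which(qs <= seq_len(m) * alpha / m))
  if (k == 0L) {
    rep(FALSE, m)
  } else {
    # all values tied with q_(k) satisfy their own thresholds too, so
    # rejecting q <= q_(k) returns exactly the step-up set
    q <= qs[k]
  }
}

new_rejection_result <- function(rejected, alpha, weights = NULL) {
  structure(
    list(
      rejected = rejected,
      k = sum(rejected),
      alpha = alpha,
      weights_used = weights
    ),
    class = "rejection_result"
  )
}

#' @export
print.rejection_result <- function(x, ...) {
  w <- if (is.null(x$weights_used)) "unit weights" else "covariate weights"
  cat(sprintf(
    "<rejection_result> %d of %d hypotheses rejected at alpha = %g (%s)\n",
    x$k, length(x$rejected), x$alpha, w
  ))
  invisible(x)
}

check_pvalues <- function(p, arg = "p") {
  if (length(p) == 0L) {
    abort(sprintf("`%s` must be non-empty.", arg))
  }
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort(sprintf("`%s` must contain p-values in [0, 1] with no missing values.", arg))
  }
  invisible(p)
}

#' Benjamini-Hochberg step-up procedure
#'
#' Rejects the k smallest p-values where k is the largest index i with
#' \eqn{p_{(i)} \le i\alpha/m}.  Under independence (or PRDS) this controls
#' the false discovery rate at level \eqn{\pi_0 \alpha \le \alpha}.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param alpha Nominal FDR level in (0, 1).
#' @return A `rejection_result`: list with `rejected` (logical per
#'   hypothesis, in input order), `k` (number of rejections), `alpha`, and
#'   `weights_used` (`NULL`, i.e. unit weights).
#' @examples
#' bh_stepup(c(0.001, 0.008, 0.039, 0.041, 0.2), alpha = 0.05)
#' @seealso [weighted_bh()], [qvalue_procedure()], [wbha()]
#' @export
bh_stepup <- function(p, alpha = 0.05) {
  check_pvalues(p)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  new_rejection_result(stepup_rejected(p, alpha), alpha)
}

#' Covariate-driven p-value weights
#'
#' The weight family \eqn{w(x_i, a) = m\, x_i^{-a} / \sum_j x_j^{-a}}: a
#' power function of a positive informative covariate (typically minor
#' allele frequency), normalized so weights sum to the number of
#' hypotheses m.  `a = 0` gives unit weights; larger `a` up-weights small
#' covariate values more aggressively.  Computed in log space so extreme
#' `a` never produces non-finite weights.
#'
#' @param x Positive covariate values, one per hypothesis.
#' @param a Exponent, finite and `>= 0`.
#' @return Numeric weight vector summing to `length(x)`, with the
#'   generating exponent attached as attribute `"a"`.
#' @examples
#' covariate_weights(c(0.1, 0.4), a = 1)  # c(1.6, 0.4)
#' @export
covariate_weights <- function(x, a) {
  if (length(x) == 0L) abort("`x` must be non-empty.")
  if (anyNA(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort("`x` must be strictly positive and finite (weights are undefined otherwise).")
  }
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a >= 0)
  lw <- -a * log(x)
  lw <- lw - max(lw)                     # log-sum-exp guard
  w <- exp(lw)
  w <- length(x) * w / sum(w)
  attr(w, "a") <- a
  w
}

#' Weighted Benjamini-Hochberg procedure
#'
#' Applies the BH step-up to \eqn{p_i / w_i} with non-negative weights
#' summing to m.  Any hypothesis with weight zero has weighted p-value
#' \eqn{+\infty} and is never rejected.  With unit weights the rejected set
#' is exactly [bh_stepup()]'s.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param w Non-negative weights, same length as `p`, summing to
#'   `length(p)` (relative tolerance 1e-6); e.g. from [covariate_weights()].
#' @param alpha Nominal FDR level in (0, 1).
#' @return A `rejection_result` (see [bh_stepup()]) with `weights_used = w`.
#' @examples
#' w <- covariate_weights(c(0.02, 0.3, 0.4), a = 1)
#' weighted_bh(c(0.01, 0.01, 0.5), w, alpha = 0.05)
#' @export
weighted_bh <- function(p, w, alpha = 0.05) {
  check_pvalues(p)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  if (length(w) != length(p)) {
    abort("`w` must have the same length as `p`.")
  }
  if (anyNA(w) || any(w < 0)) {
    abort("`w` must be non-negative with no missing values.")
  }
  m <- length(p)
  if (abs(sum(w) - m) > 1e-6 * m) {
    abort("`w` must sum to the number of hypotheses (within tolerance).")
  }
  q <- ifelse(w > 0, p / w, Inf)
  new_rejection_result(stepup_rejected(q, alpha, m), alpha, weights = w)
}

#' Storey-type estimate of the proportion of true nulls
#'
#' Computes \eqn{\hat\pi_0(\lambda) = \#\{p_i > \lambda\} / (m(1-\lambda))}
#' over a grid of tuning values and smooths with a natural cubic spline
#' (3 effective degrees of freedom), taking the fitted value at the largest
#' \eqn{\lambda} as the estimate of \eqn{\lim_{\lambda\to 1}\hat\pi_0(\lambda)},
#' clipped to (0, 1].
#'
#' @param p Numeric vector of p-values; at least 20 are needed to support
#'   the spline (fewer fall back conservatively to \eqn{\hat\pi_0 = 1} with
#'   a warning).
#' @param lambda_grid Increasing grid in (0, 1); default `seq(0.05, 0.95, 0.05)`.
#' @return A `pi0_estimate`: list with `pi0_hat`, `lambda_grid`, and the
#'   unsmoothed `raw_estimates`.
#' @export
storey_pi0 <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  check_pvalues(p)
  if (any(diff(lambda_grid) <= 0) || any(lambda_grid <= 0 | lambda_grid >= 1)) {
    abort("`lambda_grid` must be strictly increasing within (0, 1).")
  }
  m <- length(p)
  if (m < 20L) {
    warn("Fewer than 20 p-values: falling back to pi0_hat = 1 (conservative).")
    return(structure(
      list(pi0_hat = 1, lambda_grid = lambda_grid,
           raw_estimates = rep(NA_real_, length(lambda_grid))),
      class = "pi0_estimate"
    ))
  }
  raw <- vapply(lambda_grid, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  fit <- smooth.spline(lambda_grid, raw, df = 3)
  pi0 <- predict(fit, x = max(lambda_grid))$y
  pi0 <- min(max(pi0, .Machine$double.eps), 1)
  structure(
    list(pi0_hat = pi0, lambda_grid = lambda_grid, raw_estimates = raw),
    class = "pi0_estimate"
  )
}

#' @export
print.pi0_estimate <- function(x, ...) {
  cat(sprintf("<pi0_estimate> pi0_hat = %.4f (lambda grid of %d points)\n",
              x$pi0_hat, length(x$lambda_grid)))
  invisible(x)
}

#' Adaptive q-value style procedure
#'
#' BH step-up run at the effective level \eqn{\alpha / \hat\pi_0} with
#' \eqn{\hat\pi_0} from [storey_pi0()].  Since \eqn{\hat\pi_0 \le 1} this
#' never rejects fewer hypotheses than [bh_stepup()] at the same level.
#'
#' @inheritParams bh_stepup
#' @param lambda_grid Passed to [storey_pi0()].
#' @return A `rejection_result` with the estimate attached as attribute
#'   `"pi0"`.
#' @export
qvalue_procedure <- function(p, alpha = 0.05,
                             lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  check_pvalues(p)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  pi0 <- storey_pi0(p, lambda_grid)$pi0_hat
  res <- new_rejection_result(stepup_rejected(p, alpha / pi0), alpha)
  attr(res, "pi0") <- pi0
  res
}
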