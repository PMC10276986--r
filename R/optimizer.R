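# Exponent selection for the covariate weight family: grid search over a,
# tie-breaking over runs of consecutive maximizers, bagging over bootstrap
# subsamples, and the full wBHa procedure.

#' Rejection counts over an exponent grid
#'
#' For each exponent in `grid`, builds [covariate_weights()] from `x`
#' (normalized over the supplied hypotheses, so a bootstrap subsample is
#' treated as a self-contained set) and counts the rejections of
#' [weighted_bh()] at level `alpha`.
#'
#' @param p,x P-values and positive covariate values, equal length.
#' @param grid Numeric vector of exponents `>= 0`.
#' @param alpha Nominal FDR level.
#' @return Integer vector of rejection counts, one per grid value.
#' @export
rejections_over_grid <- function(p, x, grid = seq(0, 10, by = 0.1),
                                 alpha = 0.05) {
  check_pvalues(p)
  if (length(x) != length(p)) abort("`x` must have the same length as `p`.")
  if (anyNA(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort("`x` must be strictly positive and finite (weights are undefined otherwise).")
  }
  m <- length(p)
  lx <- log(x)
  vapply(grid, function(a) {
    lw <- -a * lx
    lw <- lw - max(lw)
    w <- exp(lw)
    w <- m * w / sum(w)
    sum(stepup_rejected(p / w, alpha, m))
  }, integer(1))
}

#' Tie-break rule for tied exponent maximizers
#'
#' Given the (sorted) set `A` of grid exponents that all attain the maximal
#' rejection count, splits `A` into runs of consecutive grid values (a gap
#' larger than `grid_step` starts a new run) and returns: the single element
#' if `A` has one; the maximum of the unique run if there is one run; the
#' maximum of the longest run if one run is strictly longest; otherwise the
#' maximum of the tied-longest run closest to 1 (run distance = smallest
#' endpoint distance to 1; a residual tie goes to the run with the larger
#' maximum).
#'
#' @param A Non-empty numeric vector of tied maximizers (subset of the grid);
#'   duplicates are removed defensively.
#' @param grid_step Constant spacing of the grid `A` was drawn from.
#' @return A single exponent value.
#' @examples
#' tie_break_a(c(0.1, 0.2, 0.3, 2.0, 2.1), grid_step = 0.1)  # 0.3
#' @export
tie_break_a <- function(A, grid_step = 0.1) {
  if (length(A) == 0L || anyNA(A)) abort("`A` must be non-empty with no missing values.")
  A <- sort(unique(A))
  if (length(A) == 1L) return(A)
  # split where the gap exceeds the grid step (small tolerance for fp noise)
  gap <- diff(A) > grid_step * (1 + 1e-8)
  run_id <- cumsum(c(0L, gap))
  runs <- split(A, run_id)
  if (length(runs) == 1L) return(max(A))
  len <- lengths(runs)
  longest <- which(len == max(len))
  if (length(longest) == 1L) return(max(runs[[longest]]))
  cand <- runs[longest]
  dist1 <- vapply(cand, function(r) min(abs(range(r) - 1)), numeric(1))
  maxes <- vapply(cand, max, numeric(1))
  best <- which(dist1 <= min(dist1) + 1e-9)   # exact ties, fp-safe
  if (length(best) > 1L) best <- best[which.max(maxes[best])]
  maxes[[best[1]]]
}

# Winner of one grid search: exponent maximizing the rejection counts,
# ties broken by tie_break_a.  A count vector that is zero everywhere
# carries no evidence about a and yields the neutral exponent 0 (unit
# weights): treating "nothing rejected anywhere" as a full-grid tie would
# push the bagged average toward the top of the grid and collapse the
# weights onto the very rarest markers.
grid_winner <- function(counts, grid, step) {
  if (max(counts) == 0L) return(0)
  tie_break_a(grid[counts == max(counts)], step)
}

# Naive (full-data) optimizer.
naive_optimize_a <- function(p, x, grid, alpha) {
  counts <- rejections_over_grid(p, x, grid, alpha)
  step <- if (length(grid) > 1L) grid[2] - grid[1] else 0.1
  grid_winner(counts, grid, step)
}

#' Bagged grid search for the weight exponent
#'
#' Runs `K` bootstrap rounds: each round samples `sample_size` hypotheses
#' with replacement (p-values and covariates drawn jointly), scores the
#' exponent grid by rejection count on the subsample (weights renormalized
#' within it), and picks a round winner with [tie_break_a()].  The final
#' exponent is the arithmetic mean of the round winners (not re-snapped to
#' the grid).  A round that rejects nothing at every exponent carries no
#' information about `a` and contributes the neutral winner 0 (unit
#' weights), so the procedure falls back toward plain BH when subsamples
#' hold no signal.  Subsampling round k seeds the RNG with `seed + k`, so
#' increasing `K` extends rather than reshuffles earlier rounds.
#'
#' @inheritParams rejections_over_grid
#' @param grid Strictly increasing exponent grid with constant step
#'   (default `seq(0, 10, by = 0.1)`).
#' @param K Number of bagging rounds (default 100).
#' @param sample_size Hypotheses drawn per round; default
#'   `max(1, floor(length(p) / K))`.
#' @param seed Integer seed; `NULL` uses the current RNG state (and round
#'   reproducibility is then up to the caller).
#' @param resample Optional test hook: `function(k, m, size)` returning the
#'   indices for round `k`, replacing bootstrap sampling.
#' @return A `wbha_trace`: list with `a` (final averaged exponent), `a_k`
#'   (per-round winners), `counts` (K x length(grid) rejection counts),
#'   `grid`, `K`, `sample_size`.
#' @export
bagging_optimize <- function(p, x, grid = seq(0, 10, by = 0.1), K = 100,
                             sample_size = NULL, alpha = 0.05, seed = NULL,
                             resample = NULL) {
  check_pvalues(p)
  if (length(x) != length(p)) abort("`x` must have the same length as `p`.")
  if (length(grid) > 1L) {
    steps <- diff(grid)
    if (any(steps <= 0) || diff(range(steps)) > 1e-8 * max(steps)) {
      abort("`grid` must be strictly increasing with constant step.")
    }
  }
  stopifnot(K >= 1)
  m <- length(p)
  if (is.null(sample_size)) sample_size <- max(1L, m %/% K)
  stopifnot(sample_size >= 1)
  step <- if (length(grid) > 1L) grid[2] - grid[1] else 0.1

  a_k <- numeric(K)
  counts <- matrix(NA_integer_, nrow = K, ncol = length(grid))
  for (k in seq_len(K)) {
    idx <- if (is.null(resample)) {
      if (!is.null(seed)) set.seed(seed + k)
      sample.int(m, sample_size, replace = TRUE)
    } else {
      resample(k, m, sample_size)
    }
    counts[k, ] <- rejections_over_grid(p[idx], x[idx], grid, alpha)
    a_k[k] <- grid_winner(counts[k, ], grid, step)
  }
  structure(
    list(a = mean(a_k), a_k = a_k, counts = counts, grid = grid,
         K = K, sample_size = sample_size),
    class = "wbha_trace"
  )
}

#' @export
print.wbha_trace <- function(x, ...) {
  cat(sprintf(
    "<wbha_trace> final a = %.3f over K = %d rounds (sample size %d, grid %g..%g)\n",
    x$a, x$K, x$sample_size, min(x$grid), max(x$grid)
  ))
  invisible(x)
}

#' wBHa: weighted BH with a bagged, covariate-adaptive exponent
#'
#' The full procedure: choose the weight exponent `a` by bagged grid search
#' ([bagging_optimize()]), build [covariate_weights()] at the chosen
#' exponent over *all* m hypotheses, and apply [weighted_bh()] at level
#' `alpha`.  With minor allele frequency as the covariate this prioritizes
#' rare variants while the data decide how aggressively.
#'
#' @param data A data frame with one row per hypothesis (a p-value table,
#'   e.g. from [scan_quantitative()] or [read_pvalue_table()]).
#' @param p,covariate Tidy-selected columns holding the p-values and the
#'   positive informative covariate (defaults: `p`, `covariate`).
#' @param alpha Nominal FDR level.
#' @inheritParams bagging_optimize
#' @return A `wbha_fit` object.  `tidy()` returns the per-marker table with
#'   `weight`, `weighted_p` and `rejected` columns appended; `glance()`
#'   returns a one-row summary; `autoplot()` shows the weight function.
#' @examples
#' tab <- tibble::tibble(
#'   marker_id = paste0("snp", 1:60),
#'   p = c(rep(1e-5, 3), runif(57)),
#'   covariate = runif(60, 0.01, 0.5)
#' )
#' fit <- wbha(tab, alpha = 0.05, K = 5, seed = 1)
#' glance(fit)
#' @export
wbha <- function(data, p = p, covariate = covariate, alpha = 0.05,
                 grid = seq(0, 10, by = 0.1), K = 100, sample_size = NULL,
                 seed = NULL, resample = NULL) {
  stopifnot(is.data.frame(data))
  pv <- eval_tidy(enquo(p), data)
  x <- eval_tidy(enquo(covariate), data)
  trace <- bagging_optimize(pv, x, grid = grid, K = K,
                            sample_size = sample_size, alpha = alpha,
                            seed = seed, resample = resample)
  w <- covariate_weights(x, trace$a)
  res <- weighted_bh(pv, w, alpha)
  table <- dplyr::mutate(
    tibble::as_tibble(data),
    weight = as.numeric(w),
    weighted_p = ifelse(w > 0, pv / w, Inf),
    rejected = res$rejected
  )
  structure(
    list(table = table, a = trace$a, alpha = alpha, k = res$k,
         trace = trace, result = res),
    class = "wbha_fit"
  )
}

#' @export
print.wbha_fit <- function(x, ...) {
  cat(sprintf(
    "<wbha_fit> a = %.3f; %d of %d hypotheses rejected at alpha = %g\n",
    x$a, x$k, nrow(x$table), x$alpha
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname wbha
#' @param x,object A `wbha_fit`.
#' @param ... Unused.
#' @export
tidy.wbha_fit <- function(x, ...) x$table

#' @rdname wbha
#' @export
glance.wbha_fit <- function(x, ...) {
  tibble::tibble(
    m = nrow(x$table),
    rejections = x$k,
    a = x$a,
    alpha = x$alpha,
    K = x$trace$K,
    sample_size = x$trace$sample_size
  )
}

#' @rdname wbha
#' @export
autoplot.wbha_fit <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$covariate, y = .data$weight)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$rejected), alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = "covariate (e.g. minor allele frequency)",
      y = "weight",
      colour = "rejected",
      title = sprintf("wBHa weights, a = %.2f (%d rejections)",
                      object$a, object$k)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Adjust a marker table with a chosen multiple-testing procedure
#'
#' Data-frame-first wrapper around the procedures: appends `weight`,
#' `weighted_p` and `rejected` columns.  Methods: `"bh"` (unit weights),
#' `"qvalue"` (unit weights at level \eqn{\alpha/\hat\pi_0}), `"wbh"`
#' (fixed covariate weights with exponent 1), `"wbha"` (bagged adaptive
#' exponent; extra arguments are passed to [wbha()]).
#'
#' @inheritParams wbha
#' @param method One of `"bh"`, `"qvalue"`, `"wbh"`, `"wbha"`.
#' @param ... Passed to [wbha()] when `method = "wbha"`.
#' @return The input as a tibble with `weight`, `weighted_p`, `rejected`
#'   appended.
#' @export
adjust_markers <- function(data, method = c("bh", "qvalue", "wbh", "wbha"),
                           p = p, covariate = covariate, alpha = 0.05, ...) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data))
  pq <- enquo(p)
  xq <- enquo(covariate)
  pv <- eval_tidy(pq, data)
  if (method == "wbha") {
    return(tidy(wbha(data, p = !!pq, covariate = !!xq, alpha = alpha, ...)))
  }
  if (method %in% c("bh", "qvalue")) {
    res <- if (method == "bh") bh_stepup(pv, alpha) else qvalue_procedure(pv, alpha)
    w <- rep(1, length(pv))
  } else {
    x <- eval_tidy(xq, data)
    w <- covariate_weights(x, 1)
    res <- weighted_bh(pv, w, alpha)
  }
  dplyr::mutate(
    tibble::as_tibble(data),
    weight = as.numeric(w),
    weighted_p = ifelse(w > 0, pv / w, Inf),
    rejected = res$rejected
  )
}
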