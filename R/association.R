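# Single-marker association scans producing the p-value tables the
# multiple-testing procedures consume.

#' Observed minor allele frequency per marker
#'
#' Allele frequency `mean(G_j) / 2` per column, folded to the minor allele:
#' `min(f, 1 - f)`.
#'
#' @param G Genotype matrix (individuals x markers, 0/1/2 coding).
#' @return Numeric vector of observed MAFs in \[0, 0.5\].
#' @export
observed_maf <- function(G) {
  f <- colMeans(G) / 2
  pmin(f, 1 - f)
}

scan_result <- function(G, estimate, std_error, statistic, p) {
  m <- ncol(G)
  ids <- colnames(G)
  if (is.null(ids)) ids <- sprintf("snp%0*d", nchar(m), seq_len(m))
  tibble::tibble(
    marker_id = ids,
    estimate = estimate,
    std_error = std_error,
    statistic = statistic,
    p = p,
    covariate = observed_maf(G)
  )
}

#' Single-marker linear-regression scan (quantitative trait)
#'
#' For each marker j fits the simple linear regression
#' `y ~ intercept + G_j` and reports the two-sided t-test p-value on the
#' slope.  Vectorized across markers through the closed-form least-squares
#' solution.  Monomorphic markers carry no information and get `p = 1`
#' (with a warning) and missing estimates.
#'
#' @param G Genotype matrix (individuals x markers, 0/1/2 coding).
#' @param y Real-valued phenotype of length `nrow(G)`.
#' @return A tibble with one row per marker: `marker_id`, `estimate`
#'   (slope), `std_error`, `statistic`, `p`, and `covariate` (observed MAF,
#'   ready for the weighted procedures).
#' @export
scan_quantitative <- function(G, y) {
  n <- nrow(G)
  if (n < 3) abort("At least 3 individuals are required.")
  if (length(y) != n || !is.numeric(y)) {
    abort("`y` must be a numeric vector with one value per individual.")
  }
  yc <- y - mean(y)
  gbar <- colMeans(G)
  sxy <- as.numeric(crossprod(G, yc))          # = sum((g - gbar) * yc)
  sxx <- colSums(G * G) - n * gbar^2
  syy <- sum(yc^2)
  mono <- sxx <= 0
  if (any(mono)) {
    warn(sprintf("%d monomorphic marker(s): p-value set to 1.", sum(mono)))
  }
  sxx_safe <- ifelse(mono, NA_real_, sxx)
  slope <- sxy / sxx_safe
  sse <- pmax(syy - slope * sxy, 0)
  se <- sqrt(sse / (n - 2) / sxx_safe)
  tstat <- slope / se
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[mono] <- 1
  # an exact fit gives se = 0 -> infinite t; report p = 0
  p[!mono & se == 0] <- 0
  scan_result(G, slope, se, tstat, p)
}

#' Single-marker logistic-regression scan (binary trait)
#'
#' For each marker j fits `y ~ intercept + G_j` by logistic regression and
#' reports the two-sided Wald p-value on the slope.  Monomorphic markers,
#' non-converged fits and (quasi-)separated fits are reported conservatively
#' with `p = 1` and a warning.
#'
#' @param G Genotype matrix (individuals x markers, 0/1/2 coding).
#' @param y 0/1 phenotype with both classes present.
#' @return A tibble in the same layout as [scan_quantitative()] (`estimate`
#'   is the log odds ratio).
#' @export
scan_binary <- function(G, y) {
  n <- nrow(G)
  if (length(y) != n) abort("`y` must have one value per individual.")
  y <- as.integer(y)
  if (!all(y %in% 0:1) || length(unique(y)) < 2L) {
    abort("`y` must be 0/1 with both classes present.")
  }
  m <- ncol(G)
  estimate <- se <- z <- rep(NA_real_, m)
  p <- rep(1, m)
  n_bad <- 0L
  fam <- stats::binomial()
  for (j in seq_len(m)) {
    g <- G[, j]
    if (max(g) == min(g)) {
      n_bad <- n_bad + 1L
      next
    }
    X <- cbind(1, g)
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = fam, control = list(maxit = 25))
    )
    cov <- tryCatch(chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE]),
                    error = function(e) NULL)
    b <- fit$coefficients[2]
    s <- if (is.null(cov)) NA_real_ else sqrt(cov[2, 2])
    if (!fit$converged || !is.finite(b) || !is.finite(s) || abs(b) > 20) {
      n_bad <- n_bad + 1L
      next
    }
    estimate[j] <- b
    se[j] <- s
    z[j] <- b / s
    p[j] <- 2 * pnorm(-abs(z[j]))
  }
  if (n_bad > 0) {
    warn(sprintf("%d marker(s) monomorphic, separated or non-converged: p-value set to 1.", n_bad))
  }
  scan_result(G, estimate, se, z, p)
}

#' Scan a simulated study with the trait-appropriate test
#'
#' Dispatches [scan_quantitative()] or [scan_binary()] on a
#' [simulate_study()] result and carries the truth columns along, yielding
#' a p-value table ready for [adjust_markers()] or [wbha()].
#'
#' @param study A `simulated_study`.
#' @return The scan tibble joined with `maf_group`, `is_causal` and `beta`.
#' @export
scan_study <- function(study) {
  stopifnot(inherits(study, "simulated_study"))
  scan <- if (study$design$trait == "quantitative") {
    scan_quantitative(study$G, as.numeric(study$y))
  } else {
    scan_binary(study$G, study$y)
  }
  dplyr::left_join(
    scan,
    dplyr::select(study$markers, "marker_id", "maf_group", "is_causal", "beta"),
    by = "marker_id"
  )
}
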