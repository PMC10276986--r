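# Genotype-phenotype simulator: block-equicorrelated latent Gaussians
# discretized to 0/1/2 genotypes under Hardy-Weinberg, MAF-stratified
# causal effects, quantitative or binary traits.

maf_group_levels <- c("rare", "medium-rare", "medium", "common", "null")

# U[lower, upper] MAF ranges of the four causal groups, rare -> common
causal_maf_ranges <- list(
  rare          = c(0.01, 0.05),
  `medium-rare` = c(0.05, 0.15),
  medium        = c(0.15, 0.25),
  common        = c(0.30, 0.40)
)

#' Describe one simulated association study
#'
#' Bundles and validates the generative configuration: `n` individuals
#' carry `m` markers of which `m1` are causal; genotypes come from latent
#' Gaussians equicorrelated at `rho` within blocks of `block_size`
#' (mimicking linkage disequilibrium) discretized under Hardy-Weinberg;
#' causal effect sizes follow the scenario (1: rare variants have the
#' largest effects; 2: common variants do; 3: all equal); the trait is
#' quantitative (linear model calibrated to `r_squared`) or binary
#' (logistic model calibrated to 50% prevalence).
#'
#' @param n Number of individuals (reference setting: 2000).
#' @param m Number of markers.
#' @param m1 Number of causal markers, `0 <= m1 <= m`.
#' @param rho Within-block latent equicorrelation in \[0, 1).
#' @param block_size Markers per correlation block (reference: 10).
#' @param trait `"quantitative"` or `"binary"`.
#' @param scenario Effect-size scenario 1, 2 or 3.
#' @param r_squared Target coefficient of determination of the quantitative
#'   trait (reference: 0.2).
#' @param seed Optional integer seed consumed by [simulate_study()].
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n = 2000, m = 8000, m1 = 25, rho = 0,
                              block_size = 10,
                              trait = c("quantitative", "binary"),
                              scenario = 1, r_squared = 0.2, seed = NULL) {
  trait <- match.arg(trait)
  stopifnot(
    n >= 3, m >= 1, m1 >= 0, m1 <= m,
    rho >= 0, rho < 1, block_size >= 1,
    scenario %in% 1:3,
    r_squared > 0, r_squared < 1
  )
  structure(
    list(n = as.integer(n), m = as.integer(m), m1 = as.integer(m1),
         rho = rho, block_size = as.integer(block_size), trait = trait,
         scenario = as.integer(scenario), r_squared = r_squared,
         seed = seed),
    class = "simulation_design"
  )
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf(
    "<simulation_design> n = %d, m = %d (m1 = %d causal), rho = %g (blocks of %d),\n  %s trait, scenario %d, R^2 = %g%s\n",
    x$n, x$m, x$m1, x$rho, x$block_size, x$trait, x$scenario, x$r_squared,
    if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)
  ))
  invisible(x)
}

# Sizes of the four causal MAF groups: quotient of m1 by 4 each, remainder
# added to the common group.
causal_group_sizes <- function(m1) {
  q <- m1 %/% 4L
  c(rare = q, `medium-rare` = q, medium = q, common = q + m1 %% 4L)
}

#' Assign design minor allele frequencies and causal labels
#'
#' Null markers get MAF ~ U\[0.01, 0.5\].  The `m1` causal markers are split
#' into four MAF groups (rare U\[0.01, 0.05\], medium-rare U\[0.05, 0.15\],
#' medium U\[0.15, 0.25\], common U\[0.30, 0.40\]) of size `floor(m1/4)`
#' each, remainder added to the common group; causal positions are drawn
#' uniformly without replacement.  Consumes the current RNG state.
#'
#' @param design A [simulation_design()].
#' @return A tibble with one row per marker: `marker_id`, `maf`,
#'   `is_causal`, `maf_group` (factor; `"null"` for non-causal markers).
#' @export
assign_mafs <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  m <- design$m
  m1 <- design$m1
  maf <- runif(m, 0.01, 0.5)
  group <- factor(rep("null", m), levels = maf_group_levels)
  is_causal <- rep(FALSE, m)
  if (m1 > 0) {
    sizes <- causal_group_sizes(m1)
    causal_idx <- sample.int(m, m1)
    labels <- rep(names(sizes), times = sizes)
    is_causal[causal_idx] <- TRUE
    group[causal_idx] <- labels
    for (g in names(causal_maf_ranges)) {
      sel <- causal_idx[labels == g]
      r <- causal_maf_ranges[[g]]
      maf[sel] <- runif(length(sel), r[1], r[2])
    }
  }
  tibble::tibble(
    marker_id = sprintf("snp%0*d", nchar(m), seq_len(m)),
    maf = maf, is_causal = is_causal, maf_group = group
  )
}

#' Simulate additive genotypes from block-correlated latent Gaussians
#'
#' Each individual's latent vector has unit-variance components that are
#' equicorrelated at `rho` within consecutive blocks of `block_size`
#' markers and independent across blocks (one-factor construction
#' \eqn{\sqrt\rho\, Z_{block} + \sqrt{1-\rho}\, Z_i}, never materializing
#' the full covariance).  Per marker with minor allele frequency p, the
#' latent value is cut at \eqn{\Phi^{-1}(p^2)} and
#' \eqn{\Phi^{-1}(1-(1-p)^2)}, giving genotypes 2 / 1 / 0 with
#' Hardy-Weinberg frequencies \eqn{(p^2,\; 2p(1-p),\; (1-p)^2)}.
#' Consumes the current RNG state.
#'
#' @param n Number of individuals.
#' @param maf Per-marker minor allele frequencies in (0, 0.5\].
#' @param rho Within-block equicorrelation in \[0, 1).
#' @param block_size Markers per block.
#' @return An `n x m` integer matrix with entries in \{0, 1, 2\}.
#' @export
simulate_genotypes <- function(n, maf, rho = 0, block_size = 10) {
  stopifnot(n >= 1, length(maf) >= 1, rho >= 0, rho < 1, block_size >= 1)
  if (anyNA(maf) || any(maf <= 0 | maf > 0.5)) {
    abort("`maf` must lie in (0, 0.5].")
  }
  m <- length(maf)
  latent <- matrix(rnorm(n * m), nrow = n, ncol = m)
  if (rho > 0) {
    n_blocks <- ceiling(m / block_size)
    block_of <- rep(seq_len(n_blocks), each = block_size, length.out = m)
    factors <- matrix(rnorm(n * n_blocks), nrow = n, ncol = n_blocks)
    latent <- sqrt(1 - rho) * latent + sqrt(rho) * factors[, block_of, drop = FALSE]
  }
  lower <- qnorm(maf^2)
  upper <- qnorm(1 - (1 - maf)^2)
  G <- (latent < rep(upper, each = n)) + (latent < rep(lower, each = n))
  storage.mode(G) <- "integer"
  G
}

#' Causal effect sizes by scenario
#'
#' Maps each marker's MAF group to its effect size.  Quantitative trait:
#' scenario 1 gives (4, 3, 2, 1) from rare to common, scenario 2 the
#' reverse, scenario 3 all 2.  Binary trait (log odds ratios): scenario 1
#' gives (log 2.2, log 1.8, log 1.5, log 1.3), scenario 2 the reverse,
#' scenario 3 all log 1.5.  Null markers get 0.
#'
#' @param design A [simulation_design()] (supplies trait and scenario).
#' @param maf_group Factor of group labels per marker, as produced by
#'   [assign_mafs()].
#' @return Numeric effect-size vector, one per marker.
#' @export
assign_effects <- function(design, maf_group) {
  stopifnot(inherits(design, "simulation_design"))
  base <- if (design$trait == "quantitative") c(4, 3, 2, 1) else log(c(2.2, 1.8, 1.5, 1.3))
  eff <- switch(design$scenario,
    base,
    rev(base),
    rep(if (design$trait == "quantitative") 2 else log(1.5), 4)
  )
  lookup <- c(stats::setNames(eff, names(causal_maf_ranges)), null = 0)
  unname(lookup[as.character(maf_group)])
}

#' Quantitative trait from an additive genetic model
#'
#' Computes the genetic score \eqn{s = G\beta} and adds i.i.d. Gaussian
#' noise with variance
#' \eqn{\sigma^2 = (1 - R^2)\sum_i(s_i - \bar s)^2 / (R^2 (n - 2))},
#' the value that calibrates the realized coefficient of determination of
#' the phenotype-on-score regression to `r_squared`.
#'
#' @param G Genotype matrix (individuals x markers, additive 0/1/2 coding).
#' @param beta Per-marker effect sizes.
#' @param r_squared Target coefficient of determination in (0, 1).
#' @return Numeric phenotype vector with the residual variance attached as
#'   attribute `"sigma2"`.  If all effects are zero the score carries no
#'   signal and \eqn{\sigma^2 = 1} is used with a warning.
#' @export
simulate_quantitative_trait <- function(G, beta, r_squared = 0.2) {
  n <- nrow(G)
  stopifnot(n >= 3, length(beta) == ncol(G), r_squared > 0, r_squared < 1)
  nz <- which(beta != 0)
  s <- if (length(nz)) as.numeric(G[, nz, drop = FALSE] %*% beta[nz]) else numeric(n)
  ss <- sum((s - mean(s))^2)
  if (ss == 0) {
    warn("All effects are zero (or the score is constant): using sigma^2 = 1, the phenotype is pure noise.")
    sigma2 <- 1
  } else {
    sigma2 <- (1 - r_squared) * ss / (r_squared * (n - 2))
  }
  y <- s + rnorm(n, 0, sqrt(sigma2))
  attr(y, "sigma2") <- sigma2
  y
}

#' Binary trait from a logistic model with balanced prevalence
#'
#' Draws \eqn{Y_i \sim Bernoulli(expit(\beta_0 + \sum_j G_{ij}\beta_j))}
#' with the intercept \eqn{\beta_0} solved numerically so that the mean
#' case probability over the realized genotypes is exactly 0.5 (balanced
#' cases and controls in expectation).
#'
#' @inheritParams simulate_quantitative_trait
#' @return Integer 0/1 phenotype vector with the calibrated intercept
#'   attached as attribute `"beta0"`.
#' @export
simulate_binary_trait <- function(G, beta) {
  n <- nrow(G)
  stopifnot(n >= 2, length(beta) == ncol(G))
  nz <- which(beta != 0)
  eta <- if (length(nz)) as.numeric(G[, nz, drop = FALSE] %*% beta[nz]) else numeric(n)
  f <- function(b0) mean(plogis(b0 + eta)) - 0.5
  beta0 <- if (length(nz) == 0L) 0 else {
    uniroot(f, lower = -50 - max(eta), upper = 50 - min(eta), tol = 1e-12)$root
  }
  prob <- plogis(beta0 + eta)
  y <- rbinom(n, 1L, prob)
  attr(y, "beta0") <- beta0
  y
}

# Marker table for a user-supplied genotype matrix: observed MAFs, groups by
# the MAF cutoffs 0.01-0.05 / 0.05-0.15 / 0.15-0.30 / >0.30, causal markers
# drawn per group with the quotient/remainder size rule.
assign_mafs_from_genotypes <- function(G, m1) {
  m <- ncol(G)
  stopifnot(m1 <= m)
  maf <- observed_maf(G)
  bin <- cut(maf, breaks = c(-Inf, 0.05, 0.15, 0.30, Inf),
             labels = names(causal_maf_ranges))
  group <- factor(rep("null", m), levels = maf_group_levels)
  is_causal <- rep(FALSE, m)
  if (m1 > 0) {
    sizes <- causal_group_sizes(m1)
    for (g in names(sizes)) {
      pool <- which(bin == g & !is_causal)
      if (length(pool) < sizes[[g]]) {
        abort(sprintf("Genotype matrix has only %d markers in MAF group '%s' but %d causal markers were requested there.",
                      length(pool), g, sizes[[g]]))
      }
      sel <- pool[sample.int(length(pool), sizes[[g]])]
      is_causal[sel] <- TRUE
      group[sel] <- g
    }
  }
  tibble::tibble(
    marker_id = if (is.null(colnames(G))) sprintf("snp%0*d", nchar(m), seq_len(m)) else colnames(G),
    maf = maf, is_causal = is_causal, maf_group = group
  )
}

#' Realize one simulated study
#'
#' Composes [assign_mafs()], [simulate_genotypes()], [assign_effects()] and
#' the trait simulator into one reproducible dataset.  Supplying
#' `genotypes` replaces the genotype simulation with a user matrix
#' (individuals x markers, 0/1/2 coding): observed MAFs are computed from
#' it, markers are binned into the four MAF groups by the cutoffs 0.05 /
#' 0.15 / 0.30, and causal markers are drawn per group — the semi-simulation
#' mechanism for real genotype panels.
#'
#' @param design A [simulation_design()].
#' @param genotypes Optional plug-in genotype matrix; its dimensions
#'   override `design$n` and `design$m`.
#' @return A `simulated_study`: list with `G` (genotypes), `y` (phenotype),
#'   `markers` (tibble: `marker_id`, `maf`, `maf_group`, `is_causal`,
#'   `beta`), and `design`.
#' @export
simulate_study <- function(design, genotypes = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  if (is.null(genotypes)) {
    markers <- assign_mafs(design)
    G <- simulate_genotypes(design$n, markers$maf, design$rho, design$block_size)
  } else {
    stopifnot(is.matrix(genotypes), all(genotypes %in% 0:2))
    G <- genotypes
    design$n <- nrow(G)
    design$m <- ncol(G)
    markers <- assign_mafs_from_genotypes(G, design$m1)
  }
  colnames(G) <- markers$marker_id
  markers$beta <- assign_effects(design, markers$maf_group)
  y <- if (design$trait == "quantitative") {
    simulate_quantitative_trait(G, markers$beta, design$r_squared)
  } else {
    simulate_binary_trait(G, markers$beta)
  }
  structure(
    list(G = G, y = y, markers = markers, design = design),
    class = "simulated_study"
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "<simulated_study> %d individuals x %d markers (%d causal), %s trait\n",
    nrow(x$G), ncol(x$G), sum(x$markers$is_causal), x$design$trait
  ))
  invisible(x)
}
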