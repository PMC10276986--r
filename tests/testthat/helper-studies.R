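# Memoised reference studies shared across acceptance checks.  The study
# conditions are the reference simulation protocol (scenario 1,
# quantitative trait, n = 2000, m = 8000, m1 = 25, rho = 0, R^2 = 0.2,
# nominal FDR 5%) at 100 replicates.

.study_cache <- new.env(parent = emptyenv())

reference_design <- function() {
  simulation_design(n = 2000, m = 8000, m1 = 25, rho = 0,
                    trait = "quantitative", scenario = 1, r_squared = 0.2)
}

# scenario-1 study with the MAF covariate: BH, wBH and wBHa
reference_study <- function() {
  if (is.null(.study_cache$maf)) {
    .study_cache$maf <- suppressWarnings(
      run_study(reference_design(), procedures = c("bh", "wbh", "wbha"),
                replicates = 100, seed = 101, alpha = 0.05,
                covariate = "maf")
    )
  }
  .study_cache$maf
}

# same protocol with an uninformative U(0, 1) covariate, all procedures
uninformative_study <- function() {
  if (is.null(.study_cache$unif)) {
    .study_cache$unif <- suppressWarnings(
      run_study(reference_design(),
                procedures = c("bh", "qvalue", "wbh", "wbha"),
                replicates = 100, seed = 202, alpha = 0.05,
                covariate = "uniform")
    )
  }
  .study_cache$unif
}

metric_of <- function(summary, proc, metric) {
  row <- summary[summary$procedure == proc & summary$metric == metric, ]
  stopifnot(nrow(row) == 1)
  row
}

fdp_bound <- function(summary, proc, alpha = 0.05) {
  counts <- attr(summary, "replicates")
  fdp <- counts$fdp[counts$procedure == proc]
  c(mean = mean(fdp), bound = alpha + 2 * sd(fdp) / sqrt(length(fdp)))
}
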