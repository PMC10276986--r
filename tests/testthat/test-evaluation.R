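test_that("confusion counts follow the FP/max(R,1) convention", {
  none <- confusion_counts(rep(FALSE, 10), c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_equal(none$tp, 0)
  expect_equal(none$fp, 0)
  expect_equal(none$fdp, 0)

  all_rej <- confusion_counts(rep(TRUE, 10), c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_equal(all_rej$tp, 3)
  expect_equal(all_rej$fp, 7)
  expect_equal(all_rej$fdp, 0.7)

  expect_error(confusion_counts(c(TRUE, FALSE), TRUE), "length")
})

test_that("cluster-level counts treat any-causal/any-rejected clusters as units", {
  # clusters {1,2}, {3}, {4,5}; causal = {1}; rejected = {2, 5}
  cc <- confusion_counts(
    rejected = c(FALSE, TRUE, FALSE, FALSE, TRUE),
    is_causal = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    clusters = c(1, 1, 2, 3, 3)
  )
  expect_equal(cc$tp, 1)
  expect_equal(cc$fp, 1)
  expect_equal(cc$fn, 0)
  expect_equal(cc$tn, 1)
  expect_equal(cc$n_units, 3)
  expect_equal(cc$granularity, "cluster")

  # invariant to marker order
  o <- c(4, 2, 5, 1, 3)
  cc2 <- confusion_counts(
    rejected = c(FALSE, TRUE, FALSE, FALSE, TRUE)[o],
    is_causal = c(TRUE, FALSE, FALSE, FALSE, FALSE)[o],
    clusters = c(1, 1, 2, 3, 3)[o]
  )
  expect_equal(cc2[c("tp", "fp", "tn", "fn")], cc[c("tp", "fp", "tn", "fn")])
})

test_that("correlation clustering finds components and respects thresholds", {
  withr::local_seed(61)
  # chain: col2 copies col1, col3 copies col2 (r12, r23 high; r13 lower)
  base <- rbinom(4000, 2, 0.3)
  flip <- function(g, rate) ifelse(runif(length(g)) < rate, rbinom(length(g), 2, 0.3), g)
  G <- cbind(base, flip(base, 0.1), flip(flip(base, 0.1), 0.1), rbinom(4000, 2, 0.3))
  cc <- cor(G)
  cl <- cluster_markers(G, threshold = 0.8)
  expect_true(cc[1, 2] >= 0.8 && cc[1, 3] < cc[1, 2])
  expect_equal(cl[1], cl[2])
  expect_equal(cl[2], cl[3])   # joined through the chain
  expect_false(cl[1] == cl[4])

  # threshold 1 isolates everything
  expect_equal(length(unique(cluster_markers(G, threshold = 1))), 4)

  # independent markers at n = 2000: no pair reaches |r| >= 0.8
  Gi <- simulate_genotypes(2000, runif(200, 0.05, 0.5))
  expect_equal(length(unique(cluster_markers(Gi, threshold = 0.8))), 200)

  # block-restricted clustering matches genome-wide on block data
  Gb <- simulate_genotypes(2000, rep(0.3, 20), rho = 0.9, block_size = 5)
  blocks <- rep(1:4, each = 5)
  expect_equal(cluster_markers(Gb, 0.8, blocks = blocks),
               cluster_markers(Gb, 0.8))
})

test_that("power estimates summarize replicate counts with binomial accuracy", {
  perfect <- tibble::tibble(
    procedure = "bh", replicate = 1:4, tp = 5, fp = 0, fdp = 0, m1 = 5
  )
  out <- power_estimates(perfect)
  expect_equal(out$estimate[out$metric == "power_overall"], 1)
  expect_equal(out$estimate[out$metric == "fdr"], 0)

  single <- perfect[1, ]
  expect_warning(out1 <- power_estimates(single), "Single replicate")
  expect_true(all(out1$se == 0))

  withr::local_seed(62)
  reps <- 500
  toy <- tibble::tibble(
    procedure = "bh", replicate = seq_len(reps),
    tp = rbinom(reps, 10, 0.3), fp = 0, fdp = 0, m1 = 10
  )
  est <- power_estimates(toy)
  p_hat <- est$estimate[est$metric == "power_overall"]
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / (10 * reps)))

  zero <- tibble::tibble(procedure = "bh", replicate = 1:3,
                         tp = 0, fp = 1, fdp = 1, m1 = 0)
  out0 <- power_estimates(zero)
  expect_true(is.na(out0$estimate[out0$metric == "power_overall"]))
})

test_that("a small replicated study runs end to end for all procedures", {
  d <- simulation_design(n = 150, m = 240, m1 = 8, rho = 0, seed = NULL)
  res <- suppressWarnings(
    run_study(d, procedures = c("bh", "qvalue", "wbh", "wbha"),
              replicates = 3, seed = 63, alpha = 0.1,
              wbha_args = list(K = 10))
  )
  expect_s3_class(res, "study_summary")
  expect_setequal(unique(res$procedure), c("bh", "qvalue", "wbh", "wbha"))
  est <- res$estimate[!is.na(res$estimate)]
  expect_true(all(est >= 0 & est <= 1))
  g <- glance(res)
  expect_equal(g$replicates, 3)
  expect_equal(g$m, 240)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")

  counts <- attr(res, "replicates")
  expect_equal(nrow(counts), 12)
  expect_true(all(counts$tp + counts$fp == counts$r))

  # reproducible given the same seed
  res2 <- suppressWarnings(
    run_study(d, procedures = "bh", replicates = 3, seed = 63, alpha = 0.1)
  )
  c1 <- dplyr::filter(counts, procedure == "bh")
  c2 <- attr(res2, "replicates")
  expect_equal(c1$tp, c2$tp)
  expect_equal(c1$fp, c2$fp)
})

test_that("correlated designs switch to cluster granularity", {
  d <- simulation_design(n = 150, m = 100, m1 = 4, rho = 0.75, seed = NULL)
  res <- suppressWarnings(run_study(d, procedures = "bh", replicates = 2, seed = 64))
  counts <- attr(res, "replicates")
  expect_true(all(counts$granularity == "cluster"))
  expect_true(all(counts$n_units <= 100))
})

test_that("the global-null study keeps the empirical FDP within the bound", {
  d <- simulation_design(n = 100, m = 200, m1 = 0, seed = NULL)
  res <- suppressWarnings(
    run_study(d, procedures = "bh", replicates = 40, seed = 65, alpha = 0.05)
  )
  counts <- attr(res, "replicates")
  mcse <- sd(counts$fdp) / sqrt(nrow(counts))
  expect_lte(mean(counts$fdp), 0.05 + 2 * mcse)
})
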