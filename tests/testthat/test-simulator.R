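test_that("causal group sizes follow the quotient/remainder rule", {
  expect_sizes <- function(m1, expected) {
    withr::local_seed(41)
    d <- simulation_design(n = 10, m = 400, m1 = m1)
    tab <- assign_mafs(d)
    got <- table(factor(tab$maf_group[tab$is_causal],
                        levels = c("rare", "medium-rare", "medium", "common")))
    expect_equal(as.integer(got), expected)
  }
  expect_sizes(10, c(2L, 2L, 2L, 4L))
  expect_sizes(4, c(1L, 1L, 1L, 1L))
  for (m1 in c(5, 15, 20, 25, 50, 100, 150)) {
    q <- m1 %/% 4L
    expect_sizes(m1, c(q, q, q, q + m1 %% 4L))
  }
})

test_that("design MAFs respect the group ranges and null markers span U[0.01, 0.5]", {
  withr::local_seed(42)
  d <- simulation_design(n = 10, m = 2000, m1 = 100)
  tab <- assign_mafs(d)
  ranges <- list(
    rare = c(0.01, 0.05), `medium-rare` = c(0.05, 0.15),
    medium = c(0.15, 0.25), common = c(0.30, 0.40)
  )
  for (g in names(ranges)) {
    v <- tab$maf[tab$maf_group == g]
    expect_true(all(v >= ranges[[g]][1] & v <= ranges[[g]][2]))
  }
  nulls <- tab$maf[!tab$is_causal]
  expect_true(all(nulls >= 0.01 & nulls <= 0.5))
  expect_equal(sum(tab$is_causal), 100)

  d0 <- simulation_design(n = 10, m = 50, m1 = 0)
  tab0 <- assign_mafs(d0)
  expect_false(any(tab0$is_causal))
  expect_true(all(tab0$maf_group == "null"))
  expect_error(simulation_design(n = 10, m = 5, m1 = 6))
})

test_that("genotype frequencies recover Hardy-Weinberg proportions", {
  withr::local_seed(43)
  n <- 20000
  for (p in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    G <- simulate_genotypes(n, rep(p, 3), rho = 0)
    target <- c((1 - p)^2, 2 * p * (1 - p), p^2)   # P(G = 0, 1, 2)
    for (g in 0:2) {
      freq <- mean(G == g)
      se <- sqrt(target[g + 1] * (1 - target[g + 1]) / (3 * n))
      expect_lt(abs(freq - target[g + 1]), 4 * se + 1e-12)
    }
  }
})

test_that("latent block correlation is recovered and blocks are independent", {
  withr::local_seed(44)
  n <- 20000
  # high within-block correlation induces positive genotype correlation
  G <- simulate_genotypes(n, rep(0.3, 2), rho = 0.75, block_size = 2)
  expect_gt(cor(G[, 1], G[, 2]), 0.5)

  # markers in different blocks stay uncorrelated
  G2 <- simulate_genotypes(n, rep(0.3, 4), rho = 0.75, block_size = 2)
  expect_lt(abs(cor(G2[, 2], G2[, 3])), 0.05)

  # latent correlation check via the one-factor construction itself
  z0 <- rnorm(n); z1 <- rnorm(n); z2 <- rnorm(n)
  l1 <- sqrt(0.75) * z0 + sqrt(0.25) * z1
  l2 <- sqrt(0.75) * z0 + sqrt(0.25) * z2
  expect_lt(abs(cor(l1, l2) - 0.75), 0.02)
})

test_that("effect sizes follow the scenario table", {
  groups <- factor(c("rare", "medium-rare", "medium", "common", "null"),
                   levels = c("rare", "medium-rare", "medium", "common", "null"))
  dq1 <- simulation_design(n = 10, m = 5, m1 = 4, scenario = 1)
  expect_equal(assign_effects(dq1, groups), c(4, 3, 2, 1, 0))
  dq2 <- simulation_design(n = 10, m = 5, m1 = 4, scenario = 2)
  expect_equal(assign_effects(dq2, groups), c(1, 2, 3, 4, 0))
  dq3 <- simulation_design(n = 10, m = 5, m1 = 4, scenario = 3)
  expect_equal(assign_effects(dq3, groups), c(2, 2, 2, 2, 0))

  db1 <- simulation_design(n = 10, m = 5, m1 = 4, trait = "binary", scenario = 1)
  expect_equal(assign_effects(db1, groups), c(log(2.2), log(1.8), log(1.5), log(1.3), 0))
  db3 <- simulation_design(n = 10, m = 5, m1 = 4, trait = "binary", scenario = 3)
  expect_equal(assign_effects(db3, groups), c(rep(log(1.5), 4), 0))
  expect_error(simulation_design(n = 10, m = 5, m1 = 4, scenario = 7))
})

test_that("quantitative noise variance matches the hand-evaluated calibration", {
  G <- matrix(c(0, 1, 2, 3), ncol = 1)   # genetic scores 0,1,2,3
  withr::local_seed(45)
  y <- simulate_quantitative_trait(G, 1, r_squared = 0.2)
  expect_equal(attr(y, "sigma2"), 10)    # (0.8 * 5) / (0.2 * 2)

  # near-deterministic trait as R^2 -> 1
  y1 <- simulate_quantitative_trait(G, 1, r_squared = 1 - 1e-12)
  expect_equal(as.numeric(y1), c(0, 1, 2, 3), tolerance = 1e-4)

  expect_warning(
    y0 <- simulate_quantitative_trait(matrix(0:3, ncol = 1), 0, 0.2),
    "pure noise"
  )
  expect_equal(attr(y0, "sigma2"), 1)
})

test_that("realized R^2 concentrates on the target", {
  withr::local_seed(46)
  n <- 5000
  G <- simulate_genotypes(n, runif(10, 0.05, 0.5))
  beta <- c(rep(1.5, 10))
  r2 <- replicate(5, {
    y <- simulate_quantitative_trait(G, beta, r_squared = 0.2)
    s <- as.numeric(G %*% beta)
    summary(lm(y ~ s))$r.squared
  })
  expect_lt(abs(mean(r2) - 0.2), 0.02)
})

test_that("binary traits are calibrated to balanced prevalence", {
  withr::local_seed(47)
  G <- simulate_genotypes(20000, runif(25, 0.01, 0.4))
  d <- simulation_design(n = 20000, m = 25, m1 = 24, trait = "binary", scenario = 1)
  beta <- assign_effects(d, assign_mafs(d)$maf_group)
  y <- simulate_binary_trait(G, beta)
  eta <- attr(y, "beta0") + as.numeric(G[, beta != 0, drop = FALSE] %*% beta[beta != 0])
  expect_lt(abs(mean(plogis(eta)) - 0.5), 1e-8)
  expect_gt(mean(y), 0.47)
  expect_lt(mean(y), 0.53)

  y0 <- simulate_binary_trait(G, rep(0, 25))
  expect_equal(attr(y0, "beta0"), 0)
})

test_that("a full study composes reproducibly and supports plug-in genotypes", {
  d <- simulation_design(n = 150, m = 300, m1 = 8, rho = 0.35, seed = 77)
  s1 <- simulate_study(d)
  s2 <- simulate_study(d)
  expect_identical(s1$G, s2$G)
  expect_identical(as.numeric(s1$y), as.numeric(s2$y))
  expect_identical(s1$markers, s2$markers)
  expect_equal(dim(s1$G), c(150L, 300L))
  expect_equal(sum(s1$markers$beta != 0), 8)

  # user-supplied genotype matrix: observed MAFs, groupwise causal draw
  withr::local_seed(48)
  Gu <- simulate_genotypes(400, runif(200, 0.02, 0.45))
  du <- simulation_design(n = 400, m = 200, m1 = 8, seed = 78)
  su <- simulate_study(du, genotypes = Gu)
  expect_identical(unname(su$G), unname(Gu))
  expect_equal(sum(su$markers$is_causal), 8)
  expect_equal(su$markers$maf, observed_maf(Gu))
  grp <- table(droplevels(su$markers$maf_group[su$markers$is_causal]))
  expect_equal(as.integer(grp), c(2L, 2L, 2L, 2L))
})

test_that("the large-m code path produces well-shaped output", {
  d <- simulation_design(n = 40, m = 20000, m1 = 100, seed = 79)
  s <- simulate_study(d)
  expect_equal(dim(s$G), c(40L, 20000L))
  expect_true(all(s$G %in% 0:2))
  expect_equal(sum(s$markers$is_causal), 100)
  expect_equal(length(s$y), 40)
})
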