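test_that("haplotype pools are deterministic under a seed and internally consistent", {
  p1 <- generate_haplotype_pool(p = 30, H = 60, seed = 5)
  p2 <- generate_haplotype_pool(p = 30, H = 60, seed = 5)
  expect_identical(p1, p2)
  expect_equal(sum(p1$frequencies), 1, tolerance = 1e-12)
  expect_true(all(p1$frequencies >= 0))
  expect_true(all(p1$pop_maf <= 0.5))
  expect_equal(p1$pop_maf, as.vector(p1$frequencies %*% p1$haplotypes))
  # pool JSON round-trip
  tmp <- withr::local_tempfile(fileext = ".json")
  write_pool(p1, tmp)
  p3 <- read_pool(tmp)
  expect_equal(p3$haplotypes, p1$haplotypes)
  expect_equal(p3$frequencies, p1$frequencies)
  expect_equal(as.data.frame(p3$annotations), as.data.frame(p1$annotations))
})

test_that("annotation algorithms reach the target concordance", {
  pool <- generate_haplotype_pool(p = 2500, H = 40, concordance = 1, seed = 2,
                                  require_functional = FALSE)
  ann <- pool$annotations
  expect_identical(ann$algoA, ann$algoB)
  expect_identical(ann$algoA, ann$algoC)

  pool <- generate_haplotype_pool(p = 4000, H = 40, concordance = 0.6, seed = 3,
                                  require_functional = FALSE)
  ann <- pool$annotations
  ns <- ann$algoA != "synonymous"
  for (pair in list(c("algoA", "algoB"), c("algoA", "algoC"), c("algoB", "algoC")))
    expect_equal(mean(ann[[pair[1]]][ns] == ann[[pair[2]]][ns]), 0.6,
                 tolerance = 0.05 / 0.6)
})

test_that("the frequency spectrum is rare-heavy and genotype draws respect pool MAFs", {
  fr <- sapply(1:10, function(k)
    mean(generate_haplotype_pool(p = 40, H = 100, seed = k)$pop_maf < 0.01))
  expect_equal(mean(fr), 0.85, tolerance = 0.08)

  pool <- generate_haplotype_pool(p = 20, H = 50, seed = 9)
  dat <- sample_quantitative(pool, rep(0, 20), n = 40000, seed = 4)
  emp <- colSums(dat$genotypes$dosages) / (2 * 40000)
  expect_lt(max(abs(emp - pool$pop_maf)), 0.01)
  expect_gt(cor(emp, pool$pop_maf), 0.99)
})

test_that("scenario effect vectors follow the generative definitions", {
  pool <- toy_pool()   # pop_maf (0.004, 0.006, 0.19); algoA del on v1, v2

  # scenario 1: constant log OR on rare functional variants
  b1 <- scenario_betas(pool, scenario_config(1, effect = 2, cutoff = 0.01))
  expect_equal(b1, c(log(2), log(2), 0))
  b1b <- scenario_betas(pool, scenario_config(1, effect = 2, cutoff = 0.005))
  expect_equal(b1b, c(log(2), 0, 0))

  # scenario 3: effect proportional to 1 - score over nonsynonymous variants
  b3 <- scenario_betas(pool, scenario_config(3, effect = 2))
  expect_equal(b3, log(2) * c(1, 0.5, 0))

  # scenario 4: decay lambda/(lambda+maf) rescaled to 1 at the rarest
  cfg4 <- scenario_config(4, effect = 2, lambda = 0.001)
  b4 <- scenario_betas(pool, cfg4)
  k <- (0.001 / (0.001 + pool$pop_maf))
  k <- k / k[1]
  expect_equal(b4, log(2) * k * c(1, 1, 0))
  expect_lt(max(abs(b4[pool$pop_maf > 0.1])), 0.05 * log(2))

  # scenario 5 with deleterious_fraction 1 degenerates to scenario 1
  set.seed(1)
  b5 <- scenario_betas(pool, scenario_config(5, effect = 2, cutoff = 0.01,
                                             deleterious_fraction = 1))
  expect_equal(b5, b1)
  # a 50/50 split assigns opposite directions with equal magnitude
  set.seed(2)
  b5h <- scenario_betas(pool, scenario_config(5, effect = 2, cutoff = 0.01,
                                              deleterious_fraction = 0.5))
  expect_setequal(abs(b5h[1:2]), c(log(2), log(2)))
  expect_equal(sort(sign(b5h[1:2])), c(-1, 1))

  # magnitudes never exceed log(effect)
  for (sc in 1:5) {
    bb <- scenario_betas(pool, scenario_config(sc, effect = 3))
    expect_lte(max(abs(bb)), log(3) + 1e-12)
  }
})

test_that("a random causal threshold adds between-replicate variability", {
  pool <- generate_haplotype_pool(p = 40, H = 100, seed = 31)
  set.seed(10)
  n1 <- replicate(100, sum(scenario_betas(pool, scenario_config(1, effect = 2)) != 0))
  n2 <- replicate(100, sum(scenario_betas(pool, scenario_config(2, effect = 2)) != 0))
  expect_equal(var(n1), 0)
  expect_gt(var(n2), 0)
})

test_that("intercept calibration hits the target prevalence", {
  pool <- toy_pool()
  # no effects: closed form logit(K)
  expect_equal(calibrate_intercept(pool, rep(0, 3), 0.01), qlogis(0.01))

  beta <- scenario_betas(pool, scenario_config(1, effect = 2))
  b0 <- calibrate_intercept(pool, beta, 0.01)
  # independent brute-force enumeration over all ordered haplotype pairs
  f <- pool$frequencies
  prev <- 0
  for (i in 1:4) for (j in 1:4) {
    g <- pool$haplotypes[i, ] + pool$haplotypes[j, ]
    prev <- prev + f[i] * f[j] * plogis(b0 + sum(g * beta))
  }
  expect_equal(prev, 0.01, tolerance = 1e-6)

  # exact enumeration agrees with Monte-Carlo root-finding to ~3 decimals
  b0_mc <- rarestep:::with_seed(99,
    calibrate_intercept(pool, beta, 0.01, exact_limit = 1, mc_n = 4e5))
  expect_equal(b0_mc, b0, tolerance = 1e-2)

  expect_error(calibrate_intercept(pool, rep(0.1, 3), 1.5), "in \\(0, 1\\)")
})

test_that("case-control sampling respects dimensions, direction, and its budget", {
  pool <- generate_haplotype_pool(p = 25, H = 60, seed = 41)
  beta <- rep(0, 25)
  j <- which.min(abs(pool$pop_maf - 0.05))
  beta[j] <- log(6)
  model <- disease_model(pool, beta, prevalence = 0.05)
  dat <- sample_case_control(pool, model, 300, 300, seed = 8)
  expect_equal(dim(dat$genotypes), c(600L, 25L))
  expect_equal(sum(dat$phenotypes$values), 300)
  case <- dat$phenotypes$values == 1
  expect_gt(mean(dat$genotypes$dosages[case, j]),
            mean(dat$genotypes$dosages[!case, j]))

  # null model: case and control dosage means agree within noise
  model0 <- disease_model(pool, rep(0, 25), prevalence = 0.05)
  dat0 <- sample_case_control(pool, model0, 500, 500, seed = 9)
  d <- colMeans(dat0$genotypes$dosages[1:500, ]) -
       colMeans(dat0$genotypes$dosages[501:1000, ])
  expect_lt(max(abs(d)), 0.15)

  expect_error(sample_case_control(pool, model0, 1000, 10, seed = 1,
                                   max_draws = 500),
               "budget")
})

test_that("quantitative traits have the modelled means and unit residual variance", {
  pool <- generate_haplotype_pool(p = 15, H = 50, seed = 51)
  beta <- rep(0, 15)
  j <- which.min(abs(pool$pop_maf - 0.2))
  beta[j] <- 0.6
  dat <- sample_quantitative(pool, beta, n = 20000, seed = 6)
  g <- dat$genotypes$dosages[, j]
  y <- dat$phenotypes$values
  expect_equal(mean(y[g == 1]) - mean(y[g == 0]), 0.6, tolerance = 0.1)
  expect_equal(sd(y - g * 0.6), 1, tolerance = 0.03)
  expect_equal(dat$phenotypes$trait_type, "continuous")

  dat0 <- sample_quantitative(pool, rep(0, 15), n = 20000, seed = 7)
  expect_equal(mean(dat0$phenotypes$values), 0, tolerance = 0.03)
  expect_equal(sd(dat0$phenotypes$values), 1, tolerance = 0.03)
})
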