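test_that("aggregate scores follow the multiplicative weight model", {
  G <- genotype_matrix(rbind(c(1L, 0L), c(0L, 2L)), orient = FALSE)
  expect_equal(aggregate_score(G, model_spec(1, 1, c(1L, 1L), "m")), c(1, 2))
  expect_equal(aggregate_score(G, model_spec(1, 1, c(0L, 0L), "m")), c(0, 0))
  G1 <- genotype_matrix(rbind(c(1L, 1L), c(0L, 0L)), orient = FALSE)
  expect_equal(aggregate_score(G1, model_spec(c(2, 1), c(1, -1), c(1L, 1L), "m")),
               c(2 - 1, 0))
})

test_that("score statistic matches the hand-computed centred-score formula", {
  # U = 0.5, sigma2_ML = 0.25, sum (S - Sbar)^2 = 0.75 -> T = 4/3
  expect_equal(score_statistic(c(1, 0, 0, 0), c(1, 1, 0, 0)), 4 / 3)
  # degenerate inputs score zero
  expect_equal(score_statistic(rep(2, 4), c(1, 1, 0, 0)), 0)
  expect_equal(score_statistic(c(1, 0, 0, 0), rep(1, 4)), 0)
})

test_that("score statistic is invariant to affine rescaling of S and of a continuous Y", {
  set.seed(8)
  S <- rnorm(25); y <- rnorm(25)
  t0 <- score_statistic(S, y)
  expect_equal(score_statistic(3.7 * S - 2, y), t0)
  expect_equal(score_statistic(-0.4 * S + 1, y), t0)
  expect_equal(score_statistic(S, 2.2 * y + 5), t0)
})

test_that("score statistic equals a from-scratch logistic score test", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    while (length(unique(y)) < 2) y <- rbinom(n, 1, 0.5)
    S <- rbinom(n, 2, runif(1, 0.05, 0.4)) + rnorm(n, sd = 0.02)
    expect_equal(score_statistic(S, y), logistic_score_oracle(S, y),
                 tolerance = 1e-10)
  }
})

test_that("single-variant dichotomous statistic equals the Cochran-Armitage trend test", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(30:80, 1)
    g <- rbinom(n, 2, runif(1, 0.1, 0.4))
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2 || var(g) == 0) next
    tab <- table(factor(g, levels = 0:2), factor(y, levels = 0:1))
    ca <- suppressWarnings(prop.trend.test(tab[, 2], rowSums(tab), score = 0:2))
    expect_equal(score_statistic(g, y), unname(ca$statistic))
  }
})

test_that("max over models equals brute-force maximisation with first-wins ties", {
  set.seed(12)
  G <- rand_geno(30, 4)
  Y <- rand_balanced_y(30)
  specs <- list(model_spec(1, 1, c(1L, 0L, 0L, 0L), "a"),
                model_spec(1, 1, c(1L, 1L, 0L, 0L), "b"),
                model_spec(1, 1, c(1L, 1L, 1L, 1L), "c"))
  res <- max_over_models(G, Y, model_set(specs))
  direct <- sapply(specs, function(m) score_statistic(aggregate_score(G, m), Y))
  expect_equal(res$statistic, max(direct))
  expect_equal(res$best_model, c("a", "b", "c")[which.max(direct)])

  # a duplicated model (same gamma, later label) cannot displace the first
  specs2 <- c(specs[which.max(direct)], specs, list(
    model_spec(1, 1, specs[[which.max(direct)]]$gamma, "dup")))
  specs2[[1]]$label <- "first"
  res2 <- max_over_models(G, Y, model_set(specs2))
  expect_equal(res2$statistic, res$statistic)
  expect_equal(res2$best_model, "first")

  # singleton set reduces to the plain score statistic
  res1 <- max_over_models(G, Y, model_set(specs[2]))
  expect_equal(res1$statistic, direct[2])
})

test_that("unsigned constant-weight statistic is invariant to variant order", {
  set.seed(19)
  G <- rand_geno(40, 6)
  Y <- rand_balanced_y(40)
  perm <- sample.int(6)
  G2 <- genotype_matrix(G$dosages[, perm], orient = FALSE)
  spec_all <- function(g) model_spec(1, 1, rep(1L, 6), "all")
  expect_equal(score_statistic(aggregate_score(G2, spec_all(G2)), Y),
               score_statistic(aggregate_score(G, spec_all(G)), Y))
  expect_equal(step_up(G2, Y)$statistic, step_up(G, Y)$statistic)
})

test_that("fixed-threshold burden test matches its definition", {
  set.seed(7)
  G <- rand_geno(40, 5, maf_lo = 0.02, maf_hi = 0.3)
  Y <- rand_balanced_y(40)
  cutoff <- stats::median(G$maf)
  spec <- model_spec(1, 1, maf_threshold_inclusion(G$maf, cutoff), "x")
  expect_equal(cast_test(G, Y, cutoff)$statistic,
               score_statistic(aggregate_score(G, spec), Y))
  # cutoff below every MAF -> empty model -> statistic 0
  expect_equal(cast_test(G, Y, min(G$maf) / 2)$statistic, 0)
})

test_that("CMC likelihood-ratio test matches direct likelihood maximisation", {
  loglik <- function(b, X, y) { eta <- X %*% b; sum(y * eta - log1p(exp(eta))) }
  set.seed(61)
  G <- rand_geno(80, 6, maf_lo = 0.01, maf_hi = 0.35)
  Y <- rand_balanced_y(80)
  cutoff <- stats::median(G$maf)
  res <- cmc_test(G, Y, cutoff)
  n_common <- sum(G$maf > cutoff)
  expect_equal(res$df, 1L + n_common)

  rare <- G$maf > 0 & G$maf <= cutoff
  X <- cbind(1, as.integer(rowSums(G$dosages[, rare, drop = FALSE]) > 0),
             G$dosages[, G$maf > cutoff, drop = FALSE])
  o1 <- optim(rep(0, ncol(X)), function(b) -loglik(b, X, Y$values),
              method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
  o0 <- optim(0, function(b) -loglik(b, matrix(1, 80), Y$values),
              method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
  expect_equal(res$statistic, 2 * (o0$value - o1$value), tolerance = 1e-6)

  # boundary layouts of the design
  G_rare <- rand_geno(60, 3, maf_lo = 0.02, maf_hi = 0.1)
  expect_equal(cmc_test(G_rare, rand_balanced_y(60), 0.2)$df, 1L)
  G_comm <- rand_geno(60, 3, maf_lo = 0.25, maf_hi = 0.45)
  expect_equal(cmc_test(G_comm, rand_balanced_y(60), 0.01)$df, 3L)

  # duplicated (collinear) common column is dropped with a warning
  Gd <- genotype_matrix(cbind(G_comm$dosages, G_comm$dosages[, 1]), orient = FALSE)
  expect_warning(resd <- cmc_test(Gd, rand_balanced_y(60), 0.01), "collinear")
  expect_equal(resd$df, 3L)
})
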