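test_that("constant weights reduce the aggregate score to a dosage sum", {
  expect_equal(constant_weights(3), c(1, 1, 1))
  expect_equal(constant_weights(1), 1)
  G <- rand_geno(8, 4)
  spec <- model_spec(constant_weights(4), 1, rep(1L, 4), "sum")
  expect_equal(aggregate_score(G, spec), unname(rowSums(G$dosages)))
})

test_that("allele-frequency weights match the pseudocount formula", {
  # 2 cases + 2 controls, control minor-allele count 0
  G <- genotype_matrix(matrix(c(1L, 0L, 0L, 0L), 4, 1), orient = FALSE)
  Y <- phenotype_vector(c(1, 1, 0, 0))
  q <- (0 + 1) / (2 * 2 + 2)
  expect_equal(madsen_browning_weights(G, Y), 1 / sqrt(4 * q * (1 - q)))
  expect_equal(madsen_browning_weights(G, Y), 1.342, tolerance = 1e-3)

  # monomorphic variant still gets a finite positive weight
  G0 <- genotype_matrix(matrix(0L, 4, 1), orient = FALSE)
  w0 <- madsen_browning_weights(G0, Y)
  expect_true(is.finite(w0) && w0 > 0)

  # equal control counts give equal weights
  G2 <- genotype_matrix(cbind(c(1L, 0L, 1L, 0L), c(0L, 1L, 0L, 1L)), orient = FALSE)
  w <- madsen_browning_weights(G2, Y)
  expect_equal(w[1], w[2])

  # continuous traits use all subjects as the reference group
  Yc <- phenotype_vector(c(0.2, 1.4, -1, 0.5), trait_type = "continuous")
  q4 <- (1 + 1) / (2 * 4 + 2)
  expect_equal(madsen_browning_weights(G, Yc), 1 / sqrt(4 * q4 * (1 - q4)))
})

test_that("weights are invariant to permuting individuals within controls", {
  set.seed(11)
  G <- rand_geno(30, 6)
  Y <- phenotype_vector(rep(c(1, 0), each = 15))
  w1 <- madsen_browning_weights(G, Y)
  perm <- c(1:15, 15 + sample.int(15))
  G2 <- genotype_matrix(G$dosages[perm, ], orient = FALSE)
  expect_equal(madsen_browning_weights(G2, Y), w1)
})

test_that("signs follow case-control enrichment with +1 ties, and flip with labels", {
  # cases carry dosages (2,1), controls (0,0) -> deleterious
  G <- genotype_matrix(matrix(c(2L, 1L, 0L, 0L), 4, 1), orient = FALSE)
  Y <- phenotype_vector(c(1, 1, 0, 0))
  expect_equal(sign_variants(G, Y), 1)

  # exactly equal frequencies -> +1 by the tie rule
  Gt <- genotype_matrix(matrix(c(1L, 0L, 1L, 0L), 4, 1), orient = FALSE)
  expect_equal(sign_variants(Gt, Y), 1)

  # continuous: negative trait-dosage covariance
  Gc <- genotype_matrix(matrix(c(2L, 1L, 0L), 3, 1), orient = FALSE)
  Yc <- phenotype_vector(c(1, 2, 3), trait_type = "continuous")
  expect_equal(sign_variants(Gc, Yc), -1)

  # flipping case/control labels flips every non-tied sign
  set.seed(3)
  for (rep in 1:5) {
    G <- rand_geno(40, 8)
    Y <- rand_balanced_y(40)
    Yf <- phenotype_vector(1 - Y$values)
    s <- sign_variants(G, Y); sf <- sign_variants(G, Yf)
    case <- Y$values == 1
    tied <- colSums(G$dosages[case, , drop = FALSE]) ==
            colSums(G$dosages[!case, , drop = FALSE])
    expect_equal(sf[!tied], -s[!tied])
    expect_true(all(s[tied] == 1 & sf[tied] == 1))
  }
  # continuous: negating the trait negates every (nonzero) covariance
  Ycc <- phenotype_vector(rnorm(40), trait_type = "continuous")
  G <- rand_geno(40, 8)
  expect_equal(sign_variants(G, phenotype_vector(-Ycc$values, "continuous")),
               -sign_variants(G, Ycc))
})

test_that("MAF threshold inclusion is inclusive and excludes monomorphic", {
  expect_equal(maf_threshold_inclusion(c(0.005, 0.02, 0.2), 0.01), c(1L, 0L, 0L))
  expect_equal(maf_threshold_inclusion(c(0.005, 0, 0.2), 0.5), c(1L, 0L, 1L))
  expect_equal(maf_threshold_inclusion(0.01, 0.01), 1L)
  expect_error(maf_threshold_inclusion(0.1, 0), "0, 0.5")
})

test_that("all-MAF model sets deduplicate thresholds and are nested", {
  ms <- all_maf_model_set(c(0.01, 0.01, 0.03))
  expect_equal(length(ms), 2)
  expect_equal(length(all_maf_model_set(0.02)), 1)
  maf <- c(0.004, 0.02, 0.11, 0.3)
  ms <- all_maf_model_set(maf)
  expect_equal(length(ms), 4)
  gam <- sapply(ms$specs, function(m) m$gamma)
  for (k in seq_len(ncol(gam) - 1)) expect_true(all(gam[, k] <= gam[, k + 1]))
})

test_that("functional model sets cross groups with thresholds and drop empties", {
  set.seed(21)
  G <- rand_geno(40, 6, maf_lo = 0.01, maf_hi = 0.3)
  ann <- variant_annotation(data.frame(
    variant_id = G$variant_ids,
    algoA = c("deleterious", "deleterious", "tolerated", "synonymous", "synonymous", "tolerated"),
    algoB = c("deleterious", "tolerated", "tolerated", "synonymous", "synonymous", "deleterious"),
    algoC = c("tolerated", "deleterious", "deleterious", "synonymous", "synonymous", "tolerated"),
    score = c(0.01, 0.2, 0.6, NA, NA, 0.9)))
  ms1 <- functional_model_set(ann, G, groups = "nonsynonymous", maf_sets = 0.5)
  expect_equal(length(ms1), 1)
  # nonsynonymous group = deleterious OR tolerated calls
  expect_equal(ms1$specs[[1]]$gamma,
               as.integer(ann$algoA != "synonymous" & G$maf > 0))

  n_thresh <- length(unique(G$maf[G$maf > 0]))
  msA <- suppressWarnings(functional_model_set(
    ann, G, groups = c("algoA_deleterious", "algoB_deleterious", "algoC_deleterious"),
    maf_sets = "all_maf"))
  expect_lte(length(msA), 3 * n_thresh)

  # all-empty groups error
  ann_syn <- variant_annotation(data.frame(
    variant_id = G$variant_ids, algoA = "synonymous", algoB = "synonymous",
    algoC = "synonymous", score = NA_real_))
  expect_error(suppressWarnings(functional_model_set(ann_syn, G)), "empty")
})
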