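# Shared fixtures and independent oracles used across the suite.

# random case-control toy data: p variants with column-constant MAFs
rand_geno <- function(n, p, maf_lo = 0.05, maf_hi = 0.3) {
  genotype_matrix(matrix(stats::rbinom(n * p, 2, stats::runif(p, maf_lo, maf_hi)),
                         n, p, byrow = TRUE))
}

rand_balanced_y <- function(n) phenotype_vector(rep(c(1, 0), length.out = n)[sample.int(n)])

# all permutations of 1..n (n! rows); recursion is fine for the n <= 7 used here
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

# brute-force best-subset search over all nonempty subsets of polymorphic
# variants, computed through the direct aggregate-score formula (a code
# path independent of the incremental step-up engine)
exhaustive_best_subset <- function(G, Y, w = rep(1, G$p), s = rep(1, G$p)) {
  poly <- which(G$maf > 0)
  best_t <- -Inf; best_set <- integer()
  for (m in seq_len(2^length(poly) - 1)) {
    idx <- poly[bitwAnd(m, 2^(seq_along(poly) - 1)) > 0]
    gamma <- integer(G$p); gamma[idx] <- 1L
    t_m <- score_statistic(aggregate_score(G, model_spec(w, s, gamma, "x")), Y)
    if (t_m > best_t) { best_t <- t_m; best_set <- idx }
  }
  list(statistic = best_t, subset = best_set)
}

# logistic-regression Rao score test of y on S, built from the likelihood:
# the null intercept is fitted by Newton-Raphson on the score equation, the
# score vector and expected information are then assembled and the statistic
# is the information-standardised squared score for the S coefficient.
logistic_score_oracle <- function(S, y) {
  b0 <- 0
  for (i in 1:100) {
    mu <- 1 / (1 + exp(-b0))
    step <- sum(y - mu) / (length(y) * mu * (1 - mu))
    b0 <- b0 + step
    if (abs(step) < 1e-15) break
  }
  mu <- 1 / (1 + exp(-b0))
  X <- cbind(1, S)
  U <- crossprod(X, y - mu)                    # score vector at the null fit
  I <- crossprod(X * (mu * (1 - mu)), X)       # expected information
  drop(t(U) %*% solve(I, U))
}

# hand-built haplotype pool for scenario unit tests
make_pool <- function(haplotypes, frequencies, annotations) {
  structure(list(haplotypes = haplotypes, frequencies = frequencies,
                 pop_maf = as.vector(frequencies %*% haplotypes),
                 annotations = variant_annotation(annotations),
                 variant_ids = annotations$variant_id,
                 concordance = NA_real_),
            class = "haplotype_pool")
}

# 4-haplotype, 3-variant pool with known frequencies and annotations
toy_pool <- function() {
  hap <- rbind(c(1, 0, 0),
               c(0, 1, 0),
               c(0, 0, 1),
               c(0, 0, 0))
  ann <- data.frame(variant_id = c("v1", "v2", "v3"),
                    algoA = c("deleterious", "deleterious", "tolerated"),
                    algoB = c("deleterious", "tolerated", "tolerated"),
                    algoC = c("deleterious", "deleterious", "deleterious"),
                    score = c(0, 0.5, 1), stringsAsFactors = FALSE)
  make_pool(hap, c(0.004, 0.006, 0.19, 0.8), ann)
}
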