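#' Per-individual aggregated genotype score
#'
#' Computes \eqn{S_i = \sum_j w_j s_j \gamma_j G_{ij}}, the weighted,
#' signed, selected combination of minor-allele dosages that the score
#' test evaluates.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param spec a \code{\link{model_spec}}.
#' @return Numeric vector of length n.
#' @export
aggregate_score <- function(G, spec) {
  if (length(spec$gamma) != G$p) stop("model dimension does not match genotype matrix")
  as.vector(G$dosages %*% (spec$w * spec$s * spec$gamma))
}

#' Score statistic for an aggregated genotype score
#'
#' The mean-centred score cross-product divided by its empirical
#' variance,
#' \deqn{T = \frac{\left(\sum_i (Y_i - \bar Y) S_i\right)^2}
#'                {\hat\sigma^2_Y \sum_i (S_i - \bar S)^2},}
#' with the maximum-likelihood variance \eqn{\hat\sigma^2_Y =
#' \frac1n \sum_i (Y_i - \bar Y)^2}.  Under the null hypothesis of no
#' association T follows a chi-squared distribution with one degree of
#' freedom; for a dichotomous trait T is algebraically identical to the
#' Rao score test of logistic regression of Y on S.  Degenerate inputs
#' (constant S or constant Y) return 0 so that maximisation over model
#' sets containing empty models remains well defined.
#'
#' @param S numeric aggregated score (from \code{\link{aggregate_score}}).
#' @param Y a \code{\link{phenotype_vector}} or numeric vector.
#' @return Non-negative scalar test statistic.
#' @export
score_statistic <- function(S, Y) {
  y <- if (inherits(Y, "phenotype_vector")) Y$values else as.numeric(Y)
  n <- length(y)
  if (n < 2 || length(S) != n) stop("S and Y must have equal length >= 2")
  yc <- y - mean(y)
  sigma2 <- mean(yc^2)
  Sc <- S - mean(S)
  vS <- sum(Sc^2)
  if (sigma2 <= 0 || vS <= 0) return(0)
  sum(yc * S)^2 / (sigma2 * vS)
}

# ---- internal score engine -------------------------------------------------
#
# Precomputes, once per genotype matrix, the centred cross-product matrix
# C0[j,k] = sum_i (G_ij - mean_j)(G_ik - mean_k).  For any model with
# per-variant coefficient a_j = w_j s_j gamma_j,
#   T = (sum_j a_j u0_j)^2 / (sigma2 * a' C0 a),
# where u0_j = sum_i (Y_i - Ybar) G_ij depends on the phenotype only
# through an O(np) cross-product.  Column scaling commutes with centring,
# so C0 never has to be recomputed inside permutations, which makes the
# full-procedure permutation loop cheap.

score_engine <- function(G) {
  Gc <- sweep(G$dosages, 2L, colMeans(G$dosages))
  C0 <- crossprod(Gc)
  dimnames(C0) <- NULL
  list(G = G, C0 = C0, poly = which(G$maf > 0))
}

engine_phenotype <- function(engine, y) {
  yc <- y - mean(y)
  list(u0 = as.vector(crossprod(engine$G$dosages, yc)),
       sigma2 = mean(yc^2))
}

engine_model_stat <- function(engine, ph, a) {
  idx <- which(a != 0)
  if (length(idx) == 0 || ph$sigma2 <= 0) return(0)
  ai <- a[idx]
  U <- sum(ai * ph$u0[idx])
  V <- as.numeric(ai %*% engine$C0[idx, idx, drop = FALSE] %*% ai)
  if (V <= 0) return(0)
  U^2 / (ph$sigma2 * V)
}

# Greedy step-up search on precomputed quantities.  b_j = a_j u0_j,
# C = C0 scaled by a outer a; maintains the current group's score sum,
# variance and cross terms so each candidate evaluation is O(1) after an
# O(p) vector update per accepted step.
engine_step_up <- function(engine, ph, a) {
  cand <- engine$poly
  if (length(cand) == 0) return(list(statistic = 0, selected = integer()))
  if (ph$sigma2 <= 0) return(list(statistic = 0, selected = cand[1]))
  b <- a * ph$u0
  Cdiag <- diag(engine$C0) * a^2
  t_uni <- ifelse(Cdiag[cand] > 0, b[cand]^2 / (ph$sigma2 * Cdiag[cand]), 0)
  best <- cand[which.max(t_uni)]
  sel <- best
  t_cur <- max(t_uni)
  usum <- b[best]
  vsum <- Cdiag[best]
  cross <- engine$C0[, best] * a * a[best]   # sum over selected of C[j, sel]
  remaining <- setdiff(cand, sel)
  while (length(remaining) > 0) {
    denom <- vsum + 2 * cross[remaining] + Cdiag[remaining]
    num <- (usum + b[remaining])^2
    t_try <- ifelse(denom > 0, num / (ph$sigma2 * denom), 0)
    k <- which.max(t_try)          # ties: lowest variant index wins
    if (t_try[k] <= t_cur) break   # plateau terminates the search
    j <- remaining[k]
    t_cur <- t_try[k]
    usum <- usum + b[j]
    vsum <- vsum + 2 * cross[j] + Cdiag[j]
    cross <- cross + engine$C0[, j] * a * a[j]
    sel <- c(sel, j)
    remaining <- remaining[-k]
  }
  list(statistic = t_cur, selected = sel)
}

# ---------------------------------------------------------------------------

test_result <- function(statistic, best_model, selected_variants, method,
                        p_value = NA_real_, n_permutations = 0L,
                        adaptive = FALSE, extra = list()) {
  structure(c(list(statistic = statistic, best_model = best_model,
                   selected_variants = selected_variants,
                   p_value = p_value, n_permutations = n_permutations,
                   adaptive = adaptive, method = method), extra),
            class = "rarestep_result")
}

#' @export
print.rarestep_result <- function(x, ...) {
  cat("Rare-variant aggregation test\n")
  cat(sprintf("  method:    %s\n", x$method))
  cat(sprintf("  statistic: %.5g\n", x$statistic))
  if (!is.na(x$p_value)) {
    cat(sprintf("  p-value:   %.5g  (%d permutation%s%s)\n", x$p_value,
                x$n_permutations, if (x$n_permutations == 1) "" else "s",
                if (isTRUE(x$adaptive)) ", adaptive early stop" else ""))
  }
  if (!is.null(x$best_model) && !is.na(x$best_model))
    cat(sprintf("  best model: %s\n", x$best_model))
  if (length(x$selected_variants))
    cat(sprintf("  selected:  %s\n", paste(x$selected_variants, collapse = ", ")))
  invisible(x)
}

#' Maximum score statistic over a family of weight models
#'
#' Evaluates the score statistic for every model in the set and returns
#' the maximum; the first model in set order wins ties, so the result is
#' deterministic given the set order.  The returned p-value is NA: the
#' maximised statistic must be calibrated by permutation
#' (\code{\link{permutation_pvalue}}) because the model search is
#' data-adaptive.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param Y a \code{\link{phenotype_vector}}.
#' @param M a \code{\link{model_set}}.
#' @return A \code{rarestep_result} (without p-value).
#' @export
max_over_models <- function(G, Y, M) {
  check_dimensions(G, Y)
  engine <- score_engine(G)
  ph <- engine_phenotype(engine, Y$values)
  stats <- vapply(M$specs, function(m)
    engine_model_stat(engine, ph, m$w * m$s * m$gamma), 0)
  k <- which.max(stats)
  best <- M$specs[[k]]
  test_result(statistic = stats[k], best_model = best$label,
              selected_variants = G$variant_ids[best$gamma == 1],
              method = paste0("max over ", length(M$specs), " model(s) [",
                              M$generator, "]"),
              extra = list(model_statistics = stats))
}

#' Greedy step-up variant selection
#'
#' Data-driven search for the best single aggregated group of variants:
#' first the univariate score statistic is computed for every
#' (polymorphic) variant with the chosen weight and sign model applied
#' marginally; the best variant seeds the group; then the variant whose
#' addition most increases the statistic is repeatedly added until no
#' addition strictly increases it.  Ties are broken towards the lowest
#' variant index.  The search costs at worst a squared number of
#' statistic evaluations in the number of variants.  Weights and signs
#' are computed once from the full data before selection and are not
#' re-estimated per subset.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param Y a \code{\link{phenotype_vector}}.
#' @param weights \code{"constant"} or \code{"maf"} (allele-frequency
#'   weights of \code{\link{madsen_browning_weights}}).
#' @param signed if \code{TRUE}, apply \code{\link{sign_variants}}
#'   directions.
#' @return A \code{rarestep_result} (without p-value) whose
#'   \code{selected_variants} is the chosen group in addition order.
#' @export
step_up <- function(G, Y, weights = c("constant", "maf"), signed = FALSE) {
  check_dimensions(G, Y)
  weights <- match.arg(weights)
  if (!any(G$maf > 0)) stop("step-up needs at least one polymorphic variant")
  engine <- score_engine(G)
  ph <- engine_phenotype(engine, Y$values)
  w <- if (weights == "maf") madsen_browning_weights(G, Y) else constant_weights(G$p)
  s <- if (signed) sign_variants(G, Y) else rep(1, G$p)
  res <- engine_step_up(engine, ph, w * s)
  lab <- sprintf("step-up(%s,%s)", if (weights == "maf") "W" else "C",
                 if (signed) "s=±" else "s=1")
  test_result(statistic = res$statistic, best_model = lab,
              selected_variants = G$variant_ids[res$selected],
              method = lab)
}

#' Fixed-threshold dosage-sum burden test
#'
#' Sums minor-allele dosages over all variants with \code{0 < maf <=
#' cutoff} with unit weights and no signing, and computes the score
#' statistic: a dosage-sum analogue of the cohort allelic sums test.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param Y a \code{\link{phenotype_vector}}.
#' @param cutoff MAF threshold in (0, 0.5].
#' @return A \code{rarestep_result} (without p-value).
#' @export
cast_test <- function(G, Y, cutoff = 0.01) {
  gamma <- maf_threshold_inclusion(G$maf, cutoff)
  spec <- model_spec(1, 1, gamma, label = sprintf("C,s=1,MAF<=%.6g", cutoff))
  if (sum(gamma) == 0)
    return(test_result(0, spec$label, character(), method = spec$label))
  max_over_models(G, Y, model_set(list(spec)))
}

#' Combined multivariate and collapsing (CMC) comparator test
#'
#' Likelihood-ratio test of a logistic regression of disease status on
#' one collapsed term (indicator of carrying any rare variant, MAF at
#' or below \code{cutoff}) plus one dosage term per common variant,
#' against the intercept-only model.  Collinear columns are dropped with
#' a warning; non-convergence or separation yields an NA statistic with
#' a warning.  This comparator uses its asymptotic chi-squared p-value
#' rather than permutation.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param Y a dichotomous \code{\link{phenotype_vector}}.
#' @param cutoff MAF threshold separating rare from common variants.
#' @return List with \code{statistic}, \code{df}, \code{p_value},
#'   \code{method}.
#' @export
cmc_test <- function(G, Y, cutoff = 0.01) {
  check_dimensions(G, Y)
  if (Y$trait_type != "dichotomous")
    stop("the CMC comparator requires a dichotomous trait")
  rare <- G$maf > 0 & G$maf <= cutoff
  common <- G$maf > cutoff
  X <- NULL
  if (any(rare))
    X <- cbind(collapsed = as.integer(rowSums(G$dosages[, rare, drop = FALSE]) > 0))
  if (any(common))
    X <- cbind(X, G$dosages[, common, drop = FALSE])
  if (is.null(X))
    return(list(statistic = 0, df = 0L, p_value = 1, method = "CMC"))
  y <- Y$values
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged || sep_warn) {
    warning("CMC logistic regression did not converge (possible separation); returning NA")
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                method = "CMC"))
  }
  aliased <- is.na(fit$coefficients)
  if (any(aliased)) {
    warning("CMC: dropped ", sum(aliased), " collinear column(s)")
    keep <- which(!aliased[-1])
    fit <- stats::glm.fit(cbind(1, X[, keep, drop = FALSE]), y,
                          family = stats::binomial())
  }
  null_dev <- stats::glm.fit(matrix(1, length(y)), y,
                             family = stats::binomial())$deviance
  df <- sum(!is.na(fit$coefficients)) - 1L
  stat <- null_dev - fit$deviance
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       method = "CMC")
}
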