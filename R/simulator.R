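#' Generate a synthetic haplotype pool
#'
#' Builds the simulator's population: H haplotypes of p biallelic
#' variants with random simplex frequencies, a mostly-rare variant
#' frequency spectrum (by default about 85\% of variants have population
#' MAF below 0.01, echoing deep-sequenced candidate-gene data in which
#' the large majority of discovered SNVs are rare), and synthetic
#' functional annotations: a fraction of variants is nonsynonymous, each
#' nonsynonymous variant carries a continuous deleteriousness score in
#' [0,1] (0 = most deleterious, like a tolerance index) and three
#' partially concordant binary deleterious/tolerated calls.  The three
#' algorithms each report a latent deleterious state with accuracy
#' chosen so their expected pairwise agreement equals
#' \code{concordance}.
#'
#' Pools are drawn conditional on every algorithm calling at least one
#' rare (MAF <= 0.01) variant deleterious, mirroring the usual study
#' design in which genes without any putatively deleterious variant are
#' not analysed; set \code{require_functional = FALSE} to disable.
#'
#' @param p number of variants.
#' @param H number of distinct haplotypes.
#' @param spectrum frequency spectrum; currently \code{"rare_heavy"}.
#' @param rare_fraction fraction of variants targeted below MAF 0.01.
#' @param concordance target pairwise agreement of the three annotation
#'   algorithms, in [0.5, 1].
#' @param nonsyn_fraction fraction of variants that are nonsynonymous.
#' @param deleterious_rate latent probability that a nonsynonymous
#'   variant is truly deleterious.
#' @param seed optional integer seed (the pool is byte-identical under
#'   the same seed).
#' @param require_functional retry the annotation draw until every
#'   algorithm has at least one deleterious rare variant.
#' @return Object of class \code{haplotype_pool}: \code{haplotypes}
#'   (H x p 0/1 matrix), \code{frequencies} (sum to 1), \code{pop_maf},
#'   \code{annotations} (a \code{\link{variant_annotation}} table) and
#'   \code{variant_ids}.
#' @export
generate_haplotype_pool <- function(p = 40, H = 100, spectrum = "rare_heavy",
                                    rare_fraction = 0.85, concordance = 0.6,
                                    nonsyn_fraction = 0.3,
                                    deleterious_rate = 0.4,
                                    seed = NULL, require_functional = TRUE) {
  if (p < 1 || H < 2) stop("need p >= 1 variants and H >= 2 haplotypes")
  spectrum <- match.arg(spectrum, "rare_heavy")
  if (concordance < 0.5 || concordance > 1)
    stop("concordance must lie in [0.5, 1] (independent coin flips give 0.5)")
  with_seed(seed, {
    g <- stats::rgamma(H, 1)          # symmetric Dirichlet(1) simplex draw
    freq <- g / sum(g)
    rare <- stats::runif(p) < rare_fraction
    target <- ifelse(rare,
                     exp(stats::runif(p, log(5e-4), log(0.01))),
                     exp(stats::runif(p, log(0.01), log(0.35))))
    hap <- matrix(0L, nrow = H, ncol = p)
    pop_maf <- numeric(p)
    for (j in seq_len(p)) {
      # scan haplotypes in random order, keeping any that still fits the
      # remaining target mass, so carriers are scattered across haplotypes
      # and the realized MAF tracks the drawn spectrum
      ord <- sample.int(H)
      cum <- 0
      keep <- integer()
      for (h in ord) {
        if (cum + freq[h] <= target[j]) {
          keep <- c(keep, h)
          cum <- cum + freq[h]
        }
      }
      if (length(keep) == 0) {
        # nothing fits: use the single haplotype closest to the target
        keep <- which.min(abs(freq - target[j]))
        cum <- freq[keep]
      }
      hap[keep, j] <- 1L
      pop_maf[j] <- cum
    }
    ids <- sprintf("v%02d", seq_len(p))
    # annotation accuracy giving pairwise agreement a^2 + (1-a)^2 = concordance
    acc <- (1 + sqrt(2 * concordance - 1)) / 2
    draw_annotations <- function() {
      nonsyn <- stats::runif(p) < nonsyn_fraction
      latent <- nonsyn & stats::runif(p) < deleterious_rate
      score <- rep(NA_real_, p)
      score[nonsyn & latent] <- stats::runif(sum(nonsyn & latent), 0, 0.05)
      score[nonsyn & !latent] <- stats::runif(sum(nonsyn & !latent), 0.05, 1)
      calls <- lapply(1:3, function(a) {
        correct <- stats::runif(p) < acc
        del <- ifelse(correct, latent, !latent)
        ifelse(nonsyn, ifelse(del, "deleterious", "tolerated"), "synonymous")
      })
      data.frame(variant_id = ids, algoA = calls[[1]], algoB = calls[[2]],
                 algoC = calls[[3]], score = score, stringsAsFactors = FALSE)
    }
    ann <- draw_annotations()
    if (require_functional) {
      ok <- function(a) all(vapply(c("algoA", "algoB", "algoC"), function(al)
        any(a[[al]] == "deleterious" & pop_maf <= 0.01 & pop_maf > 0), TRUE))
      tries <- 1L
      while (!ok(ann)) {
        tries <- tries + 1L
        if (tries > 200L)
          stop("could not draw a pool with a deleterious rare variant for every algorithm; increase p or nonsyn_fraction")
        ann <- draw_annotations()
      }
    }
    structure(list(haplotypes = hap, frequencies = freq, pop_maf = pop_maf,
                   annotations = variant_annotation(ann), variant_ids = ids,
                   concordance = concordance),
              class = "haplotype_pool")
  })
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("haplotype_pool: %d haplotypes x %d variants\n",
              nrow(x$haplotypes), ncol(x$haplotypes)))
  cat(sprintf("  %.0f%% of variants below MAF 0.01; %d nonsynonymous, of which %d called deleterious by algoA\n",
              100 * mean(x$pop_maf < 0.01),
              sum(x$annotations$algoA != "synonymous"),
              sum(x$annotations$algoA == "deleterious")))
  invisible(x)
}

#' Serialize a haplotype pool to JSON
#' @param pool a \code{\link{generate_haplotype_pool}} result.
#' @param path output path.
#' @export
write_pool <- function(pool, path) {
  obj <- list(haplotypes = unname(apply(pool$haplotypes, 1, paste0, collapse = "")),
              frequencies = pool$frequencies,
              variant_ids = pool$variant_ids,
              annotations = as.data.frame(pool$annotations),
              concordance = pool$concordance)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Read a haplotype pool from JSON
#' @param path file written by \code{\link{write_pool}}.
#' @return A \code{haplotype_pool}.
#' @export
read_pool <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hap <- do.call(rbind, lapply(strsplit(obj$haplotypes, ""), as.integer))
  freq <- as.numeric(obj$frequencies)
  if (abs(sum(freq) - 1) > 1e-12) stop("pool frequencies must sum to 1")
  structure(list(haplotypes = hap, frequencies = freq,
                 pop_maf = as.vector(freq %*% hap),
                 annotations = variant_annotation(obj$annotations),
                 variant_ids = as.character(obj$variant_ids),
                 concordance = obj$concordance),
            class = "haplotype_pool")
}

#' Scenario configuration for the simulation study
#'
#' The five generative effect models:
#' \enumerate{
#'   \item fixed threshold: constant log-odds for every functional
#'     variant with population MAF at or below \code{cutoff};
#'   \item random threshold: as 1, but the cutoff is redrawn each
#'     replicate uniformly from the pool's distinct MAFs below 0.05;
#'   \item continuous penetrance: effect proportional to
#'     \eqn{1 - score}, so the most deleterious variants (score near 0)
#'     get the full effect;
#'   \item rare plus common: every functional variant has an effect
#'     decaying with MAF as \eqn{\lambda/(\lambda + maf)}, rescaled to 1
#'     at the rarest functional variant — small \eqn{\lambda} gives
#'     common variants almost no effect;
#'   \item mixed direction: rare functional variants are split so that
#'     approximately \code{deleterious_fraction} of their total MAF is
#'     deleterious (+log OR) and the rest protective (-log OR).
#' }
#'
#' @param scenario integer 1-5.
#' @param effect odds ratio (dichotomous; >= 1) or per-dosage mean
#'   difference (continuous).
#' @param cutoff MAF threshold defining "rare and causal" (scenarios 1,
#'   5).
#' @param lambda rare-vs-common sharing parameter (scenario 4).
#' @param deleterious_fraction fraction of total rare functional MAF
#'   assigned deleterious (scenario 5); the study arms use 0.5 and 0.8.
#' @param functional_algo which annotation algorithm defines
#'   "functional" (default \code{"algoA"}, the generating algorithm;
#'   scenario 3 uses all nonsynonymous variants via their scores).
#' @param n_cases,n_controls case-control sample sizes.
#' @param n_quantitative sample size for a continuous trait.
#' @param trait \code{"dichotomous"} or \code{"continuous"}.
#' @param prevalence target population disease prevalence (dichotomous).
#' @return Object of class \code{scenario_config}.
#' @export
scenario_config <- function(scenario, effect = 2, cutoff = 0.01,
                            lambda = 0.01, deleterious_fraction = 0.5,
                            functional_algo = "algoA",
                            n_cases = 1000, n_controls = 1000,
                            n_quantitative = 2000,
                            trait = c("dichotomous", "continuous"),
                            prevalence = 0.01) {
  if (!scenario %in% 1:5) stop("scenario must be 1..5")
  trait <- match.arg(trait)
  if (trait == "dichotomous" && effect < 1)
    stop("odds ratio must be >= 1 (use the protective split of scenario 5 for protective effects)")
  if (cutoff <= 0 || cutoff > 0.5) stop("cutoff must lie in (0, 0.5]")
  if (deleterious_fraction < 0 || deleterious_fraction > 1)
    stop("deleterious_fraction must lie in [0, 1]")
  structure(list(scenario = as.integer(scenario), effect = effect,
                 cutoff = cutoff, lambda = lambda,
                 deleterious_fraction = deleterious_fraction,
                 functional_algo = functional_algo,
                 n_cases = n_cases, n_controls = n_controls,
                 n_quantitative = n_quantitative, trait = trait,
                 prevalence = prevalence),
            class = "scenario_config")
}

#' Per-variant effect sizes under a generative scenario
#'
#' Draws (scenarios 2 and 5 are stochastic per replicate; seed the RNG
#' for reproducibility) the vector of per-variant log odds ratios
#' (dichotomous) or per-dosage mean shifts (continuous) defined by the
#' scenario.  The per-variant effect magnitude never exceeds
#' \code{log(effect)} so the maximum contribution of any allele is
#' bounded by the nominal odds ratio.
#'
#' @param pool a \code{haplotype_pool}.
#' @param cfg a \code{\link{scenario_config}}.
#' @return Numeric vector of p effect coefficients.
#' @export
scenario_betas <- function(pool, cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  ann <- pool$annotations
  maf <- pool$pop_maf
  b <- log(cfg$effect)
  func <- ann[[cfg$functional_algo]] == "deleterious"
  beta <- numeric(length(maf))
  if (cfg$scenario %in% c(1, 2)) {
    cc <- cfg$cutoff
    if (cfg$scenario == 2) {
      pool_mafs <- unique(maf[maf > 0 & maf < 0.05])
      if (length(pool_mafs) == 0) stop("no MAFs below 0.05 to draw a cutoff from")
      cc <- sample(pool_mafs, 1)
    }
    sel <- func & maf > 0 & maf <= cc
    # a fixed threshold below every functional variant is a misconfiguration;
    # a randomly drawn one (scenario 2) can legitimately give a null replicate
    if (!any(sel) && b != 0 && cfg$scenario == 1)
      stop("no functional variant at or below the cutoff")
    beta[sel] <- b
  } else if (cfg$scenario == 3) {
    nonsyn <- ann$algoA != "synonymous"
    if (!any(nonsyn)) stop("no nonsynonymous variants in the pool")
    beta[nonsyn] <- b * (1 - ann$score[nonsyn])
  } else if (cfg$scenario == 4) {
    if (!any(func)) stop("no functional variants in the pool")
    k <- cfg$lambda / (cfg$lambda + maf)
    k <- k / max(k[func])         # rarest functional variant gets full effect
    beta[func] <- b * k[func]
  } else {
    sel <- which(func & maf > 0 & maf <= cfg$cutoff)
    if (length(sel) == 0 && b != 0)
      stop("no rare functional variants for the mixed-direction scenario")
    ord <- sel[sample.int(length(sel))]
    total <- sum(maf[sel])
    # random-order prefix whose summed MAF lands closest to the target split
    cum <- c(0, cumsum(maf[ord]))
    k <- which.min(abs(cum - cfg$deleterious_fraction * total)) - 1L
    delset <- ord[seq_len(k)]
    beta[delset] <- b
    beta[setdiff(sel, delset)] <- -b
  }
  beta
}

#' Calibrate the disease-model intercept to a target prevalence
#'
#' Solves \eqn{E_G[\mathrm{expit}(\beta_0 + G\beta)] = K} for
#' \eqn{\beta_0}, the expectation taken over genotypes formed by two
#' independent haplotype draws from the pool (Hardy-Weinberg random
#' mating).  When the number of haplotype pairs is enumerable
#' (\eqn{H^2 \le} \code{exact_limit}) the expectation is exact and the
#' root is found to \code{|achieved - K| <= 1e-6}; otherwise a seeded
#' Monte-Carlo sample of genotypes is used inside the same monotone
#' root finder.
#'
#' @param pool a \code{haplotype_pool}.
#' @param beta per-variant effect vector.
#' @param K target prevalence in (0, 1).
#' @param exact_limit maximum number of haplotype pairs enumerated
#'   exactly.
#' @param mc_n Monte-Carlo genotype sample size for large pools.
#' @return The calibrated intercept \eqn{\beta_0}.
#' @export
calibrate_intercept <- function(pool, beta, K, exact_limit = 1e6, mc_n = 2e5) {
  if (K <= 0 || K >= 1) stop("K must lie in (0, 1)")
  H <- nrow(pool$haplotypes)
  eta_h <- as.vector(pool$haplotypes %*% beta)
  if (all(beta == 0)) return(stats::qlogis(K))
  if (H^2 <= exact_limit) {
    eta_pair <- outer(eta_h, eta_h, "+")
    f <- pool$frequencies
    prev <- function(b0) as.numeric(f %*% stats::plogis(b0 + eta_pair) %*% f)
  } else {
    i1 <- sample.int(H, mc_n, replace = TRUE, prob = pool$frequencies)
    i2 <- sample.int(H, mc_n, replace = TRUE, prob = pool$frequencies)
    eta_mc <- eta_h[i1] + eta_h[i2]
    prev <- function(b0) mean(stats::plogis(b0 + eta_mc))
  }
  lo <- -40; hi <- 40
  if (prev(lo) > K || prev(hi) < K)
    stop("target prevalence is outside the achievable range for these effects")
  stats::uniroot(function(b0) prev(b0) - K, c(lo, hi), tol = 1e-12)$root
}

#' Disease model for the case-control simulator
#'
#' Bundles the per-variant effects, link and (for the logit link) an
#' intercept calibrated so the population prevalence equals
#' \code{prevalence}.
#'
#' @param pool a \code{haplotype_pool}.
#' @param beta per-variant effect vector.
#' @param prevalence target population prevalence (logit link); ignored
#'   for the identity link.
#' @param link \code{"logit"} (dichotomous) or \code{"identity"}
#'   (continuous trait).
#' @param beta0 optional intercept override (skips calibration).
#' @return Object of class \code{disease_model}.
#' @export
disease_model <- function(pool, beta, prevalence = 0.01,
                          link = c("logit", "identity"), beta0 = NULL) {
  link <- match.arg(link)
  if (length(beta) != ncol(pool$haplotypes))
    stop("beta length must equal the pool's variant count")
  if (link == "logit" && is.null(beta0))
    beta0 <- calibrate_intercept(pool, beta, prevalence)
  structure(list(beta = beta, beta0 = if (is.null(beta0)) 0 else beta0,
                 link = link, prevalence_target = prevalence),
            class = "disease_model")
}

draw_haplotype_pairs <- function(pool, m) {
  H <- nrow(pool$haplotypes)
  cbind(sample.int(H, m, replace = TRUE, prob = pool$frequencies),
        sample.int(H, m, replace = TRUE, prob = pool$frequencies))
}

#' Sample an ascertained case-control dataset from the pool
#'
#' Each individual is two independent haplotype draws from the pool
#' (Hardy-Weinberg random mating); disease status is Bernoulli with
#' probability \eqn{\mathrm{expit}(\beta_0 + G\beta)}.  Individuals are
#' rejection-sampled until the requested numbers of cases and controls
#' are collected; the genotype coding keeps the pool's (population)
#' minor-allele orientation, with sample MAFs reported as
#' \code{min(af, 1 - af)}.
#'
#' @param pool a \code{haplotype_pool}.
#' @param model a \code{\link{disease_model}} with logit link.
#' @param n_cases,n_controls numbers to collect.
#' @param seed optional seed.
#' @param max_draws rejection-sampling budget; defaults to 1000 times
#'   the expected number of draws.  Exceeding it raises an error
#'   advising a smaller sample or higher prevalence.
#' @return List with \code{genotypes} (a \code{genotype_matrix}, cases
#'   first) and \code{phenotypes} (dichotomous
#'   \code{phenotype_vector}).
#' @export
sample_case_control <- function(pool, model, n_cases, n_controls,
                                seed = NULL, max_draws = NULL) {
  stopifnot(inherits(model, "disease_model"))
  if (model$link != "logit") stop("case-control sampling needs a logit-link model")
  K <- model$prevalence_target
  expected <- n_cases / K + n_controls / (1 - K)
  if (is.null(max_draws)) max_draws <- 1000 * expected
  with_seed(seed, {
    eta_h <- as.vector(pool$haplotypes %*% model$beta)
    case_idx <- matrix(integer(), 0, 2)
    ctrl_idx <- matrix(integer(), 0, 2)
    drawn <- 0
    while (nrow(case_idx) < n_cases || nrow(ctrl_idx) < n_controls) {
      need_c <- n_cases - nrow(case_idx)
      need_k <- n_controls - nrow(ctrl_idx)
      m <- ceiling(1.2 * max(need_c / K, need_k / (1 - K), 100))
      m <- min(m, 5e6)
      if (drawn + m > max_draws)
        stop("rejection-sampling budget exceeded; reduce the sample size or raise the prevalence")
      drawn <- drawn + m
      idx <- draw_haplotype_pairs(pool, m)
      pD <- stats::plogis(model$beta0 + eta_h[idx[, 1]] + eta_h[idx[, 2]])
      D <- stats::rbinom(m, 1, pD) == 1
      if (need_c > 0 && any(D))
        case_idx <- rbind(case_idx, idx[D, , drop = FALSE][seq_len(min(need_c, sum(D))), , drop = FALSE])
      if (need_k > 0 && any(!D))
        ctrl_idx <- rbind(ctrl_idx, idx[!D, , drop = FALSE][seq_len(min(need_k, sum(!D))), , drop = FALSE])
    }
    idx <- rbind(case_idx, ctrl_idx)
    G <- pool$haplotypes[idx[, 1], , drop = FALSE] +
         pool$haplotypes[idx[, 2], , drop = FALSE]
    list(genotypes = genotype_matrix(G, variant_ids = pool$variant_ids,
                                     orient = FALSE),
         phenotypes = phenotype_vector(rep(c(1, 0), c(n_cases, n_controls))))
  })
}

#' Sample an unascertained quantitative-trait dataset
#'
#' Genotypes are two independent haplotype draws per individual; the
#' trait is \eqn{Y_i \sim N(\sum_j \beta_j G_{ij},\ 1)}.
#'
#' @param pool a \code{haplotype_pool}.
#' @param beta per-dosage mean differences.
#' @param n sample size (>= 2).
#' @param seed optional seed.
#' @return List with \code{genotypes} and a continuous
#'   \code{phenotypes}.
#' @export
sample_quantitative <- function(pool, beta, n, seed = NULL) {
  if (n < 2) stop("n must be >= 2")
  with_seed(seed, {
    idx <- draw_haplotype_pairs(pool, n)
    G <- pool$haplotypes[idx[, 1], , drop = FALSE] +
         pool$haplotypes[idx[, 2], , drop = FALSE]
    mu <- as.vector(G %*% beta)
    list(genotypes = genotype_matrix(G, variant_ids = pool$variant_ids,
                                     orient = FALSE),
         phenotypes = phenotype_vector(stats::rnorm(n, mu, 1),
                                       trait_type = "continuous"))
  })
}
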