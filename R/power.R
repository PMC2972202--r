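#' Empirical type-I error / power study
#'
#' Replicate-level driver: for each scenario, and for each haplotype
#' pool, generates \code{n_sims} independent datasets, tests every
#' dataset with every requested method (each permutation test uses
#' \code{B} permutations of the full procedure; the CMC comparator uses
#' its asymptotic p-value) and tallies rejections at \code{p <= alpha}.
#' Power is averaged across pools exactly as a multi-gene study
#' averages across genes, so each (scenario, method) row pools
#' \code{length(pools) * n_sims} replicates.  Each replicate reseeds
#' the RNG from the master seed and a running counter, so any single
#' replicate can be reproduced in isolation.
#'
#' CMC replicates whose logistic fit fails to converge are excluded
#' from that method's tally; methods incompatible with a scenario's
#' trait (CMC on a continuous trait) are skipped with a warning.
#'
#' @param pools a \code{haplotype_pool} or list of them.
#' @param scenarios a \code{\link{scenario_config}} or list of them.
#' @param methods a \code{\link{burden_method}} or list of them.
#' @param n_sims replicates per pool per scenario.
#' @param B permutations per test; defaults to 199 so that
#'   \eqn{(B+1)\alpha} is an integer at \eqn{\alpha = 0.05} and the
#'   add-one p-value can hit alpha exactly.
#' @param alpha nominal significance level.
#' @param seed master seed.
#' @param out optional TSV path; rows are streamed to it as each
#'   (scenario, method) cell finishes.
#' @param verbose print progress messages.
#' @return Data frame of class \code{power_result}: one row per
#'   (scenario, effect, method) with \code{n_replicates},
#'   \code{rejections}, \code{power} and a Clopper-Pearson 95\% CI.
#' @export
run_power_study <- function(pools, scenarios, methods, n_sims = 200,
                            B = 199L, alpha = 0.05, seed = 1L,
                            out = NULL, verbose = FALSE) {
  if (inherits(pools, "haplotype_pool")) pools <- list(pools)
  if (inherits(scenarios, "scenario_config")) scenarios <- list(scenarios)
  if (inherits(methods, "burden_method")) methods <- list(methods)
  if (n_sims < 1 || B < 1 || alpha <= 0 || alpha > 1)
    stop("need n_sims >= 1, B >= 1 and alpha in (0, 1]")
  labels <- vapply(methods, function(m) m$label, "")
  if (anyDuplicated(labels)) stop("method labels must be unique")
  counter <- 0L
  rows <- list()
  for (sc in scenarios) {
    rej <- integer(length(methods))
    nrep <- integer(length(methods))
    skipped <- logical(length(methods))
    for (pool in pools) {
      for (sim in seq_len(n_sims)) {
        counter <- counter + 1L
        set.seed((seed + 104729 * counter) %% 2147483647L)
        beta <- scenario_betas(pool, sc)
        if (sc$trait == "dichotomous") {
          model <- disease_model(pool, beta, prevalence = sc$prevalence)
          dat <- sample_case_control(pool, model, sc$n_cases, sc$n_controls)
        } else {
          dat <- sample_quantitative(pool, beta, sc$n_quantitative)
        }
        for (k in seq_along(methods)) {
          m <- methods[[k]]
          if (m$inclusion == "cmc" && sc$trait != "dichotomous") {
            if (!skipped[k]) {
              warning("skipping method '", m$label, "' for a continuous trait")
              skipped[k] <- TRUE
            }
            next
          }
          pv <- if (m$inclusion == "cmc") {
            suppressWarnings(cmc_test(dat$genotypes, dat$phenotypes,
                                      cutoff = m$cutoff)$p_value)
          } else {
            res <- rare_burden_test(dat$genotypes, dat$phenotypes, method = m,
                                    annotations = pool$annotations, B = B)
            res$p_value
          }
          if (is.na(pv)) next   # non-converged comparator replicate
          nrep[k] <- nrep[k] + 1L
          if (pv <= alpha) rej[k] <- rej[k] + 1L
        }
      }
      if (verbose)
        message(sprintf("scenario %d (effect %.3g): pool done, %d replicates so far",
                        sc$scenario, sc$effect, max(nrep)))
    }
    for (k in seq_along(methods)) {
      if (skipped[k] || nrep[k] == 0L) next
      ci <- stats::binom.test(rej[k], nrep[k])$conf.int
      rows[[length(rows) + 1L]] <- data.frame(
        method = labels[k], scenario = sc$scenario, trait = sc$trait,
        effect = sc$effect, n_replicates = nrep[k], rejections = rej[k],
        power = rej[k] / nrep[k], ci_lower = ci[1], ci_upper = ci[2],
        stringsAsFactors = FALSE)
      if (!is.null(out)) {
        utils::write.table(rows[[length(rows)]], out, sep = "\t",
                           quote = FALSE, row.names = FALSE,
                           col.names = !file.exists(out), append = file.exists(out))
      }
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("power_result", "data.frame")
  res
}

#' @export
print.power_result <- function(x, ...) {
  cat("Empirical power study (rejection at p <= alpha):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Bar chart of a power study (cosmetic helper)
#' @param x a \code{power_result}.
#' @param ... passed to \code{barplot}.
#' @export
plot.power_result <- function(x, ...) {
  lab <- paste(x$method, x$scenario, x$effect, sep = " / ")
  mid <- graphics::barplot(x$power, names.arg = lab, las = 2,
                           ylab = "empirical power", ylim = c(0, 1), ...)
  graphics::arrows(mid, x$ci_lower, mid, x$ci_upper, angle = 90, code = 3,
                   length = 0.03)
  invisible(x)
}
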