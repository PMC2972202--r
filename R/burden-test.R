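#' Describe an aggregation test method
#'
#' A method descriptor names the three model components used by
#' \code{\link{rare_burden_test}} and \code{\link{run_power_study}}:
#' how variants are included (\code{inclusion}), how they are weighted
#' (\code{weights}: constant, allele-frequency weighted, or the best of
#' both) and whether directions are estimated from the data
#' (\code{signed}).  Labels follow the C/W/B, s=1/s=±, grouping
#' convention, e.g. \code{"W,s=±,step"}.
#'
#' @param inclusion \code{"cutoff"} (hard MAF threshold),
#'   \code{"all_maf"} (every observed MAF threshold),
#'   \code{"functional"} (annotation groups x thresholds),
#'   \code{"step"} (greedy step-up selection) or \code{"cmc"}
#'   (asymptotic CMC comparator; ignores \code{weights}/\code{signed}).
#' @param weights \code{"constant"}, \code{"maf"} or \code{"both"}.
#' @param signed estimate per-variant directions from the data?
#' @param cutoff MAF threshold for \code{"cutoff"}/\code{"cmc"} and the
#'   rare/common split.
#' @param groups functional groups for \code{inclusion = "functional"}.
#' @param functional_maf \code{"all_maf"} or a numeric cutoff: the MAF
#'   thresholds crossed with the functional groups.
#' @param label optional label override.
#' @return Object of class \code{burden_method}.
#' @export
burden_method <- function(inclusion = c("step", "cutoff", "all_maf",
                                        "functional", "cmc"),
                          weights = c("constant", "maf", "both"),
                          signed = FALSE, cutoff = 0.01,
                          groups = "nonsynonymous",
                          functional_maf = "all_maf", label = NULL) {
  inclusion <- match.arg(inclusion)
  weights <- match.arg(weights)
  if (is.null(label)) {
    wlab <- c(constant = "C", maf = "W", both = "B")[[weights]]
    slab <- if (signed) "s=±" else "s=1"
    ilab <- switch(inclusion,
                   cutoff = sprintf("MAF<=%.6g", cutoff),
                   all_maf = "MAF",
                   functional = "F",
                   step = "step",
                   cmc = sprintf("CMC(%.6g)", cutoff))
    label <- if (inclusion == "cmc") ilab else paste(wlab, slab, ilab, sep = ",")
  }
  structure(list(inclusion = inclusion, weights = weights, signed = signed,
                 cutoff = cutoff, groups = groups,
                 functional_maf = functional_maf, label = label),
            class = "burden_method")
}

#' @export
print.burden_method <- function(x, ...) {
  cat("burden_method:", x$label, "\n")
  invisible(x)
}

#' Build a reusable test procedure for permutation inference
#'
#' Returns a closure \code{function(G, Y)} computing the method's final
#' statistic (max over its model set, or the step-up statistic).  The
#' genotype-only quantities (centred cross-products, inclusion
#' indicators) are precomputed once; everything that depends on the
#' phenotype — allele-frequency weights in controls and estimated signs
#' — is recomputed on every call, so the same closure drives both the
#' observed data and every permutation.
#'
#' @param G a \code{\link{genotype_matrix}} the procedure will be used
#'   with (the closure checks it is handed the same matrix).
#' @param method a \code{\link{burden_method}} (not \code{"cmc"}).
#' @param annotations annotation table, required for
#'   \code{inclusion = "functional"}.
#' @return Closure \code{function(G, Y) -> rarestep_result}.
#' @export
burden_procedure <- function(G, method, annotations = NULL) {
  stopifnot(inherits(method, "burden_method"))
  if (method$inclusion == "cmc")
    stop("the CMC comparator is asymptotic; call cmc_test() directly")
  engine <- score_engine(G)
  p <- G$p
  weight_kinds <- switch(method$weights, constant = "constant",
                         maf = "maf", both = c("constant", "maf"))

  gammas <- NULL; labels <- NULL
  if (method$inclusion == "cutoff") {
    gammas <- list(maf_threshold_inclusion(G$maf, method$cutoff))
    labels <- sprintf("MAF<=%.6g", method$cutoff)
  } else if (method$inclusion == "all_maf") {
    th <- sort(unique(G$maf[G$maf > 0]))
    if (length(th) == 0) stop("no polymorphic variants")
    gammas <- lapply(th, function(t) maf_threshold_inclusion(G$maf, t))
    labels <- sprintf("MAF<=%.6g", th)
  } else if (method$inclusion == "functional") {
    if (is.null(annotations))
      stop("functional inclusion requires an annotation table")
    ms <- functional_model_set(annotations, G, groups = method$groups,
                               maf_sets = method$functional_maf)
    gammas <- lapply(ms$specs, function(m) m$gamma)
    labels <- vapply(ms$specs, function(m) m$label, "")
  }

  function(G2, Y) {
    if (!identical(dim(G2$dosages), dim(G$dosages)))
      stop("procedure was built for a different genotype matrix")
    ph <- engine_phenotype(engine, Y$values)
    s <- if (method$signed) sign_variants(G, Y) else rep(1, p)
    best_t <- -Inf; best_lab <- NA_character_; best_sel <- integer()
    for (wk in weight_kinds) {
      w <- if (wk == "maf") madsen_browning_weights(G, Y) else rep(1, p)
      wlab <- if (wk == "maf") "W" else "C"
      a <- w * s
      if (method$inclusion == "step") {
        res <- engine_step_up(engine, ph, a)
        if (res$statistic > best_t) {
          best_t <- res$statistic
          best_lab <- sprintf("%s,%s,step", wlab, if (method$signed) "s=±" else "s=1")
          best_sel <- res$selected
        }
      } else {
        for (k in seq_along(gammas)) {
          t_k <- engine_model_stat(engine, ph, a * gammas[[k]])
          if (t_k > best_t) {
            best_t <- t_k
            best_lab <- paste0(wlab, ",", if (method$signed) "s=±" else "s=1",
                               ",", labels[k])
            best_sel <- which(gammas[[k]] == 1)
          }
        }
      }
    }
    test_result(statistic = best_t, best_model = best_lab,
                selected_variants = G$variant_ids[best_sel],
                method = method$label)
  }
}

#' Rare-variant aggregation association test
#'
#' The main fitting interface: aggregates rare-variant dosages under the
#' requested weight/sign/inclusion model (or searches over a family of
#' such models, or runs the greedy step-up selection), computes the
#' maximised score statistic and calibrates it by permuting phenotypes
#' with the whole procedure recomputed in each permutation.  The CMC
#' comparator (\code{method = "cmc"}) instead reports its asymptotic
#' chi-squared p-value.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param Y a \code{\link{phenotype_vector}} (or numeric vector).
#' @param method a \code{\link{burden_method}}, or a character shortcut:
#'   \code{"step"}, \code{"cast"} (constant-weight fixed threshold),
#'   \code{"weighted"} (allele-frequency weights, fixed threshold),
#'   \code{"all-maf"}, \code{"functional"}, \code{"cmc"}.
#' @param annotations annotation table for functional groupings.
#' @param signed,weights,cutoff,groups forwarded to
#'   \code{\link{burden_method}} when \code{method} is a character
#'   shortcut.
#' @param B number of permutations (default 199).
#' @param seed optional seed for the permutation stream.
#' @param adaptive stop permuting early for clearly null regions (see
#'   \code{\link{perm_config}}).
#' @return Object of class \code{rare_burden_test}: statistic, p-value,
#'   best model label, selected variants, permutation count.
#' @examples
#' set.seed(1)
#' pool <- generate_haplotype_pool(p = 30, H = 80, seed = 7)
#' cfg <- scenario_config(1, effect = 3, n_cases = 120, n_controls = 120)
#' beta <- scenario_betas(pool, cfg)
#' model <- disease_model(pool, beta, prevalence = 0.01)
#' dat <- sample_case_control(pool, model, 120, 120, seed = 11)
#' rare_burden_test(dat$genotypes, dat$phenotypes, method = "step",
#'                  signed = TRUE, B = 99, seed = 3)
#' @export
rare_burden_test <- function(G, Y, method = "step", annotations = NULL,
                             signed = FALSE, weights = "constant",
                             cutoff = 0.01, groups = "nonsynonymous",
                             B = 199L, seed = NULL, adaptive = FALSE) {
  if (!inherits(G, "genotype_matrix")) G <- genotype_matrix(G)
  if (!inherits(Y, "phenotype_vector")) Y <- phenotype_vector(Y)
  if (is.character(method)) {
    method <- match.arg(method, c("step", "cast", "weighted", "all-maf",
                                  "functional", "cmc"))
    method <- switch(method,
      step = burden_method("step", weights = weights, signed = signed,
                           cutoff = cutoff),
      cast = burden_method("cutoff", weights = "constant", signed = signed,
                           cutoff = cutoff),
      weighted = burden_method("cutoff", weights = "maf", signed = signed,
                               cutoff = cutoff),
      `all-maf` = burden_method("all_maf", weights = weights, signed = signed),
      functional = burden_method("functional", weights = weights,
                                 signed = signed, groups = groups),
      cmc = burden_method("cmc", cutoff = cutoff))
  }
  stopifnot(inherits(method, "burden_method"))
  out <- if (method$inclusion == "cmc") {
    cmc <- cmc_test(G, Y, cutoff = method$cutoff)
    test_result(statistic = cmc$statistic, best_model = method$label,
                selected_variants = character(), method = "CMC (asymptotic)",
                p_value = cmc$p_value, n_permutations = 0L,
                extra = list(df = cmc$df))
  } else {
    proc <- burden_procedure(G, method, annotations = annotations)
    permutation_pvalue(proc, G, Y,
                       perm_config(B = B, seed = seed, adaptive = adaptive))
  }
  out$trait_type <- Y$trait_type
  out$n <- G$n
  out$n_variants <- G$p
  out$label <- method$label
  class(out) <- c("rare_burden_test", class(out))
  out
}

#' @export
print.rare_burden_test <- function(x, ...) {
  cat("\n\tRare-variant aggregation association test\n\n")
  cat(sprintf("method: %s   (n = %d individuals, %d variants, %s trait)\n",
              x$label, x$n, x$n_variants, x$trait_type))
  cat(sprintf("statistic = %.5g", x$statistic))
  if (!is.null(x$df)) cat(sprintf(", df = %d", x$df))
  if (x$n_permutations > 0) {
    cat(sprintf(", p-value = %.5g (%d permutations%s)\n", x$p_value,
                x$n_permutations,
                if (isTRUE(x$adaptive)) ", adaptive early stop" else ""))
  } else {
    cat(sprintf(", p-value = %.5g (asymptotic)\n", x$p_value))
  }
  if (!is.na(x$best_model)) cat("best model:", x$best_model, "\n")
  invisible(x)
}

#' @export
summary.rare_burden_test <- function(object, ...) {
  print(object)
  if (length(object$selected_variants)) {
    cat("variants in the selected model:\n")
    cat(" ", paste(object$selected_variants, collapse = ", "), "\n")
  }
  if (!is.null(object$model_statistics)) {
    cat(sprintf("model-set statistics: %d models, range [%.4g, %.4g]\n",
                length(object$model_statistics),
                min(object$model_statistics), max(object$model_statistics)))
  }
  invisible(object)
}

#' Write one or more test results to the output TSV dialect
#'
#' Columns: method, statistic, best_model, selected_variants
#' (comma-joined), p_value, n_permutations.
#'
#' @param results a \code{rare_burden_test}/\code{rarestep_result} or a
#'   list of them.
#' @param path output file path.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "rarestep_result")) results <- list(results)
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(method = if (!is.null(r$label)) r$label else r$method,
               statistic = r$statistic,
               best_model = r$best_model,
               selected_variants = paste(r$selected_variants, collapse = ","),
               p_value = r$p_value,
               n_permutations = r$n_permutations,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
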