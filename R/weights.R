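#' Constant (unit) variant weights
#'
#' The simplest weight model: every variant gets weight 1, so the
#' aggregated score is a plain dosage sum (a dosage-based analogue of
#' the cohort allelic sums test).
#'
#' @param p number of variants (>= 1).
#' @return Numeric vector of \code{p} ones.
#' @export
constant_weights <- function(p) {
  if (p < 1) stop("p must be >= 1")
  rep(1, p)
}

#' Allele-frequency (inverse-variance) variant weights
#'
#' Madsen-Browning style weights: each variant is weighted by the
#' inverse square root of the expected dosage variance under an allele
#' frequency estimated in the reference group with pseudocounts,
#' \eqn{q_j = (m_j + 1) / (2 n_{ref} + 2)} and
#' \eqn{w_j = 1 / \sqrt{n q_j (1 - q_j)}}, where \eqn{m_j} is the
#' minor-allele count in the reference group, \eqn{n_{ref}} its size and
#' \eqn{n} the total sample size.  For a dichotomous trait the reference
#' group is the controls; for a continuous trait it is all subjects.
#' The pseudocount keeps every weight finite and positive even for
#' variants absent from the reference group.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param Y a \code{\link{phenotype_vector}}.
#' @return Numeric vector of p strictly positive weights.
#' @export
madsen_browning_weights <- function(G, Y) {
  check_dimensions(G, Y)
  n <- G$n
  if (Y$trait_type == "dichotomous") {
    ref <- Y$values == 0
    if (!any(ref)) stop("no controls: allele-frequency weights need at least one control")
    m <- colSums(G$dosages[ref, , drop = FALSE])
    n_ref <- sum(ref)
  } else {
    m <- colSums(G$dosages)
    n_ref <- n
  }
  q <- (m + 1) / (2 * n_ref + 2)
  unname(1 / sqrt(n * q * (1 - q)))
}

#' Data-driven variant effect directions
#'
#' For a dichotomous trait, variant j gets sign +1 when its minor allele
#' is more frequent in cases than in controls (putatively deleterious)
#' and -1 when it is more frequent in controls (putatively protective);
#' an exact tie gives +1, so the signed test reduces to the unsigned
#' test when the data carry no directional information.  For a
#' continuous trait the sign of the sample covariance between trait and
#' dosage is used (+1 at zero covariance).  Because these directions are
#' estimated from the phenotype, any test using them must recompute them
#' inside each permutation.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param Y a \code{\link{phenotype_vector}}.
#' @return Vector of p values in \{+1, -1\}.
#' @export
sign_variants <- function(G, Y) {
  check_dimensions(G, Y)
  if (Y$trait_type == "dichotomous") {
    case <- Y$values == 1
    n_case <- sum(case); n_ctrl <- sum(!case)
    m_case <- colSums(G$dosages[case, , drop = FALSE])
    m_ctrl <- colSums(G$dosages[!case, , drop = FALSE])
    # integer-exact comparison of case vs control allele frequencies
    d <- n_ctrl * m_case - n_case * m_ctrl
    unname(ifelse(d >= 0, 1, -1))
  } else {
    yc <- Y$values - mean(Y$values)
    cv <- as.vector(crossprod(G$dosages, yc))
    ifelse(cv >= 0, 1, -1)
  }
}

#' Hard minor-allele-frequency inclusion threshold
#'
#' @param maf vector of sample minor-allele frequencies.
#' @param cutoff threshold in (0, 0.5]; inclusion is \code{0 < maf <=
#'   cutoff} (inclusive boundary, monomorphic variants always excluded).
#' @return 0/1 inclusion vector.
#' @export
maf_threshold_inclusion <- function(maf, cutoff) {
  if (length(cutoff) != 1 || cutoff <= 0 || cutoff > 0.5)
    stop("cutoff must lie in (0, 0.5]")
  as.integer(maf > 0 & maf <= cutoff)
}

#' A concrete weight-model assignment
#'
#' Bundles the three multiplicative components of the variant weight:
#' continuous weight \code{w} (> 0), direction \code{s} (+1/-1) and
#' inclusion indicator \code{gamma} (0/1).  The per-individual
#' aggregated score of the model is \eqn{S_i = \sum_j w_j s_j \gamma_j
#' G_{ij}}.
#'
#' @param w positive finite weights (length p).
#' @param s directions, +1 or -1 (length p or scalar).
#' @param gamma inclusion indicators, 0 or 1 (length p).
#' @param label unique text label for the model.
#' @return Object of class \code{model_spec}.
#' @export
model_spec <- function(w, s, gamma, label) {
  p <- length(gamma)
  if (length(w) == 1) w <- rep(w, p)
  if (length(s) == 1) s <- rep(s, p)
  if (length(w) != p || length(s) != p)
    stop("w, s and gamma must have equal length")
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be finite and strictly positive")
  if (!all(s %in% c(-1, 1))) stop("signs must be +1 or -1")
  if (!all(gamma %in% c(0, 1))) stop("gamma must be 0 or 1")
  structure(list(w = as.numeric(w), s = as.numeric(s),
                 gamma = as.integer(gamma), label = as.character(label)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec '%s': %d of %d variants included; %s weights; %s\n",
              x$label, sum(x$gamma), length(x$gamma),
              if (all(x$w == x$w[1])) "constant" else "variable",
              if (all(x$s == 1)) "unsigned" else "signed"))
  invisible(x)
}

#' An ordered family of weight models to maximise over
#'
#' @param specs list of \code{\link{model_spec}} objects with unique
#'   labels.
#' @param generator how the set was generated: \code{"fixed"},
#'   \code{"all_maf"}, \code{"functional"}, \code{"step_up"} or
#'   \code{"union"}.
#' @return Object of class \code{model_set}.
#' @export
model_set <- function(specs, generator = "fixed") {
  if (length(specs) == 0) stop("model set must be non-empty")
  labels <- vapply(specs, function(m) m$label, "")
  if (anyDuplicated(labels)) stop("model labels must be unique")
  generator <- match.arg(generator, c("fixed", "all_maf", "functional", "step_up", "union"))
  structure(list(specs = specs, generator = generator), class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("model_set (%s): %d model(s)\n", x$generator, length(x$specs)))
  for (m in x$specs) cat("  -", m$label, "\n")
  invisible(x)
}

#' @export
length.model_set <- function(x) length(x$specs)

#' Model set over all observed allele-frequency thresholds
#'
#' Testing all allele frequencies is equivalent to running the
#' fixed-threshold test once per unique nonzero observed MAF; this
#' builds that family, ordered by increasing threshold, sharing the
#' supplied weights and signs.
#'
#' @param maf sample minor-allele frequencies.
#' @param w,s weights and signs to attach to every model (defaults:
#'   constant unsigned).
#' @param max_maf optional upper bound: only thresholds \code{<= max_maf}
#'   are used (default 0.5, i.e. all).
#' @return A \code{\link{model_set}} with generator \code{"all_maf"}.
#' @export
all_maf_model_set <- function(maf, w = 1, s = 1, max_maf = 0.5) {
  thresholds <- sort(unique(maf[maf > 0 & maf <= max_maf]))
  if (length(thresholds) == 0) stop("no polymorphic variant at or below max_maf")
  specs <- lapply(thresholds, function(t)
    model_spec(w, s, maf_threshold_inclusion(maf, t),
               label = sprintf("MAF<=%.6g", t)))
  model_set(specs, generator = "all_maf")
}

functional_group_names <- c("nonsynonymous", "algoA_deleterious",
                            "algoB_deleterious", "algoC_deleterious")

#' Functional-group membership indicators
#'
#' \code{"nonsynonymous"} selects every protein-changing variant
#' (any call other than synonymous); \code{"algoX_deleterious"} selects
#' the variants algorithm X calls deleterious.
#'
#' @param annotations a \code{\link{variant_annotation}} table already
#'   aligned to the genotype variant order (see
#'   \code{\link{read_annotations}}).
#' @param group one of \code{"nonsynonymous"}, \code{"algoA_deleterious"},
#'   \code{"algoB_deleterious"}, \code{"algoC_deleterious"}.
#' @return Logical membership vector.
#' @export
functional_group <- function(annotations, group) {
  group <- match.arg(group, functional_group_names)
  if (group == "nonsynonymous") {
    annotations$algoA != "synonymous"
  } else {
    algo <- sub("_deleterious$", "", group)
    annotations[[algo]] == "deleterious"
  }
}

#' Model set from functional annotation groups
#'
#' Builds the Cartesian product of the requested functional groupings
#' and MAF thresholds: a variant is included in a model iff it belongs
#' to the group and its MAF is at or below the model's threshold.
#' Models whose inclusion vector is empty are dropped with a warning.
#'
#' @param annotations annotation table (aligned to \code{G} internally).
#' @param G a \code{\link{genotype_matrix}} providing variant order and
#'   MAFs.
#' @param groups subset of \code{"nonsynonymous"},
#'   \code{"algoA_deleterious"}, \code{"algoB_deleterious"},
#'   \code{"algoC_deleterious"}.
#' @param maf_sets either a single numeric cutoff, or \code{"all_maf"}
#'   for one threshold per unique observed MAF.
#' @param w,s weights and signs shared by all models (defaults constant,
#'   unsigned).
#' @return A \code{\link{model_set}} with generator \code{"functional"}.
#' @export
functional_model_set <- function(annotations, G, groups = "nonsynonymous",
                                 maf_sets = 0.01, w = 1, s = 1) {
  ann <- align_annotations(annotations, G)
  groups <- match.arg(groups, functional_group_names, several.ok = TRUE)
  thresholds <- if (identical(maf_sets, "all_maf")) {
    sort(unique(G$maf[G$maf > 0]))
  } else {
    as.numeric(maf_sets)
  }
  specs <- list()
  dropped <- character()
  for (g in groups) {
    member <- functional_group(ann, g)
    for (t in thresholds) {
      gamma <- maf_threshold_inclusion(G$maf, t) * as.integer(member)
      lab <- sprintf("%s,MAF<=%.6g", g, t)
      if (sum(gamma) == 0) { dropped <- c(dropped, lab); next }
      specs[[length(specs) + 1L]] <- model_spec(w, s, gamma, label = lab)
    }
  }
  if (length(dropped))
    warning("dropped empty functional model(s): ", paste(dropped, collapse = ", "))
  if (length(specs) == 0) stop("all functional groups are empty")
  model_set(specs, generator = "functional")
}

#' Union of model sets
#'
#' Concatenates several model sets into one family to maximise over,
#' implementing "consider any combination of the approaches".
#'
#' @param ... \code{\link{model_set}} objects.
#' @return A \code{\link{model_set}} with generator \code{"union"}.
#' @export
union_model_sets <- function(...) {
  sets <- list(...)
  specs <- do.call(c, lapply(sets, function(s) s$specs))
  labels <- vapply(specs, function(m) m$label, "")
  specs <- specs[!duplicated(labels)]
  model_set(specs, generator = "union")
}
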