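#' Genotype dosage matrix
#'
#' Container for an n individuals by p variants matrix of minor-allele
#' dosages (0, 1 or 2) together with per-variant sample minor-allele
#' frequencies.  Dosages are oriented to the minor allele: if a column's
#' allele frequency exceeds 0.5 the coding is flipped (dosage becomes
#' \code{2 - dosage}) and the flip recorded, so that \code{maf <= 0.5}
#' always holds.
#'
#' @param dosages integer matrix, one row per individual, one column per
#'   variant; entries must be 0, 1 or 2 with no missing values.
#' @param variant_ids character vector of unique variant labels; defaults
#'   to the column names of \code{dosages} or \code{v1..vp}.
#' @param orient if \code{TRUE} (default) flip any column whose sample
#'   allele frequency exceeds 0.5 so the dosage counts the minor allele.
#'   When \code{FALSE} the coding is preserved and \code{maf} is reported
#'   as \code{min(af, 1 - af)}; used by the simulator, which keeps the
#'   population (pool) orientation even in ascertained samples.
#' @return An object of class \code{genotype_matrix} with elements
#'   \code{dosages}, \code{variant_ids}, \code{maf}, \code{flipped},
#'   \code{n}, \code{p}.
#' @export
genotype_matrix <- function(dosages, variant_ids = NULL, orient = TRUE) {
  dosages <- as.matrix(dosages)
  if (!is.numeric(dosages)) stop("dosages must be numeric")
  if (anyNA(dosages)) stop("missing genotypes are not supported; remove or recode them upstream")
  if (!all(dosages %in% c(0, 1, 2)))
    stop("every dosage must be 0, 1 or 2 (minor-allele count)")
  storage.mode(dosages) <- "integer"
  n <- nrow(dosages); p <- ncol(dosages)
  if (n < 1L || p < 1L) stop("genotype matrix must have at least one row and one column")
  if (is.null(variant_ids)) variant_ids <- colnames(dosages)
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(p))
  variant_ids <- as.character(variant_ids)
  if (length(variant_ids) != p) stop("variant_ids length must equal the number of variants")
  if (anyDuplicated(variant_ids)) stop("variant_ids must be unique")
  af <- colSums(dosages) / (2 * n)
  flipped <- orient & af > 0.5
  if (any(flipped)) {
    dosages[, flipped] <- 2L - dosages[, flipped, drop = FALSE]
    af[flipped] <- 1 - af[flipped]
  }
  maf <- pmin(af, 1 - af)
  colnames(dosages) <- variant_ids
  structure(list(dosages = dosages, variant_ids = variant_ids,
                 maf = unname(maf), flipped = unname(flipped),
                 n = n, p = p),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants\n", x$n, x$p))
  cat(sprintf("  MAF range: [%.4g, %.4g]; %d monomorphic; %d column(s) flipped to minor allele\n",
              min(x$maf), max(x$maf), sum(x$maf == 0), sum(x$flipped)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(x$n, x$p)

#' Phenotype vector
#'
#' @param values numeric vector, one entry per individual.
#' @param trait_type \code{"dichotomous"} (values in \{0,1\}, both classes
#'   present) or \code{"continuous"}; if \code{NULL}, auto-detected
#'   (all values in \{0,1\} implies dichotomous).
#' @return Object of class \code{phenotype_vector} with elements
#'   \code{values} and \code{trait_type}.
#' @export
phenotype_vector <- function(values, trait_type = NULL) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("missing phenotype values are not supported")
  if (is.null(trait_type)) {
    trait_type <- if (all(values %in% c(0, 1))) "dichotomous" else "continuous"
  }
  trait_type <- match.arg(trait_type, c("dichotomous", "continuous"))
  if (trait_type == "dichotomous") {
    if (!all(values %in% c(0, 1)))
      stop("dichotomous phenotype must contain only 0 (control) and 1 (case)")
    if (length(unique(values)) < 2L)
      stop("dichotomous phenotype must contain both cases and controls")
  }
  structure(list(values = values, trait_type = trait_type),
            class = "phenotype_vector")
}

#' @export
print.phenotype_vector <- function(x, ...) {
  if (x$trait_type == "dichotomous") {
    cat(sprintf("phenotype_vector: dichotomous, %d cases / %d controls\n",
                sum(x$values == 1), sum(x$values == 0)))
  } else {
    cat(sprintf("phenotype_vector: continuous, n = %d, mean = %.3g, sd = %.3g\n",
                length(x$values), mean(x$values), stats::sd(x$values)))
  }
  invisible(x)
}

#' @export
length.phenotype_vector <- function(x) length(x$values)

check_dimensions <- function(G, Y) {
  if (G$n != length(Y$values))
    stop(sprintf("genotypes have %d individuals but phenotypes have %d",
                 G$n, length(Y$values)))
  invisible(TRUE)
}

#' Read a genotype matrix from TSV or VCF
#'
#' The TSV dialect is a tab-separated table whose header row holds the
#' variant ids and whose subsequent rows each hold one individual's
#' integer dosages.  The VCF reader accepts biallelic sites with a GT
#' field only; dosages are counted from the GT alleles and oriented to
#' the minor allele.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "numeric")
    genotype_matrix(as.matrix(tab), variant_ids = colnames(tab))
  } else {
    read_genotypes_vcf(path)
  }
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  rec_name <- function(i) {
    id <- fix[i, "ID"]
    if (is.na(id) || id == ".") paste0(fix[i, "CHROM"], ":", fix[i, "POS"]) else id
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop("non-biallelic VCF record(s): ",
         paste(vapply(which(multi), rec_name, ""), collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  ids <- vapply(seq_len(nrow(fix)), rec_name, "")
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  for (j in seq_len(nrow(gt))) {
    g <- gt[j, ]
    if (anyNA(g) || any(grepl("\\.", g)))
      stop("missing genotype at record ", ids[j],
           "; missing-data handling is not supported")
    alleles <- strsplit(g, "[/|]")
    if (any(vapply(alleles, function(a) any(!a %in% c("0", "1")), TRUE)))
      stop("allele other than 0/1 at record ", ids[j])
    dos[, j] <- vapply(alleles, function(a) sum(a == "1"), 0L)
  }
  genotype_matrix(dos, variant_ids = ids)
}

#' Write a genotype matrix in the package's TSV dialect
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param path output file path.
#' @export
write_genotypes <- function(G, path) {
  utils::write.table(G$dosages, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a phenotype vector
#'
#' Accepts either one value per line or a two-column (id, value) TSV
#' with no header.
#'
#' @param path file path.
#' @param trait_type optional override; by default the trait type is
#'   auto-detected (all values in \{0,1\} implies dichotomous).
#' @return A \code{\link{phenotype_vector}}.
#' @export
read_phenotypes <- function(path, trait_type = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t")
  vals <- if (ncol(tab) >= 2) tab[[2]] else tab[[1]]
  phenotype_vector(as.numeric(vals), trait_type = trait_type)
}

#' Write a phenotype vector as one value per line
#' @param Y a \code{\link{phenotype_vector}}.
#' @param path output file path.
#' @export
write_phenotypes <- function(Y, path) {
  writeLines(format(Y$values, trim = TRUE, digits = 15), path)
  invisible(path)
}

annotation_tokens <- c("deleterious", "tolerated", "nonsynonymous_only", "synonymous")

#' Read a variant annotation table
#'
#' Expects a header row and tab-separated columns \code{variant_id},
#' \code{algoA}, \code{algoB}, \code{algoC}, \code{score}.  The three
#' algorithm columns carry functional calls (\code{deleterious},
#' \code{tolerated}, \code{nonsynonymous_only} or \code{synonymous});
#' \code{score} is a continuous deleteriousness index in [0,1] (0 = most
#' deleterious, as in the SIFT tolerance index), present exactly for
#' nonsynonymous variants (empty or NA otherwise).
#'
#' @param path file path.
#' @return A data frame of class \code{variant_annotation} with columns
#'   \code{variant_id}, \code{algoA}, \code{algoB}, \code{algoC},
#'   \code{score}.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ".", ""))
  variant_annotation(tab)
}

#' Construct/validate a variant annotation table
#'
#' @param tab data frame with columns \code{variant_id}, \code{algoA},
#'   \code{algoB}, \code{algoC}, \code{score}.
#' @return The validated table, classed \code{variant_annotation}.
#' @export
variant_annotation <- function(tab) {
  need <- c("variant_id", "algoA", "algoB", "algoC", "score")
  if (!all(need %in% colnames(tab)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  tab <- as.data.frame(tab)[need]
  tab$variant_id <- as.character(tab$variant_id)
  if (anyDuplicated(tab$variant_id)) stop("duplicated variant_id in annotations")
  for (a in c("algoA", "algoB", "algoC")) {
    bad <- !tab[[a]] %in% annotation_tokens
    if (any(bad))
      stop(sprintf("unknown call token(s) in %s: %s; allowed tokens are: %s",
                   a, paste(unique(tab[[a]][bad]), collapse = ", "),
                   paste(annotation_tokens, collapse = ", ")))
  }
  syn <- tab$algoA == "synonymous" | tab$algoB == "synonymous" | tab$algoC == "synonymous"
  nonsyn <- tab$algoA != "synonymous"
  if (any(syn & nonsyn | (!syn & !nonsyn)))
    stop("inconsistent calls: a variant must be synonymous for all algorithms or none")
  tab$score <- as.numeric(tab$score)
  if (any(!is.na(tab$score) & (tab$score < 0 | tab$score > 1)))
    stop("deleteriousness score must lie in [0, 1]")
  if (any(nonsyn & is.na(tab$score)))
    stop("nonsynonymous variants must carry a deleteriousness score")
  if (any(!nonsyn & !is.na(tab$score)))
    stop("synonymous variants must not carry a deleteriousness score")
  class(tab) <- c("variant_annotation", "data.frame")
  tab
}

#' Write a variant annotation table as TSV
#' @param annotations a \code{\link{variant_annotation}} table.
#' @param path output file path.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

# Align an annotation table to a genotype matrix's variant order.
# Errors if any genotyped variant lacks an annotation row.
align_annotations <- function(annotations, G) {
  idx <- match(G$variant_ids, annotations$variant_id)
  if (anyNA(idx))
    stop("annotations missing for variant(s): ",
         paste(G$variant_ids[is.na(idx)], collapse = ", "))
  out <- annotations[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
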