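#' Construct a GenotypeData object
#'
#' @param dosage integer matrix of additive dosages, variants in rows and
#'   samples in columns; values 0/1/2 count alternate alleles, NA marks a
#'   missing call. A numeric matrix of whole numbers is coerced.
#' @param variants data.frame (or DataFrame) of variant metadata with
#'   columns \code{chrom}, \code{pos}, \code{id}, \code{ref}, \code{alt}.
#'   Defaults place all variants on one synthetic chromosome at 1 kb
#'   spacing, 1-based.
#' @param samples data.frame of per-sample metadata; must contain
#'   \code{sample_id}. Extra columns (cohort, status, age, sex, ...) ride
#'   along in \code{colData}.
#' @return A \linkS4class{GenotypeData}.
#' @examples
#' g <- GenotypeData(matrix(c(0L, 1L, 2L, 0L), 2, 2))
#' alleleFreq(g)
#' @export
GenotypeData <- function(dosage, variants = NULL, samples = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  if (!is.integer(dosage)) {
    stopifnot(all(is.na(dosage) | dosage == round(dosage)))
    storage.mode(dosage) <- "integer"
  }
  m <- nrow(dosage); n <- ncol(dosage)
  if (is.null(variants)) {
    variants <- data.frame(
      chrom = "1", pos = seq_len(m) * 1000L,
      id = sprintf("var%05d", seq_len(m)),
      ref = "A", alt = "G", stringsAsFactors = FALSE)
  }
  if (is.null(samples)) {
    ids <- colnames(dosage)
    if (is.null(ids)) ids <- sprintf("S%05d", seq_len(n))
    samples <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  }
  variants <- as.data.frame(variants)
  rownames(variants) <- NULL
  rownames(samples) <- NULL
  rownames(dosage) <- variants$id
  colnames(dosage) <- samples$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage),
    rowData = S4Vectors::DataFrame(variants),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
  new("GenotypeData", se)
}

#' @describeIn GenotypeData the dosage matrix (variants x samples)
#' @param x a GenotypeData
#' @export
setMethod("dosages", "GenotypeData", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @describeIn GenotypeData variant metadata as a data.frame
#' @export
setMethod("variantInfo", "GenotypeData", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @describeIn GenotypeData sample sheet as a data.frame
#' @export
setMethod("sampleInfo", "GenotypeData", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @describeIn GenotypeData per-variant alternate-allele frequency
#'   (missing calls excluded)
#' @export
setMethod("alleleFreq", "GenotypeData", function(x)
  rowMeans(dosages(x), na.rm = TRUE) / 2)

#' @describeIn GenotypeData per-variant minor-allele count
#' @export
setMethod("minorAlleleCount", "GenotypeData", function(x) {
  d <- dosages(x)
  ac <- rowSums(d, na.rm = TRUE)
  tot <- 2L * rowSums(!is.na(d))
  as.integer(round(pmin(ac, tot - ac)))
})

#' Per-variant or per-sample call rate
#' @param x a GenotypeData
#' @param margin "variant" or "sample"
#' @return numeric vector of non-missing fractions
#' @export
callRate <- function(x, margin = c("variant", "sample")) {
  margin <- match.arg(margin)
  d <- dosages(x)
  if (margin == "variant") rowMeans(!is.na(d)) else colMeans(!is.na(d))
}

setMethod("show", "GenotypeData", function(object) {
  d <- dosages(object)
  cat("GenotypeData:", nrow(object), "variants x", ncol(object), "samples\n")
  cat("  missing calls:",
      sprintf("%.2f%%", 100 * mean(is.na(d))), "\n")
  extra <- setdiff(colnames(SummarizedExperiment::colData(object)), "sample_id")
  if (length(extra))
    cat("  sample fields:", paste(extra, collapse = ", "), "\n")
})

setMethod("show", "PCModel", function(object) {
  cat("PCModel:", nrow(object@variants), "variants,", object@k, "components\n")
  cat("  singular values:", paste(signif(head(object@d, 5), 4), collapse = " "),
      if (object@k > 5) "...\n" else "\n")
  cat("  shrinkage:", paste(signif(head(object@shrinkage, 5), 4), collapse = " "),
      if (object@k > 5) "...\n" else "\n")
})

#' @describeIn ScoreSet score matrix (samples x k)
#' @param x a ScoreSet
#' @export
setMethod("scores", "ScoreSet", function(x) x@scores)

#' @describeIn ScoreSet provenance flag
#' @export
setMethod("provenance", "ScoreSet", function(x) x@provenance)

setMethod("show", "ScoreSet", function(object) {
  cat("ScoreSet (", object@provenance, "): ", nrow(object@scores),
      " samples x ", ncol(object@scores), " components\n", sep = "")
})

#' @describeIn PropensityFit per-sample propensity scores
#' @param x a PropensityFit
#' @export
setMethod("propensity", "PropensityFit", function(x) x@fitted)

setMethod("show", "PropensityFit", function(object) {
  cat("PropensityFit:", length(object@fitted), "samples,",
      length(object@coefficients), "coefficients;",
      if (object@penalized) "Firth-penalized;" else "ML;",
      if (object@converged) "converged" else "NOT converged",
      sprintf("(%d iterations)\n", object@n_iter))
})

#' @describeIn MatchResult ids of selected (matched) target samples
#' @param x a MatchResult
#' @export
setMethod("matchedSamples", "MatchResult", function(x)
  x@table$sample_id[x@table$matched])

#' @describeIn MatchResult named per-sample weight vector
#' @export
setMethod("matchWeights", "MatchResult", function(x)
  setNames(x@table$weight, x@table$sample_id))

setMethod("show", "MatchResult", function(object) {
  tab <- object@table
  ref <- tab$cohort == object@reference
  cat("MatchResult: reference '", object@reference, "' (", sum(ref),
      " samples, weight 1), target ", sum(!ref), " samples\n", sep = "")
  cat("  subclasses:", length(unique(tab$subclass)),
      " matched targets (weight >=", object@threshold, "):",
      sum(tab$matched), "\n")
})

#' @describeIn QCReport samples removed, with reason codes
#' @param x a QCReport
#' @export
setMethod("removedSamples", "QCReport", function(x) x@removedSamples)

#' @describeIn QCReport variants removed, with reason codes
#' @export
setMethod("removedVariants", "QCReport", function(x) x@removedVariants)

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", paste(object@steps, collapse = " -> "), "\n")
  cat("  removed", nrow(object@removedSamples), "samples,",
      nrow(object@removedVariants), "variants\n")
})
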