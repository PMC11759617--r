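#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#'   "colData<-" SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @importFrom stats pchisq pnorm qnorm qchisq rbinom runif rgamma quantile
#'   median sd var cor glm binomial coef complete.cases setNames aggregate
#'   uniroot na.omit
#' @importFrom utils read.delim write.table head
#' @useDynLib pcmatch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Genotype matrix with variant and sample annotation
#'
#' A thin wrapper around \linkS4class{SummarizedExperiment} holding an
#' additive dosage matrix (variants in rows, samples in columns, values in
#' \{0, 1, 2, NA\}), per-variant metadata (\code{chrom}, \code{pos},
#' \code{id}, \code{ref}, \code{alt}) in \code{rowData} and the sample
#' sheet (cohort label, affection status, age, sex, ...) in \code{colData}.
#'
#' @slot .. inherited from \code{SummarizedExperiment}; the single assay is
#'   named \code{"dosage"}.
#' @seealso [GenotypeData()], [dosages()], [alleleFreq()]
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is missing")
  d <- SummarizedExperiment::assay(object, "dosage")
  if (!is.integer(d))
    return("dosage assay must be an integer matrix")
  rng <- suppressWarnings(range(d, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0L || rng[2] > 2L))
    return("dosages must lie in {0, 1, 2, NA}")
  need <- c("chrom", "pos", "id", "ref", "alt")
  miss <- setdiff(need, colnames(SummarizedExperiment::rowData(object)))
  if (length(miss))
    return(paste0("rowData is missing column(s): ", paste(miss, collapse = ", ")))
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    return("sample ids (colnames) must be present and unique")
  TRUE
})

#' Reference principal-component model
#'
#' Holds everything needed to place new samples into a reference PC space:
#' the pruned variant list with the reference standardization frequencies,
#' orthonormal variant loadings, singular values, and per-component
#' shrinkage-correction factors applied to projected scores.
#'
#' @slot variants data.frame with columns \code{id}, \code{chrom},
#'   \code{pos}, \code{freq} (reference alternate-allele frequency used for
#'   standardization, strictly inside (0, 1)).
#' @slot loadings variants x k orthonormal matrix.
#' @slot d length-k positive singular values.
#' @slot shrinkage length-k factors (>= 1) multiplied onto projected scores.
#' @slot k number of components.
#' @export
setClass("PCModel", representation(
  variants = "data.frame", loadings = "matrix", d = "numeric",
  shrinkage = "numeric", k = "integer"))

setValidity("PCModel", function(object) {
  k <- object@k
  if (ncol(object@loadings) != k || length(object@d) != k ||
      length(object@shrinkage) != k)
    return("loadings, singular values and shrinkage factors must all have k components")
  if (nrow(object@variants) != nrow(object@loadings))
    return("variant table and loadings disagree on the number of variants")
  if (any(object@variants$freq <= 0 | object@variants$freq >= 1))
    return("standardization frequencies must lie strictly inside (0, 1)")
  ortho <- crossprod(object@loadings)
  if (max(abs(ortho - diag(k))) > 1e-8)
    return("loadings columns are not orthonormal (tolerance 1e-8)")
  if (any(object@shrinkage < 1 - 1e-6))
    return("shrinkage factors must be >= 1")
  TRUE
})

#' Principal-component scores
#'
#' Samples x k score matrix together with a provenance flag recording
#' whether the scores come from the reference decomposition itself or from
#' projecting an external cohort into the reference space.
#'
#' @slot scores samples x k numeric matrix, rownames are sample ids.
#' @slot provenance "reference" or "projected".
#' @export
setClass("ScoreSet", representation(scores = "matrix", provenance = "character"))

setValidity("ScoreSet", function(object) {
  if (!object@provenance %in% c("reference", "projected", "jaccard"))
    return("provenance must be 'reference', 'projected' or 'jaccard'")
  if (is.null(rownames(object@scores)))
    return("score matrix must carry sample ids as rownames")
  TRUE
})

#' Propensity model fit for cohort membership
#'
#' @slot coefficients named coefficient vector (intercept + covariates).
#' @slot fitted per-sample propensity score, strictly inside (0, 1).
#' @slot converged logical.
#' @slot n_iter IRLS iterations used.
#' @slot penalized whether a Firth penalty was applied.
#' @export
setClass("PropensityFit", representation(
  coefficients = "numeric", fitted = "numeric", converged = "logical",
  n_iter = "integer", penalized = "logical", samples = "data.frame",
  reference = "character"))

setValidity("PropensityFit", function(object) {
  if (any(!is.finite(object@coefficients)))
    return("coefficients must be finite")
  if (any(object@fitted <= 0 | object@fitted >= 1))
    return("propensity scores must lie strictly inside (0, 1)")
  TRUE
})

#' Subclassification matching result
#'
#' Per-sample subclass assignments and matching weights under the
#' reference-as-estimand convention: every reference-cohort sample has
#' weight exactly 1; target weights are within-subclass reference/target
#' density ratios rescaled to mean 1, and the matched set is the target
#' samples whose weight reaches the selection threshold.
#'
#' @slot table data.frame with columns \code{sample_id}, \code{cohort},
#'   \code{score}, \code{subclass}, \code{weight}, \code{matched}.
#' @slot reference label of the reference cohort.
#' @slot threshold weight-selection threshold (inclusive).
#' @export
setClass("MatchResult", representation(
  table = "data.frame", reference = "character", threshold = "numeric"))

setValidity("MatchResult", function(object) {
  tab <- object@table
  need <- c("sample_id", "cohort", "score", "subclass", "weight", "matched")
  if (!all(need %in% names(tab)))
    return("match table is missing required columns")
  ref <- tab$cohort == object@reference
  if (any(tab$weight[ref] != 1))
    return("reference samples must have weight exactly 1")
  tw <- tab$weight[!ref]
  tw <- tw[tw > 0]
  if (length(tw) && abs(mean(tw) - 1) > 1e-9)
    return("mean nonzero target weight must equal 1 (tolerance 1e-9)")
  if (any(tab$matched & ref))
    return("matched mask may only cover the target cohort")
  TRUE
})

#' Quality-control report
#'
#' Records which samples and variants each filter removed and why, the
#' thresholds used, and the order in which filters ran.
#'
#' @slot removedSamples data.frame(sample_id, reason).
#' @slot removedVariants data.frame(id, reason).
#' @slot thresholds named list of the thresholds applied.
#' @slot steps character vector of filters in application order.
#' @slot counts named integer vector: samples/variants in and out.
#' @export
setClass("QCReport", representation(
  removedSamples = "data.frame", removedVariants = "data.frame",
  thresholds = "list", steps = "character", counts = "integer"))
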