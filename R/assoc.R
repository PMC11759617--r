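as_covariate_matrix <- function(covariates, x) {
  if (is.null(covariates)) return(NULL)
  if (is(covariates, "ScoreSet")) {
    m <- scores(covariates)
    return(m[match(colnames(x), rownames(m)), , drop = FALSE])
  }
  if (is.character(covariates)) {
    info <- sampleInfo(x)
    miss <- setdiff(covariates, names(info))
    if (length(miss)) stop("covariate column(s) not in the sample sheet: ",
                           paste(miss, collapse = ", "))
    return(as.matrix(info[, covariates, drop = FALSE]))
  }
  as.matrix(covariates)
}

#' Per-variant logistic association scan
#'
#' Additive-dosage maximum-likelihood logistic regression of case/control
#' status on each variant plus covariates (missing dosages mean-imputed
#' per variant), with Wald p-values on the dosage coefficient. Records
#' that fail to converge or give a runaway effect (|beta| > 10) are
#' flagged for Firth refitting rather than reported as Wald results; see
#' [firthFallbackPolicy()].
#'
#' @param x a GenotypeData
#' @param status binary phenotype: a vector aligned with samples, or the
#'   name of a sample-sheet column (default "status")
#' @param covariates covariate matrix (samples x p, no intercept), a
#'   ScoreSet, or character names of sample-sheet columns; NULL for none
#' @param maxit,tol IRLS controls
#' @param beta_max absolute effect size beyond which a fit is flagged
#' @param on_singular what to do when a variant's information matrix is
#'   singular (e.g. dosage collinear with a covariate): "error" (default)
#'   or "skip" (record left NA)
#' @return data.frame with one row per variant: chrom, pos, id,
#'   effect_allele, other_allele, eaf, maf, mac, n, n_cases, beta, se, p,
#'   test ("wald"/"none"), converged, flagged
#' @export
logisticScan <- function(x, status = "status", covariates = NULL,
                         maxit = 50, tol = 1e-8, beta_max = 10,
                         on_singular = c("error", "skip")) {
  on_singular <- match.arg(on_singular)
  y <- if (is.character(status) && length(status) == 1)
    sampleInfo(x)[[status]] else status
  if (is.null(y)) stop("phenotype column not found")
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("status must be binary 0/1 with no missing values")
  if (length(unique(y)) < 2) stop("both cases and controls are required")
  C <- as_covariate_matrix(covariates, x)
  X <- if (is.null(C)) matrix(1, ncol(x), 1) else cbind(1, C)
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  res <- cpp_logistic_scan(dosages(x), X, y, maxit, tol, beta_max)
  if (on_singular == "error" && any(res$status == 3))
    stop("singular fit (dosage collinear with covariates) for variant(s): ",
         paste(head(rownames(x)[res$status == 3]), collapse = ", "))
  vi <- variantInfo(x)
  data.frame(
    chrom = vi$chrom, pos = vi$pos, id = vi$id,
    effect_allele = vi$alt, other_allele = vi$ref,
    eaf = res$eaf, maf = res$maf, mac = res$mac, n = res$n_obs,
    n_cases = sum(y == 1), beta = res$beta, se = res$se, p = res$p,
    test = ifelse(res$status == 0, "wald", "none"),
    converged = res$converged,
    flagged = res$status == 1,
    stringsAsFactors = FALSE)
}

#' Firth-fallback refitting policy
#'
#' Refits with [firthFit()] every record whose Wald p-value falls below
#' \code{threshold_p}, plus every record flagged for non-convergence or
#' separation, provided its minor-allele count reaches \code{min_mac};
#' other records pass through unchanged. Applying the policy twice is a
#' no-op.
#'
#' @param records scan output from [logisticScan()]
#' @param x the GenotypeData the scan ran on
#' @param status,covariates as in [logisticScan()]
#' @param threshold_p Wald p-value below which records are refit
#' @param min_mac minimum minor-allele count for the Firth refit
#' @return records with refit rows labeled \code{test = "firth"}
#' @export
firthFallbackPolicy <- function(records, x, status = "status",
                                covariates = NULL, threshold_p = 0.01,
                                min_mac = 20) {
  y <- if (is.character(status) && length(status) == 1)
    sampleInfo(x)[[status]] else status
  y <- as.numeric(y)
  C <- as_covariate_matrix(covariates, x)
  todo <- which((records$test == "wald" & !is.na(records$p) &
                   records$p < threshold_p & records$mac >= min_mac) |
                  (records$flagged & records$mac >= min_mac))
  for (i in todo) {
    g <- dosages(x)[match(records$id[i], rownames(x)), ]
    ft <- firthFit(g, y, C, min_mac = min_mac)
    if (ft$converged) {
      records$beta[i] <- ft$beta
      records$se[i] <- ft$se
      records$p[i] <- ft$p
      records$test[i] <- "firth"
      records$converged[i] <- TRUE
      records$flagged[i] <- FALSE
    } else {
      records$test[i] <- "none"
      records$converged[i] <- FALSE
      records$flagged[i] <- FALSE
    }
  }
  records
}

#' Genomic-control inflation factor
#'
#' \code{lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)}; values near
#' 1 indicate a well-calibrated scan, values above 1 systematic inflation
#' such as uncorrected population stratification.
#'
#' @param p vector of p-values (at least 100 non-missing)
#' @return list(lambda, n_variants)
#' @export
genomicLambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 100)
    stop("at least 100 p-values are required for a stable lambda")
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  list(lambda = median(chisq) / qchisq(0.5, df = 1),
       n_variants = length(p))
}

#' Scan + Firth fallback + inflation diagnostics
#'
#' @inheritParams logisticScan
#' @param firth_p Firth-fallback p-value threshold
#' @param min_mac minimum minor-allele count for Firth refits
#' @return list(records, lambda)
#' @export
runGWAS <- function(x, status = "status", covariates = NULL,
                    firth_p = 0.01, min_mac = 20,
                    on_singular = c("error", "skip")) {
  rec <- logisticScan(x, status, covariates,
                      on_singular = match.arg(on_singular))
  rec <- firthFallbackPolicy(rec, x, status, covariates,
                             threshold_p = firth_p, min_mac = min_mac)
  lam <- genomicLambda(rec$p)
  list(records = rec, lambda = lam)
}

#' Write / read summary statistics
#'
#' Tab-delimited with columns (chrom, pos, id, effect_allele,
#' other_allele, eaf, n, n_cases, beta, se, p, test, converged) — a
#' superset of what standard meta-analysis tools import.
#'
#' @param records a scan result
#' @param path file path
#' @return invisibly, the path
#' @export
writeSumstats <- function(records, path) {
  cols <- c("chrom", "pos", "id", "effect_allele", "other_allele", "eaf",
            "maf", "mac", "n", "n_cases", "beta", "se", "p", "test",
            "converged")
  write.table(records[, intersect(cols, names(records))], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSumstats
#' @export
readSumstats <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(chrom = "character", id = "character"))
}
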