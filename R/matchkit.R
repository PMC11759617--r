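#' Fit the cohort-membership propensity model
#'
#' Logistic regression of cohort membership (reference cohort coded 1) on
#' the leading projected PCs and affection status, optionally plus age and
#' sex — the "Cohort ~ PCs + status (+ age + sex)" model. Fitting is by
#' iteratively reweighted least squares; complete separation raises an
#' error suggesting \code{penalize = TRUE}, which switches to a
#' Firth-penalized fit.
#'
#' @param pcs ScoreSet (or matrix) of scores for all samples of both
#'   cohorts, rownames = sample ids
#' @param sheet sample sheet with \code{sample_id}, \code{cohort},
#'   \code{status} and, if used, \code{age}, \code{sex}
#' @param reference label of the reference (disease) cohort
#' @param include_age_sex add age and sex to the model
#' @param n_pcs number of leading PCs (default 20)
#' @param penalize use a Firth-penalized fit (for separation)
#' @param maxit,tol IRLS controls
#' @return a \linkS4class{PropensityFit}
#' @export
fitPropensity <- function(pcs, sheet, reference, include_age_sex = FALSE,
                          n_pcs = 20, penalize = FALSE, maxit = 100,
                          tol = 1e-8) {
  s <- if (is(pcs, "ScoreSet")) scores(pcs) else pcs
  idx <- match(sheet$sample_id, rownames(s))
  if (anyNA(idx)) stop("scores are missing for some samples in the sheet")
  s <- s[idx, seq_len(min(n_pcs, ncol(s))), drop = FALSE]
  if (!reference %in% sheet$cohort) stop("reference cohort not in sheet")
  if (length(unique(sheet$cohort)) != 2)
    stop("exactly two cohort labels are required")
  y <- as.numeric(sheet$cohort == reference)
  X <- cbind(s, status = sheet$status)
  if (include_age_sex) X <- cbind(X, age = sheet$age, sex = sheet$sex)
  if (anyNA(X)) stop("missing covariate values in the propensity model")
  Xd <- cbind(`(Intercept)` = 1, X)
  if (penalize) {
    fit <- firthLogistic(Xd, y, maxit = maxit, tol = tol)
    if (!fit$converged) stop("penalized propensity fit did not converge")
    eta <- drop(Xd %*% fit$beta)
    fitted <- stats::plogis(eta)
    cf <- setNames(fit$beta, colnames(Xd))
    niter <- fit$niter
    conv <- fit$converged
  } else {
    gf <- withCallingHandlers(
      glm.fit(Xd, y, family = binomial(),
              control = list(maxit = maxit, epsilon = tol)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          stop("propensity model separation detected; refit with penalize = TRUE",
               call. = FALSE)
        invokeRestart("muffleWarning")
      })
    if (!gf$converged)
      stop("propensity model did not converge; consider penalize = TRUE")
    fitted <- gf$fitted.values
    if (any(fitted <= 1e-14 | fitted >= 1 - 1e-14))
      stop("propensity model separation detected; refit with penalize = TRUE")
    cf <- setNames(coef(gf), colnames(Xd))
    niter <- gf$iter
    conv <- gf$converged
  }
  fitted <- pmin(pmax(fitted, 1e-12), 1 - 1e-12)
  new("PropensityFit", coefficients = cf,
      fitted = setNames(fitted, sheet$sample_id), converged = conv,
      n_iter = as.integer(niter), penalized = penalize,
      samples = data.frame(sample_id = sheet$sample_id,
                           cohort = sheet$cohort, stringsAsFactors = FALSE),
      reference = reference)
}

#' @importFrom stats glm.fit
NULL

#' Propensity-score subclassification
#'
#' Subclass boundaries are the propensity-score quantiles of the
#' *reference* cohort (the treated-group convention matching reference
#' weights of 1); every sample of both cohorts is then assigned by score.
#' Subclasses left without a reference sample are merged downward (toward
#' lower scores; an empty first subclass merges upward).
#'
#' @param fit a \linkS4class{PropensityFit}
#' @param n_subclasses requested number of subclasses (default 500;
#'   reduced with a warning when the reference cohort is smaller)
#' @return integer vector of subclass indices (1..S), named by sample id
#' @export
subclassify <- function(fit, n_subclasses = 500) {
  stopifnot(n_subclasses >= 2)
  score <- fit@fitted
  ref <- fit@samples$cohort == fit@reference
  S <- n_subclasses
  if (sum(ref) < S) {
    S <- max(2, sum(ref))
    warning("reference cohort smaller than requested subclasses; using S = ", S)
  }
  br <- quantile(score[ref], probs = seq(0, 1, length.out = S + 1),
                 names = FALSE)
  sub <- findInterval(score, br[2:S]) + 1L      # 1..S, open-ended tails
  # merge subclasses with no reference member
  refcnt <- tabulate(sub[ref], nbins = S)
  map <- seq_len(S)
  for (s in seq_len(S)) {
    if (refcnt[s] == 0) {
      lower <- which(refcnt[seq_len(s - 1)] > 0)
      map[s] <- if (length(lower)) max(lower) else
        min(which(refcnt > 0))
    }
  }
  sub <- map[sub]
  relabel <- match(sub, sort(unique(map)))
  setNames(as.integer(relabel), fit@samples$sample_id)
}

#' Subclassification matching weights
#'
#' Reference samples get weight exactly 1. A target sample in subclass s
#' gets the raw density ratio \code{n_ref(s)/n_target(s)}, and all target
#' weights are rescaled so their mean over weighted target samples is 1 —
#' making the selection threshold a relative-density criterion.
#'
#' @param subclasses named subclass vector from [subclassify()]
#' @param cohort cohort labels aligned with \code{subclasses}
#' @param reference the reference cohort label
#' @return named numeric weight vector
#' @export
computeWeights <- function(subclasses, cohort, reference) {
  ref <- cohort == reference
  S <- max(subclasses)
  n_ref <- tabulate(subclasses[ref], nbins = S)
  n_tgt <- tabulate(subclasses[!ref], nbins = S)
  if (any(n_ref == 0 & n_tgt > 0))
    stop("subclass without reference members; merge before weighting")
  empty_tgt <- which(n_ref > 0 & n_tgt == 0)
  if (length(empty_tgt))
    message(length(empty_tgt),
            " subclass(es) have reference but no target members")
  raw <- ifelse(n_tgt > 0, n_ref / pmax(n_tgt, 1), 0)
  w <- numeric(length(subclasses))
  w[ref] <- 1
  w[!ref] <- raw[subclasses[!ref]]
  nz <- !ref & w > 0
  if (any(nz)) w[nz] <- w[nz] / mean(w[nz])
  setNames(w, names(subclasses))
}

#' Select matched target samples by weight threshold
#'
#' @param weights named weights from [computeWeights()]
#' @param cohort cohort labels aligned with \code{weights}
#' @param reference reference cohort label
#' @param threshold inclusive weight threshold (default 1: "matching or
#'   exceeding the reference weight")
#' @return named logical mask, TRUE for selected target samples
#' @export
selectMatched <- function(weights, cohort, reference, threshold = 1.0) {
  mask <- cohort != reference & weights >= threshold
  setNames(mask, names(weights))
}

#' One-call propensity matching
#'
#' Runs [fitPropensity()], [subclassify()], [computeWeights()] and
#' [selectMatched()] and bundles the result.
#'
#' @inheritParams fitPropensity
#' @param n_subclasses number of subclasses
#' @param threshold weight-selection threshold
#' @return a \linkS4class{MatchResult}
#' @export
propensityMatch <- function(pcs, sheet, reference, include_age_sex = FALSE,
                            n_pcs = 20, n_subclasses = 500, threshold = 1.0,
                            penalize = FALSE) {
  fit <- fitPropensity(pcs, sheet, reference,
                       include_age_sex = include_age_sex, n_pcs = n_pcs,
                       penalize = penalize)
  sub <- subclassify(fit, n_subclasses)
  w <- computeWeights(sub, fit@samples$cohort, reference)
  mask <- selectMatched(w, fit@samples$cohort, reference, threshold)
  new("MatchResult",
      table = data.frame(sample_id = fit@samples$sample_id,
                         cohort = fit@samples$cohort,
                         score = unname(fit@fitted),
                         subclass = unname(sub), weight = unname(w),
                         matched = unname(mask), stringsAsFactors = FALSE),
      reference = reference, threshold = threshold)
}

smd <- function(a, b) {
  pooled <- sqrt((var(a) + var(b)) / 2)
  if (!is.finite(pooled) || pooled == 0) return(0)
  (mean(a) - mean(b)) / pooled
}

#' Covariate balance before and after matching
#'
#' Standardized mean differences between the reference cohort and the
#' target cohort, for every PC plus age, sex and affection status, before
#' matching (all target samples) and after (matched subset only).
#'
#' @param pcs ScoreSet or score matrix for all samples
#' @param sheet sample sheet (sample_id, cohort, status, age, sex)
#' @param result a \linkS4class{MatchResult}
#' @return data.frame(covariate, smd_unmatched, smd_matched)
#' @export
balanceReport <- function(pcs, sheet, result) {
  s <- if (is(pcs, "ScoreSet")) scores(pcs) else pcs
  s <- s[match(sheet$sample_id, rownames(s)), , drop = FALSE]
  covs <- cbind(as.data.frame(s),
                age = sheet$age, sex = sheet$sex, status = sheet$status)
  ref <- sheet$cohort == result@reference
  matched <- sheet$sample_id %in% matchedSamples(result)
  data.frame(
    covariate = names(covs),
    smd_unmatched = vapply(covs, function(v) smd(v[ref], v[!ref]),
                           numeric(1)),
    smd_matched = vapply(covs, function(v) smd(v[ref], v[matched]),
                         numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
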