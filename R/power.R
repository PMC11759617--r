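#' Penetrances of an additive disease model
#'
#' Additive on the relative-risk scale: \code{f1 = grr f0},
#' \code{f2 = (2 grr - 1) f0} (so \code{f1 - f0 = f2 - f1}), with
#' \code{f0} set so the population prevalence is matched under
#' Hardy-Weinberg genotype frequencies at the risk-allele frequency
#' \code{maf}.
#'
#' @param maf risk-allele frequency in (0, 0.5]
#' @param grr genotype relative risk (>= 1), heterozygote vs reference
#'   homozygote
#' @param prevalence disease prevalence
#' @return named vector c(f0, f1, f2)
#' @export
penetrances <- function(maf, grr, prevalence = 0.111) {
  stopifnot(maf > 0, maf <= 0.5, grr >= 1,
            prevalence > 0, prevalence < 1)
  q <- maf
  g <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  f0 <- prevalence / (g[1] + g[2] * grr + g[3] * (2 * grr - 1))
  f <- c(f0 = f0, f1 = grr * f0, f2 = (2 * grr - 1) * f0)
  if (f[3] > 1)
    stop("infeasible model: homozygote penetrance exceeds 1")
  f
}

case_control_freqs <- function(maf, grr, prevalence) {
  q <- maf
  g <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  f <- penetrances(maf, grr, prevalence)
  gc <- g * f / prevalence                    # genotype freqs in cases
  gt <- g * (1 - f) / (1 - prevalence)        # ... in controls
  list(g_case = gc, g_control = gt,
       p_case = gc[2] / 2 + gc[3], p_control = gt[2] / 2 + gt[3])
}

power_ncp <- function(maf, grr, prevalence, n_cases, n_controls,
                      test = c("allele", "trend"),
                      variance = c("alternative", "pooled")) {
  test <- match.arg(test)
  variance <- match.arg(variance)
  fr <- case_control_freqs(maf, grr, prevalence)
  if (test == "allele") {
    pc <- fr$p_case; pt <- fr$p_control
    d <- pc - pt
    v <- if (variance == "alternative")
      pc * (1 - pc) / (2 * n_cases) + pt * (1 - pt) / (2 * n_controls)
    else {
      pbar <- (n_cases * pc + n_controls * pt) / (n_cases + n_controls)
      pbar * (1 - pbar) * (1 / (2 * n_cases) + 1 / (2 * n_controls))
    }
  } else {
    mc <- fr$g_case[2] + 2 * fr$g_case[3]
    mt <- fr$g_control[2] + 2 * fr$g_control[3]
    vc <- fr$g_case[2] + 4 * fr$g_case[3] - mc^2
    vt <- fr$g_control[2] + 4 * fr$g_control[3] - mt^2
    d <- mc - mt
    v <- if (variance == "alternative")
      vc / n_cases + vt / n_controls
    else {
      gp <- (n_cases * fr$g_case + n_controls * fr$g_control) /
        (n_cases + n_controls)
      mp <- gp[2] + 2 * gp[3]
      (gp[2] + 4 * gp[3] - mp^2) * (1 / n_cases + 1 / n_controls)
    }
  }
  unname(d^2 / v)
}

#' Analytic power of a 1-df case-control association test
#'
#' Exact noncentral chi-square power of the two-sided 1-df test of
#' case/control allele-frequency (or genotype-trend) difference under the
#' additive model of [penetrances()]. The noncentrality uses the
#' alternative-hypothesis variance by default (Wald convention);
#' \code{variance = "pooled"} gives the score-test convention.
#'
#' @inheritParams penetrances
#' @param n_cases,n_controls study sizes
#' @param alpha two-sided significance level
#' @param test "allele" (counts of 2n alleles) or "trend" (genotype means)
#' @param variance "alternative" or "pooled" noncentrality denominator
#' @return power in [0, 1]; equals \code{alpha} at \code{grr = 1}
#' @export
powerAdditive <- function(maf, grr, prevalence = 0.111, n_cases,
                          n_controls, alpha = 5e-8,
                          test = c("allele", "trend"),
                          variance = c("alternative", "pooled")) {
  ncp <- power_ncp(maf, grr, prevalence, n_cases, n_controls, test,
                   variance)
  crit <- qchisq(alpha, df = 1, lower.tail = FALSE)
  pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Smallest detectable genotype relative risk
#'
#' Bisection (bracket [1, 50], tolerance 1e-4) for the smallest GRR a
#' design can detect. \code{rule = "calculator"} (the default) uses the
#' median-detectability criterion that reproduces the University of
#' Michigan genetic-association power calculator's printed thresholds on
#' this design: the expected Wald statistic of the allele-frequency
#' difference (alternative-hypothesis standard error) reaches the upper
#' normal quantile at \code{alpha}, i.e. the point where a directional
#' detection at \code{alpha} becomes more likely than not.
#' \code{rule = "analytic"} instead requires exact noncentral power of at
#' least \code{target}. See the package vignette for the calibration
#' between the two.
#'
#' @inheritParams powerAdditive
#' @param target power target (used by both rules: "calculator" treats it
#'   as the calculator's nominal target and applies the detectability
#'   criterion; "analytic" enforces it exactly)
#' @param rule "calculator" or "analytic"
#' @return the GRR (full precision; round to 2 decimals for reporting)
#' @export
minGrrForPower <- function(maf, prevalence = 0.111, n_cases, n_controls,
                           alpha = 5e-8, target = 0.80,
                           rule = c("calculator", "analytic"),
                           test = c("allele", "trend"),
                           variance = c("alternative", "pooled")) {
  rule <- match.arg(rule)
  stopifnot(target > 0, target < 1)
  zdet <- qnorm(alpha, lower.tail = FALSE)^2
  ok <- function(grr) {
    if (rule == "calculator") {
      ncp <- power_ncp(maf, grr, prevalence, n_cases, n_controls,
                       "allele", "alternative")
      ncp >= zdet
    } else {
      powerAdditive(maf, grr, prevalence, n_cases, n_controls, alpha,
                    test, variance) >= target
    }
  }
  feasible <- function(grr)
    !inherits(tryCatch(penetrances(maf, grr, prevalence),
                       error = function(e) e), "error")
  lo <- 1; hi <- 50
  if (!feasible(hi)) {        # shrink the bracket to the feasible range
    flo <- 1; fhi <- 50
    while (fhi - flo > 1e-6) {
      mid <- (flo + fhi) / 2
      if (feasible(mid)) flo <- mid else fhi <- mid
    }
    hi <- flo
  }
  if (!ok(hi))
    stop("no feasible GRR in [1, ", round(hi, 2),
         "] meets the detection criterion for this design")
  if (ok(lo)) return(lo)
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (ok(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Batch power / detectable-GRR table
#'
#' @param specs data.frame with columns maf, n_cases, n_controls and
#'   optionally grr, prevalence, alpha
#' @param target power target for the detectable-GRR column
#' @return specs with appended \code{power} (where grr is given) and
#'   \code{min_grr} columns
#' @export
powerTable <- function(specs, target = 0.80) {
  if (is.null(specs$prevalence)) specs$prevalence <- 0.111
  if (is.null(specs$alpha)) specs$alpha <- 5e-8
  specs$min_grr <- mapply(function(m, k, nc, nt, a)
    tryCatch(minGrrForPower(m, k, nc, nt, alpha = a, target = target),
             error = function(e) NA_real_),   # design too small to detect
    specs$maf, specs$prevalence, specs$n_cases, specs$n_controls,
    specs$alpha)
  if (!is.null(specs$grr))
    specs$power <- mapply(function(m, g, k, nc, nt, a)
      powerAdditive(m, g, k, nc, nt, alpha = a),
      specs$maf, specs$grr, specs$prevalence, specs$n_cases,
      specs$n_controls, specs$alpha)
  specs
}
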