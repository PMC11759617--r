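#' Draw differentiated ancestral allele frequencies (Balding-Nichols)
#'
#' Ancestral base frequencies are drawn uniformly inside \code{base_bounds};
#' each population's variant frequency is then drawn from
#' \code{Beta(p(1-F)/F, (1-p)(1-F)/F)} around the base frequency \code{p},
#' where \code{F} is that population's fixation index. \code{F = 0}
#' degenerates to copying the base frequency. All frequencies are clamped
#' to \code{[1e-4, 1 - 1e-4]}.
#'
#' @param m number of variants (>= 1)
#' @param k number of ancestral populations (>= 1)
#' @param fst per-population fixation index, recycled to length \code{k};
#'   each value in \code{[0, 1)}
#' @param base_bounds lower/upper bound of the ancestral frequency, both
#'   strictly inside (0, 1)
#' @param base_freqs optional length-\code{m} vector of ancestral
#'   frequencies, bypassing the uniform draw
#' @param seed optional integer seed
#' @return list with elements \code{n_pops}, \code{base_freqs} (length m),
#'   \code{fst} (length k), \code{pop_freqs} (k x m matrix)
#' @examples
#' panel <- drawAncestralFrequencies(100, 3, fst = 0.1, seed = 1)
#' dim(panel$pop_freqs)
#' @export
drawAncestralFrequencies <- function(m, k, fst, base_bounds = c(0.05, 0.5),
                                     base_freqs = NULL, seed = NULL) {
  stopifnot(m >= 1, k >= 1)
  fst <- rep_len(fst, k)
  if (any(fst < 0 | fst >= 1))
    stop("fst must lie in [0, 1)")
  if (any(base_bounds <= 0 | base_bounds >= 1) ||
      base_bounds[1] > base_bounds[2])
    stop("base_bounds must be an increasing pair strictly inside (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  eps <- 1e-4
  if (is.null(base_freqs))
    base_freqs <- runif(m, base_bounds[1], base_bounds[2])
  else
    stopifnot(length(base_freqs) == m, all(base_freqs > 0 & base_freqs < 1))
  pop_freqs <- matrix(0, k, m)
  for (j in seq_len(k)) {
    F <- fst[j]
    if (F == 0) {
      pop_freqs[j, ] <- base_freqs
    } else {
      sc <- (1 - F) / F
      pop_freqs[j, ] <- stats::rbeta(m, base_freqs * sc, (1 - base_freqs) * sc)
    }
  }
  pop_freqs <- pmin(pmax(pop_freqs, eps), 1 - eps)
  list(n_pops = as.integer(k), base_freqs = base_freqs,
       fst = fst, pop_freqs = pop_freqs)
}

#' Draw Dirichlet admixture proportions
#'
#' Rows are i.i.d. Dirichlet(\code{alpha}); each row sums to one.
#'
#' @param n number of samples
#' @param alpha Dirichlet concentration parameters, all > 0; its length
#'   sets the number of ancestral components
#' @param seed optional integer seed
#' @return list with \code{dirichlet_alpha}, \code{n_samples}, and the
#'   \code{Q} matrix (n x K)
#' @export
drawAdmixture <- function(n, alpha, seed = NULL) {
  stopifnot(n >= 1)
  if (any(alpha <= 0)) stop("all Dirichlet alpha parameters must be > 0")
  if (!is.null(seed)) set.seed(seed)
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  # tiny concentrations can underflow every gamma draw to zero; the
  # limiting Dirichlet is then one-hot with probabilities prop. to alpha
  zero <- rowSums(g) == 0
  if (any(zero)) {
    idx <- sample.int(k, sum(zero), replace = TRUE, prob = alpha)
    g[zero, ] <- 0
    g[cbind(which(zero), idx)] <- 1
  }
  Q <- g / rowSums(g)
  list(dirichlet_alpha = alpha, n_samples = as.integer(n), Q = Q)
}

#' Simulate genotypes under an admixture model
#'
#' Each sample's per-variant alternate-allele probability is the admixture-
#' weighted mixture of its ancestral population frequencies,
#' \code{p_ij = sum_k Q[i,k] pop_freqs[k,j]}; the genotype is Binomial(2,
#' p_ij) and each call is independently set missing with probability
#' \code{missing_rate}. Variants are simulated independently (no linkage
#' disequilibrium); see [simulateLDBlock()] for a crude LD construction.
#'
#' @param panel ancestral panel from [drawAncestralFrequencies()]
#' @param admix admixture spec from [drawAdmixture()]
#' @param missing_rate per-call missingness probability in [0, 1)
#' @param seed optional integer seed
#' @param sample_prefix prefix for generated sample ids
#' @param chrom chromosome label for the variant metadata
#' @param start_index 1-based index of the first variant; positions are
#'   written at 1 kb spacing so chunked generation yields disjoint loci
#' @return a \linkS4class{GenotypeData}
#' @export
simulateGenotypes <- function(panel, admix, missing_rate = 0, seed = NULL,
                              sample_prefix = "S", chrom = "1",
                              start_index = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (ncol(admix$Q) != nrow(panel$pop_freqs))
    stop("admixture and panel disagree on the number of populations")
  if (!is.null(seed)) set.seed(seed)
  G <- cpp_simulate_genotypes(panel$pop_freqs, admix$Q, missing_rate)
  m <- nrow(G); n <- ncol(G)
  idx <- seq.int(start_index, length.out = m)
  variants <- data.frame(
    chrom = chrom, pos = idx * 1000L, id = sprintf("var%06d", idx),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("%s%05d", sample_prefix, seq_len(n)),
                        stringsAsFactors = FALSE)
  GenotypeData(G, variants, samples)
}

#' Append a crude LD block to simulated genotypes
#'
#' Duplicates one variant's dosages \code{n_copies} times; each copied call
#' is independently replaced by a fresh Binomial(2, allele frequency) draw
#' with probability \code{flip_prob}, so copies correlate with the seed
#' variant at roughly \code{r^2 = (1 - flip_prob)^2} while keeping its
#' allele frequency. Intended for exercising pruning and clumping.
#'
#' @param x a GenotypeData
#' @param index row index of the variant to duplicate
#' @param n_copies number of copies to append
#' @param flip_prob per-call redraw probability in [0, 1]
#' @param seed optional integer seed
#' @return a GenotypeData with the copies appended (positions continue at
#'   1 kb spacing after the template variant)
#' @export
simulateLDBlock <- function(x, index, n_copies = 1, flip_prob = 0,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- dosages(x)
  g <- d[index, ]
  af <- mean(g, na.rm = TRUE) / 2
  vi <- variantInfo(x)
  copies <- matrix(NA_integer_, n_copies, ncol(d))
  for (i in seq_len(n_copies)) {
    gi <- g
    redraw <- runif(length(g)) < flip_prob
    gi[redraw] <- rbinom(sum(redraw), 2, af)
    copies[i, ] <- gi
  }
  newvi <- data.frame(
    chrom = vi$chrom[index],
    pos = vi$pos[index] + seq_len(n_copies),
    id = paste0(vi$id[index], "_ld", seq_len(n_copies)),
    ref = vi$ref[index], alt = vi$alt[index], stringsAsFactors = FALSE)
  all <- rbind(cbind(vi, row = seq_len(nrow(vi))),
               cbind(newvi, row = nrow(vi) + seq_len(n_copies)))
  ord <- order(all$chrom, all$pos)
  dd <- rbind(d, copies)[all$row[ord], , drop = FALSE]
  GenotypeData(dd, all[ord, setdiff(names(all), "row")], sampleInfo(x))
}

#' Phenotype-model specification for the simulator
#'
#' @param prevalence marginal disease probability the liability intercept
#'   is calibrated to
#' @param causal data.frame with columns \code{index} (variant row) and
#'   \code{beta} (per-allele log-odds); NULL for a null phenotype
#' @param ancestry_confound per-ancestry log-odds offsets (length K, or a
#'   scalar recycled); entered into the liability as \code{Q \%*\% offset}
#' @param age_effect log-odds per standard deviation of age
#' @param sex_effect log-odds for sex = 1
#' @param proxy_sensitivity probability a clinical case is proxy-positive
#' @param proxy_specificity probability a clinical control is proxy-negative
#' @return a validated list
#' @export
phenotypeSpec <- function(prevalence = 0.111, causal = NULL,
                          ancestry_confound = 0, age_effect = 0,
                          sex_effect = 0, proxy_sensitivity = 1,
                          proxy_specificity = 1) {
  stopifnot(prevalence > 0, prevalence < 1,
            proxy_sensitivity > 0, proxy_sensitivity <= 1,
            proxy_specificity > 0, proxy_specificity <= 1)
  if (!is.null(causal))
    stopifnot(is.data.frame(causal), all(c("index", "beta") %in% names(causal)))
  list(prevalence = prevalence, causal = causal,
       ancestry_confound = ancestry_confound, age_effect = age_effect,
       sex_effect = sex_effect, proxy_sensitivity = proxy_sensitivity,
       proxy_specificity = proxy_specificity)
}

#' Simulate a liability phenotype with ancestry confounding
#'
#' The case probability is \code{plogis(b0 + G beta + Q c + a z(age) +
#' s sex)} with the intercept \code{b0} solved numerically so the marginal
#' case probability equals the requested prevalence. Clinical status is
#' Bernoulli in that probability; proxy status applies the specified
#' sensitivity/specificity as symmetric misclassification of clinical
#' status. Ages are Uniform(\code{age_bounds}) and standardized before
#' entering the liability; sex is Bernoulli(1/2), coded 0/1.
#'
#' @param x a GenotypeData (used for causal-variant dosages; missing calls
#'   are mean-imputed)
#' @param admix admixture spec from [drawAdmixture()]; its Q matrix enters
#'   the liability and is recorded in the sheet (simulation-only columns)
#' @param spec a [phenotypeSpec()]
#' @param cohort cohort label written to the sheet
#' @param status_type which status the \code{status} column carries;
#'   \code{"proxy"} emulates a noisy biobank family-history phenotype
#' @param age_bounds uniform age range in years
#' @param seed optional integer seed
#' @return the sample sheet: data.frame with \code{sample_id},
#'   \code{cohort}, \code{status}, \code{status_type}, \code{age},
#'   \code{sex}, plus \code{status_clinical}, \code{status_proxy} and the
#'   true admixture proportions \code{Q1..QK}
#' @export
simulatePhenotypes <- function(x, admix, spec = phenotypeSpec(),
                               cohort = "cohort", status_type = c("clinical",
                               "proxy"), age_bounds = c(55, 90),
                               seed = NULL) {
  status_type <- match.arg(status_type)
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(x)
  stopifnot(nrow(admix$Q) == n)
  age <- runif(n, age_bounds[1], age_bounds[2])
  sex <- rbinom(n, 1, 0.5)
  lp <- rep(0, n)
  if (!is.null(spec$causal)) {
    if (any(spec$causal$index < 1 | spec$causal$index > nrow(x)))
      stop("causal variant index out of range")
    for (r in seq_len(nrow(spec$causal))) {
      g <- dosages(x)[spec$causal$index[r], ]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      lp <- lp + spec$causal$beta[r] * g
    }
  }
  conf <- rep_len(spec$ancestry_confound, ncol(admix$Q))
  lp <- lp + drop(admix$Q %*% conf)
  zage <- if (sd(age) > 0) (age - mean(age)) / sd(age) else age * 0
  lp <- lp + spec$age_effect * zage + spec$sex_effect * sex
  fb <- function(b0) mean(stats::plogis(b0 + lp)) - spec$prevalence
  if (fb(-50) > 0 || fb(50) < 0)
    stop("no liability intercept in [-50, 50] attains the requested prevalence")
  b0 <- uniroot(fb, c(-50, 50), tol = 1e-10)$root
  pr <- stats::plogis(b0 + lp)
  clinical <- rbinom(n, 1, pr)
  u <- runif(n)
  proxy <- ifelse(clinical == 1, as.integer(u < spec$proxy_sensitivity),
                  as.integer(u >= spec$proxy_specificity))
  sheet <- data.frame(
    sample_id = colnames(x), cohort = cohort,
    status = if (status_type == "clinical") clinical else proxy,
    status_type = status_type, age = age, sex = sex,
    status_clinical = clinical, status_proxy = proxy,
    stringsAsFactors = FALSE)
  Qd <- as.data.frame(admix$Q)
  names(Qd) <- paste0("Q", seq_len(ncol(admix$Q)))
  cbind(sheet, Qd)
}

#' Attach a sample sheet to a GenotypeData
#'
#' @param x a GenotypeData
#' @param sheet a data.frame with a \code{sample_id} column covering all
#'   samples of \code{x}; rows are aligned by id
#' @return GenotypeData with the sheet as colData
#' @export
setSampleInfo <- function(x, sheet) {
  stopifnot("sample_id" %in% names(sheet))
  idx <- match(colnames(x), sheet$sample_id)
  if (anyNA(idx)) stop("sheet is missing sample(s): ",
                       paste(head(colnames(x)[is.na(idx)]), collapse = ", "))
  SummarizedExperiment::colData(x) <-
    S4Vectors::DataFrame(sheet[idx, , drop = FALSE],
                         row.names = colnames(x))
  x
}
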