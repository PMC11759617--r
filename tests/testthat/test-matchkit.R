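# shared fixture: two cohorts with divergent admixture, projected scores
make_match_fixture <- function(seed = 1, n_ref = 300, n_target = 900,
                               m = 400, alpha_ref = c(4, 1),
                               alpha_tgt = c(1, 4), conf = c(1, -1)) {
  panel <- drawAncestralFrequencies(m, 2, 0.1, seed = seed)
  adm_r <- drawAdmixture(n_ref, alpha_ref, seed = seed + 1)
  adm_t <- drawAdmixture(n_target, alpha_tgt, seed = seed + 2)
  g_r <- simulateGenotypes(panel, adm_r, seed = seed + 3,
                           sample_prefix = "R")
  g_t <- simulateGenotypes(panel, adm_t, seed = seed + 4,
                           sample_prefix = "T")
  sh_r <- simulatePhenotypes(g_r, adm_r,
    phenotypeSpec(prevalence = 0.2, ancestry_confound = conf),
    cohort = "ref", age_bounds = c(65, 90), seed = seed + 5)
  sh_t <- simulatePhenotypes(g_t, adm_t,
    phenotypeSpec(prevalence = 0.2, ancestry_confound = conf),
    cohort = "tgt", age_bounds = c(45, 85), seed = seed + 6)
  fit <- referencePCA(g_r, k = 10)
  proj <- projectCohort(fit$model, g_t)
  list(scores = rbind(scores(fit$scores), scores(proj)),
       sheet = rbind(sh_r, sh_t)[, c("sample_id", "cohort", "status",
                                     "age", "sex")])
}

test_that("propensity fit is null when cohorts are exchangeable", {
  set.seed(2)
  n <- 1000
  s <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(sprintf("S%04d", 1:n), NULL))
  sheet <- data.frame(sample_id = rownames(s),
                      cohort = rep(c("a", "b"), each = n / 2),
                      status = rbinom(n, 1, 0.2))
  fit <- fitPropensity(s, sheet, reference = "a", n_pcs = 5)
  expect_equal(unname(propensity(fit)), rep(0.5, n), tolerance = 0.1)
  # covariate coefficients are within ~3 SE of zero
  expect_true(all(abs(fit@coefficients[-1]) < 3 * 2 / sqrt(n) * 3))
})

test_that("separation raises an error that points at the Firth option", {
  s <- matrix(c(rnorm(50, 5), rnorm(50, -5)), ncol = 1,
              dimnames = list(sprintf("S%03d", 1:100), NULL))
  sheet <- data.frame(sample_id = rownames(s),
                      cohort = rep(c("a", "b"), each = 50),
                      status = rbinom(100, 1, 0.3))
  expect_error(fitPropensity(s, sheet, reference = "a", n_pcs = 1),
               "penalize")
  fitp <- fitPropensity(s, sheet, reference = "a", n_pcs = 1,
                        penalize = TRUE)
  expect_true(all(is.finite(fitp@coefficients)))
  expect_true(all(propensity(fitp) > 0 & propensity(fitp) < 1))
})

test_that("propensity coefficients match a direct likelihood optimizer", {
  s <- matrix(c(0.3, -1.2, 0.5, 2.0, -0.7, 1.1, -0.2, 0.9), ncol = 1,
              dimnames = list(paste0("S", 1:8), NULL))
  sheet <- data.frame(sample_id = rownames(s),
                      cohort = c("a", "b", "a", "b", "b", "a", "a", "b"),
                      status = c(1, 0, 0, 1, 0, 1, 0, 0))
  fit <- fitPropensity(s, sheet, reference = "a", n_pcs = 1)
  nll <- function(b) {
    eta <- b[1] + b[2] * s[, 1] + b[3] * sheet$status
    -sum((sheet$cohort == "a") * eta - log1p(exp(eta)))
  }
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(fit@coefficients), opt$par, tolerance = 1e-5)
})

test_that("subclassification uses reference-cohort quantiles", {
  score <- c(seq(0.001, 0.999, length.out = 400),   # reference, uniform
             runif(200))
  ids <- sprintf("S%04d", seq_along(score))
  fit <- new("PropensityFit", coefficients = c(a = 0),
             fitted = setNames(score, ids), converged = TRUE,
             n_iter = 1L, penalized = FALSE,
             samples = data.frame(sample_id = ids,
                                  cohort = rep(c("ref", "tgt"),
                                               c(400, 200))),
             reference = "ref")
  sub <- subclassify(fit, 4)
  expect_equal(as.integer(table(sub[1:400])), rep(100L, 4))  # 100 per subclass
  # all targets below the lowest reference score land in subclass 1
  fit2 <- fit
  fit2@fitted[401:600] <- score[1] / 2
  expect_true(all(subclassify(fit2, 4)[401:600] == 1))
  # hand-worked 2-subclass assignment: boundary at the reference median
  sc <- c(0.1, 0.2, 0.3, 0.4, 0.15, 0.35)
  ids3 <- paste0("x", 1:6)
  fit3 <- new("PropensityFit", coefficients = c(a = 0),
              fitted = setNames(sc, ids3), converged = TRUE, n_iter = 1L,
              penalized = FALSE,
              samples = data.frame(sample_id = ids3,
                                   cohort = c(rep("ref", 4), "tgt", "tgt")),
              reference = "ref")
  expect_identical(unname(subclassify(fit3, 2)), c(1L, 1L, 2L, 2L, 1L, 2L))
})

test_that("weights follow the reference-as-estimand convention", {
  # hand example: n_ref = (30, 10), n_target = (10, 30) -> weights (3, 1/3)
  sub <- c(rep(1L, 30), rep(2L, 10), rep(1L, 10), rep(2L, 30))
  cohort <- rep(c("ref", "tgt"), c(40, 40))
  names(sub) <- sprintf("S%02d", 1:80)
  w <- computeWeights(sub, cohort, "ref")
  expect_true(all(w[1:40] == 1))
  expect_equal(unname(w[41:50]), rep(3, 10))
  expect_equal(unname(w[51:80]), rep(1 / 3, 30))
  expect_equal(mean(w[41:80]), 1, tolerance = 1e-12)
  # single subclass: all target weights exactly 1
  w1 <- computeWeights(setNames(rep(1L, 20), letters[1:20]),
                       rep(c("ref", "tgt"), 10), "ref")
  expect_true(all(w1 == 1))
})

test_that("matched selection is inclusive at the threshold", {
  w <- setNames(c(1, 1.5, 0.99, 1.0, 0.2), paste0("s", 1:5))
  cohort <- c("ref", "tgt", "tgt", "tgt", "tgt")
  mask <- selectMatched(w, cohort, "ref", 1.0)
  expect_identical(unname(mask), c(FALSE, TRUE, FALSE, TRUE, FALSE))
})

test_that("balanced cohorts select about half the target", {
  set.seed(7)
  n <- 1200
  s <- matrix(rnorm(n), ncol = 1,
              dimnames = list(sprintf("S%04d", 1:n), NULL))
  sheet <- data.frame(sample_id = rownames(s),
                      cohort = rep(c("a", "b"), each = n / 2),
                      status = rbinom(n, 1, 0.15))
  res <- suppressWarnings(suppressMessages(
    propensityMatch(s, sheet, reference = "a", n_pcs = 1,
                    n_subclasses = 20)))
  frac <- length(matchedSamples(res)) / (n / 2)
  expect_gt(frac, 0.25)
  expect_lt(frac, 0.75)
  expect_true(validObject(res))
})

test_that("targets outside the reference's support are rarely selected", {
  # reference drawn from pops 1-2 only; target mixes in a divergent pop 3
  panel <- drawAncestralFrequencies(500, 3, c(0.1, 0.1, 0.7), seed = 40)
  ar <- drawAdmixture(300, c(5, 5, 1e-6), seed = 41)
  at <- drawAdmixture(900, c(2, 2, 4), seed = 42)
  gr <- simulateGenotypes(panel, ar, seed = 43, sample_prefix = "R")
  gt <- simulateGenotypes(panel, at, seed = 44, sample_prefix = "T")
  shr <- simulatePhenotypes(gr, ar, phenotypeSpec(prevalence = 0.2),
                            cohort = "ref", seed = 45)
  sht <- simulatePhenotypes(gt, at, phenotypeSpec(prevalence = 0.2),
                            cohort = "tgt", seed = 46)
  f <- referencePCA(gr, k = 5)
  sc <- rbind(scores(f$scores), scores(projectCohort(f$model, gt)))
  sheet <- rbind(shr, sht)[, c("sample_id", "cohort", "status", "age",
                               "sex")]
  res <- suppressWarnings(suppressMessages(
    propensityMatch(sc, sheet, reference = "ref", n_pcs = 5,
                    n_subclasses = 50)))
  sel <- matchedSamples(res)
  out_of_support <- sht$sample_id[at$Q[, 3] > 0.8]
  expect_gt(length(out_of_support), 20)
  expect_lt(mean(out_of_support %in% sel), 0.05)
})

test_that("matching improves PC balance on confounded simulations", {
  for (seed in c(101, 202)) {
    fx <- make_match_fixture(seed = seed)
    res <- suppressWarnings(suppressMessages(
      propensityMatch(fx$scores, fx$sheet, reference = "ref", n_pcs = 10,
                      n_subclasses = 100)))
    bal <- balanceReport(fx$scores, fx$sheet, res)
    pcs <- grepl("^PC", bal$covariate)
    expect_lt(mean(abs(bal$smd_matched[pcs])),
              mean(abs(bal$smd_unmatched[pcs])))
    # weight normalization invariant
    w <- matchWeights(res)
    tgt <- fx$sheet$cohort == "tgt"
    nz <- tgt & w[fx$sheet$sample_id] > 0
    expect_equal(mean(w[fx$sheet$sample_id][nz]), 1, tolerance = 1e-9)
  }
})

test_that("balance report covers every covariate and nulls out for identical cohorts", {
  set.seed(9)
  n <- 400
  s <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(sprintf("S%04d", 1:n), paste0("PC", 1:3)))
  sheet <- data.frame(sample_id = rownames(s),
                      cohort = rep(c("a", "b"), each = n / 2),
                      status = rbinom(n, 1, 0.2), age = rnorm(n, 70, 5),
                      sex = rbinom(n, 1, 0.5))
  res <- suppressWarnings(suppressMessages(
    propensityMatch(s, sheet, reference = "a", n_pcs = 3,
                    n_subclasses = 10)))
  bal <- balanceReport(s, sheet, res)
  expect_equal(nrow(bal), 3 + 3)  # PCs + age, sex, status
  expect_true(all(abs(bal$smd_unmatched) < 0.3))
})
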