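test_that("LD pruning keeps independent variants and drops duplicates", {
  g <- sim_pop(1000, 300, p = 0.3, seed = 1)
  kept <- ldPrune(g)
  expect_gt(length(kept) / 1000, 0.95)
  # exact duplicate at the adjacent position: one survivor
  g2 <- simulateLDBlock(g, index = 10, n_copies = 1, flip_prob = 0,
                        seed = 2)
  kept2 <- ldPrune(g2)
  pair <- c("var000010", "var000010_ld1")
  expect_equal(sum(pair %in% kept2), 1)
})

test_that("LD pruning matches a hand-worked 3-variant example", {
  # v1 and v2 nearly identical (r2 > 0.9), v3 independent;
  # v2 has the higher MAF so v1 is dropped
  v1 <- c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 0L, 1L, 0L)
  v2 <- v1; v2[8] <- 1L                          # one extra carrier
  v3 <- c(2L, 0L, 1L, 1L, 0L, 2L, 2L, 0L, 1L, 2L)
  x <- gd(rbind(v1, v2, v3))
  expect_gt(cor(v1, v2)^2, 0.8)
  expect_lt(cor(v2, v3)^2, 0.5)
  kept <- ldPrune(x, r2_max = 0.5, maf_min = 0.01)
  expect_identical(kept, rownames(x)[2:3])
})

test_that("reference PCA separates populations and is reproducible", {
  s <- sim_structured(400, 300, alpha = c(1e-2, 1e-2), fst = 0.1, seed = 3)
  pop <- apply(s$adm$Q, 1, which.max)
  fit <- referencePCA(s$g, k = 5)
  pc1 <- scores(fit$scores)[, 1]
  expect_gt(abs(cor(pc1, pop)), 0.9)
  # permuting samples permutes the scores
  perm <- sample(ncol(s$g))
  fit2 <- referencePCA(s$g[, perm], k = 5)
  expect_equal(scores(fit2$scores), scores(fit$scores)[perm, ],
               tolerance = 1e-8)
  # loadings are orthonormal (class validity) and signs deterministic
  expect_true(validObject(fit$model))
})

test_that("full-rank PCA reconstructs the standardized matrix", {
  g <- sim_pop(30, 80, p = 0.4, seed = 4)
  p <- alleleFreq(g)
  fit <- referencePCA(g, k = 30)
  Z <- t((dosages(g) - 2 * p) / sqrt(2 * p * (1 - p)))
  hat <- scores(fit$scores) %*% t(fit$model@loadings)
  expect_lt(max(abs(Z - hat)), 1e-6)
})

test_that("projection of the reference reproduces its own scores", {
  s <- sim_structured(300, 200, alpha = c(1, 2), fst = 0.1, seed = 5)
  fit <- referencePCA(s$g, k = 10)
  proj <- projectCohort(fit$model, s$g)
  expect_lt(max(abs(scores(proj) - scores(fit$scores))), 1e-8)
  expect_identical(provenance(proj), "projected")
})

test_that("projected held-out samples agree with a joint PCA", {
  s <- sim_structured(400, 600, alpha = c(0.4, 0.4), fst = 0.15, seed = 6)
  hold <- seq_len(150)
  fit <- referencePCA(s$g[, -hold], k = 4)
  proj <- projectCohort(fit$model, s$g[, hold])
  joint <- referencePCA(s$g, k = 4)
  j1 <- scores(joint$scores)[hold, 1]
  expect_gt(abs(cor(scores(proj)[, 1], j1)), 0.9)
})

test_that("a population absent from the reference projects outside its hull", {
  # pop 3 lies on the pop-1/pop-2 axis but beyond pop 1, so its offset has
  # a component along the reference's leading PC that exceeds the
  # reference spread
  panel <- drawAncestralFrequencies(500, 3, c(0.15, 0.15, 0), seed = 7)
  panel$pop_freqs[3, ] <- pmin(pmax(
    panel$base_freqs + 2.5 * (panel$pop_freqs[1, ] - panel$base_freqs),
    1e-4), 1 - 1e-4)
  adm_ref <- drawAdmixture(200, c(5, 5, 1e-6), seed = 8)   # pops 1-2 only
  adm_new <- drawAdmixture(50, c(1e-6, 1e-6, 5), seed = 9) # pop 3
  g_ref <- simulateGenotypes(panel, adm_ref, seed = 10)
  g_new <- simulateGenotypes(panel, adm_new, seed = 11, sample_prefix = "N")
  fit <- referencePCA(g_ref, k = 4)
  proj <- projectCohort(fit$model, g_new)
  outside <- vapply(seq_len(4), function(c) {
    rng <- range(scores(fit$scores)[, c])
    mean(scores(proj)[, c] < rng[1] | scores(proj)[, c] > rng[2])
  }, numeric(1))
  expect_gt(max(outside), 0.5)
})

test_that("projection standardizes by the model's reference frequencies", {
  g_ref <- sim_pop(100, 150, p = 0.5, seed = 12)
  fit <- referencePCA(g_ref, k = 3)
  g_tgt <- sim_pop(100, 40, p = 0.2, seed = 13)  # very different frequencies
  proj <- projectCohort(fit$model, g_tgt)
  p <- fit$model@variants$freq
  Z <- t((ifelse(is.na(dosages(g_tgt)), 2 * p, dosages(g_tgt)) - 2 * p) /
           sqrt(2 * p * (1 - p)))
  manual <- Z %*% fit$model@loadings
  expect_equal(unname(scores(proj)), unname(manual), tolerance = 1e-10)
})

test_that("projection refuses a target missing too many model variants", {
  g_ref <- sim_pop(100, 60, seed = 14)
  fit <- referencePCA(g_ref, k = 3)
  expect_error(projectCohort(fit$model, g_ref[1:70, ]), "not comparable")
  expect_silent(projectCohort(fit$model, g_ref[1:85, ]))
})

test_that("jackknife shrinkage factors are >= 1 and approach 1 with n", {
  fac_at <- function(n) {
    s <- sim_structured(150, n, alpha = c(0.5, 0.5), fst = 0.3,
                        seed = 20 + n)
    fit <- referencePCA(s$g, k = 2)
    m <- estimateShrinkage(fit$model, s$g, method = "jackknife",
                           seed = 1)
    m@shrinkage[1]
  }
  f <- vapply(c(200, 1000, 5000), fac_at, numeric(1))
  expect_true(all(f >= 1 - 1e-6))
  expect_lt(f[3], f[1])          # monotone trend toward 1
  expect_lt(f[3], 1.05)
  # method "none" gives identity factors
  g <- sim_pop(50, 40, seed = 15)
  fit <- referencePCA(g, k = 2)
  expect_identical(estimateShrinkage(fit$model, g, "none")@shrinkage,
                   c(1, 1))
})

test_that("Jaccard PCs match a dense eigen-solver oracle on a toy", {
  # 4 samples with hand-computable carrier profiles over 3 rare variants
  d <- matrix(0L, 3, 40)
  d[1, 1] <- 1L; d[2, 1] <- 1L          # sample 1 carries v1, v2
  d[1, 2] <- 1L                          # sample 2 carries v1
  d[3, 3] <- 1L                          # sample 3 carries v3
  x <- gd(d)
  expect_warning(ss <- jaccardPCs(x, rare_maf_max = 0.2, k = 2),
                 "no rare alleles")
  C <- t(d >= 1)
  inter <- tcrossprod(C)
  un <- outer(rowSums(C), rowSums(C), `+`) - inter
  S <- ifelse(un > 0, inter / un, 0)
  expect_equal(S[1, 2], 0.5)             # |{v1}| / |{v1, v2}|
  expect_equal(S[1, 3], 0)               # disjoint profiles
  expect_equal(S[2, 2], 1)
  n <- nrow(S)
  Sc <- S - matrix(rowMeans(S), n, n) -
    matrix(colMeans(S), n, n, byrow = TRUE) + mean(S)
  ev <- eigen(Sc, symmetric = TRUE)$vectors[, 1:2]
  got <- scores(ss)
  for (c in 1:2)
    expect_equal(abs(cor(got[, c], ev[, c])), 1, tolerance = 1e-8)
  expect_equal(unname(apply(got, 2, sd)), c(1, 1))  # unit variance
})

test_that("nearest-centroid ancestry labeling follows the tie rule", {
  cent <- rbind(A = c(0, 0), B = c(2, 0), C = c(0, 2))
  s <- rbind(s1 = c(0, 0), s2 = c(1, 0), s3 = c(0.2, 1.9))
  lab <- assignAncestry(s, cent)
  expect_identical(unname(lab), c("A", "A", "C"))   # tie s2 -> first label
  # 3-population simulation: unadmixed samples recover their population
  s3 <- sim_structured(300, 450, alpha = c(1e-3, 1e-3), fst = 0.2,
                       seed = 30)
  pop <- apply(s3$adm$Q, 1, which.max)
  fit <- referencePCA(s3$g, k = 2)
  sc <- scores(fit$scores)
  cent2 <- rbind(p1 = colMeans(sc[pop == 1, ]),
                 p2 = colMeans(sc[pop == 2, ]))
  lab2 <- assignAncestry(sc, cent2)
  expect_gt(mean(lab2 == paste0("p", pop)), 0.95)
})

test_that("PCModel serialization round-trips", {
  g <- sim_pop(60, 50, seed = 16)
  fit <- referencePCA(g, k = 4)
  dir <- withr::local_tempdir()
  writePCModel(fit$model, dir)
  back <- readPCModel(dir)
  expect_equal(back@loadings, fit$model@loadings, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back@d, fit$model@d)
  expect_equal(back@variants$freq, fit$model@variants$freq)
  proj <- projectCohort(back, g)
  expect_equal(scores(proj), scores(fit$scores), tolerance = 1e-6)
})
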