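test_that("variant missingness filter uses a strict threshold", {
  d <- matrix(1L, 3, 100)
  d[1, 1:11] <- NA   # 11% missing: removed
  d[2, 1:10] <- NA   # exactly 10%: retained
  x <- gd(d)
  res <- filterVariantMissingness(x, 0.10)
  expect_identical(rownames(res$data), rownames(x)[2:3])
  expect_identical(removedVariants(res$report)$reason, "missingness")
  # staged toy matrix equals hand enumeration
  d2 <- matrix(0L, 5, 20)
  for (i in 1:5) d2[i, seq_len((i - 1) * 2)] <- NA  # 0,2,4,6,8 of 20 missing
  res2 <- filterVariantMissingness(gd(d2), 0.25)
  expect_identical(which(rownames(gd(d2)) %in% rownames(res2$data)),
                   1:3)  # 0%, 10%, 20% kept; 30%, 40% dropped
})

test_that("sample missingness filter mirrors the variant filter", {
  d <- matrix(1L, 100, 3)
  d[1:6, 1] <- NA    # 6% missing: removed at 5%
  d[1:5, 2] <- NA    # exactly 5%: retained
  res <- filterSampleMissingness(gd(d), 0.05)
  expect_equal(ncol(res$data), 2)
  expect_identical(removedSamples(res$report)$sample_id, colnames(gd(d))[1])
  d2 <- matrix(0L, 10, 4)
  d2[1:3, 4] <- NA
  res2 <- filterSampleMissingness(gd(d2), 0.25)
  expect_equal(ncol(res2$data), 3)
})

test_that("HET/HOM outlier removal matches direct computation", {
  g <- sim_pop(200, 50, p = 0.4, seed = 1)
  res <- hetHomOutliers(g, 6)
  expect_equal(ncol(res$data), 50)          # homogeneous: none removed
  # constructed outlier: all heterozygous
  d <- dosages(g); d[, 1] <- 1L
  x <- gd(d)
  res2 <- hetHomOutliers(x, 6)
  r <- hetHomRatio(x)
  drop_direct <- abs(r - mean(r)) > 6 * sd(r)
  expect_identical(removedSamples(res2$report)$sample_id,
                   names(r)[drop_direct])
  expect_true(colnames(x)[1] %in% removedSamples(res2$report)$sample_id)
  # brute-force agreement on a noisy 20-sample set at a tighter threshold
  g3 <- sim_pop(300, 20, p = 0.25, seed = 2)
  r3 <- hetHomRatio(g3)
  res3 <- hetHomOutliers(g3, 1.5)
  expect_identical(sort(removedSamples(res3$report)$sample_id),
                   sort(names(r3)[abs(r3 - mean(r3)) > 1.5 * sd(r3)]))
})

test_that("KING-robust kinship recovers duplicate, parent-offspring, unrelated", {
  m <- 2000
  p <- runif(m, 0.1, 0.5)
  set.seed(3)
  draw <- function() rbinom(m, 2, p)
  a <- draw(); b <- draw()
  # child: one allele from parent a, one from the population
  inherit <- ifelse(a == 2, 1L, ifelse(a == 0, 0L, rbinom(m, 1, 0.5)))
  child <- inherit + rbinom(m, 1, p)
  x <- gd(cbind(a, dup = a, b, child))
  kin <- kingKinship(x, min_overlap = 100)
  phi <- function(i, j) kin$kinship[(kin$id1 == i & kin$id2 == j) |
                                      (kin$id1 == j & kin$id2 == i)]
  expect_equal(phi("a", "dup"), 0.5, tolerance = 0.02)
  expect_equal(phi("a", "child"), 0.25, tolerance = 0.03)
  expect_equal(phi("a", "b"), 0, tolerance = 0.02)
  # insufficient overlap is skipped with a warning
  d <- dosages(x); d[1:1950, 3] <- NA
  expect_warning(k2 <- kingKinship(gd(d), min_overlap = 100), "skipped")
  expect_equal(nrow(k2), 3)
})

test_that("greedy relatedness pruning follows the tie rules", {
  g <- sim_pop(100, 4, seed = 4)
  none <- data.frame(id1 = "S00001", id2 = "S00002", kinship = 0.01)
  expect_equal(ncol(removeRelated(none, g)$data), 4)
  dup <- data.frame(id1 = "S00001", id2 = "S00002", kinship = 0.3)
  res <- removeRelated(dup, g)
  expect_equal(ncol(res$data), 3)
  expect_identical(removedSamples(res$report)$sample_id, "S00001")
  # triangle: lexicographically first member of the tie dropped first,
  # then one more member of the remaining pair -> 2 removed
  tri <- data.frame(id1 = c("S00001", "S00001", "S00002"),
                    id2 = c("S00002", "S00003", "S00003"),
                    kinship = 0.4)
  res2 <- removeRelated(tri, g)
  expect_identical(removedSamples(res2$report)$sample_id,
                   c("S00001", "S00002"))
  expect_equal(ncol(res2$data), 2)
})

test_that("HWE mid-p equals the full-enumeration oracle", {
  expect_equal(hweMidp(0, 0, 100), 1)           # monomorphic
  expect_equal(hweMidp(25, 50, 25), hwe_midp_oracle(25, 50, 25))
  # extreme heterozygote deficit excluded at the 1e-15 gate
  expect_lt(hweMidp(50, 0, 50), 1e-15)
  expect_equal(hweMidp(50, 0, 50), hwe_midp_oracle(50, 0, 50),
               tolerance = 1e-10)
  # spot grid
  for (tab in list(c(3, 1, 7), c(10, 20, 10), c(1, 1, 1), c(0, 5, 0),
                   c(12, 0, 3), c(40, 55, 25)))
    expect_equal(hweMidp(tab[1], tab[2], tab[3]),
                 hwe_midp_oracle(tab[1], tab[2], tab[3]),
                 info = paste(tab, collapse = ","))
})

test_that("minor-allele count and carrier filters use inclusive bounds", {
  n <- 100
  d <- matrix(0L, 3, n)
  d[1, 1:19] <- 1L                      # 19 carriers, MAC 19: removed
  d[2, 1:20] <- 1L                      # 20 carriers, MAC 20: retained
  d[3, 1:30] <- 1L
  res <- macPrivacyFilter(gd(d), 20, 20)
  expect_identical(rownames(res$data), rownames(gd(d))[2:3])
  # staged toy: carrier count and MAC disagree (10 hom carriers = MAC 20)
  d2 <- rbind(c(rep(2L, 10), rep(0L, 90)),    # 10 carriers, MAC 20: removed
              c(rep(1L, 25), rep(0L, 75)),    # 25 carriers, MAC 25: kept
              c(rep(2L, 98), rep(1L, 2)))     # minor allele is REF, MAC 2
  res2 <- macPrivacyFilter(gd(d2), min_carriers = 20, min_mac = 20)
  expect_identical(which(rownames(gd(d2)) %in% rownames(res2$data)), 2L)
})

test_that("PC outliers are flagged on the top components", {
  set.seed(5)
  s <- matrix(rnorm(200 * 12), 200, 12,
              dimnames = list(sprintf("S%03d", 1:200), NULL))
  expect_true(!any(pcOutlierMask(s, 6)))
  s[7, 2] <- 100
  out <- pcOutlierMask(s, 6)
  expect_identical(names(out)[out], "S007")
  # direct computation at a loose threshold
  out2 <- pcOutlierMask(s, 2, n_pcs = 10)
  z <- scale(s[, 1:10])
  expect_identical(unname(out2), unname(rowSums(abs(z) > 2) > 0))
})

test_that("replicate removal keeps the least-missing copy", {
  g <- sim_pop(50, 6, seed = 6)
  d <- dosages(g); d[1:10, 2] <- NA
  info <- sampleInfo(g)
  info$replicate_group <- c("g1", "g1", NA, NA, "g2", "g2")
  x <- GenotypeData(d, variantInfo(g), info)
  res <- removeReplicates(x)
  expect_true(!"S00002" %in% colnames(res$data))   # more missing copy
  expect_equal(ncol(res$data), 4)
})

test_that("QC filters are idempotent", {
  g <- sim_pop(120, 60, p = 0.2, seed = 7, missing_rate = 0.08)
  for (f in list(function(x) filterVariantMissingness(x, 0.06)$data,
                 function(x) filterSampleMissingness(x, 0.07)$data,
                 function(x) hetHomOutliers(x, 6)$data,
                 function(x) macPrivacyFilter(x, 5, 5)$data,
                 function(x) hweFilter(x, 1e-4)$data)) {
    once <- f(g)
    expect_identical(dosages(f(once)), dosages(once))
  }
})

test_that("the QC cascade records its order and reasons", {
  g <- sim_pop(200, 40, p = 0.3, seed = 8, missing_rate = 0.03)
  res <- qcPipeline(g, min_carriers = 3, min_mac = 3,
                    kinship_min_overlap = 50)
  expect_identical(res$report@steps,
                   c("replicates", "sample_missingness", "het_hom",
                     "relatedness", "variant_missingness", "mac_privacy",
                     "hwe"))
  rs <- removedSamples(res$report)
  expect_true(all(rs$reason %in% c("replicate", "missingness", "het_hom",
                                   "related", "pc_outlier")))
  cnt <- res$report@counts
  expect_equal(unname(cnt["samples_out"] + nrow(rs)),
               unname(cnt["samples_in"]))
})
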