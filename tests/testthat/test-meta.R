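mk_study <- function(id, beta, se, eaf = 0.3, n = 1000, ea = "G", oa = "A",
                     chrom = "1", pos = NULL) {
  if (is.null(pos)) pos <- seq_along(id) * 1000
  data.frame(chrom = chrom, pos = pos, id = id, effect_allele = ea,
             other_allele = oa, eaf = eaf, n = n, n_cases = n / 2,
             beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)),
             test = "wald", converged = TRUE, stringsAsFactors = FALSE)
}

test_that("inverse-variance weighting matches closed forms", {
  one <- mk_study("v1", 0.5, 0.1)
  m1 <- ivwMeta(list(a = one))
  expect_equal(m1$beta, 0.5)
  expect_equal(m1$se, 0.1)
  expect_identical(m1$direction, "+")
  expect_equal(m1$df, 0L)
  # two identical studies: se / sqrt(2)
  m2 <- ivwMeta(list(a = one, b = one))
  expect_equal(m2$beta, 0.5)
  expect_equal(m2$se, 0.1 / sqrt(2), tolerance = 1e-12)
  # hand-worked example: w = (100, 25) -> beta 0.34, se 125^-1/2
  m3 <- ivwMeta(list(a = mk_study("v1", 0.4, 0.1),
                     b = mk_study("v1", 0.1, 0.2)))
  expect_equal(m3$beta, 0.34, tolerance = 1e-12)
  expect_equal(m3$se, 0.08944272, tolerance = 1e-7)
  expect_identical(m3$direction, "++")
  expect_equal(m3$df, 1L)
  # meta se below the smallest study se whenever df >= 1
  expect_lt(m3$se, 0.1)
})

test_that("alleles are harmonized by swapping and frequency for ambiguity", {
  a <- mk_study(c("v1", "v2", "v3"), c(0.3, 0.2, 0.4), 0.1,
                eaf = c(0.2, 0.2, 0.3),
                ea = c("G", "G", "A"), oa = c("A", "A", "T"))
  # v1 swapped alleles; v2 mismatched; v3 strand-ambiguous, frequencies agree
  b <- mk_study(c("v1", "v2", "v3"), c(-0.3, 0.2, 0.38), 0.1,
                eaf = c(0.8, 0.2, 0.28),
                ea = c("A", "G", "A"), oa = c("G", "C", "T"))
  m <- ivwMeta(list(a = a, b = b))
  expect_identical(attr(m, "dropped"), "v2")
  v1 <- m[m$id == "v1", ]
  expect_equal(v1$beta, 0.3, tolerance = 1e-12)    # flip restores agreement
  expect_equal(v1$df, 1L)
  expect_equal(v1$avg_eaf, 0.2)
  v3 <- m[m$id == "v3", ]
  expect_equal(v3$df, 1L)                          # kept: frequencies informative
  # ambiguous with uninformative frequencies is dropped
  a2 <- mk_study("v9", 0.3, 0.1, eaf = 0.5, ea = "C", oa = "G")
  b2 <- mk_study("v9", 0.3, 0.1, eaf = 0.52, ea = "C", oa = "G")
  m2 <- ivwMeta(list(a = a2, b = b2))
  expect_identical(attr(m2, "dropped"), "v9")
})

test_that("direction strings mark missing studies with '?'", {
  a <- mk_study(c("v1", "v2"), c(0.3, -0.2), 0.1)
  b <- mk_study("v1", 0.1, 0.1)
  m <- ivwMeta(list(a = a, b = b))
  expect_identical(m$direction[m$id == "v1"], "++")
  expect_identical(m$direction[m$id == "v2"], "-?")
  expect_equal(m$df[m$id == "v2"], 0L)
  # df + 1 equals the count of non-'?' entries
  expect_true(all(m$df + 1 ==
                    nchar(gsub("\\?", "", m$direction))))
})

test_that("meta filters apply the strict amplitude and df rules", {
  recs <- data.frame(
    id = paste0("v", 1:6),
    freq_amplitude = c(0.39, 0.40, 0.41, 0.1, 0.0, 0.2),
    df = c(1L, 1L, 1L, 0L, 1L, 1L))
  out <- metaFilters(recs, max_amplitude = 0.4, require_df = 1)
  expect_identical(out$id, c("v1", "v5", "v6"))   # hand enumeration
  # HWE gate with per-population tables
  tabs <- list(data.frame(id = c("v1", "v5"), n_AA = c(40, 50),
                          n_Aa = c(45, 0), n_aa = c(15, 50)))
  out2 <- metaFilters(recs, hwe_tables = tabs)
  expect_identical(out2$id, c("v1", "v6"))        # v5 fails HWE
  # idempotence
  expect_identical(metaFilters(out, max_amplitude = 0.4, require_df = 1),
                   out)
})

test_that("greedy clumping groups variants by LD around the lead", {
  g <- sim_pop(6, 600, p = 0.3, seed = 21)
  g2 <- simulateLDBlock(g, index = 2, n_copies = 1, flip_prob = 0,
                        seed = 22)
  ids <- variantInfo(g2)$id
  recs <- data.frame(chrom = variantInfo(g2)$chrom,
                     pos = variantInfo(g2)$pos, id = ids,
                     p = c(1e-10, 1e-12, 2e-12, 0.5, 1e-9, 1e-9, 1e-3))
  # make the duplicated pair the two most significant entries
  recs$p[ids == "var000002"] <- 1e-12
  recs$p[ids == "var000002_ld1"] <- 2e-12
  out <- clumpVariants(recs, g2, r2_min = 0.01, window_kb = 1000,
                       p_threshold = 5e-8)
  lead <- out[out$id == "var000002", ]
  expect_true(lead$lead)
  expect_identical(out$clump[out$id == "var000002_ld1"], "var000002")
  expect_false(out$lead[out$id == "var000002_ld1"])
  # far-apart independent significant variants form their own clumps
  far <- out[out$id %in% c("var000001", "var000005"), ]
  expect_true(all(far$lead))
  # non-significant rows stay unassigned
  nonsig <- out$id[out$p >= 5e-8]
  expect_true(all(is.na(out$clump[out$id %in% nonsig])))
  # idempotence / order stability
  again <- clumpVariants(out[, setdiff(names(out),
                                       c("clump", "lead", "ld_missing"))],
                         g2)
  expect_identical(again$clump, out$clump)
})

test_that("clump assignment matches a brute-force oracle on an LD block", {
  g <- sim_pop(5, 500, p = 0.4, seed = 23)
  g2 <- simulateLDBlock(g, index = 3, n_copies = 3, flip_prob = 0.3,
                        seed = 24)
  ids <- variantInfo(g2)$id
  set.seed(25)
  recs <- data.frame(chrom = variantInfo(g2)$chrom,
                     pos = variantInfo(g2)$pos, id = ids,
                     p = 10^-runif(length(ids), 8, 14))
  out <- clumpVariants(recs, g2, r2_min = 0.05, window_kb = 1000,
                       p_threshold = 5e-8)
  # oracle: replay the greedy definition with plain loops on r2 from cor()
  d <- dosages(g2); storage.mode(d) <- "double"
  o <- recs[order(recs$p, recs$id), ]
  assigned <- setNames(rep(NA_character_, nrow(o)), o$id)
  for (i in seq_len(nrow(o))) {
    if (!is.na(assigned[o$id[i]])) next
    assigned[o$id[i]] <- o$id[i]
    zi <- d[match(o$id[i], ids), ]
    for (j in seq_len(nrow(o))) {
      if (!is.na(assigned[o$id[j]])) next
      if (abs(o$pos[j] - o$pos[i]) > 1e6) next
      if (cor(zi, d[match(o$id[j], ids), ])^2 > 0.05)
        assigned[o$id[j]] <- o$id[i]
    }
  }
  expect_identical(out$clump, unname(assigned[out$id]))
})

test_that("meta-analysis of two null scans stays calibrated", {
  n <- 800; m <- 2500
  g1 <- sim_pop(m, n, p = 0.3, seed = 26)
  g2 <- sim_pop(m, n, p = 0.3, seed = 27)
  set.seed(28)
  r1 <- logisticScan(g1, status = rbinom(n, 1, 0.2))
  r2 <- logisticScan(g2, status = rbinom(n, 1, 0.2))
  m12 <- ivwMeta(list(a = r1, b = r2))
  lam_meta <- genomicLambda(m12$p)$lambda
  lam_max <- max(genomicLambda(r1$p)$lambda, genomicLambda(r2$p)$lambda)
  expect_lte(lam_meta, lam_max + 0.02)
})

test_that("meta results serialize with METAL-like columns", {
  m <- ivwMeta(list(a = mk_study("v1", 0.4, 0.1),
                    b = mk_study("v1", 0.1, 0.2)))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeMetaResults(m, path)
  back <- read.delim(path, check.names = FALSE)
  expect_identical(back$MarkerName, "v1")
  expect_equal(back$Effect, 0.34, tolerance = 1e-10)
  expect_identical(back$Direction, "++")
})
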