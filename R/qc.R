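sample_frame <- function(ids, reason) {
  data.frame(sample_id = ids, reason = rep_len(reason, length(ids)),
             stringsAsFactors = FALSE)
}

variant_frame <- function(ids, reason) {
  data.frame(id = ids, reason = rep_len(reason, length(ids)),
             stringsAsFactors = FALSE)
}

qc_report <- function(step, samples = NULL, variants = NULL,
                      thresholds = list(), counts = integer()) {
  if (is.null(samples))
    samples <- data.frame(sample_id = character(), reason = character(),
                          stringsAsFactors = FALSE)
  if (is.null(variants))
    variants <- data.frame(id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  new("QCReport", removedSamples = samples, removedVariants = variants,
      thresholds = thresholds, steps = step, counts = counts)
}

#' Combine QC reports in application order
#' @param ... QCReport objects
#' @return a single QCReport
#' @export
combineQCReports <- function(...) {
  reps <- list(...)
  new("QCReport",
      removedSamples = do.call(rbind, lapply(reps, removedSamples)),
      removedVariants = do.call(rbind, lapply(reps, removedVariants)),
      thresholds = do.call(c, lapply(reps, function(r) r@thresholds)),
      steps = do.call(c, lapply(reps, function(r) r@steps)),
      counts = do.call(c, lapply(reps, function(r) r@counts)))
}

#' Remove variants with excessive missingness
#'
#' A variant is removed when its missing-call fraction strictly exceeds
#' \code{max_miss}; a variant missing in exactly the threshold fraction is
#' retained.
#'
#' @param x a GenotypeData
#' @param max_miss maximum tolerated missing fraction, in [0, 1)
#' @return list with the filtered \code{data} and a \code{report}
#' @export
filterVariantMissingness <- function(x, max_miss = 0.10) {
  stopifnot(max_miss >= 0, max_miss < 1)
  miss <- rowMeans(is.na(dosages(x)))
  drop <- miss > max_miss
  list(data = x[!drop, ],
       report = qc_report("variant_missingness",
         variants = variant_frame(rownames(x)[drop], "missingness"),
         thresholds = list(variant_max_miss = max_miss),
         counts = c(variants_removed = sum(drop))))
}

#' Remove samples with excessive missingness
#'
#' @param x a GenotypeData
#' @param max_miss maximum tolerated missing fraction, strict inequality
#' @return list(data, report)
#' @export
filterSampleMissingness <- function(x, max_miss = 0.05) {
  stopifnot(max_miss >= 0, max_miss < 1)
  miss <- colMeans(is.na(dosages(x)))
  drop <- miss > max_miss
  list(data = x[, !drop],
       report = qc_report("sample_missingness",
         samples = sample_frame(colnames(x)[drop], "missingness"),
         thresholds = list(sample_max_miss = max_miss),
         counts = c(samples_removed = sum(drop))))
}

#' Heterozygosity/homozygosity ratio per sample
#'
#' Ratio of heterozygous calls to non-reference homozygous calls; the
#' denominator is floored at 1 so all-homozygous samples yield a finite
#' ratio (such samples are listed under \code{thresholds$denominator_floored}
#' in reports that use this).
#'
#' @param x a GenotypeData
#' @return named numeric vector
#' @export
hetHomRatio <- function(x) {
  d <- dosages(x)
  het <- colSums(d == 1L, na.rm = TRUE)
  hom <- colSums(d == 2L, na.rm = TRUE)
  setNames(het / pmax(hom, 1L), colnames(x))
}

#' Remove HET/HOM ratio outliers
#'
#' Samples whose het/hom ratio lies more than \code{n_sd} standard
#' deviations from the cohort mean are removed.
#'
#' @param x a GenotypeData (>= 3 samples)
#' @param n_sd outlier threshold in standard deviations
#' @return list(data, report)
#' @export
hetHomOutliers <- function(x, n_sd = 6) {
  stopifnot(ncol(x) >= 3)
  r <- hetHomRatio(x)
  floored <- names(r)[colSums(dosages(x) == 2L, na.rm = TRUE) == 0]
  s <- sd(r)
  drop <- if (s > 0) abs(r - mean(r)) > n_sd * s else rep(FALSE, length(r))
  list(data = x[, !drop],
       report = qc_report("het_hom",
         samples = sample_frame(names(r)[drop], "het_hom"),
         thresholds = list(het_hom_n_sd = n_sd,
                           denominator_floored = floored),
         counts = c(samples_removed = sum(drop))))
}

king_phi <- function(nhh, nopp, hi, hj) {
  nmin <- pmin(hi, hj)
  ifelse(nmin > 0,
         (nhh - 2 * nopp) / (2 * nmin) + 0.5 - (hi + hj) / (4 * nmin),
         NA_real_)
}

#' KING-robust pairwise kinship
#'
#' The between-family robust kinship estimator computed from counts of
#' double heterozygotes, opposite homozygotes, and per-sample heterozygous
#' calls over each pair's mutually non-missing variants. A duplicated
#' sample gives phi ~ 0.5, parent-offspring ~ 0.25, unrelated ~ 0.
#'
#' @param x a GenotypeData
#' @param pairs optional 2-column matrix/data.frame of sample-id pairs to
#'   restrict to; default all pairs
#' @param min_overlap minimum number of mutually non-missing variants; a
#'   pair below it is skipped with a warning
#' @return data.frame(id1, id2, kinship, n_variants), one row per computed
#'   pair (i < j)
#' @export
kingKinship <- function(x, pairs = NULL, min_overlap = 100) {
  d <- dosages(x)
  M <- !is.na(d); storage.mode(M) <- "double"
  H <- !is.na(d) & d == 1L; storage.mode(H) <- "double"
  R0 <- !is.na(d) & d == 0L; storage.mode(R0) <- "double"
  A2 <- !is.na(d) & d == 2L; storage.mode(A2) <- "double"
  nhh <- crossprod(H)
  nopp <- crossprod(R0, A2); nopp <- nopp + t(nopp)
  hm <- crossprod(H, M)       # hm[i,j]: sites het in i, non-missing in j
  ov <- crossprod(M)
  ids <- colnames(x)
  if (is.null(pairs)) {
    idx <- which(upper.tri(ov), arr.ind = TRUE)
  } else {
    pairs <- as.matrix(pairs)
    idx <- cbind(match(pairs[, 1], ids), match(pairs[, 2], ids))
    if (anyNA(idx)) stop("unknown sample id in pairs")
  }
  keep <- ov[idx] >= min_overlap
  if (any(!keep))
    warning(sum(!keep), " pair(s) skipped: fewer than ", min_overlap,
            " mutually non-missing variants")
  idx <- idx[keep, , drop = FALSE]
  phi <- king_phi(nhh[idx], nopp[idx],
                  hm[idx], hm[idx[, c(2, 1), drop = FALSE]])
  data.frame(id1 = ids[idx[, 1]], id2 = ids[idx[, 2]],
             kinship = phi, n_variants = ov[idx],
             stringsAsFactors = FALSE)
}

#' Greedy removal of related samples
#'
#' Iteratively drops the sample participating in the most kinship pairs at
#' or above the threshold until none remain; ties are broken by higher
#' genotype missingness, then lexicographic sample id. The default
#' threshold 0.0884 (= 2^-3.5) is the standard KING boundary between
#' second- and third-degree relatives.
#'
#' @param kinship data.frame from [kingKinship()]
#' @param x the GenotypeData the table refers to
#' @param threshold kinship coefficient at or above which a pair counts as
#'   related
#' @return list(data, report)
#' @export
removeRelated <- function(kinship, x, threshold = 0.0884) {
  rel <- kinship[!is.na(kinship$kinship) & kinship$kinship >= threshold,
                 c("id1", "id2"), drop = FALSE]
  miss <- 1 - callRate(x, "sample")
  dropped <- character()
  while (nrow(rel) > 0) {
    cnt <- table(c(rel$id1, rel$id2))
    cand <- names(cnt)[cnt == max(cnt)]
    cand <- cand[order(-miss[cand], cand)][1]
    dropped <- c(dropped, cand)
    rel <- rel[rel$id1 != cand & rel$id2 != cand, , drop = FALSE]
  }
  list(data = x[, !(colnames(x) %in% dropped)],
       report = qc_report("relatedness",
         samples = sample_frame(dropped, "related"),
         thresholds = list(kinship_threshold = threshold),
         counts = c(samples_removed = length(dropped))))
}

hwe_midp_one <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n - nA
  nr <- min(nA, na)                     # rarer allele count
  if (nr == 0L) return(1)
  # heterozygote counts share the parity of the rarer allele count
  hets <- seq.int(nr %% 2L, nr, by = 2L)
  # Wigginton-style recurrence on P(n_Aa = h | allele counts):
  # P(h) / P(h-2) = 4 nAA(h-2) naa(h-2) / (h (h-1)), accumulated in logs
  if (length(hets) > 1) {
    h <- hets[-1]
    inc <- log(4 * ((nA - h + 2) / 2) * ((na - h + 2) / 2)) -
      log(h * (h - 1))
    lp <- c(0, cumsum(inc))
  } else lp <- 0
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  less <- p < obs * (1 - 1e-12)
  equal <- abs(p - obs) <= obs * 1e-12
  min(1, sum(p[less]) + 0.5 * sum(p[equal]))
}

#' Exact Hardy-Weinberg test with mid-p correction
#'
#' Enumerates all heterozygote counts compatible with the observed allele
#' counts and returns the probability of tables less probable than the
#' observed one plus half the probability of equally probable tables.
#' Monomorphic variants return 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectors are accepted and
#'   recycled to a common length)
#' @return mid-p values in (0, 1]
#' @export
hweMidp <- function(n_AA, n_Aa, n_aa) {
  nn <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(n_AA, nn); n_Aa <- rep_len(n_Aa, nn)
  n_aa <- rep_len(n_aa, nn)
  stopifnot(all(n_AA >= 0), all(n_Aa >= 0), all(n_aa >= 0),
            all(n_AA + n_Aa + n_aa >= 1))
  vapply(seq_len(nn),
         function(i) hwe_midp_one(n_AA[i], n_Aa[i], n_aa[i]), numeric(1))
}

#' Hardy-Weinberg mid-p filter over a GenotypeData
#'
#' @param x a GenotypeData
#' @param threshold variants with mid-p <= threshold are removed
#' @return list(data, report); the report also records each removed
#'   variant's mid-p
#' @export
hweFilter <- function(x, threshold = 1e-15) {
  d <- dosages(x)
  p <- hweMidp(rowSums(d == 0L, na.rm = TRUE),
               rowSums(d == 1L, na.rm = TRUE),
               rowSums(d == 2L, na.rm = TRUE))
  drop <- p <= threshold
  list(data = x[!drop, ],
       report = qc_report("hwe",
         variants = variant_frame(rownames(x)[drop], "hwe"),
         thresholds = list(hwe_midp = threshold),
         counts = c(variants_removed = sum(drop))))
}

#' Minor-allele count and carrier-count (privacy) filter
#'
#' Removes variants carried by fewer than \code{min_carriers} individuals
#' or with minor-allele count below \code{min_mac}; a variant meeting both
#' bounds exactly is retained.
#'
#' @param x a GenotypeData
#' @param min_carriers minimum number of minor-allele carriers
#' @param min_mac minimum minor-allele count
#' @return list(data, report)
#' @export
macPrivacyFilter <- function(x, min_carriers = 20, min_mac = 20) {
  d <- dosages(x)
  af <- alleleFreq(x)
  mac <- minorAlleleCount(x)
  carriers <- ifelse(af <= 0.5,
                     rowSums(d >= 1L, na.rm = TRUE),
                     rowSums(d <= 1L, na.rm = TRUE))
  drop <- carriers < min_carriers | mac < min_mac
  reason <- ifelse(mac < min_mac, "mac", "privacy")
  list(data = x[!drop, ],
       report = qc_report("mac_privacy",
         variants = variant_frame(rownames(x)[drop], reason[drop]),
         thresholds = list(min_carriers = min_carriers, min_mac = min_mac),
         counts = c(variants_removed = sum(drop))))
}

#' Flag principal-component outliers
#'
#' @param pcs a ScoreSet or samples x k score matrix
#' @param n_sd threshold in standard deviations
#' @param n_pcs number of leading components examined (default 10, capped
#'   at the available k)
#' @return named logical vector, TRUE for outliers
#' @export
pcOutlierMask <- function(pcs, n_sd = 6, n_pcs = 10) {
  s <- if (is(pcs, "ScoreSet")) scores(pcs) else pcs
  s <- s[, seq_len(min(n_pcs, ncol(s))), drop = FALSE]
  z <- scale(s)
  out <- rowSums(abs(z) > n_sd, na.rm = TRUE) > 0
  setNames(out, rownames(s))
}

#' Remove technical replicates using a metadata column
#'
#' Replicate identity is taken from a sample-sheet column naming each
#' sample's replicate group (NA = not replicated); within a group the
#' sample with the fewest missing calls is kept.
#'
#' @param x a GenotypeData
#' @param column colData column holding the replicate group labels
#' @return list(data, report)
#' @export
removeReplicates <- function(x, column = "replicate_group") {
  info <- sampleInfo(x)
  if (!column %in% names(info))
    return(list(data = x, report = qc_report("replicates",
                counts = c(samples_removed = 0L))))
  grp <- info[[column]]
  miss <- 1 - callRate(x, "sample")
  dropped <- character()
  for (g in unique(grp[!is.na(grp)])) {
    ids <- colnames(x)[!is.na(grp) & grp == g]
    if (length(ids) > 1) {
      keep <- ids[order(miss[ids], ids)][1]
      dropped <- c(dropped, setdiff(ids, keep))
    }
  }
  list(data = x[, !(colnames(x) %in% dropped)],
       report = qc_report("replicates",
         samples = sample_frame(dropped, "replicate"),
         counts = c(samples_removed = length(dropped))))
}

#' Full sample- and variant-level QC cascade
#'
#' Applies, in order: technical-replicate removal, sample missingness,
#' HET/HOM outliers, relatedness pruning, PC outliers (when scores are
#' supplied), then variant missingness, minor-allele/privacy and
#' Hardy-Weinberg filters. The report records the order and every removal
#' with its primary reason code.
#'
#' @param x a GenotypeData
#' @param pcs optional ScoreSet/matrix for the PC-outlier step
#' @param sample_max_miss,het_hom_n_sd,kinship_threshold,pc_n_sd,
#'   variant_max_miss,min_carriers,min_mac,hwe_threshold thresholds,
#'   defaulting to the pipeline's standard values
#' @param kinship_min_overlap minimum pair overlap for kinship estimation
#' @return list(data, report)
#' @export
qcPipeline <- function(x, pcs = NULL, sample_max_miss = 0.05,
                       het_hom_n_sd = 6, kinship_threshold = 0.0884,
                       pc_n_sd = 6, variant_max_miss = 0.10,
                       min_carriers = 20, min_mac = 20,
                       hwe_threshold = 1e-15, kinship_min_overlap = 100) {
  st1 <- removeReplicates(x)
  st2 <- filterSampleMissingness(st1$data, sample_max_miss)
  st3 <- hetHomOutliers(st2$data, het_hom_n_sd)
  kin <- kingKinship(st3$data, min_overlap = kinship_min_overlap)
  st4 <- removeRelated(kin, st3$data, kinship_threshold)
  cur <- st4$data
  reports <- list(st1$report, st2$report, st3$report, st4$report)
  if (!is.null(pcs)) {
    out <- pcOutlierMask(pcs, pc_n_sd)
    out <- names(out)[out]
    drop <- colnames(cur) %in% out
    reports <- c(reports, list(qc_report("pc_outliers",
      samples = sample_frame(colnames(cur)[drop], "pc_outlier"),
      thresholds = list(pc_n_sd = pc_n_sd),
      counts = c(samples_removed = sum(drop)))))
    cur <- cur[, !drop]
  }
  st5 <- filterVariantMissingness(cur, variant_max_miss)
  st6 <- macPrivacyFilter(st5$data, min_carriers, min_mac)
  st7 <- hweFilter(st6$data, hwe_threshold)
  reports <- c(reports, list(st5$report, st6$report, st7$report))
  report <- do.call(combineQCReports, reports)
  report@counts <- c(samples_in = ncol(x), samples_out = ncol(st7$data),
                     variants_in = nrow(x), variants_out = nrow(st7$data))
  list(data = st7$data, report = report)
}

#' Write a QC report's removal log
#' @param report a QCReport
#' @param path output file (tab-delimited)
#' @return invisibly, the path
#' @export
writeQCReport <- function(report, path) {
  s <- removedSamples(report)
  v <- removedVariants(report)
  log <- rbind(
    if (nrow(s)) data.frame(axis = "sample", id = s$sample_id,
                            reason = s$reason) else NULL,
    if (nrow(v)) data.frame(axis = "variant", id = v$id,
                            reason = v$reason) else NULL)
  if (is.null(log)) log <- data.frame(axis = character(), id = character(),
                                      reason = character())
  write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
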