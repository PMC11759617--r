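#' Candidate variants for the PC space
#'
#' Common variants (reference MAF >= \code{maf_min}) meeting call-rate and
#' Hardy-Weinberg mid-p criteria, the variant set the reference PCA and
#' projection are built on (before LD pruning).
#'
#' @param x a GenotypeData (the reference cohort)
#' @param maf_min minimum minor-allele frequency
#' @param call_rate_min minimum per-variant call rate
#' @param hwe_threshold variants with HWE mid-p <= this are excluded
#' @return character vector of variant ids
#' @export
pcCandidateVariants <- function(x, maf_min = 0.01, call_rate_min = 0.9,
                                hwe_threshold = 1e-15) {
  af <- alleleFreq(x)
  maf <- pmin(af, 1 - af)
  ok <- maf >= maf_min & callRate(x, "variant") >= call_rate_min
  if (any(ok)) {
    d <- dosages(x)[ok, , drop = FALSE]
    p <- hweMidp(rowSums(d == 0L, na.rm = TRUE),
                 rowSums(d == 1L, na.rm = TRUE),
                 rowSums(d == 2L, na.rm = TRUE))
    ok[ok] <- p > hwe_threshold
  }
  rownames(x)[ok]
}

#' Greedy LD pruning
#'
#' Scans variants left to right along each chromosome; whenever two
#' variants within \code{window_kb} have squared Pearson dosage
#' correlation above \code{r2_max}, the lower-MAF member of the pair is
#' dropped. Variants below the MAF prefilter are excluded up front.
#' Missing dosages are mean-imputed before computing correlations.
#'
#' @param x a GenotypeData, variants sorted by position
#' @param window_kb window size in kilobases
#' @param step scan step in bases (the greedy scan advances one variant at
#'   a time, equivalent to a single-base step)
#' @param r2_max correlation threshold (strictly above is pruned)
#' @param maf_min common-variant prefilter
#' @return character vector: ids of retained variants
#' @export
ldPrune <- function(x, window_kb = 100, step = 1, r2_max = 0.1,
                    maf_min = 0.01) {
  vi <- variantInfo(x)
  if (is.unsorted(order(vi$chrom, vi$pos)[seq_len(nrow(vi))]) &&
      any(diff(vi$pos[vi$chrom == vi$chrom[1]]) < 0))
    stop("variants must be sorted by position")
  af <- alleleFreq(x)
  maf <- pmin(af, 1 - af)
  keep_pre <- which(maf >= maf_min)
  if (!length(keep_pre)) return(character())
  d <- dosages(x)[keep_pre, , drop = FALSE]
  storage.mode(d) <- "double"
  rm_mean <- rowMeans(d, na.rm = TRUE)
  idx_na <- which(is.na(d))
  if (length(idx_na))
    d[idx_na] <- rm_mean[(idx_na - 1) %% nrow(d) + 1]
  z <- d - rowMeans(d)
  ss <- sqrt(rowSums(z^2))
  vi <- vi[keep_pre, , drop = FALSE]
  maf <- maf[keep_pre]
  win <- window_kb * 1000
  kept <- integer()
  for (j in seq_len(nrow(vi))) {
    in_win <- kept[vi$chrom[kept] == vi$chrom[j] &
                   vi$pos[j] - vi$pos[kept] <= win]
    drop_j <- FALSE
    for (k in in_win) {
      if (ss[j] == 0 || ss[k] == 0) next
      r2 <- (sum(z[j, ] * z[k, ]) / (ss[j] * ss[k]))^2
      if (r2 > r2_max) {
        if (maf[j] < maf[k] ||
            (maf[j] == maf[k] && j > k)) { drop_j <- TRUE; break }
        kept <- setdiff(kept, k)
      }
    }
    if (!drop_j) kept <- c(kept, j)
  }
  vi$id[sort(kept)]
}

std_dosage <- function(d, p) {
  # (g - 2p)/sqrt(2p(1-p)) with missing calls imputed to the mean dosage 2p
  z <- sweep(d, 1, 2 * p) / sqrt(2 * p * (1 - p))
  z[is.na(z)] <- 0
  z
}

#' Reference principal-component analysis
#'
#' Standardizes dosages by the reference allele frequencies,
#' \code{(g - 2p)/sqrt(2p(1-p))} (residual missingness imputed to mean
#' dosage), and takes the truncated SVD. The sign convention makes the
#' largest-magnitude loading of each component positive, so results are
#' reproducible across runs and platforms.
#'
#' @param x the reference GenotypeData
#' @param variant_ids variants to use (normally the LD-pruned common set);
#'   NULL for all
#' @param k number of components (default 20; reduced with a warning when
#'   it exceeds the matrix rank)
#' @return list with \code{model} (a \linkS4class{PCModel}, shrinkage
#'   factors 1) and \code{scores} (a reference \linkS4class{ScoreSet})
#' @export
referencePCA <- function(x, variant_ids = NULL, k = 20) {
  if (!is.null(variant_ids)) x <- x[variant_ids, ]
  p <- alleleFreq(x)
  usable <- p > 0 & p < 1
  if (!all(usable)) x <- x[usable, ]
  p <- p[usable]
  if (ncol(x) < k + 1) stop("need at least k + 1 samples for a k-component PCA")
  d <- dosages(x); storage.mode(d) <- "double"
  Z <- t(std_dosage(d, p))                       # samples x variants
  m <- ncol(Z); n <- nrow(Z)
  if (m <= n) {
    ee <- eigen(crossprod(Z), symmetric = TRUE)
    ev <- pmax(ee$values, 0)
    pos <- sum(ev > max(ev) * 1e-12)
    if (k > pos) { warning("rank ", pos, " < k; using k = ", pos); k <- pos }
    V <- ee$vectors[, seq_len(k), drop = FALSE]
    dvals <- sqrt(ev[seq_len(k)])
  } else {
    ee <- eigen(tcrossprod(Z), symmetric = TRUE)
    ev <- pmax(ee$values, 0)
    pos <- sum(ev > max(ev) * 1e-12)
    if (k > pos) { warning("rank ", pos, " < k; using k = ", pos); k <- pos }
    dvals <- sqrt(ev[seq_len(k)])
    U <- ee$vectors[, seq_len(k), drop = FALSE]
    V <- crossprod(Z, U) %*% diag(1 / dvals, k)
  }
  # deterministic sign: largest-magnitude loading per component positive
  for (c in seq_len(k)) {
    i <- which.max(abs(V[, c]))
    if (V[i, c] < 0) V[, c] <- -V[, c]
  }
  scores <- Z %*% V
  rownames(scores) <- colnames(x)
  colnames(scores) <- paste0("PC", seq_len(k))
  colnames(V) <- paste0("PC", seq_len(k))
  vi <- variantInfo(x)
  model <- new("PCModel",
               variants = data.frame(id = vi$id, chrom = vi$chrom,
                                     pos = vi$pos, freq = p,
                                     stringsAsFactors = FALSE),
               loadings = V, d = dvals, shrinkage = rep(1, k),
               k = as.integer(k))
  list(model = model,
       scores = new("ScoreSet", scores = scores, provenance = "reference"))
}

#' Project a cohort into a reference PC space
#'
#' Target dosages are standardized with the *model's* reference
#' frequencies (entries missing or absent imputed to mean dosage), then
#' least-squares projected onto the loadings; each component is finally
#' multiplied by the model's shrinkage-correction factor.
#'
#' @param model a \linkS4class{PCModel}
#' @param x the target GenotypeData; must cover at least 80\% of the
#'   model's variants (matched by id)
#' @return a projected \linkS4class{ScoreSet}
#' @export
projectCohort <- function(model, x) {
  idx <- match(model@variants$id, rownames(x))
  frac_absent <- mean(is.na(idx))
  if (frac_absent > 0.2)
    stop(sprintf(paste0("%.0f%% of the model's variants are absent from the",
                        " target; the PC space is not comparable"),
                 100 * frac_absent))
  p <- model@variants$freq
  n <- ncol(x)
  m <- nrow(model@variants)
  d <- matrix(NA_real_, m, n)
  have <- !is.na(idx)
  d[have, ] <- dosages(x)[idx[have], , drop = FALSE]
  Z <- t(std_dosage(d, p))
  sc <- Z %*% model@loadings
  sc <- sweep(sc, 2, model@shrinkage, `*`)
  rownames(sc) <- colnames(x)
  colnames(sc) <- paste0("PC", seq_len(model@k))
  new("ScoreSet", scores = sc, provenance = "projected")
}

#' Estimate projection shrinkage-correction factors
#'
#' Out-of-sample projections contract toward the origin relative to
#' in-sample reference scores. \code{method = "jackknife"} estimates a
#' per-component correction by 10-fold leave-out: each fold's held-out
#' samples are projected onto a PCA fit without them, and the factor is
#' the mean ratio of in-sample score magnitude to projected score
#' magnitude, averaged over folds and floored at 1.
#'
#' @param model a fitted \linkS4class{PCModel}
#' @param x the reference GenotypeData the model was fit on
#' @param method "none" (identity factors) or "jackknife"
#' @param folds number of leave-out folds
#' @param seed optional seed for the fold assignment
#' @return the model with its shrinkage factors replaced
#' @export
estimateShrinkage <- function(model, x, method = c("jackknife", "none"),
                              folds = 10, seed = NULL) {
  method <- match.arg(method)
  k <- model@k
  if (method == "none") {
    model@shrinkage <- rep(1, k)
    return(model)
  }
  if (!is.null(seed)) set.seed(seed)
  x <- x[model@variants$id, ]
  full <- referencePCA(x, k = k)
  ref_sc <- scores(full$scores)
  n <- ncol(x)
  fold <- sample(rep_len(seq_len(folds), n))
  acc <- matrix(NA_real_, folds, k)
  for (f in seq_len(folds)) {
    hold <- fold == f
    fit <- suppressWarnings(referencePCA(x[, !hold], k = k))
    kk <- fit$model@k
    proj <- scores(projectCohort(fit$model, x[, hold]))
    # align fold components to the full decomposition by correlation sign
    ref_hold <- ref_sc[hold, , drop = FALSE]
    for (c in seq_len(min(k, kk))) {
      pc <- proj[, c]
      if (sd(pc) == 0) { warning("fold ", f, " component ", c,
                                 " has zero variance; factor 1"); next }
      if (cor(ref_hold[, c], pc) < 0) pc <- -pc
      ok <- abs(pc) > 1e-12
      if (any(ok)) acc[f, c] <- mean(abs(ref_hold[ok, c]) / abs(pc[ok]))
    }
  }
  fac <- colMeans(acc, na.rm = TRUE)
  fac[!is.finite(fac)] <- 1
  model@shrinkage <- pmax(fac, 1)
  model
}

#' Jaccard principal components over rare-allele carrier profiles
#'
#' Builds each sample's set of carried rare minor alleles (reference MAF
#' below \code{rare_maf_max}), computes pairwise Jaccard similarity
#' (intersection over union of carried sites; 0 by convention when a
#' sample carries none), double-centers the similarity matrix and takes
#' the top-k eigenvectors scaled to unit variance.
#'
#' @param x a GenotypeData
#' @param rare_maf_max rare-variant MAF bound (exclusive)
#' @param k number of components
#' @return a \linkS4class{ScoreSet} with provenance "jaccard"
#' @export
jaccardPCs <- function(x, rare_maf_max = 0.01, k = 5) {
  af <- alleleFreq(x)
  maf <- pmin(af, 1 - af)
  rare <- maf < rare_maf_max & maf > 0
  if (!any(rare)) stop("no rare variants below MAF ", rare_maf_max)
  d <- dosages(x)[rare, , drop = FALSE]
  minor_is_alt <- af[rare] <= 0.5
  carrier <- matrix(0, nrow(d), ncol(d))
  carrier[minor_is_alt, ] <- (d[minor_is_alt, , drop = FALSE] >= 1L)
  carrier[!minor_is_alt, ] <- (d[!minor_is_alt, , drop = FALSE] <= 1L)
  carrier[is.na(d)] <- 0
  C <- t(carrier)                               # samples x rare variants
  inter <- tcrossprod(C)
  sizes <- rowSums(C)
  if (any(sizes == 0))
    warning(sum(sizes == 0), " sample(s) carry no rare alleles; ",
            "their similarities are 0 by convention")
  un <- outer(sizes, sizes, `+`) - inter
  S <- ifelse(un > 0, inter / un, 0)
  n <- nrow(S)
  Sc <- S - matrix(rowMeans(S), n, n) -
    matrix(colMeans(S), n, n, byrow = TRUE) + mean(S)
  ee <- eigen(Sc, symmetric = TRUE)
  k <- min(k, sum(ee$values > 1e-12))
  V <- ee$vectors[, seq_len(k), drop = FALSE]
  for (c in seq_len(k)) {
    i <- which.max(abs(V[, c]))
    if (V[i, c] < 0) V[, c] <- -V[, c]
    V[, c] <- V[, c] / sd(V[, c])
  }
  rownames(V) <- colnames(x)
  colnames(V) <- paste0("JPC", seq_len(k))
  new("ScoreSet", scores = V, provenance = "jaccard")
}

#' Nearest-centroid ancestry labels
#'
#' Assigns each sample the label of the closest centroid in Euclidean PC
#' distance; exact ties go to the earlier centroid in row order.
#'
#' @param pcs a ScoreSet or score matrix
#' @param centroids labeled matrix (rownames are labels) with the same
#'   number of columns as the scores
#' @return named character vector of labels
#' @export
assignAncestry <- function(pcs, centroids) {
  s <- if (is(pcs, "ScoreSet")) scores(pcs) else pcs
  if (ncol(centroids) != ncol(s))
    stop("centroid dimension does not match the scores")
  d2 <- outer(rowSums(s^2), rep(1, nrow(centroids))) -
    2 * s %*% t(centroids) +
    outer(rep(1, nrow(s)), rowSums(centroids^2))
  lab <- rownames(centroids)[apply(d2, 1, which.min)]
  setNames(lab, rownames(s))
}

#' Serialize / load a PCModel
#'
#' The model is written as a directory holding \code{variants.tsv}
#' (id, chrom, pos, standardization frequency, one loading column per
#' component) and \code{meta.json} (k, singular values, shrinkage).
#'
#' @param model a PCModel
#' @param dir directory to create/fill
#' @return invisibly, \code{dir}
#' @export
writePCModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- cbind(model@variants, as.data.frame(model@loadings))
  write.table(tab, file.path(dir, "variants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(k = model@k, d = model@d, shrinkage = model@shrinkage),
    file.path(dir, "meta.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname writePCModel
#' @export
readPCModel <- function(dir) {
  tab <- read.delim(file.path(dir, "variants.tsv"),
                    colClasses = c(id = "character", chrom = "character"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  k <- as.integer(meta$k)
  new("PCModel",
      variants = tab[, c("id", "chrom", "pos", "freq")],
      loadings = as.matrix(tab[, paste0("PC", seq_len(k))]),
      d = as.numeric(meta$d), shrinkage = as.numeric(meta$shrinkage), k = k)
}

#' Write scores to a tab-delimited file
#' @param x a ScoreSet
#' @param path output path
#' @return invisibly, the path
#' @export
writeScores <- function(x, path) {
  tab <- data.frame(sample_id = rownames(scores(x)), scores(x),
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
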