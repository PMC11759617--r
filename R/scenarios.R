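panel_subset <- function(panel, idx) {
  panel$base_freqs <- panel$base_freqs[idx]
  panel$pop_freqs <- panel$pop_freqs[, idx, drop = FALSE]
  panel
}

admix_subset <- function(admix, rows) {
  admix$Q <- admix$Q[rows, , drop = FALSE]
  admix$n_samples <- nrow(admix$Q)
  admix
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 7919) %% 2147483647)
}

#' Two-cohort stratification-control scenario
#'
#' Simulates a disease (reference) cohort and a larger biobank (target)
#' cohort drawn from divergent Dirichlet mixtures of differentiated
#' ancestral populations, builds the reference PC space on an LD-pruned
#' common-variant subset, projects the target, performs propensity
#' subclassification matching on the 20 projected PCs, and measures
#' genomic-control inflation of covariate-adjusted logistic scans over
#' null variants. Three scans are available: the matched target cohort
#' under a null phenotype (calibration), the matched target under an
#' ancestry-confounded phenotype (stratification control), and the
#' unmatched pooled two-cohort scan of the confounded phenotype (the
#' inflated contrast). Genotypes are generated and scanned in chunks so
#' the variant count scales without holding the full matrix.
#'
#' @param seed integer seed governing every draw
#' @param n_ref,n_target cohort sizes
#' @param n_variants total null variants scanned
#' @param n_pops,fst ancestral populations and their fixation index
#' @param alpha_ref,alpha_target per-cohort Dirichlet concentrations
#' @param confound per-ancestry log-odds offsets of the confounded
#'   phenotype
#' @param prevalence phenotype prevalence
#' @param n_pca variants (the leading block) used for the PC space
#' @param n_pcs projected components used for matching and adjustment
#' @param n_subclasses propensity subclasses
#' @param chunk_size scan chunk width in variants
#' @param verbose emit per-chunk progress messages
#' @param scans which scans to run: subset of "matched_null",
#'   "matched_confounded", "pooled_confounded"
#' @return list with the requested lambdas (named as the scans), the
#'   matched target count, p-value vectors (as \code{p_<scan>}), and the
#'   per-scan variant counts
#' @export
stratificationScenario <- function(seed, n_ref = 4000, n_target = 20000,
                                   n_variants = 50000, n_pops = 3,
                                   fst = 0.1,
                                   alpha_ref = c(5, 3, 2),
                                   alpha_target = c(3, 4, 5),
                                   confound = c(1, 0, -1),
                                   prevalence = 0.111, n_pca = 2000,
                                   n_pcs = 20, n_subclasses = 500,
                                   chunk_size = 2000, verbose = FALSE,
                                   scans = c("matched_null",
                                             "matched_confounded",
                                             "pooled_confounded")) {
  scans <- match.arg(scans, several.ok = TRUE)
  panel <- drawAncestralFrequencies(n_variants, n_pops, fst,
                                    seed = derive_seed(seed, 1))
  adm_ref <- drawAdmixture(n_ref, alpha_ref, seed = derive_seed(seed, 2))
  adm_tgt <- drawAdmixture(n_target, alpha_target,
                           seed = derive_seed(seed, 3))

  # leading variant block: generated once, used for the PC space and
  # reused verbatim when those variants come up in the scans
  pca_idx <- seq_len(n_pca)
  g_ref_pca <- simulateGenotypes(panel_subset(panel, pca_idx), adm_ref,
                                 seed = derive_seed(seed, 4),
                                 sample_prefix = "R")
  g_tgt_pca <- simulateGenotypes(panel_subset(panel, pca_idx), adm_tgt,
                                 seed = derive_seed(seed, 5),
                                 sample_prefix = "T")
  pruned <- ldPrune(g_ref_pca)
  pca <- referencePCA(g_ref_pca, pruned, k = n_pcs)
  proj <- projectCohort(pca$model, g_tgt_pca)
  all_scores <- rbind(scores(pca$scores), scores(proj))

  phenos <- list()
  if ("matched_null" %in% scans)
    phenos$null <- list(
      ref = simulatePhenotypes(g_ref_pca, adm_ref,
        phenotypeSpec(prevalence = prevalence), cohort = "reference",
        seed = derive_seed(seed, 6)),
      tgt = simulatePhenotypes(g_tgt_pca, adm_tgt,
        phenotypeSpec(prevalence = prevalence), cohort = "target",
        seed = derive_seed(seed, 7)))
  if (any(c("matched_confounded", "pooled_confounded") %in% scans))
    phenos$conf <- list(
      ref = simulatePhenotypes(g_ref_pca, adm_ref,
        phenotypeSpec(prevalence = prevalence,
                      ancestry_confound = confound),
        cohort = "reference", seed = derive_seed(seed, 8)),
      tgt = simulatePhenotypes(g_tgt_pca, adm_tgt,
        phenotypeSpec(prevalence = prevalence,
                      ancestry_confound = confound),
        cohort = "target", seed = derive_seed(seed, 9)))

  match_for <- function(ph) {
    sheet <- rbind(ph$ref, ph$tgt)
    res <- propensityMatch(all_scores, sheet, reference = "reference",
                           n_pcs = n_pcs, n_subclasses = n_subclasses)
    matchedSamples(res)
  }
  matched <- lapply(phenos, match_for)

  tgt_ids <- rownames(scores(proj))
  scan_defs <- list()
  if ("matched_null" %in% scans)
    scan_defs$matched_null <- list(
      ids = matched$null, y = setNames(phenos$null$tgt$status, tgt_ids),
      covars = TRUE)
  if ("matched_confounded" %in% scans)
    scan_defs$matched_confounded <- list(
      ids = matched$conf, y = setNames(phenos$conf$tgt$status, tgt_ids),
      covars = TRUE)
  if ("pooled_confounded" %in% scans)
    scan_defs$pooled_confounded <- list(
      ids = c(rownames(scores(pca$scores)), tgt_ids),
      y = setNames(c(phenos$conf$ref$status, phenos$conf$tgt$status),
                   c(rownames(scores(pca$scores)), tgt_ids)),
      covars = FALSE)

  pvals <- lapply(scan_defs, function(d) numeric(0))
  ref_ids <- rownames(scores(pca$scores))
  needed <- unique(unlist(lapply(scan_defs, `[[`, "ids")))
  need_ref <- intersect(ref_ids, needed)
  need_tgt <- intersect(tgt_ids, needed)
  starts <- unique(c(seq(1L, n_variants, by = chunk_size), n_pca + 1L))
  starts <- sort(starts[starts <= n_variants])
  for (ci in seq_along(starts)) {
    from <- starts[ci]
    to <- if (ci < length(starts)) starts[ci + 1] - 1L else n_variants
    if (from <= n_pca && to > n_pca) to <- n_pca
    # one genotype draw per chunk covering every sample any scan needs
    if (to <= n_pca) {
      gd <- cbind(dosages(g_ref_pca)[from:to, need_ref, drop = FALSE],
                  dosages(g_tgt_pca)[from:to, need_tgt, drop = FALSE])
    } else {
      pan <- panel_subset(panel, from:to)
      parts <- list()
      if (length(need_ref)) {
        parts$ref <- dosages(simulateGenotypes(
          pan, admix_subset(adm_ref, match(need_ref, ref_ids)),
          seed = derive_seed(seed, 100 + 2 * ci)))
        colnames(parts$ref) <- need_ref
      }
      if (length(need_tgt)) {
        parts$tgt <- dosages(simulateGenotypes(
          pan, admix_subset(adm_tgt, match(need_tgt, tgt_ids)),
          seed = derive_seed(seed, 101 + 2 * ci)))
        colnames(parts$tgt) <- need_tgt
      }
      gd <- do.call(cbind, parts)
    }
    for (nm in names(scan_defs)) {
      def <- scan_defs[[nm]]
      g <- GenotypeData(gd[, def$ids, drop = FALSE],
                        samples = data.frame(sample_id = def$ids))
      covars <- if (def$covars)
        all_scores[def$ids, seq_len(n_pcs), drop = FALSE] else NULL
      rec <- logisticScan(g, status = unname(def$y[def$ids]),
                          covariates = covars, on_singular = "skip")
      pvals[[nm]] <- c(pvals[[nm]], rec$p)
      rm(g); gc(FALSE)
    }
    rm(gd); gc(FALSE)
    if (verbose)
      message(sprintf("[scenario] variants %d-%d done", from, to))
  }
  out <- list(n_matched = vapply(matched, length, integer(1)),
              n_variants = n_variants)
  for (nm in names(pvals)) {
    out[[paste0("lambda_", nm)]] <- genomicLambda(pvals[[nm]])$lambda
    out[[paste0("p_", nm)]] <- pvals[[nm]]
  }
  out
}
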