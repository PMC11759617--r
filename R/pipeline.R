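#' Default pipeline configuration
#'
#' All stage parameters with their standard values (thresholds follow the
#' pipeline's QC, matching, association, meta and power defaults; the
#' simulate block describes a small demonstration study). Pass overrides
#' as nested lists to [runPipeline()], or point it at a YAML file with the
#' same structure. Unknown keys are rejected.
#'
#' @param print print the configuration to the console
#' @return the configuration list, invisibly when printed
#' @export
defaultConfig <- function(print = FALSE) {
  cfg <- list(
    seed = 1L,
    simulate = list(
      n_ref = 400, n_target = 1600, n_variants = 6000, n_pops = 3,
      fst = 0.1, alpha_ref = c(8, 3, 1), alpha_target = c(2, 4, 6),
      missing_rate = 0.02, prevalence = 0.111, confound = c(1, 0, -1),
      age_effect = 0.3, sex_effect = 0.1,
      age_bounds_ref = c(65, 90), age_bounds_target = c(45, 85),
      proxy_sensitivity = 0.9, proxy_specificity = 0.95,
      status_type_target = "proxy",
      causal = NULL),    # optional list(index = ..., beta = ...)
    qc = list(
      sample_max_miss = 0.05, het_hom_n_sd = 6, kinship_threshold = 0.0884,
      variant_max_miss = 0.10, min_carriers = 20, min_mac = 20,
      hwe_threshold = 1e-15, kinship_min_overlap = 100),
    pca = list(n_pcs = 20, maf_min = 0.01, window_kb = 100, r2_max = 0.1,
               shrinkage = "none"),
    match = list(n_pcs = 20, include_age_sex = FALSE, n_subclasses = 500,
                 weight_threshold = 1.0),
    gwas = list(firth_p = 0.01, min_mac = 20, n_covariate_pcs = 20,
                n_jaccard_pcs = 5),
    meta = list(max_amplitude = 0.4, require_df = 1, hwe_gate = 1e-15,
                r2 = 0.01, window_kb = 1000, sig = 5e-8),
    power = list(maf = c(0.001, 0.003, 0.005), target = 0.8, alpha = 5e-8))
  if (print) utils::str(cfg)
  if (print) invisible(cfg) else cfg
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    key <- if (nzchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(base))
      stop("unknown configuration key: ", key)
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], key)
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' @param config NULL (defaults), a nested list of overrides, or the path
#'   to a YAML file
#' @return the merged configuration
#' @export
loadConfig <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  merge_config(defaultConfig(), config)
}

stage_done <- function(manifest, stage, outdir) {
  st <- manifest$stages[[stage]]
  if (is.null(st)) return(FALSE)
  paths <- file.path(outdir, names(st$md5))
  all(file.exists(paths)) &&
    identical(unname(tools::md5sum(paths)), unname(unlist(st$md5)))
}

record_stage <- function(manifest, stage, outdir, files, info = list()) {
  md5 <- as.list(tools::md5sum(file.path(outdir, files)))
  names(md5) <- files
  manifest$stages[[stage]] <- c(list(md5 = md5), info)
  manifest
}

#' Run the full matching/GWAS/meta pipeline
#'
#' Executes simulate, qc, pca, match, gwas, meta and power in order,
#' writing each stage's outputs plus a JSON manifest (input hashes, seed,
#' per-stage counts) into \code{outdir}. A rerun skips every stage whose
#' recorded outputs still exist with matching checksums; corrupt or
#' missing intermediates are recomputed.
#'
#' @param config see [loadConfig()]
#' @param outdir run directory (created if needed)
#' @param quiet suppress progress messages
#' @return invisibly, the manifest (also written to manifest.json)
#' @export
runPipeline <- function(config = NULL, outdir, quiet = FALSE) {
  cfg <- loadConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(outdir, "manifest.json")
  manifest <- if (file.exists(mpath))
    jsonlite::read_json(mpath, simplifyVector = FALSE) else list()
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  cfg_hash <- digest_string(as.character(cfg_json))
  if (!identical(manifest$config_hash, cfg_hash)) {
    manifest <- list(
      config_hash = cfg_hash,
      version = as.character(utils::packageVersion("pcmatch")),
      stages = list())
  }
  if (is.null(manifest$stages)) manifest$stages <- list()
  say <- function(...) if (!quiet) message("[pcmatch] ", ...)
  seed <- cfg$seed

  ## simulate ----------------------------------------------------------
  sim_files <- c("ref.vcf", "ref.samples.tsv", "target.vcf",
                 "target.samples.tsv")
  if (!stage_done(manifest, "simulate", outdir)) {
    say("simulate: generating cohorts")
    sc <- cfg$simulate
    panel <- drawAncestralFrequencies(sc$n_variants, sc$n_pops, sc$fst,
                                      seed = derive_seed(seed, 11))
    adm_ref <- drawAdmixture(sc$n_ref, sc$alpha_ref,
                             seed = derive_seed(seed, 12))
    adm_tgt <- drawAdmixture(sc$n_target, sc$alpha_target,
                             seed = derive_seed(seed, 13))
    g_ref <- simulateGenotypes(panel, adm_ref, sc$missing_rate,
                               seed = derive_seed(seed, 14),
                               sample_prefix = "R")
    g_tgt <- simulateGenotypes(panel, adm_tgt, sc$missing_rate,
                               seed = derive_seed(seed, 15),
                               sample_prefix = "T")
    causal <- if (!is.null(sc$causal))
      data.frame(index = sc$causal$index, beta = sc$causal$beta)
    sh_ref <- simulatePhenotypes(g_ref, adm_ref,
      phenotypeSpec(prevalence = sc$prevalence, causal = causal,
                    ancestry_confound = sc$confound,
                    age_effect = sc$age_effect, sex_effect = sc$sex_effect),
      cohort = "reference", status_type = "clinical",
      age_bounds = sc$age_bounds_ref, seed = derive_seed(seed, 16))
    sh_tgt <- simulatePhenotypes(g_tgt, adm_tgt,
      phenotypeSpec(prevalence = sc$prevalence, causal = causal,
                    ancestry_confound = sc$confound,
                    age_effect = sc$age_effect, sex_effect = sc$sex_effect,
                    proxy_sensitivity = sc$proxy_sensitivity,
                    proxy_specificity = sc$proxy_specificity),
      cohort = "target", status_type = sc$status_type_target,
      age_bounds = sc$age_bounds_target, seed = derive_seed(seed, 17))
    writeCohort(setSampleInfo(g_ref, sh_ref), outdir, "ref")
    writeCohort(setSampleInfo(g_tgt, sh_tgt), outdir, "target")
    manifest <- record_stage(manifest, "simulate", outdir, sim_files,
                             list(seed = seed))
    write_manifest(manifest, mpath)
  } else say("simulate: up to date, skipping")
  g_ref <- readCohort(file.path(outdir, "ref.vcf"),
                      file.path(outdir, "ref.samples.tsv"))
  g_tgt <- readCohort(file.path(outdir, "target.vcf"),
                      file.path(outdir, "target.samples.tsv"))

  ## qc ---------------------------------------------------------------
  qc_files <- c("ref_qc.vcf", "ref_qc.samples.tsv", "target_qc.vcf",
                "target_qc.samples.tsv", "qc_removals.tsv")
  if (!stage_done(manifest, "qc", outdir)) {
    say("qc: filter cascade")
    qc <- cfg$qc
    run_qc <- function(g) qcPipeline(g,
      sample_max_miss = qc$sample_max_miss, het_hom_n_sd = qc$het_hom_n_sd,
      kinship_threshold = qc$kinship_threshold,
      variant_max_miss = qc$variant_max_miss,
      min_carriers = qc$min_carriers, min_mac = qc$min_mac,
      hwe_threshold = qc$hwe_threshold,
      kinship_min_overlap = qc$kinship_min_overlap)
    r <- run_qc(g_ref); t <- run_qc(g_tgt)
    writeCohort(r$data, outdir, "ref_qc")
    writeCohort(t$data, outdir, "target_qc")
    writeQCReport(combineQCReports(r$report, t$report),
                  file.path(outdir, "qc_removals.tsv"))
    manifest <- record_stage(manifest, "qc", outdir, qc_files,
      list(ref = unname(dim(r$data)), target = unname(dim(t$data))))
    write_manifest(manifest, mpath)
  } else say("qc: up to date, skipping")
  g_ref <- readCohort(file.path(outdir, "ref_qc.vcf"),
                      file.path(outdir, "ref_qc.samples.tsv"))
  g_tgt <- readCohort(file.path(outdir, "target_qc.vcf"),
                      file.path(outdir, "target_qc.samples.tsv"))

  ## pca --------------------------------------------------------------
  pca_files <- c("pcmodel/variants.tsv", "pcmodel/meta.json", "scores.tsv")
  if (!stage_done(manifest, "pca", outdir)) {
    say("pca: reference PCA and projection")
    pc <- cfg$pca
    cand <- pcCandidateVariants(g_ref, maf_min = pc$maf_min)
    pruned <- ldPrune(g_ref[cand, ], window_kb = pc$window_kb,
                      r2_max = pc$r2_max, maf_min = pc$maf_min)
    fit <- referencePCA(g_ref, pruned, k = pc$n_pcs)
    model <- estimateShrinkage(fit$model, g_ref, method = pc$shrinkage,
                               seed = derive_seed(seed, 21))
    proj <- projectCohort(model, g_tgt)
    writePCModel(model, file.path(outdir, "pcmodel"))
    comb <- rbind(scores(fit$scores), scores(proj))
    writeScores(new("ScoreSet", scores = comb, provenance = "projected"),
                file.path(outdir, "scores.tsv"))
    manifest <- record_stage(manifest, "pca", outdir, pca_files,
      list(n_pruned = length(pruned)))
    write_manifest(manifest, mpath)
  } else say("pca: up to date, skipping")
  sc_tab <- read.delim(file.path(outdir, "scores.tsv"),
                       colClasses = c(sample_id = "character"))
  all_scores <- as.matrix(sc_tab[, -1])
  rownames(all_scores) <- sc_tab$sample_id

  ## match ------------------------------------------------------------
  match_files <- c("weights.tsv", "matched_samples.txt", "balance.tsv")
  sheet <- rbind(sampleInfo(g_ref)[, c("sample_id", "cohort", "status",
                                       "age", "sex")],
                 sampleInfo(g_tgt)[, c("sample_id", "cohort", "status",
                                      "age", "sex")])
  if (!stage_done(manifest, "match", outdir)) {
    say("match: propensity subclassification")
    mc <- cfg$match
    res <- propensityMatch(all_scores, sheet, reference = "reference",
                           include_age_sex = mc$include_age_sex,
                           n_pcs = mc$n_pcs,
                           n_subclasses = mc$n_subclasses,
                           threshold = mc$weight_threshold)
    write.table(res@table, file.path(outdir, "weights.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(matchedSamples(res), file.path(outdir, "matched_samples.txt"))
    write.table(balanceReport(all_scores, sheet, res),
                file.path(outdir, "balance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest <- record_stage(manifest, "match", outdir, match_files,
      list(n_matched = length(matchedSamples(res))))
    write_manifest(manifest, mpath)
  } else say("match: up to date, skipping")
  matched <- readLines(file.path(outdir, "matched_samples.txt"))

  ## gwas -------------------------------------------------------------
  gwas_files <- c("gwas_ref.tsv", "gwas_target.tsv")
  if (!stage_done(manifest, "gwas", outdir)) {
    say("gwas: association scans")
    gw <- cfg$gwas
    jac <- tryCatch(scores(jaccardPCs(g_ref, k = gw$n_jaccard_pcs)),
                    error = function(e) NULL)
    cov_ref <- cbind(age = sampleInfo(g_ref)$age,
                     sex = sampleInfo(g_ref)$sex)
    if (!is.null(jac)) cov_ref <- cbind(cov_ref, jac)
    ref_res <- runGWAS(g_ref, covariates = cov_ref, firth_p = gw$firth_p,
                       min_mac = gw$min_mac, on_singular = "skip")
    g_m <- g_tgt[, matched]
    cov_tgt <- cbind(
      age = sampleInfo(g_m)$age, sex = sampleInfo(g_m)$sex,
      all_scores[matched, seq_len(min(gw$n_covariate_pcs,
                                      ncol(all_scores))), drop = FALSE])
    tgt_res <- runGWAS(g_m, covariates = cov_tgt, firth_p = gw$firth_p,
                       min_mac = gw$min_mac, on_singular = "skip")
    writeSumstats(ref_res$records, file.path(outdir, "gwas_ref.tsv"))
    writeSumstats(tgt_res$records, file.path(outdir, "gwas_target.tsv"))
    manifest <- record_stage(manifest, "gwas", outdir, gwas_files,
      list(lambda_ref = ref_res$lambda$lambda,
           lambda_target = tgt_res$lambda$lambda))
    write_manifest(manifest, mpath)
  } else say("gwas: up to date, skipping")
  ref_rec <- readSumstats(file.path(outdir, "gwas_ref.tsv"))
  tgt_rec <- readSumstats(file.path(outdir, "gwas_target.tsv"))

  ## meta -------------------------------------------------------------
  if (!stage_done(manifest, "meta", outdir)) {
    say("meta: inverse-variance meta-analysis")
    mt <- cfg$meta
    meta <- ivwMeta(list(reference = ref_rec, target = tgt_rec))
    meta_f <- metaFilters(meta, max_amplitude = mt$max_amplitude,
                          require_df = mt$require_df,
                          hwe_gate = mt$hwe_gate)
    meta_c <- clumpVariants(meta_f, g_tgt, r2_min = mt$r2,
                            window_kb = mt$window_kb,
                            p_threshold = mt$sig)
    writeMetaResults(meta_c, file.path(outdir, "meta.tsv"))
    manifest <- record_stage(manifest, "meta", outdir, "meta.tsv",
      list(n_meta = nrow(meta_f),
           n_lead = sum(meta_c$lead, na.rm = TRUE)))
    write_manifest(manifest, mpath)
  } else say("meta: up to date, skipping")

  ## power ------------------------------------------------------------
  if (!stage_done(manifest, "power", outdir)) {
    say("power: detectable-GRR table")
    pw <- cfg$power
    n_cases <- sum(sheet$status[sheet$sample_id %in%
                                  c(colnames(g_ref), matched)] == 1)
    n_total <- ncol(g_ref) + length(matched)
    tab <- powerTable(data.frame(maf = pw$maf, n_cases = n_cases,
                                 n_controls = n_total - n_cases,
                                 alpha = pw$alpha), target = pw$target)
    write.table(tab, file.path(outdir, "power.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest <- record_stage(manifest, "power", outdir, "power.tsv")
    write_manifest(manifest, mpath)
  } else say("power: up to date, skipping")
  invisible(manifest)
}

digest_string <- function(s) {
  tf <- tempfile()
  writeLines(s, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Compare the two matching schemas on one simulated dataset
#'
#' Simulates a confounded two-cohort study in which the target (biobank)
#' cohort is younger than the reference (disease) cohort, matches the
#' target twice — on projected PCs plus affection status alone, and
#' additionally on age and sex — and contrasts the matched cohorts: the
#' age imbalance (standardized mean difference vs the reference) must
#' shrink when age enters the model, while both matched PC-adjusted scans
#' of null variants stay calibrated.
#'
#' @param seed integer seed
#' @param n_ref,n_target,n_variants,n_pca scenario scale
#' @return list: per-schema matched counts, age SMDs (reference vs
#'   matched target), scan lambdas, and the schema tables
#' @export
twoScenarioDemo <- function(seed = 1, n_ref = 800, n_target = 4000,
                            n_variants = 12000, n_pca = 1500) {
  panel <- drawAncestralFrequencies(n_variants, 3, 0.1,
                                    seed = derive_seed(seed, 31))
  adm_ref <- drawAdmixture(n_ref, c(8, 3, 1), seed = derive_seed(seed, 32))
  adm_tgt <- drawAdmixture(n_target, c(2, 4, 6),
                           seed = derive_seed(seed, 33))
  g_ref <- simulateGenotypes(panel_subset(panel, seq_len(n_pca)), adm_ref,
                             seed = derive_seed(seed, 34),
                             sample_prefix = "R")
  g_tgt <- simulateGenotypes(panel_subset(panel, seq_len(n_pca)), adm_tgt,
                             seed = derive_seed(seed, 35),
                             sample_prefix = "T")
  spec <- phenotypeSpec(prevalence = 0.111, ancestry_confound = c(1, 0, -1),
                        age_effect = 0.5)
  sh_ref <- simulatePhenotypes(g_ref, adm_ref, spec, cohort = "reference",
                               age_bounds = c(65, 90),
                               seed = derive_seed(seed, 36))
  sh_tgt <- simulatePhenotypes(g_tgt, adm_tgt, spec, cohort = "target",
                               age_bounds = c(45, 85),
                               seed = derive_seed(seed, 37))
  pruned <- ldPrune(g_ref)
  fit <- referencePCA(g_ref, pruned, k = 20)
  proj <- projectCohort(fit$model, g_tgt)
  all_scores <- rbind(scores(fit$scores), scores(proj))
  sheet <- rbind(sh_ref, sh_tgt)[, c("sample_id", "cohort", "status",
                                     "age", "sex")]
  out <- list(seed = seed)
  schemas <- list(pcs_only = FALSE, pcs_age_sex = TRUE)
  for (nm in names(schemas)) {
    res <- propensityMatch(all_scores, sheet, reference = "reference",
                           include_age_sex = schemas[[nm]], n_pcs = 20,
                           n_subclasses = 500)
    matched <- matchedSamples(res)
    bal <- balanceReport(all_scores, sheet, res)
    # scan the matched target over the remaining (non-PCA) null variants
    rows <- match(matched, colnames(g_tgt))
    g_scan <- simulateGenotypes(
      panel_subset(panel, (n_pca + 1):n_variants),
      admix_subset(adm_tgt, rows),
      seed = derive_seed(seed, 40 + match(nm, names(schemas))))
    gd <- dosages(g_scan); colnames(gd) <- matched
    g_scan <- GenotypeData(gd, samples = data.frame(sample_id = matched))
    rec <- logisticScan(
      g_scan, status = sh_tgt$status[match(matched, sh_tgt$sample_id)],
      covariates = all_scores[matched, 1:20, drop = FALSE],
      on_singular = "skip")
    out[[nm]] <- list(
      n_matched = length(matched),
      age_smd = abs(bal$smd_matched[bal$covariate == "age"]),
      lambda = genomicLambda(rec$p)$lambda,
      balance = bal)
  }
  out
}
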