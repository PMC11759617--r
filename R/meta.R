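AMBIGUOUS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

is_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Combines per-study summary statistics aligned on variant id with
#' inverse squared-standard-error weights: \code{beta = sum(w b)/sum(w)},
#' \code{se = sum(w)^-1/2}, two-sided normal p-value. Effect alleles are
#' harmonized to the first study (swapped alleles flip the effect sign and
#' frequency); strand-ambiguous variants (A/T, C/G) are resolved by
#' frequency proximity when both studies have |eaf - 0.5| > 0.1 and are
#' dropped otherwise. The direction string has one of +/-/? per input
#' study, the degrees of freedom are the number of contributing studies
#' minus one, and the reported allele frequency is the sample-size
#' weighted average across studies.
#'
#' @param studies named list of scan results (see [logisticScan()]); only
#'   converged records with finite beta and se contribute
#' @return data.frame of meta records (one per variant seen in any
#'   study): chrom, pos, id, effect_allele, other_allele, beta, se, p,
#'   direction, df, n, avg_eaf, min_eaf, max_eaf, freq_amplitude. Dropped
#'   (unharmonizable) variants are recorded in the "dropped" attribute.
#' @export
ivwMeta <- function(studies) {
  stopifnot(is.list(studies), length(studies) >= 1)
  ns <- length(studies)
  if (is.null(names(studies))) names(studies) <- paste0("study", seq_len(ns))
  base <- studies[[1]][, c("id", "effect_allele", "other_allele")]
  dropped <- character()
  aligned <- vector("list", ns)
  aligned[[1]] <- studies[[1]]
  if (ns > 1) {
    for (s in 2:ns) {
      st <- studies[[s]]
      i <- match(st$id, base$id)
      flip <- rep(FALSE, nrow(st))
      bad <- rep(FALSE, nrow(st))
      known <- !is.na(i)
      ea <- base$effect_allele[i]; oa <- base$other_allele[i]
      same <- known & st$effect_allele == ea & st$other_allele == oa
      swap <- known & st$effect_allele == oa & st$other_allele == ea
      amb <- known & same & is_ambiguous(st$effect_allele, st$other_allele)
      # ambiguous: trust the frequencies when informative, else drop
      if (any(amb)) {
        b_eaf <- studies[[1]]$eaf[i]
        informative <- abs(st$eaf - 0.5) > 0.1 & abs(b_eaf - 0.5) > 0.1
        agree <- (st$eaf > 0.5) == (b_eaf > 0.5)
        flip[amb & informative & !agree] <- TRUE
        bad[amb & !informative] <- TRUE
      }
      flip[swap] <- TRUE
      bad[known & !(same | swap)] <- TRUE
      if (any(bad)) {
        dropped <- union(dropped, st$id[bad])
        st <- st[!bad, ]; flip <- flip[!bad]
      }
      st$beta[flip] <- -st$beta[flip]
      st$eaf[flip] <- 1 - st$eaf[flip]
      tmp <- st$effect_allele[flip]
      st$effect_allele[flip] <- st$other_allele[flip]
      st$other_allele[flip] <- tmp
      aligned[[s]] <- st
      extra <- st[is.na(match(st$id, base$id)),
                  c("id", "effect_allele", "other_allele")]
      base <- rbind(base, extra)
    }
  }
  base <- base[!base$id %in% dropped, ]
  ids <- base$id
  m <- length(ids)
  B <- SE <- EAF <- N <- matrix(NA_real_, m, ns)
  for (s in seq_len(ns)) {
    st <- aligned[[s]]
    ok <- !is.na(st$beta) & !is.na(st$se) & st$se > 0 &
      (is.null(st$converged) | st$converged)
    st <- st[ok, ]
    i <- match(st$id, ids)
    st <- st[!is.na(i), ]          # e.g. variants dropped as unharmonizable
    i <- i[!is.na(i)]
    B[i, s] <- st$beta; SE[i, s] <- st$se; EAF[i, s] <- st$eaf
    N[i, s] <- st$n
  }
  W <- 1 / SE^2
  sw <- rowSums(W, na.rm = TRUE)
  beta <- rowSums(W * B, na.rm = TRUE) / sw
  se <- 1 / sqrt(sw)
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  dirmat <- matrix("?", m, ns)
  dirmat[!is.na(B) & B >= 0] <- "+"
  dirmat[!is.na(B) & B < 0] <- "-"
  direction <- apply(dirmat, 1, paste, collapse = "")
  df <- rowSums(!is.na(B)) - 1L
  avg_eaf <- rowSums(EAF * N, na.rm = TRUE) / rowSums(N * !is.na(EAF),
                                                     na.rm = TRUE)
  min_eaf <- suppressWarnings(apply(EAF, 1, min, na.rm = TRUE))
  max_eaf <- suppressWarnings(apply(EAF, 1, max, na.rm = TRUE))
  meta_pos <- function(col) {
    v <- rep(NA, m)
    for (s in seq_len(ns)) {
      i2 <- match(aligned[[s]]$id, ids)
      ok <- which(!is.na(i2))
      ok <- ok[is.na(v[i2[ok]])]
      v[i2[ok]] <- aligned[[s]][[col]][ok]
    }
    v
  }
  out <- data.frame(
    chrom = as.character(meta_pos("chrom")), pos = meta_pos("pos"),
    id = ids,
    effect_allele = base$effect_allele, other_allele = base$other_allele,
    beta = beta, se = se, p = p, direction = direction, df = df,
    n = rowSums(N, na.rm = TRUE), avg_eaf = avg_eaf,
    min_eaf = min_eaf, max_eaf = max_eaf,
    freq_amplitude = max_eaf - min_eaf, stringsAsFactors = FALSE)
  out <- out[order(out$p, out$id), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Post-meta-analysis filters
#'
#' Keeps variants with frequency amplitude strictly below
#' \code{max_amplitude}, exactly \code{require_df} degrees of freedom
#' (df = 1 means detected in both studies of a two-study meta), and, when
#' per-population genotype tables are supplied, Hardy-Weinberg mid-p above
#' \code{hwe_gate} in every population.
#'
#' @param records meta records from [ivwMeta()]
#' @param max_amplitude strict upper bound on max - min effect-allele
#'   frequency across studies
#' @param require_df required degrees of freedom
#' @param hwe_gate mid-p at or below this excludes the variant
#' @param hwe_tables optional list (one element per population) of
#'   data.frames with columns id, n_AA, n_Aa, n_aa
#' @return the filtered records, original order preserved
#' @export
metaFilters <- function(records, max_amplitude = 0.4, require_df = 1,
                        hwe_gate = 1e-15, hwe_tables = NULL) {
  keep <- records$freq_amplitude < max_amplitude &
    records$df == require_df
  if (!is.null(hwe_tables)) {
    for (tab in hwe_tables) {
      i <- match(records$id, tab$id)
      have <- !is.na(i)
      midp <- rep(NA_real_, nrow(records))
      midp[have] <- hweMidp(tab$n_AA[i[have]], tab$n_Aa[i[have]],
                            tab$n_aa[i[have]])
      keep <- keep & (is.na(midp) | midp > hwe_gate)
    }
  }
  out <- records[keep, ]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping of significant variants
#'
#' Significant variants are sorted by ascending p (ties by id); the
#' lowest-p unassigned variant seeds a clump and absorbs every unassigned
#' significant variant within the window whose dosage r-squared with it
#' exceeds \code{r2_min}. Seeds are the lead variants. Variants without
#' LD genotypes form singleton clumps and are flagged.
#'
#' @param records meta (or scan) records with id, chrom, pos, p
#' @param x GenotypeData supplying dosages for LD (need not cover all
#'   records)
#' @param r2_min clumping r-squared threshold (strictly above joins)
#' @param window_kb half-window in kilobases around the lead
#' @param p_threshold significance threshold; only records with
#'   p < threshold are clumped
#' @return records with added columns \code{clump} (lead id, NA for
#'   non-significant rows), \code{lead}, and \code{ld_missing}; rows
#'   sorted by p with id tie-break
#' @export
clumpVariants <- function(records, x, r2_min = 0.01, window_kb = 1000,
                          p_threshold = 5e-8) {
  ord <- order(records$p, records$id)
  records <- records[ord, ]
  rownames(records) <- NULL
  records$clump <- NA_character_
  records$lead <- FALSE
  records$ld_missing <- FALSE
  sig <- which(!is.na(records$p) & records$p < p_threshold)
  if (!length(sig)) return(records)
  d <- dosages(x)
  storage.mode(d) <- "double"
  gid <- match(records$id, rownames(x))
  getz <- function(i) {
    g <- d[gid[i], ]
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    g - mean(g)
  }
  win <- window_kb * 1000
  assigned <- rep(FALSE, nrow(records))
  for (i in sig) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    records$clump[i] <- records$id[i]
    records$lead[i] <- TRUE
    if (is.na(gid[i])) { records$ld_missing[i] <- TRUE; next }
    zi <- getz(i)
    ssi <- sum(zi^2)
    for (j in sig) {
      if (assigned[j] || is.na(gid[j])) next
      if (records$chrom[j] != records$chrom[i] ||
          abs(records$pos[j] - records$pos[i]) > win) next
      zj <- getz(j)
      ssj <- sum(zj^2)
      if (ssi == 0 || ssj == 0) next
      r2 <- sum(zi * zj)^2 / (ssi * ssj)
      if (r2 > r2_min) {
        assigned[j] <- TRUE
        records$clump[j] <- records$id[i]
      }
    }
  }
  records
}

#' Write meta-analysis results (METAL-like columns)
#'
#' @param records meta records (optionally clumped)
#' @param path output path
#' @return invisibly, the path
#' @export
writeMetaResults <- function(records, path) {
  out <- data.frame(
    MarkerName = records$id, Allele1 = records$effect_allele,
    Allele2 = records$other_allele, Freq1 = records$avg_eaf,
    FreqAmplitude = records$freq_amplitude, Effect = records$beta,
    StdErr = records$se, `P-value` = records$p,
    Direction = records$direction, df = records$df,
    check.names = FALSE, stringsAsFactors = FALSE)
  if ("clump" %in% names(records)) {
    out$Clump <- records$clump
    out$Lead <- records$lead
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
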