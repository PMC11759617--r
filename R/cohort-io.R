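#' Write a cohort to VCF + sample sheet
#'
#' Genotypes are written as a VCF v4.2 with a single GT FORMAT field
#' (\code{0/0}, \code{0/1}, \code{1/1}, \code{./.}), 1-based positions;
#' the sample sheet goes to a tab-delimited file with a header.
#'
#' @param x a \linkS4class{GenotypeData}
#' @param dir output directory (created if needed)
#' @param prefix file name prefix; writes \code{<prefix>.vcf} and
#'   \code{<prefix>.samples.tsv}
#' @return invisibly, the two paths (named \code{vcf}, \code{sheet})
#' @export
writeCohort <- function(x, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, paste0(prefix, ".vcf"))
  sheet <- file.path(dir, paste0(prefix, ".samples.tsv"))
  vi <- variantInfo(x)
  d <- dosages(x)
  codes <- c("0/0", "0/1", "1/1")
  gt <- matrix(codes[d + 1L], nrow(d), ncol(d))
  gt[is.na(d)] <- "./."
  body <- paste(vi$chrom, vi$pos, vi$id, vi$ref, vi$alt, ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pcmatch",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(x)), collapse = "\t"))
  writeLines(c(header, body), vcf)
  write.table(sampleInfo(x), sheet, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(vcf = vcf, sheet = sheet))
}

#' Read a cohort from VCF + sample sheet
#'
#' Reads genotypes with \pkg{vcfR}, converts GT calls to additive dosages,
#' and aligns the genotype columns to the sample sheet's \code{sample_id}
#' order, so a permutation of sample columns on disk round-trips to the
#' same object.
#'
#' @param vcf path to the VCF
#' @param sheet path to the tab-delimited sample sheet (needs a
#'   \code{sample_id} column); NULL for a bare sheet of ids in VCF order
#' @return a \linkS4class{GenotypeData}
#' @export
readCohort <- function(vcf, sheet = NULL) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))               # single-variant files drop to vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  variants <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"],
    stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  d[gt %in% c("0/0", "0|0")] <- 0L
  d[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  d[gt %in% c("1/1", "1|1")] <- 2L
  bad <- !is.na(gt) & is.na(d) & gt != "./." & gt != ".|."
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("unparseable GT call '%s' at variant %s, sample %s",
                 gt[bad][1], rownames(gt)[w[1]], colnames(gt)[w[2]]))
  }
  if (is.null(sheet)) {
    samples <- data.frame(sample_id = colnames(gt), stringsAsFactors = FALSE)
  } else {
    samples <- read.delim(sheet, stringsAsFactors = FALSE,
                          colClasses = c(sample_id = "character"))
    if (!"sample_id" %in% names(samples))
      stop("sample sheet has no 'sample_id' column: ", sheet)
    missing <- setdiff(samples$sample_id, colnames(gt))
    if (length(missing))
      stop("sample sheet lists sample(s) absent from the VCF: ",
           paste(head(missing), collapse = ", "))
    d <- d[, samples$sample_id, drop = FALSE]
  }
  GenotypeData(d, variants, samples)
}
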