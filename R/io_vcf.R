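# VCF input and the in-memory genotype container.

#' Construct a genotype matrix object
#'
#' The central container of the package: an n-sample by m-variant dosage
#' matrix (0/1/2, `NA` = missing call) plus a per-variant metadata table.
#'
#' @param dosages integer/numeric matrix, samples in rows, variants in
#'   columns; entries in `{0, 1, 2, NA}`.
#' @param sample_ids character vector, one per row, unique.
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, and optionally `pop_af`, `cons_score`, `effect_class`,
#'   `mean_depth` (absent values `NA`).
#' @param dropped named integer vector of records excluded on read
#'   (e.g. `multiallelic`, `non_autosomal`).
#' @return An object of class `genotype_matrix` with elements `dosages`,
#'   `sample_ids`, `variants` (with a `key` and a `missing_rate` column
#'   appended), and `dropped`.
#' @export
genotype_matrix <- function(dosages, sample_ids, variants,
                            dropped = c(multiallelic = 0L, non_autosomal = 0L)) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(sample_ids))
    enh_data_error("dosage rows != number of samples")
  if (ncol(dosages) != nrow(variants))
    enh_data_error("dosage columns != number of variants")
  if (anyDuplicated(sample_ids))
    enh_data_error("duplicate sample ids")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) enh_data_error("dosages must be 0, 1, 2 or NA")
  variants <- as.data.frame(variants)
  for (col in c("pop_af", "cons_score", "mean_depth"))
    if (is.null(variants[[col]])) variants[[col]] <- NA_real_
  if (is.null(variants$effect_class)) variants$effect_class <- NA_character_
  if (any(variants$pos < 1)) enh_data_error("positions must be >= 1")
  ok_af <- is.na(variants$pop_af) |
    (variants$pop_af >= 0 & variants$pop_af <= 1)
  if (!all(ok_af)) enh_data_error("pop_af outside [0,1]")
  ok_cs <- is.na(variants$cons_score) |
    (variants$cons_score >= 0 & variants$cons_score <= 1)
  if (!all(ok_cs)) enh_data_error("cons_score outside [0,1]")
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  variants$missing_rate <- colMeans(is.na(dosages))
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$key
  structure(list(dosages = dosages, sample_ids = sample_ids,
                 variants = variants, dropped = dropped),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  if (sum(x$dropped) > 0)
    cat("  dropped on read:",
        paste(names(x$dropped), x$dropped, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# subset by sample and/or variant index, keeping metadata in step
subset_geno <- function(geno, samples = NULL, variants = NULL) {
  d <- geno$dosages
  ids <- geno$sample_ids
  vt <- geno$variants
  if (!is.null(samples)) {
    d <- d[samples, , drop = FALSE]
    ids <- ids[samples]
  }
  if (!is.null(variants)) {
    d <- d[, variants, drop = FALSE]
    vt <- vt[variants, , drop = FALSE]
  }
  genotype_matrix(d, ids, vt[setdiff(names(vt), c("key", "missing_rate"))],
                  dropped = geno$dropped)
}

gt_to_dosage <- function(gt) {
  # GT strings -> dosage; any allele ".", or GT ".", is a missing call
  gt <- gsub("\\|", "/", gt)
  out <- rep(NA_real_, length(gt))
  out[gt == "0/0"] <- 0
  out[gt %in% c("0/1", "1/0")] <- 1
  out[gt == "1/1"] <- 2
  out
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Retains biallelic autosomal records only; multi-allelic and non-autosomal
#' records are dropped and counted in `$dropped`.  Missing genotype calls
#' (`./.`) become `NA` dosages.  If a per-genotype `DP` field is present,
#' per-variant mean depth is recorded.
#'
#' @param path path to an uncompressed or bgzipped VCF with a `GT` FORMAT
#'   field.
#' @param region_filter optional data.frame with columns `chrom`, `start0`,
#'   `end0` (0-based half-open); only variants inside a region are kept.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, region_filter = NULL) {
  if (!file.exists(path)) enh_config_error(paste("no such VCF:", path))
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "cohort")),
    error = function(e)
      enh_data_error(paste0("malformed VCF '", path, "': ", conditionMessage(e))))
  if (ncol(vcf) == 0) enh_data_error("VCF contains no samples (empty cohort)")

  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  chrom <- as.character(GenomicRanges::seqnames(rr))

  multi <- n_alt != 1L
  nonaut <- !is_autosome(chrom)
  keep <- !multi & !nonaut
  dropped <- c(multiallelic = sum(multi),
               non_autosomal = sum(nonaut & !multi))

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) enh_data_error("VCF has no GT field")
  gt <- gt[keep, , drop = FALSE]
  pos <- BiocGenerics::start(rr)[keep]
  chrom <- chrom[keep]
  ref <- as.character(VariantAnnotation::ref(vcf))[keep]
  altc <- unlist(lapply(alt[keep], function(a) as.character(a)[1]))
  if (length(altc) == 0) altc <- character(0)

  dos <- matrix(gt_to_dosage(t(gt)), nrow = ncol(vcf),
                ncol = sum(keep))  # samples x variants
  variants <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = altc,
                         stringsAsFactors = FALSE)

  dp <- VariantAnnotation::geno(vcf)$DP
  if (!is.null(dp)) {
    dp <- dp[keep, , drop = FALSE]
    variants$mean_depth <- rowMeans(dp, na.rm = TRUE)
  }

  if (!is.null(region_filter)) {
    p0 <- pos1_to_pos0(variants$pos)
    inside <- rep(FALSE, nrow(variants))
    for (i in seq_len(nrow(region_filter))) {
      inside <- inside | (variants$chrom == region_filter$chrom[i] &
        point_in_interval(p0, region_filter$start0[i], region_filter$end0[i]))
    }
    dos <- dos[, inside, drop = FALSE]
    variants <- variants[inside, , drop = FALSE]
  }

  genotype_matrix(dos, colnames(gt), variants, dropped = dropped)
}

#' Write a genotype matrix back to VCF
#'
#' Minimal VCF 4.2 writer used by the simulator and for round-trip testing.
#'
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @param header_extra optional character vector of extra `##` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path, header_extra = character()) {
  vt <- geno$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               header_extra,
               sprintf("##contig=<ID=%s>", unique(vt$chrom)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$sample_ids), collapse = "\t")), con)
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(nrow(vt))) {
    g <- geno$dosages[, j]
    gt <- ifelse(is.na(g), "./.", code[as.character(g)])
    writeLines(paste(c(vt$chrom[j], vt$pos[j], ".", vt$ref[j], vt$alt[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
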