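# Fixture builders (all fixtures are generated in code at test time).

vcf_header <- function(samples, contigs = "1") {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", contigs),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_row <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

write_tmp <- function(lines, ext = ".vcf") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# a small fully in-memory cohort for association tests
toy_cohort <- function(n_case = 300, n_ctrl = 300, m = 10, seed = 1,
                       maf = NULL, covariates = TRUE) {
  set.seed(seed)
  n <- n_case + n_ctrl
  if (is.null(maf)) maf <- runif(m, 0.002, 0.02)
  G <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m)
  samp <- data.frame(sample_id = sprintf("s%05d", seq_len(n)),
                     status = rep(c(1L, 0L), c(n_case, n_ctrl)),
                     sex = rbinom(n, 1, 0.5))
  if (covariates) {
    pcs <- matrix(rnorm(n * 10), n, 10)
    colnames(pcs) <- paste0("pc", 1:10)
    samp <- cbind(samp, pcs)
  }
  list(G = G, samples = samp, maf = maf)
}

toy_geno <- function(dosages, chrom = "1", pos = NULL, ...) {
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq(101L, by = 10L, length.out = m)
  vt <- data.frame(chrom = chrom, pos = pos,
                   ref = rep("A", m), alt = rep("C", m), ...)
  genotype_matrix(dosages, sprintf("s%03d", seq_len(nrow(dosages))), vt)
}

toy_samples <- function(status) {
  data.frame(sample_id = sprintf("s%03d", seq_along(status)), status = status)
}

meme_minimal <- function(probs, id = "M1", bg = c(0.25, 0.25, 0.25, 0.25)) {
  c("MEME version 4", "", "ALPHABET= ACGT", "",
    "Background letter frequencies",
    paste("A", bg[1], "C", bg[2], "G", bg[3], "T", bg[4]), "",
    paste("MOTIF", id),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
            nrow(probs)),
    apply(probs, 1, paste, collapse = " "))
}

# consensus +1/-1 toy matrix wrapped as a pssm (scores used directly)
consensus_pssm <- function(consensus) {
  L <- nchar(consensus)
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  W <- matrix(-1, L, 4)
  W[cbind(seq_len(L), idx)] <- 1
  pssm("toy", W)
}
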