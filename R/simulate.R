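# Seeded synthetic-cohort generator.
#
# Emulates the statistical structure the pipeline assumes: rare-variant MAF
# spectra (truncated Beta), Hardy-Weinberg genotype sampling, enhancer
# interval structure (two intervals per gene set), conservation-score
# mixtures, sex + 10 PC covariates with mild case-control shifts, genotype
# missingness, per-variant depth, and planted set-level carrier risk ratios.
# Planted signal operates at the carrier level: case/control carrier
# frequencies implying the target risk ratio are drawn per sample, and each
# carrier receives one alternate allele at a uniformly chosen variant of the
# set, so the ground truth is directly comparable to carrier_stats output.
# Planted variants are given high conservation scores and zero population AF
# so they survive the prioritization filters (the planted effect is the
# object under test, not the filter).

#' Simulation configuration
#'
#' Defaults describe a discovery-scale cohort: 4,495 cases and 1,925
#' controls, rare-variant MAF spectrum Beta(0.3, 80) truncated to
#' (1e-4, 0.01), 40% of variants with conservation score above 0.8, 0.5%
#' genotype missingness, ~40x mean depth.
#'
#' @param seed integer seed; a single seeded stream drives the whole run.
#' @param n_case,n_ctrl cohort sizes.
#' @param n_sets number of enhancer sets.
#' @param variants_per_set variants per set.
#' @param maf_shape1,maf_shape2 Beta parameters of the true-MAF spectrum.
#' @param maf_min,maf_max truncation bounds of the spectrum.
#' @param cons_frac fraction of variants drawn conserved (score > 0.8).
#' @param planted_sets data.frame with columns `set_id`, `risk_ratio`,
#'   `case_carrier_freq` (empty for an all-null cohort).
#' @param sex_shift,pc_shift additive case-mean shifts of the sex and first
#'   three eigenvector covariates (mild confounding for the null model to
#'   absorb).
#' @param miss_rate per-genotype missing-call probability.
#' @param depth_mean,depth_sd per-variant mean-depth distribution.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_case = 4495, n_ctrl = 1925,
                       n_sets = 10, variants_per_set = 20,
                       maf_shape1 = 0.3, maf_shape2 = 80,
                       maf_min = 1e-4, maf_max = 0.01,
                       cons_frac = 0.4,
                       planted_sets = data.frame(set_id = character(),
                                                 risk_ratio = numeric(),
                                                 case_carrier_freq = numeric()),
                       sex_shift = 0.05, pc_shift = 0.1,
                       miss_rate = 0.005,
                       depth_mean = 40, depth_sd = 8) {
  rates <- c(cons_frac, miss_rate, maf_min, maf_max,
             planted_sets$case_carrier_freq)
  if (any(rates < 0 | rates > 1)) enh_config_error("rates must lie in [0,1]")
  if (any(planted_sets$risk_ratio < 1))
    enh_config_error("planted risk ratios must be >= 1")
  ctrl_freq <- planted_sets$case_carrier_freq / planted_sets$risk_ratio
  if (any(planted_sets$case_carrier_freq > 1 | ctrl_freq > 1))
    enh_config_error("infeasible planted carrier frequencies")
  structure(as.list(environment())[names(formals(sim_config))],
            class = "sim_config")
}

# truncated Beta sampler via inverse CDF
rbeta_trunc <- function(n, shape1, shape2, lo, hi) {
  u <- runif(n, pbeta(lo, shape1, shape2), pbeta(hi, shape1, shape2))
  qbeta(u, shape1, shape2)
}

random_alleles <- function(n) {
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), "")
  list(ref = ref, alt = unname(alt))
}

#' Simulate a cohort in memory
#'
#' The substrate of [simulate_cohort()] and of the calibration batteries:
#' same generative model, no files.
#'
#' @param config a [sim_config()].
#' @return list with `geno` (a [genotype_matrix()]), `samples`, `map`
#'   (interval rows), `set_of_variant` (set id per variant column) and
#'   `truth`.
#' @export
simulate_cohort_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_case + config$n_ctrl
  status <- c(rep(1L, config$n_case), rep(0L, config$n_ctrl))
  sample_ids <- sprintf("S%05d", seq_len(n))

  sex <- rbinom(n, 1, 0.5 + config$sex_shift * status)
  pcs <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))
  pcs[, 1:3] <- pcs[, 1:3] + config$pc_shift * status
  samples <- data.frame(sample_id = sample_ids, status = status, sex = sex,
                        pcs, stringsAsFactors = FALSE)

  m_per <- config$variants_per_set
  n_sets <- config$n_sets
  set_ids <- sprintf("GENE%03d", seq_len(n_sets))
  planted <- config$planted_sets
  if (nrow(planted) && !all(planted$set_id %in% set_ids))
    enh_config_error("planted set_id outside simulated sets")

  dosage_blocks <- vector("list", n_sets)
  variant_blocks <- vector("list", n_sets)
  interval_blocks <- vector("list", n_sets)
  chrom_count <- integer(22)

  for (s in seq_len(n_sets)) {
    chrom <- as.character((s - 1L) %% 22L + 1L)
    ci <- (s - 1L) %/% 22L
    base <- 100000L + ci * 100000L
    # two enhancer intervals per set, variants inside their union
    iv <- data.frame(set_id = set_ids[s], chrom = chrom,
                     start0 = c(base, base + 3000L),
                     end0 = c(base + 2000L, base + 5000L),
                     flavor = "tissue_agnostic")
    pool <- c(seq(base, base + 1999L), seq(base + 3000L, base + 4999L))
    pos0 <- sort(sample(pool, m_per))
    pl <- which(planted$set_id == set_ids[s])
    if (length(pl)) {
      f_case <- planted$case_carrier_freq[pl]
      f_ctrl <- f_case / planted$risk_ratio[pl]
      carrier <- rbinom(n, 1, ifelse(status == 1, f_case, f_ctrl))
      d <- matrix(0L, n, m_per)
      idx <- which(carrier == 1)
      if (length(idx))
        d[cbind(idx, sample(m_per, length(idx), replace = TRUE))] <- 1L
      maf <- pmax(colMeans(d) / 2, config$maf_min)
      cons <- runif(m_per, 0.85, 1)
      pop_af <- rep(0, m_per)
    } else {
      maf <- rbeta_trunc(m_per, config$maf_shape1, config$maf_shape2,
                         config$maf_min, config$maf_max)
      d <- matrix(rbinom(n * m_per, 2L, rep(maf, each = n)), n, m_per)
      conserved <- runif(m_per) < config$cons_frac
      cons <- ifelse(conserved, runif(m_per, 0.8 + 1e-6, 1),
                     runif(m_per, 0, 0.8))
      pop_af <- maf
    }
    if (config$miss_rate > 0) {
      miss <- matrix(runif(n * m_per) < config$miss_rate, n, m_per)
      d[miss] <- NA_integer_
    }
    al <- random_alleles(m_per)
    variant_blocks[[s]] <- data.frame(
      set_id = set_ids[s], chrom = chrom, pos = pos0_to_pos1(pos0),
      ref = al$ref, alt = al$alt, pop_af = pop_af, cons_score = cons,
      effect_class = NA_character_,
      mean_depth = rnorm(m_per, config$depth_mean, config$depth_sd),
      stringsAsFactors = FALSE)
    dosage_blocks[[s]] <- d
    interval_blocks[[s]] <- iv
    chrom_count[as.integer(chrom)] <- chrom_count[as.integer(chrom)] + 1L
  }

  variants <- do.call(rbind, variant_blocks)
  dosages <- do.call(cbind, dosage_blocks)
  ord <- order(as.integer(variants$chrom), variants$pos)
  variants <- variants[ord, ]
  dosages <- dosages[, ord, drop = FALSE]

  truth <- data.frame(set_id = set_ids,
                      planted = set_ids %in% planted$set_id,
                      risk_ratio = 1, case_carrier_freq = 0)
  if (nrow(planted)) {
    i <- match(planted$set_id, truth$set_id)
    truth$risk_ratio[i] <- planted$risk_ratio
    truth$case_carrier_freq[i] <- planted$case_carrier_freq
  }

  geno <- genotype_matrix(
    dosages, sample_ids,
    variants[, c("chrom", "pos", "ref", "alt", "pop_af", "cons_score",
                 "effect_class", "mean_depth")])
  list(geno = geno, samples = samples,
       map = do.call(rbind, interval_blocks),
       set_of_variant = variants$set_id, truth = truth)
}

#' Simulate a complete cohort to disk
#'
#' Writes five files into `dir`: `cohort.vcf`, `samples.tsv`,
#' `enhancers.tsv`, `annotations.tsv`, `truth.tsv`.  All outputs parse back
#' through the package readers; the same seed produces byte-identical files.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return named list of file paths (invisibly also the in-memory objects as
#'   attribute `data`).
#' @export
simulate_cohort <- function(config, dir) {
  dat <- simulate_cohort_data(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                samples = file.path(dir, "samples.tsv"),
                map = file.path(dir, "enhancers.tsv"),
                annotations = file.path(dir, "annotations.tsv"),
                truth = file.path(dir, "truth.tsv"))
  seed_line <- sprintf("##enhburden_seed=%d", config$seed)
  write_vcf(dat$geno, paths$vcf, header_extra = seed_line)

  write_tsv_seeded <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# enhburden simulate seed=", config$seed), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  samples_out <- dat$samples
  samples_out$status <- ifelse(samples_out$status == 1, "case", "control")
  for (k in paste0("pc", 1:10))
    samples_out[[k]] <- formatC(samples_out[[k]], digits = 10, format = "g")
  write_tsv_seeded(samples_out, paths$samples)
  write_tsv_seeded(dat$map, paths$map)
  vt <- dat$geno$variants
  ann <- data.frame(chrom = vt$chrom, pos1 = vt$pos, ref = vt$ref,
                    alt = vt$alt,
                    pop_af = formatC(vt$pop_af, digits = 10, format = "g"),
                    cons_score = formatC(vt$cons_score, digits = 10,
                                         format = "g"),
                    effect_class = vt$effect_class,
                    mean_depth = formatC(vt$mean_depth, digits = 10,
                                         format = "g"))
  write_tsv_seeded(ann, paths$annotations)
  write_tsv_seeded(dat$truth, paths$truth)
  structure(paths, data = dat)
}

#' Empirical type-I error of the set tests on null simulations
#'
#' Simulates one covariate-adjusted cohort containing `n_replicates`
#' independent null sets, runs SKAT-O on each, and tabulates rejection
#' fractions at the requested alpha levels with exact binomial 99%
#' confidence intervals.
#'
#' @param config a [sim_config()] with no planted sets; `n_sets` is
#'   overridden by `n_replicates`.
#' @param n_replicates number of null sets.
#' @param alpha significance levels to tabulate.
#' @param a2 weight shape used for the tests.
#' @return list with `p` (the null p-values) and `table` (data.frame
#'   `alpha`, `rejections`, `fraction`, `ci_lo`, `ci_hi`).
#' @export
null_pvalue_battery <- function(config, n_replicates,
                                alpha = c(0.05, 0.01, 0.001), a2 = 25) {
  if (nrow(config$planted_sets) > 0)
    enh_config_error("null battery requires an all-null config")
  if (n_replicates == 0)
    return(list(p = numeric(0),
                table = data.frame(alpha = numeric(), rejections = integer(),
                                   fraction = numeric(), ci_lo = numeric(),
                                   ci_hi = numeric())))
  # chunk the replicates so the dosage block stays small in memory
  n <- config$n_case + config$n_ctrl
  chunk <- max(1L, min(n_replicates,
                       floor(4e6 / (n * config$variants_per_set))))
  starts <- seq(1L, n_replicates, by = chunk)
  p <- unlist(lapply(seq_along(starts), function(ci) {
    cfg <- config
    cfg$n_sets <- min(chunk, n_replicates - starts[ci] + 1L)
    cfg$seed <- config$seed + ci - 1L
    dat <- simulate_cohort_data(cfg)
    null <- fit_null(dat$samples)
    vapply(split(seq_len(ncol(dat$geno$dosages)), dat$set_of_variant),
           function(idx) {
      G <- impute_dosages(dat$geno$dosages[, idx, drop = FALSE])
      maf <- cohort_maf(G)
      poly <- maf > 0
      if (!any(poly)) return(NA_real_)
      G <- G[, poly, drop = FALSE]
      skato_p(G, beta_weight(maf[poly], 1, a2), null)$p
    }, 0)
  }))
  p <- unname(p[!is.na(p)])
  tab <- do.call(rbind, lapply(alpha, function(a) {
    k <- sum(p < a)
    n <- length(p)
    ci <- c(qbeta(0.005, k, n - k + 1), qbeta(0.995, k + 1, n - k))
    data.frame(alpha = a, rejections = k, fraction = k / n,
               ci_lo = ci[1], ci_hi = ci[2])
  }))
  list(p = p, table = tab)
}
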