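# Orchestration: QC -> filters -> set assignment -> per-set association ->
# carrier stats -> multiple testing -> inflation.

#' Run configuration
#'
#' @param vcf,samples,map,annotations input file paths (annotations may be
#'   `NULL` if the VCF is pre-annotated).
#' @param mode `"enhancer"` (SKAT-O), `"coding"` (Firth) or `"pathway"`
#'   (SKAT-O on gene unions from `pathways`).
#' @param pathways optional data.frame `pathway_id`, `gene_id` defining
#'   pathway sets as unions of gene sets.
#' @param filter a [filter_spec()].
#' @param a1,a2 Beta weight shapes (defaults 1 and 250, the tuned value).
#' @param rho_grid SKAT-O mixing grid.
#' @param covariates covariate columns of the sample table.
#' @param qc_thresholds list overriding [qc_defaults()].
#' @param min_variants sets with fewer retained variants are still reported
#'   but flagged insufficiently variable (default 10).
#' @param seed seed recorded in output provenance.
#' @param out_dir optional output directory; when set, results / Q-Q / QC
#'   tables are written there.
#' @return list of class `run_config`.
#' @export
run_config <- function(vcf, samples, map, annotations = NULL,
                       mode = c("enhancer", "coding", "pathway"),
                       pathways = NULL,
                       filter = filter_spec(), a1 = 1, a2 = 250,
                       rho_grid = skato_config()$rho_grid,
                       covariates = c("sex", paste0("pc", 1:10)),
                       qc_thresholds = list(), min_variants = 10,
                       seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  for (p in c(vcf, samples, map, annotations))
    if (!file.exists(p)) enh_config_error(paste("input file missing:", p))
  if (mode == "pathway" && is.null(pathways))
    enh_config_error("pathway mode requires a pathways table")
  structure(list(vcf = vcf, samples = samples, map = map,
                 annotations = annotations, mode = mode, pathways = pathways,
                 filter = filter, a1 = a1, a2 = a2, rho_grid = rho_grid,
                 covariates = covariates, qc_thresholds = qc_thresholds,
                 min_variants = min_variants, seed = seed, out_dir = out_dir),
            class = "run_config")
}

load_inputs <- function(config) {
  geno <- read_vcf(config$vcf)
  samples <- read_sample_table(config$samples)
  if (!setequal(geno$sample_ids, samples$sample_id))
    enh_data_error("VCF and sample table disagree on sample ids")
  if (!is.null(config$annotations))
    geno <- attach_annotations(geno, read_annotations(config$annotations))
  sets <- read_enhancer_map(config$map)
  if (config$mode == "pathway") {
    pw <- config$pathways
    sets <- lapply(split(pw$gene_id, pw$pathway_id), function(genes) {
      union_sets(sets, genes, pathway_id = NA)
    })
    for (i in seq_along(sets)) sets[[i]]$set_id <- names(sets)[i]
  }
  list(geno = geno, samples = samples, sets = sets)
}

run_qc <- function(geno, samples, thresholds) {
  s <- qc_samples(geno, samples, thresholds)
  v <- qc_variants(s$geno, s$samples, thresholds)
  report <- qc_report(s$report$excluded_samples, v$report$excluded_variants,
                      warnings = c(s$report$warnings, v$report$warnings))
  list(geno = v$geno, samples = s$samples, report = report)
}

#' Run the burden-testing pipeline
#'
#' Applies QC, variant prioritization, set assignment and the per-set
#' association test of the configured mode (SKAT-O for enhancer/pathway
#' sets, Firth logistic regression on the carrier indicator for coding
#' sets), then carrier statistics, Bonferroni/BH adjustment and
#' genomic-inflation diagnostics.  Sets with fewer than `min_variants`
#' retained variants are reported with `insufficient_flag = TRUE`.
#'
#' @param config a [run_config()].
#' @return list with `results` (data.frame, one row per set), `qc`
#'   (a `qc_report`), `qq` (Q-Q table) and `inflation`.
#' @export
run_burden <- function(config) {
  inp <- load_inputs(config)
  qc <- run_qc(inp$geno, inp$samples, config$qc_thresholds)
  geno <- qc$geno
  samples <- qc$samples
  if (nrow(geno$dosages) == 0 || ncol(geno$dosages) == 0)
    enh_data_error("empty cohort after QC")

  flt <- if (config$mode == "coding")
    filter_coding_variants(geno$variants, config$filter)
  else filter_enhancer_variants(geno$variants, config$filter)
  keep <- which(flt$retained)
  if (length(keep) == 0) enh_data_error("no variants pass filtering")
  assignment <- assign_to_sets(geno$variants, inp$sets)
  assignment <- lapply(assignment, intersect, keep)
  if (all(lengths(assignment) == 0))
    enh_data_error("no sets with retained variants")

  null <- fit_null(samples, config$covariates)
  message(sprintf("[run_burden] %d samples (%d cases), %d variants pass QC, %d pass filters",
                  nrow(geno$dosages), sum(samples$status),
                  ncol(geno$dosages), length(keep)))

  rows <- lapply(names(assignment), function(sid) {
    idx <- assignment[[sid]]
    flavor <- inp$sets[[sid]]$flavor %||% NA_character_
    base <- data.frame(set_id = sid, flavor = flavor, n_variants = length(idx),
                       stringsAsFactors = FALSE)
    if (length(idx) == 0)
      return(cbind(base,
                   test = if (config$mode == "coding") "firth" else "skato",
                   statistic = NA_real_,
                   p = NA_real_, carriers_case = 0L, n_case = sum(samples$status),
                   carriers_ctrl = 0L, n_ctrl = sum(samples$status == 0),
                   risk_ratio = NA_real_, fallback_flag = FALSE,
                   insufficient_flag = TRUE))
    G <- impute_dosages(geno$dosages[, idx, drop = FALSE])
    cs <- carrier_stats(geno, samples, idx)
    maf <- cohort_maf(G)
    poly <- maf > 0
    fallback <- FALSE
    if (config$mode == "coding") {
      carrier <- as.integer(rowSums(geno$dosages[, idx, drop = FALSE] >= 1,
                                    na.rm = TRUE) > 0)
      test <- "firth"
      ft <- tryCatch(firth_fit(carrier, samples, config$covariates),
                     enh_data_error = function(e) NULL)
      if (is.null(ft)) {  # e.g. no carriers at all in the cohort
        stat <- NA_real_; p <- NA_real_
      } else {
        stat <- ft$beta; p <- ft$p
        fallback <- !ft$converged
      }
    } else if (!any(poly)) {
      stat <- NA_real_; p <- NA_real_; test <- "skato"
    } else {
      Gp <- G[, poly, drop = FALSE]
      w <- beta_weight(maf[poly], config$a1, config$a2)
      sk <- skato_p(Gp, w, null, skato_config(config$rho_grid))
      stat <- sk$q; p <- sk$p; test <- "skato"
      fallback <- sk$fallback
    }
    cbind(base, test = test, statistic = stat, p = p,
          carriers_case = cs$carriers_case, n_case = cs$n_case,
          carriers_ctrl = cs$carriers_ctrl, n_ctrl = cs$n_ctrl,
          risk_ratio = cs$risk_ratio, fallback_flag = fallback,
          insufficient_flag = length(idx) < config$min_variants)
  })
  results <- do.call(rbind, rows)
  tested <- !is.na(results$p)
  results <- adjust_multiple(results)
  results <- results[, intersect(RESULT_COLUMNS, names(results))]

  qq <- if (sum(tested) >= 1) qq_points(results$p[tested]) else
    data.frame(expected = numeric(), observed = numeric())
  infl <- if (sum(tested) >= 2)
    inflation(results$p[tested], sum(samples$status), sum(samples$status == 0))
  else NULL

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- provenance_lines(config)
    write_results(results, file.path(config$out_dir, "results.tsv"), prov)
    con <- file(file.path(config$out_dir, "qq.tsv"), "w")
    writeLines(paste0("# ", prov), con)
    write.table(qq, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    write_qc_report(qc$report, file.path(config$out_dir, "qc_report.tsv"), prov)
  }
  list(results = results, qc = qc$report, qq = qq, inflation = infl)
}

#' Tune the rarity-weight shape on a positive-control set
#'
#' @param config a [run_config()].
#' @param control_set_id set used as positive control (a gene whose
#'   enhancers are expected to carry association).
#' @param grid candidate `a2` values.
#' @return list with `a2` and the tuning `table`; written to
#'   `tuning.tsv` when `out_dir` is set.
#' @export
run_tune <- function(config, control_set_id, grid = c(25, 250, 2500)) {
  inp <- load_inputs(config)
  qc <- run_qc(inp$geno, inp$samples, config$qc_thresholds)
  geno <- qc$geno
  flt <- filter_enhancer_variants(geno$variants, config$filter)
  assignment <- assign_to_sets(geno$variants, inp$sets)
  if (!control_set_id %in% names(assignment))
    enh_config_error(paste("control set not in map:", control_set_id))
  idx <- intersect(assignment[[control_set_id]], which(flt$retained))
  if (length(idx) == 0)
    enh_data_error("control set empty after filtering")
  null <- fit_null(qc$samples, config$covariates)
  tuned <- tune_a2(geno$dosages[, idx, drop = FALSE], null, grid = grid,
                   a1 = config$a1, config = skato_config(config$rho_grid))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    con <- file(file.path(config$out_dir, "tuning.tsv"), "w")
    writeLines(paste0("# ", provenance_lines(config)), con)
    write.table(tuned$table, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  tuned
}

provenance_lines <- function(config) {
  hash <- tryCatch(unname(tools::md5sum(config$vcf)), error = function(e) NA)
  c(sprintf("enhburden %s", as.character(utils::packageVersion("enhburden"))),
    sprintf("seed=%d input_md5=%s mode=%s a1=%g a2=%g",
            config$seed, hash, config$mode, config$a1, config$a2))
}

write_qc_report <- function(report, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  s <- report$excluded_samples
  v <- report$excluded_variants
  df <- rbind(
    if (nrow(s)) data.frame(level = "sample", id = s$sample_id,
                            reason = s$reason, value = s$value) else NULL,
    if (nrow(v)) data.frame(level = "variant", id = v$key,
                            reason = v$reason, value = v$value) else NULL)
  if (is.null(df)) df <- data.frame(level = character(), id = character(),
                                    reason = character(), value = numeric())
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
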