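# Tabular readers/writers: enhancer-gene maps, annotations, sample tables,
# result tables.

#' Read an enhancer-gene map
#'
#' Tab-separated columns `set_id`, `chrom`, `start0`, `end0`, `flavor`
#' (0-based half-open intervals; flavor `tissue_agnostic` or `cns_hic`).
#' Intervals within a set are merged when overlapping or book-ended, and the
#' total bp of genetic material per set is computed.
#'
#' @param path path to the TSV (lines starting `#` ignored).
#' @return A named list of `enhancer_set` objects, each with `set_id`,
#'   `flavor`, `intervals` (data.frame `chrom`, `start0`, `end0`) and
#'   `total_bp`.
#' @export
read_enhancer_map <- function(path) {
  if (!file.exists(path)) enh_config_error(paste("no such map:", path))
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("set_id", "chrom", "start0", "end0")
  if (!all(need %in% names(df)))
    enh_data_error("enhancer map needs columns set_id, chrom, start0, end0")
  if (is.null(df$flavor)) df$flavor <- "tissue_agnostic"
  if (!is.numeric(df$start0) || !is.numeric(df$end0))
    enh_data_error("enhancer map coordinates must be integers")
  if (any(df$start0 >= df$end0))
    enh_data_error("enhancer map has interval with start0 >= end0")
  sets <- split(df, df$set_id)
  out <- lapply(sets, function(s) {
    merged <- merge_intervals(s[, c("chrom", "start0", "end0")])
    structure(list(set_id = s$set_id[1], flavor = s$flavor[1],
                   intervals = merged,
                   total_bp = sum(merged$end0 - merged$start0)),
              class = "enhancer_set")
  })
  out[order(names(out))]
}

#' Merge 0-based half-open intervals
#'
#' Overlapping or book-ended intervals on the same chromosome are unioned
#' (via [IRanges::reduce()]); duplicates collapse.  Idempotent and
#' order-independent.
#'
#' @param intervals data.frame with `chrom`, `start0`, `end0`.
#' @return data.frame of merged intervals sorted by chrom then start.
#' @export
merge_intervals <- function(intervals) {
  pieces <- lapply(split(intervals, intervals$chrom), function(s) {
    ir <- IRanges::reduce(intervals_to_iranges(s$start0, s$end0))
    cbind(chrom = s$chrom[1], iranges_to_intervals(ir))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start0), ]
  rownames(out) <- NULL
  out
}

#' Read a per-variant annotation table
#'
#' Tab-separated columns `chrom`, `pos1`, `ref`, `alt`, `pop_af`,
#' `cons_score`, `effect_class`; joined to variants by exact
#' `chrom:pos:ref:alt` key (no proximity matching).  Empty fields are kept as
#' `NA` ("absent"); downstream filters fail closed on absent conservation.
#'
#' @param path path to the TSV.
#' @return data.frame keyed by `key` with `pop_af`, `cons_score`,
#'   `effect_class`, `mean_depth` (if present).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) enh_config_error(paste("no such annotation:", path))
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE,
                   na.strings = c("NA", "", "."))
  need <- c("chrom", "pos1", "ref", "alt")
  if (!all(need %in% names(df)))
    enh_data_error("annotation table needs columns chrom, pos1, ref, alt")
  df$key <- variant_key(df$chrom, df$pos1, df$ref, df$alt)
  if (anyDuplicated(df$key)) {
    dup <- df[df$key %in% df$key[duplicated(df$key)], ]
    distinct <- unique(dup)
    if (anyDuplicated(distinct$key))
      enh_data_error(paste("conflicting duplicate annotation for key(s):",
                           paste(unique(distinct$key[duplicated(distinct$key)]),
                                 collapse = ", ")))
    df <- unique(df)
  }
  keep <- intersect(c("key", "pop_af", "cons_score", "effect_class",
                      "mean_depth"), names(df))
  df[, keep, drop = FALSE]
}

#' Attach annotations to a genotype matrix
#'
#' Exact-key left join; unmatched variants keep absent (`NA`) fields and are
#' counted in the returned `unmatched` attribute (recorded, not fatal).
#'
#' @param geno a [genotype_matrix()].
#' @param ann annotation data.frame from [read_annotations()].
#' @return the genotype matrix with annotation columns filled in;
#'   `attr(, "unmatched")` holds the number of variants with no annotation.
#' @export
attach_annotations <- function(geno, ann) {
  idx <- match(geno$variants$key, ann$key)
  for (col in c("pop_af", "cons_score", "effect_class", "mean_depth")) {
    if (!is.null(ann[[col]])) {
      hit <- !is.na(idx)
      geno$variants[[col]][hit] <- ann[[col]][idx[hit]]
    }
  }
  attr(geno, "unmatched") <- sum(is.na(idx))
  geno
}

#' Read the phenotype / covariate table
#'
#' Tab-separated columns `sample_id`, `status` (`case`/`control` or 1/0),
#' `sex`, and `pc1` ... `pc10`.
#'
#' @param path path to the TSV.
#' @param require_pcs if TRUE (default), all ten eigenvector columns must be
#'   present.
#' @return data.frame with `status` coded 1 = case, 0 = control.
#' @export
read_sample_table <- function(path, require_pcs = TRUE) {
  if (!file.exists(path)) enh_config_error(paste("no such table:", path))
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(df)))
    enh_data_error("sample table needs sample_id and status")
  if (anyDuplicated(df$sample_id)) enh_data_error("duplicate sample ids")
  if (is.character(df$status)) {
    if (!all(df$status %in% c("case", "control")))
      enh_data_error("status must be case/control or 1/0")
    df$status <- as.integer(df$status == "case")
  }
  if (!all(df$status %in% c(0, 1))) enh_data_error("status must be binary")
  if (require_pcs && !all(paste0("pc", 1:10) %in% names(df)))
    enh_data_error("sample table needs pc1..pc10 (10 eigenvectors)")
  df
}

RESULT_COLUMNS <- c("set_id", "flavor", "test", "n_variants", "statistic",
                    "p", "p_bonf", "q_bh", "carriers_case", "n_case",
                    "carriers_ctrl", "n_ctrl", "risk_ratio",
                    "fallback_flag", "insufficient_flag")

#' Write a burden-test result table
#'
#' Deterministic column order; numeric columns serialized with 15 significant
#' digits so a round-trip read reproduces values to at least 12 significant
#' digits.  Header `#` comment lines (provenance) may be prepended.
#'
#' @param results data.frame of per-set results.
#' @param path output path.
#' @param comments character vector of header comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, comments = character()) {
  cols <- intersect(RESULT_COLUMNS, names(results))
  extra <- setdiff(names(results), cols)
  out <- results[, c(cols, extra), drop = FALSE]
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read.delim(path, header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}
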