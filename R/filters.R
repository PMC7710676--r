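# Variant prioritization for enhancer and coding burden testing.
#
# Enhancer variants: rare (population AF < maf_max, default 0.01) AND
# evolutionarily constrained (conservation score > cons_min, default 0.8).
# Coding variants: rare AND annotated HIGH/MODERATE/LOW impact; the
# annotation classes 'synonymous' and 'TF_binding_site_variant' are always
# excluded because they leave the amino-acid sequence intact.
#
# Absent population AF passes the rarity filter (unobserved in the reference
# panel = ultra-rare, frequency 0); absent conservation score fails the
# enhancer filter (the filter demands positive evidence of constraint).
# Both thresholds are strict inequalities.

#' Filter specification
#'
#' @param maf_max population (reference-panel) allele-frequency threshold;
#'   variants are retained when AF < `maf_max` (default 0.01).
#' @param cons_min conservation-score threshold; enhancer variants are
#'   retained when score > `cons_min` (default 0.8).
#' @param coding_classes_keep effect classes retained in coding mode.
#' @param coding_classes_drop effect classes always excluded in coding mode.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(maf_max = 0.01, cons_min = 0.8,
                        coding_classes_keep = c("HIGH", "MODERATE", "LOW"),
                        coding_classes_drop = c("synonymous",
                                                "TF_binding_site_variant")) {
  if (!(maf_max > 0 && maf_max < 0.5))
    enh_config_error("maf_max must be in (0, 0.5)")
  if (!(cons_min >= 0 && cons_min <= 1))
    enh_config_error("cons_min must be in [0, 1]")
  structure(list(maf_max = maf_max, cons_min = cons_min,
                 coding_classes_keep = coding_classes_keep,
                 coding_classes_drop = coding_classes_drop),
            class = "filter_spec")
}

#' Enhancer-variant filter
#'
#' Retains variants with `pop_af < maf_max` (absent AF treated as 0: a novel
#' variant passes rarity) and `cons_score > cons_min` (absent score fails).
#'
#' @param variants variant data.frame (columns `pop_af`, `cons_score`).
#' @param spec a [filter_spec()].
#' @return list with `retained` (logical index), `drops` (named counts per
#'   first-failing rule).
#' @export
filter_enhancer_variants <- function(variants, spec = filter_spec()) {
  af <- variants$pop_af
  af[is.na(af)] <- 0
  cs <- variants$cons_score
  rare <- af < spec$maf_max
  conserved <- !is.na(cs) & cs > spec$cons_min
  retained <- rare & conserved
  drops <- c(common = sum(!rare),
             not_conserved = sum(rare & !conserved))
  list(retained = retained, drops = drops)
}

#' Coding-variant filter
#'
#' Retains variants with `pop_af < maf_max` and effect class in the keep set;
#' the named drop classes, class `other` and absent classes are excluded.
#'
#' @inheritParams filter_enhancer_variants
#' @return list with `retained` and `drops`.
#' @export
filter_coding_variants <- function(variants, spec = filter_spec()) {
  af <- variants$pop_af
  af[is.na(af)] <- 0
  ec <- variants$effect_class
  rare <- af < spec$maf_max
  keep_class <- !is.na(ec) & ec %in% spec$coding_classes_keep &
    !(ec %in% spec$coding_classes_drop)
  retained <- rare & keep_class
  drops <- c(common = sum(!rare),
             effect_class = sum(rare & !keep_class))
  list(retained = retained, drops = drops)
}

#' Assign variants to enhancer sets
#'
#' A variant belongs to a set iff its 0-based position lies inside any merged
#' interval of the set; a variant may belong to several sets (enhancer maps
#' of neighbouring genes overlap).
#'
#' @param variants variant data.frame with `chrom` and `pos` (1-based).
#' @param sets list of `enhancer_set` from [read_enhancer_map()].
#' @return named list: set_id -> integer vector of variant row indices.
#' @export
assign_to_sets <- function(variants, sets) {
  p0 <- pos1_to_pos0(variants$pos)
  out <- lapply(sets, function(s) {
    iv <- s$intervals
    hit <- rep(FALSE, nrow(variants))
    for (i in seq_len(nrow(iv))) {
      hit <- hit | (variants$chrom == iv$chrom[i] &
                      point_in_interval(p0, iv$start0[i], iv$end0[i]))
    }
    which(hit)
  })
  names(out) <- vapply(sets, `[[`, "", "set_id")
  out
}

#' Union several gene sets into one pathway set
#'
#' @param sets list of `enhancer_set` objects.
#' @param member_ids set_ids to union.
#' @param pathway_id name of the combined set.
#' @return a single `enhancer_set` whose intervals are the merged union.
#' @export
union_sets <- function(sets, member_ids, pathway_id) {
  ids <- vapply(sets, `[[`, "", "set_id")
  missing_ids <- setdiff(member_ids, ids)
  if (length(missing_ids))
    enh_config_error(paste("pathway member set(s) not in map:",
                           paste(missing_ids, collapse = ", ")))
  pieces <- lapply(sets[match(member_ids, ids)], `[[`, "intervals")
  merged <- merge_intervals(do.call(rbind, pieces))
  structure(list(set_id = pathway_id,
                 flavor = sets[[match(member_ids[1], ids)]]$flavor,
                 intervals = merged,
                 total_bp = sum(merged$end0 - merged$start0)),
            class = "enhancer_set")
}
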