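test_that("enhancer filter enforces strict rarity and conservation bounds", {
  v <- data.frame(pop_af = c(0.02, 0.005, 0.005, NA, 0.001),
                  cons_score = c(0.90, 0.81, 0.80, 0.95, NA))
  out <- filter_enhancer_variants(v)
  expect_equal(out$retained, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(out$drops["common"]), 1)
  expect_equal(unname(out$drops["not_conserved"]), 2)
  expect_equal(sum(out$drops) + sum(out$retained), nrow(v))
})

test_that("coding filter keeps impact classes and drops named exclusions", {
  v <- data.frame(pop_af = c(0.001, 0.0001, 0.05, 0.002, 0.002),
                  effect_class = c("MODERATE", "synonymous", "HIGH",
                                   "TF_binding_site_variant", NA))
  out <- filter_coding_variants(v)
  expect_equal(out$retained, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(unname(out$drops["common"]), 1)
  expect_equal(unname(out$drops["effect_class"]), 3)
})

test_that("filters are monotone in their thresholds", {
  set.seed(5)
  v <- data.frame(pop_af = c(runif(80, 0, 0.05), rep(NA, 20)),
                  cons_score = c(runif(90), rep(NA, 10)))
  loose <- filter_enhancer_variants(v, filter_spec(maf_max = 0.02,
                                                   cons_min = 0.5))
  for (mm in c(0.01, 0.005)) {
    for (cm in c(0.7, 0.9)) {
      tight <- filter_enhancer_variants(v, filter_spec(maf_max = mm,
                                                       cons_min = cm))
      expect_true(all(!tight$retained | loose$retained))
    }
  }
})

test_that("variants map to sets by 0-based position with shared membership", {
  sets <- list(
    structure(list(set_id = "CAV1", flavor = "tissue_agnostic",
                   intervals = data.frame(chrom = "7", start0 = 100,
                                          end0 = 200)),
              class = "enhancer_set"),
    structure(list(set_id = "CAV2", flavor = "tissue_agnostic",
                   intervals = data.frame(chrom = "7", start0 = 150,
                                          end0 = 400)),
              class = "enhancer_set"))
  v <- data.frame(chrom = "7", pos = c(150, 201, 180, 101))
  idx <- assign_to_sets(v, sets)
  expect_true(1 %in% idx$CAV1)           # pos1 150 -> base 149 in [100,200)
  expect_false(2 %in% idx$CAV1)          # pos1 201 -> base 200, half-open out
  expect_true(all(c(1, 3) %in% idx$CAV1) && all(c(3, 2) %in% idx$CAV2))
  expect_true(3 %in% idx$CAV1 && 3 %in% idx$CAV2)  # overlap -> both sets
})

test_that("pathway union equals the union of per-gene retained variants", {
  set.seed(9)
  sets <- lapply(1:3, function(i)
    structure(list(set_id = paste0("G", i), flavor = "tissue_agnostic",
                   intervals = data.frame(chrom = "1",
                                          start0 = 100 * i,
                                          end0 = 100 * i + 60)),
              class = "enhancer_set"))
  v <- data.frame(chrom = "1", pos = sample(90:420, 60),
                  pop_af = runif(60, 0, 0.02), cons_score = runif(60))
  flt <- filter_enhancer_variants(v)
  per_gene <- assign_to_sets(v, sets)
  pw <- union_sets(sets, c("G1", "G2", "G3"), "PW")
  pw_idx <- assign_to_sets(v, list(pw))$PW
  union_oracle <- sort(unique(unlist(per_gene)))
  expect_equal(sort(pw_idx), union_oracle)
  expect_equal(sort(intersect(pw_idx, which(flt$retained))),
               sort(unique(unlist(lapply(per_gene, intersect,
                                         which(flt$retained))))))
  expect_error(union_sets(sets, c("G1", "NOPE"), "PW"), "not in map")
})
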