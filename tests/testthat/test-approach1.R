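test_that("the platform quality filter has inclusive boundaries", {
  v <- variants_df(
    make_variant(coverage = 20L, call_quality = 25, allele_fraction = 0.30,
                 pos = 1),
    make_variant(coverage = 19L, pos = 2),
    make_variant(allele_fraction = 0.29, pos = 3),
    make_variant(call_quality = 24.9, pos = 4)
  )
  expect_identical(pass_quality(v), c(TRUE, FALSE, FALSE, FALSE))
  v_na <- make_variant(coverage = NA_integer_)
  expect_warning(ok <- pass_quality(v_na), "absent quality")
  expect_false(ok)
})

test_that("in-frame indels are non-silent only in the cascade", {
  v <- variants_df(
    make_variant(consequence = "synonymous", pos = 1),
    make_variant(consequence = "inframe_indel", pos = 2),
    make_variant(consequence = "splice_region", pos = 3),
    make_variant(consequence = "other", pos = 4)
  )
  expect_identical(is_non_silent(v, include_inframe = TRUE),
                   c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(is_non_silent(v, include_inframe = FALSE),
                   c(FALSE, FALSE, TRUE, FALSE))
})

test_that("splice-region variants need splicing evidence to count as LoF", {
  v <- variants_df(
    make_variant(consequence = "splice_canonical", spliceai = 0.99, pos = 1),
    make_variant(consequence = "splice_region", spliceai = 0.85, pos = 2),
    make_variant(consequence = "splice_region", spliceai = 0.02, pos = 3),
    make_variant(consequence = "splice_region", spliceai = NA,
                 maxentscan_effect = TRUE, pos = 4),
    make_variant(consequence = "missense", pos = 5)
  )
  expect_identical(is_predicted_lof(v), c(TRUE, TRUE, FALSE, TRUE, FALSE))
})

test_that("printed exemplar variants land in their printed categories", {
  v <- variants_df(
    # ClinVar-pathogenic stop-gain: category i despite being LoF
    make_variant(consequence = "stop_gain", clinvar = "P", cadd = 33,
                 sift = NA, polyphen = NA, revel = NA, fathmm_cancer = NA,
                 pos = 1),
    # unlisted stop-gain: category ii
    make_variant(consequence = "stop_gain", clinvar = NA, cadd = 42,
                 sift = NA, polyphen = NA, revel = NA, fathmm_cancer = NA,
                 pos = 2),
    # VUS missense deleterious by every tool: category iii
    make_variant(consequence = "missense", clinvar = "VUS", cadd = 27,
                 sift = "D", polyphen = "PrD", revel = 0.859,
                 fathmm_cancer = -9.14, pos = 3),
    # VUS missense failing FATHMM but CADD 32: category iv
    make_variant(consequence = "missense", clinvar = "VUS", cadd = 32,
                 sift = "D", polyphen = "PoD", revel = 0.414,
                 fathmm_cancer = 2.28, pos = 4),
    # weak missense: no category
    make_variant(consequence = "missense", clinvar = NA, cadd = 16,
                 revel = 0.3, pos = 5),
    # missense with no FATHMM prediction, other tools deleterious: iii
    make_variant(consequence = "missense", clinvar = "VUS", cadd = 29.2,
                 sift = "D", polyphen = "PrD", revel = 0.885,
                 fathmm_cancer = NA, pos = 6)
  )
  expect_identical(classify_variant(v),
                   c("i", "ii", "iii", "iv", NA, "iii"))
})

test_that("category assignment agrees with a straight-line oracle", {
  v <- random_variants(1000, seed = 99)
  got <- classify_variant(v)
  want <- vapply(seq_len(nrow(v)),
                 function(i) oracle_classify_one(v[i, ]), character(1))
  expect_identical(got, want)
})

test_that("tightening thresholds never prioritizes more variants", {
  v <- random_variants(800, seed = 7)
  panels <- list(list(name = "toy", category = "CPG",
                      genes = unique(v$gene)))
  base <- suppressMessages(suppressWarnings(
    run_approach1(v, panels, approach1_config())))
  for (cfg in list(approach1_config(maf_max = 0.001),
                   approach1_config(cadd_gate = 25),
                   approach1_config(high_cadd_min = 35),
                   approach1_config(revel_min = 0.9),
                   approach1_config(spliceai_lof_min = 0.95))) {
    tight <- suppressMessages(suppressWarnings(run_approach1(v, panels, cfg)))
    expect_lte(nrow(tight$prioritized), nrow(base$prioritized))
  }
})

test_that("category precedence is strict and assignment total on the fixture", {
  res <- suppressMessages(run_approach1(table1_variants(), table1_panels()))
  p <- res$prioritized
  # every eligible variant got exactly one category
  expect_false(anyNA(p$pathogenicity_category))
  # an LP/P LoF variant is category i, never ii
  lp_lof <- p$clinvar %in% c("P", "LP", "LP_P") &
    is_predicted_lof(p)
  expect_true(all(p$pathogenicity_category[lp_lof] == "i"))
  # a multi-carrier variant has one category across its carriers
  key <- paste(p$chrom, p$pos, p$ref, p$alt)
  per_key <- tapply(p$pathogenicity_category, key,
                    function(x) length(unique(x)))
  expect_true(all(per_key == 1))
})

test_that("variants outside both panels are excluded from the cascade", {
  v <- variants_df(
    make_variant(gene = "ATM", clinvar = "P", pos = 1),
    make_variant(gene = "NOT_A_PANEL_GENE", clinvar = "P", pos = 2)
  )
  panels <- list(list(name = "toy", category = "CPG", genes = "ATM"))
  expect_message(res <- run_approach1(v, panels), "no panel")
  expect_identical(res$prioritized$gene, "ATM")
  expect_equal(unname(res$funnel["in_panel"]), 1)
})

test_that("an empty variant table gives an all-zero summary", {
  res <- run_approach1(table1_variants()[0, ], table1_panels())
  expect_equal(res$summary$n_variants, 0)
  expect_equal(unname(res$summary$category_counts),
               c(0L, 0L, 0L, 0L))
})
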