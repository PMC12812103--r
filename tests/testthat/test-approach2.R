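test_that("the qualifying predicate follows its truth table", {
  rule <- qualifying_rule()
  v <- variants_df(
    make_variant(consequence = "stop_gain", maf_nfe = 0, cadd = 40,
                 pos = 1),                                     # LoF, novel
    make_variant(consequence = "inframe_indel", maf_nfe = 0, cadd = 35,
                 pos = 2),                # excluded consequence, both arms
    make_variant(consequence = "missense", cadd = 32, maf_nfe = 0.002,
                 clinvar = "VUS", pos = 3),      # not ultrarare, not LP/P
    make_variant(consequence = "missense", cadd = 12, clinvar = "P",
                 maf_nfe = 0, pos = 4),      # neither LoF nor CADD >= 30
    make_variant(consequence = "missense", cadd = 30, maf_nfe = 0,
                 pos = 5),                            # CADD arm, boundary
    make_variant(consequence = "missense", cadd = 32, maf_nfe = 0.002,
                 clinvar = "LP_P", pos = 6),            # ClinVar override
    make_variant(consequence = "splice_region", maxentscan_effect = TRUE,
                 cadd = 5, maf_nfe = 0, pos = 7),  # splice with MES effect
    make_variant(consequence = "splice_region", maxentscan_effect = FALSE,
                 spliceai = 0.9, cadd = 5, maf_nfe = 0, pos = 8)
    # SpliceAI alone is not the burden rule's splice evidence
  )
  expect_identical(is_qualifying(v, rule),
                   c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("carrier collapsing counts a family once per gene", {
  idx <- c(F1 = "F1-III.1", F2 = "F2-III.1")
  v <- variants_df(
    make_variant(gene = "BRCA2", patient_id = "F1-III.1", pos = 1),
    make_variant(gene = "BRCA2", patient_id = "F1-III.1", pos = 2),
    make_variant(gene = "BRCA2", patient_id = "F2-III.1", pos = 3),
    make_variant(gene = "BRCA2", patient_id = "F1-III.2", pos = 4)
  )
  expect_message(out <- collapse_carriers(v, idx), "non-index")
  expect_identical(sort(out$BRCA2), c("F1", "F2"))
  # controls: per individual, no index map
  ctrl <- collapse_carriers(v[1:3, ], index_map = NULL)
  expect_length(ctrl$BRCA2, 2)
})

test_that("the gene gate requires zero controls and three case families", {
  expect_identical(gene_gate(c(3L, 5L, 2L), c(0L, 1L, 0L)),
                   c(TRUE, FALSE, FALSE))
})

test_that("Fisher's exact test reproduces the printed p-values", {
  expect_equal(round(fisher_two_sided(5, 206, 0, 391), 3), 0.005)
  expect_equal(round(fisher_two_sided(4, 6, 20, 140), 3), 0.007)
  expect_equal(fisher_two_sided(0, 206, 0, 391), 1)
})

test_that("Fisher's exact test matches fisher.test and is symmetric", {
  set.seed(20)
  for (i in 1:200) {
    n1 <- sample(1:80, 1); n2 <- sample(1:80, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    ft <- stats::fisher.test(matrix(c(a, n1 - a, b, n2 - b), 2))$p.value
    expect_equal(fisher_two_sided(a, n1, b, n2), ft, tolerance = 1e-10)
    # group order does not matter
    expect_equal(fisher_two_sided(a, n1, b, n2),
                 fisher_two_sided(b, n2, a, n1), tolerance = 1e-12)
    # consistent carrier/non-carrier relabeling does not matter
    expect_equal(fisher_two_sided(a, n1, b, n2),
                 fisher_two_sided(n1 - a, n1, n2 - b, n2),
                 tolerance = 1e-12)
  }
  expect_error(fisher_two_sided(-1, 10, 0, 10), "non-negative")
  expect_error(fisher_two_sided(11, 10, 0, 10), "exceeds")
})

test_that("the two-stage FDR handles edge cases and is monotone in q", {
  expect_identical(bky_two_stage_fdr(rep(1, 10)), rep(FALSE, 10))
  expect_identical(bky_two_stage_fdr(0.001, q = 0.10), TRUE)
  expect_identical(bky_two_stage_fdr(numeric(0)), logical(0))
  # r1 = m edge: everything rejected
  expect_identical(bky_two_stage_fdr(rep(1e-6, 5)), rep(TRUE, 5))
  expect_error(bky_two_stage_fdr(c(0.5, 0)), "\\(0, 1\\]")
  set.seed(31)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    r_low <- bky_two_stage_fdr(p, q = 0.05)
    r_high <- bky_two_stage_fdr(p, q = 0.20)
    expect_true(all(r_high[r_low]))  # larger q rejects a superset
  }
})

test_that("the two-stage FDR agrees with an independent step-up oracle", {
  set.seed(77)
  for (i in 1:300) {
    m <- sample(1:50, 1)
    p <- pmin(1, pmax(1e-12, runif(m)^sample(1:4, 1)))
    q <- sample(c(0.05, 0.10, 0.25), 1)
    expect_identical(bky_two_stage_fdr(p, q), oracle_bky(p, q))
  }
})

test_that("a planted enrichment is gated, tested and rejected", {
  cfg <- sim_config(seed = 101, plants = list(
    list(gene = "BRCA2", case_carriers = 5, control_carriers = 0),
    list(gene = "GENEX", case_carriers = 2, control_carriers = 0)
  ))
  sim <- simulate_cohort(cfg)
  res <- suppressMessages(run_approach2(
    sim$case_variants, sim$control_variants,
    cohort = list(patients = sim$patients, families = sim$families),
    n_controls = 391))
  brca2 <- res$results[res$results$gene == "BRCA2", ]
  expect_true(brca2$passed_gate)
  expect_equal(brca2$case_carrier_families, 5)
  expect_equal(round(brca2$fisher_p, 3), 0.005)
  expect_true(brca2$fdr_rejected)
  # two carriers never pass the gate, whatever the p-value
  genex <- res$results[res$results$gene == "GENEX", ]
  expect_false(genex$passed_gate)
  expect_false(genex$fdr_rejected)
  # fdr_rejected implies passed_gate, everywhere
  expect_true(all(res$results$passed_gate[res$results$fdr_rejected]))
})

test_that("a null cohort with no background yields nothing", {
  cfg <- sim_config(seed = 55, background_qualifying_rate = 0,
                    background_benign_rate = 0)
  sim <- simulate_cohort(cfg)
  res <- suppressMessages(run_approach2(
    sim$case_variants, sim$control_variants,
    cohort = list(patients = sim$patients, families = sim$families),
    n_controls = 391))
  expect_equal(nrow(res$results), 0)
  expect_equal(res$summary$n_hit_genes, 0)
})

test_that("overlapping patient ids across cohorts are rejected", {
  sim <- simulate_cohort(sim_config(seed = 9))
  expect_error(
    suppressMessages(run_approach2(
      sim$case_variants, sim$case_variants,
      cohort = list(patients = sim$patients, families = sim$families))),
    "both cohorts")
})
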