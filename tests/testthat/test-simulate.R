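test_that("the default cohort reproduces the study composition", {
  sim <- simulate_cohort(sim_config(seed = 2))
  expect_equal(nrow(sim$families), 206)
  expect_equal(nrow(sim$patients), 213)
  expect_equal(as.vector(table(sim$families$family_type)[
    c("glioma_family", "brain_tumor_family", "tumor_family",
      "multiple_tumors")]), c(22, 36, 107, 41))
  expect_equal(as.vector(table(sim$patients$histology)[
    c("glioblastoma_IDHwt", "astrocytoma_IDHmut", "oligodendroglioma",
      "other_glioma")]), c(112, 33, 25, 43))
  expect_true(all(sim$patients$age_at_dx >= 18 &
                    sim$patients$age_at_dx <= 90))
  # generated metadata is well-formed and exactly one index per family
  expect_identical(validate_cohort(sim$patients, sim$families),
                   character(0))
  expect_equal(sum(sim$patients$is_index), 206)
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(seed = 17, plants = list(
    list(gene = "BRCA2", case_carriers = 4, control_carriers = 1)))
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cfg2 <- cfg; cfg2$seed <- 18L
  expect_false(identical(simulate_cohort(cfg)$case_variants,
                         simulate_cohort(cfg2)$case_variants))
})

test_that("planted carrier counts are exact and recoverable", {
  for (seed in c(1, 23, 456)) {
    cfg <- sim_config(seed = seed, plants = list(
      list(gene = "BRCA2", case_carriers = 5, control_carriers = 0),
      list(gene = "CFTR", case_carriers = 3, control_carriers = 2)))
    sim <- simulate_cohort(cfg)
    expect_equal(sim$truth$planted$case_carriers, c(5, 3))
    # parameter recovery: collapsed carrier counts equal the plant
    res <- suppressMessages(run_approach2(
      sim$case_variants, sim$control_variants,
      cohort = list(patients = sim$patients, families = sim$families),
      n_controls = 391))
    r <- res$results
    expect_equal(r$case_carrier_families[r$gene == "BRCA2"], 5)
    expect_equal(r$control_carriers[r$gene == "BRCA2"], 0)
    expect_equal(r$case_carrier_families[r$gene == "CFTR"], 3)
    expect_equal(r$control_carriers[r$gene == "CFTR"], 2)
  }
})

test_that("planted variants qualify by construction, benign ones do not", {
  cfg <- sim_config(seed = 4, plants = list(
    list(gene = "BRCA2", case_carriers = 5, control_carriers = 0)))
  sim <- simulate_cohort(cfg)
  v <- sim$case_variants
  planted <- v[v$gene == "BRCA2", ]
  expect_true(all(is_qualifying(planted)))
  expect_true(all(pass_quality(planted)))
  benign <- v[v$consequence == "synonymous", ]
  if (nrow(benign)) expect_false(any(is_qualifying(benign)))
})

test_that("generated tables survive the TSV round trip unchanged", {
  sim <- simulate_cohort(sim_config(seed = 31, plants = list(
    list(gene = "BRCA2", case_carriers = 3, control_carriers = 0))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(sim$case_variants, path)
  back <- read_variant_table(path)
  expect_equal(back, sim$case_variants)
})

test_that("infeasible plants are rejected up front", {
  expect_error(sim_config(plants = list(
    list(gene = "X", case_carriers = 300, control_carriers = 0))),
    "infeasible")
  expect_error(sim_config(plants = list(
    list(gene = "X", case_carriers = 1, control_carriers = 500))),
    "infeasible")
  expect_error(sim_config(n_case_families = 10L), "family_type_mix")
})

test_that("replicate summaries have the documented shape", {
  out <- simulate_null_pvalues(sim_config(seed = 61), n_replicates = 1)
  expect_equal(nrow(out), 1)
  expect_named(out, c("replicate", "n_gate_passed", "n_rejected",
                      "n_true_discoveries", "n_false_discoveries",
                      "fdp", "recovered"))
  expect_true(is.na(out$recovered))  # nothing planted
})
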