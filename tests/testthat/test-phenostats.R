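test_that("diagnostic yield uses set semantics per family and class", {
  families <- data.frame(
    family_id = c("F1", "F2", "F3", "F4"),
    family_type = c("glioma_family", "glioma_family", "tumor_family",
                    "multiple_tumors"),
    stringsAsFactors = FALSE
  )
  hits <- data.frame(
    family_id = c("F1", "F1", "F1", "F3"),
    gene = c("ATM", "ATM", "BRCA2", "CFTR"),
    gene_class = c("CPG", "CPG", "CPG", "novel"),
    stringsAsFactors = FALSE
  )
  y <- diagnostic_yield(hits, list(families = families))
  gf_cpg <- y[y$family_type == "glioma_family" & y$gene_class == "CPG", ]
  expect_equal(gf_cpg$families_hit, 1)        # F1 counted once
  expect_equal(gf_cpg$fraction, 0.5)
  ov_novel <- y[y$family_type == "overall" & y$gene_class == "novel", ]
  expect_equal(ov_novel$families_hit, 1)
  expect_equal(ov_novel$fraction, 0.25)

  # duplicating hit rows changes nothing
  y2 <- diagnostic_yield(rbind(hits, hits, hits), list(families = families))
  expect_equal(y2, y)

  # no hits at all -> all-zero yields
  y0 <- diagnostic_yield(hits[0, ], list(families = families))
  expect_true(all(y0$families_hit == 0))
})

test_that("per-gene family counts on the fixture match the printed ones", {
  res <- suppressMessages(run_approach1(table1_variants(), table1_panels()))
  gf <- res$summary$gene_families
  expect_equal(unname(gf["ATM"]), 6)
  expect_equal(unname(gf["BRCA2"]), 5)
  expect_equal(unname(gf["GBA1"]), 4)
  expect_equal(unname(gf[c("EGFR", "GJB2", "SDHA")]), c(3, 3, 3))
})

test_that("Mann-Whitney p-values are exact where enumeration is exact", {
  expect_equal(mann_whitney_two_sided(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(mann_whitney_two_sided(c(4, 8, 15), c(4, 8, 15)), 1)
  expect_error(mann_whitney_two_sided(numeric(0), 1:3), "non-empty")
  # exhaustive rank-enumeration oracle, all tie-free shapes with n <= 7
  set.seed(5)
  for (n in 2:7) {
    for (n1 in 1:(n - 1)) {
      x <- sample(100, n)  # distinct values, random arrangement
      a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
      expect_equal(mann_whitney_two_sided(a, b), oracle_mann_whitney(a, b),
                   tolerance = 1e-12)
    }
  }
})

test_that("Mann-Whitney p-values are near-uniform under the null", {
  set.seed(88)
  p <- replicate(300, mann_whitney_two_sided(rnorm(30), rnorm(30)))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 1e-3)
})

test_that("histology enrichment reproduces the printed comparison", {
  carriers <- rep(c("astrocytoma_IDHmut", "glioblastoma_IDHwt"), c(4, 2))
  noncarriers <- rep(c("astrocytoma_IDHmut", "glioblastoma_IDHwt"),
                     c(20, 120))
  he <- histology_enrichment(carriers, noncarriers, "astrocytoma_IDHmut")
  expect_equal(round(he$p, 3), 0.007)
  expect_equal(he$table["carrier", "astrocytoma_IDHmut"], 4L)

  # all patients one histology: nothing to detect
  same <- histology_enrichment(rep("other_glioma", 5),
                               rep("other_glioma", 50), "other_glioma")
  expect_equal(same$p, 1)

  # zero carriers: degenerate, flagged, p = 1
  none <- histology_enrichment(character(0), noncarriers,
                               "astrocytoma_IDHmut")
  expect_true(none$degenerate)
  expect_equal(none$p, 1)
})

test_that("age groups are half-open, conserving and configurable", {
  expect_identical(age_group_partition(c(36, 58, 70)),
                   c("<40" = 1L, "40-49" = 0L, "50-64" = 1L, ">65" = 1L))
  expect_identical(sum(age_group_partition(numeric(0))), 0L)
  # boundary ages all land in exactly one bin (left-closed)
  on_edge <- age_group_partition(rep(c(40, 50, 65), 4))
  expect_equal(sum(on_edge), 12)
  expect_equal(unname(on_edge["40-49"]), 4)
  expect_equal(unname(on_edge[">65"]), 4)  # 65 is right-open out of 50-64
  # missing ages are excluded but everything else is conserved
  expect_message(out <- age_group_partition(c(30, NA, 80)), "missing age")
  expect_equal(sum(out), 2)
  # custom boundaries
  expect_identical(names(age_group_partition(50, breaks = c(50, 65))),
                   c("<50", "50-64", ">65"))
})
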