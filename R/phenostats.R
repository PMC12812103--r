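#' Diagnostic yield by family type
#'
#' Fraction of families with at least one pathogenic germline variant per
#' gene class (CPG, glioma-risk, novel burden-test gene), overall and per
#' family type. Counting is set-semantic: a family counts once per gene
#' class however many hits it has, so duplicated hit rows never change the
#' yield.
#'
#' @param hits data.frame with columns `family_id`, `gene`, `gene_class`
#'   (values among `CPG`, `glioma_risk`, `novel`). Typically assembled
#'   from `run_approach1()$prioritized` (classes from `panel_category`)
#'   and `run_approach2()$hits` carriers (class `novel` for genes outside
#'   both panels).
#' @param cohort List with `families` (columns `family_id`,
#'   `family_type`).
#' @return data.frame with one row per (family_type incl. `"overall"`,
#'   gene_class): `families_total`, `families_hit`, `fraction`.
#' @export
diagnostic_yield <- function(hits, cohort) {
  check_columns(hits, c("family_id", "gene", "gene_class"), "hits")
  families <- cohort$families
  check_columns(families, c("family_id", "family_type"), "families")
  classes <- c("CPG", "glioma_risk", "novel")
  bad <- setdiff(unique(hits$gene_class), classes)
  if (length(bad)) {
    stop("unknown gene_class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  type_of <- setNames(families$family_type, families$family_id)
  groups <- c(FAMILY_TYPE_LEVELS, "overall")
  rows <- do.call(rbind, lapply(groups, function(g) {
    fams <- if (g == "overall") families$family_id else
      families$family_id[families$family_type == g]
    do.call(rbind, lapply(classes, function(cl) {
      hit_fams <- unique(hits$family_id[hits$gene_class == cl])
      n_hit <- length(intersect(fams, hit_fams))
      data.frame(family_type = g, gene_class = cl,
                 families_total = length(fams), families_hit = n_hit,
                 fraction = if (length(fams)) n_hit / length(fams) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  rows
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration when both samples have at most 20 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction. Backed by [stats::wilcox.test()].
#'
#' @param sample_a,sample_b Numeric vectors (e.g. ages at diagnosis).
#' @return Two-sided p-value.
#' @export
mann_whitney_two_sided <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (!length(sample_a) || !length(sample_b)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  use_exact <- length(sample_a) <= 20 && length(sample_b) <= 20 && !ties
  suppressWarnings(
    wilcox.test(sample_a, sample_b, alternative = "two.sided",
                exact = use_exact, correct = TRUE)$p.value
  )
}

#' Histology enrichment in gene-variant carriers
#'
#' Builds the 2x2 table carrier-status x (target histology vs rest) and
#' tests it with the two-sided Fisher's exact test. The comparison group
#' is intended to be patients without any pathogenic germline variant,
#' not mere non-carriers of the one gene.
#'
#' @param carrier_histology Character vector of histology labels for the
#'   carriers of the gene of interest.
#' @param noncarrier_histology Histology labels of the comparison group.
#' @param target Target histology label, e.g. `"astrocytoma_IDHmut"`.
#' @return List with `table` (2x2 integer matrix), `p` and `degenerate`
#'   (TRUE when either group is empty; then p = 1).
#' @export
histology_enrichment <- function(carrier_histology, noncarrier_histology,
                                 target) {
  a <- sum(carrier_histology == target)
  n1 <- length(carrier_histology)
  b <- sum(noncarrier_histology == target)
  n2 <- length(noncarrier_histology)
  tab <- matrix(as.integer(c(a, n1 - a, b, n2 - b)), nrow = 2,
                dimnames = list(c("carrier", "noncarrier"),
                                c(target, "other")))
  degenerate <- n1 == 0 || n2 == 0
  p <- if (degenerate) 1 else fisher_two_sided(a, n1, b, n2)
  list(table = tab, p = p, degenerate = degenerate)
}

#' Partition patients into age-at-diagnosis groups
#'
#' Default bins are `<40`, `40-49`, `50-65` and `>65` years, with a
#' left-closed, right-open convention at every boundary (so exactly 40
#' falls in `40-49`, and exactly 65 in the oldest bin). Boundaries are
#' configurable. Patients with missing age are excluded (with a message);
#' the returned counts sum to the number of non-missing ages.
#'
#' @param ages Numeric vector of ages at diagnosis.
#' @param breaks Increasing interior boundaries; default `c(40, 50, 65)`.
#' @return Named integer vector of bin counts.
#' @export
age_group_partition <- function(ages, breaks = c(40, 50, 65)) {
  stopifnot(length(breaks) >= 1, !is.unsorted(breaks, strictly = TRUE))
  miss <- is.na(ages)
  if (any(miss)) {
    message(sum(miss), " patient(s) with missing age excluded")
    ages <- ages[!miss]
  }
  labs <- c(paste0("<", breaks[1]),
            if (length(breaks) > 1)
              paste0(breaks[-length(breaks)], "-", breaks[-1] - 1),
            paste0(">", breaks[length(breaks)]))
  bins <- cut(ages, breaks = c(-Inf, breaks, Inf), right = FALSE,
              labels = labs)
  setNames(as.integer(table(bins)), labs)
}
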