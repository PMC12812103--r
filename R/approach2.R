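#' Qualifying-variant rule for the burden test
#'
#' A variant qualifies for the case-control collapsing test when it is
#' either strict loss-of-function (stop gain, frameshift, start loss,
#' canonical splice, or splice region with a MaxEntScan-predicted splicing
#' effect; in-frame indels never qualify) or any non-silent,
#' non-in-frame-indel variant with `cadd >= cadd_min`, AND it is ultrarare
#' (`maf_nfe < maf_ultrarare`, absent treated as 0) or ClinVar likely
#' pathogenic/pathogenic at any review level.
#'
#' @param cadd_min CADD threshold for the deleterious-missense arm (`>=`);
#'   default 30.
#' @param maf_ultrarare Ultrarare threshold on the gnomAD NFE fraction
#'   (strict `<`); default 1e-4.
#' @return List of class `qualifying_rule`.
#' @export
qualifying_rule <- function(cadd_min = 30, maf_ultrarare = 1e-4) {
  stopifnot(is.finite(cadd_min), maf_ultrarare > 0, maf_ultrarare < 1)
  structure(list(
    lof_set = c("stop_gain", "frameshift", "start_loss", "splice_canonical"),
    cadd_min = cadd_min,
    maf_ultrarare = maf_ultrarare,
    clinvar_override = CLINVAR_LP_P
  ), class = "qualifying_rule")
}

#' Does a variant qualify for the burden test?
#'
#' Pure predicate of one variant record; vectorised over rows. See
#' [qualifying_rule()] for the definition.
#'
#' @param v Variant data.frame.
#' @param rule [qualifying_rule()].
#' @return Logical vector.
#' @export
is_qualifying <- function(v, rule = qualifying_rule()) {
  stopifnot(inherits(rule, "qualifying_rule"))
  cons <- v$consequence
  lof <- !is.na(cons) & (
    cons %in% rule$lof_set |
      (cons == "splice_region" & isTRUE_vec(v$maxentscan_effect))
  )
  high_cadd <- is_non_silent(v, include_inframe = FALSE) &
    isTRUE_vec(v$cadd >= rule$cadd_min)
  maf <- ifelse(is.na(v$maf_nfe), 0, v$maf_nfe)
  rare_or_lp <- maf < rule$maf_ultrarare |
    (!is.na(v$clinvar) & v$clinvar %in% rule$clinvar_override)
  (lof | high_cadd) & rare_or_lp
}

#' Collapse qualifying variants to per-gene carrier sets
#'
#' Cases are counted at the family level: a family contributes at most
#' once per gene, through its index patient, regardless of how many
#' qualifying variants that patient carries; variants from non-index
#' patients are ignored (with a message). Controls are counted per
#' individual.
#'
#' @param variants Qualifying variant data.frame.
#' @param index_map Named vector family_id -> patient_id from
#'   [select_index_patients()]; `NULL` for a control cohort (every
#'   individual counts).
#' @return Named list gene -> character vector of carrier family ids
#'   (cases) or carrier individual ids (controls).
#' @export
collapse_carriers <- function(variants, index_map = NULL) {
  v <- variants
  if (!is.null(index_map)) {
    keep <- !is.na(v$family_id) & v$family_id %in% names(index_map) &
      v$patient_id == unname(index_map[v$family_id])
    if (any(!keep)) {
      message(sum(!keep), " variant(s) from non-index patients ignored")
    }
    v <- v[keep, , drop = FALSE]
    carriers <- split(v$family_id, v$gene)
  } else {
    carriers <- split(v$patient_id, v$gene)
  }
  lapply(carriers, unique)
}

#' Zero-control / three-case gene gate
#'
#' A gene enters multiple-testing adjustment only when it carries no
#' qualifying variants in the control cohort and qualifying variants in at
#' least three case families.
#'
#' @param case_carrier_families Integer vector of case carrier-family
#'   counts.
#' @param control_carriers Integer vector of control carrier counts.
#' @param min_cases Case-family threshold (`>=`); default 3.
#' @return Logical vector.
#' @export
gene_gate <- function(case_carrier_families, control_carriers, min_cases = 3) {
  control_carriers == 0 & case_carrier_families >= min_cases
}

#' Two-sided Fisher's exact test for a 2x2 carrier table
#'
#' Exact two-sided p for the table `(a, n_cases - a; b, n_controls - b)`
#' by the minimum-likelihood convention: the sum of hypergeometric point
#' probabilities not exceeding that of the observed table (same margins),
#' with the customary `1 + 1e-7` relative tolerance on the comparison.
#' This is the convention of [stats::fisher.test()] and the one that
#' reproduces the study's printed p-values; it is computed directly from
#' [stats::dhyper()] so that large enumerations stay cheap.
#'
#' @param a Case carriers.
#' @param n_cases Number of cases.
#' @param b Control carriers.
#' @param n_controls Number of controls.
#' @return p-value in (0, 1]. All four arguments are vectorised.
#' @export
fisher_two_sided <- function(a, n_cases, b, n_controls) {
  args <- cbind(a = a, n_cases = n_cases, b = b, n_controls = n_controls)
  if (any(args < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(a > n_cases) || any(b > n_controls)) {
    stop("carrier count exceeds group size", call. = FALSE)
  }
  vapply(seq_len(nrow(args)), function(i) {
    fisher_two_sided_1(args[i, 1], args[i, 2], args[i, 3], args[i, 4])
  }, numeric(1))
}

fisher_two_sided_1 <- function(a, n1, b, n2) {
  k <- a + b
  support <- max(0, k - n2):min(k, n1)
  d <- dhyper(support, n1, n2, k)
  obs <- d[support == a]
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

#' Benjamini-Krieger-Yekutieli two-stage FDR
#'
#' The adaptive two-stage linear step-up procedure at level `q`: stage 1
#' is a Benjamini-Hochberg step-up at `q' = q / (1 + q)` yielding `r1`
#' rejections; with `r1 = 0` nothing is rejected, with `r1 = m` everything
#' is; otherwise stage 2 is a BH step-up at `q' * m / (m - r1)` and its
#' rejection set is returned.
#'
#' @param p Vector of p-values in (0, 1].
#' @param q Target false discovery rate; default 0.10.
#' @return Logical rejection vector in the input order (empty input gives
#'   an empty output).
#' @export
bky_two_stage_fdr <- function(p, q = 0.10) {
  m <- length(p)
  if (m == 0) return(logical(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  q1 <- q / (1 + q)
  stage1 <- bh_step_up(p, q1)
  r1 <- sum(stage1)
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bh_step_up(p, q1 * m / (m - r1))
}

# linear step-up: reject the k smallest p-values where k is the largest i
# with p_(i) <= alpha * i / m
bh_step_up <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= alpha * seq_len(m) / m)
  if (!length(ok)) return(rep(FALSE, m))
  p <= ps[max(ok)]
}

#' Run the case-control gene-burden analysis
#'
#' Filters both cohorts to qualifying variants (platform quality filter
#' first), collapses cases to index-patient carrier families and controls
#' to carrier individuals, applies the zero-control/three-case gene gate,
#' computes a two-sided Fisher's exact p per gene, and adjusts the
#' gate-passed genes at a false discovery rate of `q` with the
#' Benjamini-Krieger-Yekutieli two-stage procedure. Genes are reported
#' sorted by p then symbol.
#'
#' @param case_variants Case-cohort variant data.frame.
#' @param control_variants Control-cohort variant data.frame.
#' @param cohort List with `patients` and `families`
#'   ([read_cohort_table()]), used to pick one index patient per family.
#' @param rule [qualifying_rule()].
#' @param q Target FDR; default 0.10.
#' @param n_controls Number of control individuals; default: distinct
#'   patient ids in `control_variants` cannot recover non-carriers, so
#'   this should normally be given (the study used 391).
#' @param min_cases Gene-gate case threshold; default 3.
#' @return List with:
#'   \describe{
#'     \item{results}{data.frame: `gene`, `case_carrier_families`,
#'       `control_carriers`, `n_cases`, `n_controls`, `fisher_p`,
#'       `passed_gate`, `fdr_rejected`;}
#'     \item{hits}{the gate-passed, FDR-rejected subset;}
#'     \item{summary}{list with per-hit-gene distinct qualifying variant
#'       and variant-carrier tallies (`n_distinct_variants`,
#'       `n_variant_carrier_pairs`).}
#'   }
#' @export
run_approach2 <- function(case_variants, control_variants, cohort,
                          rule = qualifying_rule(), q = 0.10,
                          n_controls = NULL, min_cases = 3) {
  overlap <- intersect(unique(case_variants$patient_id),
                       unique(control_variants$patient_id))
  if (length(overlap)) {
    stop("patient id(s) present in both cohorts: ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)
  }
  index_map <- select_index_patients(cohort$families, cohort$patients)
  n_cases <- length(index_map)
  if (is.null(n_controls)) {
    n_controls <- length(unique(control_variants$patient_id))
  }

  qual_case <- case_variants[pass_quality(case_variants) &
                               is_qualifying(case_variants, rule), ,
                             drop = FALSE]
  qual_ctrl <- control_variants[pass_quality(control_variants) &
                                  is_qualifying(control_variants, rule), ,
                                drop = FALSE]
  case_carriers <- collapse_carriers(qual_case, index_map)
  ctrl_carriers <- collapse_carriers(qual_ctrl, index_map = NULL)

  genes <- sort(union(names(case_carriers), names(ctrl_carriers)))
  a <- vapply(genes, function(g) length(case_carriers[[g]]), integer(1))
  b <- vapply(genes, function(g) length(ctrl_carriers[[g]]), integer(1))
  results <- data.frame(
    gene = genes,
    case_carrier_families = unname(a),
    control_carriers = unname(b),
    n_cases = rep(n_cases, length(genes)),
    n_controls = rep(n_controls, length(genes)),
    stringsAsFactors = FALSE
  )
  results$fisher_p <- if (length(genes)) {
    fisher_two_sided(results$case_carrier_families, n_cases,
                     results$control_carriers, n_controls)
  } else {
    numeric(0)
  }
  results$passed_gate <- gene_gate(results$case_carrier_families,
                                   results$control_carriers, min_cases)
  results$fdr_rejected <- rep(FALSE, nrow(results))
  gated <- which(results$passed_gate)
  if (length(gated)) {
    results$fdr_rejected[gated] <-
      bky_two_stage_fdr(results$fisher_p[gated], q)
  }
  results <- results[order(results$fisher_p, results$gene), , drop = FALSE]
  rownames(results) <- NULL

  hits <- results[results$fdr_rejected, , drop = FALSE]
  im <- unname(index_map[qual_case$family_id])
  hit_case <- qual_case[qual_case$gene %in% hits$gene &
                          isTRUE_vec(qual_case$patient_id == im), ,
                        drop = FALSE]
  summary <- list(
    n_hit_genes = nrow(hits),
    n_distinct_variants = length(unique(variant_key(hit_case))),
    n_variant_carrier_pairs = nrow(hit_case)
  )
  list(results = results, hits = hits, summary = summary)
}
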