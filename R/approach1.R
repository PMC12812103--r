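#' Configuration of the candidate-gene prioritization cascade
#'
#' Thresholds of the four-category cascade. The gates applied to every
#' variant before classification are rarity (`maf_nfe < maf_max`, absent
#' frequencies count as 0, i.e. novel) and deleteriousness
#' (`cadd > cadd_gate`, strict). Category iii (missense deleterious by all
#' in silico tools) additionally requires `cadd >= cadd_missense_min`,
#' `sift == "D"`, `polyphen` in `{PoD, PrD}`, `revel > revel_min` and
#' `fathmm_cancer <= fathmm_max`; a tool without an available prediction
#' does not veto (the criterion reads "deleterious by all tools used").
#' Category iv is `cadd >= high_cadd_min`. A splice-region variant counts
#' as predicted loss-of-function when `spliceai >= spliceai_lof_min` or
#' MaxEntScan predicts an effect.
#'
#' @param maf_max Rarity gate on the gnomAD NFE fraction (strict `<`);
#'   default 0.002.
#' @param cadd_gate CADD PHRED gate (strict `>`); default 15.
#' @param cadd_missense_min Category-iii CADD threshold (`>=`); default 20.
#' @param revel_min Category-iii REVEL threshold (strict `>`); default 0.5.
#' @param fathmm_max Category-iii FATHMM Cancer threshold (`<=`); default
#'   -0.75.
#' @param high_cadd_min Category-iv CADD threshold (`>=`); default 30.
#' @param spliceai_lof_min SpliceAI delta-score threshold for calling a
#'   splice-region variant LoF (`>=`); default 0.5.
#' @return List of class `approach1_config`.
#' @export
approach1_config <- function(maf_max = 0.002, cadd_gate = 15,
                             cadd_missense_min = 20, revel_min = 0.5,
                             fathmm_max = -0.75, high_cadd_min = 30,
                             spliceai_lof_min = 0.5) {
  cfg <- list(maf_max = maf_max, cadd_gate = cadd_gate,
              cadd_missense_min = cadd_missense_min, revel_min = revel_min,
              fathmm_max = fathmm_max, high_cadd_min = high_cadd_min,
              spliceai_lof_min = spliceai_lof_min)
  stopifnot(all(vapply(cfg, is.finite, logical(1))),
            maf_max > 0, maf_max < 1)
  structure(cfg, class = "approach1_config")
}

#' Platform quality filter
#'
#' A call passes when `coverage >= 20`, `call_quality >= 25` and
#' `allele_fraction >= 0.30` (all boundaries inclusive). A call with an
#' absent quality field fails, with a warning.
#'
#' @param v Variant data.frame.
#' @return Logical vector, one element per row.
#' @export
pass_quality <- function(v) {
  check_columns(v, c("coverage", "call_quality", "allele_fraction"), "variants")
  ok <- !is.na(v$coverage) & !is.na(v$call_quality) &
    !is.na(v$allele_fraction)
  if (any(!ok)) {
    warning(sum(!ok), " variant(s) with absent quality fields fail the ",
            "quality filter", call. = FALSE)
  }
  ok & isTRUE_vec(v$coverage >= 20) & isTRUE_vec(v$call_quality >= 25) &
    isTRUE_vec(v$allele_fraction >= 0.30)
}

#' Non-silent consequence filter
#'
#' Retains missense, stop gain/loss, start loss, frameshift and splice
#' variants (canonical +/- 1-2 and splice region up to 5 bases into the
#' intron). In-frame indels are non-silent only in the candidate-gene
#' cascade (`include_inframe = TRUE`); the burden test excludes them.
#'
#' @param v Variant data.frame (or a character vector of consequences).
#' @param include_inframe Count `inframe_indel` as non-silent?
#' @return Logical vector.
#' @export
is_non_silent <- function(v, include_inframe = TRUE) {
  cons <- if (is.data.frame(v)) v$consequence else v
  set <- c("missense", "stop_gain", "stop_loss", "start_loss", "frameshift",
           "splice_canonical", "splice_region")
  if (include_inframe) set <- c(set, "inframe_indel")
  !is.na(cons) & cons %in% set
}

#' Predicted loss-of-function
#'
#' Stop gain/loss, frameshift, start loss and canonical splice variants
#' are predicted LoF outright; a splice-region variant counts when there
#' is splicing evidence (`spliceai >= cfg$spliceai_lof_min` or a
#' MaxEntScan-predicted effect).
#'
#' @param v Variant data.frame.
#' @param cfg [approach1_config()].
#' @return Logical vector.
#' @export
is_predicted_lof <- function(v, cfg = approach1_config()) {
  cons <- v$consequence
  hard <- !is.na(cons) &
    cons %in% c("stop_gain", "stop_loss", "start_loss", "frameshift",
                "splice_canonical")
  splice_ev <- isTRUE_vec(v$spliceai >= cfg$spliceai_lof_min) |
    isTRUE_vec(v$maxentscan_effect)
  hard | (!is.na(cons) & cons == "splice_region" & splice_ev)
}

#' Assign the pathogenicity category
#'
#' For variants that already passed the cascade gates (quality,
#' non-silence, panel membership, rarity, CADD gate), returns the single
#' highest-precedence category each satisfies:
#'
#' * `i` - ClinVar likely pathogenic or pathogenic (`P`, `LP`, `LP_P`);
#' * `ii` - predicted loss-of-function, ClinVar conflicting or not LP/P;
#' * `iii` - missense deleterious by all in silico tools with available
#'   predictions (CADD >= 20, SIFT D, PolyPhen-2 PoD/PrD, REVEL > 0.5,
#'   FATHMM Cancer <= -0.75);
#' * `iv` - CADD >= 30 but none of the above.
#'
#' Precedence is strict (`i > ii > iii > iv`): a ClinVar-pathogenic
#' stop-gain is category `i`, never `ii`.
#'
#' @param v Variant data.frame.
#' @param cfg [approach1_config()].
#' @return Character vector in `c("i","ii","iii","iv")`, `NA` where no
#'   category applies.
#' @export
classify_variant <- function(v, cfg = approach1_config()) {
  n <- nrow(v)
  lp_p <- !is.na(v$clinvar) & v$clinvar %in% CLINVAR_LP_P
  lof <- is_predicted_lof(v, cfg)
  # a tool with no available prediction does not veto category iii
  tool_ok <- function(x, pass) is.na(x) | pass
  miss3 <- !is.na(v$consequence) & v$consequence == "missense" &
    isTRUE_vec(v$cadd >= cfg$cadd_missense_min) &
    tool_ok(v$sift, v$sift == "D") &
    tool_ok(v$polyphen, v$polyphen %in% c("PoD", "PrD")) &
    tool_ok(v$revel, v$revel > cfg$revel_min) &
    tool_ok(v$fathmm_cancer, v$fathmm_cancer <= cfg$fathmm_max)
  high <- isTRUE_vec(v$cadd >= cfg$high_cadd_min)
  out <- rep(NA_character_, n)
  out[high] <- "iv"
  out[miss3] <- "iii"
  out[lof & !lp_p] <- "ii"
  out[lp_p] <- "i"
  out
}

#' Run the candidate-gene prioritization cascade
#'
#' Applies, in order: the platform quality filter, the non-silent filter
#' (in-frame indels included), panel membership (variants in no panel are
#' dropped with a message), the rarity gate (`maf_nfe < maf_max`, absent
#' treated as 0) and the CADD gate (`> cadd_gate`), then assigns
#' pathogenicity categories with [classify_variant()]. Variants passing
#' every gate but no category stay inspectable in `$unclassified`, so the
#' full funnel from detected to pathogenic variants can be audited.
#'
#' @param variants Variant data.frame ([read_variant_table()]).
#' @param panels List of panels from [read_gene_panel()]; their gene sets
#'   must be disjoint.
#' @param cfg [approach1_config()].
#' @return List with:
#'   \describe{
#'     \item{prioritized}{data.frame of pathogenic calls with
#'       `panel_category` and `pathogenicity_category` columns;}
#'     \item{unclassified}{gate-passed variants with no category;}
#'     \item{funnel}{named integer vector of row counts after each gate;}
#'     \item{summary}{list with `n_assignments` (patient-variant rows),
#'       `n_variants` (distinct alleles), `n_patients`, `n_families`,
#'       `category_counts` (distinct alleles per category),
#'       `panel_gene_counts` (distinct genes hit per panel) and
#'       `gene_families` (distinct families per gene).}
#'   }
#' @export
run_approach1 <- function(variants, panels, cfg = approach1_config()) {
  stopifnot(inherits(cfg, "approach1_config"))
  validate_variants(variants)
  panel_of <- panel_lookup(panels)
  funnel <- c(detected = nrow(variants))

  v <- variants[pass_quality(variants), , drop = FALSE]
  funnel["quality"] <- nrow(v)
  v <- v[is_non_silent(v, include_inframe = TRUE), , drop = FALSE]
  funnel["non_silent"] <- nrow(v)

  in_panel <- v$gene %in% names(panel_of)
  if (any(!in_panel)) {
    message(sum(!in_panel), " variant(s) in no panel excluded")
  }
  v <- v[in_panel, , drop = FALSE]
  funnel["in_panel"] <- nrow(v)

  maf <- ifelse(is.na(v$maf_nfe), 0, v$maf_nfe)  # absent = novel
  v <- v[maf < cfg$maf_max, , drop = FALSE]
  funnel["rare"] <- nrow(v)
  v <- v[isTRUE_vec(v$cadd > cfg$cadd_gate), , drop = FALSE]
  funnel["cadd_gate"] <- nrow(v)

  cat_ <- classify_variant(v, cfg)
  v$panel_category <- unname(panel_of[v$gene])
  v$pathogenicity_category <- cat_
  prioritized <- v[!is.na(cat_), , drop = FALSE]
  unclassified <- v[is.na(cat_), , drop = FALSE]
  funnel["pathogenic"] <- nrow(prioritized)

  list(prioritized = prioritized, unclassified = unclassified,
       funnel = funnel, summary = approach1_summary(prioritized))
}

panel_lookup <- function(panels) {
  if (!is.list(panels) || is.null(panels$genes)) {
    # list of panels
    all_genes <- unlist(lapply(panels, `[[`, "genes"))
    if (anyDuplicated(all_genes)) {
      stop("panels are not disjoint: ", all_genes[anyDuplicated(all_genes)],
           call. = FALSE)
    }
    setNames(rep(vapply(panels, `[[`, character(1), "category"),
                 vapply(panels, function(p) length(p$genes), integer(1))),
             all_genes)
  } else {
    setNames(rep(panels$category, length(panels$genes)), panels$genes)
  }
}

approach1_summary <- function(prioritized) {
  key <- variant_key(prioritized)
  first <- !duplicated(key)
  counts <- table(factor(prioritized$pathogenicity_category[first],
                         levels = c("i", "ii", "iii", "iv")))
  gene_fam <- if (nrow(prioritized)) {
    sort(vapply(split(prioritized$family_id, prioritized$gene),
                function(f) length(unique(f)), integer(1)),
         decreasing = TRUE)
  } else {
    integer(0)
  }
  panel_genes <- if (nrow(prioritized)) {
    vapply(split(prioritized$gene, prioritized$panel_category),
           function(g) length(unique(g)), integer(1))
  } else {
    integer(0)
  }
  list(
    n_assignments = nrow(prioritized),
    n_variants = sum(first),
    n_patients = length(unique(prioritized$patient_id)),
    n_families = length(unique(prioritized$family_id)),
    category_counts = setNames(as.integer(counts), names(counts)),
    panel_gene_counts = panel_genes,
    gene_families = gene_fam
  )
}
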