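#' Immunoreactivity score (IRS) arithmetic
#'
#' The IRS of one microscope field is the product of a proportion score
#' (0: 0% positive nuclei; 1: below 10%; 2: 10-50%; 3: above 50 up to
#' 80%; 4: above 80%) and an intensity score (0 negative to 3 strong),
#' giving a 0-12 range. Staining is assessed in five non-overlapping
#' fields per section and the section's score is the arithmetic mean,
#' categorised as negative (mean below 2), weak (2 to below 4), moderate
#' (4 to below 9) or strong (9-12).
#'
#' The printed interval labels overlap at 10, 50 and 80%; the adopted
#' convention (`[10,50] -> 2`, `(50,80] -> 3`) maps every fraction to
#' exactly one score.
#'
#' @param positive_fraction Percentage of positive cells in `[0, 100]`.
#' @return `proportion_score()`: integer score 0-4 (vectorised).
#' @export
proportion_score <- function(positive_fraction) {
  x <- positive_fraction
  if (any(is.na(x)) || any(x < 0 | x > 100)) {
    stop("positive_fraction must lie in [0, 100]", call. = FALSE)
  }
  out <- integer(length(x))
  out[x > 0] <- 1L
  out[x >= 10] <- 2L
  out[x > 50] <- 3L
  out[x > 80] <- 4L
  out
}

#' @rdname proportion_score
#' @param intensity Integer staining intensity 0-3 (vectorised).
#' @return `field_irs()`: integer 0-12 per field.
#' @export
field_irs <- function(positive_fraction, intensity) {
  if (any(is.na(intensity)) || any(!(intensity %in% 0:3))) {
    stop("intensity must be an integer in 0..3", call. = FALSE)
  }
  proportion_score(positive_fraction) * as.integer(intensity)
}

#' @rdname proportion_score
#' @param fields data.frame with columns `positive_fraction` and
#'   `intensity`, one row per field (five expected; a warning is issued
#'   otherwise).
#' @return `mean_irs()`: list with `mean` (0-12) and `category` among
#'   `negative`, `weak`, `moderate`, `strong`.
#' @export
mean_irs <- function(fields) {
  check_columns(fields, c("positive_fraction", "intensity"), "fields")
  if (nrow(fields) == 0) stop("at least one field required", call. = FALSE)
  if (nrow(fields) != 5) {
    warning("expected five fields per section, got ", nrow(fields),
            call. = FALSE)
  }
  m <- mean(field_irs(fields$positive_fraction, fields$intensity))
  category <- if (m < 2) "negative" else if (m < 4) "weak" else
    if (m < 9) "moderate" else "strong"
  list(mean = m, category = category)
}

#' Panel tumor mutational burden configuration
#'
#' Quality and population filters for the TMB count: coverage at least 60
#' reads, strand-bias metric at least 0.9 (pass-if-greater; the
#' comparator's polarity is platform specific, so the direction is
#' configurable), population MAF strictly below 0.05; counts are divided
#' by the panel's exonic footprint (1.7 Mb for the 409-gene assay used in
#' the study).
#'
#' @param coverage_min Minimum coverage (`>=`); default 60.
#' @param strand_bias_min Strand-bias threshold; default 0.9.
#' @param strand_bias_pass_if `">="` (default) or `"<="`.
#' @param maf_max Population-frequency ceiling (strict `<`); default 0.05.
#' @param panel_size_mb Panel exonic footprint in Mb; default 1.7.
#' @return List of class `tmb_config`.
#' @export
tmb_config <- function(coverage_min = 60, strand_bias_min = 0.9,
                       strand_bias_pass_if = c(">=", "<="),
                       maf_max = 0.05, panel_size_mb = 1.7) {
  strand_bias_pass_if <- match.arg(strand_bias_pass_if)
  stopifnot(panel_size_mb > 0)
  structure(list(coverage_min = coverage_min,
                 strand_bias_min = strand_bias_min,
                 strand_bias_pass_if = strand_bias_pass_if,
                 maf_max = maf_max, panel_size_mb = panel_size_mb),
            class = "tmb_config")
}

#' Tumor mutational burden of a panel run
#'
#' Count of tumor calls passing the [tmb_config()] filters divided by the
#' panel footprint, in mutations per megabase.
#'
#' @param calls Tumor-call data.frame ([read_tumor_calls()]).
#' @param cfg [tmb_config()].
#' @return Mutations per megabase (numeric scalar).
#' @export
tmb <- function(calls, cfg = tmb_config()) {
  stopifnot(inherits(cfg, "tmb_config"))
  if (nrow(calls) == 0) return(0)
  sb_ok <- if (cfg$strand_bias_pass_if == ">=") {
    isTRUE_vec(calls$strand_bias >= cfg$strand_bias_min)
  } else {
    isTRUE_vec(calls$strand_bias <= cfg$strand_bias_min)
  }
  pass <- isTRUE_vec(calls$coverage >= cfg$coverage_min) & sb_ok &
    isTRUE_vec(calls$maf_population < cfg$maf_max)
  sum(pass) / cfg$panel_size_mb
}

#' Screen a tumor for somatic second hits in a germline-mutated gene
#'
#' Returns the tumor calls in the given gene with a population MAF below
#' 0.01, excluding the position of the germline variant itself, as
#' candidate second hits of two-hit inactivation.
#'
#' @param tumor_calls Tumor-call data.frame.
#' @param germline_gene HGNC symbol of the germline-mutated gene.
#' @param germline_pos Optional genomic position(s) of the germline
#'   variant to exclude.
#' @param maf_max Population-frequency ceiling (strict `<`); default 0.01.
#' @return Subset of `tumor_calls`.
#' @export
second_hit_screen <- function(tumor_calls, germline_gene,
                              germline_pos = NULL, maf_max = 0.01) {
  stopifnot(is.character(germline_gene), length(germline_gene) == 1)
  keep <- tumor_calls$gene == germline_gene &
    isTRUE_vec(tumor_calls$maf_population < maf_max)
  if (!is.null(germline_pos)) {
    keep <- keep & !(tumor_calls$pos %in% germline_pos)
  }
  tumor_calls[keep, , drop = FALSE]
}
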