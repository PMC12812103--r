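#' Configuration of the synthetic cohort generator
#'
#' Emulates the study's cohort structure so every analysis stage can be
#' exercised without patient-level sequencing data: 206 case families
#' (22 glioma families, 36 brain-tumor families, 107 tumor families, 41
#' multiple-tumor patients), 213 sequenced case patients (so seven
#' families contribute a second patient and exercise index selection),
#' 391 controls, and the published histology mix (112 IDH-wildtype
#' glioblastoma, 33 IDH-mutant astrocytoma, 25 oligodendroglioma, 43
#' other gliomas). Ages at diagnosis are drawn per histology from normal
#' models (means 62/38/45/55, sd 10/9/10/12, clipped to 18-90 years) that
#' reproduce the cohort's qualitative medians (IDH-mutant astrocytoma
#' around 38 y versus glioblastoma around 62 y); per-patient ages are not
#' published, so these are generator defaults, not study data.
#'
#' Background qualifying variants arise independently per gene per
#' individual at `background_qualifying_rate`; the predicate outcome is
#' drawn first and annotation scores are then sampled consistently with
#' it, so the rate is exact by construction. Benign background variants
#' (synonymous, common, low CADD) are added at `background_benign_rate` to
#' exercise the filters. A planted enrichment `list(gene =, case_carriers
#' =, control_carriers =)` puts exactly that many qualifying carrier
#' index-patients (cases) and individuals (controls) in the gene;
#' background generation is suppressed in planted genes so the truth
#' record is exact.
#'
#' @param seed Integer seed; every simulation is reproducible given it.
#' @param n_case_families,n_case_patients,n_controls Cohort sizes.
#' @param family_type_mix Named integer vector summing to
#'   `n_case_families`.
#' @param histology_mix Named integer vector summing to
#'   `n_case_patients`.
#' @param age_model Named list histology -> `c(mean, sd)`.
#' @param genes Gene universe (character); default 200 synthetic symbols.
#' @param background_qualifying_rate Per-gene per-individual probability
#'   of a background qualifying variant; default 2e-4.
#' @param background_benign_rate Ditto for benign variants; default 1e-3.
#' @param plants List of planted enrichments (see above).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_case_families = 206L,
                       n_case_patients = 213L,
                       family_type_mix = c(glioma_family = 22L,
                                           brain_tumor_family = 36L,
                                           tumor_family = 107L,
                                           multiple_tumors = 41L),
                       n_controls = 391L,
                       histology_mix = c(glioblastoma_IDHwt = 112L,
                                         astrocytoma_IDHmut = 33L,
                                         oligodendroglioma = 25L,
                                         other_glioma = 43L),
                       age_model = list(
                         glioblastoma_IDHwt = c(mean = 62, sd = 10),
                         astrocytoma_IDHmut = c(mean = 38, sd = 9),
                         oligodendroglioma = c(mean = 45, sd = 10),
                         other_glioma = c(mean = 55, sd = 12)),
                       genes = sprintf("GENE%03d", seq_len(200)),
                       background_qualifying_rate = 2e-4,
                       background_benign_rate = 1e-3,
                       plants = list()) {
  stopifnot(sum(family_type_mix) == n_case_families,
            identical(sort(names(family_type_mix)),
                      sort(FAMILY_TYPE_LEVELS)),
            sum(histology_mix) == n_case_patients,
            identical(sort(names(histology_mix)), sort(HISTOLOGY_LEVELS)),
            n_case_patients >= n_case_families,
            background_qualifying_rate >= 0, background_qualifying_rate <= 1,
            background_benign_rate >= 0, background_benign_rate <= 1)
  for (pl in plants) {
    stopifnot(is.character(pl$gene),
              pl$case_carriers >= 0, pl$control_carriers >= 0)
    if (pl$case_carriers > n_case_families) {
      stop("infeasible plant: ", pl$gene, " asks for more case carriers ",
           "than there are families", call. = FALSE)
    }
    if (pl$control_carriers > n_controls) {
      stop("infeasible plant: ", pl$gene, " asks for more control carriers ",
           "than there are controls", call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a case/control cohort with annotated variant tables
#'
#' See [sim_config()] for the generative model. Generated tables pass
#' [validate_cohort()] with an empty report and are accepted unchanged by
#' the readers/writers, and planted carrier counts equal the collapsed
#' carrier counts recovered by [run_approach2()] for every seed.
#'
#' @param cfg [sim_config()].
#' @return List with `patients`, `families`, `case_variants`,
#'   `control_variants` and `truth` (data.frame of planted genes and
#'   carrier ids).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  fam_ids <- sprintf("FAM%03d", seq_len(cfg$n_case_families))
  families <- data.frame(
    family_id = fam_ids,
    family_type = sample(rep(names(cfg$family_type_mix),
                             cfg$family_type_mix)),
    stringsAsFactors = FALSE
  )
  n_second <- cfg$n_case_patients - cfg$n_case_families
  second <- sample(fam_ids, n_second)
  pat_fam <- c(fam_ids, second)
  patient_id <- c(paste0(fam_ids, "-III.1"), paste0(second, "-III.2"))
  histology <- sample(rep(names(cfg$histology_mix), cfg$histology_mix))
  age <- vapply(histology, function(h) {
    m <- cfg$age_model[[h]]
    round(min(90, max(18, rnorm(1, m[["mean"]], m[["sd"]]))))
  }, numeric(1))
  patients <- data.frame(
    patient_id = patient_id, family_id = pat_fam,
    age_at_dx = unname(age), histology = histology,
    is_index = FALSE, stringsAsFactors = FALSE
  )
  # index = youngest at diagnosis per family (deterministic tie-break)
  idx <- select_index_patients(families, patients, rule = "youngest")
  patients$is_index <- patients$patient_id %in% unname(idx)
  control_ids <- sprintf("CTRL%03d", seq_len(cfg$n_controls))

  planted_genes <- vapply(cfg$plants, `[[`, character(1), "gene")
  bg_genes <- setdiff(cfg$genes, planted_genes)

  case_rows <- list(
    background_variants(patients$patient_id, patients$family_id, bg_genes,
                        cfg$background_qualifying_rate, qualifying = TRUE,
                        gene_universe = cfg$genes),
    background_variants(patients$patient_id, patients$family_id, bg_genes,
                        cfg$background_benign_rate, qualifying = FALSE,
                        gene_universe = cfg$genes)
  )
  ctrl_rows <- list(
    background_variants(control_ids, control_ids, bg_genes,
                        cfg$background_qualifying_rate, qualifying = TRUE,
                        gene_universe = cfg$genes),
    background_variants(control_ids, control_ids, bg_genes,
                        cfg$background_benign_rate, qualifying = FALSE,
                        gene_universe = cfg$genes)
  )

  truth <- data.frame(gene = character(0), case_carriers = integer(0),
                      control_carriers = integer(0),
                      stringsAsFactors = FALSE)
  truth_ids <- list()
  for (pl in cfg$plants) {
    gi <- match(pl$gene, cfg$genes)
    if (is.na(gi)) gi <- length(cfg$genes) + match(pl$gene, planted_genes)
    carrier_fams <- sample(fam_ids, pl$case_carriers)
    carrier_pats <- unname(idx[carrier_fams])
    carrier_ctrls <- sample(control_ids, pl$control_carriers)
    if (length(carrier_pats)) {
      case_rows[[length(case_rows) + 1L]] <- qualifying_template(
        carrier_pats, family_from_sim_id(carrier_pats), pl$gene, gi,
        offset = seq_along(carrier_pats) - 1L)
    }
    if (length(carrier_ctrls)) {
      ctrl_rows[[length(ctrl_rows) + 1L]] <- qualifying_template(
        carrier_ctrls, carrier_ctrls, pl$gene, gi,
        offset = 500L + seq_along(carrier_ctrls))
    }
    truth <- rbind(truth, data.frame(
      gene = pl$gene, case_carriers = pl$case_carriers,
      control_carriers = pl$control_carriers, stringsAsFactors = FALSE))
    truth_ids[[pl$gene]] <- list(case_families = carrier_fams,
                                 controls = carrier_ctrls)
  }

  case_variants <- rbind_variants(case_rows)
  control_variants <- rbind_variants(ctrl_rows)
  validate_variants(case_variants)
  validate_variants(control_variants)

  list(patients = patients, families = families,
       case_variants = case_variants, control_variants = control_variants,
       truth = list(planted = truth, carriers = truth_ids))
}

family_from_sim_id <- function(patient_id) {
  sub("-[IVX]+\\.[0-9]+$", "", patient_id)
}

# Bernoulli background draw over individuals x genes; the qualifying
# predicate outcome is fixed first, annotations follow from it.
background_variants <- function(ids, fam_ids, genes, rate, qualifying,
                                gene_universe) {
  if (!length(genes) || rate == 0 || !length(ids)) {
    return(empty_variant_table())
  }
  hit <- which(rbinom(length(ids) * length(genes), 1L, rate) == 1L)
  if (!length(hit)) return(empty_variant_table())
  i_ind <- ((hit - 1L) %% length(ids)) + 1L
  i_gene <- ((hit - 1L) %/% length(ids)) + 1L
  gene <- genes[i_gene]
  gi <- match(gene, gene_universe)
  if (qualifying) {
    v <- qualifying_template(ids[i_ind], fam_ids[i_ind], gene, gi,
                             offset = 1000L + seq_along(hit))
  } else {
    v <- benign_template(ids[i_ind], fam_ids[i_ind], gene, gi,
                         offset = 5000L + seq_along(hit))
  }
  v
}

# a stop-gain, novel, CADD-40 variant: qualifies under the burden rule and
# is category ii material under the cascade
qualifying_template <- function(patient_id, family_id, gene, gene_index,
                                offset) {
  v <- data.frame(
    patient_id = patient_id, family_id = family_id, gene = gene,
    chrom = as.character((gene_index %% 22L) + 1L),
    pos = as.integer(gene_index * 100000L + offset + 1L),
    ref = "C", alt = "T",
    hgvs_c = NA_character_, hgvs_p = NA_character_,
    consequence = "stop_gain", clinvar = NA_character_,
    maf_nfe = 0, cadd = 40,
    sift = NA_character_, polyphen = NA_character_,
    revel = NA_real_, fathmm_cancer = NA_real_, spliceai = NA_real_,
    maxentscan_effect = NA,
    coverage = 100L, call_quality = 99, allele_fraction = 0.5,
    zygosity = "het", stringsAsFactors = FALSE
  )
  v
}

# a common synonymous variant: fails non-silence, rarity and CADD filters
benign_template <- function(patient_id, family_id, gene, gene_index,
                            offset) {
  v <- qualifying_template(patient_id, family_id, gene, gene_index, offset)
  v$consequence <- "synonymous"
  v$maf_nfe <- 0.01
  v$cadd <- 5
  v
}

rbind_variants <- function(rows) {
  rows <- lapply(rows, function(r) {
    if (".row" %in% names(r)) r[, setdiff(names(r), ".row"), drop = FALSE]
    else r
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) return(empty_variant_table())
  out <- out[order(out$patient_id, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out$.row <- seq_len(nrow(out))
  out
}

#' Replicate-level FDR and power summary of the burden pipeline
#'
#' Runs [simulate_cohort()] and [run_approach2()] `n_replicates` times
#' (replicate r uses seed `cfg$seed + r`) and summarises, per replicate,
#' the number of gate-passed genes, rejections, true and false
#' discoveries, the false-discovery proportion (0 when nothing is
#' rejected) and the fraction of planted genes recovered.
#'
#' @param cfg [sim_config()].
#' @param n_replicates Number of replicates (>= 1).
#' @param q Target FDR passed to [run_approach2()]; default 0.10.
#' @return data.frame with one row per replicate.
#' @export
simulate_null_pvalues <- function(cfg = sim_config(), n_replicates = 100L,
                                  q = 0.10) {
  stopifnot(n_replicates >= 1)
  planted_genes <- vapply(cfg$plants, `[[`, character(1), "gene")
  rows <- lapply(seq_len(n_replicates), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r
    sim <- simulate_cohort(cfg_r)
    res <- suppressMessages(run_approach2(
      sim$case_variants, sim$control_variants,
      cohort = list(patients = sim$patients, families = sim$families),
      q = q, n_controls = cfg$n_controls))
    rej <- res$results$gene[res$results$fdr_rejected]
    n_true <- length(intersect(rej, planted_genes))
    n_false <- length(setdiff(rej, planted_genes))
    data.frame(
      replicate = r,
      n_gate_passed = sum(res$results$passed_gate),
      n_rejected = length(rej),
      n_true_discoveries = n_true,
      n_false_discoveries = n_false,
      fdp = if (length(rej)) n_false / length(rej) else 0,
      recovered = if (length(planted_genes))
        n_true / length(planted_genes) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
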