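# Builders and independent oracles shared across the suite.

# one-row annotated variant with sensible defaults (a rare, high-quality,
# deleterious missense); override any field
make_variant <- function(consequence = "missense", clinvar = NA_character_,
                         maf_nfe = 0, cadd = 25, sift = "D",
                         polyphen = "PrD", revel = 0.8,
                         fathmm_cancer = -2, spliceai = NA_real_,
                         maxentscan_effect = NA, coverage = 100L,
                         call_quality = 99, allele_fraction = 0.5,
                         gene = "GENE1", patient_id = "FAMX-III.1",
                         family_id = NULL, chrom = "1", pos = 1000L,
                         ref = "C", alt = "T", zygosity = "het",
                         hgvs_c = NA_character_, hgvs_p = NA_character_) {
  if (is.null(family_id)) family_id <- sub("-[IVX]+\\.[0-9]+$", "", patient_id)
  v <- data.frame(
    patient_id = patient_id, family_id = family_id, gene = gene,
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    hgvs_c = hgvs_c, hgvs_p = hgvs_p, consequence = consequence,
    clinvar = clinvar, maf_nfe = maf_nfe, cadd = cadd, sift = sift,
    polyphen = polyphen, revel = revel, fathmm_cancer = fathmm_cancer,
    spliceai = spliceai, maxentscan_effect = maxentscan_effect,
    coverage = coverage, call_quality = call_quality,
    allele_fraction = allele_fraction, zygosity = zygosity,
    stringsAsFactors = FALSE
  )
  v$.row <- seq_len(nrow(v))
  v
}

variants_df <- function(...) {
  out <- do.call(rbind, list(...))
  out$.row <- seq_len(nrow(out))
  out
}

# random annotated variants with unique keys, for property tests
random_variants <- function(n, seed) {
  set.seed(seed)
  conss <- c("missense", "stop_gain", "stop_loss", "start_loss",
             "frameshift", "inframe_indel", "splice_canonical",
             "splice_region", "synonymous", "other")
  v <- data.frame(
    patient_id = sprintf("FAM%03d-III.1", sample(200, n, replace = TRUE)),
    gene = sprintf("GENE%02d", sample(40, n, replace = TRUE)),
    chrom = as.character(sample(22, n, replace = TRUE)),
    pos = sample(1e6, n),
    ref = "C", alt = "T",
    hgvs_c = NA_character_, hgvs_p = NA_character_,
    consequence = sample(conss, n, replace = TRUE),
    clinvar = sample(c("P", "LP", "LP_P", "conflicting", "VUS",
                       NA_character_), n, replace = TRUE),
    maf_nfe = ifelse(runif(n) < 0.3, NA, runif(n) * 0.004),
    cadd = round(runif(n, 0, 45), 1),
    sift = sample(c("D", "T", NA_character_), n, replace = TRUE),
    polyphen = sample(c("B", "PoD", "PrD", NA_character_), n,
                      replace = TRUE),
    revel = ifelse(runif(n) < 0.3, NA, runif(n)),
    fathmm_cancer = ifelse(runif(n) < 0.3, NA, runif(n, -10, 5)),
    spliceai = ifelse(runif(n) < 0.5, NA, runif(n)),
    maxentscan_effect = sample(c(TRUE, FALSE, NA), n, replace = TRUE),
    coverage = sample(10:200, n, replace = TRUE),
    call_quality = round(runif(n, 10, 99)),
    allele_fraction = round(runif(n, 0.1, 1), 2),
    zygosity = sample(c("het", "hom"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  v$family_id <- sub("-[IVX]+\\.[0-9]+$", "", v$patient_id)
  v <- v[!duplicated(paste(v$patient_id, v$chrom, v$pos)), , drop = FALSE]
  rownames(v) <- NULL
  v$.row <- seq_len(nrow(v))
  v
}

table1_variants <- function() {
  read_variant_table(gliovar_extdata("table1_variants.tsv"))
}

table1_panels <- function() {
  list(
    read_gene_panel(gliovar_extdata("cpg_panel_synthetic.txt"),
                    category = "CPG"),
    read_gene_panel(gliovar_extdata("glioma_risk_panel_synthetic.txt"),
                    category = "glioma_risk")
  )
}

# ---- independent oracles --------------------------------------------------

# straight-line reimplementation of the four-category cascade predicate,
# one record at a time
oracle_classify_one <- function(v) {
  if (!is.na(v$clinvar) && v$clinvar %in% c("P", "LP", "LP_P")) return("i")
  lof <- v$consequence %in% c("stop_gain", "stop_loss", "start_loss",
                              "frameshift", "splice_canonical")
  if (!lof && v$consequence == "splice_region") {
    if (!is.na(v$spliceai) && v$spliceai >= 0.5) lof <- TRUE
    if (!is.na(v$maxentscan_effect) && v$maxentscan_effect) lof <- TRUE
  }
  if (lof) return("ii")
  if (v$consequence == "missense" && !is.na(v$cadd) && v$cadd >= 20) {
    ok <- TRUE
    if (!is.na(v$sift) && v$sift != "D") ok <- FALSE
    if (!is.na(v$polyphen) && !(v$polyphen %in% c("PoD", "PrD"))) ok <- FALSE
    if (!is.na(v$revel) && v$revel <= 0.5) ok <- FALSE
    if (!is.na(v$fathmm_cancer) && v$fathmm_cancer > -0.75) ok <- FALSE
    if (ok) return("iii")
  }
  if (!is.na(v$cadd) && v$cadd >= 30) return("iv")
  NA_character_
}

# exhaustive same-margin enumeration of the two-sided Fisher p via
# log-binomial coefficients (vectorised over a and b for fixed margins)
oracle_fisher <- function(a, n1, b, n2) {
  mapply(function(ai, bi) {
    k <- ai + bi
    x <- max(0, k - n2):min(k, n1)
    logp <- lchoose(n1, x) + lchoose(n2, k - x) - lchoose(n1 + n2, k)
    p <- exp(logp)
    sum(p[p <= p[x == ai] * (1 + 1e-7)])
  }, a, b)
}

# two-stage step-up expressed through p.adjust("BH") thresholding
oracle_bky <- function(p, q = 0.10) {
  m <- length(p)
  if (m == 0) return(logical(0))
  q1 <- q / (1 + q)
  adj <- stats::p.adjust(p, "BH")
  r1 <- sum(adj <= q1)
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  adj <= q1 * m / (m - r1)
}

# exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled ranks to the first sample
oracle_mann_whitney <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_u <- apply(utils::combn(n, n1), 2,
                 function(ix) sum(ix) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs)))
}
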