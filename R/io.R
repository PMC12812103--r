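#' Variant-table dialects
#'
#' The canonical exchange format is a UTF-8 tab-separated table with one
#' header line, one row per patient-variant call, `.` for absent values and
#' the columns listed under [read_variant_table()]. A VCF 4.2 dialect is
#' supported as an adapter: annotations are read from INFO keys and
#' per-sample quality fields from FORMAT keys. The default key mapping can
#' be overridden per field.
#'
#' @param format `"tsv"` or `"vcf"`.
#' @param info_keys Named character vector overriding the default INFO key
#'   for any of: gene, consequence, clinvar, maf_nfe, cadd, sift, polyphen,
#'   revel, fathmm_cancer, spliceai, maxentscan_effect, hgvs_c, hgvs_p,
#'   patient_id, family_id, zygosity.
#' @param format_keys Named character vector overriding the default FORMAT
#'   keys `DP` (coverage), `GQ` (call quality), `AF` (allele fraction).
#' @return An object of class `variant_dialect`.
#' @export
variant_dialect <- function(format = c("tsv", "vcf"),
                            info_keys = character(0),
                            format_keys = character(0)) {
  format <- match.arg(format)
  info <- c(
    gene = "GENE", consequence = "Consequence", clinvar = "CLNSIG",
    maf_nfe = "gnomAD_AF_nfe", cadd = "CADD_PHRED", sift = "SIFT",
    polyphen = "PolyPhen", revel = "REVEL", fathmm_cancer = "FATHMM_CANCER",
    spliceai = "SpliceAI_DS_max", maxentscan_effect = "MES_effect",
    hgvs_c = "HGVSc", hgvs_p = "HGVSp", patient_id = "PID",
    family_id = "FID", zygosity = "ZYG"
  )
  fmt <- c(coverage = "DP", call_quality = "GQ", allele_fraction = "AF")
  bad <- setdiff(names(info_keys), names(info))
  if (length(bad)) {
    warning("ignoring unknown dialect key(s): ", paste(bad, collapse = ", "))
    info_keys <- info_keys[setdiff(names(info_keys), bad)]
  }
  info[names(info_keys)] <- info_keys
  fmt[names(format_keys)] <- format_keys
  structure(list(format = format, info_keys = info, format_keys = fmt),
            class = "variant_dialect")
}

#' Read an annotated germline variant table
#'
#' Produces one record per patient-variant call with all the annotation
#' fields the downstream filters consume: identifiers (`patient_id`,
#' `family_id`, `gene`), the hg38 coordinate (`chrom` without a `chr`
#' prefix, 1-based `pos`, `ref`, `alt`), HGVS strings, the molecular
#' `consequence` (one of `r paste(CONSEQUENCE_LEVELS, collapse = ", ")`),
#' the ClinVar class (`P`, `LP`, `LP_P`, `conflicting`, `VUS`, or absent),
#' the gnomAD non-Finnish European allele frequency `maf_nfe` as a
#' fraction, in silico scores (`cadd`, `sift`, `polyphen`, `revel`,
#' `fathmm_cancer`, `spliceai`, logical `maxentscan_effect`), and the
#' platform quality fields (`coverage`, `call_quality`, `allele_fraction`,
#' `zygosity`). Enum fields are parsed strictly; a malformed value raises
#' an error naming the row and field. ClinVar strings are normalised
#' case-insensitively (`"LP/P"` and `"Pathogenic/Likely_pathogenic"` both
#' map to `LP_P`; `"C"` and `"conflicting classifications"` to
#' `conflicting`).
#'
#' For the VCF dialect, multi-allelic records are split per ALT allele
#' before the annotation mapping is applied.
#'
#' @param path File path.
#' @param dialect A [variant_dialect()]; default TSV.
#' @return data.frame with the canonical columns plus `.row` (source row
#'   number, for diagnostics).
#' @export
read_variant_table <- function(path, dialect = variant_dialect("tsv")) {
  stopifnot(inherits(dialect, "variant_dialect"))
  v <- if (dialect$format == "tsv") {
    read_variant_tsv(path)
  } else {
    read_variant_vcf(path, dialect)
  }
  validate_variants(v)
  v
}

read_variant_tsv <- function(path) {
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", na.strings = c(".", ""),
                    check.names = FALSE)
  check_columns(raw, setdiff(VARIANT_COLUMNS, "family_id"), basename(path))
  n <- nrow(raw)
  fam <- if ("family_id" %in% names(raw) && n > 0) {
    ifelse(is.na(raw$family_id),
           family_from_patient_id(raw$patient_id), raw$family_id)
  } else if (n > 0) {
    family_from_patient_id(raw$patient_id)
  } else {
    character(0)
  }
  v <- data.frame(
    patient_id = chr0(raw$patient_id), family_id = chr0(fam),
    gene = chr0(raw$gene),
    chrom = sub("^chr", "", chr0(raw$chrom)),
    pos = as.integer(raw$pos),
    ref = chr0(raw$ref), alt = chr0(raw$alt),
    hgvs_c = chr0(raw$hgvs_c), hgvs_p = chr0(raw$hgvs_p),
    consequence = parse_enum(raw$consequence, CONSEQUENCE_LEVELS,
                             "consequence"),
    clinvar = parse_clinvar(raw$clinvar),
    maf_nfe = as.numeric(raw$maf_nfe),
    cadd = as.numeric(raw$cadd),
    sift = parse_enum(raw$sift, SIFT_LEVELS, "sift", allow_na = TRUE),
    polyphen = parse_enum(raw$polyphen, POLYPHEN_LEVELS, "polyphen",
                          allow_na = TRUE),
    revel = as.numeric(raw$revel),
    fathmm_cancer = as.numeric(raw$fathmm_cancer),
    spliceai = as.numeric(raw$spliceai),
    maxentscan_effect = parse_logical(raw$maxentscan_effect,
                                      "maxentscan_effect"),
    coverage = as.integer(raw$coverage),
    call_quality = as.numeric(raw$call_quality),
    allele_fraction = as.numeric(raw$allele_fraction),
    zygosity = parse_enum(raw$zygosity, ZYGOSITY_LEVELS, "zygosity",
                          allow_na = TRUE),
    stringsAsFactors = FALSE
  )
  v$.row <- seq_len(n)
  v
}

chr0 <- function(x) { x <- as.character(x); x }

parse_enum <- function(x, levels, field, allow_na = FALSE) {
  x <- as.character(x)
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad)) {
    stop(sprintf("row %d: invalid %s value '%s' (expected one of %s)",
                 bad[1], field, x[bad[1]], paste(levels, collapse = ", ")),
         call. = FALSE)
  }
  if (!allow_na && anyNA(x) && length(x)) {
    stop(sprintf("row %d: missing mandatory %s value",
                 which(is.na(x))[1], field), call. = FALSE)
  }
  x
}

# ClinVar label normalisation; returns NA for "not listed".
parse_clinvar <- function(x) {
  x <- as.character(x)
  key <- tolower(gsub("[ _]+", "_", trimws(x)))
  map <- c(
    "p" = "P", "pathogenic" = "P",
    "lp" = "LP", "likely_pathogenic" = "LP",
    "lp/p" = "LP_P", "lp_p" = "LP_P",
    "pathogenic/likely_pathogenic" = "LP_P",
    "likely_pathogenic/pathogenic" = "LP_P",
    "c" = "conflicting", "conflicting" = "conflicting",
    "conflicting_classifications" = "conflicting",
    "conflicting_classifications_of_pathogenicity" = "conflicting",
    "conflicting_interpretations_of_pathogenicity" = "conflicting",
    "vus" = "VUS", "uncertain_significance" = "VUS",
    "-" = NA_character_, "–" = NA_character_,
    "absent" = NA_character_, "not_listed" = NA_character_
  )
  out <- unname(map[key])
  bad <- which(!is.na(x) & is.na(out) & !(key %in% names(map)))
  if (length(bad)) {
    stop(sprintf("row %d: invalid clinvar value '%s'", bad[1], x[bad[1]]),
         call. = FALSE)
  }
  out
}

# Structural invariants of a variant table; raises on violation.
validate_variants <- function(v) {
  check_columns(v, VARIANT_COLUMNS, "variant table")
  if (!nrow(v)) return(invisible(v))
  if (any(is.na(v$pos)) || any(v$pos < 1L)) {
    stop("pos must be a 1-based positive integer", call. = FALSE)
  }
  for (f in c("maf_nfe", "revel", "spliceai", "allele_fraction")) {
    x <- v[[f]]
    if (any(!is.na(x) & (x < 0 | x > 1))) {
      stop(f, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (any(!is.na(v$cadd) & v$cadd < 0)) {
    stop("cadd must be non-negative", call. = FALSE)
  }
  key <- paste(v$patient_id, variant_key(v))
  if (anyDuplicated(key)) {
    stop("duplicate (patient_id, chrom, pos, ref, alt) record: ",
         key[anyDuplicated(key)], call. = FALSE)
  }
  invisible(v)
}

#' @rdname read_variant_table
#' @param variants Variant data.frame (canonical columns).
#' @export
write_variant_table <- function(variants, path,
                                dialect = variant_dialect("tsv")) {
  stopifnot(inherits(dialect, "variant_dialect"))
  if (dialect$format == "vcf") {
    return(write_variant_vcf(variants, path, dialect))
  }
  out <- variants[, VARIANT_COLUMNS, drop = FALSE]
  num <- c("maf_nfe", "cadd", "revel", "fathmm_cancer", "spliceai",
           "call_quality", "allele_fraction")
  for (f in num) out[[f]] <- format_absent(format_num(out[[f]]))
  for (f in setdiff(VARIANT_COLUMNS, num)) {
    x <- out[[f]]
    if (is.logical(x)) x <- tolower(as.character(x))
    out[[f]] <- format_absent(as.character(x))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# full-precision numeric formatting that survives a read round trip
format_num <- function(x) {
  out <- vapply(x, function(xi) {
    if (is.na(xi)) NA_character_ else format(xi, digits = 17, scientific = TRUE,
                                             trim = TRUE)
  }, character(1))
  out
}

# ---- VCF dialect ----------------------------------------------------------

read_variant_vcf <- function(path, dialect) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0) {
    v <- empty_variant_table()
    return(v)
  }
  ik <- dialect$info_keys
  info_get <- function(key) {
    x <- vcfR::extract.info(vcf, element = key)
    if (is.null(x)) rep(NA_character_, n) else as.character(x)
  }
  gt_get <- function(key) {
    if (is.null(vcf@gt) || ncol(vcf@gt) < 2) return(rep(NA_character_, n))
    as.character(vcfR::extract.gt(vcf, element = key)[, 1])
  }
  # one sample per record in this dialect; multi-ALT rows are split
  alts <- strsplit(as.character(fix$ALT), ",", fixed = TRUE)
  idx <- rep(seq_len(n), lengths(alts))
  build <- function(x) x[idx]
  fk <- dialect$format_keys
  gt <- gt_get("GT")
  zyg <- ifelse(is.na(gt), NA_character_,
                ifelse(gt %in% c("1/1", "1|1"), "hom", "het"))
  v <- data.frame(
    patient_id = build(info_get(ik[["patient_id"]])),
    family_id = build(info_get(ik[["family_id"]])),
    gene = build(info_get(ik[["gene"]])),
    chrom = sub("^chr", "", build(as.character(fix$CHROM))),
    pos = as.integer(build(fix$POS)),
    ref = build(as.character(fix$REF)),
    alt = unlist(alts),
    hgvs_c = build(info_get(ik[["hgvs_c"]])),
    hgvs_p = build(info_get(ik[["hgvs_p"]])),
    consequence = parse_enum(build(info_get(ik[["consequence"]])),
                             CONSEQUENCE_LEVELS, "consequence"),
    clinvar = parse_clinvar(build(info_get(ik[["clinvar"]]))),
    maf_nfe = as.numeric(build(info_get(ik[["maf_nfe"]]))),
    cadd = as.numeric(build(info_get(ik[["cadd"]]))),
    sift = parse_enum(build(info_get(ik[["sift"]])), SIFT_LEVELS, "sift",
                      allow_na = TRUE),
    polyphen = parse_enum(build(info_get(ik[["polyphen"]])),
                          POLYPHEN_LEVELS, "polyphen", allow_na = TRUE),
    revel = as.numeric(build(info_get(ik[["revel"]]))),
    fathmm_cancer = as.numeric(build(info_get(ik[["fathmm_cancer"]]))),
    spliceai = as.numeric(build(info_get(ik[["spliceai"]]))),
    maxentscan_effect = parse_logical(build(info_get(ik[["maxentscan_effect"]])),
                                      "maxentscan_effect"),
    coverage = as.integer(build(gt_get(fk[["coverage"]]))),
    call_quality = as.numeric(build(gt_get(fk[["call_quality"]]))),
    allele_fraction = as.numeric(build(gt_get(fk[["allele_fraction"]]))),
    zygosity = build(zyg),
    stringsAsFactors = FALSE
  )
  miss <- is.na(v$family_id) & !is.na(v$patient_id)
  v$family_id[miss] <- family_from_patient_id(v$patient_id[miss])
  v$.row <- seq_len(nrow(v))
  v
}

write_variant_vcf <- function(variants, path,
                              dialect = variant_dialect("vcf")) {
  ik <- dialect$info_keys
  fk <- dialect$format_keys
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=gliovar",
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="%s">',
            ik[c("patient_id", "family_id", "gene", "consequence",
                 "clinvar", "sift", "polyphen", "hgvs_c", "hgvs_p",
                 "maxentscan_effect")],
            c("Patient id", "Family id", "HGNC gene symbol",
              "Molecular consequence", "ClinVar class", "SIFT class",
              "PolyPhen-2 class", "HGVS c.", "HGVS p.",
              "MaxEntScan predicted splicing effect")),
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="%s">',
            ik[c("maf_nfe", "cadd", "revel", "fathmm_cancer", "spliceai")],
            c("gnomAD NFE allele frequency", "CADD PHRED", "REVEL",
              "FATHMM Cancer", "SpliceAI max delta score")),
    sprintf('##FORMAT=<ID=%s,Number=1,Type=%s,Description="%s">',
            c("GT", fk), c("String", "Integer", "Float", "Float"),
            c("Genotype", "Read depth", "Call quality", "Allele fraction")),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "SAMPLE"), collapse = "\t")
  )
  ival <- function(key, x) {
    x <- as.character(x)
    ifelse(is.na(x), NA_character_, paste0(key, "=", gsub("[;= ]", "_", x)))
  }
  rows <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    parts <- c(
      ival(ik[["patient_id"]], v$patient_id),
      ival(ik[["family_id"]], v$family_id),
      ival(ik[["gene"]], v$gene),
      ival(ik[["consequence"]], v$consequence),
      ival(ik[["clinvar"]], v$clinvar),
      ival(ik[["maf_nfe"]], format_num(v$maf_nfe)),
      ival(ik[["cadd"]], format_num(v$cadd)),
      ival(ik[["sift"]], v$sift),
      ival(ik[["polyphen"]], v$polyphen),
      ival(ik[["revel"]], format_num(v$revel)),
      ival(ik[["fathmm_cancer"]], format_num(v$fathmm_cancer)),
      ival(ik[["spliceai"]], format_num(v$spliceai)),
      ival(ik[["maxentscan_effect"]],
           if (is.na(v$maxentscan_effect)) NA else
             tolower(as.character(v$maxentscan_effect))),
      ival(ik[["hgvs_c"]], v$hgvs_c),
      ival(ik[["hgvs_p"]], v$hgvs_p)
    )
    info <- paste(parts[!is.na(parts)], collapse = ";")
    gt <- if (!is.na(v$zygosity) && v$zygosity == "hom") "1/1" else "0/1"
    sample <- paste(gt,
                    format_absent(as.character(v$coverage)),
                    format_absent(format_num(v$call_quality)),
                    format_absent(format_num(v$allele_fraction)),
                    sep = ":")
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info,
          paste(c("GT", fk), collapse = ":"), sample, sep = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

empty_variant_table <- function() {
  v <- data.frame(
    patient_id = character(0), family_id = character(0),
    gene = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), hgvs_c = character(0),
    hgvs_p = character(0), consequence = character(0),
    clinvar = character(0), maf_nfe = numeric(0), cadd = numeric(0),
    sift = character(0), polyphen = character(0), revel = numeric(0),
    fathmm_cancer = numeric(0), spliceai = numeric(0),
    maxentscan_effect = logical(0), coverage = integer(0),
    call_quality = numeric(0), allele_fraction = numeric(0),
    zygosity = character(0), stringsAsFactors = FALSE
  )
  v$.row <- integer(0)
  v
}

# ---- gene panels ----------------------------------------------------------

#' Read a gene panel
#'
#' One HGNC symbol per line; `#` starts a comment; an optional second
#' tab-separated column carries the inheritance tag (`AD`, `AR`, `AD_AR`,
#' `unknown`).
#'
#' @param path File path.
#' @param name Panel name (default: file name).
#' @param category `"CPG"`, `"glioma_risk"` or `"other"`.
#' @return List with `name`, `category`, `genes` (character vector) and
#'   `inheritance` (named character vector).
#' @export
read_gene_panel <- function(path, name = basename(path),
                            category = c("CPG", "glioma_risk", "other")) {
  category <- match.arg(category)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  genes <- vapply(parts, `[[`, character(1), 1L)
  inh <- vapply(parts, function(p) if (length(p) > 1) p[2] else "unknown",
                character(1))
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbol in panel ", name, ": ",
         genes[anyDuplicated(genes)], call. = FALSE)
  }
  bad <- !(inh %in% c("AD", "AR", "AD_AR", "unknown"))
  if (any(bad)) {
    stop("invalid inheritance tag '", inh[bad][1], "' in panel ", name,
         call. = FALSE)
  }
  list(name = name, category = category, genes = genes,
       inheritance = setNames(inh, genes))
}

# ---- tumor variant calls --------------------------------------------------

#' Read a tumor variant-call table
#'
#' Tab-separated with header columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `coverage`, `strand_bias`, `maf_population`, `somatic_af`. Consumed by
#' [tmb()] and [second_hit_screen()].
#'
#' @param path File path.
#' @return data.frame, one record per row.
#' @export
read_tumor_calls <- function(path) {
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", na.strings = c(".", ""),
                    check.names = FALSE)
  check_columns(raw, TUMOR_CALL_COLUMNS, basename(path))
  out <- data.frame(
    chrom = sub("^chr", "", chr0(raw$chrom)),
    pos = as.integer(raw$pos),
    ref = chr0(raw$ref), alt = chr0(raw$alt), gene = chr0(raw$gene),
    coverage = as.integer(raw$coverage),
    strand_bias = as.numeric(raw$strand_bias),
    maf_population = as.numeric(raw$maf_population),
    somatic_af = as.numeric(raw$somatic_af),
    stringsAsFactors = FALSE
  )
  if (any(!is.na(out$coverage) & out$coverage < 0)) {
    stop("negative coverage in ", basename(path), call. = FALSE)
  }
  out
}

# ---- reports --------------------------------------------------------------

#' Write the prioritization report
#'
#' One row per prioritized patient-variant, sorted deterministically by
#' gene, then chromosome, then position, then patient id; the category
#' column uses the labels `i`, `ii`, `iii`, `iv`.
#'
#' @param prioritized data.frame as returned in `run_approach1()$prioritized`.
#' @param path Output file path.
#' @export
write_prioritization_report <- function(prioritized, path) {
  cols <- c("patient_id", "family_id", "gene", "chrom", "pos", "ref", "alt",
            "hgvs_c", "hgvs_p", "consequence", "clinvar", "maf_nfe", "cadd",
            "panel_category", "pathogenicity_category")
  if (nrow(prioritized)) {
    check_columns(prioritized, cols, "prioritized variants")
    ord <- order(prioritized$gene, prioritized$chrom, prioritized$pos,
                 prioritized$patient_id)
    out <- prioritized[ord, cols, drop = FALSE]
    num <- c("maf_nfe", "cadd")
    for (f in num) out[[f]] <- format_absent(format_num(out[[f]]))
    for (f in setdiff(cols, num)) out[[f]] <- format_absent(as.character(out[[f]]))
  } else {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
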