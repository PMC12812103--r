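#' Validate a cohort of patients and families
#'
#' Checks the structural invariants of the cohort metadata: every patient
#' references a known family, no family has more than one index patient,
#' every patient has a recognised histology label, and family types are
#' from the four study groups (families with at least one further glioma /
#' brain tumor / non-brain tumor patient, or a glioma patient with
#' syn-/metachronous non-brain tumors and unremarkable family history).
#'
#' Violations are reported, not raised, so a partially dirty cohort can be
#' inspected in full.
#'
#' @param patients data.frame with columns `patient_id`, `family_id`,
#'   `age_at_dx`, `histology`, `is_index`.
#' @param families data.frame with columns `family_id`, `family_type`.
#' @return Character vector of human-readable violations; `character(0)`
#'   iff the cohort is well-formed.
#' @seealso [select_index_patients()], [read_cohort_table()]
#' @export
validate_cohort <- function(patients, families) {
  check_columns(patients, c("patient_id", "family_id", "histology", "is_index"),
                "patients")
  check_columns(families, c("family_id", "family_type"), "families")
  out <- character(0)

  dup_pat <- unique(patients$patient_id[duplicated(patients$patient_id)])
  for (p in dup_pat) {
    out <- c(out, sprintf("duplicate patient_id '%s'", p))
  }
  dup_fam <- unique(families$family_id[duplicated(families$family_id)])
  for (f in dup_fam) {
    out <- c(out, sprintf("duplicate family_id '%s'", f))
  }
  unknown <- setdiff(patients$family_id, families$family_id)
  for (f in unknown) {
    out <- c(out, sprintf("patient references unknown family '%s'", f))
  }
  empty <- setdiff(families$family_id, patients$family_id)
  for (f in empty) {
    out <- c(out, sprintf("family '%s' has no member patients", f))
  }
  idx <- patients[isTRUE_vec(patients$is_index), , drop = FALSE]
  multi <- names(which(table(idx$family_id) > 1))
  for (f in multi) {
    out <- c(out, sprintf("family '%s' has more than one index patient", f))
  }
  bad_hist <- !(patients$histology %in% HISTOLOGY_LEVELS)
  for (i in which(bad_hist)) {
    out <- c(out, sprintf("patient '%s' has missing or unknown histology '%s'",
                          patients$patient_id[i],
                          as.character(patients$histology[i])))
  }
  bad_type <- !(families$family_type %in% FAMILY_TYPE_LEVELS)
  for (i in which(bad_type)) {
    out <- c(out, sprintf("family '%s' has unknown family_type '%s'",
                          families$family_id[i],
                          as.character(families$family_type[i])))
  }
  out
}

# NA-safe elementwise isTRUE
isTRUE_vec <- function(x) !is.na(x) & x

#' Select one index patient per family
#'
#' The burden comparison uses unrelated genetic data only, i.e. one glioma
#' patient per family. When a family has several sequenced patients the
#' index is chosen deterministically: a patient flagged `is_index` wins;
#' otherwise the lowest age at diagnosis, with lexicographically smallest
#' `patient_id` as the final tie-break (missing ages sort last).
#'
#' @param families data.frame with column `family_id`.
#' @param patients data.frame with columns `patient_id`, `family_id` and
#'   optionally `age_at_dx`, `is_index`.
#' @param rule `"flag_then_youngest"` (default) honours an `is_index` flag
#'   first; `"youngest"` ignores the flag.
#' @return Named character vector: `family_id` -> `patient_id`.
#' @export
select_index_patients <- function(families, patients,
                                  rule = c("flag_then_youngest", "youngest")) {
  rule <- match.arg(rule)
  check_columns(families, "family_id", "families")
  check_columns(patients, c("patient_id", "family_id"), "patients")
  fams <- unique(families$family_id)
  empty <- setdiff(fams, patients$family_id)
  if (length(empty)) {
    stop("family with no member patients: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  age <- if ("age_at_dx" %in% names(patients)) {
    as.numeric(patients$age_at_dx)
  } else {
    rep(NA_real_, nrow(patients))
  }
  flag <- if (rule == "flag_then_youngest" && "is_index" %in% names(patients)) {
    isTRUE_vec(patients$is_index)
  } else {
    rep(FALSE, nrow(patients))
  }
  age[is.na(age)] <- Inf
  # order: flagged first, then youngest, then id
  ord <- order(patients$family_id, !flag, age, patients$patient_id)
  p <- patients[ord, , drop = FALSE]
  first <- !duplicated(p$family_id)
  map <- setNames(p$patient_id[first], p$family_id[first])
  map[fams]
}

#' Read / write a cohort metadata table
#'
#' Tab-separated, one header line, columns `patient_id`, `family_id`,
#' `family_type`, `age_at_dx`, `histology`, `is_index`; `.` for absent
#' values. The family table is derived by collapsing the per-patient rows
#' (the `family_type` must be consistent within a family).
#'
#' @param path File path.
#' @return `read_cohort_table()`: list with data.frames `patients`
#'   (patient_id, family_id, age_at_dx, histology, is_index) and
#'   `families` (family_id, family_type).
#' @export
read_cohort_table <- function(path) {
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", na.strings = c(".", "NA", ""),
                    check.names = FALSE)
  check_columns(raw, c("patient_id", "family_id", "family_type",
                       "age_at_dx", "histology", "is_index"),
                basename(path))
  patients <- data.frame(
    patient_id = raw$patient_id,
    family_id = raw$family_id,
    age_at_dx = as.numeric(raw$age_at_dx),
    histology = raw$histology,
    is_index = parse_logical(raw$is_index, "is_index"),
    stringsAsFactors = FALSE
  )
  ft <- tapply(raw$family_type, raw$family_id, function(x) unique(x))
  inconsistent <- names(ft)[lengths(ft) > 1L]
  if (length(inconsistent)) {
    stop("inconsistent family_type within family: ",
         paste(inconsistent, collapse = ", "), call. = FALSE)
  }
  fam_ids <- unique(raw$family_id)
  families <- data.frame(
    family_id = fam_ids,
    family_type = vapply(ft[fam_ids], `[[`, character(1), 1L),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  list(patients = patients, families = families)
}

#' @rdname read_cohort_table
#' @param cohort List as returned by [read_cohort_table()].
#' @export
write_cohort_table <- function(cohort, path) {
  p <- cohort$patients
  f <- cohort$families
  type <- setNames(f$family_type, f$family_id)[p$family_id]
  out <- data.frame(
    patient_id = p$patient_id,
    family_id = p$family_id,
    family_type = as.character(type),
    age_at_dx = format_absent(p$age_at_dx),
    histology = p$histology,
    is_index = tolower(as.character(p$is_index)),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

parse_logical <- function(x, field) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("row %d: cannot parse %s value '%s' as logical",
                 bad[1], field, x[bad[1]]), call. = FALSE)
  }
  out
}

format_absent <- function(x) {
  out <- as.character(x)
  out[is.na(x)] <- "."
  out
}
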