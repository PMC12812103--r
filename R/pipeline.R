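#' End-to-end pipeline run
#'
#' Chains ingest -> candidate-gene cascade -> (optionally) case-control
#' burden test -> genotype-phenotype yield into an output directory, with
#' a run manifest recording inputs, outputs, their MD5 checksums, row
#' counts per stage and the configuration, so a run can be reproduced and
#' verified file by file. No stage mutates its inputs; all intermediates
#' are files. Re-running with identical inputs produces byte-identical
#' outputs.
#'
#' @param variants Path to the case variant table (TSV dialect).
#' @param cpg_panel,risk_panel Paths to the panel files.
#' @param cohort Path to the cohort metadata table.
#' @param out_dir Output directory (created if needed).
#' @param control_variants Optional path to the control variant table;
#'   when given the burden test runs.
#' @param cfg [approach1_config()].
#' @param rule [qualifying_rule()].
#' @param q Target FDR for the burden test.
#' @param n_controls Control cohort size (defaults to the distinct
#'   patient ids seen in the control table).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
full_run <- function(variants, cpg_panel, risk_panel, cohort, out_dir,
                     control_variants = NULL, cfg = approach1_config(),
                     rule = qualifying_rule(), q = 0.10,
                     n_controls = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- c(variants = variants, cpg_panel = cpg_panel,
              risk_panel = risk_panel, cohort = cohort,
              control_variants = control_variants)
  for (f in inputs) {
    if (!file.exists(f)) stop("input not readable: ", f, call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  v <- stage("ingest", read_variant_table(variants))
  coh <- stage("ingest", read_cohort_table(cohort))
  panels <- stage("ingest", list(
    read_gene_panel(cpg_panel, category = "CPG"),
    read_gene_panel(risk_panel, category = "glioma_risk")
  ))
  counts <- c(variants_in = nrow(v), patients = nrow(coh$patients),
              families = nrow(coh$families))

  a1 <- stage("approach1", suppressMessages(run_approach1(v, panels, cfg)))
  prior_path <- file.path(out_dir, "prioritized_variants.tsv")
  write_prioritization_report(a1$prioritized, prior_path)
  counts["prioritized"] <- nrow(a1$prioritized)

  a2 <- NULL
  burden_path <- NULL
  hits <- data.frame(family_id = a1$prioritized$family_id,
                     gene = a1$prioritized$gene,
                     gene_class = a1$prioritized$panel_category,
                     stringsAsFactors = FALSE)
  if (!is.null(control_variants)) {
    cv <- stage("ingest", read_variant_table(control_variants))
    a2 <- stage("approach2", suppressMessages(
      run_approach2(v, cv, coh, rule, q, n_controls = n_controls)))
    burden_path <- file.path(out_dir, "burden_results.tsv")
    out <- a2$results
    out$fisher_p <- format_num(out$fisher_p)
    write.table(out, burden_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    counts["burden_genes"] <- nrow(a2$results)
    counts["burden_hits"] <- nrow(a2$hits)
    if (nrow(a2$hits)) {
      panel_genes <- unlist(lapply(panels, `[[`, "genes"))
      im <- select_index_patients(coh$families, coh$patients)
      qc <- cv_hits_carriers(v, a2$hits$gene, im, rule)
      if (nrow(qc)) {
        hits <- rbind(hits, data.frame(
          family_id = qc$family_id, gene = qc$gene,
          gene_class = ifelse(qc$gene %in% panel_genes, "CPG", "novel"),
          stringsAsFactors = FALSE))
      }
    }
  }

  yield <- stage("phenostats", diagnostic_yield(hits, coh))
  yield_path <- file.path(out_dir, "diagnostic_yield.tsv")
  write.table(yield, yield_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  summary <- list(
    approach1 = a1$summary, funnel = as.list(a1$funnel),
    approach2 = if (!is.null(a2))
      list(hit_genes = a2$hits$gene, summary = a2$summary),
    yield = yield
  )
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  outputs <- c(prioritized = prior_path, burden = burden_path,
               yield = yield_path, summary = summary_path)
  manifest <- list(
    package_version = as.character(packageVersion("gliovar")),
    inputs = file_entries(inputs),
    outputs = file_entries(outputs),
    row_counts = as.list(counts),
    config = c(unclass(cfg), unclass(rule)[c("cadd_min", "maf_ultrarare")],
               list(q = q))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(approach1 = a1, approach2 = a2, yield = yield,
                 manifest = manifest, out_dir = out_dir))
}

# qualifying carriers (index patients) of the given genes, for yield rows
cv_hits_carriers <- function(case_variants, genes, index_map, rule) {
  qc <- case_variants[pass_quality(case_variants) &
                        is_qualifying(case_variants, rule), , drop = FALSE]
  im <- unname(index_map[qc$family_id])
  qc[qc$gene %in% genes & isTRUE_vec(qc$patient_id == im), , drop = FALSE]
}

file_entries <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  lapply(as.list(paths), function(p) {
    list(path = as.character(p), md5 = unname(tools::md5sum(p)),
         bytes = unname(file.size(p)))
  })
}

#' Command-line dispatcher
#'
#' Thin subcommand interface over the package functions, used by the
#' `inst/scripts/gliovar` Rscript wrapper:
#'
#' ```
#' gliovar simulate  --out-dir DIR [--seed N]
#' gliovar approach1 --variants F --cpg-panel F --risk-panel F --out-prefix P
#' gliovar approach2 --case-variants F --control-variants F --cohort F
#'                   [--q 0.10] [--n-controls N] --out F
#' gliovar phenostats --hits F --cohort F --out-prefix P
#' gliovar irs       --fields F --out F
#' gliovar tmb       --calls F [--panel-mb 1.7]
#' gliovar second-hit --calls F --gene SYMBOL
#' gliovar full-run  --variants F --cpg-panel F --risk-panel F --cohort F
#'                   [--control-variants F] --out-dir DIR
#' ```
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first), e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return Invisibly, 0 on success, 2 on validation failure.
#' @export
gliovar_cli <- function(args) {
  if (!length(args)) {
    message("usage: gliovar {simulate|approach1|approach2|phenostats|",
            "irs|tmb|second-hit|full-run} ...")
    return(invisible(2L))
  }
  cmd <- args[1]
  opt <- parse_cli_flags(args[-1])
  need <- function(...) {
    miss <- setdiff(c(...), names(opt))
    if (length(miss)) {
      stop("missing required option(s): --", paste(miss, collapse = ", --"),
           call. = FALSE)
    }
  }
  code <- tryCatch({
    switch(cmd,
      "simulate" = {
        need("out-dir")
        cfg <- sim_config(seed = as.integer(opt[["seed"]] %||% "1"))
        sim <- simulate_cohort(cfg)
        dir.create(opt[["out-dir"]], showWarnings = FALSE, recursive = TRUE)
        write_variant_table(sim$case_variants,
                            file.path(opt[["out-dir"]], "case_variants.tsv"))
        write_variant_table(sim$control_variants,
                            file.path(opt[["out-dir"]],
                                      "control_variants.tsv"))
        write_cohort_table(list(patients = sim$patients,
                                families = sim$families),
                           file.path(opt[["out-dir"]], "cohort.tsv"))
        jsonlite::write_json(sim$truth,
                             file.path(opt[["out-dir"]], "truth.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        0L
      },
      "approach1" = {
        need("variants", "cpg-panel", "risk-panel", "out-prefix")
        v <- read_variant_table(opt[["variants"]])
        panels <- list(
          read_gene_panel(opt[["cpg-panel"]], category = "CPG"),
          read_gene_panel(opt[["risk-panel"]], category = "glioma_risk"))
        res <- run_approach1(v, panels)
        write_prioritization_report(
          res$prioritized, paste0(opt[["out-prefix"]], "_prioritized.tsv"))
        jsonlite::write_json(res$summary,
                             paste0(opt[["out-prefix"]], "_summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        0L
      },
      "approach2" = {
        need("case-variants", "control-variants", "cohort", "out")
        res <- run_approach2(
          read_variant_table(opt[["case-variants"]]),
          read_variant_table(opt[["control-variants"]]),
          read_cohort_table(opt[["cohort"]]),
          q = as.numeric(opt[["q"]] %||% "0.10"),
          n_controls = if (!is.null(opt[["n-controls"]]))
            as.integer(opt[["n-controls"]]))
        out <- res$results
        out$fisher_p <- format_num(out$fisher_p)
        write.table(out, opt[["out"]], sep = "\t", quote = FALSE,
                    row.names = FALSE)
        0L
      },
      "phenostats" = {
        need("hits", "cohort", "out-prefix")
        hits <- read.delim(opt[["hits"]], sep = "\t",
                           colClasses = "character")
        coh <- read_cohort_table(opt[["cohort"]])
        yield <- diagnostic_yield(hits, coh)
        write.table(yield, paste0(opt[["out-prefix"]], "_yield.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        ages <- age_group_partition(coh$patients$age_at_dx)
        jsonlite::write_json(list(age_groups = as.list(ages)),
                             paste0(opt[["out-prefix"]], "_stats.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        0L
      },
      "irs" = {
        need("fields", "out")
        f <- read.delim(opt[["fields"]], sep = "\t")
        check_columns(f, c("section_id", "positive_fraction", "intensity"),
                      "fields")
        per_section <- lapply(split(f, f$section_id), mean_irs)
        out <- data.frame(
          section_id = names(per_section),
          mean_irs = vapply(per_section, `[[`, numeric(1), "mean"),
          category = vapply(per_section, `[[`, character(1), "category"))
        write.table(out, opt[["out"]], sep = "\t", quote = FALSE,
                    row.names = FALSE)
        0L
      },
      "tmb" = {
        need("calls")
        cfg <- tmb_config(panel_size_mb =
                            as.numeric(opt[["panel-mb"]] %||% "1.7"))
        cat(tmb(read_tumor_calls(opt[["calls"]]), cfg), "\n")
        0L
      },
      "second-hit" = {
        need("calls", "gene")
        hits <- second_hit_screen(read_tumor_calls(opt[["calls"]]),
                                  opt[["gene"]])
        write.table(hits, stdout(), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        0L
      },
      "full-run" = {
        need("variants", "cpg-panel", "risk-panel", "cohort", "out-dir")
        full_run(opt[["variants"]], opt[["cpg-panel"]], opt[["risk-panel"]],
                 opt[["cohort"]], opt[["out-dir"]],
                 control_variants = opt[["control-variants"]],
                 q = as.numeric(opt[["q"]] %||% "0.10"))
        0L
      },
      {
        message("unknown subcommand: ", cmd)
        2L
      }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_cli_flags <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      stop("unexpected argument: ", a, call. = FALSE)
    }
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opt[[key]] <- "true"
      i <- i + 1L
    } else {
      opt[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opt
}
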