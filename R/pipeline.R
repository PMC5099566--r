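.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full serum-miRNA analysis pipeline
#'
#' Orchestrates QC, reference-gene stability ranking, relative
#' quantification and biomarker evaluation from a single configuration.
#' Samples failing QC are excluded from every downstream stage; the returned
#' manifest records parameters, per-stage sample/gene counts and every
#' exclusion, making the run auditable. The output is a pure function of
#' (inputs, config, seed).
#'
#' The configuration is a named list (or path to a YAML file) with entries:
#' \describe{
#'   \item{preset / seed}{simulate the study via [preset_config()], or}
#'   \item{cq / annotation}{paths to a Cq table (wide) and annotation TSV;}
#'   \item{genes}{`candidates`, `targets`, `hemolysis` (two marker names),
#'     `spikein`;}
#'   \item{qc}{`enabled`, `hemolysis_threshold`, `spikein_max_dev`;}
#'   \item{stability}{`enabled`, `efficiency`, `v_threshold`;}
#'   \item{quantify}{`refs` (defaults to the comprehensive rank-1 gene),
#'     `calibrator` (defaults to the first group);}
#'   \item{biomarker}{`control` group, `orientation` for ROC;}
#'   \item{out_dir}{optional directory for qc_report.tsv, stability.tsv,
#'     rel_expr.tsv, roc.json, manifest.json.}
#' }
#'
#' @param config named list or YAML file path.
#' @return a `pipeline_run`: list with `qc`, `stability`, `rel_expr`,
#'   `group_tests`, `roc`, `correlations` and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  manifest <- list(parameters = config, stages = list())
  note <- function(stage, ...) manifest$stages[[stage]] <<- list(...)

  ## -- input stage ---------------------------------------------------------
  if (!is.null(config$preset)) {
    sim <- .stage("input", {
      if (is.null(config$seed)) stop("preset simulation requires a seed")
      simulate_cq_study(preset_config(config$preset, seed = config$seed))
    })
    cq <- sim$cq; ann <- sim$annotation
  } else {
    cq <- .stage("input", read_cq_table(config$cq, layout = "wide",
      missing_policy = if (is.null(config$missing_policy)) "drop"
                       else config$missing_policy))
    ann <- .stage("input", {
      tab <- utils::read.table(config$annotation, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      covn <- setdiff(colnames(tab), c("sample_id", "group", "bmd"))
      sample_annotation(tab$sample_id, tab$group,
                        covariates = if (length(covn)) tab[covn],
                        outcome = tab$bmd)
    })
  }
  note("input", n_genes = nrow(cq), n_samples = ncol(cq))

  genes <- config$genes
  if (is.null(genes$hemolysis)) genes$hemolysis <- c("miR-23a-3p", "miR-451a")
  if (is.null(genes$spikein)) genes$spikein <- "cel-miR-39"
  if (is.null(genes$candidates)) {
    genes$candidates <- if (!is.null(config$preset))
      sim$truth$reference_genes
    else
      setdiff(rownames(cq), c(genes$hemolysis, genes$spikein, genes$targets))
  }
  if (is.null(genes$targets))
    genes$targets <- setdiff(rownames(cq),
      c(genes$candidates, genes$hemolysis, genes$spikein))

  ## -- qc stage ------------------------------------------------------------
  qc <- NULL
  if (!isFALSE(config$qc$enabled)) {
    qc <- .stage("qc", qc_report(cq,
      gene_23a = genes$hemolysis[1], gene_451a = genes$hemolysis[2],
      threshold = config$qc$hemolysis_threshold %||% 7,
      spikein_gene = if (genes$spikein %in% rownames(cq)) genes$spikein,
      max_abs_dev = config$qc$spikein_max_dev %||% 1.5))
    excluded <- qc$sample_id[!qc$pass]
    cq <- qc_filter(cq, qc)
    ann <- ann[ann$sample_id %in% colnames(cq), , drop = FALSE]
    note("qc", n_excluded = length(excluded), excluded = as.list(excluded),
         n_samples_out = ncol(cq))
  }

  ## -- stability stage -----------------------------------------------------
  fit <- NULL
  refs <- config$quantify$refs
  if (!isFALSE(config$stability$enabled)) {
    fit <- .stage("stability", reference_stability(cq, ann,
      genes = intersect(genes$candidates, rownames(cq)),
      efficiency = config$stability$efficiency %||% 2,
      v_threshold = config$stability$v_threshold %||% 0.15))
    if (is.null(refs)) refs <- fit$table$gene[1]
    note("stability", recommended = fit$table$gene[1],
         most_stable_pair = as.list(fit$most_stable_pair),
         recommended_n = fit$recommended_n)
  } else if (is.null(refs)) {
    .stage("quantify",
           stop("stability stage disabled: quantify requires explicit refs"))
  }

  ## -- quantify stage ------------------------------------------------------
  targets <- setdiff(genes$targets, refs)
  if (!length(targets))
    .stage("quantify", stop("no target genes left after excluding references"))
  calibrator <- config$quantify$calibrator %||% unique(ann$group)[1]
  rel <- .stage("quantify", delta_delta_ct(cq, targets = targets, refs = refs,
    ann = ann, calibrator = calibrator,
    efficiency = config$stability$efficiency %||% 2))
  note("quantify", refs = as.list(refs), calibrator = calibrator,
       n_targets = length(targets))

  ## -- biomarker stage -----------------------------------------------------
  control <- config$biomarker$control %||% calibrator
  gt <- NULL; rocs <- list(); cors <- list()
  if (!isFALSE(config$biomarker$enabled) && length(unique(ann$group)) >= 2) {
    gt <- .stage("biomarker", group_compare(rel, control = control))
    is_case <- ann$group != control
    for (g in targets) {
      rocs[[g]] <- .stage("biomarker",
        roc_analysis(rel$rel_expr[g, ], is_case,
                     orientation = config$biomarker$orientation %||% "auto"))
    }
    if ("bmd" %in% colnames(ann)) {
      covn <- intersect(c("age", "weight", "height"), colnames(ann))
      for (g in targets) {
        cors[[g]] <- .stage("biomarker",
          adjusted_correlation(rel$rel_expr[g, ], ann$bmd,
                               covars = if (length(covn)) ann[covn]))
      }
    }
    note("biomarker", control = control, n_roc = length(rocs),
         n_correlations = length(cors))
  }

  manifest$n_stages_complete <- length(manifest$stages)
  run <- structure(list(qc = qc, stability = fit, rel_expr = rel,
                        group_tests = gt, roc = rocs, correlations = cors,
                        annotation = ann, manifest = manifest),
                   class = "pipeline_run")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    o <- function(f) file.path(config$out_dir, f)
    if (!is.null(qc)) write_report(as.data.frame(qc), o("qc_report.tsv"))
    if (!is.null(fit)) write_report(fit, o("stability.tsv"))
    write_report(as.data.frame(rel), o("rel_expr.tsv"))
    if (!is.null(gt)) write_report(as.data.frame(gt), o("group_tests.tsv"))
    if (length(rocs))
      jsonlite::write_json(lapply(rocs, function(r)
        r[c("auc", "ci_low", "ci_high", "p", "cutoff", "sensitivity",
            "specificity", "youden_J", "direction")]),
        o("roc.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Pipeline run: %d stages complete (%s)\n", m$n_stages_complete,
              paste(names(m$stages), collapse = " -> ")))
  if (!is.null(x$qc))
    cat(sprintf("  QC: %d/%d samples pass\n", attr(x$qc, "n_pass"),
                attr(x$qc, "n_samples")))
  if (!is.null(x$stability))
    cat("  Recommended reference:", x$stability$table$gene[1], "\n")
  if (length(x$roc)) {
    cat("  Biomarker AUCs:\n")
    for (g in names(x$roc))
      cat(sprintf("    %-12s AUC = %.3f (%.3f-%.3f)\n", g, x$roc[[g]]$auc,
                  x$roc[[g]]$ci_low, x$roc[[g]]$ci_high))
  }
  invisible(x)
}
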