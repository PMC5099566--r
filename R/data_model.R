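#' Construct a validated Cq matrix
#'
#' A Cq matrix holds quantification-cycle values with genes (miRNAs) in rows
#' and samples in columns. Cq is the PCR cycle at which fluorescence crosses
#' the detection threshold and is inversely proportional to the log2 template
#' abundance, so all downstream statistics treat it as a log-scale quantity.
#'
#' @param values numeric matrix (genes x samples) with unique row and column
#'   names. `NA` encodes an undetermined well.
#' @param max_cycles total number of PCR cycles run; every non-missing Cq must
#'   lie in `(0, max_cycles]`. Default 40.
#' @return a numeric matrix of class `cq_matrix` with attribute `max_cycles`.
#' @export
cq_matrix <- function(values, max_cycles = 40) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("Cq matrix requires gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  ok <- is.na(values) | (is.finite(values) & values > 0 & values <= max_cycles)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("Cq value out of (0, %g] at gene '%s', sample '%s': %g",
                 max_cycles, rownames(values)[bad[1]], colnames(values)[bad[2]],
                 values[bad[1], bad[2]]))
  }
  structure(values, max_cycles = max_cycles, class = c("cq_matrix", "matrix", "array"))
}

#' @export
`[.cq_matrix` <- function(x, i, j, ..., drop = FALSE) {
  mc <- attr(x, "max_cycles")
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "max_cycles") <- mc
    class(out) <- c("cq_matrix", "matrix", "array")
  }
  out
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat(sprintf("Cq matrix: %d genes x %d samples (max %g cycles, %d undetermined)\n",
              nrow(x), ncol(x), attr(x, "max_cycles"), sum(is.na(x))))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE], ...)
  invisible(x)
}

#' Construct a validated intensity matrix
#'
#' Linear-scale expression intensities (e.g. summarised microarray signal),
#' genes in rows and samples in columns; all values must be nonnegative.
#'
#' @param values nonnegative numeric matrix with unique dimnames.
#' @return a matrix of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("intensity matrix requires gene row names and sample column names")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("gene and sample ids must be unique")
  if (any(!is.finite(values)) || any(values < 0))
    stop("intensities must be finite and >= 0")
  structure(values, class = c("intensity_matrix", "matrix", "array"))
}

#' Construct a sample annotation table
#'
#' Per-sample metadata: group label, optional numeric covariates (age, weight,
#' height, ...) and an optional continuous outcome such as bone mineral
#' density (BMD, g/cm2).
#'
#' @param sample_id character vector of unique sample ids.
#' @param group group label per sample (factor or character).
#' @param covariates optional data.frame of numeric covariates, one row per
#'   sample.
#' @param outcome optional numeric outcome per sample.
#' @param outcome_name column name used for the outcome (default `"bmd"`).
#' @return a data.frame of class `sample_annotation` with columns `sample_id`,
#'   `group`, covariates, and the outcome.
#' @export
sample_annotation <- function(sample_id, group, covariates = NULL,
                              outcome = NULL, outcome_name = "bmd") {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (length(group) != length(sample_id))
    stop("group must have one entry per sample")
  ann <- data.frame(sample_id = sample_id, group = as.character(group),
                    stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(sample_id))
      stop("covariates must have one row per sample")
    if (!all(vapply(covariates, is.numeric, logical(1))))
      stop("covariates must be numeric")
    ann <- cbind(ann, covariates)
  }
  if (!is.null(outcome)) {
    if (length(outcome) != length(sample_id))
      stop("outcome must have one entry per sample")
    ann[[outcome_name]] <- as.numeric(outcome)
  }
  class(ann) <- c("sample_annotation", "data.frame")
  ann
}

#' Align an annotation table against a matrix's samples
#'
#' Checks that every sample in `x` has exactly one annotation row and returns
#' the annotation reordered to the matrix's column order.
#'
#' @param ann a [sample_annotation()] table.
#' @param x a matrix with sample column names.
#' @return the annotation, one row per column of `x`, in column order.
#' @export
align_annotation <- function(ann, x) {
  missing <- setdiff(colnames(x), ann$sample_id)
  if (length(missing))
    stop("samples missing from annotation: ", paste(missing, collapse = ", "))
  out <- ann[match(colnames(x), ann$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.parse_cq_cell <- function(x, missing_policy, max_cycles) {
  x <- trimws(as.character(x))
  undet <- is.na(x) | x == "" | tolower(x) %in% c("undetermined", "undet", "na")
  val <- suppressWarnings(as.numeric(x))
  if (any(!undet & is.na(val))) {
    bad <- x[!undet & is.na(val)][1]
    stop("non-numeric Cq value: '", bad, "'")
  }
  if (missing_policy == "max_cycle") val[undet] <- max_cycles else val[undet] <- NA_real_
  val
}

#' Read a Cq table from file
#'
#' Supports a wide layout (genes x samples, first column the gene id, header
#' row of sample ids) and a long layout (columns `gene`, `sample`, `cq`).
#' Cells reading "Undetermined" (any case), "NA" or empty are treated as
#' undetermined wells and handled per `missing_policy`: `"drop"` keeps them as
#' `NA` (genes with any `NA` are dropped by the stability functions), while
#' `"max_cycle"` imputes the total cycle number.
#'
#' The field separator is inferred from the extension (`.csv` comma,
#' otherwise tab). Duplicate (gene, sample) pairs and non-numeric Cq values
#' are hard errors.
#'
#' @param path path to a CSV/TSV file.
#' @param layout `"wide"` or `"long"`.
#' @param missing_policy `"drop"` or `"max_cycle"`.
#' @param max_cycles passed to [cq_matrix()]; also the imputation value.
#' @return a [cq_matrix()].
#' @export
read_cq_table <- function(path, layout = c("wide", "long"),
                          missing_policy = c("drop", "max_cycle"),
                          max_cycles = 40) {
  layout <- match.arg(layout)
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .infer_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(tab) == 0) stop("empty Cq table: ", path)
  if (layout == "wide") {
    genes <- tab[[1]]
    if (anyDuplicated(genes))
      stop("duplicate gene rows: ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "))
    vals <- vapply(tab[-1], .parse_cq_cell, numeric(nrow(tab)),
                   missing_policy = missing_policy, max_cycles = max_cycles)
    vals <- matrix(vals, nrow = nrow(tab),
                   dimnames = list(genes, colnames(tab)[-1]))
  } else {
    need <- c("gene", "sample", "cq")
    if (!all(need %in% tolower(colnames(tab))))
      stop("long layout requires columns gene, sample, cq")
    colnames(tab) <- tolower(colnames(tab))
    key <- paste(tab$gene, tab$sample, sep = "\r")
    if (anyDuplicated(key)) {
      d <- tab[duplicated(key), , drop = FALSE][1, ]
      stop(sprintf("duplicate (gene, sample) pair: ('%s', '%s')", d$gene, d$sample))
    }
    genes <- unique(tab$gene)
    samples <- unique(tab$sample)
    vals <- matrix(NA_real_, length(genes), length(samples),
                   dimnames = list(genes, samples))
    vals[cbind(match(tab$gene, genes), match(tab$sample, samples))] <-
      .parse_cq_cell(tab$cq, missing_policy, max_cycles)
  }
  cq_matrix(vals, max_cycles = max_cycles)
}

#' Write an analysis result to file
#'
#' Generic report writer. Tabular results go to TSV/CSV with a deterministic
#' column order and numeric fields at 6 significant digits; nested results
#' (e.g. ROC curves) serialise to JSON.
#'
#' @param result a result object (data.frame, `stability_fit`, `roc_result`,
#'   or any list for JSON).
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return invisibly, the path written.
#' @export
write_report <- function(result, path, format = c("tsv", "json")) {
  UseMethod("write_report")
}

.fmt_num <- function(df) {
  for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  df
}

#' @export
write_report.data.frame <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.table(.fmt_num(as.data.frame(result)), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @export
write_report.stability_fit <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- result$table[, c("gene", "M", "normfinder_stability",
                          "genorm_rank", "normfinder_rank", "comprehensive_rank")]
  if (format == "json") {
    jsonlite::write_json(list(ranking = tab,
                              pairwise_variation = result$pairwise_variation,
                              recommended_n = result$recommended_n,
                              most_stable_pair = result$most_stable_pair),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    write_report.data.frame(tab, path, "tsv")
  }
  invisible(path)
}

#' @export
write_report.roc_result <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write_report.data.frame(as.data.frame(result$curve), path, "tsv")
  } else {
    out <- result[c("auc", "ci_low", "ci_high", "p", "cutoff", "sensitivity",
                    "specificity", "youden_J", "direction", "flipped",
                    "n_case", "n_control")]
    out$curve <- as.data.frame(result$curve)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' @export
write_report.default <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv" && is.list(result) && !is.null(result$table))
    return(write_report.data.frame(as.data.frame(result$table), path, "tsv"))
  jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a Cq matrix to file (wide layout)
#'
#' @param cq a [cq_matrix()].
#' @param path output path (`.csv` or `.tsv`).
#' @return invisibly, the path.
#' @export
write_cq_table <- function(cq, path) {
  sep <- .infer_sep(path)
  df <- data.frame(gene = rownames(cq), unclass(cq), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
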