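#' Hemolysis index per sample
#'
#' Red blood cells are rich in miR-451a while miR-23a-3p is unaffected by
#' hemolysis, so the Cq difference Cq(miR-23a-3p) - Cq(miR-451a) grows when a
#' serum sample is contaminated by lysed erythrocytes. A sample passes iff its
#' index is strictly below `threshold` (default 7 cycles); the boundary value
#' itself fails.
#'
#' @param cq a [cq_matrix()].
#' @param gene_23a,gene_451a names of the two marker genes in `cq`. miRNA
#'   naming varies between assay vendors (miR-451a vs miR-451a-5p), so the
#'   names are explicit arguments rather than resolved internally.
#' @param threshold pass threshold in cycles (strict `<`).
#' @return data.frame with `sample_id`, `hemolysis_delta` (cycles) and
#'   `hemolysis_pass`.
#' @export
hemolysis_index <- function(cq, gene_23a = "miR-23a-3p", gene_451a = "miR-451a",
                            threshold = 7) {
  for (g in c(gene_23a, gene_451a)) {
    if (!g %in% rownames(cq))
      stop("gene '", g, "' not found; available genes: ",
           paste(rownames(cq), collapse = ", "))
  }
  delta <- as.numeric(cq[gene_23a, ]) - as.numeric(cq[gene_451a, ])
  if (anyNA(delta))
    stop("hemolysis markers have undetermined Cq in samples: ",
         paste(colnames(cq)[is.na(delta)], collapse = ", "))
  data.frame(sample_id = colnames(cq),
             hemolysis_delta = delta,
             hemolysis_pass = delta < threshold,
             stringsAsFactors = FALSE)
}

#' Spike-in consistency check
#'
#' A synthetic exogenous RNA (cel-miR-39) spiked into each sample before
#' extraction should yield near-constant Cq across samples; large deviations
#' flag failed isolation or reverse transcription. A sample passes iff its Cq
#' deviates from the across-sample median by at most `max_abs_dev` cycles.
#'
#' @param cq a [cq_matrix()].
#' @param spikein_gene name of the spike-in control in `cq`.
#' @param max_abs_dev maximum allowed |Cq - median| in cycles (default 1.5).
#' @return data.frame with `sample_id`, `spikein_cq`, `spikein_dev` and
#'   `spikein_pass`; attributes `median` and `sd`.
#' @export
spikein_check <- function(cq, spikein_gene = "cel-miR-39", max_abs_dev = 1.5) {
  if (!spikein_gene %in% rownames(cq))
    stop("gene '", spikein_gene, "' not found; available genes: ",
         paste(rownames(cq), collapse = ", "))
  v <- as.numeric(cq[spikein_gene, ])
  if (anyNA(v))
    stop("spike-in has undetermined Cq in samples: ",
         paste(colnames(cq)[is.na(v)], collapse = ", "))
  if (length(v) < 3) {
    warning("fewer than 3 samples: spike-in median is unstable, all samples pass")
    out <- data.frame(sample_id = colnames(cq), spikein_cq = v,
                      spikein_dev = 0, spikein_pass = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    med <- stats::median(v)
    dev <- abs(v - med)
    out <- data.frame(sample_id = colnames(cq), spikein_cq = v,
                      spikein_dev = dev, spikein_pass = dev <= max_abs_dev,
                      stringsAsFactors = FALSE)
    attr(out, "median") <- med
  }
  attr(out, "sd") <- stats::sd(v)
  out
}

#' Full sample-level QC report
#'
#' Combines the hemolysis index and the spike-in consistency check; a sample
#' passes overall iff it passes every check that was run. QC operates on raw
#' Cq, before any normalisation, because the hemolysis markers are themselves
#' miRNAs.
#'
#' @inheritParams hemolysis_index
#' @inheritParams spikein_check
#' @param spikein_gene spike-in gene name, or `NULL` to skip that check.
#' @return a `qc_report`: data.frame of per-sample results with a `pass`
#'   column and summary counts in attributes.
#' @export
qc_report <- function(cq, gene_23a = "miR-23a-3p", gene_451a = "miR-451a",
                      threshold = 7, spikein_gene = "cel-miR-39",
                      max_abs_dev = 1.5) {
  hem <- hemolysis_index(cq, gene_23a, gene_451a, threshold)
  out <- hem
  if (!is.null(spikein_gene)) {
    sp <- spikein_check(cq, spikein_gene, max_abs_dev)
    out <- merge(hem, sp, by = "sample_id", sort = FALSE)
    out$pass <- out$hemolysis_pass & out$spikein_pass
  } else {
    out$pass <- out$hemolysis_pass
  }
  out <- out[match(colnames(cq), out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_samples") <- nrow(out)
  attr(out, "n_pass") <- sum(out$pass)
  class(out) <- c("qc_report", "data.frame")
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d/%d samples pass\n",
              attr(x, "n_pass"), attr(x, "n_samples")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Drop QC-failing samples from a Cq matrix
#'
#' Samples failing any QC check are excluded from all downstream group
#' statistics. Filtering is idempotent: re-running QC on an already filtered
#' matrix removes nothing.
#'
#' @param cq a [cq_matrix()].
#' @param report a [qc_report()] for the same samples.
#' @return the filtered `cq_matrix`.
#' @export
qc_filter <- function(cq, report) {
  keep <- report$sample_id[report$pass]
  cq[, colnames(cq) %in% keep, drop = FALSE]
}
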