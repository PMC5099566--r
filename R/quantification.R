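#' Relative quantification by the 2^-ddCt method
#'
#' Per sample, the reference Cq is the arithmetic mean of the reference
#' genes' Cq (equivalent to a geometric-mean normalisation factor in linear
#' space); dCq = Cq_target - Cq_ref. ddCq is dCq minus the calibrator
#' reference point — by default the mean dCq over the calibrator group's
#' samples, or a single named calibrator sample. Relative expression is
#' E^-ddCq, so with E = 2 a ddCq of -1 is a two-fold increase and the
#' calibrator group's geometric-mean relative expression is exactly 1.
#'
#' Because dCq subtracts the reference genes' Cq within the same sample, a
#' global per-sample Cq shift (pipetting / input-amount variation) cancels:
#' this is the normalisation contract of the method.
#'
#' @param cq a [cq_matrix()] with complete Cq for the listed genes.
#' @param targets target gene names.
#' @param refs reference gene names (disjoint from `targets`).
#' @param ann a [sample_annotation()] giving each sample's group.
#' @param calibrator group name used as the calibrator.
#' @param efficiency amplification efficiency E (default 2).
#' @param calibrator_sample optional single sample id to calibrate against
#'   instead of the calibrator group mean.
#' @return a `rel_expr_table` with matrices `dcq`, `ddcq`, `rel_expr`
#'   (targets x samples) and the fit metadata.
#' @export
delta_delta_ct <- function(cq, targets, refs, ann, calibrator,
                           efficiency = 2, calibrator_sample = NULL) {
  if (length(intersect(targets, refs)))
    stop("targets and refs must be disjoint; overlapping: ",
         paste(intersect(targets, refs), collapse = ", "))
  missing <- setdiff(c(targets, refs), rownames(cq))
  if (length(missing))
    stop("genes not in Cq matrix: ", paste(missing, collapse = ", "))
  sub <- cq[c(targets, refs), , drop = FALSE]
  if (anyNA(sub)) stop("missing Cq among targets/refs; resolve via missing_policy")
  ann <- align_annotation(ann, cq)
  cal_idx <- which(ann$group == calibrator)
  if (!length(cal_idx)) stop("empty calibrator group '", calibrator, "'")

  ref_cq <- colMeans(unclass(cq)[refs, , drop = FALSE])
  dcq <- unclass(cq)[targets, , drop = FALSE] -
    rep(ref_cq, each = length(targets))
  if (is.null(calibrator_sample)) {
    cal <- rowMeans(dcq[, cal_idx, drop = FALSE])
  } else {
    if (!calibrator_sample %in% colnames(cq))
      stop("calibrator sample '", calibrator_sample, "' not found")
    cal <- dcq[, calibrator_sample]
  }
  ddcq <- dcq - cal
  rel <- efficiency^(-ddcq)
  structure(list(dcq = dcq, ddcq = ddcq, rel_expr = rel,
                 targets = targets, refs = refs, calibrator = calibrator,
                 efficiency = efficiency, annotation = ann),
            class = "rel_expr_table")
}

#' @export
print.rel_expr_table <- function(x, ...) {
  cat(sprintf("Relative expression (E = %g, refs: %s, calibrator: %s)\n",
              x$efficiency, paste(x$refs, collapse = " + "), x$calibrator))
  grp <- split(seq_len(ncol(x$rel_expr)), x$annotation$group)
  means <- sapply(grp, function(i) rowMeans(x$rel_expr[, i, drop = FALSE]))
  means <- matrix(means, nrow = nrow(x$rel_expr),
                  dimnames = list(rownames(x$rel_expr), names(grp)))
  cat("Group mean fold changes:\n")
  print(signif(means, 4), ...)
  invisible(x)
}

#' @export
as.data.frame.rel_expr_table <- function(x, ...) {
  data.frame(gene = rep(rownames(x$rel_expr), ncol(x$rel_expr)),
             sample_id = rep(colnames(x$rel_expr), each = nrow(x$rel_expr)),
             group = rep(x$annotation$group, each = nrow(x$rel_expr)),
             dcq = as.numeric(x$dcq), ddcq = as.numeric(x$ddcq),
             rel_expr = as.numeric(x$rel_expr),
             stringsAsFactors = FALSE)
}
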