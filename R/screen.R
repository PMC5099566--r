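# Welch t on log2 intensities, safe on (near-)constant input: when both
# groups are constant the test is undefined, so return p = 1 for equal means
# and p = 0 otherwise.
.welch_log2_p <- function(a, b, pseudocount = 1) {
  la <- log2(a + pseudocount); lb <- log2(b + pseudocount)
  if (stats::sd(la) == 0 && stats::sd(lb) == 0)
    return(if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0)
  tryCatch(stats::t.test(la, lb)$p.value, error = function(e) 1)
}

.two_groups <- function(expr, ann) {
  ann <- align_annotation(ann, expr)
  groups <- unique(ann$group)
  if (length(groups) != 2)
    stop("exactly 2 groups required, got: ", paste(groups, collapse = ", "))
  tab <- table(ann$group)
  if (any(tab < 2)) stop("each group needs >= 2 samples")
  list(ann = ann, groups = groups)
}

.cv <- function(x) {
  m <- mean(x)
  if (m == 0) return(Inf)   # undefined CV counts as a fail
  stats::sd(x) / m
}

#' Select candidate reference genes from an expression matrix
#'
#' Screens genes by three criteria: (1) highly expressed in all samples —
#' detected (intensity > 0) in at least `min_detect_frac` of samples and
#' pooled mean at or above the `expr_quantile` quantile of gene means;
#' (2) no differential expression between the two groups — two-sided Welch t
#' on log2 intensities with p > `de_p_floor`; (3) low variation within and
#' between groups — the gene's worst coefficient of variation (max of pooled
#' and per-group CV, computed on linear intensities) ranks within the
#' `cv_rank_k` smallest among genes passing (1)-(2). Candidates are returned
#' sorted by worst CV ascending; ties keep input order.
#'
#' @param expr an [intensity_matrix()].
#' @param ann a [sample_annotation()] with exactly 2 groups, >= 2 samples each.
#' @param min_detect_frac minimum fraction of samples with intensity > 0.
#' @param expr_quantile quantile of gene means defining "highly expressed".
#' @param de_p_floor genes with DE p at or below this fail criterion 2.
#' @param cv_rank_k number of candidates retained by the CV ranking.
#' @param pseudocount added before log2 for the t-test.
#' @return a `candidate_selection`: per-gene data.frame (means, detection
#'   fraction, DE p, CVs, per-criterion flags) with the final candidate list
#'   in `attr(, "candidates")`.
#' @export
select_candidates <- function(expr, ann, min_detect_frac = 1.0,
                              expr_quantile = 0.75, de_p_floor = 0.05,
                              cv_rank_k = 10, pseudocount = 1) {
  tg <- .two_groups(expr, ann)
  ann <- tg$ann; groups <- tg$groups
  if (all(apply(expr, 1, stats::sd) == 0) && stats::sd(rowMeans(expr)) == 0 &&
      all(expr == 0))
    stop("degenerate all-zero expression matrix")
  i1 <- ann$group == groups[1]; i2 <- ann$group == groups[2]

  detect_frac <- rowMeans(expr > 0)
  pooled_mean <- rowMeans(expr)
  mean_cut <- stats::quantile(pooled_mean, expr_quantile, names = FALSE)
  crit1 <- detect_frac >= min_detect_frac & pooled_mean >= mean_cut

  de_p <- apply(expr, 1, function(x) .welch_log2_p(x[i1], x[i2], pseudocount))
  crit2 <- de_p > de_p_floor

  cv_pooled <- apply(expr, 1, .cv)
  cv_g1 <- apply(expr[, i1, drop = FALSE], 1, .cv)
  cv_g2 <- apply(expr[, i2, drop = FALSE], 1, .cv)
  worst_cv <- pmax(cv_pooled, cv_g1, cv_g2)

  eligible <- which(crit1 & crit2)
  ord <- eligible[order(worst_cv[eligible])]   # stable sort keeps input order on ties
  candidates <- rownames(expr)[utils::head(ord, cv_rank_k)]
  crit3 <- rownames(expr) %in% candidates

  tab <- data.frame(gene = rownames(expr),
                    mean_pooled = pooled_mean,
                    mean_g1 = rowMeans(expr[, i1, drop = FALSE]),
                    mean_g2 = rowMeans(expr[, i2, drop = FALSE]),
                    detect_frac = detect_frac, de_p = de_p,
                    cv_pooled = cv_pooled, cv_intra_g1 = cv_g1,
                    cv_intra_g2 = cv_g2, worst_cv = worst_cv,
                    pass_expressed = crit1, pass_stable_de = crit2,
                    pass_cv = crit3,
                    candidate = crit1 & crit2 & crit3,
                    stringsAsFactors = FALSE)
  names(tab)[names(tab) == "mean_g1"] <- paste0("mean_", groups[1])
  names(tab)[names(tab) == "mean_g2"] <- paste0("mean_", groups[2])
  names(tab)[names(tab) == "cv_intra_g1"] <- paste0("cv_", groups[1])
  names(tab)[names(tab) == "cv_intra_g2"] <- paste0("cv_", groups[2])
  rownames(tab) <- NULL
  attr(tab, "candidates") <- candidates
  class(tab) <- c("candidate_selection", "data.frame")
  tab
}

#' @export
print.candidate_selection <- function(x, ...) {
  cand <- attr(x, "candidates")
  cat(sprintf("Candidate reference genes (%d of %d genes):\n  %s\n",
              length(cand), nrow(x), paste(cand, collapse = ", ")))
  invisible(x)
}

#' Two-group differential expression with fold-change and p-value thresholds
#'
#' Per gene: linear fold change FC = mean(case)/mean(control), two-sided
#' Welch t on log2(intensity + pseudocount), Benjamini-Hochberg adjusted p
#' reported alongside. A gene is significant iff FC >= `fc_thresh` or
#' FC <= 1/`fc_thresh` (boundary inclusive) AND raw p <= `p_thresh`; the
#' filter deliberately uses the raw p, with the BH column provided for
#' transparency. A zero control mean with a nonzero case mean yields an
#' infinite FC: the gene is flagged (`fc_finite = FALSE`) and excluded from
#' the significant set.
#'
#' @param expr an [intensity_matrix()].
#' @param ann a [sample_annotation()] with exactly two groups.
#' @param case,control group labels; default control = first group in the
#'   annotation, case = the other.
#' @param fc_thresh linear fold-change threshold (default 2).
#' @param p_thresh raw p-value threshold (default 0.05).
#' @param pseudocount added before log2.
#' @return a `diff_expr_table` data.frame: gene, fc, log2fc, p, p_adj,
#'   direction, fc_finite, significant.
#' @export
differential_expression <- function(expr, ann, case = NULL, control = NULL,
                                    fc_thresh = 2, p_thresh = 0.05,
                                    pseudocount = 1) {
  tg <- .two_groups(expr, ann)
  ann <- tg$ann; groups <- tg$groups
  if (is.null(control)) control <- groups[1]
  if (is.null(case)) case <- setdiff(groups, control)
  if (!all(c(case, control) %in% groups))
    stop("case/control must be among groups: ", paste(groups, collapse = ", "))
  ic <- ann$group == case; ik <- ann$group == control

  mc <- rowMeans(expr[, ic, drop = FALSE])
  mk <- rowMeans(expr[, ik, drop = FALSE])
  fc <- mc / mk
  fc[mc == 0 & mk == 0] <- 1
  p <- apply(expr, 1, function(x) .welch_log2_p(x[ic], x[ik], pseudocount))
  fin <- is.finite(fc)
  sig <- fin & (fc >= fc_thresh | fc <= 1 / fc_thresh) & p <= p_thresh
  out <- data.frame(gene = rownames(expr), fc = fc, log2fc = log2(fc),
                    p = p, p_adj = stats::p.adjust(p, "BH"),
                    direction = ifelse(fc >= 1, "up", "down"),
                    fc_finite = fin, significant = sig,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "case") <- case
  attr(out, "control") <- control
  class(out) <- c("diff_expr_table", "data.frame")
  out
}
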