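.anova_oneway <- function(y, g) {
  g <- factor(g)
  ni <- tabulate(g)
  k <- nlevels(g)
  n <- length(y)
  gm <- mean(y)
  mi <- tapply(y, g, mean)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((y - mi[g])^2)
  if (ssw == 0 && ssb == 0) return(c(F = 0, p = 1))
  if (ssw == 0) return(c(F = Inf, p = 0))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  c(F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

#' Group comparison of relative expression
#'
#' Per gene: group means and SDs of the relative expression, a one-way ANOVA
#' F test across all groups, and pairwise two-sided Welch t tests of each
#' non-control group against the control with Holm adjustment within gene.
#'
#' @param rel a `rel_expr_table` from [delta_delta_ct()], or a numeric matrix
#'   (genes x samples).
#' @param ann a [sample_annotation()]; ignored (taken from `rel`) when `rel`
#'   is a `rel_expr_table`.
#' @param control name of the control group for the pairwise contrasts.
#' @return a `group_test_table` data.frame: one row per gene x non-control
#'   group with group mean, sd, ANOVA F and p (repeated within gene), Welch
#'   p, Holm-adjusted p and significance stars.
#' @export
group_compare <- function(rel, ann = NULL, control) {
  if (inherits(rel, "rel_expr_table")) {
    ann <- rel$annotation
    rel <- rel$rel_expr
  } else {
    ann <- align_annotation(ann, rel)
  }
  g <- ann$group
  lev <- unique(g)
  if (!control %in% lev) stop("control group '", control, "' not found")
  if (length(lev) < 2) stop("need >= 2 groups")
  if (any(table(g) < 2)) stop("every group needs >= 2 samples")
  others <- setdiff(lev, control)
  rows <- list()
  for (i in seq_len(nrow(rel))) {
    y <- as.numeric(rel[i, ])
    av <- .anova_oneway(y, g)
    pw <- vapply(others, function(gr) {
      a <- y[g == gr]; b <- y[g == control]
      if (stats::sd(a) == 0 && stats::sd(b) == 0)
        return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
      tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    }, numeric(1))
    padj <- stats::p.adjust(pw, "holm")
    rows[[i]] <- data.frame(
      gene = rownames(rel)[i], group = others,
      mean = vapply(others, function(gr) mean(y[g == gr]), numeric(1)),
      sd = vapply(others, function(gr) stats::sd(y[g == gr]), numeric(1)),
      control_mean = mean(y[g == control]),
      control_sd = stats::sd(y[g == control]),
      anova_F = av["F"], anova_p = av["p"],
      p = pw, p_holm = padj,
      stars = ifelse(padj < 0.001, "***",
                     ifelse(padj < 0.01, "**", ifelse(padj < 0.05, "*", ""))),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "control") <- control
  class(out) <- c("group_test_table", "data.frame")
  out
}

# Placement values: for each case score, the fraction of control scores it
# beats (ties count 1/2), and vice versa. AUC is their common mean.
.placements <- function(cases, controls) {
  v10 <- vapply(cases, function(x)
    mean((x > controls) + 0.5 * (x == controls)), numeric(1))
  v01 <- vapply(controls, function(y)
    mean((cases > y) + 0.5 * (cases == y)), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' ROC analysis with DeLong inference
#'
#' Builds the empirical ROC curve over all distinct score thresholds,
#' computes the AUC by trapezoidal integration (identical to the
#' Mann-Whitney estimator with ties counted 1/2), a 95 percent confidence
#' interval and a p-value against AUC = 0.5 by DeLong's paired nonparametric
#' variance (or a stratified bootstrap), and the Youden-optimal operating
#' point.
#'
#' Orientation: `"high"` treats high scores as case-like, `"low"` the
#' opposite (circulating biomarkers that fall in disease). `"auto"` starts
#' from `"high"` and flips when the resulting AUC is below 0.5, recording
#' the flip in `$flipped`.
#'
#' @param scores numeric marker values, one per sample.
#' @param labels case/control labels: logical (`TRUE` = case), 0/1, or a
#'   factor/character with `positive` naming the case level.
#' @param orientation `"auto"`, `"high"` or `"low"`.
#' @param positive case level when `labels` is a factor/character.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param conf_level confidence level (default 0.95).
#' @param n_boot bootstrap replicates when `ci_method = "bootstrap"`.
#' @return a `roc_result`: `auc`, `ci_low`, `ci_high`, `p`, `curve`
#'   (data.frame fpr/sensitivity from (0,0) to (1,1)), `cutoff`,
#'   `sensitivity` and `specificity` in percent, `youden_J`, `direction`
#'   (`">="` or `"<="`: the side of the cutoff called case, in the original
#'   score space), `flipped`, and the class counts.
#' @export
roc_analysis <- function(scores, labels, orientation = c("auto", "high", "low"),
                         positive = NULL, ci_method = c("delong", "bootstrap"),
                         conf_level = 0.95, n_boot = 2000) {
  orientation <- match.arg(orientation)
  ci_method <- match.arg(ci_method)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (is.logical(labels)) {
    is_case <- labels
  } else if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    is_case <- labels == 1
  } else {
    labels <- as.character(labels)
    if (is.null(positive)) positive <- sort(unique(labels))[length(unique(labels))]
    is_case <- labels == positive
  }
  if (!any(is_case) || all(is_case)) stop("both classes must be present")

  flip_score <- function(s) -s
  oriented <- scores
  flipped <- FALSE
  if (orientation == "low") {
    oriented <- flip_score(scores); flipped <- TRUE
  } else if (orientation == "auto") {
    pl <- .placements(scores[is_case], scores[!is_case])
    if (mean(pl$v10) < 0.5) { oriented <- flip_score(scores); flipped <- TRUE }
  }
  cases <- oriented[is_case]; controls <- oriented[!is_case]
  m <- length(cases); n <- length(controls)
  pl <- .placements(cases, controls)
  auc <- mean(pl$v10)

  # empirical curve: predict case when oriented score >= threshold
  thr <- sort(unique(oriented), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(cases >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(controls >= t), numeric(1))
  curve <- data.frame(fpr = c(0, fpr, 1), sensitivity = c(0, sens, 1))

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (ci_method == "delong") {
    s2 <- stats::var(pl$v10) / m + stats::var(pl$v01) / n
    se <- sqrt(s2)
    if (se == 0) {
      ci <- c(auc, auc)
      p <- if (auc == 0.5) 1 else 0
    } else {
      ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * se))
      p <- 2 * stats::pnorm(-abs((auc - 0.5) / se))
    }
  } else {
    reps <- vapply(seq_len(n_boot), function(i) {
      bc <- sample(cases, m, replace = TRUE)
      bk <- sample(controls, n, replace = TRUE)
      mean(.placements(bc, bk)$v10)
    }, numeric(1))
    ci <- as.numeric(stats::quantile(reps, c((1 - conf_level) / 2,
                                             1 - (1 - conf_level) / 2)))
    p <- 2 * min(mean(reps <= 0.5), mean(reps >= 0.5))
    p <- min(1, max(p, 1 / n_boot))
  }

  cut <- .youden_scan(cases, controls)
  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2], p = p,
                 curve = curve,
                 cutoff = if (flipped) -cut$cutoff else cut$cutoff,
                 sensitivity = 100 * cut$sens, specificity = 100 * cut$spec,
                 youden_J = cut$J,
                 direction = if (flipped) "<=" else ">=",
                 flipped = flipped, n_case = m, n_control = n,
                 conf_level = conf_level, ci_method = ci_method,
                 oriented_scores = oriented, is_case = is_case),
            class = "roc_result")
}

# Scan all thresholds (midpoints between adjacent distinct oriented scores,
# plus sentinels beyond the range); predict case when score >= threshold.
# Ties on J broken by higher sensitivity, then lower threshold.
.youden_scan <- function(cases, controls) {
  s <- sort(unique(c(cases, controls)))
  cand <- if (length(s) == 1) c(s[1] - 1, s[1] + 1) else
    c(s[1] - 1, (s[-length(s)] + s[-1]) / 2, s[length(s)] + 1)
  best <- NULL
  for (t in cand) {
    sens <- mean(cases >= t); spec <- mean(controls < t)
    J <- sens + spec - 1
    if (is.null(best) || J > best$J + 1e-12 ||
        (abs(J - best$J) <= 1e-12 &&
         (sens > best$sens + 1e-12 ||
          (abs(sens - best$sens) <= 1e-12 && t < best$cutoff)))) {
      best <- list(cutoff = t, sens = sens, spec = spec, J = J)
    }
  }
  best
}

#' Youden-optimal operating point of a ROC result
#'
#' @param roc a `roc_result` from [roc_analysis()].
#' @return list with `cutoff`, `sensitivity` and `specificity` (percent) and
#'   `youden_J`, plus the `direction` of the call.
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  roc[c("cutoff", "sensitivity", "specificity", "youden_J", "direction")]
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC analysis (%d cases vs %d controls%s)\n", x$n_case,
              x$n_control, if (x$flipped) ", low scores predict case" else ""))
  cat(sprintf("AUC = %.3f (%.0f%% CI %.3f-%.3f, p = %.4g, %s)\n",
              x$auc, 100 * x$conf_level, x$ci_low, x$ci_high, x$p, x$ci_method))
  cat(sprintf("Optimal cutoff (Youden): case if score %s %.4g; sensitivity %.1f%%, specificity %.1f%%, J = %.3f\n",
              x$direction, x$cutoff, x$sensitivity, x$specificity, x$youden_J))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = sprintf("ROC, AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Covariate-adjusted (partial) correlation
#'
#' Correlation between a marker and a continuous outcome after removing the
#' linear effects of covariates from both: each variable is regressed on the
#' covariates (with intercept) and the residuals are Pearson-correlated. The
#' p-value uses t = r sqrt(df / (1 - r^2)) with df = n - 2 - k, two-sided.
#' With no covariates this is exactly the Pearson correlation.
#'
#' @param x numeric marker values per sample.
#' @param y numeric outcome per sample (e.g. BMD in g/cm2).
#' @param covars optional data.frame/matrix of numeric covariates.
#' @return an `adjusted_correlation` list: `r`, `p`, `n`, `df`, `covariates`.
#' @export
adjusted_correlation <- function(x, y, covars = NULL) {
  if (length(x) != length(y)) stop("x and y differ in length")
  k <- 0L
  if (!is.null(covars)) {
    covars <- as.matrix(as.data.frame(covars))
    if (nrow(covars) != length(x)) stop("covars must have one row per sample")
    k <- ncol(covars)
  }
  cc <- stats::complete.cases(x, y, if (is.null(covars)) rep(TRUE, length(x)) else covars)
  x <- x[cc]; y <- y[cc]
  if (!is.null(covars)) covars <- covars[cc, , drop = FALSE]
  n <- length(x)
  df <- n - 2L - k
  if (df <= 0) stop("too few complete cases: df = n - 2 - k = ", df)
  if (k > 0) {
    X <- cbind(1, covars)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      dep <- colnames(covars)[qx$pivot[seq(qx$rank + 1, ncol(X))] - 1]
      stop("collinear covariates: ", paste(dep, collapse = ", "))
    }
    rx <- stats::lsfit(covars, x)$residuals
    ry <- stats::lsfit(covars, y)$residuals
  } else {
    rx <- x - mean(x); ry <- y - mean(y)
  }
  r <- stats::cor(rx, ry)
  tval <- r * sqrt(df / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(tval), df)
  structure(list(r = r, p = p, n = n, df = df,
                 covariates = if (k) colnames(covars) else character(0)),
            class = "adjusted_correlation")
}

#' @export
print.adjusted_correlation <- function(x, ...) {
  adj <- if (length(x$covariates))
    paste0(" adjusted for ", paste(x$covariates, collapse = ", ")) else ""
  cat(sprintf("Partial correlation%s: r = %.3f, p = %.4g (n = %d, df = %d)\n",
              adj, x$r, x$p, x$n, x$df))
  invisible(x)
}
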