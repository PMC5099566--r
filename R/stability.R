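#' Convert Cq values to relative quantities
#'
#' Standard geNorm preprocessing: per gene, Q = E^(Cq_min - Cq) where Cq_min
#' is the gene's lowest Cq across samples and E the amplification efficiency
#' per cycle (2 = perfect doubling). Each gene's maximum quantity is 1.
#'
#' @param cq a [cq_matrix()] with complete (non-missing) values for every
#'   gene used.
#' @param efficiency amplification efficiency E (default 2).
#' @return a matrix of class `rq_matrix` of relative quantities in (0, 1],
#'   with attribute `efficiency`.
#' @export
cq_to_quantity <- function(cq, efficiency = 2) {
  if (efficiency <= 1) stop("efficiency must be > 1")
  if (anyNA(cq)) {
    bad <- rownames(cq)[apply(cq, 1, anyNA)]
    stop("missing Cq for gene(s) ", paste(bad, collapse = ", "),
         "; drop them or reread with read_cq_table(missing_policy = 'max_cycle')")
  }
  q <- efficiency^(apply(cq, 1, min) - unclass(cq))
  structure(q, efficiency = efficiency, class = c("rq_matrix", "matrix", "array"))
}

#' geNorm gene-stability measure M
#'
#' For each pair of genes (j, k), V_jk is the sample standard deviation
#' (n - 1 denominator) of log2(Q_j / Q_k) across samples; M_j is the mean of
#' V_jk over all k != j. Lower M means more stable. M is invariant to
#' per-gene rescaling of Q and to sample order.
#'
#' @param Q relative-quantity matrix (genes x samples), all values > 0.
#' @return named numeric vector of M values.
#' @export
genorm_m <- function(Q) {
  if (nrow(Q) < 2) stop("geNorm M needs >= 2 genes")
  if (ncol(Q) < 3) stop("geNorm M needs >= 3 samples")
  if (any(Q <= 0)) stop("all relative quantities must be > 0")
  lq <- log2(unclass(Q))
  G <- nrow(lq)
  V <- matrix(0, G, G)
  for (j in seq_len(G - 1)) {
    d <- lq[(j + 1):G, , drop = FALSE] - rep(lq[j, ], each = G - j)
    s <- apply(d, 1, stats::sd)
    V[j, (j + 1):G] <- s
    V[(j + 1):G, j] <- s
  }
  M <- rowSums(V) / (G - 1)
  names(M) <- rownames(Q)
  M
}

#' geNorm stepwise exclusion ranking
#'
#' Iteratively computes M on the surviving gene set and removes the gene with
#' the highest M until two genes remain; those two form the most stable pair.
#' Ties at any step are broken by input order (the earlier gene survives).
#' The final pair is assigned ranks 1 and 2 by their M on the full candidate
#' set (input order as last resort), so that ranks are a permutation of 1..G.
#'
#' @param Q relative-quantity matrix (genes x samples).
#' @return list with `ranks` (named integer vector), `exclusion_order`
#'   (genes in removal order, least stable first), `most_stable_pair`,
#'   `M` (per-gene M on the full set), and `M_at_removal`.
#' @export
genorm_rank <- function(Q) {
  G <- nrow(Q)
  if (G < 2) stop("need >= 2 genes")
  M_full <- if (G >= 2 && ncol(Q) >= 3) genorm_m(Q) else
    stats::setNames(rep(NA_real_, G), rownames(Q))
  if (G == 2) {
    ranks <- stats::setNames(c(1L, 2L), rownames(Q))
    return(list(ranks = ranks, exclusion_order = character(0),
                most_stable_pair = rownames(Q), M = M_full,
                M_at_removal = stats::setNames(numeric(0), character(0))))
  }
  surviving <- rownames(Q)
  excluded <- character(0)
  m_at_rem <- numeric(0)
  while (length(surviving) > 2) {
    M <- genorm_m(Q[surviving, , drop = FALSE])
    # which.max takes the first maximum -> earlier gene survives ties
    worst <- surviving[which.max(M)]
    m_at_rem <- c(m_at_rem, max(M))
    excluded <- c(excluded, worst)
    surviving <- setdiff(surviving, worst)
  }
  pair <- surviving[order(M_full[surviving])]  # stable: input order on ties
  ranks <- stats::setNames(integer(G), rownames(Q))
  ranks[pair] <- 1:2
  ranks[rev(excluded)] <- 3:G
  names(m_at_rem) <- excluded
  list(ranks = ranks, exclusion_order = excluded,
       most_stable_pair = pair, M = M_full, M_at_removal = m_at_rem)
}

#' geNorm pairwise variation V(n/n+1) and recommended reference count
#'
#' NF_n(sample) is the geometric mean of the relative quantities of the n
#' top-ranked genes. V(n/n+1) is the standard deviation across samples of
#' log2(NF_n / NF_(n+1)), for n = 2..G-1. The recommended number of reference
#' genes is the smallest n with V(n/n+1) below `v_threshold` (0.15 by the
#' original geNorm heuristic), or G if none.
#'
#' @param Q relative-quantity matrix (genes x samples).
#' @param ranked_genes gene names ordered most stable first (from
#'   [genorm_rank()]).
#' @param v_threshold cutoff on V (default 0.15).
#' @return list with `V` (named vector "V2/3", ...), `recommended_n`, and
#'   `nf` (samples x (G) matrix of log2 normalisation factors).
#' @export
pairwise_variation <- function(Q, ranked_genes, v_threshold = 0.15) {
  if (!all(ranked_genes %in% rownames(Q)))
    stop("ranked_genes must all be present in Q")
  G <- length(ranked_genes)
  if (G < 3) stop("pairwise variation needs >= 3 ranked genes")
  lq <- log2(unclass(Q)[ranked_genes, , drop = FALSE])
  # log2 NF_n per sample = mean of the top-n genes' log2 quantities
  lnf <- apply(lq, 2, cumsum) / seq_len(G)
  V <- vapply(2:(G - 1), function(n)
    stats::sd(lnf[n, ] - lnf[n + 1, ]), numeric(1))
  names(V) <- sprintf("V%d/%d", 2:(G - 1), 3:G)
  below <- which(V < v_threshold)
  recommended_n <- if (length(below)) below[1] + 1L else G
  list(V = V, recommended_n = as.integer(recommended_n), nf = t(lnf))
}

# Unbiased per-gene intragroup variance under two-way (gene + sample)
# centering with heterogeneous gene variances:
#   E[RSS_i / (n-1)] = sigma_i^2 (1 - 2/G) + sigma_bar^2 / G
# so sigma_hat_i^2 = (z_i - z_bar/(G-1)) * G/(G-2), floored at 0.
.nf_group_var <- function(y) {
  G <- nrow(y); n <- ncol(y)
  r <- y - rowMeans(y) - rep(colMeans(y), each = G) + mean(y)
  z <- rowSums(r^2) / (n - 1)
  pmax(0, (z - mean(z) / (G - 1)) * G / (G - 2))
}

#' NormFinder model-based stability
#'
#' Decomposes log-scale expression into intragroup variance and intergroup
#' deviation per gene. Each group's matrix is centered by gene and sample
#' means; intragroup variances are estimated with a small-sample bias
#' correction for the centering (negative estimates floored at 0). The
#' intergroup deviation d_ig is the gene-by-group interaction of the group
#' means, shrunk towards 0 by an empirical-Bayes factor tau^2/(tau^2 + v_ig)
#' where v_ig = sigma^2_ig/n_g is the sampling variance of d_ig and tau^2
#' the moment estimate of the true deviation variance across genes. The
#' stability value of gene i is the average over groups of
#' |d_shrunk_ig| + sqrt(v_ig); lower is more stable. With a single group the
#' stability reduces to the estimated intragroup standard deviation.
#'
#' @param log_expr matrix of log2-scale expression (genes x samples), e.g.
#'   `log2(cq_to_quantity(cq))`.
#' @param groups group label per sample (column), or `NULL` / a single level
#'   for single-group mode.
#' @return a `normfinder_fit` list: `stability` (named, lower = better),
#'   `rank`, `d` (shrunk intergroup deviations, genes x groups), `sigma2`
#'   (intragroup variances, genes x groups), `groups`.
#' @export
normfinder_stability <- function(log_expr, groups = NULL) {
  y <- as.matrix(log_expr)
  G <- nrow(y)
  if (G < 3) stop("NormFinder needs >= 3 genes")
  if (is.null(groups)) groups <- rep("all", ncol(y))
  groups <- as.character(groups)
  if (length(groups) != ncol(y)) stop("one group label per sample required")
  glev <- unique(groups)
  ng <- table(factor(groups, levels = glev))
  if (any(ng < 2)) stop("every group needs >= 2 samples, offending: ",
                        paste(names(ng)[ng < 2], collapse = ", "))
  K <- length(glev)

  sigma2 <- sapply(glev, function(g) .nf_group_var(y[, groups == g, drop = FALSE]))
  sigma2 <- matrix(sigma2, nrow = G, dimnames = list(rownames(y), glev))

  if (K == 1) {
    stab <- sqrt(sigma2[, 1])
    rk <- rank(stab, ties.method = "first")
    return(structure(list(stability = stab, rank = rk,
                          d = matrix(0, G, 1, dimnames = list(rownames(y), glev)),
                          sigma2 = sigma2, groups = glev),
                     class = "normfinder_fit"))
  }

  # gene-by-group interaction of sample-centered group means (groups unweighted)
  yc <- y - rep(colMeans(y), each = G)
  gm <- sapply(glev, function(g) rowMeans(yc[, groups == g, drop = FALSE]))
  gm <- matrix(gm, nrow = G)
  d_raw <- gm - rowMeans(gm) - rep(colMeans(gm), each = G) + mean(gm)
  v <- sweep(sigma2, 2, as.numeric(ng), "/")
  tau2 <- max(0, mean(d_raw^2) - mean(v))
  d <- d_raw * tau2 / (tau2 + v)
  d[tau2 == 0] <- 0
  dimnames(d) <- list(rownames(y), glev)

  stab <- rowMeans(abs(d) + sqrt(v))
  names(stab) <- rownames(y)
  rk <- rank(stab, ties.method = "first")
  structure(list(stability = stab, rank = rk, d = d, sigma2 = sigma2,
                 groups = glev),
            class = "normfinder_fit")
}

#' @export
print.normfinder_fit <- function(x, ...) {
  ord <- order(x$rank)
  cat("NormFinder stability (lower = more stable):\n")
  print(data.frame(gene = names(x$stability)[ord],
                   stability = signif(x$stability[ord], 4),
                   rank = x$rank[ord], row.names = NULL), ...)
  invisible(x)
}

#' Comprehensive ranking across geNorm and NormFinder
#'
#' Aggregates the two per-gene ranks by their geometric mean (the usual
#' comprehensive-ranking convention); genes are sorted by the aggregate score
#' ascending, with ties broken by lower geNorm M, then input order.
#'
#' @param genorm_ranks named integer vector of geNorm ranks.
#' @param normfinder_ranks named integer vector of NormFinder ranks over the
#'   same gene set.
#' @param M optional named vector of geNorm M values for tie-breaking.
#' @return data.frame: gene, genorm_rank, normfinder_rank, score,
#'   comprehensive_rank.
#' @export
aggregate_rank <- function(genorm_ranks, normfinder_ranks, M = NULL) {
  genes <- names(genorm_ranks)
  if (is.null(genes) || is.null(names(normfinder_ranks)))
    stop("rank vectors must be named by gene")
  if (!setequal(genes, names(normfinder_ranks)))
    stop("gene sets differ between the two rankings")
  nf <- normfinder_ranks[genes]
  score <- sqrt(as.numeric(genorm_ranks) * as.numeric(nf))
  tie_m <- if (is.null(M)) rep(0, length(genes)) else as.numeric(M[genes])
  ord <- order(score, tie_m, seq_along(genes))
  comp <- integer(length(genes))
  comp[ord] <- seq_along(genes)
  data.frame(gene = genes, genorm_rank = as.integer(genorm_ranks),
             normfinder_rank = as.integer(nf), score = score,
             comprehensive_rank = comp, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fit reference-gene stability (geNorm + NormFinder + aggregate)
#'
#' The package's central fit: transforms Cq to relative quantities, runs the
#' geNorm stepwise ranking with the pairwise-variation series, runs
#' NormFinder on the log2 quantities (grouped when an annotation is given),
#' and aggregates the two rankings into a comprehensive rank.
#'
#' @param cq a [cq_matrix()] of the candidate reference genes.
#' @param ann optional [sample_annotation()]; its `group` drives NormFinder's
#'   grouped mode.
#' @param genes optional subset of candidate gene names to rank.
#' @param efficiency amplification efficiency E (default 2).
#' @param v_threshold geNorm pairwise-variation cutoff (default 0.15).
#' @return a `stability_fit` with `table` (per-gene M, NormFinder stability,
#'   all three ranks), `pairwise_variation`, `recommended_n`,
#'   `most_stable_pair`, `exclusion_order`, `normfinder` and `Q`.
#' @export
reference_stability <- function(cq, ann = NULL, genes = NULL,
                                efficiency = 2, v_threshold = 0.15) {
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(cq))
    if (length(missing))
      stop("genes not in Cq matrix: ", paste(missing, collapse = ", "))
    cq <- cq[genes, , drop = FALSE]
  }
  drop <- apply(cq, 1, anyNA)
  if (any(drop)) {
    message("dropping gene(s) with missing Cq: ",
            paste(rownames(cq)[drop], collapse = ", "))
    cq <- cq[!drop, , drop = FALSE]
  }
  if (nrow(cq) < 3) stop("need >= 3 complete candidate genes")
  groups <- NULL
  if (!is.null(ann)) groups <- align_annotation(ann, cq)$group

  Q <- cq_to_quantity(cq, efficiency)
  gn <- genorm_rank(Q)
  ranked <- names(sort(gn$ranks))
  pv <- pairwise_variation(Q, ranked, v_threshold)
  nf <- normfinder_stability(log2(unclass(Q)), groups)
  agg <- aggregate_rank(gn$ranks, nf$rank, M = gn$M)

  tab <- data.frame(gene = agg$gene, M = as.numeric(gn$M[agg$gene]),
                    normfinder_stability = as.numeric(nf$stability[agg$gene]),
                    genorm_rank = agg$genorm_rank,
                    normfinder_rank = agg$normfinder_rank,
                    comprehensive_score = agg$score,
                    comprehensive_rank = agg$comprehensive_rank,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$comprehensive_rank), ]
  rownames(tab) <- NULL
  structure(list(table = tab, pairwise_variation = pv$V,
                 recommended_n = pv$recommended_n,
                 most_stable_pair = gn$most_stable_pair,
                 exclusion_order = gn$exclusion_order,
                 normfinder = nf, Q = Q, efficiency = efficiency,
                 v_threshold = v_threshold, groups = groups),
            class = "stability_fit")
}

#' @export
print.stability_fit <- function(x, ...) {
  cat(sprintf("Reference-gene stability fit: %d genes x %d samples\n",
              nrow(x$table), ncol(x$Q)))
  cat("Comprehensive ranking (rank 1 = recommended reference):\n")
  tab <- x$table
  tab$M <- signif(tab$M, 4)
  tab$normfinder_stability <- signif(tab$normfinder_stability, 4)
  tab$comprehensive_score <- signif(tab$comprehensive_score, 4)
  print(tab, ...)
  cat(sprintf("Most stable geNorm pair: %s\n",
              paste(x$most_stable_pair, collapse = " + ")))
  cat(sprintf("Recommended number of reference genes (V < %g): %d\n",
              x$v_threshold, x$recommended_n))
  invisible(x)
}

#' @export
summary.stability_fit <- function(object, ...) {
  structure(list(fit = object,
                 recommended = object$table$gene[1],
                 pair = object$most_stable_pair,
                 recommended_n = object$recommended_n,
                 V = object$pairwise_variation), class = "summary.stability_fit")
}

#' @export
print.summary.stability_fit <- function(x, ...) {
  cat("Recommended reference gene (comprehensive rank 1):", x$recommended, "\n")
  cat("geNorm most stable pair:", paste(x$pair, collapse = " + "), "\n")
  cat("Pairwise variation series:\n")
  print(signif(x$V, 4))
  cat("Optimal number of reference genes:", x$recommended_n, "\n")
  invisible(x)
}

#' @export
coef.stability_fit <- function(object, ...) {
  stats::setNames(object$table$normfinder_stability, object$table$gene)
}

#' Plot a stability fit
#'
#' Two base-graphics panels: per-gene geNorm M and NormFinder stability
#' (ordered least stable to most stable, the geNorm convention), and the
#' pairwise-variation series with the decision threshold.
#'
#' @param x a `stability_fit`.
#' @param ... further arguments passed to [graphics::barplot()].
#' @return invisibly, `x`.
#' @export
plot.stability_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op))
  tab <- x$table[order(-x$table$genorm_rank), ]
  graphics::barplot(tab$M, names.arg = tab$gene, las = 2,
                    ylab = "geNorm M", main = "Stability (least -> most stable)",
                    ...)
  graphics::barplot(x$pairwise_variation, las = 2, ylab = "V(n/n+1)",
                    main = "Pairwise variation")
  graphics::abline(h = x$v_threshold, lty = 2)
  invisible(x)
}
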