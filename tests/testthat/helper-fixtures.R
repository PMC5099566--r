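# Shared fixture builders. All randomness is seeded by the caller.

random_cq <- function(n_genes, n_samples, seed, base = 24, sd = 2) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * n_samples, base, sd), n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  cq_matrix(pmin(pmax(m, 1), 40))
}

random_Q <- function(n_genes, n_samples, seed) {
  cq_to_quantity(random_cq(n_genes, n_samples, seed))
}

two_group_ann <- function(n1, n2, labels = c("control", "case")) {
  sample_annotation(paste0("s", seq_len(n1 + n2)),
                    rep(labels, c(n1, n2)))
}

# Independent brute-force geNorm M: explicit double loop over gene pairs.
brute_genorm_m <- function(Q) {
  lq <- log2(unclass(Q))
  G <- nrow(lq)
  M <- numeric(G)
  for (j in seq_len(G)) {
    vs <- c()
    for (k in seq_len(G)) {
      if (k == j) next
      vs <- c(vs, stats::sd(lq[j, ] - lq[k, ]))
    }
    M[j] <- mean(vs)
  }
  stats::setNames(M, rownames(Q))
}

# Independent V(n/n+1): geometric means computed in the linear domain.
brute_pairwise_variation <- function(Q, ranked) {
  q <- unclass(Q)[ranked, , drop = FALSE]
  G <- nrow(q)
  sapply(2:(G - 1), function(n) {
    nf_n <- apply(q[1:n, , drop = FALSE], 2, function(x) prod(x)^(1 / n))
    nf_n1 <- apply(q[1:(n + 1), , drop = FALSE], 2,
                   function(x) prod(x)^(1 / (n + 1)))
    stats::sd(log2(nf_n / nf_n1))
  })
}

# Exhaustive pair-counting AUC with ties counted 1/2.
brute_auc <- function(cases, controls) {
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# Brute-force Youden scan over all midpoints with the documented tie rule.
brute_youden <- function(cases, controls) {
  s <- sort(unique(c(cases, controls)))
  cand <- if (length(s) == 1) c(s - 1, s + 1) else
    c(s[1] - 1, (s[-length(s)] + s[-1]) / 2, s[length(s)] + 1)
  res <- data.frame(t = cand,
                    sens = sapply(cand, function(t) mean(cases >= t)),
                    spec = sapply(cand, function(t) mean(controls < t)))
  res$J <- res$sens + res$spec - 1
  # round J before sorting so exact mathematical ties (which differ by ~1e-16
  # from summation order) fall through to the sensitivity tie rule
  res <- res[order(-round(res$J, 9), -res$sens, res$t), ]
  res[1, ]
}
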