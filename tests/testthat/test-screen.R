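# Independent re-implementation of the three candidate criteria, written
# directly from their definitions (no shared code with select_candidates).
brute_candidates <- function(expr, ann, k = 10, q = 0.75, p_floor = 0.05) {
  g <- ann$group[match(colnames(expr), ann$sample_id)]
  lev <- unique(g)
  pass12 <- cv <- rep(NA, nrow(expr))
  for (i in seq_len(nrow(expr))) {
    x <- expr[i, ]
    c1 <- all(x > 0) && mean(x) >= quantile(rowMeans(expr), q)
    p <- t.test(log2(x[g == lev[1]] + 1), log2(x[g == lev[2]] + 1))$p.value
    pass12[i] <- c1 && p > p_floor
    cv[i] <- max(sd(x) / mean(x),
                 sd(x[g == lev[1]]) / mean(x[g == lev[1]]),
                 sd(x[g == lev[2]]) / mean(x[g == lev[2]]))
  }
  ord <- order(cv)
  head(rownames(expr)[ord[pass12[ord]]], k)
}

test_that("candidate screening applies the three criteria", {
  set.seed(101)
  n_genes <- 20
  ann <- two_group_ann(4, 4)
  base <- runif(n_genes, 8, 12)
  lmat <- matrix(rnorm(n_genes * 8, 0, 0.4), n_genes, 8) + base
  # three designed stable, highly expressed genes with CV < 0.05
  lmat[1:3, ] <- 13 + matrix(rnorm(24, 0, 0.02), 3)
  # one gene with a clear group effect
  lmat[4, 5:8] <- lmat[4, 5:8] + 3
  dimnames(lmat) <- list(paste0("g", 1:n_genes), ann$sample_id)
  expr <- intensity_matrix(2^lmat)

  sel <- select_candidates(expr, ann, cv_rank_k = 5)
  cand <- attr(sel, "candidates")
  expect_equal(sort(cand[1:3]), c("g1", "g2", "g3"))
  expect_false("g4" %in% cand)
  expect_equal(cand, brute_candidates(expr, ann, k = 5))
  # the DE criterion excludes genes with p at or below the floor
  expect_true(all(sel$de_p[sel$gene %in% cand] > 0.05))
})

test_that("a constant matrix passes criteria 1-2 with input-order ties", {
  expr <- intensity_matrix(matrix(100, 12, 6,
    dimnames = list(paste0("g", 1:12), paste0("s", 1:6))))
  ann <- two_group_ann(3, 3)
  sel <- select_candidates(expr, ann, cv_rank_k = 10)
  expect_true(all(sel$pass_expressed))
  expect_true(all(sel$pass_stable_de))
  expect_equal(attr(sel, "candidates"), paste0("g", 1:10))
})

test_that("screening is invariant to sample and gene order", {
  sim <- simulate_intensity_matrix(n_genes = 30, seed = 5,
    de_genes = data.frame(gene = 1:3, fold = 3))
  sel <- select_candidates(sim$expr, sim$annotation, cv_rank_k = 5)
  perm_s <- sample(ncol(sim$expr))
  sel2 <- select_candidates(sim$expr[, perm_s], sim$annotation, cv_rank_k = 5)
  expect_equal(attr(sel, "candidates"), attr(sel2, "candidates"))
})

test_that("differential expression applies the fold and p thresholds", {
  sim <- simulate_intensity_matrix(n_per_group = c(control = 8, case = 8),
    n_genes = 60, de_genes = data.frame(gene = 1:5, fold = 2.5),
    sigma = 0.3, seed = 12)
  de <- differential_expression(sim$expr, sim$annotation,
                                case = "case", control = "control")
  # independent re-implementation of the filter
  g <- sim$annotation$group
  brute_sig <- vapply(seq_len(nrow(sim$expr)), function(i) {
    x <- sim$expr[i, ]
    fc <- mean(x[g == "case"]) / mean(x[g == "control"])
    p <- t.test(log2(x[g == "case"] + 1), log2(x[g == "control"] + 1))$p.value
    (fc >= 2 || fc <= 0.5) && p <= 0.05
  }, logical(1))
  expect_equal(de$significant, brute_sig)
  expect_true(all(sim$truth$de_genes %in% de$gene[de$significant]))
  # up + down = total significant
  expect_equal(sum(de$significant & de$direction == "up") +
               sum(de$significant & de$direction == "down"),
               sum(de$significant))
})

test_that("fold-change boundary FC = 2 is inclusive and null data yield nothing", {
  ann <- two_group_ann(4, 4)
  x <- c(10, 10.2, 9.9, 10.1)
  m <- rbind(gA = c(x, 2 * x)); colnames(m) <- ann$sample_id
  expr <- intensity_matrix(m)
  de <- differential_expression(expr, ann, case = "case", control = "control")
  expect_gte(de$fc, 2)
  expect_true(de$significant)

  # identical case/control profiles -> empty significant list
  m0 <- rbind(gA = rep(x, 2), gB = rep(2 * x, 2)); colnames(m0) <- ann$sample_id
  expr0 <- intensity_matrix(m0)
  de0 <- differential_expression(expr0, ann, case = "case", control = "control")
  expect_false(any(de0$significant))
})

test_that("fold changes are reciprocal under case/control swap", {
  sim <- simulate_intensity_matrix(n_genes = 25, seed = 3,
    de_genes = data.frame(gene = 1:4, fold = c(3, 0.4, 2, 0.5)))
  a <- differential_expression(sim$expr, sim$annotation,
                               case = "case", control = "control")
  b <- differential_expression(sim$expr, sim$annotation,
                               case = "control", control = "case")
  expect_equal(a$fc * b$fc, rep(1, nrow(a)))
})

test_that("a zero control mean yields a flagged infinite fold change", {
  ann <- two_group_ann(3, 3)
  mz <- rbind(gA = c(0, 0, 0, 5, 6, 7), gB = c(1, 2, 1, 2, 1, 2))
  colnames(mz) <- ann$sample_id
  expr <- intensity_matrix(mz)
  de <- differential_expression(expr, ann, case = "case", control = "control")
  expect_false(de$fc_finite[de$gene == "gA"])
  expect_false(de$significant[de$gene == "gA"])
})
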