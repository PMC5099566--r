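test_that("Cq-to-quantity transform follows Q = E^(Cqmin - Cq)", {
  m <- rbind(a = c(20, 20, 20), b = c(25, 26, 27))
  colnames(m) <- paste0("s", 1:3)
  cq <- cq_matrix(m)
  Q <- cq_to_quantity(cq)
  expect_equal(unclass(Q)["a", ], c(s1 = 1, s2 = 1, s3 = 1))
  expect_equal(unclass(Q)["b", ], c(s1 = 1, s2 = 0.5, s3 = 0.25))
  # log-domain cross-check at non-ideal efficiency
  Q19 <- cq_to_quantity(cq, efficiency = 1.9)
  expect_equal(unclass(Q19)["b", "s3"], exp(-2 * log(1.9)), tolerance = 1e-12)
  expect_equal(unclass(Q19)["b", "s3"], 1.9^-2)

  cq[1, 2] <- NA
  expect_error(cq_to_quantity(cq), "missing_policy")
})

test_that("geNorm M matches an independent brute-force pairwise-SD oracle", {
  for (seed in 1:5) {
    Q <- random_Q(3 + seed %% 4, 4 + seed, seed)
    expect_equal(genorm_m(Q), brute_genorm_m(Q), tolerance = 1e-10)
  }
})

test_that("geNorm M is zero for proportional genes and invariant to scaling", {
  q <- rbind(a = c(1, .5, .25, .8), b = 10 * c(1, .5, .25, .8))
  colnames(q) <- paste0("s", 1:4)
  M <- genorm_m(q)
  expect_equal(unname(M), c(0, 0))

  Q <- random_Q(5, 8, seed = 21)
  M1 <- genorm_m(Q)
  Q2 <- unclass(Q); Q2[3, ] <- Q2[3, ] * 10
  expect_equal(genorm_m(Q2), M1, tolerance = 1e-12)
  perm <- sample(ncol(Q))
  expect_equal(genorm_m(unclass(Q)[, perm]), M1, tolerance = 1e-12)
})

test_that("stepwise exclusion removes the noisiest gene first", {
  set.seed(31)
  n <- 10
  cqv <- rbind(matrix(rnorm(4 * n, 24, 0.3), 4), rnorm(n, 24, 1.5))
  dimnames(cqv) <- list(paste0("g", 1:5), paste0("s", 1:n))
  gr <- genorm_rank(cq_to_quantity(cq_matrix(pmin(pmax(cqv, 1), 40))))
  expect_equal(gr$exclusion_order[1], "g5")
  # full recomputation of every iteration by independent code
  Q <- cq_to_quantity(cq_matrix(pmin(pmax(cqv, 1), 40)))
  surv <- rownames(Q); excl <- character(0)
  while (length(surv) > 2) {
    M <- brute_genorm_m(unclass(Q)[surv, ])
    excl <- c(excl, names(which.max(M)))
    surv <- setdiff(surv, names(which.max(M)))
  }
  expect_equal(gr$exclusion_order, excl)
  expect_setequal(gr$most_stable_pair, surv)
  expect_equal(sort(unname(gr$ranks)), 1:5)
})

test_that("degenerate ranking inputs follow the documented rules", {
  Q2 <- random_Q(2, 5, seed = 41)
  gr <- genorm_rank(Q2)
  expect_equal(gr$most_stable_pair, rownames(Q2))
  expect_equal(gr$M[[1]], gr$M[[2]])

  # constant matrix: all M = 0, exclusion by input order (first max)
  qc_const <- matrix(1, 4, 5, dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  grc <- genorm_rank(qc_const)
  expect_equal(grc$exclusion_order, c("g1", "g2"))
  expect_equal(grc$most_stable_pair, c("g3", "g4"))
})

test_that("pairwise variation matches brute force and the decision rule", {
  Q <- random_Q(6, 10, seed = 51)
  gr <- genorm_rank(Q)
  ranked <- names(sort(gr$ranks))
  pv <- pairwise_variation(Q, ranked)
  expect_equal(unname(pv$V), brute_pairwise_variation(Q, ranked),
               tolerance = 1e-10)

  # a duplicate of NF_n as gene n+1 gives V = 0
  q <- unclass(random_Q(3, 6, seed = 52))
  nf3 <- apply(q, 2, function(x) prod(x)^(1 / 3))
  q4 <- rbind(q, g4 = nf3 / max(nf3))
  pv4 <- pairwise_variation(q4, rownames(q4))
  expect_equal(unname(pv4$V["V3/4"]), 0, tolerance = 1e-12)

  # recommended n is the first n with V < threshold
  expect_equal(
    pairwise_variation(q4, rownames(q4), v_threshold = 1e9)$recommended_n, 2L)
})

test_that("NormFinder single-group ranking follows the residual SD", {
  set.seed(61)
  n <- 40
  y <- rbind(g1 = rnorm(n, 0, 0.1), g2 = rnorm(n, 0, 0.5), g3 = rnorm(n, 0, 1))
  colnames(y) <- paste0("s", 1:n)
  nf <- normfinder_stability(y)
  expect_equal(unname(nf$rank[c("g1", "g2", "g3")]), c(1, 2, 3))

  # a gene whose centered values are constant (zero) within and across
  # groups: build the other genes with zero column sums per group so the
  # sample centering leaves the constant gene untouched
  grp <- rep(c("a", "b"), each = 12)
  noise <- matrix(rnorm(9 * 24, 0, 0.5), 9, 24)
  for (g in c("a", "b"))
    noise[, grp == g] <- sweep(noise[, grp == g], 2, colMeans(noise[, grp == g]))
  y2 <- rbind(noise, 0)
  dimnames(y2) <- list(paste0("g", 1:10), paste0("s", 1:24))
  nf2 <- normfinder_stability(y2, groups = grp)
  expect_equal(unname(nf2$rank["g10"]), 1)
  expect_equal(unname(nf2$stability["g10"]), 0, tolerance = 1e-12)
  expect_equal(unname(nf2$sigma2["g10", ]), c(0, 0), ignore_attr = TRUE)
  expect_true(all(nf2$sigma2 >= 0))
})

test_that("NormFinder recovers a designed stable gene and its variances", {
  # one designed stable gene (sigma 0.1, no group bias) among nine sigma-0.5
  # candidates whose group biases span up to 1 cycle in a balanced panel
  # (mean zero: the intergroup deviation is identified relative to the
  # panel average, so a net panel shift is not attributable to any gene)
  n_seeds <- 40
  rank1 <- logical(n_seeds)
  sig_est <- matrix(0, 10, 2)
  true_sigma <- c(0.1, rep(0.5, 9))
  bias <- cbind(0, c(0, seq(-1, 1, length.out = 9)))
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    y <- matrix(0, 10, 24, dimnames = list(paste0("g", 1:10), paste0("s", 1:24)))
    grp <- rep(c("a", "b"), each = 12)
    for (i in 1:10)
      y[i, ] <- bias[i, (grp == "b") + 1] + rnorm(24, 0, true_sigma[i])
    nf <- normfinder_stability(y, grp)
    rank1[s] <- nf$rank["g1"] == 1
    sig_est <- sig_est + nf$sigma2
  }
  expect_gte(mean(rank1), 0.9)
  # seed-averaged intragroup variance within 25% of truth
  rel_err <- abs(sig_est / n_seeds - true_sigma^2) / true_sigma^2
  expect_lt(mean(rel_err), 0.25)
})

test_that("comprehensive ranking is the geometric mean with M tie-break", {
  gr <- setNames(c(1L, 2L), c("A", "B"))
  nfr <- setNames(c(2L, 1L), c("A", "B"))
  M <- setNames(c(0.2, 0.3), c("A", "B"))
  agg <- aggregate_rank(gr, nfr, M)
  expect_equal(agg$score, rep(sqrt(2), 2))
  expect_equal(agg$comprehensive_rank[agg$gene == "A"], 1)

  # unanimity
  agg1 <- aggregate_rank(setNames(1:3, letters[1:3]), setNames(1:3, letters[1:3]))
  expect_equal(agg1$comprehensive_rank, 1:3)

  # seeded pairs against a brute-force sort
  set.seed(71)
  g <- setNames(sample(9), paste0("g", 1:9))
  n <- setNames(sample(9), paste0("g", 1:9))
  M9 <- setNames(runif(9), paste0("g", 1:9))
  agg9 <- aggregate_rank(g, n, M9)
  ord <- order(sqrt(g * n[names(g)]), M9[names(g)])
  expect_equal(agg9$gene[order(agg9$comprehensive_rank)], names(g)[ord])

  expect_error(aggregate_rank(g, setNames(1:9, paste0("x", 1:9))),
               "gene sets differ")
})

test_that("the stability fit is deterministic and permutation-invariant", {
  sim <- simulate_cq_study(preset_config("ovx_rat", seed = 81))
  cand <- sim$truth$reference_genes
  f1 <- reference_stability(sim$cq, sim$annotation, genes = cand)
  f2 <- reference_stability(sim$cq, sim$annotation, genes = cand)
  expect_identical(f1$table, f2$table)
  # removing a sample and re-adding it changes nothing (no hidden state)
  perm <- sample(ncol(sim$cq))
  f3 <- reference_stability(sim$cq[, perm], sim$annotation, genes = cand)
  expect_equal(f3$table$M, f1$table$M[match(f3$table$gene, f1$table$gene)],
               tolerance = 1e-12)
})
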