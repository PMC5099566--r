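#' Simulation configuration for a serum qPCR study
#'
#' Describes a Cq study generatively: per-gene baseline Cq, gene-specific
#' noise SD (cycles), additive group effects (cycles; positive = higher Cq =
#' lower abundance), a per-sample global load shift shared by all genes
#' (pipetting / input-amount variation), hemolysis contamination affecting
#' only the red-blood-cell marker gene, a spike-in control, and a covariate
#' model in which BMD is a linear function of group plus noise.
#'
#' @param n_per_group named integer vector of samples per group.
#' @param genes data.frame with columns `gene`, `base_cq`, `sigma`, optional
#'   `is_reference` (logical), and one `effect_<group>` column per
#'   non-baseline group giving the Cq shift in that group (absent = 0).
#' @param load_sigma SD (cycles) of the per-sample global Cq shift.
#' @param hemolysis_fraction fraction of samples contaminated by hemolysis.
#' @param hemolysis_delta_range range (cycles) of the Cq drop applied to the
#'   RBC-marker gene in contaminated samples.
#' @param hemolysis_marker gene whose Cq drops under hemolysis (miR-451a
#'   analog); `NULL` disables the mechanism.
#' @param spikein_gene,spikein_cq,spikein_sigma spike-in control name, target
#'   Cq, and technical SD; `spikein_gene = NULL` omits it.
#' @param covariates list of `c(mean, sd)` pairs per covariate, or per-group
#'   named lists thereof.
#' @param bmd_by_group named vector of group BMD means (g/cm2); `NULL` omits
#'   the outcome.
#' @param bmd_sigma SD of BMD noise.
#' @param max_cycles total PCR cycles (Cq values are clamped into
#'   `(0, max_cycles]`).
#' @param seed mandatory integer seed: the same configuration always yields
#'   the same study.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_per_group, genes, load_sigma = 0.5,
                       hemolysis_fraction = 0, hemolysis_delta_range = c(3, 8),
                       hemolysis_marker = "miR-451a",
                       spikein_gene = "cel-miR-39", spikein_cq = 20,
                       spikein_sigma = 0.1,
                       covariates = NULL, bmd_by_group = NULL,
                       bmd_sigma = 0.05, max_cycles = 40, seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  genes <- as.data.frame(genes)
  stopifnot(all(c("gene", "base_cq", "sigma") %in% colnames(genes)),
            all(genes$sigma >= 0), !anyDuplicated(genes$gene),
            hemolysis_fraction >= 0, hemolysis_fraction <= 1,
            load_sigma >= 0, all(n_per_group >= 1))
  if (is.null(names(n_per_group)))
    names(n_per_group) <- paste0("group", seq_along(n_per_group))
  if (!is.null(bmd_by_group) &&
      !setequal(names(bmd_by_group), names(n_per_group)))
    stop("bmd_by_group must name the same groups as n_per_group")
  structure(list(n_per_group = n_per_group, genes = genes,
                 load_sigma = load_sigma,
                 hemolysis_fraction = hemolysis_fraction,
                 hemolysis_delta_range = hemolysis_delta_range,
                 hemolysis_marker = hemolysis_marker,
                 spikein_gene = spikein_gene, spikein_cq = spikein_cq,
                 spikein_sigma = spikein_sigma,
                 covariates = covariates, bmd_by_group = bmd_by_group,
                 bmd_sigma = bmd_sigma, max_cycles = max_cycles, seed = seed),
            class = "sim_config")
}

.preset_genes_serum <- function(groups) {
  eff <- function(...) {
    v <- c(...)
    out <- stats::setNames(rep(0, length(groups) - 1), groups[-1])
    out[names(v)] <- v
    out
  }
  # candidate reference panel: one designed stable gene, the rest noisier or
  # group-shifted; biomarker targets rise in Cq (fall in abundance) in disease
  g <- list(
    list("miR-25-3p",  24.0, 0.15, eff(), TRUE),
    list("miR-140-5p", 26.0, 0.25, eff(), TRUE),
    list("miR-342-5p", 25.0, 0.30, eff(), TRUE),
    list("miR-150-5p", 23.0, 0.45, eff(), TRUE),
    list("miR-19b-3p", 22.0, 0.50, eff(), TRUE),
    list("miR-133b-3p", 29.0, 0.60, eff(), TRUE),
    list("miR-199a-3p", 27.0, 0.50, stats::setNames(rep(0.6, length(groups) - 1), groups[-1]), TRUE),
    list("miR-3473",   30.0, 0.70, eff(), TRUE),
    list("let-7i-5p",  21.5, 0.55, stats::setNames(rep(-0.5, length(groups) - 1), groups[-1]), TRUE)
  )
  g
}

.assemble_genes <- function(glist, groups) {
  eff <- do.call(rbind, lapply(glist, `[[`, 4))
  df <- data.frame(gene = vapply(glist, `[[`, character(1), 1),
                   base_cq = vapply(glist, `[[`, numeric(1), 2),
                   sigma = vapply(glist, `[[`, numeric(1), 3),
                   is_reference = vapply(glist, `[[`, logical(1), 5),
                   stringsAsFactors = FALSE)
  colnames(eff) <- paste0("effect_", groups[-1])
  cbind(df, eff)
}

#' Built-in study presets
#'
#' Three ready-made simulation configurations mirroring common serum-miRNA
#' study designs: `"ovx_rat"` (sham vs ovariectomised rats, n = 8 + 8),
#' `"clinical"` (postmenopausal women: normal / osteopenia / osteoporosis,
#' n = 19 / 7 / 10, with age, weight, height covariates and BMD outcome),
#' and `"bedrest_monkey"` (control n = 9 vs bedrest n = 6). All include the
#' hemolysis marker pair, a spike-in control, a candidate reference panel
#' with one designed stable gene (miR-25-3p analog), and down-regulated
#' biomarker targets.
#'
#' @param preset one of `"ovx_rat"`, `"clinical"`, `"bedrest_monkey"`.
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
preset_config <- function(preset = c("ovx_rat", "clinical", "bedrest_monkey"),
                          seed) {
  preset <- match.arg(preset)
  spec <- switch(preset,
    ovx_rat = list(groups = c(sham = 8L, ovx = 8L), bmd = c(sham = 0.25, ovx = 0.21),
                   bmd_sigma = 0.015, covars = NULL),
    clinical = list(groups = c(normal = 19L, osteopenia = 7L, osteoporosis = 10L),
                    bmd = c(normal = 1.06, osteopenia = 0.79, osteoporosis = 0.58),
                    bmd_sigma = 0.07,
                    covars = list(
                      age = list(normal = c(51.9, 2.6), osteopenia = c(72.9, 7.7),
                                 osteoporosis = c(77.4, 4.5)),
                      weight = c(62, 8), height = c(158, 6))),
    bedrest_monkey = list(groups = c(control = 9L, bedrest = 6L),
                          bmd = c(control = 0.60, bedrest = 0.54),
                          bmd_sigma = 0.03, covars = NULL))
  groups <- names(spec$groups)
  eff_dis <- function(x) stats::setNames(x, groups[-1])
  glist <- .preset_genes_serum(groups)
  targets <- if (preset == "clinical") list(
    # miR-30b-5p falls in both osteopenia and osteoporosis; the others only
    # in osteoporosis (Cq up = abundance down)
    list("miR-30b-5p", 25.0, 0.5, eff_dis(c(1.2, 1.5)), FALSE),
    list("miR-103-3p", 24.0, 0.5, eff_dis(c(0.2, 1.3)), FALSE),
    list("miR-142-3p", 26.0, 0.5, eff_dis(c(0.2, 1.6)), FALSE),
    list("miR-328-3p", 28.0, 0.5, eff_dis(c(0.3, 1.8)), FALSE)
  ) else list(
    list("miR-30b-5p", 25.0, 0.5, eff_dis(1.5), FALSE),
    list("miR-103-3p", 24.0, 0.5, eff_dis(1.3), FALSE),
    list("miR-142-3p", 26.0, 0.5, eff_dis(1.6), FALSE),
    list("miR-328-3p", 28.0, 0.5, eff_dis(1.2), FALSE)
  )
  markers <- list(
    list("miR-23a-3p", 24.0, 0.3, stats::setNames(rep(0, length(groups) - 1), groups[-1]), FALSE),
    list("miR-451a", 18.5, 0.3, stats::setNames(rep(0, length(groups) - 1), groups[-1]), FALSE))
  genes <- .assemble_genes(c(glist, targets, markers), groups)
  sim_config(n_per_group = spec$groups, genes = genes, load_sigma = 0.5,
             hemolysis_fraction = 0.05, hemolysis_delta_range = c(3, 8),
             covariates = spec$covars, bmd_by_group = spec$bmd,
             bmd_sigma = spec$bmd_sigma, seed = seed)
}

#' Designed reference-recovery benchmark scenario
#'
#' A two-group study (12 + 12 samples) with one designed stable candidate
#' ("stable": sigma 0.1 cycles, no group effect) among nine unstable
#' candidates that are either noisy (sigma 0.4-0.8 cycles) or carry group
#' effects of at least 0.8 cycles in a balanced panel (effects summing to
#' zero, since stability algorithms attribute intergroup deviation relative
#' to the panel average). Includes the hemolysis marker pair and a spike-in
#' so the scenario exercises QC as well. Used to benchmark whether the
#' stability ranking recovers the designed gene as comprehensive rank 1.
#'
#' @param seed integer seed.
#' @return a [sim_config()] whose ground truth lists `"stable"` as the
#'   designed reference.
#' @export
reference_recovery_config <- function(seed) {
  groups <- c(a = 12L, b = 12L)
  genes <- data.frame(
    gene = c("stable", paste0("noisy", 1:5), paste0("shift", 1:4),
             "miR-23a-3p", "miR-451a"),
    base_cq = c(24, 22, 23, 25, 26, 27, 24.5, 25.5, 23.5, 26.5, 24, 18.5),
    sigma = c(0.1, 0.4, 0.5, 0.6, 0.7, 0.8, 0.4, 0.4, 0.4, 0.4, 0.3, 0.3),
    is_reference = c(rep(TRUE, 10), FALSE, FALSE),
    effect_b = c(rep(0, 6), 0.8, -0.8, 1.0, -1.0, 0, 0),
    stringsAsFactors = FALSE)
  sim_config(n_per_group = groups, genes = genes, load_sigma = 0.5,
             hemolysis_fraction = 0.05, seed = seed)
}

.draw_covar <- function(spec, groups_vec, glev) {
  if (is.list(spec) && !is.null(names(spec)) && all(glev %in% names(spec))) {
    out <- numeric(length(groups_vec))
    for (g in glev) {
      idx <- groups_vec == g
      out[idx] <- stats::rnorm(sum(idx), spec[[g]][1], spec[[g]][2])
    }
    out
  } else {
    stats::rnorm(length(groups_vec), spec[1], spec[2])
  }
}

#' Simulate a Cq study
#'
#' Generates Cq_gj = base_g + load_j + effect_g(group_j) + eps_gj with
#' eps ~ N(0, sigma_g^2) and load_j ~ N(0, load_sigma^2) — normal noise on
#' the Cq (log-abundance) scale, matching the multiplicative error model of
#' qPCR. A configured fraction of samples is hemolysed: only the RBC-marker
#' gene's Cq is reduced by a uniform draw from `hemolysis_delta_range`,
#' leaving every other gene untouched. The spike-in gene ignores load and
#' group effects (it is added in fixed quantity after serum collection).
#' Cq values are clamped into `(0, max_cycles]`.
#'
#' @param config a [sim_config()].
#' @return list with `cq` (a [cq_matrix()]), `annotation` (a
#'   [sample_annotation()]) and `truth` (designed reference genes, true group
#'   effects, per-sample hemolysis status and load shifts, covariate model).
#' @export
simulate_cq_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  glev <- names(config$n_per_group)
  groups_vec <- rep(glev, times = config$n_per_group)
  n <- length(groups_vec)
  sample_ids <- sprintf("s%02d", seq_len(n))
  genes <- config$genes
  G <- nrow(genes)

  eff_cols <- paste0("effect_", glev[-1])
  eff <- matrix(0, G, length(glev), dimnames = list(genes$gene, glev))
  for (g in glev[-1]) {
    cl <- paste0("effect_", g)
    if (cl %in% colnames(genes)) eff[, g] <- genes[[cl]]
  }

  load <- stats::rnorm(n, 0, config$load_sigma)
  cq <- matrix(genes$base_cq, G, n) +
    rep(load, each = G) + eff[, groups_vec] +
    matrix(stats::rnorm(G * n, 0, rep(genes$sigma, n)), G, n)
  dimnames(cq) <- list(genes$gene, sample_ids)

  hemolysed <- stats::runif(n) < config$hemolysis_fraction
  if (!is.null(config$hemolysis_marker) &&
      config$hemolysis_marker %in% rownames(cq) && any(hemolysed)) {
    drop <- stats::runif(sum(hemolysed), config$hemolysis_delta_range[1],
                         config$hemolysis_delta_range[2])
    cq[config$hemolysis_marker, hemolysed] <-
      cq[config$hemolysis_marker, hemolysed] - drop
  }
  if (!is.null(config$spikein_gene)) {
    cq <- rbind(cq, stats::rnorm(n, config$spikein_cq, config$spikein_sigma))
    rownames(cq)[nrow(cq)] <- config$spikein_gene
  }
  cq <- pmin(pmax(cq, 0.01), config$max_cycles)

  covars <- NULL
  if (!is.null(config$covariates)) {
    covars <- as.data.frame(lapply(config$covariates, .draw_covar,
                                   groups_vec = groups_vec, glev = glev))
  }
  outcome <- NULL
  if (!is.null(config$bmd_by_group)) {
    outcome <- config$bmd_by_group[groups_vec] +
      stats::rnorm(n, 0, config$bmd_sigma)
  }
  ann <- sample_annotation(sample_ids, groups_vec, covariates = covars,
                           outcome = outcome)
  truth <- list(
    reference_genes = genes$gene[isTRUE_col(genes$is_reference)],
    designed_stable = if (nrow(genes)) genes$gene[which.min(genes$sigma +
      apply(abs(eff), 1, max))] else character(0),
    group_effects = eff, sigma = stats::setNames(genes$sigma, genes$gene),
    load = stats::setNames(load, sample_ids),
    hemolysed = stats::setNames(hemolysed, sample_ids),
    bmd_by_group = config$bmd_by_group, seed = config$seed)
  list(cq = cq_matrix(cq, max_cycles = config$max_cycles),
       annotation = ann, truth = truth)
}

isTRUE_col <- function(x) if (is.null(x)) logical(0) else !is.na(x) & x

#' Simulate a linear-intensity expression matrix
#'
#' Log-normal intensities: log2 intensity = base + effect (log2 fold in the
#' case group for designated DE genes) + N(0, sigma^2). Ground truth (which
#' genes are differentially expressed, at what linear fold) is returned for
#' power and type-I-error studies.
#'
#' @param n_per_group named 2-vector of group sizes (control first).
#' @param n_genes total number of genes.
#' @param de_genes data.frame with columns `gene` (indices or names) and
#'   `fold` (linear fold change, case over control); `NULL` for a global
#'   null.
#' @param sigma SD of log2 noise (default 0.3).
#' @param base_log2 mean log2 intensity (default 10).
#' @param seed integer seed.
#' @return list with `expr` (an [intensity_matrix()]), `annotation`, `truth`.
#' @export
simulate_intensity_matrix <- function(n_per_group = c(control = 8, case = 8),
                                      n_genes = 200, de_genes = NULL,
                                      sigma = 0.3, base_log2 = 10, seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(length(n_per_group) == 2, sigma >= 0)
  if (is.null(names(n_per_group))) names(n_per_group) <- c("control", "case")
  set.seed(seed)
  glev <- names(n_per_group)
  groups_vec <- rep(glev, times = n_per_group)
  n <- length(groups_vec)
  gene_ids <- sprintf("gene%03d", seq_len(n_genes))
  l2fc <- stats::setNames(rep(0, n_genes), gene_ids)
  if (!is.null(de_genes)) {
    de_genes <- as.data.frame(de_genes)
    idx <- if (is.numeric(de_genes$gene)) gene_ids[de_genes$gene] else
      as.character(de_genes$gene)
    l2fc[idx] <- log2(de_genes$fold)
  }
  lmat <- base_log2 +
    outer(l2fc, as.numeric(groups_vec == glev[2])) +
    matrix(stats::rnorm(n_genes * n, 0, sigma), n_genes, n)
  expr <- 2^lmat
  dimnames(expr) <- list(gene_ids, sprintf("s%02d", seq_len(n)))
  ann <- sample_annotation(colnames(expr), groups_vec)
  list(expr = intensity_matrix(expr), annotation = ann,
       truth = list(de_genes = names(l2fc)[l2fc != 0],
                    fold = 2^l2fc, sigma = sigma, seed = seed))
}
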