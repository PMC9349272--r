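#' Polygenic scores from a simulated cohort
#'
#' Convenience wrapper running the standard scoring chain on a cohort from
#' [simulate_cohort()]: harmonise panel and summary statistics
#' ([filter_variants()]), LD-clump ([ld_clump()]) and score ([score_prs()])
#' at a fixed threshold.
#'
#' @param cohort output of [simulate_cohort()]
#' @param p_T inclusion threshold, default 0.05
#' @return a [score_prs()] result
#' @export
prs_from_cohort <- function(cohort, p_T = 0.05) {
  harm <- filter_variants(cohort$panel, cohort$gwas)
  kept <- ld_clump(harm$panel, harm$summary)
  sub <- snp_panel(harm$panel$dosage[, kept, drop = FALSE],
                   harm$panel$map[match(kept, harm$panel$map$id), ])
  score_prs(sub, harm$summary, p_T)
}

# Shared scaffolding: stratify a cohort subset and run the discovery EWAS
# with the standard covariate set (sex, age, ancestry, tissue, batch and
# estimated cell fractions, dropping the dominant cell type to avoid
# sum-to-one collinearity).
discovery_scan <- function(cohort, sample_ids, prs_std, seed,
                           bacon_iterations = 5000, bacon_burnin = 2000,
                           with_mds = TRUE) {
  cells <- estimate_cell_counts(cohort$meth$beta, cohort$meth$cell_ref)
  use_cells <- setdiff(colnames(cells), colnames(cells)[which.max(colMeans(cells))])
  s <- cohort$samples
  s$prs <- prs_std[match(s$sample_id, names(prs_std))]
  s$batchf <- factor(cohort$meth$truth$batch)
  if (with_mds) {
    mds <- mds_ancestry(cohort$panel, k = 4)
    s$C1 <- mds[, 1]; s$C2 <- mds[, 2]
  }
  s <- cbind(s, cells[match(s$sample_id, rownames(cells)), use_cells])
  s_disc <- s[match(sample_ids, s$sample_id), ]
  st <- quintile_strata(setNames(s_disc$prs, s_disc$sample_id))
  keep <- st$assignment$stratum != "Mid"
  sd2 <- s_disc[match(st$assignment$sample_id[keep], s_disc$sample_id), ]
  sd2$stratum <- st$assignment$stratum[keep]
  M <- beta_to_m(cohort$meth$beta[setdiff(rownames(cohort$meth$beta),
                                          "cg05575921"), sd2$sample_id])
  covs <- c("sex", "age", if (with_mds) c("C1", "C2"), "tissue", "batchf",
            use_cells)
  ew <- run_ewas(M, sd2, covariate_cols = covs,
                 bacon_iterations = bacon_iterations,
                 bacon_burnin = bacon_burnin, seed = seed)
  list(ewas = ew, strata = st, samples = s, use_cells = use_cells)
}

#' Null-calibration experiment
#'
#' Runs the full synthetic pipeline with zero polygenic-score/methylation
#' coupling: simulate a cohort, compute polygenic scores by clumping and
#' thresholding, stratify into top/bottom-two-quintile groups, estimate cell
#' fractions and ancestry components, run the surrogate-variable-adjusted
#' per-probe scan with empirical-null correction, and report the uniformity
#' of corrected p-values and the count of Bonferroni-significant probes
#' (which should be zero under the null).
#'
#' @param seed integer seed (drives every stochastic step)
#' @param n_samples cohort size (103 gives the 41 vs 41 strata design)
#' @param n_probes number of probes scanned
#' @return list: `ks_p` (Kolmogorov-Smirnov p against uniform), `n_hits`,
#'   `bias`, `inflation`, `n_probes`, `n_ewas_samples`
#' @export
null_calibration_run <- function(seed, n_samples = 103, n_probes = 5000) {
  cfg <- cohort_config(n_samples = n_samples, n_snps = 800, n_blocks = 80,
                       n_probes = n_probes, n_coupled_probes = 0,
                       coupling_effect = 0, seed = seed)
  co <- simulate_cohort(cfg)
  prs <- prs_from_cohort(co)
  sc <- discovery_scan(co, co$samples$sample_id,
                       setNames(prs$scores$standardized, prs$scores$sample_id),
                       seed = seed)
  ks <- suppressWarnings(ks.test(sc$ewas$table$p_corr, "punif"))$p.value
  list(ks_p = ks, n_hits = sum(sc$ewas$table$pass_bonferroni),
       bias = sc$ewas$empnull$bias, inflation = sc$ewas$empnull$inflation,
       n_probes = nrow(sc$ewas$table), n_ewas_samples = ncol(sc$ewas$design))
}

#' Profile-score recovery experiment
#'
#' Simulates one generator cohort of `2 * n_per_set` samples with
#' polygenic-score-coupled probes, splits it into a discovery and an
#' independent target set, runs the discovery stratified EWAS, scores the
#' target set's poly-methylomic profile at `p_T = 0.05`, and reports the
#' target-set correlation between profile score and standardized polygenic
#' score together with the p-value of the High-vs-Low stratum effect on the
#' profile score in a covariate-adjusted GLM.
#'
#' @param seed integer seed
#' @param coupling logit-scale probe coupling per SD of the score, default 0.4
#' @param n_per_set samples per set, default 200
#' @param n_probes number of probes, default 3000
#' @return list: `r` (PMPS-PRS correlation in the target set), `stratum_p`,
#'   `n_cpgs`
#' @export
pmps_recovery_run <- function(seed, coupling = 0.4, n_per_set = 200,
                              n_probes = 3000) {
  cfg <- cohort_config(n_samples = 2 * n_per_set, n_snps = 800, n_blocks = 80,
                       n_probes = n_probes, n_coupled_probes = 40,
                       coupling_effect = coupling, seed = seed)
  co <- simulate_cohort(cfg)
  prs <- prs_from_cohort(co)
  prs_std <- setNames(prs$scores$standardized, prs$scores$sample_id)
  disc_ids <- co$samples$sample_id[seq_len(n_per_set)]
  targ_ids <- co$samples$sample_id[seq.int(n_per_set + 1, 2 * n_per_set)]
  sc <- discovery_scan(co, disc_ids, prs_std, seed = seed, with_mds = FALSE)
  pm <- compute_pmps(co$meth$beta[, targ_ids], sc$ewas$table, 0.05)
  targ <- sc$samples[match(targ_ids, sc$samples$sample_id), ]
  targ$pmps <- pm$scores$pmps[match(targ_ids, pm$scores$sample_id)]
  r <- cor(targ$pmps, targ$prs)
  st <- quintile_strata(setNames(targ$prs, targ$sample_id))
  keep <- st$assignment$stratum != "Mid"
  tg <- targ[match(st$assignment$sample_id[keep], targ$sample_id), ]
  tg$stratum <- st$assignment$stratum[keep]
  rep <- validate_glm(tg, "pmps", "stratum",
                      covariates = c("age", "sex", "tissue", sc$use_cells))
  list(r = r, stratum_p = rep$terms$p[rep$terms$term == "stratum"],
       n_cpgs = pm$n_cpgs)
}

#' Cell-deconvolution error experiment
#'
#' Builds synthetic beta-scale mixtures of the generator's cell-type
#' reference profiles with Dirichlet fractions and Gaussian probe noise,
#' estimates fractions by constrained projection, and reports the mean
#' absolute error against the known fractions.
#'
#' @param seed integer seed
#' @param n_samples number of mixtures, default 50
#' @param noise_sd beta-scale noise SD, default 0.02
#' @return list: `mae`, `n_samples`, `n_probes`
#' @export
cell_deconvolution_mae <- function(seed, n_samples = 50, noise_sd = 0.02) {
  cfg <- cohort_config(n_samples = 10, n_probes = 500, n_coupled_probes = 0,
                       coupling_effect = 0, seed = seed)
  meth <- simulate_methylation(rep(0, 10), cfg)
  ref <- meth$cell_ref
  with_seed(sub_seed(seed, 31L), {
    W <- rdirichlet(n_samples, cfg$dirichlet_alpha)
    X <- ref %*% t(W) + matrix(rnorm(nrow(ref) * n_samples, 0, noise_sd),
                               nrow(ref))
    X <- clip01(X)
    colnames(X) <- sprintf("MIX%03d", seq_len(n_samples))
    est <- estimate_cell_counts(X, ref)
    list(mae = mean(abs(est - W)), n_samples = n_samples, n_probes = nrow(ref))
  })
}
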