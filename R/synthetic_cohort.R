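#' Configuration for a synthetic cohort
#'
#' Bundles every tunable of the synthetic data generator: an LD-blocked
#' genotype panel, external GWAS summary statistics with planted causal
#' effects, a beta-valued methylation matrix with cell-composition, batch and
#' smoking structure plus a configurable set of CpGs coupled to the
#' standardized polygenic score, and liability-threshold phenotypes.
#'
#' @param n_samples number of cohort samples
#' @param n_snps number of biallelic variants
#' @param n_blocks number of LD blocks the variants are divided into
#' @param block_rho latent adjacent-variant correlation within a block, in \[0,1)
#' @param maf_range range the per-variant minor-allele frequency is drawn from,
#'   within (0, 0.5]
#' @param n_causal_snps number of variants with non-zero liability effects
#' @param h2_liability proportion of liability variance explained by the
#'   genetic score, in \[0,1\]
#' @param gwas_n effective sample size of the emulated external GWAS
#' @param n_probes number of CpG probes (a dedicated smoking probe named
#'   cg05575921 is appended on top of this count)
#' @param n_coupled_probes number of probes whose logit-scale methylation
#'   depends linearly on the standardized polygenic score
#' @param coupling_effect M-value (log2-odds) shift per 1 SD of the score at
#'   coupled probes
#' @param cell_types labels of the mixed blood cell types
#' @param dirichlet_alpha positive Dirichlet concentration vector (one entry
#'   per cell type) for per-sample cell fractions
#' @param batch_sd SD of probe-by-batch logit-scale effects
#' @param n_batches number of methylation batches
#' @param noise_sd_range range of per-probe residual SD on the M-value scale
#' @param smoker_fraction expected fraction of probable smokers
#' @param n_sib_pairs number of sibling pairs (placed first in the cohort) to
#'   exercise relatedness filtering; remaining samples are unrelated
#' @param case_threshold liability quantile above which a sample is a case
#' @param hr_fraction fraction of non-cases labelled high-risk (assigned from
#'   the top of the non-case liability distribution, so group means order
#'   control < high-risk < case)
#' @param low_info_fraction fraction of variants given INFO below 0.8
#' @param ambiguous_fraction fraction of variants given strand-ambiguous
#'   (A/T or C/G) allele pairs
#' @param seed integer seed; every stochastic operation derives its own
#'   sub-stream from it
#'
#' @return an object of class `cohort_config` (a validated list)
#' @export
cohort_config <- function(n_samples = 200, n_snps = 1000, n_blocks = 100,
                          block_rho = 0.8, maf_range = c(0.05, 0.5),
                          n_causal_snps = 50, h2_liability = 0.3,
                          gwas_n = 50000, n_probes = 5000,
                          n_coupled_probes = 50, coupling_effect = 0.4,
                          cell_types = c("Bcell", "CD4T", "CD8T", "Gran", "Mono", "NK"),
                          dirichlet_alpha = c(1.5, 4.5, 2.4, 18, 2.4, 1.2),
                          batch_sd = 0.2, n_batches = 3,
                          noise_sd_range = c(0.25, 0.65),
                          smoker_fraction = 0.1, n_sib_pairs = 0,
                          case_threshold = 0.9, hr_fraction = 0.35,
                          low_info_fraction = 0.05, ambiguous_fraction = 0.08,
                          seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_samples, n_snps, n_blocks, n_probes, gwas_n, n_batches)
  if (any(counts <= 0)) stop("counts must be positive")
  if (n_snps < n_blocks) stop("n_snps must be >= n_blocks")
  if (block_rho < 0 || block_rho >= 1) stop("block_rho must be in [0,1)")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (n_causal_snps > n_snps) stop("n_causal_snps must be <= n_snps")
  if (n_coupled_probes > n_probes) stop("n_coupled_probes must be <= n_probes")
  if (h2_liability < 0 || h2_liability > 1) stop("h2_liability must be in [0,1]")
  if (length(dirichlet_alpha) != length(cell_types))
    stop("dirichlet_alpha must have one entry per cell type")
  if (any(dirichlet_alpha <= 0)) stop("dirichlet_alpha must be positive")
  if (2 * n_sib_pairs > n_samples) stop("too many sib pairs for n_samples")
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> n =", x$n_samples, "| SNPs =", x$n_snps,
      "in", x$n_blocks, "blocks | probes =", x$n_probes,
      "(", x$n_coupled_probes, "coupled, effect", x$coupling_effect, ")\n")
  invisible(x)
}

#' Construct a genotype panel object
#'
#' @param dosage numeric matrix, samples x variants, dosage of A1 in \[0,2\];
#'   column names are variant ids, row names sample ids
#' @param map data frame with columns id, chr, pos, A1, A2, maf, info
#' @return object of class `snp_panel`
#' @export
snp_panel <- function(dosage, map) {
  stopifnot(is.matrix(dosage), ncol(dosage) == nrow(map))
  if (anyDuplicated(map$id)) stop("variant ids must be unique")
  if (any(map$maf < 0 | map$maf > 0.5)) stop("MAF must lie in [0, 0.5]")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  colnames(dosage) <- map$id
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  structure(list(dosage = dosage, map = map), class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("<snp_panel>", nrow(x$dosage), "samples x", ncol(x$dosage), "variants\n")
  invisible(x)
}

# Draw one haplotype's latent Gaussians for all samples: AR(1) within blocks.
ar1_latent <- function(n, block_sizes, rho) {
  z <- matrix(NA_real_, n, sum(block_sizes))
  j <- 0L
  for (bs in block_sizes) {
    z[, j + 1L] <- rnorm(n)
    if (bs > 1L) for (k in seq_len(bs - 1L))
      z[, j + k + 1L] <- rho * z[, j + k] + sqrt(1 - rho^2) * rnorm(n)
    j <- j + bs
  }
  z
}

ALLELES <- c("A", "C", "G", "T")
is_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Simulate an LD-blocked genotype panel
#'
#' Genotypes are built from two latent-Gaussian haplotypes per sample; within
#' each block adjacent latent variables follow an AR(1) process with
#' correlation `block_rho`, and alleles are called by thresholding at the MAF
#' quantile, so local dosage correlation is controllable and across-block
#' correlation is ~0. Optional sibling pairs share, per LD block, a randomly
#' inherited parental haplotype, giving expected identity-by-descent 0.5.
#'
#' @param config a [cohort_config()]
#' @return list with `panel` (a [snp_panel()]) and `truth` (per-variant true
#'   liability effects, causal ids, family ids, per-sample true genetic score)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(sub_seed(config$seed, 1L), {
    n <- config$n_samples
    m <- config$n_snps
    block <- sort(rep_len(seq_len(config$n_blocks), m))
    block_sizes <- as.integer(table(block))
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    thr <- qnorm(maf)

    # variant map: blocks laid along chromosomes, 1 Mb apart, 5 kb SNP spacing
    chr <- ((seq_len(config$n_blocks) - 1L) %% 22L) + 1L
    within <- unlist(lapply(block_sizes, seq_len))
    blk_of <- rep(seq_len(config$n_blocks), block_sizes)
    blk_index_on_chr <- ave(seq_len(config$n_blocks), chr[seq_len(config$n_blocks)],
                            FUN = seq_along)
    pos <- 1e6 * blk_index_on_chr[blk_of] + 5000 * within + 10000
    a1 <- sample(ALLELES, m, replace = TRUE)
    pick_partner <- function(a, ambiguous) {
      if (ambiguous) c(A = "T", T = "A", C = "G", G = "C")[[a]]
      else sample(setdiff(ALLELES[ALLELES != a],
                          c(A = "T", T = "A", C = "G", G = "C")[[a]]), 1)
    }
    amb <- runif(m) < config$ambiguous_fraction
    a2 <- vapply(seq_len(m), function(j) pick_partner(a1[j], amb[j]), "")
    info <- ifelse(runif(m) < config$low_info_fraction,
                   runif(m, 0.4, 0.8), runif(m, 0.8, 1))

    n_founder_hap <- 2L * n  # generous; sibs draw from parental pools below
    draw_hap <- function() (ar1_latent(n, block_sizes, config$block_rho) <
                              matrix(thr, n, m, byrow = TRUE)) * 1L
    h1 <- draw_hap(); h2 <- draw_hap()

    family <- sprintf("F%04d", seq_len(n))
    if (config$n_sib_pairs > 0) {
      for (s in seq_len(config$n_sib_pairs)) {
        i1 <- 2L * s - 1L; i2 <- 2L * s
        # four parental haplotypes; each sib inherits one per parent, chosen
        # independently per LD block (block-wise meiosis, no within-block
        # recombination)
        ph <- (ar1_latent(4L, block_sizes, config$block_rho) <
                 matrix(thr, 4L, m, byrow = TRUE)) * 1L
        for (i in c(i1, i2)) {
          pick1 <- rep(sample(c(1L, 2L), config$n_blocks, replace = TRUE), block_sizes)
          pick2 <- rep(sample(c(3L, 4L), config$n_blocks, replace = TRUE), block_sizes)
          h1[i, ] <- ph[cbind(pick1, seq_len(m))]
          h2[i, ] <- ph[cbind(pick2, seq_len(m))]
        }
        family[c(i1, i2)] <- sprintf("F%04d", i1)
      }
    }
    dosage <- h1 + h2
    rownames(dosage) <- sprintf("S%04d", seq_len(n))

    map <- data.frame(id = sprintf("rs%06d", seq_len(m)), chr = chr[blk_of],
                      pos = pos, A1 = a1, A2 = a2, maf = maf, info = info,
                      stringsAsFactors = FALSE)
    panel <- snp_panel(dosage, map)

    # causal effects on variants that survive the standard QC filters, so the
    # planted architecture is recoverable downstream
    eligible <- which(map$maf >= 0.05 & map$info >= 0.8 & !is_ambiguous(a1, a2))
    n_causal <- min(config$n_causal_snps, length(eligible))
    causal <- sort(sample(eligible, n_causal))
    b <- numeric(m)
    b[causal] <- rnorm(n_causal)
    vg <- sum(2 * maf[causal] * (1 - maf[causal]) * b[causal]^2)
    if (vg > 0) b <- b / sqrt(vg)  # genetic value has unit variance in expectation
    g <- drop(dosage %*% b)
    g_std <- if (sd(g) > 0) (g - mean(g)) / sd(g) else g

    list(panel = panel,
         truth = list(causal_snp_ids = map$id[causal], snp_effects = b,
                      family_id = family, genetic_score = g_std))
  })
}

#' Simulate GWAS summary statistics for a panel
#'
#' Emulates summary statistics from a large external case-control GWAS:
#' the estimated log-odds effect is the true effect plus Gaussian noise with
#' `SE = 1/sqrt(2*MAF*(1-MAF)*gwas_n)`, and the two-sided p-value comes from
#' the Wald z-statistic.
#'
#' @param panel a [snp_panel()]
#' @param true_effects numeric vector of true per-variant effects (0 for
#'   non-causal variants), aligned with `panel$map`
#' @param gwas_n effective GWAS sample size (> 0)
#' @param seed integer seed
#' @return data frame with columns id, chr, pos, A1, A2, effect, se, p, info, maf
#' @export
simulate_gwas_summary <- function(panel, true_effects, gwas_n, seed = 1) {
  stopifnot(inherits(panel, "snp_panel"))
  if (gwas_n <= 0) stop("gwas_n must be > 0")
  map <- panel$map
  if (length(true_effects) != nrow(map))
    stop("true_effects must have one entry per panel variant")
  with_seed(sub_seed(seed, 2L), {
    se <- 1 / sqrt(2 * map$maf * (1 - map$maf) * gwas_n)
    eff <- true_effects + rnorm(nrow(map)) * se
    z <- eff / se
    p <- pmax(2 * pnorm(-abs(z)), 1e-300)
    data.frame(id = map$id, chr = map$chr, pos = map$pos, A1 = map$A1,
               A2 = map$A2, effect = eff, se = se, p = p, info = map$info,
               maf = map$maf, stringsAsFactors = FALSE)
  })
}

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)), n)
  g / rowSums(g)
}

#' Simulate a beta-valued methylation matrix with planted structure
#'
#' Per-probe baseline log2-odds methylation is drawn from a bimodal mixture
#' (hypo/hyper-methylated modes). Each sample's value adds a cell-composition
#' term (logit-scale cell-type offsets mixed by Dirichlet fractions), a
#' probe-by-batch effect, `coupling_effect * score` at coupled probes, and
#' Gaussian probe-level noise, then maps through the inverse logit2 so beta
#' stays strictly in (0,1). A smoking probe (cg05575921) is set below 0.75
#' for probable smokers and centred above 0.85 otherwise. Coupled probes are
#' planted among probes that pass all downstream CpG filters.
#'
#' @param score per-sample score the coupled probes follow (standardized
#'   polygenic score in the full pipeline); mean-centred scores expected
#' @param config a [cohort_config()]
#' @param smoker optional logical vector of smoker flags (drawn from
#'   `smoker_fraction` if NULL)
#' @param batch optional integer batch assignment (drawn uniformly if NULL)
#' @return list with `beta` (probes x samples), `manifest`, reference lists
#'   (`blood_variable_ids`, `blood_brain_r`), `cell_ref` (probes x cell types,
#'   beta scale) and `truth` (cell fractions, coupled probe ids and effects,
#'   smoker flags, batch, per-probe noise SD)
#' @export
simulate_methylation <- function(score, config, smoker = NULL, batch = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- length(score)
  p <- config$n_probes
  if (config$n_coupled_probes > p) stop("coupled probe count exceeds panel")
  with_seed(sub_seed(config$seed, 3L), {
    k <- length(config$cell_types)
    probe_id <- sprintf("cg%08d", seq_len(p))

    # gene models first; probes scatter around their gene's TSS so physical
    # and regulatory mapping are both exercised downstream
    n_genes <- max(20, p %/% 8)
    genes <- data.frame(gene = sprintf("GENE%04d", seq_len(n_genes)),
                        chr = sample(1:22, n_genes, replace = TRUE),
                        strand = sample(c("+", "-"), n_genes, replace = TRUE),
                        tss = sample.int(2e8, n_genes),
                        stringsAsFactors = FALSE)
    body_len <- sample(2000:50000, n_genes, replace = TRUE)
    genes$start <- ifelse(genes$strand == "+", genes$tss, genes$tss - body_len)
    genes$end <- ifelse(genes$strand == "+", genes$tss + body_len, genes$tss)
    genes$start <- pmax(genes$start, 1)
    gene_of <- sample.int(n_genes, p, replace = TRUE)
    manifest <- data.frame(
      probe_id = probe_id,
      chr = genes$chr[gene_of],
      pos = pmax(genes$tss[gene_of] + round(rnorm(p, 0, 8000)), 1),
      gene = genes$gene[gene_of],
      probe_snp = runif(p) < 0.05,
      stringsAsFactors = FALSE)

    blood_variable_ids <- probe_id[runif(p) < 0.9]
    blood_brain_r <- data.frame(probe_id = probe_id,
                                mean_r = rnorm(p, 0.1, 0.25),
                                stringsAsFactors = FALSE)

    baseline <- ifelse(runif(p) < 0.55, rnorm(p, -2.8, 1), rnorm(p, 2.8, 1))
    informative <- runif(p) < 0.2
    offsets <- matrix(0, p, k)
    offsets[informative, ] <- rnorm(sum(informative) * k, 0, 1.5)
    w <- rdirichlet(n, config$dirichlet_alpha)  # n x k true cell fractions
    if (is.null(batch)) batch <- sample.int(config$n_batches, n, replace = TRUE)
    bmat <- matrix(rnorm(p * config$n_batches, 0, config$batch_sd), p)
    noise_sd <- runif(p, config$noise_sd_range[1], config$noise_sd_range[2])

    # plant coupled probes among probes passing every downstream filter; the
    # variability filter is satisfied by construction (noise + cell mixing)
    passes <- probe_id %in% blood_variable_ids &
      abs(blood_brain_r$mean_r) >= 0.3 & !manifest$probe_snp &
      abs(baseline) < 2  # mid-methylated, so the variability filter holds too
    coupled <- sort(sample(which(passes), min(config$n_coupled_probes, sum(passes))))
    couple_eff <- numeric(p)
    couple_eff[coupled] <- config$coupling_effect

    L <- matrix(baseline, p, n) + offsets %*% t(w) + bmat[, batch] +
      outer(couple_eff, score) + matrix(rnorm(p * n), p, n) * noise_sd
    beta <- clip01(ilogit2(L))
    dimnames(beta) <- list(probe_id, names(score) %||% sprintf("S%04d", seq_len(n)))

    if (is.null(smoker)) smoker <- runif(n) < config$smoker_fraction
    smoke_beta <- ifelse(smoker, runif(n, 0.35, 0.70), runif(n, 0.86, 0.95))
    beta <- rbind(beta, cg05575921 = smoke_beta)
    manifest <- rbind(manifest, data.frame(
      probe_id = "cg05575921", chr = 5, pos = 373378, gene = "AHRR",
      probe_snp = FALSE, stringsAsFactors = FALSE))
    blood_brain_r <- rbind(blood_brain_r, data.frame(
      probe_id = "cg05575921", mean_r = 0.1, stringsAsFactors = FALSE))

    cell_ref <- clip01(ilogit2(matrix(baseline, p, k) + offsets))
    dimnames(cell_ref) <- list(probe_id, config$cell_types)
    rownames(w) <- colnames(beta)
    colnames(w) <- config$cell_types

    list(beta = beta, manifest = manifest, genes = genes,
         blood_variable_ids = blood_variable_ids, blood_brain_r = blood_brain_r,
         cell_ref = cell_ref,
         truth = list(cell_fractions = w, coupled_probe_ids = probe_id[coupled],
                      coupled_effects = couple_eff[coupled], smoker = smoker,
                      batch = batch, noise_sd = noise_sd))
  })
}

#' Simulate phenotypes under a liability-threshold model
#'
#' Liability is `sqrt(h2)*score + sqrt(1-h2)*noise`; samples above the
#' `case_threshold` liability quantile are cases, and a configurable fraction
#' of non-cases with the highest liability are labelled high-risk, so group
#' mean liability (and, for h2 > 0, the polygenic score) orders
#' control < high-risk < case.
#'
#' @param score standardized per-sample genetic score
#' @param config a [cohort_config()]
#' @param family_id optional per-sample family ids
#' @return data frame (sample sheet): sample_id, group (CON/HR/CASE), age,
#'   sex, tissue, batch, family_id, faces, liability
#' @export
simulate_phenotypes <- function(score, config, family_id = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  h2 <- config$h2_liability
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0,1]")
  n <- length(score)
  with_seed(sub_seed(config$seed, 4L), {
    liab <- sqrt(h2) * score + sqrt(1 - h2) * rnorm(n)
    case <- liab > qnorm(config$case_threshold)
    group <- rep("CON", n)
    group[case] <- "CASE"
    noncase <- which(!case)
    n_hr <- round(config$hr_fraction * length(noncase))
    if (n_hr > 0)
      group[noncase[order(liab[noncase], decreasing = TRUE)[seq_len(n_hr)]]] <- "HR"
    data.frame(
      sample_id = names(score) %||% sprintf("S%04d", seq_len(n)),
      group = group,
      age = round(runif(n, 12, 30), 1),
      sex = sample(c("F", "M"), n, replace = TRUE),
      tissue = sample(c("whole_blood", "buffy_coat", "lymphoblast"), n,
                      replace = TRUE, prob = c(0.6, 0.3, 0.1)),
      batch = sample.int(config$n_batches, n, replace = TRUE),
      family_id = family_id %||% sprintf("F%04d", seq_len(n)),
      faces = round(rnorm(n, 105, 15), 1),
      liability = liab,
      stringsAsFactors = FALSE)
  })
}

#' Simulate a complete cohort
#'
#' Runs [simulate_genotypes()], [simulate_gwas_summary()],
#' [simulate_phenotypes()] and [simulate_methylation()] in dependency order,
#' coupling methylation to the standardized true genetic score.
#'
#' @param config a [cohort_config()]
#' @return list with `panel`, `gwas`, `samples`, `meth` and `truth`
#' @export
simulate_cohort <- function(config) {
  geno <- simulate_genotypes(config)
  gwas <- simulate_gwas_summary(geno$panel, geno$truth$snp_effects,
                                config$gwas_n, seed = config$seed)
  samples <- simulate_phenotypes(geno$truth$genetic_score, config,
                                 family_id = geno$truth$family_id)
  g <- setNames(geno$truth$genetic_score, samples$sample_id)
  meth <- simulate_methylation(g, config)
  samples$batch <- meth$truth$batch  # batch drives the planted probe effects
  samples$smoker_true <- meth$truth$smoker
  list(panel = geno$panel, gwas = gwas, samples = samples, meth = meth,
       truth = c(geno$truth, meth$truth))
}

#' Write a simulated cohort to plain-text files
#'
#' Emits dosage TSV (samples x variants), a .bim-style variant map TSV, GWAS
#' summary TSV, methylation beta TSV (probes x samples), probe manifest TSV,
#' reference probe lists, cell-type reference TSV, sample sheet TSV and a
#' ground-truth JSON.
#'
#' @param cohort output of [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @return invisibly, the named vector of written paths
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    dosage = file.path(dir, "dosage.tsv"), map = file.path(dir, "variants.tsv"),
    gwas = file.path(dir, "gwas_summary.tsv"), beta = file.path(dir, "beta.tsv"),
    manifest = file.path(dir, "manifest.tsv"),
    blood_list = file.path(dir, "blood_variable.tsv"),
    brain_r = file.path(dir, "blood_brain_r.tsv"),
    cell_ref = file.path(dir, "cell_reference.tsv"),
    genes = file.path(dir, "genes.tsv"),
    samples = file.path(dir, "samples.tsv"), truth = file.path(dir, "truth.json"))
  dos <- data.frame(sample_id = rownames(cohort$panel$dosage),
                    cohort$panel$dosage, check.names = FALSE)
  write_tsv(dos, paths["dosage"])
  write_tsv(cohort$panel$map, paths["map"])
  write_tsv(cohort$gwas, paths["gwas"])
  write_tsv(data.frame(probe_id = rownames(cohort$meth$beta), cohort$meth$beta,
                       check.names = FALSE), paths["beta"])
  write_tsv(cohort$meth$manifest, paths["manifest"])
  write_tsv(data.frame(probe_id = cohort$meth$blood_variable_ids), paths["blood_list"])
  write_tsv(cohort$meth$blood_brain_r, paths["brain_r"])
  write_tsv(data.frame(probe_id = rownames(cohort$meth$cell_ref),
                       cohort$meth$cell_ref, check.names = FALSE), paths["cell_ref"])
  write_tsv(cohort$meth$genes, paths["genes"])
  write_tsv(cohort$samples, paths["samples"])
  truth <- cohort$truth
  truth$cell_fractions <- NULL  # large; kept in-memory only
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
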