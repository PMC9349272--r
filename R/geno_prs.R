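#' Read a dosage-TSV genotype panel
#'
#' Expects a samples x variants dosage TSV (first column `sample_id`) and a
#' variant map TSV with columns id, chr, pos (1-based), A1, A2, maf, info —
#' the format written by [write_cohort()].
#'
#' @param dosage_path dosage TSV path
#' @param map_path variant map TSV path
#' @return a [snp_panel()]
#' @export
read_dosage_panel <- function(dosage_path, map_path) {
  dos <- read_tsv(dosage_path)
  map <- read_tsv(map_path)
  m <- as.matrix(dos[, -1, drop = FALSE])
  rownames(m) <- dos[[1]]
  snp_panel(m, map[match(colnames(m), map$id), ])
}

#' Read GWAS summary statistics
#'
#' Accepts the conventional column names SNP, CHR, BP, A1, A2, BETA (or OR),
#' SE, P, INFO, MAF (case-insensitive) and returns the standardised internal
#' layout; odds ratios are converted to log-odds effects.
#'
#' @param path summary TSV path
#' @return data frame with columns id, chr, pos, A1, A2, effect, se, p and,
#'   when present, info and maf
#' @export
read_gwas_summary <- function(path) {
  x <- read_tsv(path)
  names(x) <- tolower(names(x))
  out <- data.frame(id = x[["snp"]] %||% x[["id"]],
                    A1 = toupper(x[["a1"]]), A2 = toupper(x[["a2"]]),
                    stringsAsFactors = FALSE)
  out$chr <- x[["chr"]]; out$pos <- x[["bp"]] %||% x[["pos"]]
  out$effect <- if (!is.null(x[["beta"]])) x[["beta"]]
                else if (!is.null(x[["effect"]])) x[["effect"]]
                else log(x[["or"]])
  out$se <- x[["se"]]; out$p <- x[["p"]]
  out$info <- x[["info"]]; out$maf <- x[["maf"]]
  if (any(out$p <= 0 | out$p > 1, na.rm = TRUE)) stop("p-values must be in (0,1]")
  out
}

#' Harmonise a genotype panel with GWAS summary statistics
#'
#' Keeps variants present in both sources with resolvable alleles. When the
#' panel codes the opposite allele as A1, the dosage is flipped to `2 - d`
#' (and the panel alleles swapped) so the effect sign is preserved and scores
#' are allele-coding invariant. Strand-ambiguous pairs (A/T, C/G) are removed
#' when `drop_ambiguous`, as are variants failing the MAF or imputation-INFO
#' filters. Unresolvable allele mismatches are dropped with a logged reason,
#' never an error.
#'
#' @param panel a [snp_panel()]
#' @param summary GWAS summary data frame (see [read_gwas_summary()])
#' @param maf_min minimum panel MAF (inclusive), default 0.05
#' @param info_min minimum INFO (inclusive), default 0.8
#' @param drop_ambiguous drop strand-ambiguous variants, default TRUE
#' @return list with harmonised `panel`, matching `summary`, and `log`
#'   (data frame of dropped variants with reasons)
#' @export
filter_variants <- function(panel, summary, maf_min = 0.05, info_min = 0.8,
                            drop_ambiguous = TRUE) {
  stopifnot(inherits(panel, "snp_panel"))
  map <- panel$map
  idx <- match(map$id, summary$id)
  reason <- rep(NA_character_, nrow(map))
  reason[is.na(idx)] <- "absent_from_summary"
  s1 <- toupper(summary$A1[idx]); s2 <- toupper(summary$A2[idx])
  same <- map$A1 == s1 & map$A2 == s2
  swapped <- map$A1 == s2 & map$A2 == s1
  reason[is.na(reason) & !(same | swapped)] <- "allele_mismatch"
  if (drop_ambiguous)
    reason[is.na(reason) & is_ambiguous(map$A1, map$A2)] <- "strand_ambiguous"
  reason[is.na(reason) & map$maf < maf_min] <- "maf_below_threshold"
  info <- summary$info[idx] %||% rep(1, nrow(map))
  info[is.na(info)] <- map$info[is.na(info)] %||% 1
  reason[is.na(reason) & info < info_min] <- "info_below_threshold"

  keep <- which(is.na(reason))
  dosage <- panel$dosage[, keep, drop = FALSE]
  map2 <- map[keep, , drop = FALSE]
  flip <- swapped[keep]
  flip[is.na(flip)] <- FALSE
  if (any(flip)) {
    dosage[, flip] <- 2 - dosage[, flip]
    tmp <- map2$A1[flip]; map2$A1[flip] <- map2$A2[flip]; map2$A2[flip] <- tmp
  }
  list(panel = snp_panel(dosage, map2),
       summary = summary[idx[keep], , drop = FALSE],
       log = data.frame(id = map$id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE))
}

#' Greedy linkage-disequilibrium clumping
#'
#' Iterates variants in ascending p-value order: the best remaining variant
#' is retained as an index SNP and every unretained variant on the same
#' chromosome within `window_kb` whose dosage correlation r-squared with the
#' index exceeds `r2_max` is removed. Equal p-values are broken by genomic
#' position (lower first).
#'
#' @param panel a [snp_panel()] (harmonised, see [filter_variants()])
#' @param summary matching summary data frame with `p`
#' @param window_kb clumping window in kilobases (default 250, the scoring
#'   tool's convention)
#' @param r2_max maximum allowed r-squared between retained variants within a
#'   window (default 0.1)
#' @return character vector of retained variant ids
#' @export
ld_clump <- function(panel, summary, window_kb = 250, r2_max = 0.1) {
  stopifnot(inherits(panel, "snp_panel"))
  map <- panel$map
  if (nrow(map) == 0) stop("empty panel")
  p <- summary$p[match(map$id, summary$id)]
  ord <- order(p, map$chr, map$pos)
  win <- window_kb * 1000
  status <- rep("free", nrow(map))  # free | index | clumped
  for (j in ord) {
    if (status[j] != "free") next
    status[j] <- "index"
    cand <- which(status == "free" & map$chr == map$chr[j] &
                    abs(map$pos - map$pos[j]) <= win)
    if (length(cand)) {
      r2 <- suppressWarnings(cor(panel$dosage[, j], panel$dosage[, cand]))^2
      r2[is.na(r2)] <- 0
      status[cand[r2 > r2_max]] <- "clumped"
    }
  }
  map$id[status == "index"]
}

#' Compute a clumping + thresholding polygenic score
#'
#' Raw score for sample i is `(1/(2m)) * sum_j effect_j * dosage_ij` over the
#' m variants with `p < p_T` (average-per-allele convention). Missing dosages
#' are imputed as `2 * MAF`. Standardisation uses the reference mean/SD (the
#' scored cohort itself by default).
#'
#' @param panel harmonised [snp_panel()]
#' @param summary matching summary data frame
#' @param p_T p-value inclusion threshold (exclusive: `p < p_T`)
#' @param standardize compute standardized scores (default TRUE)
#' @param ref_mean,ref_sd optional reference mean and SD for standardisation
#' @return object of class `prs_result`: data frame `scores` (sample_id, raw,
#'   standardized) plus `p_T`, `n_snps_included`, `ref_mean`, `ref_sd`
#' @export
score_prs <- function(panel, summary, p_T, standardize = TRUE,
                      ref_mean = NULL, ref_sd = NULL) {
  stopifnot(inherits(panel, "snp_panel"))
  p <- summary$p[match(panel$map$id, summary$id)]
  inc <- which(p < p_T)
  if (length(inc) == 0) stop(sprintf("no SNPs pass p_T = %g", p_T))
  d <- panel$dosage[, inc, drop = FALSE]
  if (anyNA(d)) {
    imp <- 2 * panel$map$maf[inc]
    for (j in seq_along(inc)) d[is.na(d[, j]), j] <- imp[j]
  }
  eff <- summary$effect[match(panel$map$id[inc], summary$id)]
  raw <- drop(d %*% eff) / (2 * length(inc))
  ref_mean <- ref_mean %||% mean(raw)
  ref_sd <- ref_sd %||% sd(raw)
  std <- if (standardize && ref_sd > 0) (raw - ref_mean) / ref_sd else rep(NA_real_, length(raw))
  structure(list(scores = data.frame(sample_id = rownames(panel$dosage),
                                     raw = raw, standardized = std,
                                     stringsAsFactors = FALSE),
                 p_T = p_T, n_snps_included = length(inc),
                 ref_mean = ref_mean, ref_sd = ref_sd),
            class = "prs_result")
}

#' @export
print.prs_result <- function(x, ...) {
  cat("<prs_result> p_T =", x$p_T, "|", x$n_snps_included, "SNPs |",
      nrow(x$scores), "samples\n")
  invisible(x)
}

#' Nagelkerke pseudo-R-squared for a fitted logistic model
#'
#' `[1 - exp((2/n)(LL0 - LL1))] / [1 - exp((2/n) LL0)]` where LL0 is the
#' log-likelihood of the null (intercept or covariate-only) model.
#'
#' @param fit fitted `glm` (binomial)
#' @param fit0 null-model `glm` fitted on the same data
#' @return scalar in \[0,1\]
#' @export
nagelkerke_r2 <- function(fit, fit0) {
  n <- length(fit$y)
  ll1 <- as.numeric(logLik(fit)); ll0 <- as.numeric(logLik(fit0))
  r2 <- (1 - exp((2 / n) * (ll0 - ll1))) / (1 - exp((2 / n) * ll0))
  min(max(r2, 0), 1)
}

#' Optimise the polygenic-score p-value threshold
#'
#' For each threshold in the grid, computes the score on clumped, harmonised
#' variants, fits `phenotype ~ PRS (+ covariates)` by logistic regression on
#' samples with a non-missing binary phenotype, and reports the Nagelkerke
#' pseudo-R-squared over and above the covariate-only model. Thresholds with
#' complete separation (or no passing SNPs) are skipped with a note.
#'
#' @param panel harmonised, clumped [snp_panel()] (clump first via
#'   [ld_clump()]; pass the subset panel)
#' @param summary matching summary data frame
#' @param phenotype 0/1 vector aligned with panel samples; NA = unlabelled
#'   (excluded from the fit, mirroring scores coded missing)
#' @param covariates optional data frame of covariates
#' @param grid p-value thresholds; the default includes the conventional
#'   optima grid 5e-8 ... 1
#' @return list: `best_p_T`, `profile` data frame (p_T, n_snps, r2,
#'   p, note)
#' @export
optimize_threshold <- function(panel, summary, phenotype, covariates = NULL,
                               grid = c(5e-8, 1e-5, 1e-4, 0.001, 0.005, 0.017,
                                        0.05, 0.105, 0.229, 0.5, 1)) {
  keep <- !is.na(phenotype)
  prof <- data.frame(p_T = grid, n_snps = NA_integer_, r2 = NA_real_,
                     p = NA_real_, note = "", stringsAsFactors = FALSE)
  for (i in seq_along(grid)) {
    prs <- tryCatch(score_prs(panel, summary, grid[i]), error = function(e) NULL)
    if (is.null(prs)) { prof$note[i] <- "no_snps"; next }
    prof$n_snps[i] <- prs$n_snps_included
    dat <- data.frame(y = phenotype[keep], prs = prs$scores$raw[keep])
    if (!is.null(covariates)) dat <- cbind(dat, covariates[keep, , drop = FALSE])
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ ., data = dat, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (sep) { prof$note[i] <- "separation"; next }
    fit0 <- glm(y ~ ., data = dat[, setdiff(names(dat), "prs"), drop = FALSE],
                family = binomial())
    prof$r2[i] <- nagelkerke_r2(fit, fit0)
    prof$p[i] <- summary(fit)$coefficients["prs", 4]
  }
  ok <- which(!is.na(prof$r2))
  if (!length(ok)) stop("no usable threshold in the grid")
  list(best_p_T = prof$p_T[ok[which.max(prof$r2[ok])]], profile = prof)
}

# Pairwise IBS-sharing counts via indicator cross-products.
# Returns list(N0, N1, N2, m_pair) of n x n matrices.
ibs_counts <- function(G) {
  G <- round(G)
  ok <- !is.na(G)
  G0 <- (G == 0) & ok; G1 <- (G == 1) & ok; G2 <- (G == 2) & ok
  mode(G0) <- mode(G1) <- mode(G2) <- "numeric"
  N0 <- G0 %*% t(G2) + G2 %*% t(G0)
  N2 <- G0 %*% t(G0) + G1 %*% t(G1) + G2 %*% t(G2)
  okn <- ok; mode(okn) <- "numeric"
  mp <- okn %*% t(okn)
  list(N0 = N0, N1 = mp - N0 - N2, N2 = N2, m_pair = mp)
}

ibs_distance_matrix <- function(panel) {
  cnt <- ibs_counts(panel$dosage)
  share <- (2 * cnt$N2 + cnt$N1) / (2 * cnt$m_pair)
  d <- 1 - share
  diag(d) <- 0
  dimnames(d) <- list(rownames(panel$dosage), rownames(panel$dosage))
  d
}

#' Method-of-moments relatedness estimation and filtering
#'
#' Estimates pairwise identity-by-descent pi-hat from identity-by-state
#' counts using HWE-expected IBS probabilities at empirical allele
#' frequencies. For each pair with `pi_hat >= pi_hat_max` the member with
#' more missing genotypes (tie: the later sample id) is listed for exclusion.
#'
#' @param panel a [snp_panel()] (>= 2 samples)
#' @param pi_hat_max relatedness threshold, default 0.1 (keep pi_hat < 0.1)
#' @return object of class `relatedness_report`: `pairs` (id1, id2, pi_hat),
#'   `exclusions` (sample ids)
#' @export
relatedness_filter <- function(panel, pi_hat_max = 0.1) {
  stopifnot(inherits(panel, "snp_panel"))
  G <- round(panel$dosage)
  n <- nrow(G)
  if (n < 2) stop("need at least 2 samples")
  pfreq <- colMeans(G, na.rm = TRUE) / 2
  poly <- pfreq > 0 & pfreq < 1
  if (!any(poly)) stop("IBD undefined: panel contains no polymorphic variants")
  p <- pfreq[poly]; q <- 1 - p
  Gp <- G[, poly, drop = FALSE]
  cnt <- ibs_counts(Gp)
  # HWE expectations summed over loci (Purcell et al. method of moments)
  E0_Z0 <- sum(2 * p^2 * q^2)
  E1_Z0 <- sum(4 * p^3 * q + 4 * p * q^3)
  E2_Z0 <- sum(p^4 + 4 * p^2 * q^2 + q^4)
  E1_Z1 <- sum(2 * p * q)
  E2_Z1 <- sum(p^2 + q^2)
  m <- sum(poly)
  Z0 <- cnt$N0 / E0_Z0
  Z1 <- (cnt$N1 - Z0 * E1_Z0) / E1_Z1
  Z2 <- (cnt$N2 - Z0 * E2_Z0 - Z1 * E2_Z1) / m
  pihat <- pmin(pmax(Z1 / 2 + Z2, 0), 1)

  ids <- rownames(G)
  ut <- which(upper.tri(pihat), arr.ind = TRUE)
  pairs <- data.frame(id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
                      pi_hat = pihat[ut], stringsAsFactors = FALSE)
  miss <- rowSums(is.na(panel$dosage))
  flagged <- pairs[pairs$pi_hat >= pi_hat_max, , drop = FALSE]
  drop_of <- function(i1, i2) {
    if (miss[i1] != miss[i2]) return(ids[c(i1, i2)][which.max(c(miss[i1], miss[i2]))])
    sort(ids[c(i1, i2)])[2]  # tie: later sample id
  }
  excl <- unique(vapply(seq_len(nrow(flagged)), function(r)
    drop_of(match(flagged$id1[r], ids), match(flagged$id2[r], ids)), ""))
  structure(list(pairs = pairs, exclusions = excl, pi_hat_max = pi_hat_max),
            class = "relatedness_report")
}

#' @export
print.relatedness_report <- function(x, ...) {
  cat("<relatedness_report>", nrow(x$pairs), "pairs;",
      length(x$exclusions), "exclusions at pi_hat >=", x$pi_hat_max, "\n")
  invisible(x)
}

#' Ancestry components by multidimensional scaling of IBS distances
#'
#' Classical MDS (double-centred squared-distance matrix, top-k eigenvectors
#' scaled by the square root of their eigenvalues) of the pairwise
#' identity-by-state distance `1 - shares/(2m)`. Components are centred.
#'
#' @param panel a [snp_panel()]
#' @param k number of components (default 4); must be < number of samples
#' @return matrix n x k with columns C1..Ck
#' @export
mds_ancestry <- function(panel, k = 4) {
  stopifnot(inherits(panel, "snp_panel"))
  n <- nrow(panel$dosage)
  if (k >= n) stop("k must be smaller than the number of samples")
  d <- ibs_distance_matrix(panel)
  pts <- cmdscale(as.dist(d), k = k)
  if (ncol(pts) < k)  # degenerate spectra pad with zeros
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  colnames(pts) <- paste0("C", seq_len(k))
  pts
}

#' Nearest-neighbour IBS outlier detection
#'
#' Per sample: mean IBS distance to its `n_neighbours` nearest neighbours,
#' Z-standardised across samples; samples with Z > `z_max` are flagged as
#' ancestry outliers.
#'
#' @param panel a [snp_panel()] with more than 5 samples
#' @param n_neighbours neighbourhood size (default 4)
#' @param z_max exclusion threshold (default 4)
#' @return list: `stat` (per-sample mean neighbour distance), `z`,
#'   `exclusions` (sample ids with Z > z_max)
#' @export
ibs_nn_outliers <- function(panel, n_neighbours = 4, z_max = 4) {
  stopifnot(inherits(panel, "snp_panel"))
  n <- nrow(panel$dosage)
  if (n <= 5) stop("need more than 5 samples")
  d <- ibs_distance_matrix(panel)
  k <- min(n_neighbours, n - 1)
  stat <- vapply(seq_len(n), function(i)
    mean(sort(d[i, -i], partial = k)[seq_len(k)]), 0)
  z <- (stat - mean(stat)) / sd(stat)
  list(stat = setNames(stat, rownames(d)), z = setNames(z, rownames(d)),
       exclusions = rownames(d)[z > z_max])
}
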