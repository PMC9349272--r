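test_that("variant harmonisation drops ambiguous, mismatched and low-quality SNPs", {
  set.seed(1)
  d <- matrix(rbinom(5 * 6, 2, 0.3), 5, 6)
  panel <- manual_panel(d, A1 = c("A", "A", "C", "G", "A", "A"),
                        A2 = c("G", "T", "G", "C", "C", "G"),
                        maf = c(0.3, 0.3, 0.3, 0.3, 0.04, 0.05))
  smry <- manual_summary(panel, effect = rep(0.1, 6), p = rep(0.01, 6))
  smry$A1[3] <- "C"; smry$A2[3] <- "G"      # ambiguous C/G
  smry$A1[4] <- "G"; smry$A2[4] <- "C"      # ambiguous G/C
  out <- filter_variants(panel, smry)
  expect_setequal(out$panel$map$id, c("snp01", "snp06"))
  expect_setequal(out$log$reason[out$log$id %in% c("snp02", "snp03", "snp04")],
                  "strand_ambiguous")
  expect_equal(out$log$reason[out$log$id == "snp05"], "maf_below_threshold")
  # boundary: MAF exactly 0.05 retained
  expect_true("snp06" %in% out$panel$map$id)
  # unresolvable allele mismatch is dropped with a reason, not an error
  smry2 <- smry; smry2$A1[1] <- "A"; smry2$A2[1] <- "C"
  out2 <- filter_variants(panel, smry2)
  expect_equal(out2$log$reason[out2$log$id == "snp01"], "allele_mismatch")
  # INFO below threshold
  smry3 <- manual_summary(panel, effect = rep(0.1, 6), p = rep(0.01, 6))
  smry3$info[6] <- 0.5
  out3 <- filter_variants(panel, smry3)
  expect_equal(out3$log$reason[out3$log$id == "snp06"], "info_below_threshold")
})

test_that("allele recoding is harmonised and scores are coding invariant", {
  set.seed(2)
  d <- matrix(rbinom(20 * 3, 2, 0.4), 20, 3)
  panel <- manual_panel(d, A1 = c("A", "C", "T"), A2 = c("G", "T", "C"))
  smry <- manual_summary(panel, effect = c(0.5, -0.2, 0.3), p = rep(0.001, 3))
  base <- score_prs(filter_variants(panel, smry)$panel, smry, p_T = 0.01)
  # the same genotypes coded on the opposite allele at snp 1: harmonisation
  # flips the dosage back and the raw scores are identical
  d_rc <- d; d_rc[, 1] <- 2 - d[, 1]
  panel_rc <- manual_panel(d_rc, A1 = c("G", "C", "T"), A2 = c("A", "T", "C"))
  harm <- filter_variants(panel_rc, smry)
  expect_equal(unname(harm$panel$dosage[, "snp01"]), d[, 1])
  rc <- score_prs(harm$panel, smry, p_T = 0.01)
  expect_equal(rc$scores$raw, base$scores$raw, tolerance = 1e-12)
  # full relabel of the summary (A1<->A2, b <-> -b): standardized invariant
  smry_rl <- smry
  smry_rl[1, c("A1", "A2")] <- smry[1, c("A2", "A1")]
  smry_rl$effect[1] <- -smry$effect[1]
  rl <- score_prs(filter_variants(panel, smry_rl)$panel, smry_rl, p_T = 0.01)
  expect_equal(rl$scores$standardized, base$scores$standardized,
               tolerance = 1e-12)
})

test_that("greedy clumping matches the brute-force oracle", {
  # stated 3-SNP case: strongly correlated trio keeps only the best p
  set.seed(3)
  base <- rbinom(200, 2, 0.4)
  flip <- function(x, k) { i <- sample(length(x), k); x[i] <- 2 - x[i]; x }
  d <- cbind(base, flip(base, 5), flip(base, 8))
  panel <- manual_panel(d, pos = c(1000, 2000, 3000))
  smry <- manual_summary(panel, effect = rep(0.1, 3), p = c(1e-8, 1e-4, 1e-2))
  expect_identical(ld_clump(panel, smry), "snp01")
  # independent SNPs are all retained
  set.seed(4)
  d2 <- matrix(rbinom(500 * 4, 2, 0.4), 500, 4)
  panel2 <- manual_panel(d2)
  smry2 <- manual_summary(panel2, effect = rep(0, 4), p = runif(4))
  expect_length(ld_clump(panel2, smry2), 4)
  # perfectly correlated pair with equal p: exactly one kept, lower pos first
  for (ord in list(c(1, 2), c(2, 1))) {
    dd <- cbind(base, base)[, ord]
    pp <- manual_panel(dd, pos = c(1000, 2000)[ord][order(ord)])
    pp <- manual_panel(cbind(base, base), pos = c(1000, 2000))
    ss <- manual_summary(pp, effect = c(0, 0), p = c(0.5, 0.5))
    expect_identical(ld_clump(pp, ss), "snp01")
  }
  # randomized small panels against the independent oracle
  for (rep_i in 1:10) {
    set.seed(100 + rep_i)
    m <- sample(5:10, 1)
    d3 <- matrix(rbinom(300 * m, 2, 0.3), 300, m)
    for (j in seq_len(m - 1))           # induce some LD between neighbours
      if (runif(1) < 0.5) d3[, j + 1] <- flip(d3[, j], sample(3:40, 1))
    pos <- sort(sample.int(5e5, m))
    panel3 <- manual_panel(d3, pos = pos)
    smry3 <- manual_summary(panel3, effect = rep(0, m),
                            p = round(runif(m), 2))  # rounded p forces ties
    r2 <- suppressWarnings(cor(d3))^2
    r2[is.na(r2)] <- 0
    expect_identical(sort(ld_clump(panel3, smry3, 250, 0.1)),
                     sort(brute_clump(panel3$map, smry3$p, r2, 250000, 0.1)))
  }
  # retained set contains no close pair above the r2 ceiling
  keep <- ld_clump(panel3, smry3, 250, 0.1)
  ki <- match(keep, panel3$map$id)
  for (a in ki) for (b in ki)
    if (a < b && abs(pos[a] - pos[b]) <= 250000)
      expect_lte(r2[a, b], 0.1)
})

test_that("scoring follows the average-per-allele convention", {
  panel <- manual_panel(matrix(c(2, 0), 2, 1), maf = 0.3)
  smry <- manual_summary(panel, effect = 0.5, p = 0.001)
  res <- score_prs(panel, smry, p_T = 0.01)
  expect_equal(res$scores$raw, c(0.5, 0))  # (0.5*2)/(2*1), (0.5*0)/(2*1)
  expect_equal(res$n_snps_included, 1)
  # zero effects give zero scores
  smry0 <- manual_summary(panel, effect = 0, p = 0.001)
  expect_equal(score_prs(panel, smry0, 0.01)$scores$raw, c(0, 0))
  # +1 dosage at one SNP shifts the score by b/(2m)
  set.seed(5)
  d <- matrix(rbinom(2 * 5, 2, 0.5), 2, 5)
  d[2, ] <- d[1, ]; d[2, 3] <- d[1, 3] + 1
  panel5 <- manual_panel(pmin(d, 2), maf = rep(0.3, 5))
  b <- c(0.1, -0.2, 0.4, 0.3, -0.1)
  smry5 <- manual_summary(panel5, effect = b, p = rep(0.001, 5))
  sc <- score_prs(panel5, smry5, 0.01)$scores$raw
  expect_equal(sc[2] - sc[1], b[3] / (2 * 5), tolerance = 1e-12)
  # missing dosage imputed as 2*MAF
  dm <- matrix(c(1, NA), 2, 1)
  panelm <- manual_panel(dm, maf = 0.3)
  panelm$dosage[2, 1] <- NA
  scm <- score_prs(panelm, manual_summary(panelm, 0.5, 0.001), 0.01)
  expect_equal(scm$scores$raw[2], 0.5 * (2 * 0.3) / 2)
  # no SNP passes the threshold: error names it
  expect_error(score_prs(panel, smry, p_T = 1e-10), "1e-10")
  # standardized scores of the reference cohort have mean 0, sd 1
  set.seed(6)
  panel6 <- manual_panel(matrix(rbinom(50 * 4, 2, 0.4), 50, 4))
  smry6 <- manual_summary(panel6, effect = rnorm(4), p = rep(0.001, 4))
  st <- score_prs(panel6, smry6, 0.01)$scores$standardized
  expect_equal(mean(st), 0, tolerance = 1e-12)
  expect_equal(sd(st), 1, tolerance = 1e-12)
})

test_that("Nagelkerke threshold optimisation behaves at the null and recovers signal", {
  set.seed(7)
  # constant PRS: R2 = 0
  y <- rbinom(200, 1, 0.5)
  f1 <- glm(y ~ 1, family = binomial())
  expect_equal(nagelkerke_r2(f1, f1), 0)
  # phenotype independent of PRS: R2 near zero
  panel <- manual_panel(matrix(rbinom(1000 * 6, 2, 0.3), 1000, 6))
  smry <- manual_summary(panel, effect = rnorm(6, 0, 0.05),
                         p = c(1e-6, 1e-3, 0.01, 0.2, 0.4, 0.9))
  y0 <- rbinom(1000, 1, 0.3)
  opt0 <- optimize_threshold(panel, smry, y0)
  expect_true(all(opt0$profile$r2[!is.na(opt0$profile$r2)] < 0.01))
  # synthetic truth: variance explained approaches the liability h2
  cfg <- cohort_config(n_samples = 500, n_snps = 400, n_blocks = 40,
                       h2_liability = 0.5, case_threshold = 0.6,
                       hr_fraction = 0, seed = 8)
  co <- simulate_cohort(cfg)
  harm <- filter_variants(co$panel, co$gwas)
  kept <- ld_clump(harm$panel, harm$summary)
  sub <- snp_panel(harm$panel$dosage[, kept, drop = FALSE],
                   harm$panel$map[match(kept, harm$panel$map$id), ])
  yb <- ifelse(co$samples$group == "CASE", 1L, 0L)
  opt <- optimize_threshold(sub, harm$summary, yb)
  expect_gt(max(opt$profile$r2, na.rm = TRUE), 0.1)
  expect_true(opt$best_p_T <= 0.05)  # causal SNPs sit at strong significance
})

test_that("relatedness estimation flags duplicates and spares the unrelated", {
  g <- simulate_genotypes(cohort_config(n_samples = 30, n_snps = 1200,
                                        n_blocks = 1200, block_rho = 0,
                                        seed = 9))
  dup <- g$panel$dosage
  dup[30, ] <- dup[1, ]  # plant a duplicate pair
  panel <- snp_panel(dup, g$panel$map)
  rr <- relatedness_filter(panel)
  pi_dup <- rr$pairs$pi_hat[rr$pairs$id1 == "S0001" & rr$pairs$id2 == "S0030"]
  expect_gt(pi_dup, 0.9)
  expect_identical(rr$exclusions, "S0030")  # tie on missingness: later id
  # unrelated panel: no pair reaches the threshold
  rr0 <- relatedness_filter(g$panel)
  expect_length(rr0$exclusions, 0)
  expect_lt(mean(rr0$pairs$pi_hat), 0.05)
  # monomorphic-only panel is an error
  mono <- manual_panel(matrix(2, 10, 3), maf = c(0, 0, 0))
  expect_error(relatedness_filter(mono), "polymorphic")
})

test_that("MDS separates divergent subpopulations and centres components", {
  set.seed(10)
  n <- 100; m <- 300
  d <- rbind(matrix(rbinom(n / 2 * m, 2, 0.10), n / 2, m),
             matrix(rbinom(n / 2 * m, 2, 0.45), n / 2, m))
  panel <- manual_panel(d)
  mds <- mds_ancestry(panel, k = 4)
  pop <- rep(0:1, each = n / 2)
  expect_gt(abs(cor(mds[, 1], pop)), 0.9)
  expect_true(all(abs(colMeans(mds)) < 1e-8))
  expect_error(mds_ancestry(panel, k = 100), "smaller")
  # homogeneous cohort: no component aligns with a random split
  set.seed(11)
  dh <- matrix(rbinom(200 * 300, 2, 0.3), 200, 300)
  mh <- mds_ancestry(manual_panel(dh), k = 2)
  split <- rep(0:1, each = 100)
  expect_lt(max(abs(cor(mh, split))), 0.2)
})

test_that("nearest-neighbour IBS statistic isolates a planted outlier", {
  set.seed(12)
  d <- matrix(rbinom(100 * 400, 2, 0.3), 100, 400)
  panel <- manual_panel(d)
  out0 <- ibs_nn_outliers(panel)
  expect_length(out0$exclusions, 0)  # homogeneous cohort: all |Z| < 4
  # inject a sample with shuffled genotypes across loci with varying MAF
  d2 <- matrix(0L, 100, 400)
  mafs <- runif(400, 0.05, 0.5)
  for (j in 1:400) d2[, j] <- rbinom(100, 2, mafs[j])
  d2[50, ] <- rbinom(400, 2, rev(mafs))
  out1 <- ibs_nn_outliers(manual_panel(d2))
  expect_identical(out1$exclusions, "S0050")
  # degenerate neighbourhood equals mean distance to everyone else
  small <- manual_panel(matrix(rbinom(8 * 100, 2, 0.3), 8, 100))
  o <- ibs_nn_outliers(small, n_neighbours = 99)
  dm <- stratmeth:::ibs_distance_matrix(small)
  expect_equal(unname(o$stat),
               sapply(1:8, function(i) mean(dm[i, -i])), tolerance = 1e-12)
  expect_error(ibs_nn_outliers(manual_panel(matrix(1, 4, 10))), "more than 5")
})
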