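test_that("surrogate-variable selection calibrates at the null and recovers a planted factor", {
  X <- cbind(Intercept = 1, stratum = rep(0:1, each = 30))
  k_null <- sapply(1:10, function(s) {
    set.seed(s)
    M <- matrix(rnorm(1000 * 60), 1000, 60)
    ncol(suppressMessages(estimate_surrogates(M, X, seed = s)))
  })
  expect_gte(sum(k_null == 0), 9)
  # planted batch factor affecting 30% of probes
  set.seed(20)
  M <- matrix(rnorm(1000 * 60), 1000, 60)
  batch <- rep(0:1, 30)
  M[1:300, ] <- M[1:300, ] + outer(rnorm(300), batch)
  sv <- estimate_surrogates(M, X, seed = 1)
  expect_gte(ncol(sv), 1)
  expect_gt(abs(cor(sv[, 1], batch)), 0.8)
  # adding the recovered SV removes the batch association from residuals
  X2 <- cbind(X, sv[, 1])
  R2 <- M - M %*% X2 %*% solve(crossprod(X2), t(X2))
  expect_lt(max(abs(cor(t(R2[1:300, ]), batch))), 0.1)
})

test_that("surrogate count agrees with the reference permutation selector", {
  skip_if_not_installed("sva")
  X <- cbind(Intercept = 1, stratum = rep(0:1, each = 30))
  set.seed(21)
  M <- matrix(rnorm(1500 * 60), 1500, 60)
  batch <- rep(0:1, 30)
  M[1:500, ] <- M[1:500, ] + outer(rnorm(500, 0, 1.2), batch)
  k_ref <- sva::num.sv(M, X, method = "be", B = 20, seed = 5)
  k_ours <- ncol(estimate_surrogates(M, X, seed = 5))
  expect_gte(k_ours, 1)
  expect_gte(k_ref, 1)
  expect_lte(abs(k_ours - k_ref), 1)
})

test_that("per-probe fits match closed-form least squares", {
  set.seed(22)
  n <- 40
  X <- cbind(Intercept = 1, stratum = rep(0:1, each = n / 2),
             age = runif(n, 12, 30))
  # exact linear probe: coefficient 2, vanishing p
  M <- rbind(exact = 2 * X[, "stratum"],
             matrix(rnorm(99 * n), 99, n))
  rownames(M) <- c("exact", sprintf("p%02d", 1:99))
  fit <- fit_probe_lm(M, X, moderate_var = FALSE)
  expect_equal(fit$coef[1], 2, tolerance = 1e-10)
  expect_lt(fit$p[1], 1e-12)
  # textbook OLS identity for an arbitrary probe
  y <- M[5, ]
  bh <- solve(crossprod(X), crossprod(X, y))
  expect_equal(fit$coef[5], unname(bh["stratum", 1]), tolerance = 1e-10)
  s2 <- sum((y - X %*% bh)^2) / (n - ncol(X))
  se <- sqrt(s2 * solve(crossprod(X))["stratum", "stratum"])
  expect_equal(fit$se[5], unname(se), tolerance = 1e-10)
  # collinear design aborts naming the column
  Xbad <- cbind(X, dup = X[, "stratum"])
  expect_error(fit_probe_lm(M, Xbad), "dup")
})

test_that("null t-statistics follow their reference distribution", {
  set.seed(23)
  n <- 30
  X <- cbind(Intercept = 1, stratum = rep(0:1, each = n / 2))
  M <- matrix(rnorm(5000 * n), 5000, n)
  rownames(M) <- sprintf("p%04d", 1:5000)
  fit <- fit_probe_lm(M, X, moderate_var = FALSE)
  u <- pt(fit$t, df = n - 2)
  expect_gt(suppressWarnings(ks.test(u, "punif"))$p.value, 0.01)
})

test_that("empirical-null correction is affine and rank preserving", {
  set.seed(24)
  z <- rnorm(2000, 0.2, 1.2)
  fit <- suppressWarnings(bacon_correct(z, iterations = 1500, burn_in = 500,
                                        seed = 1))
  # affine: corrected z reproduces (z - bias)/inflation exactly
  expect_equal(fit$z_corrected, (z - fit$bias) / fit$inflation,
               tolerance = 1e-12)
  expect_identical(order(fit$z_corrected), order(z))
  expect_true(all(fit$weights >= 0))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-6)
  expect_error(bacon_correct(c(1, NA, 2)), "non-finite")
  expect_warning(bacon_correct(rnorm(100), iterations = 200, burn_in = 50),
                 "1000")
  # determinism under a fixed seed
  fit2 <- suppressWarnings(bacon_correct(z, iterations = 1500, burn_in = 500,
                                         seed = 1))
  expect_identical(fit$bias, fit2$bias)
})

test_that("z conversion keeps extreme p-values finite and signs intact", {
  z <- z_from_p(c(1e-300, 0.05, 1), c(-1, 2, 3))
  expect_true(all(is.finite(z)))
  expect_lt(z[1], -35)
  expect_equal(z[2], qnorm(0.025, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(z[3], 0)
})

test_that("Bonferroni thresholds print to the documented precision", {
  expect_equal(bonferroni_threshold(0.05, 35907)$printed, 1.39e-6)
  expect_equal(bonferroni_threshold(0.05, 214352)$printed, 2.33e-7)
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(25)
  p <- runif(200)
  expect_true(all(bh_fdr(p) >= p))
})

test_that("QQ tables use the rank-0.5 convention", {
  qq1 <- qq_manhattan_data(data.frame(p = 0.5))
  expect_equal(qq1$qq$expected, -log10(0.5))
  set.seed(26)
  tab <- data.frame(p = runif(10000), chr = 1, pos = 1:10000)
  qd <- qq_manhattan_data(tab)
  expect_equal(nrow(qd$qq), 10000)
  expect_equal(nrow(qd$manhattan), 10000)
  bulk <- qd$qq$expected < 3  # extreme order statistics fluctuate more
  expect_lt(max(abs(qd$qq$expected - qd$qq$observed)[bulk]), 0.3)
})

test_that("an independent smoking covariate barely perturbs the fitted coefficients", {
  set.seed(27)
  n <- 80
  X <- cbind(Intercept = 1, stratum = rep(0:1, each = n / 2))
  smoke <- runif(n, 0.6, 0.95)  # independent of stratum
  # half the probes carry real stratum effects; the rest are null
  b <- c(rnorm(1000, 0, 0.5), rep(0, 1000))
  M <- outer(b, X[, "stratum"]) + matrix(rnorm(2000 * n, 0, 0.5), 2000, n)
  rownames(M) <- sprintf("p%04d", 1:2000)
  f0 <- fit_probe_lm(M, X, moderate_var = FALSE)
  f1 <- fit_probe_lm(M, cbind(X, smoke = smoke), moderate_var = FALSE)
  rel_rms <- sqrt(mean((f1$coef - f0$coef)^2)) / sqrt(mean(f0$coef^2))
  expect_lt(rel_rms, 0.1)
})

test_that("the assembled scan flags planted probes and reports its pieces", {
  cfg <- tiny_config(n_samples = 80, n_probes = 400, n_coupled_probes = 15,
                     coupling_effect = 1.2, seed = 30)
  sc <- rnorm(80); sc <- (sc - mean(sc)) / sd(sc)
  names(sc) <- sprintf("S%04d", 1:80)
  meth <- simulate_methylation(sc, cfg)
  s <- data.frame(sample_id = names(sc),
                  stratum = ifelse(sc > median(sc), "High", "Low"),
                  batchf = factor(meth$truth$batch))
  M <- beta_to_m(meth$beta[setdiff(rownames(meth$beta), "cg05575921"), ])
  ew <- suppressWarnings(run_ewas(M, s, covariate_cols = "batchf",
                                  bacon_iterations = 1500, bacon_burnin = 500,
                                  seed = 1))
  expect_s3_class(ew, "ewas_result")
  expect_equal(nrow(ew$table), 400)
  coupled <- ew$table$probe %in% meth$truth$coupled_probe_ids
  expect_gt(median(abs(ew$table$t[coupled])), median(abs(ew$table$t[!coupled])))
  expect_true(all(ew$table$q >= ew$table$p_corr - 1e-12))
})
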