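#' Estimate surrogate variables from residual methylation
#'
#' Two-step estimator: M-values are residualised on the fixed design, the
#' residual matrix is decomposed by SVD, and the number of retained
#' components is chosen by Buja-Eyuboglu permutation — each component's
#' eigenvalue share is compared to its null distribution over `B` row-wise
#' permutations of the residuals, and components are kept (from the top,
#' stopping at the first failure) while the permutation p-value is below
#' `alpha`. Deterministic given `seed`.
#'
#' @param M probes x samples M-value matrix
#' @param design samples x q fixed design matrix (full rank)
#' @param alpha permutation significance level, default 0.05
#' @param B number of row-wise permutations, default 20
#' @param max_k maximum number of surrogate variables considered, default 10
#' @param seed integer seed for the permutations
#' @return samples x k matrix of surrogate variables (0 columns allowed),
#'   with attribute `perm_p` holding the per-component permutation p-values
#' @export
estimate_surrogates <- function(M, design, alpha = 0.05, B = 20, max_k = 10,
                                seed = 1) {
  n <- ncol(M)
  stopifnot(nrow(design) == n)
  if (qr(design)$rank < ncol(design)) stop("fixed design is rank deficient")
  H <- design %*% solve(crossprod(design), t(design))
  R <- M - M %*% H
  ev_share <- function(X) {
    ev <- eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    ev / sum(ev)
  }
  obs <- ev_share(R)
  kmax <- min(max_k, length(obs) - ncol(design))
  if (kmax < 1) return(structure(matrix(0, n, 0), perm_p = numeric(0)))
  with_seed(sub_seed(seed, 11L), {
    exceed <- matrix(0L, B, kmax)
    for (b in seq_len(B)) {
      Rp <- t(apply(R, 1, function(r) r[sample.int(n)]))
      # permuted residuals re-residualised on the design, as the observed were
      Rp <- Rp - Rp %*% H
      ps <- ev_share(Rp)
      exceed[b, ] <- ps[seq_len(kmax)] >= obs[seq_len(kmax)]
    }
  })
  perm_p <- (colSums(exceed) + 1) / (B + 1)
  k <- 0L
  for (j in seq_len(kmax)) {
    if (perm_p[j] < alpha) k <- j else break
  }
  if (k == 0L) {
    message("no significant surrogate variables identified")
    return(structure(matrix(0, n, 0), perm_p = perm_p))
  }
  sv <- svd(R, nu = 0, nv = k)$v
  colnames(sv) <- paste0("SV", seq_len(k))
  structure(sv, perm_p = perm_p)
}

#' Per-probe linear model of M-values on a design
#'
#' Ordinary least squares per probe via limma's array-fit machinery. With
#' `moderate_var` the residual variances are shrunk toward a pooled
#' scaled-inverse-chi-squared prior (empirical Bayes moderated t with
#' augmented degrees of freedom); otherwise classical t-statistics with
#' `n - q` degrees of freedom are returned. Two-sided p-values.
#'
#' @param M probes x samples M-value matrix
#' @param design samples x q design matrix (full rank; collinearity aborts
#'   naming the offending columns)
#' @param coef coefficient to report (name or index), default "stratum"
#' @param moderate_var moderate residual variances (default TRUE)
#' @return data frame: probe, coef, se, t, df, p
#' @export
fit_probe_lm <- function(M, design, coef = "stratum", moderate_var = TRUE) {
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[-qrd$pivot[seq_len(qrd$rank)]]
    stop("design is collinear; offending columns: ", paste(bad, collapse = ", "))
  }
  if (anyNA(M)) {
    n_ok <- rowSums(!is.na(M))
    if (any(n_ok < 20))
      stop(sum(n_ok < 20), " probes have fewer than 20 complete observations")
  }
  fit <- limma::lmFit(M, design)
  if (is.character(coef) && !coef %in% colnames(design))
    stop("coefficient '", coef, "' not in the design")
  b <- fit$coefficients[, coef]
  su <- fit$stdev.unscaled[, coef]
  if (moderate_var) {
    eb <- limma::eBayes(fit)
    tt <- eb$t[, coef]
    p <- eb$p.value[, coef]
    se <- su * sqrt(eb$s2.post)
    df <- eb$df.total
  } else {
    se <- su * fit$sigma
    tt <- b / se
    df <- fit$df.residual
    p <- 2 * pt(-abs(tt), df)
  }
  data.frame(probe = rownames(M), coef = b, se = se, t = tt, df = df,
             p = pmax(p, 1e-300), row.names = NULL, stringsAsFactors = FALSE)
}

#' Signed z-scores from two-sided p-values
#'
#' `z = sign(b) * qnorm(1 - p/2)`, the convention for feeding t-derived
#' statistics to the empirical-null correction.
#'
#' @param p two-sided p-values
#' @param estimate signed effect estimates
#' @return numeric z-scores
#' @export
z_from_p <- function(p, estimate) {
  p <- pmin(pmax(p, 1e-300), 1)
  sign(estimate) * qnorm(p / 2, lower.tail = FALSE)
}

#' Empirical-null bias and inflation correction of z-scores
#'
#' Fits a three-component Gaussian mixture to the z-scores by Gibbs sampling
#' (conjugate Dirichlet / normal-inverse-gamma priors; a null-dominant
#' Dirichlet(5,1,1) weight prior; alternative-component means constrained
#' below/above the null mean). The null component's posterior-mean mean is
#' the bias and its posterior-mean SD the inflation; corrected statistics are
#' `z' = (z - bias)/inflation` with two-sided normal p-values — an affine
#' transform, so rank order within the null component is preserved.
#'
#' @param z finite z-scores (a warning is issued below 1000 values)
#' @param iterations total Gibbs iterations, default 5000
#' @param burn_in burn-in iterations, default 2000
#' @param seed integer seed
#' @param prior_weights Dirichlet prior on component weights, default c(5,1,1)
#' @return object of class `empnull_fit`: bias, inflation, weights, means,
#'   sds, z_corrected, p_corrected, settings
#' @export
bacon_correct <- function(z, iterations = 5000, burn_in = 2000, seed = 1,
                          prior_weights = c(5, 1, 1)) {
  if (any(!is.finite(z))) stop("non-finite z-scores present")
  if (length(z) < 1000)
    warning("fewer than 1000 z-scores; empirical-null estimates may be unstable")
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  fit <- with_seed(sub_seed(seed, 13L),
                   empnull_gibbs_cpp(as.numeric(z), as.integer(iterations),
                                     as.integer(burn_in),
                                     as.numeric(prior_weights),
                                     1.0, 0.25, 2.0, 1.0, 3.0))
  zc <- (z - fit$bias) / fit$inflation
  structure(list(bias = fit$bias, inflation = fit$inflation,
                 weights = fit$weights, means = fit$means, sds = fit$sds,
                 z_corrected = zc,
                 p_corrected = pmax(2 * pnorm(-abs(zc)), 1e-300),
                 settings = list(iterations = iterations, burn_in = burn_in,
                                 seed = seed, prior_weights = prior_weights)),
            class = "empnull_fit")
}

#' @export
print.empnull_fit <- function(x, ...) {
  cat(sprintf("<empnull_fit> bias = %.4g, inflation = %.4g (pi0 = %.2f)\n",
              x$bias, x$inflation, x$weights[1]))
  invisible(x)
}

#' Bonferroni threshold
#'
#' `alpha / m`, returned at full precision with the 3-significant-figure
#' printed form alongside.
#'
#' @param alpha family-wise error rate, default 0.05
#' @param m number of tests
#' @return list: `threshold`, `printed` (3 s.f.)
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m <= 0) stop("m must be positive")
  thr <- alpha / m
  list(threshold = thr, printed = signif(thr, 3))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH-adjusted q-values with monotonicity enforcement (delegates to
#' the standard step-up implementation).
#'
#' @param p p-values
#' @return q-values, same length
#' @export
bh_fdr <- function(p) p.adjust(p, method = "BH")

#' Plotting tables for QQ and Manhattan displays
#'
#' Expected quantiles use the rank-0.5 convention
#' `-log10((rank - 0.5)/m)`.
#'
#' @param table EWAS table with columns `p` (or the column named by
#'   `p_field`), and optionally `chr`, `pos`
#' @param p_field p-value column, default "p"
#' @param threshold epigenome-wide threshold to carry on the output
#' @return list: `qq` (expected, observed, both -log10), `manhattan`
#'   (chr, pos, neglog10p; NULL without coordinates), `threshold`
#' @export
qq_manhattan_data <- function(table, p_field = "p", threshold = NULL) {
  p <- table[[p_field]]
  m <- length(p)
  ord <- order(p)
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                   observed = -log10(p[ord]))
  man <- if (all(c("chr", "pos") %in% names(table)))
    data.frame(chr = table$chr, pos = table$pos, neglog10p = -log10(p))
  else NULL
  list(qq = qq, manhattan = man, threshold = threshold)
}

#' PRS-stratum epigenome-wide association scan
#'
#' The full discovery analysis: builds the design (stratum coded Low = 0 /
#' High = 1 plus covariates), estimates surrogate variables from the
#' residuals, fits the per-probe linear model on M-values, converts the
#' two-sided p-values to signed z-scores, applies the empirical-null bias and
#' inflation correction, and attaches BH q-values and the Bonferroni
#' threshold. A negative coefficient means hypomethylation in the high-PRS
#' stratum.
#'
#' @param M probes x samples M-value matrix
#' @param samples sample sheet data frame aligned with `colnames(M)`
#' @param stratum_col column of `samples` holding the stratum, coded
#'   "Low"/"High" (or 0/1)
#' @param covariate_cols columns of `samples` used as fixed covariates
#'   (factors expanded by `model.matrix`)
#' @param n_sv "auto" for Buja-Eyuboglu selection, or a fixed integer
#' @param moderate_var moderate residual variances (default TRUE)
#' @param bacon_iterations,bacon_burnin Gibbs settings (defaults 5000/2000)
#' @param alpha family-wise error rate for the Bonferroni threshold
#' @param seed integer seed
#' @return object of class `ewas_result`: `table` (probe, coef, se, t, p_raw,
#'   z, z_corr, p_corr, q, pass_bonferroni), `empnull` fit, `n_sv`,
#'   `threshold`, `design`
#' @export
run_ewas <- function(M, samples, stratum_col = "stratum",
                     covariate_cols = NULL, n_sv = "auto",
                     moderate_var = TRUE, bacon_iterations = 5000,
                     bacon_burnin = 2000, alpha = 0.05, seed = 1) {
  strat <- samples[[stratum_col]]
  if (is.character(strat) || is.factor(strat))
    strat <- as.integer(as.character(strat) == "High")
  dat <- data.frame(stratum = strat)
  if (!is.null(covariate_cols))
    dat <- cbind(dat, samples[, covariate_cols, drop = FALSE])
  X0 <- model.matrix(~ ., data = dat)
  colnames(X0)[colnames(X0) == "(Intercept)"] <- "Intercept"
  if (ncol(M) <= ncol(X0) + 5)
    stop("too few samples for the requested design")
  sv <- if (identical(n_sv, "auto")) {
    estimate_surrogates(M, X0, seed = seed)
  } else if (n_sv > 0) {
    H <- X0 %*% solve(crossprod(X0), t(X0))
    R <- M - M %*% H
    v <- svd(R, nu = 0, nv = n_sv)$v
    colnames(v) <- paste0("SV", seq_len(n_sv))
    v
  } else matrix(0, ncol(M), 0)
  X <- cbind(X0, sv)
  fit <- fit_probe_lm(M, X, coef = "stratum", moderate_var = moderate_var)
  z <- z_from_p(fit$p, fit$coef)
  bc <- bacon_correct(z, iterations = bacon_iterations, burn_in = bacon_burnin,
                      seed = seed)
  thr <- bonferroni_threshold(alpha, nrow(fit))
  tab <- data.frame(probe = fit$probe, coef = fit$coef, se = fit$se,
                    t = fit$t, p_raw = fit$p, z = z,
                    z_corr = bc$z_corrected, p_corr = bc$p_corrected,
                    q = bh_fdr(bc$p_corrected),
                    pass_bonferroni = bc$p_corrected < thr$threshold,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, empnull = bc, n_sv = ncol(sv),
                 threshold = thr, design = X),
            class = "ewas_result")
}

#' @export
print.ewas_result <- function(x, ...) {
  cat("<ewas_result>", nrow(x$table), "probes |", x$n_sv, "SVs | bias",
      signif(x$empnull$bias, 3), "| inflation", signif(x$empnull$inflation, 3),
      "|", sum(x$table$pass_bonferroni), "epigenome-wide hits\n")
  invisible(x)
}
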