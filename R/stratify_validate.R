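#' Quintile stratification of a score distribution
#'
#' Sorts samples by score (ties broken by stable input order) and assigns the
#' bottom `round(0.4 n)` samples to the Low stratum (bottom two quintiles),
#' the top `round(0.4 n)` to High (top two quintiles), and the remainder to
#' Mid. Rounding is half-up, which reproduces 41/41 strata at n = 103 and
#' 27/27 at n = 67.
#'
#' @param prs named numeric vector of scores (names = sample ids)
#' @return object of class `stratum_assignment`: `assignment` data frame
#'   (sample_id, prs, stratum), `counts`, `cutpoints`
#' @export
quintile_strata <- function(prs) {
  n <- length(prs)
  if (n < 5) stop("need at least 5 samples to form quintile strata")
  ids <- names(prs) %||% as.character(seq_len(n))
  k <- floor(0.4 * n + 0.5)  # round half-up
  ord <- order(prs)  # stable: ties keep input (id) order
  stratum <- rep("Mid", n)
  stratum[ord[seq_len(k)]] <- "Low"
  stratum[ord[seq.int(n - k + 1, n)]] <- "High"
  cut_low <- prs[ord[k]]
  cut_high <- prs[ord[n - k + 1]]
  structure(list(assignment = data.frame(sample_id = ids, prs = as.numeric(prs),
                                         stratum = stratum,
                                         stringsAsFactors = FALSE),
                 counts = c(Low = k, Mid = n - 2L * k, High = k),
                 cutpoints = c(low_max = as.numeric(cut_low),
                               high_min = as.numeric(cut_high))),
            class = "stratum_assignment")
}

#' @export
print.stratum_assignment <- function(x, ...) {
  cat("<stratum_assignment>"); print(x$counts); invisible(x)
}

#' Poly-methylomic profile score
#'
#' Weighted sum of target-sample methylation over the CpGs selected from a
#' discovery scan: `PMPS_i = sum_j b_j * beta_ij` over probes with discovery
#' p-value below `p_T` that are present in the target matrix (absent probes
#' are dropped silently and counted). Weights default to the raw discovery
#' coefficients; target values default to the beta scale (M optional).
#'
#' @param target_beta probes x samples beta matrix of the target set
#' @param discovery discovery EWAS table (e.g. `ewas_result$table`) with
#'   columns `probe`, the weight field and the p field
#' @param p_T discovery p-value threshold (exclusive), e.g. 0.002/0.01/0.05
#' @param weight_field coefficient column used as weights, default "coef"
#' @param p_field p-value column used for selection, default "p_corr"
#' @param scale score the target on "beta" (default) or "m" values
#' @param aggregate "sum" (default, the profile-score analogy to an unaveraged
#'   allele score) or "mean"
#' @return object of class `pmps_table`: `scores` data frame (sample_id,
#'   pmps), `p_T`, `n_cpgs`, `n_dropped`, `weight_field`, `scale`
#' @export
compute_pmps <- function(target_beta, discovery, p_T, weight_field = "coef",
                         p_field = "p_corr", scale = c("beta", "m"),
                         aggregate = c("sum", "mean")) {
  scale <- match.arg(scale)
  aggregate <- match.arg(aggregate)
  sel <- discovery[discovery[[p_field]] < p_T, , drop = FALSE]
  present <- sel$probe %in% rownames(target_beta)
  n_dropped <- sum(!present)
  sel <- sel[present, , drop = FALSE]
  if (nrow(sel) == 0) stop("no discovery probes below p_T overlap the target set")
  X <- target_beta[sel$probe, , drop = FALSE]
  if (scale == "m") X <- beta_to_m(X)
  w <- sel[[weight_field]]
  pmps <- drop(crossprod(X, w))
  if (aggregate == "mean") pmps <- pmps / nrow(sel)
  structure(list(scores = data.frame(sample_id = colnames(target_beta),
                                     pmps = as.numeric(pmps),
                                     stringsAsFactors = FALSE),
                 p_T = p_T, n_cpgs = nrow(sel), n_dropped = n_dropped,
                 weight_field = weight_field, scale = scale,
                 aggregate = aggregate),
            class = "pmps_table")
}

#' @export
print.pmps_table <- function(x, ...) {
  cat("<pmps_table> p_T =", x$p_T, "|", x$n_cpgs, "CpGs |",
      nrow(x$scores), "samples\n")
  invisible(x)
}

# partial eta^2 from a type-III ANOVA table with a Residuals row
partial_eta_sq <- function(anova_tab) {
  ss <- anova_tab[["Sum Sq"]]
  ss_res <- ss[rownames(anova_tab) == "Residuals"]
  ss / (ss + ss_res)
}

#' Validation general linear model with type-III tests
#'
#' OLS of an outcome (typically a poly-methylomic profile score) on a binary
#' group factor and covariates, with optional PRS main effect and PRS-by-group
#' interaction. Per-term type-III F-tests use sum-to-zero contrasts (the
#' univariate-GLM convention), effect sizes are partial eta-squared
#' `SS_term/(SS_term + SS_resid)`, and Shapiro-Wilk normality of the outcome
#' is reported within each group.
#'
#' @param data data frame holding all modelled columns
#' @param outcome outcome column name
#' @param group binary group column name (factor or character; < 3 members in
#'   a group is an error)
#' @param covariates character vector of covariate column names (optional)
#' @param prs PRS column name to include as a main effect (optional)
#' @param include_interaction add the PRS-by-group interaction (requires `prs`)
#' @return object of class `glm_report`: `terms` data frame (term, df, F, p,
#'   partial_eta_sq), `shapiro` per-group data frame, `model` the lm fit
#' @export
validate_glm <- function(data, outcome, group, covariates = NULL, prs = NULL,
                         include_interaction = FALSE) {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) stop("group must be binary")
  if (any(table(g) < 3)) stop("each group needs at least 3 members")
  if (include_interaction && is.null(prs))
    stop("the interaction model requires a PRS column")
  dat <- data
  dat[[group]] <- g
  rhs <- c(group, covariates, prs,
           if (include_interaction) paste0(prs, ":", group))
  fml <- stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- lm(fml, data = dat)
  a3 <- car::Anova(fit, type = 3)
  keep <- !rownames(a3) %in% c("(Intercept)", "Residuals")
  terms_df <- data.frame(term = rownames(a3)[keep],
                         df = a3$Df[keep],
                         F = a3$`F value`[keep],
                         p = a3$`Pr(>F)`[keep],
                         partial_eta_sq = partial_eta_sq(a3)[keep],
                         stringsAsFactors = FALSE)
  sw <- do.call(rbind, lapply(levels(g), function(lv) {
    y <- dat[[outcome]][g == lv]
    s <- if (length(y) >= 3 && length(y) <= 5000 && sd(y) > 0)
      shapiro.test(y) else list(statistic = NA_real_, p.value = NA_real_)
    data.frame(group = lv, W = unname(s$statistic), p = s$p.value,
               stringsAsFactors = FALSE)
  }))
  structure(list(terms = terms_df, shapiro = sw, model = fit),
            class = "glm_report")
}

#' @export
print.glm_report <- function(x, ...) {
  cat("<glm_report>\n"); print(x$terms, digits = 3); invisible(x)
}

#' Exploratory family-environment model
#'
#' Linear model of the profile score on family-environment score (FACES),
#' PRS, group, the PRS-by-group and FACES-by-group interactions, with age and
#' sex as covariates. Each single-df term is reported as a Wald chi-squared
#' `(coef/SE)^2` with a 1-df chi-squared p-value; the omnibus model p comes
#' from the overall F-test.
#'
#' @param data data frame holding all modelled columns
#' @param outcome outcome column name (PMPS)
#' @param faces family-environment score column (must not be constant)
#' @param prs PRS column
#' @param group binary group column
#' @param covariates additional covariate names, default c("age", "sex")
#' @return object of class `glm_report` with Wald columns (term, chisq, p)
#'   plus `omnibus_p` and the lm fit
#' @export
faces_model <- function(data, outcome, faces, prs, group,
                        covariates = c("age", "sex")) {
  if (sd(data[[faces]], na.rm = TRUE) == 0) stop("FACES vector is constant")
  dat <- data
  dat[[group]] <- factor(dat[[group]])
  fml <- stats::as.formula(paste(
    outcome, "~", paste(c(faces, prs, group, covariates,
                          paste0(prs, ":", group), paste0(faces, ":", group)),
                        collapse = " + ")))
  fit <- lm(fml, data = dat)
  cf <- summary(fit)$coefficients
  keep <- rownames(cf) != "(Intercept)"
  wald <- data.frame(term = rownames(cf)[keep],
                     estimate = cf[keep, 1], se = cf[keep, 2],
                     chisq = (cf[keep, 1] / cf[keep, 2])^2,
                     p = pchisq((cf[keep, 1] / cf[keep, 2])^2, df = 1,
                                lower.tail = FALSE),
                     row.names = NULL, stringsAsFactors = FALSE)
  fstat <- summary(fit)$fstatistic
  omnibus_p <- pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(terms = wald, omnibus_p = unname(omnibus_p), model = fit),
            class = "glm_report")
}
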