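#' Beta to M-value transform (and inverse)
#'
#' `M = log2(beta / (1 - beta))`; beta values are clipped to
#' \[1e-6, 1 - 1e-6\] before the logit so the transform stays finite.
#' The inverse is exact on the clipped range.
#'
#' @param beta beta values (vector or matrix) in (0,1)
#' @param m M-values
#' @return transformed values of the same shape
#' @export
beta_to_m <- function(beta) {
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE)) {
    beta <- clip01(beta)
    if (any(beta <= 0 | beta >= 1, na.rm = TRUE))
      stop("beta values must lie in (0,1)")
  }
  logit2(beta)
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) ilogit2(m)

#' Filter probes to the analysis CpG set
#'
#' Applies the four-stage probe filter: (1) data variability — the 10th-90th
#' percentile range of beta across samples must exceed `range_min`; (2)
#' membership in a blood-variable probe list; (3) blood-brain concordance —
#' |mean r| >= `r_min` (sign-agnostic), optional; (4) removal of probes with
#' an annotated SNP within 50 bp (`probe_snp` manifest flag). The final set is
#' the pure intersection, so the result is invariant to filter order; counts
#' are reported in the fixed order variability, blood list, brain
#' correlation, probe-SNP. Probes missing a brain-correlation value when that
#' filter is on are counted as failing it (reported separately).
#'
#' @param beta probes x samples beta matrix (rownames = probe ids)
#' @param manifest data frame with `probe_id` and logical `probe_snp`
#' @param blood_variable_ids character vector of blood-variable probe ids
#' @param blood_brain_r data frame with `probe_id`, `mean_r`
#' @param range_min variability threshold (strict `>`), default 0.05
#' @param r_min blood-brain correlation threshold (inclusive `>=`), default 0.3
#' @param use_brain_filter apply the blood-brain filter (default TRUE); off
#'   reproduces the wider supplementary analysis probe set
#' @return object of class `probe_filter_report`: `flags` per-probe logical
#'   data frame, `counts` retained count after each stage, `retained` final ids
#' @export
filter_probes <- function(beta, manifest, blood_variable_ids, blood_brain_r,
                          range_min = 0.05, r_min = 0.3,
                          use_brain_filter = TRUE) {
  ids <- rownames(beta)
  if (is.null(ids)) stop("beta matrix must have probe-id rownames")
  qs <- apply(beta, 1, quantile, probs = c(0.1, 0.9), na.rm = TRUE)
  pass_var <- (qs[2, ] - qs[1, ]) > range_min
  pass_blood <- ids %in% blood_variable_ids
  r <- blood_brain_r$mean_r[match(ids, blood_brain_r$probe_id)]
  missing_r <- is.na(r)
  pass_brain <- if (use_brain_filter) !missing_r & abs(r) >= r_min
                else rep(TRUE, length(ids))
  snp_flag <- manifest$probe_snp[match(ids, manifest$probe_id)]
  snp_flag[is.na(snp_flag)] <- FALSE
  pass_snp <- !snp_flag

  flags <- data.frame(probe_id = ids, pass_variability = pass_var,
                      pass_blood_list = pass_blood, pass_brain = pass_brain,
                      missing_brain_r = use_brain_filter & missing_r,
                      pass_probe_snp = pass_snp, stringsAsFactors = FALSE)
  keep <- pass_var & pass_blood & pass_brain & pass_snp
  counts <- c(input = length(ids),
              variability = sum(pass_var),
              blood_list = sum(pass_var & pass_blood),
              brain_correlation = sum(pass_var & pass_blood & pass_brain),
              probe_snp = sum(keep))
  structure(list(flags = flags, counts = counts, retained = ids[keep],
                 use_brain_filter = use_brain_filter),
            class = "probe_filter_report")
}

#' @export
print.probe_filter_report <- function(x, ...) {
  cat("<probe_filter_report> retained", length(x$retained), "of",
      x$counts[["input"]], "probes\n")
  print(x$counts)
  invisible(x)
}

#' Reference-based blood cell-type deconvolution
#'
#' Constrained projection of each sample's beta profile onto purified
#' cell-type reference profiles: per sample solve
#' `min || x - R w ||^2  s.t.  w >= 0, sum(w) <= 1`
#' by quadratic programming on the beta scale.
#'
#' @param beta probes x samples beta matrix
#' @param reference probes x cell-types reference beta matrix (rownames =
#'   probe ids); at least 10 probes must overlap `beta`
#' @return samples x cell-types matrix of estimated fractions
#' @export
estimate_cell_counts <- function(beta, reference) {
  common <- intersect(rownames(beta), rownames(reference))
  if (length(common) < 10)
    stop("fewer than 10 probes shared between data and reference")
  R <- as.matrix(reference[common, , drop = FALSE])
  k <- ncol(R)
  qrR <- qr(R)
  if (qrR$rank < k) {
    bad <- colnames(R)[-qrR$pivot[seq_len(qrR$rank)]]
    stop("reference is rank deficient; collinear cell types: ",
         paste(bad, collapse = ", "))
  }
  Dmat <- crossprod(R) + diag(1e-9, k)
  Amat <- cbind(rep(-1, k), diag(k))   # sum(w) <= 1, w >= 0
  bvec <- c(-1, rep(0, k))
  X <- as.matrix(beta[common, , drop = FALSE])
  out <- t(apply(X, 2, function(x) {
    quadprog::solve.QP(Dmat, drop(crossprod(R, x)), Amat, bvec)$solution
  }))
  out[out < 0] <- 0  # numerical dust from the QP boundary
  dimnames(out) <- list(colnames(beta), colnames(R))
  out
}

#' Epigenetic smoking inference
#'
#' Classifies samples as probable smokers from the normalised beta at the
#' AHRR probe cg05575921: `beta < beta_cut` flags a probable smoker
#' (strict inequality; beta exactly at the cut is a non-smoker).
#'
#' @param beta probes x samples beta matrix
#' @param probe smoking probe id, default "cg05575921"
#' @param beta_cut classification threshold, default 0.75
#' @return data frame: sample_id, beta, smoker (logical)
#' @export
infer_smoking <- function(beta, probe = "cg05575921", beta_cut = 0.75) {
  if (!probe %in% rownames(beta))
    stop(sprintf("probe %s absent from the matrix; check the manifest/normalised input", probe))
  b <- beta[probe, ]
  data.frame(sample_id = colnames(beta) %||% seq_along(b), beta = as.numeric(b),
             smoker = as.numeric(b) < beta_cut, stringsAsFactors = FALSE)
}
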