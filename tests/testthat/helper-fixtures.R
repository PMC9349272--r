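# Small builders shared across the test files. Everything is generated in
# code under fixed seeds; nothing is read from disk except the committed
# pilot-simulation table.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_samples = 60, n_snps = 120, n_blocks = 12, n_probes = 300,
         n_coupled_probes = 10, seed = 1),
    list(...))
  do.call(cohort_config, args)
}

# hand-built panel with explicit dosages/map, for clumping and scoring tests
manual_panel <- function(dosage, chr = 1, pos = NULL, A1 = "A", A2 = "G",
                         maf = NULL, info = 1) {
  m <- ncol(dosage)
  map <- data.frame(id = sprintf("snp%02d", seq_len(m)),
                    chr = rep_len(chr, m),
                    pos = pos %||% (seq_len(m) * 1000),
                    A1 = rep_len(A1, m), A2 = rep_len(A2, m),
                    maf = maf %||% pmin(pmax(colMeans(dosage) / 2, 0.01), 0.5),
                    info = rep_len(info, m), stringsAsFactors = FALSE)
  snp_panel(dosage, map)
}

manual_summary <- function(panel, effect, p, A1 = NULL, A2 = NULL) {
  map <- panel$map
  data.frame(id = map$id, chr = map$chr, pos = map$pos,
             A1 = A1 %||% map$A1, A2 = A2 %||% map$A2,
             effect = effect, se = 0.1, p = p, info = map$info, maf = map$maf,
             stringsAsFactors = FALSE)
}

# independent greedy-clumping oracle: quadratic scan over explicit matrices
brute_clump <- function(map, p, r2mat, window_bp, r2max) {
  keep <- character(0)
  status <- rep("free", nrow(map))
  repeat {
    free <- which(status == "free")
    if (!length(free)) break
    j <- free[order(p[free], map$chr[free], map$pos[free])][1]
    status[j] <- "index"
    keep <- c(keep, map$id[j])
    for (k in which(status == "free"))
      if (map$chr[k] == map$chr[j] && abs(map$pos[k] - map$pos[j]) <= window_bp &&
          r2mat[j, k] > r2max)
        status[k] <- "clumped"
  }
  keep
}

# exhaustive hypergeometric upper-tail oracle by draw enumeration (N <= 25)
brute_hyper_p <- function(N, K, n, k_obs) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # first K elements form the set
  mean(hits >= k_obs)
}
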