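#' @useDynLib stratmeth, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom qnorm pnorm dnorm plogis sd cor
#'   model.matrix lm glm binomial logLik pt qt p.adjust cmdscale quantile
#'   shapiro.test ks.test phyper setNames complete.cases coef rgamma median mad
#'   pf pchisq var ave
#' @importFrom utils read.delim write.table head
NULL

# logit2 / inverse-logit2: the M-value transform scale (log2 odds of beta)
logit2 <- function(b) log2(b / (1 - b))
ilogit2 <- function(x) plogis(x * log(2))

clip01 <- function(b, eps = 1e-6) pmin(pmax(b, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as TSV
#'
#' Plain tab-separated writer used for every file the pipeline emits
#' (no quoting, no row names), so outputs are diffable and hash-stable.
#'
#' @param x data frame
#' @param path output path
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file path
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

# Derive a stream-specific 32-bit sub-seed from a master seed.
sub_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 7919L) %% 2147483587L
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
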