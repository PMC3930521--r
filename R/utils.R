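#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_chr map2 pmap imap list_rbind
#' @importFrom stats pgamma optim rbinom rpois rexp runif rmultinom setNames
#'   ks.test pchisq chisq.test fisher.test var na.omit quantile
#' @importFrom utils head tail combn
NULL

# Deterministic sub-seed for a named random stream, so e.g. every cell of a
# pairwise matrix gets its own reproducible stream regardless of evaluation
# order. Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 31 + k) %% 2147483563L
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483563L)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Permutation p-value with the "+1" correction
#'
#' Computes `p = (1 + #\{null >= observed\}) / (1 + n)` so that a permutation
#' p-value is never exactly zero. Larger values of the statistic are taken as
#' more extreme.
#'
#' @param observed Observed value of the test statistic.
#' @param null_draws Numeric vector of statistic values under permuted labels.
#' @return A single p-value in `(0, 1]`.
#' @export
#' @examples
#' permutation_p(2.0, rnorm(999))
permutation_p <- function(observed, null_draws) {
  stopifnot(length(null_draws) >= 1)
  (1 + sum(null_draws >= observed)) / (1 + length(null_draws))
}

#' Sequential Bonferroni (Holm step-down) decisions
#'
#' Holm's step-down procedure: p-values are sorted ascending and the i-th is
#' rejected while `p_(i) < alpha / (k - i + 1)`; the first failure stops all
#' further rejections.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Logical vector of rejection decisions in the original order.
#' @export
#' @examples
#' sequential_bonferroni(c(0.01, 0.02, 0.04))
sequential_bonferroni <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  k <- length(p)
  ord <- order(p)
  reject <- logical(k)
  for (i in seq_len(k)) {
    pi <- p[ord[i]]
    if (is.na(pi) || pi >= alpha / (k - i + 1)) break
    reject[ord[i]] <- TRUE
  }
  reject
}

harmonic_mean_smogd <- function(x) {
  # SMOGD-style harmonic mean across loci: variance-corrected approximation
  # 1 / (1/A + V / A^3), exact when all values are equal; degrades gracefully
  # when some loci have value 0 (the plain harmonic mean would be undefined
  # or identically 0).
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  a <- mean(x)
  if (a <= 0) return(0)
  v <- if (length(x) > 1) stats::var(x) * (length(x) - 1) / length(x) else 0
  1 / (1 / a + v / a^3)
}
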