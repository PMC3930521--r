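# Drift-based power simulation for detecting weak differentiation with a
# multilocus microsatellite panel (the Powsim design): allele frequencies
# drift apart for t generations chosen to reach a target F_ST, samples are
# drawn, and an allele-frequency homogeneity test is combined across loci.

#' Generations of drift needed to reach a target F_ST
#'
#' From `F_ST = 1 - (1 - 1/(2 Ne))^t`: `t = ceil(ln(1 - F_ST) /
#' ln(1 - 1/(2 Ne)))`.
#'
#' @param target_fst Target differentiation in `[0, 1)`.
#' @param ne Effective population size (`>= 2`).
#' @return Integer number of generations (0 when `target_fst = 0`).
#' @export
#' @examples
#' drift_generations(0.05, 500)  # 52
drift_generations <- function(target_fst, ne) {
  stopifnot(target_fst >= 0, target_fst < 1, ne >= 2)
  if (target_fst == 0) return(0L)
  as.integer(ceiling(log(1 - target_fst) / log(1 - 1 / (2 * ne))))
}

drift_freqs <- function(p, ne, t) {
  # multinomial resampling of 2*Ne genes per generation
  for (g in seq_len(t)) {
    p <- as.numeric(rmultinom(1, 2 * ne, p)) / (2 * ne)
  }
  p
}

combine_fisher <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  stat <- -2 * sum(log(pmax(p, 1e-300)))
  stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
}

#' Power simulation for detecting differentiation (Powsim design)
#'
#' Each replicate drifts the base allele frequencies independently in each
#' population for `t = drift_generations(target_fst, ne)` generations by
#' binomial/multinomial resampling of `2 Ne` genes, draws `2 n` sample genes
#' per population, tests allele-frequency homogeneity per locus (chi-squared
#' by default, or Fisher's exact test), combines loci by Fisher's method, and
#' scores significance at `alpha`. Power is the proportion of significant
#' replicates; at `target_fst = 0` this estimates the type-I error rate.
#'
#' @param base_freqs List of numeric allele-frequency vectors, one per locus.
#' @param ne Effective population size used for drift.
#' @param target_fst Target F_ST level.
#' @param sample_sizes Integer vector of per-population sample sizes
#'   (individuals); its length sets the number of populations.
#' @param reps Number of simulation replicates (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param test `"chisq"` or `"fisher"` per-locus homogeneity test.
#' @param seed Seed.
#' @return An object of class `power_result`: tibble-backed list with the
#'   scenario parameters, `t` generations, per-replicate p-values and `power`.
#' @export
power_simulation <- function(base_freqs, ne, target_fst, sample_sizes,
                             reps = 1000, alpha = 0.05,
                             test = c("chisq", "fisher"), seed = 1L) {
  test <- match.arg(test)
  stopifnot(is.list(base_freqs), all(sample_sizes >= 1))
  t_gen <- drift_generations(target_fst, ne)
  npop <- length(sample_sizes)
  pvals <- with_seed(derive_seed(seed, "power", target_fst, ne), {
    vapply(seq_len(reps), function(rep) {
      locus_p <- vapply(base_freqs, function(p0) {
        freqs <- lapply(seq_len(npop), function(i) drift_freqs(p0, ne, t_gen))
        counts <- vapply(seq_len(npop), function(i) {
          as.numeric(rmultinom(1, 2 * sample_sizes[i], freqs[[i]]))
        }, numeric(length(p0)))
        tab <- t(counts)                       # pops x alleles
        tab <- tab[, colSums(tab) > 0, drop = FALSE]
        if (ncol(tab) < 2) return(NA_real_)    # allele lost everywhere
        if (test == "chisq") {
          suppressWarnings(stats::chisq.test(tab)$p.value)
        } else {
          stats::fisher.test(tab, simulate.p.value = TRUE, B = 200)$p.value
        }
      }, 0)
      combine_fisher(locus_p)
    }, 0)
  })
  structure(list(target_fst = target_fst, ne = ne, t = t_gen,
                 n_loci = length(base_freqs), sample_sizes = sample_sizes,
                 reps = reps, alpha = alpha, test = test,
                 p_values = pvals,
                 power = mean(pvals < alpha, na.rm = TRUE)),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat("<power_result> target F_ST = ", x$target_fst, ", Ne = ", x$ne,
      ", t = ", x$t, " generations: power = ", format(x$power, digits = 3),
      " (", x$reps, " replicates, alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.power_result <- function(x, ...) {
  tibble(replicate = seq_along(x$p_values), p = x$p_values,
         significant = x$p_values < x$alpha)
}

#' @export
glance.power_result <- function(x, ...) {
  tibble(target_fst = x$target_fst, ne = x$ne, t = x$t, n_loci = x$n_loci,
         reps = x$reps, alpha = x$alpha, power = x$power)
}
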