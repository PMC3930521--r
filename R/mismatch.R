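# Mismatch distribution and the sudden-expansion (Rogers-Harpending) model:
# a population at mutation-scaled size theta0 grows instantaneously to theta1
# at tau = 2*u*t mutational time units before the present. The expected
# distribution of pairwise differences has a closed form via incomplete-gamma
# integrals over the piecewise-exponential coalescence-time density, which is
# what the least-squares (SSD) fit uses.

#' Observed mismatch distribution
#'
#' Histogram of the number of pairwise differences over all `n(n-1)/2`
#' sequence pairs (comparable sites, pairwise deletion).
#'
#' @param aln Alignment tibble (`n >= 2`).
#' @return Tibble with `differences` (0..max), `count` and `freq`.
#' @export
mismatch_observed <- function(aln) {
  code <- encode_alignment(aln)
  n <- nrow(code)
  if (n < 2) abort("mismatch distribution needs n >= 2")
  diffs <- integer(0)
  for (i in seq_len(n - 1)) {
    xi <- code[i, ]
    for (j in (i + 1):n) {
      xj <- code[j, ]
      valid <- xi > 0L & xj > 0L
      diffs <- c(diffs, sum(xi[valid] != xj[valid]))
    }
  }
  mismatch_histogram(diffs)
}

mismatch_histogram <- function(diffs) {
  mx <- max(diffs)
  cnt <- tabulate(diffs + 1L, nbins = mx + 1L)
  tibble(differences = 0:mx, count = cnt, freq = cnt / sum(cnt))
}

#' Expected mismatch distribution under sudden expansion
#'
#' `F_j(tau, theta0, theta1)`: probability that a random pair differs at `j`
#' sites, when the pairwise coalescence time is exponential at rate
#' `1/theta1` more recently than `tau` and `1/theta0` beyond, and mutations
#' accrue as a Poisson process with mean equal to the elapsed mutational
#' time. At `tau = 0` this reduces to the equilibrium geometric curve with
#' mean `theta0`.
#'
#' @param j Integer vector of difference counts.
#' @param tau Mutation-scaled expansion time (`>= 0`).
#' @param theta0,theta1 Mutation-scaled sizes before/after expansion
#'   (`0 <= theta0 <= theta1`).
#' @return Probabilities `F_j`.
#' @export
expected_mismatch <- function(j, tau, theta0, theta1) {
  stopifnot(tau >= 0, theta0 >= 0, theta1 > 0)
  a1 <- 1 + 1 / theta1
  term1 <- (1 / theta1) * a1^(-(j + 1)) * stats::pgamma(tau * a1, j + 1)
  if (theta0 < 1e-10) {
    # instantaneous coalescence beyond tau
    term2 <- exp(-tau * a1 + j * log(pmax(tau, .Machine$double.xmin)) - lfactorial(j))
    if (tau == 0) term2 <- as.numeric(j == 0)
  } else {
    a0 <- 1 + 1 / theta0
    log_t2 <- -log(theta0) + tau * (1 / theta0 - 1 / theta1) -
      (j + 1) * log(a0) +
      stats::pgamma(tau * a0, j + 1, lower.tail = FALSE, log.p = TRUE)
    term2 <- exp(log_t2)
  }
  term1 + term2
}

ssd_mismatch <- function(obs_freq, tau, theta0, theta1) {
  j <- seq_along(obs_freq) - 1
  sum((obs_freq - expected_mismatch(j, tau, theta0, theta1))^2)
}

fit_mismatch_ls <- function(obs_freq) {
  jmax <- length(obs_freq) - 1
  obj <- function(par) {
    th0 <- exp(par[1]); th1 <- th0 + exp(par[2]); tau <- exp(par[3])
    ssd_mismatch(obs_freq, tau, th0, th1)
  }
  mean_obs <- sum((seq_along(obs_freq) - 1) * obs_freq)
  grid <- expand.grid(
    th0 = c(0.05, 0.25, 1, 2.5, max(mean_obs / 2, 0.05)),
    th1 = c(1, 5, 10, 25, 50, max(2 * mean_obs, 1)),
    tau = pmax(c(0.01, 0.5, 1, 2, 4, 8, mean_obs), 0.01))
  grid <- grid[grid$th1 > grid$th0, ]
  best <- NULL
  best_val <- Inf
  for (k in seq_len(nrow(grid))) {
    par <- c(log(grid$th0[k]), log(grid$th1[k] - grid$th0[k]), log(grid$tau[k]))
    v <- obj(par)
    if (v < best_val) { best_val <- v; best <- par }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(theta0 = exp(opt$par[1]),
       theta1 = exp(opt$par[1]) + exp(opt$par[2]),
       tau = exp(opt$par[3]),
       ssd = opt$value,
       converged = opt$convergence == 0)
}

# mismatch histogram (difference counts for all leaf pairs) from a simulated
# genealogy with infinite-sites mutations
sim_mismatch_counts <- function(tree) {
  n <- tree$n
  edges <- which(!is.na(tree$parent))
  elen <- tree$node_time[tree$parent[edges]] - tree$node_time[edges]
  muts <- rpois(length(edges), elen / 2)
  # leaf set below every node, children before parents
  memb_of <- vector("list", tree$n_nodes)
  for (v in seq_len(n)) memb_of[[v]] <- v
  internal <- (n + 1L):tree$n_nodes
  for (v in internal[order(tree$node_time[internal])]) {
    memb_of[[v]] <- unlist(memb_of[which(tree$parent == v)], use.names = FALSE)
  }
  membership <- matrix(FALSE, length(edges), n)
  for (idx in seq_along(edges)) membership[idx, memb_of[[edges[idx]]]] <- TRUE
  D <- matrix(0, n, n)
  for (idx in seq_along(edges)) {
    m <- muts[idx]
    if (m == 0) next
    x <- membership[idx, ]
    D[x, !x] <- D[x, !x] + m
  }
  D <- D + t(D)
  D[upper.tri(D)]
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Least-squares fit of `expected_mismatch()` to the observed frequencies
#' (coarse grid then Nelder-Mead on log-transformed parameters, enforcing
#' `0 <= theta0 <= theta1`, `tau >= 0`), with a parametric bootstrap for the
#' goodness-of-fit p-value: samples of size `n` are simulated under the
#' fitted expansion, refit, and `p = Pr(SSD_sim >= SSD_obs)`. The bootstrap
#' refits also give a percentile 95% CI for `tau` (and the other parameters).
#'
#' @param obs Observed mismatch tibble from [mismatch_observed()] (or a
#'   numeric frequency vector over 0..max differences).
#' @param n Number of sequences behind the observed distribution (used by the
#'   bootstrap).
#' @param n_boot Bootstrap replicates (default 1000; 0 skips).
#' @param seed Seed.
#' @return Object of class `expansion_fit` with `theta0`, `theta1`, `tau`,
#'   `ssd`, `p_boot`, percentile CIs, and the bootstrap parameter tibble.
#' @export
fit_sudden_expansion <- function(obs, n, n_boot = 1000, seed = 1L) {
  obs_freq <- if (is.data.frame(obs)) obs$freq else as.numeric(obs)
  if (sum(obs_freq > 0) < 2) abort("need >= 2 distinct difference counts")
  obs_freq <- obs_freq / sum(obs_freq)
  fit <- fit_mismatch_ls(obs_freq)
  if (!fit$converged) warn("mismatch optimizer did not fully converge; best point reported")
  boot <- NULL
  p_boot <- NA_real_
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    rows <- with_seed(derive_seed(seed, "mismatch_boot"), {
      map(seq_len(n_boot), function(b) {
        tree <- sim_coalescent_tree(n, fit$theta1,
                                    sizes = c(1, max(fit$theta0, 1e-6) / fit$theta1),
                                    breaks = fit$tau)
        diffs <- sim_mismatch_counts(tree)
        f <- mismatch_histogram(diffs)$freq
        bf <- fit_mismatch_ls(f)
        tibble(theta0 = bf$theta0, theta1 = bf$theta1, tau = bf$tau,
               ssd_refit = bf$ssd)
      }) |> list_rbind()
    })
    boot <- rows
    p_boot <- mean(rows$ssd_refit >= fit$ssd)
    ci <- unname(stats::quantile(rows$tau, c(0.025, 0.975)))
  }
  structure(list(theta0 = fit$theta0, theta1 = fit$theta1, tau = fit$tau,
                 ssd = fit$ssd, p_boot = p_boot,
                 tau_ci = ci, n = n, n_boot = n_boot,
                 observed = obs_freq, boot = boot,
                 converged = fit$converged),
            class = "expansion_fit")
}

#' @export
print.expansion_fit <- function(x, ...) {
  cat("<expansion_fit> tau = ", format(x$tau, digits = 4),
      ", theta0 = ", format(x$theta0, digits = 4),
      ", theta1 = ", format(x$theta1, digits = 4),
      ", SSD = ", format(x$ssd, digits = 3), sep = "")
  if (!is.na(x$p_boot)) {
    cat(" (bootstrap p = ", format(x$p_boot, digits = 3),
        ", tau 95% CI ", format(x$tau_ci[1], digits = 3), "-",
        format(x$tau_ci[2], digits = 3), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.expansion_fit <- function(x, ...) {
  tibble(term = c("theta0", "theta1", "tau", "ssd"),
         estimate = c(x$theta0, x$theta1, x$tau, x$ssd),
         conf.low = c(if (is.null(x$boot)) rep(NA_real_, 2) else
           c(stats::quantile(x$boot$theta0, 0.025),
             stats::quantile(x$boot$theta1, 0.025)), x$tau_ci[1], NA),
         conf.high = c(if (is.null(x$boot)) rep(NA_real_, 2) else
           c(stats::quantile(x$boot$theta0, 0.975),
             stats::quantile(x$boot$theta1, 0.975)), x$tau_ci[2], NA))
}

#' @export
glance.expansion_fit <- function(x, ...) {
  tibble(theta0 = x$theta0, theta1 = x$theta1, tau = x$tau, ssd = x$ssd,
         p_boot = x$p_boot, n = x$n, n_boot = x$n_boot)
}

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line labs
#' @export
autoplot.expansion_fit <- function(object, ...) {
  j <- seq_along(object$observed) - 1
  df <- tibble(differences = j, observed = object$observed,
               expected = expected_mismatch(j, object$tau, object$theta0,
                                            object$theta1))
  ggplot(df, aes(x = .data$differences)) +
    geom_col(aes(y = .data$observed), fill = "grey70") +
    geom_line(aes(y = .data$expected), colour = "firebrick", linewidth = 1) +
    labs(x = "pairwise differences", y = "frequency",
         title = "Mismatch distribution and fitted sudden-expansion curve")
}

# ---- clock and rate conversions ---------------------------------------------

#' Molecular clock configuration
#'
#' @param rate Between-lineage sequence divergence rate, percent per million
#'   years (e.g. 3.6 for a teleost control region).
#' @param L Sequence length in bp.
#' @param gen_time Generation time in years.
#' @return A `clock_config` list.
#' @export
clock_config <- function(rate = 3.6, L = 583, gen_time = 2.2) {
  stopifnot(rate > 0, L > 0, gen_time > 0)
  structure(list(rate = rate, L = L, gen_time = gen_time),
            class = "clock_config")
}

#' Convert a mismatch tau to time since expansion
#'
#' With `tau = 2 u t` and `u = (rate/100/1e6) * L` substitutions per sequence
#' per year, `t = tau / (2 u)` years. Both years and generations
#' (`years / gen_time`) are reported, along with linearly propagated CIs.
#'
#' @param tau Mutation-scaled expansion time (from [fit_sudden_expansion()]).
#' @param clock A [clock_config()].
#' @param tau_ci Optional length-2 CI for tau.
#' @return One-row tibble: `tau`, `t_years`, `t_generations`, and CI columns
#'   when `tau_ci` is given.
#' @export
time_since_expansion <- function(tau, clock, tau_ci = NULL) {
  stopifnot(tau >= 0)
  u <- (clock$rate / 100 / 1e6) * clock$L
  t_years <- tau / (2 * u)
  out <- tibble(tau = tau, t_years = t_years,
                t_generations = t_years / clock$gen_time)
  if (!is.null(tau_ci)) {
    out$t_years_low <- tau_ci[1] / (2 * u)
    out$t_years_high <- tau_ci[2] / (2 * u)
    out$t_generations_low <- out$t_years_low / clock$gen_time
    out$t_generations_high <- out$t_years_high / clock$gen_time
  }
  out
}

#' Convert coalescent-sampler outputs to demographic rates
#'
#' From mutation-scaled estimates `theta = x Ne mu` and `M = m / mu`:
#' `m = M mu`, `Ne = theta / (x mu)`, and the effective number of migrants
#' per generation `x Ne m = theta M` (also reported per-copy as
#' `theta M / x`).
#'
#' @param theta Mutation-scaled population size.
#' @param M Mutation-scaled migration rate.
#' @param x Ploidy/inheritance factor (1 for mtDNA, 4 for nuclear loci).
#' @param mu Mutation rate per generation (per locus/sequence, matching the
#'   scale of `theta`).
#' @return One-row tibble: `m`, `ne`, `migrants_xnem` (`theta * M`),
#'   `migrants_nem` (`theta * M / x`).
#' @export
rate_conversions <- function(theta, M, x, mu) {
  stopifnot(theta >= 0, M >= 0, x > 0)
  if (mu <= 0) abort("mu must be > 0")
  tibble(theta = theta, M = M, x = x, mu = mu,
         m = M * mu,
         ne = theta / (x * mu),
         migrants_xnem = theta * M,
         migrants_nem = theta * M / x)
}

#' Net-divergence dating surrogate
#'
#' `da = dxy - (d_within_1 + d_within_2)/2`; `T = da / (rate/100)` million
#' years. This is a simple net-divergence clock, not a calibrated genealogical
#' (e.g. Bayesian tmrca) estimate; it ignores ancestral polymorphism
#' uncertainty beyond the net correction.
#'
#' @param dxy Mean between-group distance (per site).
#' @param d_within_1,d_within_2 Mean within-group distances (per site).
#' @param rate Divergence rate, percent per million years.
#' @return One-row tibble: `da`, `t_my` (0, flagged, when `da < 0`).
#' @export
net_divergence_time <- function(dxy, d_within_1, d_within_2, rate = 3.6) {
  stopifnot(dxy >= 0)
  da <- dxy - (d_within_1 + d_within_2) / 2
  flagged <- da < 0
  if (flagged) warn("negative net divergence; time clamped to 0")
  tibble(dxy = dxy, da = da, t_my = max(da, 0) / (rate / 100),
         flagged = flagged)
}

#' Mean between- and within-group distances
#'
#' @param aln Alignment tibble.
#' @param popmap Population map with two groups.
#' @param model Distance model (see [distance_matrix()]).
#' @return One-row tibble: `dxy`, within-group means `d_within_1`,
#'   `d_within_2`, and group names.
#' @export
divergence_between <- function(aln, popmap, model = "K80") {
  pm <- validate_popmap(aln$id, popmap)
  groups <- unique(pm$group)
  if (length(groups) != 2) abort("exactly two groups are required")
  d <- distance_matrix(aln, model)
  i1 <- which(pm$group == groups[1])
  i2 <- which(pm$group == groups[2])
  within_mean <- function(ix) {
    if (length(ix) < 2) return(NA_real_)
    m <- d[ix, ix]
    mean(m[upper.tri(m)])
  }
  tibble(group1 = groups[1], group2 = groups[2],
         dxy = mean(d[i1, i2]),
         d_within_1 = within_mean(i1),
         d_within_2 = within_mean(i2))
}
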