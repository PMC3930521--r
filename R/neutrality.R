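# Neutrality tests: Tajima's D and Fu's F_S, with significance from neutral
# coalescent simulation conditioned on the sample size and theta-pi.

# Kingman coalescent genealogy in mutation-scaled time, so that with
# infinite-sites mutations (rate 1/2 per lineage per unit time) the expected
# pairwise difference equals theta under constant size.
sim_coalescent_tree <- function(n, theta, sizes = 1, breaks = numeric(0)) {
  n <- as.integer(n)
  # sizes: relative population sizes on time intervals defined by breaks
  # (times in the same mutation-scaled units as theta); sizes[1] applies from
  # 0 to breaks[1], etc. Pair coalescence rate on interval j is
  # (1/theta) / sizes[j].
  n_nodes <- 2L * n - 1L
  node_time <- numeric(n_nodes)
  parent <- rep(NA_integer_, n_nodes)
  active <- seq_len(n)
  t_now <- 0
  nxt <- n
  interval <- function(t) {
    j <- findInterval(t, breaks) + 1L
    min(j, length(sizes))
  }
  bounds <- c(breaks, Inf)
  while (length(active) > 1) {
    k <- length(active)
    repeat {
      j <- interval(t_now)
      rate <- k * (k - 1) / 2 / (theta * sizes[j])
      dt <- rexp(1, rate)
      if (t_now + dt <= bounds[j] || j == length(sizes)) {
        t_now <- t_now + dt
        break
      }
      t_now <- bounds[j]                      # jump to next epoch
    }
    pick <- sample(length(active), 2L)
    nxt <- nxt + 1L
    node_time[nxt] <- t_now
    parent[active[pick]] <- nxt
    active <- c(active[-pick], nxt)
  }
  list(parent = parent, node_time = node_time, n = n, n_nodes = n_nodes)
}

# mutations and summaries on a simulated genealogy (infinite sites)
tree_summaries <- function(tree) {
  n <- tree$n
  edges <- which(!is.na(tree$parent))
  elen <- tree$node_time[tree$parent[edges]] - tree$node_time[edges]
  muts <- rpois(length(edges), elen / 2)
  # leaves below each node
  below <- integer(tree$n_nodes)
  below[seq_len(n)] <- 1L
  ord <- order(tree$node_time[edges])          # children before parents
  for (v in edges[ord]) below[tree$parent[v]] <- below[tree$parent[v]] + below[v]
  S <- sum(muts)
  i_b <- below[edges]
  pi <- sum(muts * i_b * (n - i_b)) / (n * (n - 1) / 2)
  # haplotype count: leaves connected through zero-mutation edges share a type
  comp <- seq_len(tree$n_nodes)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (idx in seq_along(edges)) {
    if (muts[idx] == 0) {
      a <- find(edges[idx]); b <- find(tree$parent[edges[idx]])
      if (a != b) comp[a] <- b
    }
  }
  k <- length(unique(vapply(seq_len(n), find, integer(1))))
  list(S = S, pi = pi, k = k)
}

seg_sites <- function(aln) length(variable_sites(aln)$variable)

#' Tajima's D
#'
#' `D = (theta_pi - S/a1) / sqrt(e1 S + e2 S (S-1))` with the standard
#' constants. `theta_pi` is the mean number of pairwise differences and `S`
#' the number of segregating comparable sites. Significance comes from
#' neutral constant-size coalescent simulations conditioned on `n` and
#' `theta_pi` (two-sided: twice the smaller tail, capped at 1).
#'
#' @param aln Alignment tibble for one population (`n >= 4`).
#' @param n_sim Coalescent replicates for the p-value (default 1000; 0 skips).
#' @param seed Seed.
#' @return One-row tibble: `n`, `S`, `theta_pi`, `D`, `p`.
#' @export
tajimas_d <- function(aln, n_sim = 1000, seed = 1L) {
  n <- nrow(aln)
  if (n < 4) abort("Tajima's D needs n >= 4")
  S <- seg_sites(aln)
  th_pi <- nucleotide_diversity(aln, per_site = FALSE)
  if (S < 1) {
    warn("no segregating sites: D undefined")
    return(tibble(n = n, S = S, theta_pi = th_pi, D = NA_real_, p = NA_real_))
  }
  D <- tajima_d_value(n, S, th_pi)
  p <- NA_real_
  if (n_sim > 0) {
    sims <- with_seed(derive_seed(seed, "tajima", n, S), {
      vapply(seq_len(n_sim), function(i) {
        sm <- tree_summaries(sim_coalescent_tree(n, max(th_pi, 1e-8)))
        if (sm$S < 1) return(NA_real_)
        tajima_d_value(n, sm$S, sm$pi)
      }, 0)
    })
    sims <- sims[!is.na(sims)]
    lo <- (1 + sum(sims <= D)) / (1 + length(sims))
    hi <- (1 + sum(sims >= D)) / (1 + length(sims))
    p <- min(1, 2 * min(lo, hi))
  }
  tibble(n = n, S = S, theta_pi = th_pi, D = D, p = p)
}

#' @rdname tajimas_d
#' @param n,S,theta_pi Sample size, segregating sites and mean pairwise
#'   differences, for direct evaluation of the statistic.
#' @export
tajima_d_value <- function(n, S, theta_pi) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (theta_pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# log unsigned Stirling numbers of the first kind, row n: |s(n, k)| for
# k = 1..n, via |s(n+1,k)| = n |s(n,k)| + |s(n,k-1)| in log space.
log_stirling_row <- function(n) {
  row <- 0                                     # |s(1,1)| = 1
  if (n == 1) return(row)
  for (m in seq_len(n - 1)) {
    prev <- row
    row <- numeric(m + 1)
    row[1] <- log(m) + prev[1]
    if (m > 1) {
      for (k in 2:m) row[k] <- logsumexp(c(log(m) + prev[k], prev[k - 1]))
    }
    row[m + 1] <- prev[m]
  }
  row
}

#' Fu's F_S statistic
#'
#' Under the Ewens sampling distribution with `theta = theta_pi`,
#' `S' = Pr(K >= k_obs)` where `Pr(K = k) = |s(n,k)| theta^k /
#' (theta (theta+1) ... (theta+n-1))`; `F_S = ln(S' / (1 - S'))`. Computed in
#' log space via the unsigned-Stirling recurrence.
#'
#' @param n Sample size.
#' @param k_obs Observed number of distinct haplotypes (`1 <= k_obs <= n`).
#' @param theta_pi Mean pairwise differences (`> 0`).
#' @return `F_S` (`Inf` with a warning when `k_obs = 1`, where `S' = 1`).
#' @export
#' @examples
#' fus_fs(4, 3, 1)  # ln(7/17)
fus_fs <- function(n, k_obs, theta_pi) {
  stopifnot(n >= 2, k_obs >= 1, k_obs <= n)
  if (theta_pi <= 0) abort("theta_pi must be > 0")
  if (k_obs == 1) {
    warn("k_obs = 1 gives S' = 1: F_S is +Inf")
    return(Inf)
  }
  ls <- log_stirling_row(n)
  k <- seq_len(n)
  logp <- ls + k * log(theta_pi) - sum(log(theta_pi + 0:(n - 1)))
  log_sp <- logsumexp(logp[k >= k_obs])
  log_one_minus <- logsumexp(logp[k < k_obs])
  log_sp - log_one_minus
}

#' Neutrality test battery per group
#'
#' Runs Tajima's D and Fu's F_S (with coalescent significance, one-sided
#' `Pr(sim <= obs)` for F_S) for each group of the population map, or for the
#' whole alignment when `popmap` is `NULL`.
#'
#' @param aln Alignment tibble.
#' @param popmap Optional population map.
#' @param by Popmap column defining the units (default `"group"`).
#' @param n_sim Coalescent replicates (default 1000).
#' @param seed Seed.
#' @return Tibble with one row per unit: `n`, `S`, `theta_pi`, `k`
#'   (haplotypes), `D`, `p_D`, `FS`, `p_FS`.
#' @export
neutrality_tests <- function(aln, popmap = NULL, by = "group",
                             n_sim = 1000, seed = 1L) {
  units <- if (is.null(popmap)) {
    list(all = aln$id)
  } else {
    pm <- validate_popmap(aln$id, popmap)
    split(pm$id, pm[[by]])
  }
  imap(units, function(ids, unit) {
    sub <- aln[aln$id %in% ids, ]
    attr(sub, "L") <- attr(aln, "L")
    ht <- collapse_haplotypes(sub)
    k_obs <- nrow(ht$haplotypes)
    td <- tajimas_d(sub, n_sim = n_sim, seed = derive_seed(seed, "neut", unit))
    fs <- if (td$theta_pi > 0) fus_fs(nrow(sub), k_obs, td$theta_pi) else NA_real_
    p_fs <- NA_real_
    if (n_sim > 0 && is.finite(fs)) {
      sims <- with_seed(derive_seed(seed, "fs", unit), {
        vapply(seq_len(n_sim), function(i) {
          sm <- tree_summaries(sim_coalescent_tree(nrow(sub), max(td$theta_pi, 1e-8)))
          if (sm$pi <= 0 || sm$k < 2) return(Inf)
          fus_fs(nrow(sub), sm$k, sm$pi)
        }, 0)
      })
      p_fs <- (1 + sum(sims <= fs)) / (1 + length(sims))
    }
    tibble(unit = unit, n = nrow(sub), S = td$S, theta_pi = td$theta_pi,
           k = k_obs, D = td$D, p_D = td$p, FS = fs, p_FS = p_fs)
  }) |> list_rbind()
}
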