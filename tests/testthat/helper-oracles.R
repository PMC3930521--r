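# Independent brute-force oracles, deliberately written with explicit loops
# and the textbook formulas rather than the package's vectorized paths.

# One-level AMOVA Phi_ST from first principles: explicit double loops over
# ordered pairs for every sum of squares.
naive_phi_st <- function(d2, pop) {
  n <- length(pop)
  ssd_total <- 0
  for (i in 1:n) for (j in 1:n) ssd_total <- ssd_total + d2[i, j]
  ssd_total <- ssd_total / (2 * n)
  pops <- unique(pop)
  ssd_within <- 0
  for (p in pops) {
    idx <- which(pop == p)
    s <- 0
    for (i in idx) for (j in idx) s <- s + d2[i, j]
    ssd_within <- ssd_within + s / (2 * length(idx))
  }
  ssd_among <- ssd_total - ssd_within
  P <- length(pops)
  msd_among <- ssd_among / (P - 1)
  msd_within <- ssd_within / (n - P)
  sum_np2 <- sum(sapply(pops, function(p) sum(pop == p)^2))
  n_coef <- (n - sum_np2 / n) / (P - 1)
  sigma_b <- (msd_among - msd_within) / n_coef
  sigma_c <- msd_within
  list(phi_st = sigma_b / (sigma_b + sigma_c),
       sigma = c(among = sigma_b, within = sigma_c),
       ssd = c(among = ssd_among, within = ssd_within, total = ssd_total))
}

# Two-level AMOVA components (Excoffier-Smouse-Quattro), explicit loops.
naive_amova_two_level <- function(d2, pop, grp) {
  n <- length(pop)
  ssd_set <- function(idx) {
    s <- 0
    for (i in idx) for (j in idx) s <- s + d2[i, j]
    s / (2 * length(idx))
  }
  ssd_total <- ssd_set(1:n)
  pops <- unique(pop)
  groups <- unique(grp)
  ssd_wp <- sum(sapply(pops, function(p) ssd_set(which(pop == p))))
  ssd_wg <- sum(sapply(groups, function(g) ssd_set(which(grp == g))))
  ssd_ag <- ssd_total - ssd_wg
  ssd_ap <- ssd_wg - ssd_wp
  G <- length(groups); P <- length(pops)
  df_ag <- G - 1; df_ap <- P - G; df_wp <- n - P
  # coefficients
  s1 <- 0
  for (g in groups) {
    idx <- which(grp == g)
    s1 <- s1 + sum(sapply(unique(pop[idx]),
                          function(p) sum(pop[idx] == p)^2)) / length(idx)
  }
  s2 <- sum(sapply(pops, function(p) sum(pop == p)^2)) / n
  n1 <- (n - s1) / df_ap
  n2 <- (s1 - s2) / df_ag
  n3 <- (n - sum(sapply(groups, function(g) sum(grp == g)^2)) / n) / df_ag
  sig_c <- ssd_wp / df_wp
  sig_b <- (ssd_ap / df_ap - sig_c) / n1
  sig_a <- (ssd_ag / df_ag - sig_c - n2 * sig_b) / n3
  tot <- sig_a + sig_b + sig_c
  list(sigma = c(a = sig_a, b = sig_b, c = sig_c),
       phi_st = (sig_a + sig_b) / tot,
       phi_ct = sig_a / tot,
       phi_sc = sig_b / (sig_b + sig_c))
}

# Weir & Cockerham (1984) theta for one locus, straight from the paper's
# formulas, loops over alleles, taking raw genotype lists.
# genos: list over populations, each a 2-column matrix of alleles.
naive_wc_theta_locus <- function(genos) {
  r <- length(genos)
  ns <- sapply(genos, nrow)
  nbar <- mean(ns)
  nc <- (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1)
  alleles <- sort(unique(unlist(genos)))
  A <- B <- C <- 0
  for (al in alleles) {
    p_i <- numeric(r); h_i <- numeric(r)
    for (k in 1:r) {
      g <- genos[[k]]
      p_i[k] <- sum(g == al) / (2 * ns[k])
      h_i[k] <- sum((g[, 1] == al) != (g[, 2] == al)) / ns[k]
    }
    pbar <- sum(ns * p_i) / (r * nbar)
    s2 <- sum(ns * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ns * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  A / (A + B + C)
}

# exact unsigned Stirling numbers of the first kind, row n, by expanding the
# rising factorial x(x+1)...(x+n-1) as an integer polynomial
stirling_row_exact <- function(n) {
  coef <- c(0, 1)                      # x
  if (n > 1) {
    for (m in 1:(n - 1)) {
      coef <- c(0, coef) + m * c(coef, 0)   # multiply by (x + m)
    }
  }
  coef[2:(n + 1)]                      # |s(n, k)|, k = 1..n
}

# exact Ewens Pr(K = k) via the rational form
ewens_pr_k <- function(n, k, theta) {
  s <- stirling_row_exact(n)
  s[k] * theta^k / prod(theta + 0:(n - 1))
}

# small random alignment generator for property checks
random_alignment <- function(n, L, seed, alphabet = c("A", "C", "G", "T")) {
  set.seed(seed)
  alignment(paste0("s", seq_len(n)),
            replicate(n, paste(sample(alphabet, L, replace = TRUE),
                               collapse = "")))
}

tiny_popmap <- function(ids, sites, groups = NULL) {
  tibble::tibble(id = ids, site = sites,
                 group = if (is.null(groups)) "all" else groups)
}
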