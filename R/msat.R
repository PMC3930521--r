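# Microsatellite summary statistics: per-locus diversity, allelic richness by
# rarefaction, Hardy-Weinberg and linkage permutation tests, null-allele EM,
# Weir-Cockerham F-statistics and Jost's D.

gt_join <- function(gt, popmap) {
  validate_popmap(unique(gt$id), popmap)
  left_join(gt, popmap, by = "id")
}

scored <- function(x) !is.na(x$allele_1) & !is.na(x$allele_2)

#' Allelic richness by rarefaction
#'
#' Expected number of alleles in a subsample of `2g` genes:
#' `AR = sum_a 1 - C(N - N_a, 2g) / C(N, 2g)` where `N` is the number of
#' genes actually scored and `N_a` the copies of allele `a`.
#'
#' @param allele_counts Integer vector of allele copy numbers.
#' @param genes Rarefaction size in genes (i.e. `2 * g` for `g` diploid
#'   individuals).
#' @return Rarefied allele count; `NA` when fewer than `genes` genes were
#'   scored.
#' @export
allelic_richness <- function(allele_counts, genes) {
  allele_counts <- allele_counts[allele_counts > 0]
  N <- sum(allele_counts)
  if (genes > N) return(NA_real_)
  sum(1 - exp(lchoose(N - allele_counts, genes) - lchoose(N, genes)))
}

unbiased_he <- function(p, n) if (n < 1) NA_real_ else (2 * n / (2 * n - 1)) * (1 - sum(p^2))

# Weir & Cockerham (1984) variance components for one locus across r pops.
# freqs: matrix pops x alleles of allele frequencies; ns: genotyped
# individuals per pop; hets: matrix pops x alleles of the frequency of
# individuals heterozygous for that allele.
wc_components_locus <- function(freqs, ns, hets) {
  keep <- ns > 0
  freqs <- freqs[keep, , drop = FALSE]
  hets <- hets[keep, , drop = FALSE]
  ns <- ns[keep]
  r <- length(ns)
  if (r < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nbar <- mean(ns)
  nc <- (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1)
  a_tot <- b_tot <- c_tot <- 0
  for (al in seq_len(ncol(freqs))) {
    p <- freqs[, al]
    h <- hets[, al]
    pbar <- sum(ns * p) / (r * nbar)
    s2 <- sum(ns * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ns * h) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                          (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_tot <- a_tot + a; b_tot <- b_tot + b; c_tot <- c_tot + cc
  }
  c(a = a_tot, b = b_tot, c = c_tot)
}

# per-pop W&C f (F_IS) for one sample: 1 - sum(c)/sum(b + c)
wc_f_within <- function(p, h, n) {
  # p, h: per-allele frequency and heterozygote-carrier frequency
  b <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
  cc <- h / 2
  denom <- sum(b + cc)
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  1 - sum(cc) / denom
}

locus_pop_freqs <- function(sub) {
  # sub: scored genotype rows of one locus in one pop
  alleles <- c(sub$allele_1, sub$allele_2)
  n <- nrow(sub)
  lv <- sort(unique(alleles))
  p <- as.numeric(table(factor(alleles, levels = lv))) / (2 * n)
  het <- sub$allele_1 != sub$allele_2
  h <- vapply(lv, function(a) {
    sum(het & (sub$allele_1 == a | sub$allele_2 == a)) / n
  }, 0)
  list(levels = lv, p = p, h = h, n = n)
}

#' Per-locus, per-population diversity summary
#'
#' Computes, for every locus in every population: genotyped individuals `n`,
#' allele count `na`, allelic richness `ar` rarefied to `2 * rarefaction_g`
#' scored genes, unbiased expected heterozygosity `he`
#' (`2n/(2n-1) * (1 - sum p^2)`), observed heterozygosity `ho`, and the
#' Weir-Cockerham within-population `fis`. Multilocus rows (`locus = "all"`)
#' carry means of `n`, `na`, `ar`, `he`, `ho` and the weighted (summed
#' component) multilocus `fis`.
#'
#' @param gt Genotype tibble.
#' @param popmap Population map.
#' @param rarefaction_g Rarefaction size in diploid individuals; default is
#'   the smallest per-locus per-population scored sample.
#' @return Tibble with columns `locus`, `site`, `n`, `na`, `ar`, `he`, `ho`,
#'   `fis`.
#' @export
locus_summary <- function(gt, popmap, rarefaction_g = NULL) {
  gj <- gt_join(gt, popmap)
  gj <- gj[scored(gj), ]
  if (is.null(rarefaction_g)) {
    rarefaction_g <- gj |> count(.data$locus, .data$site) |> pull(.data$n) |> min()
  }
  cells <- gj |> group_by(.data$locus, .data$site) |> group_split()
  rows <- map(cells, function(sub) {
    st <- locus_pop_freqs(sub)
    mono <- length(st$levels) == 1
    tibble(
      locus = sub$locus[1], site = sub$site[1], n = st$n,
      na = length(st$levels),
      ar = allelic_richness(round(st$p * 2 * st$n), 2 * rarefaction_g),
      he = if (mono) 0 else unbiased_he(st$p, st$n),
      ho = if (mono) 0 else mean(sub$allele_1 != sub$allele_2),
      fis = if (mono) NA_real_ else wc_f_within(st$p, st$h, st$n))
  }) |> list_rbind()
  multi <- rows |>
    group_by(.data$site) |>
    summarise(locus = "all", n = mean(.data$n), na = mean(.data$na),
              ar = mean(.data$ar, na.rm = TRUE), he = mean(.data$he),
              ho = mean(.data$ho), .groups = "drop")
  # weighted multilocus F_IS: summed b and c components across loci
  fis_multi <- gj |> group_by(.data$site) |> group_split() |>
    map(function(subp) {
      bc <- subp |> group_by(.data$locus) |> group_split() |>
        map(function(sub) {
          st <- locus_pop_freqs(sub)
          if (length(st$levels) < 2) return(c(b = 0, c = 0))
          b <- (st$n / (st$n - 1)) *
            (st$p * (1 - st$p) - (2 * st$n - 1) / (4 * st$n) * st$h)
          c(b = sum(b), c = sum(st$h / 2))
        })
      b <- sum(map_dbl(bc, "b")); cc <- sum(map_dbl(bc, "c"))
      tibble(site = subp$site[1], fis = 1 - cc / (b + cc))
    }) |> list_rbind()
  multi <- left_join(multi, fis_multi, by = "site") |>
    select("locus", "site", "n", "na", "ar", "he", "ho", "fis")
  bind_rows(rows, multi) |> arrange(.data$locus != "all", .data$locus, .data$site)
}

#' Monte-Carlo exact test for Hardy-Weinberg proportions
#'
#' The observed alleles of each population are repeatedly shuffled into random
#' diploid genotypes; the default one-sided statistic is the homozygote count
#' (heterozygote-deficiency alternative, the usual reading for null-allele or
#' inbreeding driven deficits). `p = (1 + #\{sim >= obs\}) / (1 + n_reps)`.
#'
#' @param gt Genotype tibble.
#' @param popmap Population map.
#' @param locus Locus name.
#' @param n_reps Number of shuffles (default 1000).
#' @param seed Seed; per-population streams are derived from it.
#' @param alternative `"deficit"` (one-sided heterozygote deficiency) or
#'   `"two.sided"` (absolute deviation of the homozygote count from its
#'   permutation mean).
#' @return Tibble with columns `site`, `locus`, `n`, `p`, `flagged` (`TRUE`
#'   when fewer than 3 distinct genotypes made the test degenerate, in which
#'   case `p = 1`).
#' @export
hwe_test <- function(gt, popmap, locus, n_reps = 1000, seed = 1L,
                     alternative = c("deficit", "two.sided")) {
  alternative <- match.arg(alternative)
  gj <- gt_join(gt, popmap)
  gj <- gj[scored(gj) & gj$locus == locus, ]
  gj |> group_by(.data$site) |> group_split() |>
    map(function(sub) {
      gtypes <- paste(sub$allele_1, sub$allele_2)
      if (length(unique(gtypes)) < 3) {
        return(tibble(site = sub$site[1], locus = locus, n = nrow(sub),
                      p = 1, flagged = TRUE))
      }
      alleles <- c(sub$allele_1, sub$allele_2)
      n <- nrow(sub)
      obs <- sum(sub$allele_1 == sub$allele_2)
      sim <- with_seed(derive_seed(seed, "hwe", locus, sub$site[1]), {
        vapply(seq_len(n_reps), function(k) {
          sh <- sample(alleles)
          sum(sh[seq_len(n)] == sh[n + seq_len(n)])
        }, 0)
      })
      p <- if (alternative == "deficit") {
        permutation_p(obs, sim)
      } else {
        permutation_p(abs(obs - mean(sim)), abs(sim - mean(sim)))
      }
      tibble(site = sub$site[1], locus = locus, n = n, p = p, flagged = FALSE)
    }) |> list_rbind()
}

g_statistic <- function(tab) {
  tab <- as.matrix(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  ok <- tab > 0
  2 * sum(tab[ok] * log(tab[ok] / e[ok]))
}

#' Permutation test for linkage (genotypic) equilibrium between two loci
#'
#' The log-likelihood G statistic of the two-locus genotype contingency table
#' is compared with its distribution under random re-pairing of single-locus
#' genotypes among individuals.
#'
#' @param gt Genotype tibble.
#' @param popmap Population map.
#' @param loci Character vector of the two locus names.
#' @param n_reps Number of permutations (default 1000).
#' @param seed Seed.
#' @return Tibble with columns `site`, `locus1`, `locus2`, `n`, `p`,
#'   `flagged` (degenerate table or fewer than 5 doubly-scored individuals).
#' @export
ld_test <- function(gt, popmap, loci, n_reps = 1000, seed = 1L) {
  stopifnot(length(loci) == 2)
  gj <- gt_join(gt, popmap)
  gj <- gj[scored(gj) & gj$locus %in% loci, ]
  wide <- gj |>
    mutate(gtype = paste(.data$allele_1, .data$allele_2)) |>
    select("id", "site", "locus", "gtype") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "gtype")
  wide <- wide[!is.na(wide[[loci[1]]]) & !is.na(wide[[loci[2]]]), ]
  wide |> group_by(.data$site) |> group_split() |>
    map(function(sub) {
      g1 <- sub[[loci[1]]]; g2 <- sub[[loci[2]]]
      base <- tibble(site = sub$site[1], locus1 = loci[1], locus2 = loci[2],
                     n = nrow(sub))
      if (nrow(sub) < 5 || length(unique(g1)) < 2 || length(unique(g2)) < 2) {
        return(mutate(base, p = 1, flagged = TRUE))
      }
      obs <- g_statistic(table(g1, g2))
      sim <- with_seed(derive_seed(seed, "ld", loci[1], loci[2], sub$site[1]), {
        vapply(seq_len(n_reps), function(k) g_statistic(table(g1, sample(g2))), 0)
      })
      mutate(base, p = permutation_p(obs, sim), flagged = FALSE)
    }) |> list_rbind()
}

#' EM estimate of a single null allele's frequency
#'
#' Assumes Hardy-Weinberg proportions with one unobservable (null) allele:
#' apparent homozygotes for allele `i` are a mixture of true `i/i` homozygotes
#' and `i/null` heterozygotes, and null homozygotes are unobserved (the
#' likelihood is truncated accordingly). An EM iteration alternates imputing
#' the null-carrier fractions with refitting the allele frequencies.
#'
#' @param allele_1,allele_2 Integer allele vectors for one locus in one
#'   population (`NA` pairs, i.e. missing genotypes, are dropped).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param tol Convergence tolerance on the null frequency.
#' @return A list with `null_freq`, `converged`, `iterations` and the visible
#'   allele frequency table `allele_freqs`.
#' @export
null_allele_em <- function(allele_1, allele_2, max_iter = 1000, tol = 1e-9) {
  keep <- !is.na(allele_1) & !is.na(allele_2)
  a1 <- allele_1[keep]; a2 <- allele_2[keep]
  lv <- sort(unique(c(a1, a2)))
  if (length(lv) < 2) abort("need >= 2 visible alleles")
  nvis <- length(a1)
  hom <- a1 == a2
  hom_count <- as.numeric(table(factor(a1[hom], levels = lv)))
  het_copies <- as.numeric(table(factor(c(a1[!hom], a2[!hom]), levels = lv)))
  p <- as.numeric(table(factor(c(a1, a2), levels = lv))) / (2 * nvis)
  r <- 0.05
  p <- p * (1 - r)
  it <- 0
  repeat {
    it <- it + 1
    e <- ifelse(hom_count > 0, 2 * p * r / (p^2 + 2 * p * r), 0)
    m <- nvis * r^2 / (1 - r^2)          # expected unobserved null homozygotes
    copies <- het_copies + hom_count * (2 - e)
    null_copies <- sum(hom_count * e) + 2 * m
    tot <- 2 * (nvis + m)
    r_new <- null_copies / tot
    p_new <- copies / tot
    delta <- abs(r_new - r)
    r <- r_new; p <- p_new
    if (delta < tol || it >= max_iter) break
  }
  list(null_freq = r, converged = it < max_iter, iterations = it,
       allele_freqs = stats::setNames(p, lv))
}

#' Null-allele frequencies for every locus and population
#'
#' @param gt Genotype tibble.
#' @param popmap Population map.
#' @return Tibble with `locus`, `site`, `null_freq`, `converged`.
#' @export
null_alleles <- function(gt, popmap) {
  gj <- gt_join(gt, popmap)
  gj <- gj[scored(gj), ]
  gj |> group_by(.data$locus, .data$site) |> group_split() |>
    map(function(sub) {
      res <- tryCatch(null_allele_em(sub$allele_1, sub$allele_2),
                      error = function(e) NULL)
      tibble(locus = sub$locus[1], site = sub$site[1],
             null_freq = if (is.null(res)) NA_real_ else res$null_freq,
             converged = if (is.null(res)) NA else res$converged)
    }) |> list_rbind()
}

# fast multilocus theta for permutation testing: alleles pre-coded 1..K
theta_multilocus <- function(acode1, acode2, pop, nalleles) {
  A <- B <- C <- 0
  pops <- sort(unique(pop))
  for (l in seq_len(ncol(acode1))) {
    x1 <- acode1[, l]; x2 <- acode2[, l]
    ok <- !is.na(x1)
    if (!any(ok)) next
    K <- nalleles[l]
    freqs <- matrix(0, length(pops), K)
    hets <- matrix(0, length(pops), K)
    ns <- numeric(length(pops))
    for (pi in seq_along(pops)) {
      sel <- ok & pop == pops[pi]
      n <- sum(sel)
      ns[pi] <- n
      if (n == 0) next
      cnt <- tabulate(x1[sel], K) + tabulate(x2[sel], K)
      freqs[pi, ] <- cnt / (2 * n)
      hsel <- sel & x1 != x2
      hets[pi, ] <- (tabulate(x1[hsel], K) + tabulate(x2[hsel], K)) / n
    }
    if (sum(colSums(freqs) > 0) < 2) next     # monomorphic overall
    comp <- wc_components_locus(freqs, ns, hets)
    if (anyNA(comp)) next
    A <- A + comp["a"]; B <- B + comp["b"]; C <- C + comp["c"]
  }
  unname(A / (A + B + C))
}

gt_to_matrices <- function(gt) {
  ids <- unique(gt$id)
  loci <- unique(gt$locus)
  a1 <- matrix(NA_integer_, length(ids), length(loci), dimnames = list(ids, loci))
  a2 <- a1
  a1[cbind(match(gt$id, ids), match(gt$locus, loci))] <- gt$allele_1
  a2[cbind(match(gt$id, ids), match(gt$locus, loci))] <- gt$allele_2
  # recode alleles per locus to 1..K
  c1 <- a1; c2 <- a2
  nall <- integer(length(loci))
  for (l in seq_along(loci)) {
    lv <- sort(unique(c(a1[, l], a2[, l])))
    lv <- lv[!is.na(lv)]
    nall[l] <- length(lv)
    c1[, l] <- match(a1[, l], lv)
    c2[, l] <- match(a2[, l], lv)
  }
  list(ids = ids, loci = loci, a1 = c1, a2 = c2, nalleles = nall)
}

#' Weir-Cockerham F_ST (theta) with permutation tests
#'
#' Per-locus variance components `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals) are summed
#' over alleles and loci; `theta = sum a / sum(a + b + c)`. Significance is
#' assessed by permuting whole multilocus genotypes among populations
#' (preserving within-individual associations). Pairwise values use
#' per-pair derived permutation streams.
#'
#' @param gt Genotype tibble.
#' @param popmap Population map.
#' @param n_perm Permutations (default 10000; 0 skips tests).
#' @param seed Master seed.
#' @param pairwise Also compute the pairwise matrix (default `TRUE`).
#' @return An object of class `fst_result`: list with `global`, `p_global`,
#'   `per_locus` tibble (locus, a, b, c, theta), and `pairwise`
#'   (a `pairwise_stat` tibble) when requested.
#' @export
wc_fst <- function(gt, popmap, n_perm = 10000, seed = 1L, pairwise = TRUE) {
  pm <- validate_popmap(unique(gt$id), popmap)
  mats <- gt_to_matrices(gt)
  pop <- popmap$site[match(mats$ids, popmap$id)]
  if (length(unique(pop)) < 2) abort("need >= 2 populations")

  per_locus <- map(seq_along(mats$loci), function(l) {
    th <- theta_multilocus(mats$a1[, l, drop = FALSE], mats$a2[, l, drop = FALSE],
                           pop, mats$nalleles[l])
    tibble(locus = mats$loci[l], theta = th)
  }) |> list_rbind()
  global <- theta_multilocus(mats$a1, mats$a2, pop, mats$nalleles)
  p_global <- NA_real_
  if (n_perm > 0) {
    null <- with_seed(derive_seed(seed, "fst", "global"), {
      vapply(seq_len(n_perm), function(k) {
        theta_multilocus(mats$a1, mats$a2, sample(pop), mats$nalleles)
      }, 0)
    })
    p_global <- permutation_p(global, null)
  }
  pw <- NULL
  if (pairwise) {
    sites <- unique(pop)
    res <- list()
    for (i in seq_len(length(sites) - 1)) {
      for (j in (i + 1):length(sites)) {
        sel <- pop %in% c(sites[i], sites[j])
        th <- theta_multilocus(mats$a1[sel, , drop = FALSE],
                               mats$a2[sel, , drop = FALSE],
                               pop[sel], mats$nalleles)
        pv <- NA_real_
        if (n_perm > 0 && is.finite(th)) {
          null <- with_seed(derive_seed(seed, "fst", sites[i], sites[j]), {
            vapply(seq_len(n_perm), function(k) {
              theta_multilocus(mats$a1[sel, , drop = FALSE],
                               mats$a2[sel, , drop = FALSE],
                               sample(pop[sel]), mats$nalleles)
            }, 0)
          })
          pv <- permutation_p(th, null)
        }
        res[[length(res) + 1]] <- tibble(pop1 = sites[i], pop2 = sites[j],
                                         value = th, p = pv)
      }
    }
    pw <- bind_rows(res)
    attr(pw, "statistic") <- "wc_theta"
    class(pw) <- c("pairwise_stat", class(pw))
  }
  structure(list(global = global, p_global = p_global, per_locus = per_locus,
                 pairwise = pw, n_perm = n_perm, seed = seed),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("<fst_result> multilocus Weir-Cockerham theta = ",
      format(x$global, digits = 4), " (p = ", format(x$p_global, digits = 3),
      ", ", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' @export
tidy.fst_result <- function(x, ...) x$per_locus

#' @export
glance.fst_result <- function(x, ...) {
  tibble(theta = x$global, p = x$p_global, n_perm = x$n_perm)
}

jost_d_locus <- function(freqs, ns) {
  keep <- ns > 0
  freqs <- freqs[keep, , drop = FALSE]
  ns <- ns[keep]
  r <- length(ns)
  if (r < 2) return(NA_real_)
  ntilde <- r / sum(1 / ns)
  hs <- 1 - mean(rowSums(freqs^2))
  ht <- 1 - sum(colMeans(freqs)^2)
  hs_est <- (2 * ntilde / (2 * ntilde - 1)) * hs
  ht_est <- ht + hs_est / (2 * ntilde * r)
  if (hs_est >= 1) return(NA_real_)
  (ht_est - hs_est) / (1 - hs_est) * r / (r - 1)
}

#' Jost's D differentiation estimator
#'
#' Per-locus `D = (H_T - H_S) / (1 - H_S) * r/(r-1)` with Nei-Chesser
#' sample-size-corrected heterozygosities; the multilocus value is the SMOGD
#' harmonic-mean combination across loci (negative per-locus values clamped
#' to 0 before averaging; loci with `H_S = 1` are skipped).
#'
#' @param gt Genotype tibble.
#' @param popmap Population map.
#' @param pairwise Also compute all pairwise-population values (default
#'   `TRUE`).
#' @return List of class `jost_d` with `per_locus` (locus, d, d_clamped),
#'   `global` (multilocus harmonic mean) and optionally `pairwise`.
#' @export
jost_dest <- function(gt, popmap, pairwise = TRUE) {
  mats <- gt_to_matrices(gt)
  pop <- popmap$site[match(mats$ids, popmap$id)]
  sites <- unique(pop)
  locus_d <- function(sel_pops) {
    vapply(seq_along(mats$loci), function(l) {
      x1 <- mats$a1[, l]; x2 <- mats$a2[, l]
      K <- mats$nalleles[l]
      freqs <- matrix(0, length(sel_pops), K)
      ns <- numeric(length(sel_pops))
      for (pi in seq_along(sel_pops)) {
        sel <- !is.na(x1) & pop == sel_pops[pi]
        ns[pi] <- sum(sel)
        if (ns[pi] > 0) {
          freqs[pi, ] <- (tabulate(x1[sel], K) + tabulate(x2[sel], K)) / (2 * ns[pi])
        }
      }
      jost_d_locus(freqs, ns)
    }, 0)
  }
  d_all <- locus_d(sites)
  per_locus <- tibble(locus = mats$loci, d = d_all,
                      d_clamped = pmax(d_all, 0))
  global <- harmonic_mean_smogd(per_locus$d_clamped[!is.na(per_locus$d)])
  pw <- NULL
  if (pairwise && length(sites) >= 2) {
    res <- list()
    for (i in seq_len(length(sites) - 1)) {
      for (j in (i + 1):length(sites)) {
        dd <- locus_d(c(sites[i], sites[j]))
        res[[length(res) + 1]] <- tibble(
          pop1 = sites[i], pop2 = sites[j],
          value = harmonic_mean_smogd(pmax(dd[!is.na(dd)], 0)), p = NA_real_)
      }
    }
    pw <- bind_rows(res)
    attr(pw, "statistic") <- "jost_d"
    class(pw) <- c("pairwise_stat", class(pw))
  }
  structure(list(per_locus = per_locus, global = global, pairwise = pw),
            class = "jost_d")
}

#' @export
print.jost_d <- function(x, ...) {
  cat("<jost_d> multilocus D_est = ", format(x$global, digits = 4), " over ",
      nrow(x$per_locus), " loci\n", sep = "")
  invisible(x)
}

#' @export
tidy.jost_d <- function(x, ...) x$per_locus

#' @export
glance.jost_d <- function(x, ...) tibble(d_est = x$global)
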