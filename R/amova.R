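# Distance-based hierarchical AMOVA (Excoffier-Smouse-Quattro) with
# Phi-statistics and permutation tests.
#
# Convention: the supplied molecular distance matrix is consumed as the matrix
# of squared inter-individual distances (the Arlequin convention for sequence
# data, where e.g. the pairwise-difference or K80 distance enters the sums of
# squares directly). Negative variance components are reported as-is.

ssd_of <- function(d2, idx) sum(d2[idx, idx]) / (2 * length(idx))

amova_components <- function(d2, pop, grp = NULL) {
  N <- length(pop)
  pops <- split(seq_len(N), pop, drop = TRUE)
  P <- length(pops)
  np <- lengths(pops)
  ssd_t <- ssd_of(d2, seq_len(N))
  ssd_wp <- sum(vapply(pops, function(ix) ssd_of(d2, ix), 0))
  if (is.null(grp)) {
    df_ap <- P - 1L
    df_wp <- N - P
    sig_c <- if (df_wp > 0) (ssd_wp) / df_wp else 0
    if (df_ap < 1) {
      return(list(one_level = TRUE, ssd = c(among = 0, within = ssd_wp, total = ssd_t),
                  df = c(among = 0L, within = df_wp, total = N - 1L),
                  sigma = c(among = NA_real_, within = sig_c),
                  phi_st = NA_real_))
    }
    ssd_ap <- ssd_t - ssd_wp
    n_avg <- (N - sum(np^2) / N) / df_ap
    sig_b <- (ssd_ap / df_ap - sig_c) / n_avg
    list(one_level = TRUE,
         ssd = c(among = ssd_ap, within = ssd_wp, total = ssd_t),
         df = c(among = df_ap, within = df_wp, total = N - 1L),
         sigma = c(among = sig_b, within = sig_c),
         phi_st = sig_b / (sig_b + sig_c))
  } else {
    groups <- split(seq_len(N), grp, drop = TRUE)
    G <- length(groups)
    ng <- lengths(groups)
    ssd_wg <- sum(vapply(groups, function(ix) ssd_of(d2, ix), 0))
    ssd_ag <- ssd_t - ssd_wg
    ssd_apwg <- ssd_wg - ssd_wp
    df_ag <- G - 1L
    df_ap <- P - G
    df_wp <- N - P
    if (df_ap == 0L) {
      # every group holds a single population: the among-populations level
      # vanishes and the design collapses to a one-level AMOVA over groups
      one <- amova_components(d2, grp)
      sig_a <- unname(one$sigma["among"])
      sig_c <- unname(one$sigma["within"])
      tot <- sig_a + sig_c
      return(list(one_level = FALSE,
                  ssd = c(among_groups = ssd_ag, among_pops = 0,
                          within = ssd_wp, total = ssd_t),
                  df = c(among_groups = df_ag, among_pops = 0L,
                         within = df_wp, total = N - 1L),
                  sigma = c(among_groups = sig_a, among_pops = 0,
                            within = sig_c),
                  phi_st = sig_a / tot,
                  phi_ct = sig_a / tot,
                  phi_sc = 0))
    }
    # expected-mean-square coefficients (Excoffier et al. 1992)
    sum_np2_by_g <- vapply(names(groups), function(g) {
      ix <- groups[[g]]
      sum(table(pop[ix])^2) / length(ix)
    }, 0)
    n1 <- (N - sum(sum_np2_by_g)) / df_ap
    n2 <- (sum(sum_np2_by_g) - sum(np^2) / N) / df_ag
    n3 <- (N - sum(ng^2) / N) / df_ag
    sig_c <- ssd_wp / df_wp
    sig_b <- (ssd_apwg / df_ap - sig_c) / n1
    sig_a <- (ssd_ag / df_ag - sig_c - n2 * sig_b) / n3
    tot <- sig_a + sig_b + sig_c
    list(one_level = FALSE,
         ssd = c(among_groups = ssd_ag, among_pops = ssd_apwg,
                 within = ssd_wp, total = ssd_t),
         df = c(among_groups = df_ag, among_pops = df_ap,
                within = df_wp, total = N - 1L),
         sigma = c(among_groups = sig_a, among_pops = sig_b, within = sig_c),
         phi_st = (sig_a + sig_b) / tot,
         phi_ct = sig_a / tot,
         phi_sc = sig_b / (sig_b + sig_c))
  }
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions squared molecular distances among groups, among populations
#' within groups, and within populations; reports variance components,
#' percentages, Phi-statistics and permutation p-values. With a single
#' grouping level (all sites in one group, or `hierarchy = "one"`), a
#' one-level AMOVA returning only `phi_st` is computed.
#'
#' Permutation schemes follow the level being tested: individuals among
#' populations (whole sample) for `phi_st`; individuals among populations
#' within groups for `phi_sc`; whole populations among groups for `phi_ct`.
#'
#' @param d Distance matrix (ids as dimnames); entries are used as squared
#'   distances.
#' @param popmap Population map covering all ids in `d`.
#' @param hierarchy `"auto"` (two-level when >1 group present), `"one"`, or
#'   `"two"`.
#' @param n_perm Number of permutations for p-values (default 10000; 0 skips
#'   testing).
#' @param seed Integer seed; per-statistic permutation streams are derived
#'   deterministically from it.
#' @return An object of class `amova_fit` with elements `table` (source, df,
#'   SS, variance component, percent variance), `phi` (statistic, value, p),
#'   and metadata. Percentages are computed from the raw (possibly negative)
#'   components.
#' @export
amova <- function(d, popmap, hierarchy = c("auto", "one", "two"),
                  n_perm = 10000, seed = 1L) {
  hierarchy <- match.arg(hierarchy)
  ids <- rownames(d)
  pm <- validate_popmap(ids, popmap)
  pop <- pm$site
  grp <- pm$group
  if (any(is.na(d))) abort("distance matrix contains NA")
  two <- switch(hierarchy, auto = length(unique(grp)) > 1, one = FALSE, two = TRUE)
  if (two && length(unique(grp)) < 2) abort("two-level design needs >= 2 groups")
  d2 <- unclass(d)
  obs <- amova_components(d2, pop, if (two) grp else NULL)

  phi_tbl <- NULL
  N <- length(pop)
  if (!two) {
    p_st <- NA_real_
    if (n_perm > 0 && is.finite(obs$phi_st)) {
      null <- with_seed(derive_seed(seed, "amova", "phi_st"), {
        vapply(seq_len(n_perm), function(i) {
          amova_components(d2, sample(pop))$phi_st
        }, 0)
      })
      p_st <- permutation_p(obs$phi_st, null)
    }
    phi_tbl <- tibble(statistic = "phi_st", value = obs$phi_st, p = p_st,
                      n_perm = n_perm)
    tab <- tibble(
      source = c("among populations", "within populations", "total"),
      df = as.integer(c(obs$df["among"], obs$df["within"], obs$df["total"])),
      SS = unname(c(obs$ssd["among"], obs$ssd["within"], obs$ssd["total"])),
      variance = unname(c(obs$sigma["among"], obs$sigma["within"],
                          sum(obs$sigma))),
      pct = unname(100 * c(obs$sigma["among"], obs$sigma["within"], NA) /
                     sum(obs$sigma)))
    if (is.na(tab$variance[1])) {
      # single population: everything is within-population variance
      tab$pct[2] <- 100
      tab$variance[3] <- tab$variance[2]
    }
    tab$pct[3] <- 100
  } else {
    p_st <- p_ct <- p_sc <- NA_real_
    if (n_perm > 0) {
      null_st <- with_seed(derive_seed(seed, "amova", "phi_st"), {
        vapply(seq_len(n_perm), function(i) {
          amova_components(d2, sample(pop), grp)$phi_st
        }, 0)
      })
      p_st <- permutation_p(obs$phi_st, null_st)
      # phi_sc: individuals among populations within their group
      idx_by_grp <- split(seq_len(N), grp)
      null_sc <- with_seed(derive_seed(seed, "amova", "phi_sc"), {
        vapply(seq_len(n_perm), function(i) {
          pp <- pop
          for (ix in idx_by_grp) pp[ix] <- sample(pp[ix])
          amova_components(d2, pp, grp)$phi_sc
        }, 0)
      })
      p_sc <- permutation_p(obs$phi_sc, null_sc)
      # phi_ct: whole populations among groups
      pops <- unique(pop)
      grp_of_pop <- grp[match(pops, pop)]
      null_ct <- with_seed(derive_seed(seed, "amova", "phi_ct"), {
        vapply(seq_len(n_perm), function(i) {
          gg <- sample(grp_of_pop)
          amova_components(d2, pop, gg[match(pop, pops)])$phi_ct
        }, 0)
      })
      p_ct <- permutation_p(obs$phi_ct, null_ct)
    }
    phi_tbl <- tibble(
      statistic = c("phi_ct", "phi_sc", "phi_st"),
      value = c(obs$phi_ct, obs$phi_sc, obs$phi_st),
      p = c(p_ct, p_sc, p_st),
      n_perm = n_perm)
    sig <- unname(obs$sigma)
    tab <- tibble(
      source = c("among groups", "among populations within groups",
                 "within populations", "total"),
      df = as.integer(c(obs$df[1:3], obs$df["total"])),
      SS = unname(c(obs$ssd[1:3], obs$ssd["total"])),
      variance = c(sig, sum(sig)),
      pct = c(100 * sig / sum(sig), 100))
  }
  if (any(tab$variance < 0, na.rm = TRUE)) {
    warn("negative variance component(s) reported as-is")
  }
  structure(list(table = tab, phi = phi_tbl, two_level = two,
                 n_perm = n_perm, seed = seed,
                 n = N, n_pops = length(unique(pop)),
                 n_groups = length(unique(grp))),
            class = "amova_fit")
}

#' @export
print.amova_fit <- function(x, ...) {
  cat("<amova_fit> ", if (x$two_level) "two-level" else "one-level",
      " design: ", x$n, " individuals, ", x$n_pops, " populations",
      if (x$two_level) paste0(", ", x$n_groups, " groups"), "\n", sep = "")
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  print(as.data.frame(x$phi), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.amova_fit <- function(x, ...) x$table

#' @export
glance.amova_fit <- function(x, ...) {
  x$phi |>
    tidyr::pivot_wider(names_from = "statistic",
                       values_from = c("value", "p")) |>
    mutate(n = x$n, n_perm = x$n_perm)
}

#' Pairwise Phi_ST between sampling sites
#'
#' For each site pair a one-level two-population AMOVA `phi_st` is computed
#' from the molecular distance matrix, with a permutation p-value. Each pair's
#' permutation stream is derived deterministically from the master seed and
#' the pair's names, so the matrix is reproducible regardless of evaluation
#' order.
#'
#' @param x Alignment tibble or a precomputed distance matrix.
#' @param popmap Population map.
#' @param model Distance model when `x` is an alignment (see
#'   [distance_matrix()]).
#' @param n_perm Permutations per pair (default 10000).
#' @param seed Master seed.
#' @return A tibble of class `pairwise_stat` with columns `pop1`, `pop2`,
#'   `value` (`phi_st`), `p`, plus a `statistic` attribute.
#' @export
pairwise_phist <- function(x, popmap, model = "K80", n_perm = 10000, seed = 1L) {
  d <- if (is.matrix(x)) x else distance_matrix(x, model)
  ids <- rownames(d)
  pm <- validate_popmap(ids, popmap)
  sites <- unique(pm$site)
  if (length(sites) < 2) abort("need at least two populations")
  res <- list()
  for (i in seq_len(length(sites) - 1)) {
    for (j in (i + 1):length(sites)) {
      s1 <- sites[i]; s2 <- sites[j]
      ix <- which(pm$site %in% c(s1, s2))
      d2 <- unclass(d)[ix, ix]
      pop <- pm$site[ix]
      obs <- amova_components(d2, pop)$phi_st
      pval <- NA_real_
      if (n_perm > 0 && is.finite(obs)) {
        null <- with_seed(derive_seed(seed, "phist", s1, s2), {
          vapply(seq_len(n_perm), function(k) {
            amova_components(d2, sample(pop))$phi_st
          }, 0)
        })
        pval <- permutation_p(obs, null)
      }
      res[[length(res) + 1]] <- tibble(pop1 = s1, pop2 = s2,
                                       value = obs, p = pval)
    }
  }
  out <- bind_rows(res)
  attr(out, "statistic") <- "phi_st"
  attr(out, "n_perm") <- n_perm
  class(out) <- c("pairwise_stat", class(out))
  out
}

#' Lower-triangle matrix view of a pairwise statistic table
#'
#' @param x A `pairwise_stat` tibble.
#' @param what `"value"` or `"p"`.
#' @return A square matrix with `NA` on and above the diagonal.
#' @export
pairwise_as_matrix <- function(x, what = "value") {
  pops <- unique(c(x$pop1, x$pop2))
  m <- matrix(NA_real_, length(pops), length(pops), dimnames = list(pops, pops))
  for (k in seq_len(nrow(x))) {
    i <- match(x$pop2[k], pops); j <- match(x$pop1[k], pops)
    m[max(i, j), min(i, j)] <- x[[what]][k]
  }
  m
}

#' Inter-individual allele-sharing distance for microsatellite genotypes
#'
#' The squared distance between two individuals is the total number of
#' non-shared alleles across loci scored in both (0, 1 or 2 per locus). This
#' is the distance Arlequin uses for genotypic AMOVA of microsatellites.
#'
#' @param gt Genotype tibble.
#' @return Symmetric matrix over individuals (attribute
#'   `model = "allele_mismatch"`).
#' @export
genotype_distance <- function(gt) {
  ids <- unique(gt$id)
  loci <- unique(gt$locus)
  a1 <- matrix(NA_integer_, length(ids), length(loci), dimnames = list(ids, loci))
  a2 <- a1
  a1[cbind(match(gt$id, ids), match(gt$locus, loci))] <- gt$allele_1
  a2[cbind(match(gt$id, ids), match(gt$locus, loci))] <- gt$allele_2
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  mism <- function(x1, x2, y1, y2) {
    # unordered pairs {x1,x2} vs {y1,y2}: 2 - number of shared alleles
    shared <- (x1 == y1) + (x2 == y2)
    cross <- (x1 == y2) + (x2 == y1)
    2 - pmax(shared, cross)
  }
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      ok <- !is.na(a1[i, ]) & !is.na(a1[j, ])
      if (!any(ok)) next
      d[i, j] <- d[j, i] <-
        sum(mism(a1[i, ok], a2[i, ok], a1[j, ok], a2[j, ok]))
    }
  }
  attr(d, "model") <- "allele_mismatch"
  d
}
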