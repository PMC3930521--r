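# Coalescent synthetic-data generator. The generator's defaults are the
# study conditions the rest of the package is exercised against: two
# populations (northern/southern) split ~2 Ma with no migration, sampled at
# the study's per-site sizes, a 583-bp control-region-like locus under a
# transition-biased two-parameter mutation model, and a stepwise-mutation
# microsatellite panel. Time is in generations throughout; calendar-time
# conversion happens only through clock_config().

#' Scenario configuration for the synthetic-data generator
#'
#' @param samples Tibble with columns `site`, `group`, `n`: per-site sample
#'   sizes. Default mirrors the study sampling (six northern sites 20, 17,
#'   20, 20, 20, 7; two southern sites 20, 20).
#' @param ne Named-by-group effective number of gene copies for the sequence
#'   coalescent. Defaults (62500, 100000) give mutation-scaled diversities
#'   (`theta = 2 Ne mu`) matching the observed per-site nucleotide
#'   diversities (~0.005 and ~0.008) at the default mutation rate.
#' @param ne_ancestral Ancestral size after the split (default northern
#'   value).
#' @param t_split Split time in generations (default 909000, i.e. ~2 My at a
#'   2.2-year generation).
#' @param migration Symmetric per-generation, per-lineage migration rate
#'   (default 0).
#' @param L Sequence length in bp (default 583).
#' @param mu_site Substitutions per site per generation (default 4e-8: a
#'   1.8% per-lineage per-My control-region rate at 2.2 years per
#'   generation).
#' @param kappa Transition/transversion rate ratio (default 10, a typical
#'   control-region bias).
#' @param expansion Single-population sudden-expansion scenario: list with
#'   `n` (sample size), `n0`, `n1` (sizes before/after), `t` (generations
#'   since expansion). Defaults reproduce the fitted northern history
#'   (`theta0` 1.24, `theta1` 7.3, `tau` 2.5 at the default mutation rate).
#' @param msat Microsatellite scenario: list with `n_loci`, `n_alleles`
#'   (initial ladder size), `motif` (bp), `smm_rate` (stepwise mutations per
#'   gene copy per generation), `ne`, `t_group` (generations of independent
#'   drift per group), `t_site` (extra per-site drift), `null_freq`.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(samples = NULL,
                            ne = c(northern = 62500, southern = 100000),
                            ne_ancestral = NULL,
                            t_split = 909000,
                            migration = 0,
                            L = 583,
                            mu_site = 4e-8,
                            kappa = 10,
                            expansion = NULL,
                            msat = NULL) {
  if (is.null(samples)) {
    samples <- tibble(
      site = c("LUA", "BEN", "LUC", "NBE", "PIN", "HEN", "ARN", "PAL"),
      group = c(rep("northern", 6), rep("southern", 2)),
      n = c(20L, 17L, 20L, 20L, 20L, 7L, 20L, 20L))
  }
  mu_seq <- mu_site * L
  if (is.null(expansion)) {
    expansion <- list(n = 50L,
                      n0 = round(1.239 / (2 * mu_seq)),
                      n1 = round(7.317 / (2 * mu_seq)),
                      t = round(2.492 / (2 * mu_seq)))
  }
  if (is.null(msat)) {
    msat <- list(n_loci = 8L, n_alleles = 10L, motif = 2L, smm_rate = 5e-4,
                 ne = 2000, t_group = drift_generations(0.05, 2000),
                 t_site = 0L, null_freq = 0)
  }
  samples$n <- as.integer(samples$n)
  stopifnot(migration >= 0, migration <= 1, t_split >= 0, L > 0,
            mu_site >= 0, mu_site <= 1, kappa > 0, all(ne >= 2),
            all(samples$n >= 1))
  if (is.null(ne_ancestral)) ne_ancestral <- ne[[1]]
  structure(list(samples = samples, ne = ne, ne_ancestral = ne_ancestral,
                 t_split = t_split, migration = migration, L = L,
                 mu_site = mu_site, kappa = kappa,
                 expansion = expansion, msat = msat),
            class = "scenario_config")
}

# two-deme structured coalescent (backwards in time, generations); returns
# parent pointers and node times for n1 + n2 sampled lineages
sim_structured_tree <- function(n_by_deme, ne_by_deme, ne_anc, t_split, m) {
  n <- sum(n_by_deme)
  n_nodes <- 2L * n - 1L
  parent <- rep(NA_integer_, n_nodes)
  node_time <- numeric(n_nodes)
  deme <- rep(seq_along(n_by_deme), n_by_deme)
  active <- seq_len(n)
  deme_of <- deme
  t_now <- 0
  nxt <- n
  merged <- t_split <= 0
  if (merged) deme_of[] <- 1L
  while (length(active) > 1) {
    k_by <- tabulate(deme_of[active], nbins = 2L)
    if (!merged) {
      rate_coal <- k_by * (k_by - 1) / 2 / ne_by_deme
      rate_mig <- length(active) * m
      total <- sum(rate_coal) + rate_mig
      if (total <= 0) { t_now <- t_split } else {
        dt <- rexp(1, total)
        if (t_now + dt >= t_split) {
          t_now <- t_split
        } else {
          t_now <- t_now + dt
          u <- runif(1) * total
          if (u < rate_coal[1] || u < sum(rate_coal)) {
            d <- if (u < rate_coal[1]) 1L else 2L
            cand <- active[deme_of[active] == d]
            pick <- sample(length(cand), 2L)
            nxt <- nxt + 1L
            node_time[nxt] <- t_now
            parent[cand[pick]] <- nxt
            deme_of[nxt] <- d
            active <- c(setdiff(active, cand[pick]), nxt)
          } else {
            lx <- active[sample(length(active), 1L)]
            deme_of[lx] <- 3L - deme_of[lx]
          }
          next
        }
      }
      merged <- TRUE
      deme_of[active] <- 1L
      next
    }
    k <- length(active)
    t_now <- t_now + rexp(1, k * (k - 1) / 2 / ne_anc)
    pick <- sample(k, 2L)
    nxt <- nxt + 1L
    node_time[nxt] <- t_now
    parent[active[pick]] <- nxt
    active <- c(active[-pick], nxt)
  }
  list(parent = parent, node_time = node_time, n = n, n_nodes = n_nodes)
}

# drop K80-style mutations on a genealogy and return the tip sequences
mutate_sequences <- function(tree, L, mu_site, kappa) {
  n <- tree$n
  seqs <- matrix(0L, tree$n_nodes, L)
  root <- which(is.na(tree$parent))
  seqs[root, ] <- sample(1:4, L, replace = TRUE)
  # transitions: A<->G (1,3), C<->T (2,4); transversion targets differ in parity
  p_ts <- kappa / (kappa + 2)
  ts_partner <- c(3L, 4L, 1L, 2L)
  ord <- order(tree$node_time[seq_len(tree$n_nodes)], decreasing = TRUE)
  for (v in ord) {
    if (v == root) next
    par <- tree$parent[v]
    s <- seqs[par, ]
    len <- tree$node_time[par] - tree$node_time[v]
    nmut <- rpois(1, mu_site * L * len)
    if (nmut > 0) {
      sites <- sample.int(L, nmut, replace = TRUE)
      for (sm in sites) {
        b <- s[sm]
        if (runif(1) < p_ts) {
          s[sm] <- ts_partner[b]
        } else {
          # one of the two bases of opposite parity
          tv <- if (b %% 2L == 1L) c(2L, 4L) else c(1L, 3L)
          s[sm] <- tv[sample.int(2L, 1L)]
        }
      }
    }
    seqs[v, ] <- s
  }
  bases <- c("A", "C", "G", "T")
  apply(seqs[seq_len(n), , drop = FALSE], 1, function(r) paste(bases[r], collapse = ""))
}

#' Simulate a two-population sequence sample
#'
#' Structured coalescent for two demes that merge `t_split` generations ago
#' (optional symmetric migration before the merge, backwards in time),
#' followed by Poisson placement of finite-sites mutations under a
#' two-parameter (transition-biased) substitution model on a random ancestral
#' sequence.
#'
#' @param cfg A [scenario_config()].
#' @param seed Seed (byte-identical output for identical seed + config).
#' @return List with `aln` (alignment tibble) and `popmap`.
#' @export
simulate_two_pop_sequences <- function(cfg = scenario_config(), seed = 1L) {
  with_seed(derive_seed(seed, "twopop"), {
    groups <- unique(cfg$samples$group)
    stopifnot(length(groups) <= 2)
    n_by <- vapply(groups, function(g) {
      as.integer(sum(cfg$samples$n[cfg$samples$group == g]))
    }, integer(1))
    if (length(n_by) == 1) n_by <- c(n_by, 0L)
    ne_by <- unname(cfg$ne[seq_len(2)])
    tree <- sim_structured_tree(n_by, ne_by, cfg$ne_ancestral,
                                cfg$t_split, cfg$migration)
    seqs <- mutate_sequences(tree, cfg$L, cfg$mu_site, cfg$kappa)
    samples <- cfg$samples[order(match(cfg$samples$group, groups)), ]
    ids <- unlist(lapply(seq_len(nrow(samples)), function(i) {
      sprintf("%s_%02d", samples$site[i], seq_len(samples$n[i]))
    }))
    popmap <- tibble(id = ids,
                     site = rep(samples$site, samples$n),
                     group = rep(samples$group, samples$n))
    list(aln = alignment(ids, seqs), popmap = popmap)
  })
}

#' Simulate a single population with a sudden size change
#'
#' Present size `n1` back to `t` generations ago, `n0` beyond: the
#' sudden-expansion history whose mismatch distribution
#' [fit_sudden_expansion()] models.
#'
#' @param cfg A [scenario_config()]; uses the `expansion` block and the
#'   sequence-model fields.
#' @param seed Seed.
#' @return Alignment tibble of `cfg$expansion$n` sequences.
#' @export
simulate_expansion_sequences <- function(cfg = scenario_config(), seed = 1L) {
  with_seed(derive_seed(seed, "expansion"), {
    e <- cfg$expansion
    tree <- sim_coalescent_tree(e$n, theta = 1,
                                sizes = c(e$n1, max(e$n0, 2)),
                                breaks = e$t)
    seqs <- mutate_sequences(tree, cfg$L, cfg$mu_site, cfg$kappa)
    alignment(sprintf("EXP_%02d", seq_len(e$n)), seqs)
  })
}

smm_step <- function(counts, sizes, motif, rate) {
  total <- sum(counts)
  nmut <- rbinom(1, total, rate)
  if (nmut == 0) return(list(counts = counts, sizes = sizes))
  for (k in seq_len(nmut)) {
    src <- sample.int(length(counts), 1, prob = counts)
    counts[src] <- counts[src] - 1L
    new_size <- sizes[src] + motif * sample(c(-1L, 1L), 1)
    hit <- match(new_size, sizes)
    if (is.na(hit)) {
      sizes <- c(sizes, new_size)
      counts <- c(counts, 1L)
    } else {
      counts[hit] <- counts[hit] + 1L
    }
  }
  keep <- counts > 0
  list(counts = counts[keep], sizes = sizes[keep])
}

#' Simulate a diploid microsatellite panel under drift
#'
#' Base allele frequencies (Dirichlet over an allele-size ladder) drift
#' independently in each group for `t_group` generations by multinomial
#' resampling of `2 Ne` genes (optional stepwise mutation), then in each site
#' for `t_site` further generations; diploid genotypes are drawn under
#' Hardy-Weinberg proportions. An optional null-allele class (frequency
#' `null_freq`) converts carriers into apparent homozygotes and null
#' homozygotes into missing genotypes.
#'
#' @param cfg A [scenario_config()] (uses the `msat` and `samples` blocks).
#' @param seed Seed.
#' @return List with `gt` (genotype tibble), `popmap`, and `base_freqs`.
#' @export
simulate_msat_genotypes <- function(cfg = scenario_config(), seed = 1L) {
  with_seed(derive_seed(seed, "msat"), {
    ms <- cfg$msat
    samples <- cfg$samples
    groups <- unique(samples$group)
    loci <- sprintf("loc%02d", seq_len(ms$n_loci))
    ids <- unlist(lapply(seq_len(nrow(samples)), function(i) {
      sprintf("%s_%02d", samples$site[i], seq_len(samples$n[i]))
    }))
    popmap <- tibble(id = ids, site = rep(samples$site, samples$n),
                     group = rep(samples$group, samples$n))
    base <- lapply(loci, function(l) {
      sizes <- 100L + ms$motif * seq_len(ms$n_alleles)
      w <- rexp(ms$n_alleles)                  # Dirichlet(1,...,1)
      list(sizes = sizes, freqs = w / sum(w))
    })
    names(base) <- loci
    drift_block <- function(freqs, sizes, t) {
      st <- list(counts = freqs * 2 * ms$ne, sizes = sizes)
      for (g in seq_len(t)) {
        st$counts <- as.numeric(rmultinom(1, 2 * ms$ne, st$counts / sum(st$counts)))
        keep <- st$counts > 0
        st$counts <- st$counts[keep]; st$sizes <- st$sizes[keep]
        if (ms$smm_rate > 0) st <- smm_step(st$counts, st$sizes, ms$motif, ms$smm_rate)
      }
      st
    }
    rows <- list()
    for (l in loci) {
      group_state <- lapply(groups, function(g) {
        drift_block(base[[l]]$freqs, base[[l]]$sizes, ms$t_group)
      })
      names(group_state) <- groups
      for (i in seq_len(nrow(samples))) {
        st <- group_state[[samples$group[i]]]
        if (ms$t_site > 0) st <- drift_block(st$counts / sum(st$counts),
                                             st$sizes, ms$t_site)
        p <- st$counts / sum(st$counts)
        sz <- st$sizes
        n_i <- samples$n[i]
        null <- ms$null_freq
        draw <- function() {
          if (null > 0 && runif(1) < null) NA_integer_ else sz[sample.int(length(sz), 1, prob = p)]
        }
        a1 <- vapply(seq_len(n_i), function(k) draw(), 0L)
        a2 <- vapply(seq_len(n_i), function(k) draw(), 0L)
        vis1 <- ifelse(is.na(a1) & is.na(a2), NA_integer_,
                       ifelse(is.na(a1), a2, a1))
        vis2 <- ifelse(is.na(a1) & is.na(a2), NA_integer_,
                       ifelse(is.na(a2), vis1, ifelse(is.na(a1), a2, a2)))
        site_ids <- popmap$id[popmap$site == samples$site[i]]
        rows[[length(rows) + 1]] <- tibble(id = site_ids, locus = l,
                                           allele_1 = vis1, allele_2 = vis2)
      }
    }
    gt <- bind_rows(rows)
    gt <- new_genotypes(gt$id, gt$locus, gt$allele_1, gt$allele_2)
    list(gt = gt, popmap = popmap, base_freqs = base)
  })
}
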