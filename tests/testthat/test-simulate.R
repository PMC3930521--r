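panmictic_cfg <- function(n1 = 10, n2 = 0, L = 500, theta_site = 0.01) {
  ne <- 12500
  mu <- theta_site / (2 * ne)
  samples <- tibble::tibble(site = c("P1", "P2")[seq_len(1 + (n2 > 0))],
                            group = "g",
                            n = c(n1, n2)[seq_len(1 + (n2 > 0))])
  scenario_config(samples = samples, ne = c(g = ne, g2 = ne),
                  ne_ancestral = ne, t_split = 0, L = L, mu_site = mu)
}

test_that("identical seed and config give byte-identical outputs", {
  cfg <- scenario_config()
  s1 <- simulate_two_pop_sequences(cfg, seed = 5)
  s2 <- simulate_two_pop_sequences(cfg, seed = 5)
  expect_identical(s1$aln$seq, s2$aln$seq)
  expect_identical(s1$popmap, s2$popmap)
  s3 <- simulate_two_pop_sequences(cfg, seed = 6)
  expect_false(identical(s1$aln$seq, s3$aln$seq))

  g1 <- simulate_msat_genotypes(cfg, seed = 9)
  g2 <- simulate_msat_genotypes(cfg, seed = 9)
  expect_identical(as.data.frame(g1$gt), as.data.frame(g2$gt))

  e1 <- simulate_expansion_sequences(cfg, seed = 4)
  e2 <- simulate_expansion_sequences(cfg, seed = 4)
  expect_identical(e1$seq, e2$seq)
})

test_that("panmictic simulations match coalescent expectations for pi and S", {
  cfg <- panmictic_cfg(n1 = 10, L = 500, theta_site = 0.01)
  pis <- numeric(200); ss <- numeric(200)
  for (r in 1:200) {
    sim <- simulate_two_pop_sequences(cfg, seed = r)
    pis[r] <- nucleotide_diversity(sim$aln)
    ss[r] <- length(variable_sites(sim$aln)$variable)
  }
  expect_equal(mean(pis), 0.01, tolerance = 0.15)
  a9 <- sum(1 / 1:9)
  expect_equal(mean(ss), 0.01 * a9 * 500, tolerance = 0.15)
})

test_that("a forced single deme centres Phi_ST on zero", {
  cfg <- panmictic_cfg(n1 = 10, n2 = 10, L = 400, theta_site = 0.02)
  phis <- vapply(1:40, function(r) {
    sim <- simulate_two_pop_sequences(cfg, seed = 500 + r)
    d <- distance_matrix(sim$aln, "differences")
    # negative components are expected by construction under the null
    fit <- suppressWarnings(amova(d, sim$popmap, hierarchy = "one", n_perm = 0))
    fit$phi$value
  }, 0)
  expect_lt(abs(mean(phis)), 0.06)
})

test_that("a deep split drives pairwise Phi_ST towards one", {
  cfg <- scenario_config(samples = tibble::tibble(
    site = c("N", "S"), group = c("northern", "southern"), n = c(20L, 20L)))
  phis <- vapply(1:20, function(r) {
    sim <- simulate_two_pop_sequences(cfg, seed = 700 + r)
    d <- distance_matrix(sim$aln, "differences")
    amova(d, sim$popmap, hierarchy = "one", n_perm = 0)$phi$value
  }, 0)
  expect_true(all(phis > 0.7))
  expect_gt(mean(phis), 0.8)
})

test_that("microsatellite drift preserves expected allele frequency", {
  set.seed(77)
  p0 <- 0.3
  means <- replicate(1000, {
    geelbek:::drift_freqs(c(p0, 1 - p0), ne = 200, t = 20)[1]
  })
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - p0), 4 * se + 1e-3)
})

test_that("undrifted genotypes give theta near zero; drift reaches its target", {
  cfg0 <- scenario_config(
    samples = tibble::tibble(site = c("A", "B"), group = c("g1", "g2"),
                             n = c(50L, 50L)),
    msat = list(n_loci = 6L, n_alleles = 6L, motif = 2L, smm_rate = 0,
                ne = 2000, t_group = 0L, t_site = 0L, null_freq = 0))
  th0 <- vapply(1:30, function(r) {
    g <- simulate_msat_genotypes(cfg0, seed = r)
    wc_fst(g$gt, g$popmap, n_perm = 0, pairwise = FALSE)$global
  }, 0)
  expect_lt(abs(mean(th0)), 0.01)

  t50 <- drift_generations(0.05, 500)
  cfg5 <- scenario_config(
    samples = tibble::tibble(site = c("A", "B"), group = c("g1", "g2"),
                             n = c(50L, 50L)),
    msat = list(n_loci = 6L, n_alleles = 6L, motif = 2L, smm_rate = 0,
                ne = 500, t_group = t50, t_site = 0L, null_freq = 0))
  th5 <- vapply(1:60, function(r) {
    g <- simulate_msat_genotypes(cfg5, seed = r)
    wc_fst(g$gt, g$popmap, n_perm = 0, pairwise = FALSE)$global
  }, 0)
  expect_equal(mean(th5), 0.05, tolerance = 0.2)
})

test_that("an injected null allele produces a detectable heterozygote deficit", {
  cfg <- scenario_config(
    samples = tibble::tibble(site = "A", group = "g", n = 300L),
    msat = list(n_loci = 1L, n_alleles = 6L, motif = 2L, smm_rate = 0,
                ne = 5000, t_group = 0L, t_site = 0L, null_freq = 0.15))
  g <- simulate_msat_genotypes(cfg, seed = 21)
  hw <- hwe_test(g$gt, g$popmap, "loc01", n_reps = 500, seed = 2)
  expect_lt(hw$p, 0.05)
  sub <- g$gt[g$gt$locus == "loc01", ]
  em <- null_allele_em(sub$allele_1, sub$allele_2)
  expect_lt(abs(em$null_freq - 0.15), 0.05)
})

test_that("expansion simulations look star-like (negative D, unimodal mismatch)", {
  cfg <- scenario_config()   # default expansion block: ~100-fold growth
  ds <- vapply(1:25, function(r) {
    aln <- simulate_expansion_sequences(cfg, seed = r)
    res <- tajimas_d(aln, n_sim = 0)
    res$D
  }, 0)
  expect_lt(mean(ds, na.rm = TRUE), -0.2)
})
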