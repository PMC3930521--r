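test_that("two monomorphic populations one step apart give Phi_ST = 1", {
  aln <- alignment(paste0("s", 1:6), c(rep("AAA", 3), rep("AAT", 3)))
  pm <- tiny_popmap(aln$id, rep(c("P1", "P2"), each = 3))
  d <- distance_matrix(aln, "differences")
  fit <- amova(d, pm, n_perm = 0)
  expect_equal(fit$phi$value[fit$phi$statistic == "phi_st"], 1)
  expect_equal(fit$table$pct[fit$table$source == "within populations"], 0)
})

test_that("one-level components match the brute-force oracle to 1e-10", {
  for (s in 1:4) {
    aln <- random_alignment(18, 25, seed = 200 + s, alphabet = c("A", "C", "G"))
    set.seed(s)
    pop <- sample(c("P1", "P2", "P3"), 18, replace = TRUE,
                  prob = c(0.4, 0.4, 0.2))
    pm <- tiny_popmap(aln$id, pop)
    d <- distance_matrix(aln, "differences")
    fit <- suppressWarnings(amova(d, pm, n_perm = 0))
    oracle <- naive_phi_st(unclass(d), pop)
    expect_equal(fit$phi$value[fit$phi$statistic == "phi_st"],
                 oracle$phi_st, tolerance = 1e-10)
    expect_equal(unname(fit$table$SS[1:2]), unname(oracle$ssd[1:2]),
                 tolerance = 1e-10)
    expect_equal(unname(fit$table$variance[1:2]), unname(oracle$sigma),
                 tolerance = 1e-10)
  }
})

test_that("two-level components match the brute-force oracle to 1e-10", {
  for (s in 1:3) {
    aln <- random_alignment(20, 30, seed = 300 + s, alphabet = c("A", "T"))
    set.seed(s)
    pop <- rep(c("P1", "P2", "P3", "P4"), each = 5)
    grp <- ifelse(pop %in% c("P1", "P2"), "G1", "G2")
    pm <- tiny_popmap(aln$id, pop, grp)
    d <- distance_matrix(aln, "differences")
    fit <- suppressWarnings(amova(d, pm, n_perm = 0))
    oracle <- naive_amova_two_level(unclass(d), pop, grp)
    phi <- setNames(fit$phi$value, fit$phi$statistic)
    expect_equal(unname(phi["phi_st"]), oracle$phi_st, tolerance = 1e-10)
    expect_equal(unname(phi["phi_ct"]), oracle$phi_ct, tolerance = 1e-10)
    expect_equal(unname(phi["phi_sc"]), oracle$phi_sc, tolerance = 1e-10)
    expect_equal(unname(fit$table$variance[1:3]), unname(oracle$sigma),
                 tolerance = 1e-10)
    expect_equal(sum(fit$table$pct[1:3]), 100, tolerance = 1e-9)
  }
})

test_that("Phi_CT with singleton-population groups equals one-level Phi_ST", {
  aln <- random_alignment(16, 20, seed = 42, alphabet = c("A", "C"))
  pop <- rep(c("P1", "P2"), each = 8)
  pm2 <- tiny_popmap(aln$id, pop, pop)      # each group holds one population
  pm1 <- tiny_popmap(aln$id, pop)
  d <- distance_matrix(aln, "differences")
  two <- suppressWarnings(amova(d, pm2, n_perm = 0))
  one <- suppressWarnings(amova(d, pm1, n_perm = 0))
  expect_equal(two$phi$value[two$phi$statistic == "phi_ct"],
               one$phi$value[one$phi$statistic == "phi_st"],
               tolerance = 1e-10)
})

test_that("a single population yields 100% within-population variance", {
  aln <- random_alignment(8, 15, seed = 7)
  pm <- tiny_popmap(aln$id, rep("only", 8))
  fit <- amova(distance_matrix(aln, "differences"), pm, n_perm = 0)
  expect_true(is.na(fit$phi$value))
  expect_equal(fit$table$pct[fit$table$source == "within populations"], 100)
})

test_that("permutation p-values use the +1 estimator and match enumeration", {
  expect_equal(permutation_p(10, rep(1, 9999)), 1e-4)
  null <- seq_len(999)
  expect_equal(permutation_p(500, null), (1 + 500) / 1000)

  # 4 individuals, 2 vs 2: the permutation distribution of phi_st has only
  # C(4,2)/2 = 3 distinct partitions; exhaustive enumeration gives the exact p
  d2 <- matrix(c(0, 1, 4, 4,
                 1, 0, 4, 4,
                 4, 4, 0, 1,
                 4, 4, 1, 0), 4, 4)
  pop <- c("A", "A", "B", "B")
  obs <- naive_phi_st(d2, pop)$phi_st
  labelings <- combn(4, 2)
  null_exact <- apply(labelings, 2, function(ix) {
    pp <- rep("B", 4); pp[ix] <- "A"
    naive_phi_st(d2, pp)$phi_st
  })
  p_exact <- mean(null_exact >= obs)
  rownames(d2) <- colnames(d2) <- paste0("s", 1:4)
  pm <- tiny_popmap(rownames(d2), pop)
  fit <- amova(d2, pm, n_perm = 2000, seed = 11)
  expect_lt(abs(fit$phi$p - p_exact), 0.05)
})

test_that("pairwise Phi_ST is reproducible and near zero for split labels", {
  aln <- random_alignment(20, 40, seed = 77)
  pm <- tiny_popmap(aln$id, rep(c("X", "Y"), 10))   # arbitrary split
  pw1 <- pairwise_phist(aln, pm, model = "differences", n_perm = 99, seed = 3)
  pw2 <- pairwise_phist(aln, pm, model = "differences", n_perm = 99, seed = 3)
  expect_equal(pw1, pw2)
  expect_lt(abs(pw1$value), 0.3)
  expect_gt(pw1$p, 0.05)
  m <- pairwise_as_matrix(pw1)
  expect_equal(m["Y", "X"], pw1$value)
})

test_that("genotype allele-mismatch distance counts non-shared alleles", {
  gt <- tibble::tibble(
    id = rep(c("i1", "i2", "i3"), each = 2),
    locus = rep(c("l1", "l2"), 3),
    allele_1 = c(100L, 200L, 100L, 202L, 102L, NA),
    allele_2 = c(102L, 200L, 100L, 204L, 104L, NA))
  d <- genotype_distance(gt)
  # l1: {100,102} vs {100,100} -> 1; l2: {200,200} vs {202,204} -> 2
  expect_equal(d["i1", "i2"], 3)
  # i3 missing l2: only l1 compared; {100,102} vs {102,104} -> 1
  expect_equal(d["i1", "i3"], 1)
})
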