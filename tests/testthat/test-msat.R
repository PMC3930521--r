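make_gt <- function(genos_by_pop, locus = "l1") {
  # genos_by_pop: named list pop -> 2-col matrix of alleles
  rows <- list()
  ids <- c(); sites <- c()
  for (p in names(genos_by_pop)) {
    g <- genos_by_pop[[p]]
    id <- sprintf("%s_%02d", p, seq_len(nrow(g)))
    rows[[p]] <- tibble::tibble(id = id, locus = locus,
                                allele_1 = g[, 1], allele_2 = g[, 2])
    ids <- c(ids, id); sites <- c(sites, rep(p, nrow(g)))
  }
  list(gt = dplyr::bind_rows(rows), popmap = tiny_popmap(ids, sites))
}

test_that("allelic richness rarefaction matches the combinatorial form", {
  expect_equal(allelic_richness(c(2, 2), 2), 2 * (1 - 1 / 6))
  # rarefying to the full sample returns the allele count
  expect_equal(allelic_richness(c(3, 4, 5), 12), 3)
  expect_true(is.na(allelic_richness(c(2, 2), 6)))
  expect_lte(allelic_richness(c(5, 3, 2), 4), 3)
})

test_that("locus summary computes n, Na, He, Ho and F_IS per population", {
  g <- make_gt(list(P1 = cbind(c(100, 100, 102, 102), c(102, 102, 104, 104)),
                    P2 = cbind(rep(100, 4), rep(100, 4))))
  ls <- locus_summary(g$gt, g$popmap, rarefaction_g = 4)
  p1 <- ls[ls$site == "P1" & ls$locus == "l1", ]
  expect_equal(p1$n, 4)
  expect_equal(p1$na, 3)
  expect_equal(p1$ho, 1)           # every individual heterozygous
  p <- c(2, 4, 2) / 8
  expect_equal(p1$he, (8 / 7) * (1 - sum(p^2)))
  expect_true(p1$fis < 0)          # heterozygote excess
  p2 <- ls[ls$site == "P2" & ls$locus == "l1", ]
  expect_equal(c(p2$he, p2$ho), c(0, 0))   # monomorphic
  expect_true(is.na(p2$fis))
  expect_equal(p2$ar, 1)
  # multilocus average row exists
  expect_true(any(ls$locus == "all"))
})

test_that("Weir-Cockerham theta matches the independent oracle to 1e-10", {
  set.seed(31)
  for (s in 1:3) {
    genos <- list(
      P1 = cbind(sample(100:106, 14, TRUE), sample(100:106, 14, TRUE)),
      P2 = cbind(sample(102:108, 10, TRUE), sample(102:108, 10, TRUE)))
    g <- make_gt(genos)
    fit <- wc_fst(g$gt, g$popmap, n_perm = 0, pairwise = FALSE)
    oracle <- naive_wc_theta_locus(genos)
    expect_equal(fit$global, oracle, tolerance = 1e-10)
  }
})

test_that("populations fixed for different alleles give theta = 1 and D = 1", {
  g <- make_gt(list(P1 = cbind(rep(100, 10), rep(100, 10)),
                    P2 = cbind(rep(104, 10), rep(104, 10))))
  fit <- wc_fst(g$gt, g$popmap, n_perm = 99, seed = 1, pairwise = FALSE)
  expect_equal(fit$global, 1)
  expect_equal(fit$p_global, 1 / 100)
  jd <- jost_dest(g$gt, g$popmap, pairwise = FALSE)
  expect_equal(jd$global, 1, tolerance = 1e-9)
})

test_that("Jost's D is ~0 for identical allele frequencies and combines by harmonic mean", {
  g <- make_gt(list(P1 = cbind(rep(c(100, 102), 10), rep(c(102, 100), 10)),
                    P2 = cbind(rep(c(100, 102), 10), rep(c(102, 100), 10))))
  jd <- jost_dest(g$gt, g$popmap, pairwise = FALSE)
  # the raw estimator is slightly negative for identical finite samples;
  # the reported (clamped) value is 0
  expect_lte(jd$per_locus$d, 1e-9)
  expect_gt(jd$per_locus$d, -0.05)
  expect_equal(jd$per_locus$d_clamped, 0)
  expect_equal(jd$global, 0)

  # constructed equal-D loci: adding another locus with the same D leaves the
  # multilocus harmonic-mean combination unchanged
  two <- dplyr::bind_rows(
    make_gt(list(P1 = cbind(rep(100, 8), rep(100, 8)),
                 P2 = cbind(rep(104, 8), rep(104, 8))), locus = "l1")$gt,
    make_gt(list(P1 = cbind(rep(100, 8), rep(100, 8)),
                 P2 = cbind(rep(104, 8), rep(104, 8))), locus = "l2")$gt)
  pm <- tiny_popmap(unique(two$id), sub("_.*", "", unique(two$id)))
  three <- dplyr::bind_rows(two,
    make_gt(list(P1 = cbind(rep(100, 8), rep(100, 8)),
                 P2 = cbind(rep(104, 8), rep(104, 8))), locus = "l3")$gt)
  expect_equal(jost_dest(two, pm, pairwise = FALSE)$global,
               jost_dest(three, pm, pairwise = FALSE)$global,
               tolerance = 1e-9)
})

test_that("HWE Monte-Carlo test matches the exhaustive-shuffle distribution", {
  # 3 individuals, alleles A A A B B B: enumerate all pairings of the allele
  # vector into genotypes to get the exact null distribution of homozygotes
  g <- make_gt(list(P1 = cbind(c(1L, 1L, 2L), c(1L, 2L, 2L))))
  # observed genotypes 11, 12, 22 -> 2 homozygotes
  alleles <- c(1, 1, 1, 2, 2, 2)
  # exhaustive: all 6! orderings, pair consecutive entries
  all_ord <- expand.grid(rep(list(1:6), 6))
  all_ord <- all_ord[apply(all_ord, 1, function(r) length(unique(r)) == 6), ]
  homs <- apply(all_ord, 1, function(r) {
    sh <- alleles[unlist(r)]
    sum(sh[c(1, 3, 5)] == sh[c(2, 4, 6)])
  })
  exact_p <- mean(homs >= 2)
  res <- hwe_test(g$gt, g$popmap, "l1", n_reps = 4000, seed = 5)
  expect_lt(abs(res$p - exact_p), 0.03)
})

test_that("HWE test flags degenerate samples and passes HWE-proportioned data", {
  g <- make_gt(list(P1 = cbind(rep(100L, 6), rep(100L, 6))))
  res <- hwe_test(g$gt, g$popmap, "l1", n_reps = 100, seed = 1)
  expect_true(res$flagged)
  expect_equal(res$p, 1)

  set.seed(8)
  p <- c(0.5, 0.3, 0.2)
  a1 <- sample(3, 200, TRUE, p); a2 <- sample(3, 200, TRUE, p)
  g2 <- make_gt(list(P1 = cbind(a1, a2)))
  res2 <- hwe_test(g2$gt, g2$popmap, "l1", n_reps = 500, seed = 2)
  expect_gt(res2$p, 0.05)
})

test_that("linkage test hits the boundary for duplicated loci and not for independent ones", {
  set.seed(12)
  a1 <- sample(4, 40, TRUE); a2 <- sample(4, 40, TRUE)
  dup <- tibble::tibble(
    id = rep(sprintf("i%02d", 1:40), 2),
    locus = rep(c("l1", "l2"), each = 40),
    allele_1 = pmin(c(a1, a1), c(a2, a2)),
    allele_2 = pmax(c(a1, a1), c(a2, a2)))
  pm <- tiny_popmap(sprintf("i%02d", 1:40), rep("P1", 40))
  res <- ld_test(dup, pm, c("l1", "l2"), n_reps = 199, seed = 3)
  expect_equal(res$p, 1 / 200)

  b1 <- sample(4, 40, TRUE); b2 <- sample(4, 40, TRUE)
  ind <- dup
  ind$allele_1[41:80] <- pmin(b1, b2)
  ind$allele_2[41:80] <- pmax(b1, b2)
  res2 <- ld_test(ind, pm, c("l1", "l2"), n_reps = 199, seed = 3)
  expect_gt(res2$p, 0.01)
})

test_that("null-allele EM recovers an injected null frequency", {
  set.seed(42)
  p <- c(0.3, 0.25, 0.2, 0.15, 0.1); r <- 0.10; n <- 500
  pp <- c(p * (1 - r), r)
  a1 <- sample(6, n, TRUE, pp); a2 <- sample(6, n, TRUE, pp)
  vis1 <- ifelse(a1 == 6 & a2 == 6, NA, ifelse(a1 == 6, a2, a1))
  vis2 <- ifelse(a1 == 6 & a2 == 6, NA, ifelse(a2 == 6, vis1, a2))
  em <- null_allele_em(vis1, vis2)
  expect_true(em$converged)
  expect_lt(abs(em$null_freq - 0.10), 0.03)

  # HWE-consistent data: null frequency near zero
  set.seed(43)
  b1 <- sample(5, 400, TRUE, p); b2 <- sample(5, 400, TRUE, p)
  em0 <- null_allele_em(b1, b2)
  expect_lt(em0$null_freq, 0.03)
})

test_that("sequential Bonferroni follows the Holm step-down rule", {
  expect_equal(sequential_bonferroni(c(0.01, 0.02, 0.04), 0.05),
               c(TRUE, TRUE, TRUE))
  expect_equal(sequential_bonferroni(0.04, 0.05), TRUE)
  expect_equal(sequential_bonferroni(c(0.04, 0.04, 0.04), 0.05),
               c(FALSE, FALSE, FALSE))
  # step-down stops at the first failure even if later p would pass alpha/1
  expect_equal(sequential_bonferroni(c(0.001, 0.03, 0.04), 0.05),
               c(TRUE, FALSE, FALSE))
})
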