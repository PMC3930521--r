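test_that("haplotype collapsing counts distinct comparable-site rows", {
  aln <- alignment(c("a", "b", "c"), c("ACG", "ACG", "ACT"))
  ht <- collapse_haplotypes(aln)
  expect_equal(nrow(ht$haplotypes), 2)
  expect_equal(sort(ht$haplotypes$n), c(1L, 2L))

  same <- alignment(paste0("s", 1:5), rep("ACGT", 5))
  expect_equal(collapse_haplotypes(same)$haplotypes$n, 5L)

  # gap/ambiguity columns are excluded before collapsing
  gappy <- alignment(c("a", "b", "c"), c("A-G", "AAG", "AAT"))
  htg <- collapse_haplotypes(gappy)
  expect_equal(htg$comparable, c(1L, 3L))
  expect_equal(nrow(htg$haplotypes), 2)   # rows AG, AG, AT on sites {1,3}
})

test_that("haplotype labels follow frequency and counts sum to sample size", {
  aln <- random_alignment(20, 30, seed = 5, alphabet = c("A", "C"))
  pm <- tiny_popmap(aln$id, rep(c("P1", "P2"), each = 10))
  ht <- collapse_haplotypes(aln, pm)
  expect_equal(sum(ht$haplotypes$n), 20)
  expect_equal(sum(ht$counts$n), 20)
  expect_true(all(diff(ht$haplotypes$n) <= 0))
  # H equals distinct rows restricted to comparable sites
  expect_equal(nrow(ht$haplotypes), length(unique(aln$seq)))
})

test_that("variable and parsimony-informative sites follow their definitions", {
  aln <- alignment(c("a", "b", "c"), c("AAG", "AAT", "CAT"))
  vs <- variable_sites(aln)
  expect_equal(vs$variable, c(1L, 3L))
  expect_equal(vs$informative, integer(0))  # no state carried by >= 2 twice

  mono <- alignment(c("a", "b"), c("AAA", "AAA"))
  expect_equal(variable_sites(mono)$variable, integer(0))

  inf <- alignment(paste0("s", 1:4), c("AAT", "AAT", "AGT", "AGT"))
  expect_equal(variable_sites(inf)$informative, 2L)
})

test_that("fixed differences require disjoint group base sets", {
  aln <- alignment(paste0("s", 1:4), c("ACG", "ACG", "TCG", "TCA"))
  pm <- tiny_popmap(aln$id, c("P1", "P1", "P2", "P2"),
                    c("g1", "g1", "g2", "g2"))
  expect_equal(fixed_differences(aln, pm), 1L)  # site 3 varies within g2

  same <- alignment(paste0("s", 1:4), rep("ACGT", 4))
  expect_equal(fixed_differences(same, pm), 0L)
  pm_bad <- tiny_popmap(aln$id, pm$site, rep("g1", 4))
  expect_error(fixed_differences(aln, pm_bad), "two groups")
})

test_that("haplotype diversity matches the unbiased formula", {
  expect_equal(haplotype_diversity(c(2, 1, 1)), (4 / 3) * (1 - 0.375))
  expect_equal(haplotype_diversity(c(7)), 0)
  expect_warning(h1 <- haplotype_diversity(c(1)), "n < 2")
  expect_true(is.na(h1))
})

test_that("nucleotide diversity is the mean per-site pairwise difference", {
  two <- alignment(c("a", "b"), c("AAAAAAAAAA", "AAAAAAAAAT"))
  expect_equal(nucleotide_diversity(two), 0.1)
  expect_equal(nucleotide_diversity(two, per_site = FALSE), 1)
  same <- alignment(c("a", "b", "c"), rep("ACGT", 3))
  expect_equal(nucleotide_diversity(same), 0)
})

test_that("h and pi are invariant under relabelling and reordering", {
  aln <- random_alignment(12, 40, seed = 9)
  ht <- collapse_haplotypes(aln)
  h0 <- haplotype_diversity(ht$haplotypes$n)
  pi0 <- nucleotide_diversity(aln)
  for (s in 1:3) {
    set.seed(s)
    perm <- sample(nrow(aln))
    shuf <- alignment(paste0("relabel", seq_len(nrow(aln))), aln$seq[perm])
    expect_equal(haplotype_diversity(collapse_haplotypes(shuf)$haplotypes$n), h0)
    expect_equal(nucleotide_diversity(shuf), pi0)
  }
})

test_that("diversity summary reproduces per-site statistics and private counts", {
  aln <- alignment(paste0("s", 1:6),
                   c("AAA", "AAA", "AAT", "GGA", "GGA", "GGC"))
  pm <- tiny_popmap(aln$id, rep(c("P1", "P2"), each = 3),
                    rep(c("north", "south"), each = 3))
  ds <- diversity_summary(aln, pm)
  p1 <- ds[ds$level == "site" & ds$name == "P1", ]
  expect_equal(p1$n, 3)
  expect_equal(p1$H, 2)
  expect_equal(p1$PH, 2)   # both P1 haplotypes occur nowhere else
  north <- ds[ds$level == "group" & ds$name == "north", ]
  expect_equal(north$PH, 2)
  expect_equal(north$h, haplotype_diversity(c(2, 1)))
  expect_equal(ds$n[ds$level == "overall"], 6)
})
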