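test_that("two haplotypes give a single edge carrying their distance", {
  aln <- alignment(c("a", "b", "c"), c("AAAA", "AAAA", "ATTA"))
  net <- mj_network(collapse_haplotypes(aln))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$steps, 2L)
  expect_equal(sum(net$nodes$freq), 3)
})

test_that("the AAT/ATA/TAA triplet gains exactly one median and length 3", {
  aln <- alignment(c("a", "b", "c"), c("AAT", "ATA", "TAA"))
  net <- mj_network(collapse_haplotypes(aln))
  expect_equal(sum(net$nodes$type == "median"), 1)
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$steps == 1))
  expect_equal(sum(net$edges$steps), 3)
  # the median is the majority consensus AAA, linked to all three
  mv <- net$nodes$name[net$nodes$type == "median"]
  expect_true(all(c(net$edges$from, net$edges$to) %in%
                    c(mv, c("H1", "H2", "H3"))))
})

test_that("tree-like haplotypes give the MST with no medians (epsilon 0)", {
  # a sampled chain: each neighbour one further mutation
  aln <- alignment(paste0("s", 1:4),
                   c("AAAAA", "TAAAA", "TTAAA", "TTTAA"))
  net <- mj_network(collapse_haplotypes(aln))
  expect_equal(sum(net$nodes$type == "median"), 0)
  expect_equal(nrow(net$edges), 3)
  expect_equal(sum(net$edges$steps), 3)
})

test_that("median vectors kept in the network have degree >= 3", {
  sim <- simulate_two_pop_sequences(seed = 7)
  net <- mj_network(collapse_haplotypes(sim$aln))
  deg <- table(factor(c(net$edges$from, net$edges$to),
                      levels = net$nodes$name))
  mv <- net$nodes$name[net$nodes$type == "median"]
  if (length(mv)) expect_true(all(deg[mv] >= 3))
  expect_true(igraph::is_connected(net$graph))
  expect_true(all(net$edges$steps >= 1))
  expect_equal(sum(net$nodes$freq), nrow(sim$aln))
})

test_that("haplogroup partition cuts long bridges by path length", {
  # chain A -1- B -5- C
  aln <- alignment(c(paste0("a", 1:3), "b1", "c1"),
                   c(rep("AAAAAA", 3), "AAAAAT", "TTTTTT"))
  net <- mj_network(collapse_haplotypes(aln))
  hg <- haplogroups(net, min_steps = 3)
  expect_equal(length(unique(hg$membership$haplogroup)), 2)
  ab <- hg$membership$haplogroup[hg$membership$haplotype %in% c("H1", "H2")]
  expect_equal(length(unique(ab)), 1)
  expect_equal(hg$max_bridge, 5)

  star <- alignment(paste0("s", 1:4), c("AAA", "AAT", "ATA", "TAA"))
  hg1 <- haplogroups(mj_network(collapse_haplotypes(star)), min_steps = 3)
  expect_equal(length(unique(hg1$membership$haplogroup)), 1)
  expect_true(is.na(hg1$max_bridge))
})

test_that("minimum inter-group Hamming distance complements the bridge length", {
  aln <- alignment(paste0("s", 1:4), c("AAAA", "AATA", "TTAT", "TTTT"))
  pm <- tiny_popmap(aln$id, c("P1", "P1", "P2", "P2"),
                    c("g1", "g1", "g2", "g2"))
  expect_equal(min_intergroup_distance(aln, pm), 3)
})

test_that("network exports round-trip through the edge list", {
  aln <- alignment(c("a", "b", "c"), c("AAT", "ATA", "TAA"))
  net <- mj_network(collapse_haplotypes(aln))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f, format = "edgelist")
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(net$edges))
  g <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, g)
  expect_true(file.size(g) > 0)
})
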