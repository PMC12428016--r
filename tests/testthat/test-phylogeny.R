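test_that("p and K2P distances match closed forms and the ape cross-check", {
  expect_equal(pairwise_distances(c(a = "ACGT", b = "ACGT"), "p")[1, 2], 0)
  expect_equal(pairwise_distances(c(a = "ACGT", b = "ACGA"), "p")[1, 2], 0.25)
  # constructed pair with P = 0.1 transitions, Q = 0.05 transversions
  n <- 200L
  a <- rep("A", n)
  b <- a
  b[1:20] <- "G"        # transitions
  b[21:30] <- "C"       # transversions
  aln <- c(x = paste(a, collapse = ""), y = paste(b, collapse = ""))
  got <- pairwise_distances(aln, "K2P")[1, 2]
  expect_equal(got, k2p_closed_form(0.1, 0.05))
  # independent route: ape::dist.dna on the same pair
  bin <- ape::as.DNAbin(list(x = tolower(a), y = tolower(b)))
  expect_equal(got, as.numeric(ape::dist.dna(bin, model = "K80")),
               tolerance = 1e-12)
  # gap/N columns are pairwise-deleted
  aln2 <- c(x = "ACGTA-", y = "ACGAAN")
  expect_equal(pairwise_distances(aln2, "p")[1, 2], 1 / 5)
  expect_error(pairwise_distances(c(x = "----", y = "AAAA"), "p"),
               "no comparable")
})

test_that("neighbor joining is exact on additive matrices", {
  for (seed in 1:12) {
    ntaxa <- sample(4:8, 1)
    case <- random_additive_case(ntaxa, seed)
    tr <- neighbor_joining(case$dm)
    # identical unrooted topology
    expect_equal(ape::dist.topo(ape::unroot(case$tree), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
    # and identical path lengths (branch lengths recovered)
    got <- ape::cophenetic.phylo(tr)
    got <- got[rownames(case$dm), colnames(case$dm)]
    expect_equal(got, case$dm, tolerance = 1e-8)
  }
  expect_error(neighbor_joining(matrix(0, 2, 2)), ">= 3 taxa")
  dmna <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3,
                 dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(dmna), "incomplete")
})

test_that("three taxa resolve with closed-form branch lengths", {
  dm <- matrix(c(0, 0.3, 0.5,
                 0.3, 0, 0.6,
                 0.5, 0.6, 0), 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(dm)
  x <- (0.3 + 0.5 - 0.6) / 2   # a
  y <- (0.3 + 0.6 - 0.5) / 2   # b
  z <- (0.5 + 0.6 - 0.3) / 2   # c
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(lens[c("a", "b", "c")]), c(x, y, z))
})

test_that("bootstrap supports are reproducible, bounded and column-exchangeable", {
  rec <- generate_genome(synthetic_genome_spec(seed = 91, template = "plain",
                                               genome_length = 2000L))
  fam <- evolve_family(rec, evolver_spec(
    "(((A:0.02,B:0.02):0.04,C:0.06):0.04,D:0.1,E:0.12);", seed = 7))
  aln <- fam$sequences
  t1 <- bootstrap_support(aln, "p", replicates = 30, seed = 4)
  t2 <- bootstrap_support(aln, "p", replicates = 30, seed = 4)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$node.label >= 0 & t1$node.label <= 1))
  # a single replicate can only give 0/1 supports
  t3 <- bootstrap_support(aln, "p", replicates = 1, seed = 9)
  expect_true(all(t3$node.label %in% c(0, 1)))
  # permuting alignment columns leaves supports unchanged
  m <- matrix(unlist(strsplit(aln, "")), nrow = length(aln), byrow = TRUE,
              dimnames = list(names(aln), NULL))
  set.seed(12)
  mp <- m[, sample(ncol(m))]
  t4 <- bootstrap_support(mp, "p", replicates = 30, seed = 4)
  expect_equal(sort(t1$node.label), sort(t4$node.label))
})

test_that("monophyly verdicts follow the rooted topology", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,OUT:3);")
  expect_true(is_monophyletic(tr, c("A", "B"), "OUT")$monophyletic)
  expect_true(is_monophyletic(tr, c("C", "D"), "OUT")$monophyletic)
  mixed <- is_monophyletic(tr, c("A", "C"), "OUT")
  expect_false(mixed$monophyletic)
  expect_setequal(mixed$clade_taxa, c("A", "B", "C", "D"))
  # trivial cases
  expect_true(is_monophyletic(tr, "A", "OUT")$monophyletic)
  expect_true(is_monophyletic(tr, c("A", "B", "C", "D"), "OUT")$monophyletic)
  expect_error(is_monophyletic(tr, c("A", "Z"), "OUT"), "unknown label")
  expect_error(is_monophyletic(tr, c("A", "OUT"), "OUT"), "outgroup")
})

test_that("separated clades earn high bootstrap support in simulation", {
  rec <- generate_genome(synthetic_genome_spec(seed = 95, template = "plain",
                                               genome_length = 5000L))
  fam <- evolve_family(rec, evolver_spec(
    "(((A:0.01,B:0.01):0.08,(C:0.01,D:0.01):0.08):0.05,OUT:0.2);",
    seed = 21))
  tr <- bootstrap_support(fam$sequences, "K2P", replicates = 100, seed = 3)
  rooted <- ape::root(tr, outgroup = "OUT", resolve.root = TRUE)
  ab <- ape::getMRCA(tr, c("A", "B"))
  # support slot for the A+B bipartition
  sup <- tr$node.label[ab - length(tr$tip.label)]
  expect_gte(sup, 0.95)
  expect_true(is_monophyletic(tr, c("A", "B"), "OUT")$monophyletic)
})
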