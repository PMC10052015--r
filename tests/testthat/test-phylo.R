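test_that("sequence distances match the closed forms", {
  a <- strrep("ACGT", 25)  # 100 sites
  bc <- strsplit(a, "")[[1]]
  bc[1:10] <- ifelse(bc[1:10] == "A", "C", "A")  # exactly 10 mismatches
  b <- paste(bc, collapse = "")
  expect_equal(seqDistance(a, a, "p"), 0)
  expect_equal(seqDistance(a, a, "JC"), 0)
  nMis <- sum(strsplit(a, "")[[1]] != bc)
  expect_equal(nMis, 10L)
  expect_equal(seqDistance(a, b, "p"), 0.10)
  expect_equal(seqDistance(a, b, "JC"), -0.75 * log(1 - 0.4 / 3))
  expect_equal(signif(seqDistance(a, b, "JC"), 5), 0.10733)
})

test_that("gap columns are excluded pairwise; all-gap overlap errors", {
  expect_equal(seqDistance("AC-T", "ACG-", "p"), 0)  # only 2 compared
  expect_error(seqDistance("--", "AA", "p"), "no comparable sites")
  expect_error(seqDistance("AC", "ACG", "p"), "differ in aligned length")
})

test_that("JC saturation raises an error instead of infinity", {
  a <- strrep("A", 100); b <- strrep("C", 100)
  expect_error(seqDistance(a, b, "JC"), "saturation")
})

test_that("JC is always at least the p-distance; distances symmetric", {
  set.seed(3)
  for (i in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    p <- seqDistance(a, b, "p")
    if (p < 0.75) expect_gte(seqDistance(a, b, "JC"), p)
    expect_equal(seqDistance(a, b, "p"), seqDistance(b, a, "p"))
  }
})

test_that("NJ recovers additive trees exactly (4 to 8 taxa)", {
  set.seed(17)
  for (n in 4:8) {
    tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 0.5))
    tr <- ape::unroot(tr)
    dm <- ape::cophenetic.phylo(tr)
    nj <- neighborJoining(dm)
    expect_equal(ape::dist.topo(ape::unroot(nj), tr), 0,
                 ignore_attr = TRUE)
    # branch lengths via path-length matrix
    dnj <- ape::cophenetic.phylo(nj)[rownames(dm), colnames(dm)]
    expect_equal(dnj, dm, tolerance = 1e-9)
  }
})

test_that("NJ agrees with an independent implementation", {
  set.seed(23)
  sim <- simTreeSequences(preset = "clades3", seed = 23, length = 800)
  dm <- distanceMatrix(sim$seqs, "JC")
  ours <- neighborJoining(dm)
  theirs <- ape::nj(as.dist(dm))
  expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(theirs)), 0,
               ignore_attr = TRUE)
})

test_that("three taxa give the closed-form star lengths", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighborJoining(dm)
  la <- (3 + 4 - 5) / 2; lb <- (3 + 5 - 4) / 2; lc <- (4 + 5 - 3) / 2
  got <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                  tr$tip.label)
  expect_equal(got[c("a", "b", "c")], c(a = la, b = lb, c = lc))
})

test_that("NJ output is independent of taxon input order", {
  set.seed(31)
  tr <- ape::unroot(ape::rtree(6, br = function(k)
    stats::runif(k, 0.05, 0.5)))
  dm <- ape::cophenetic.phylo(tr)
  perm <- sample(6)
  t1 <- neighborJoining(dm)
  t2 <- neighborJoining(dm[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(t2)[rownames(dm), colnames(dm)],
               ape::cophenetic.phylo(t1)[rownames(dm), colnames(dm)],
               tolerance = 1e-9)
})

test_that("an all-equal distance matrix resolves deterministically", {
  dm <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dm) <- 0
  t1 <- neighborJoining(dm)
  t2 <- neighborJoining(dm)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))
})

test_that("fewer than three taxa is an error", {
  dm <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  expect_error(neighborJoining(dm), "at least 3")
})

test_that("Newick round-trips preserve topology and lengths", {
  set.seed(5)
  tr <- neighborJoining(ape::cophenetic.phylo(ape::unroot(ape::rtree(6))))
  f <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tr, f)
  back <- readNewick(f)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)
})

test_that("monophyly reporting detects clades and planted paraphyly", {
  tr <- ape::read.tree(text = "((A1:1,A2:1):1,(B1:1,B2:1):1,O:3);")
  rep1 <- clusterCheck(tr, c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"), "O")
  expect_true(all(rep1$monophyletic))
  tr2 <- ape::read.tree(text = "((A1:1,B1:1):1,(A2:1,B2:1):1,O:3);")
  rep2 <- clusterCheck(tr2, c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"), "O")
  expect_false(any(rep2$monophyletic))
  expect_error(clusterCheck(tr, c(A1 = "A", A2 = "A", B1 = "B",
                                  B2 = "B"), "ZZZ"), "not in tree")
})

test_that("sequences evolved on a clade tree recover the clades", {
  sim <- simTreeSequences(preset = "clades3", seed = 11, length = 1200)
  tree <- njTree(sim$seqs, model = "JC")
  rep <- clusterCheck(tree, sim$groups, sim$outgroup)
  expect_true(all(rep$monophyletic))
  expect_equal(ape::dist.topo(ape::unroot(tree),
                              ape::unroot(sim$tree)), 0,
               ignore_attr = TRUE)
})
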