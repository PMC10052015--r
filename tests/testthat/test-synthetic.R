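test_that("generators are seed-deterministic, files byte-identical", {
  t1 <- withr::local_tempdir(); t2 <- withr::local_tempdir()
  for (gen in list(
    function(out) simStructure(nRes = 5, contacts = data.frame(
      resno = 2, ligand = "FAD", distance = 2.5), out = out)$files,
    function(out) simSequences(preset = "table2", seed = 8,
                               out = out)$files,
    function(out) simSurvival(preset = "paper", seed = 8,
                              out = out)$files,
    function(out) simTreeSequences(preset = "clades3", seed = 8,
                                   out = out)$files)) {
    f1 <- gen(t1); f2 <- gen(t2)
    for (i in seq_along(f1)) {
      expect_identical(readLines(f1[i]), readLines(f2[i]),
                       info = basename(f1[i]))
    }
  }
})

test_that("planted contact distances are exact in the written structure", {
  tmp <- withr::local_tempdir()
  sim <- simStructure(nRes = 6, contacts = data.frame(
    resno = c(2, 5), ligand = c("HDF", "DNA"), distance = c(2.5, 3.0)),
    out = tmp)
  s <- readStructure(file.path(tmp, "structure.pdb"))
  g <- classifyLigands(s, cofactors = c(HDF = "HDF"))
  # independent distance computation from the re-read file
  bf <- bruteForceShell(s, g, threshold = 10)
  expect_equal(bf$min_distance_A[bf$pos == 2 & bf$ligand == "HDF"], 2.5,
               tolerance = 1e-3)  # PDB coordinate precision
  # in-memory model is exact
  bf2 <- bruteForceShell(sim$model,
                         classifyLigands(sim$model,
                                         cofactors = c(HDF = "HDF")),
                         threshold = 10)
  expect_equal(bf2$min_distance_A[bf2$pos == 2 & bf2$ligand == "HDF"],
               2.5, tolerance = 1e-9)
})

test_that("requesting nothing within threshold yields an empty shell", {
  sim <- simStructure(nRes = 5, contacts = data.frame(
    resno = 2, ligand = "FAD", distance = 4.5))
  g <- classifyLigands(sim$model, cofactors = c(FAD = "FAD"))
  expect_equal(nrow(shellEntries(contactShell(sim$model, g, 2.8))), 0L)
})

test_that("table2 preset reproduces the packaged table cell for cell", {
  sim <- simSequences(preset = "table2", seed = 2)
  vt <- table2Fixture()
  maps <- familyMaps(sim$seqs, "SEL", offsets = sim$offsets)
  m <- variantResidues(vt)
  for (st in setdiff(colnames(m), "SEL")) {
    got <- mapPosition(maps[[st]], vt@positions)$query_aa
    expect_equal(got, unname(m[, st]), info = st)
  }
  expect_false(sim$genePresent[["BOL5-4"]])
  expect_false("BOL5-4" %in% names(sim$seqs))
})

test_that("custom planted substitutions come back from diff counting", {
  subs <- list(S1 = data.frame(pos = c(50L, 413L), aa = c("V", "T")))
  sim <- simSequences(preset = "custom", substitutions = subs, seed = 6)
  maps <- familyMaps(sim$seqs, "SEL", offsets = sim$offsets)
  hit <- mapPosition(maps[["S1"]], c(50, 413))
  expect_equal(hit$query_aa, c("V", "T"))
  # zero planted substitutions = 100 percent identity
  sim0 <- simSequences(preset = "custom",
                       substitutions = list(Z = data.frame(
                         pos = integer(), aa = character())), seed = 6)
  m <- identityMatrix(sim0$seqs)
  expect_equal(m["SEL", "Z"], 100)
  expect_error(simSequences(preset = "custom", substitutions = list(
    B = data.frame(pos = 9999L, aa = "A")), seed = 1),
    "out of range")
})

test_that("zero kill rates give flat survival within noise", {
  sim <- simSurvival(preset = "custom",
                     rates = data.frame(strain = "S", k_light = 0,
                                        k_dark = 0), cv = 0.1, seed = 3)
  s <- survivalCurves(percentSurvival(sim$records))
  expect_true(all(s$percent > 60 & s$percent < 160))
})

test_that("paper-shaped survival places subsurface analogs last", {
  sim <- simSurvival(preset = "paper", seed = 10)
  rk <- rankStrains(percentSurvival(sim$records))
  subsurface <- sim$truth$rates$strain[sim$truth$rates$habitat ==
                                         "subsurface"]
  expect_setequal(utils::tail(rk$strain, 3), subsurface)
})

test_that("lognormal count noise matches its stated distribution", {
  # smoke check: CV of large-count draws close to the requested CV
  set.seed(99)
  cv <- 0.2
  sigma <- sqrt(log(1 + cv^2))
  draws <- stats::rlnorm(1e4, meanlog = log(1000) - sigma^2 / 2,
                         sdlog = sigma)
  expect_equal(stats::sd(draws) / mean(draws), cv, tolerance = 0.02)
  ks <- stats::ks.test((log(draws) - (log(1000) - sigma^2 / 2)) / sigma,
                       "pnorm")
  expect_gt(ks$p.value, 0.01)
})

test_that("zero-length branches give identical sequences", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  sim <- simTreeSequences(preset = "custom", tree = tr, length = 100,
                          seed = 4)
  expect_equal(length(unique(sim$seqs)), 1L)
  expect_error(simTreeSequences(preset = "custom",
                                tree = "((a:-1,b:1):1,c:1);",
                                seed = 1), "negative branch length")
})

test_that("gene-neighborhood truth sidecar matches the objects", {
  tmp <- withr::local_tempdir()
  sim <- simNeighborhoods(preset = "paper", out = tmp)
  truth <- jsonlite::read_json(file.path(tmp, "neighborhoods.truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$anchorAbsent, "BOL5-4")
  expect_equal(truth$indels$length_bp, c(1727L, 237L))
  nb <- sim$neighborhoods[[truth$anchorAbsent]]
  expect_false(nb@anchor %in% neighborhoodGenes(nb)$label)
})
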