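test_that("the packaged key-residue table matches its printed counts", {
  vt <- table2Fixture()
  expect_equal(length(vt@positions), 15L)
  expect_equal(length(variantPositions(vt)), 15L)
  totals <- vapply(c("BOL5-1" = "BOL5-1", "BOL6-1" = "BOL6-1",
                     Hla = "Hla", "JOR-1" = "JOR-1", "BOL3-1" = "BOL3-1",
                     "BOL4-2" = "BOL4-2", "GSL-19" = "GSL-19"),
                   function(s) diffCounts(vt, s, "NRC-1")$total,
                   numeric(1))
  expect_equal(totals,
               c("BOL5-1" = 12, "BOL6-1" = 5, Hla = 3, "JOR-1" = 2,
                 "BOL3-1" = 1, "BOL4-2" = 0, "GSL-19" = 0))
  d <- diffCounts(vt, "BOL5-1", "NRC-1")
  expect_equal(d$byInteraction, c(DNA = 9L, FAD = 2L, HDF = 1L))
  d6 <- diffCounts(vt, "BOL6-1", "NRC-1")
  expect_setequal(d6$calls$notation,
                  c("T139P", "P144H", "Y148F", "T149S", "R413E"))
})

test_that("difference counts are symmetric and additive by interaction", {
  vt <- table2Fixture()
  for (pair in list(c("BOL5-1", "NRC-1"), c("Hla", "JOR-1"),
                    c("BOL6-1", "BOL5-1"))) {
    a <- diffCounts(vt, pair[1], pair[2])
    b <- diffCounts(vt, pair[2], pair[1])
    expect_equal(a$total, b$total)
    expect_equal(sum(a$byInteraction), a$total)
  }
  expect_equal(diffCounts(vt, "Hla", "Hla")$total, 0)
  expect_error(diffCounts(vt, "NOPE", "NRC-1"), "unknown strain")
})

test_that("variant tables built from synthetic homologs flag exactly the
           planted positions", {
  set.seed(5)
  refChars <- sample(names(phrscan:::AA1TO3), 12, TRUE)
  refSeq <- paste(refChars, collapse = "")
  sim <- simStructure(nRes = 12, sequence = setNames(refChars, 1:12),
                      contacts = data.frame(
    resno = 1:10, ligand = rep(c("DNA", "FAD"), 5),
    distance = seq(2.4, 2.7, length.out = 10)))
  g <- classifyLigands(sim$model, cofactors = c(FAD = "FAD"))
  shell <- contactShell(sim$model, g, threshold = 2.8)
  expect_equal(shell@unionCount, 10L)

  planted <- data.frame(pos = c(2L, 5L, 7L, 9L), aa = c("W", "W", "W", "W"))
  mut <- strsplit(refSeq, "")[[1]]
  mut[planted$pos] <- ifelse(mut[planted$pos] == "W", "Y", "W")
  seqs <- c(SEL = refSeq, Q1 = paste(mut, collapse = ""), Q2 = refSeq)
  maps <- familyMaps(seqs, "SEL")
  vt <- buildVariantTable(shell, maps, functionalRef = "Q2")
  expect_equal(variantPositions(vt), planted$pos)
  expect_equal(diffCounts(vt, "Q1", "SEL")$total, 4)
  expect_equal(diffCounts(vt, "Q2", "SEL")$total, 0)
})

test_that("substitution conservativeness reproduces the published calls", {
  expect_equal(as.character(classifySubstitution("T", "S")), "conservative")
  expect_equal(as.character(classifySubstitution("A", "A")), "identical")
  ke <- classifySubstitution("K", "E")
  expect_equal(as.character(ke), "non-conservative")
  expect_true(attr(ke, "chargeChange"))
  expect_equal(as.character(classifySubstitution("R", "V")),
               "non-conservative")
  expect_equal(as.character(classifySubstitution("D", "N")),
               "non-conservative")
  expect_equal(as.character(classifySubstitution("L", "M")), "conservative")
  expect_false(attr(classifySubstitution("S", "T"), "chargeChange"))
  expect_error(classifySubstitution("Z", "A"), "invalid amino acid")
})

test_that("integrity scores rank reference best, gene-absent worst", {
  vt <- table2Fixture()
  scores <- integrityScore(vt, genePresent = c("BOL5-4" = FALSE))
  expect_equal(unname(scores["NRC-1"]), 0)
  expect_true(all(scores <= 0))
  expect_equal(unname(which.min(scores)), unname(which(names(scores) ==
                                                         "BOL5-4")))
  # qualitative rank consistency: surface >= sediment (Hla) >= subsurface
  surface <- c("NRC-1", "BOL4-2", "GSL-19", "JOR-1", "BOL3-1")
  subsurface <- c("BOL5-1", "BOL6-1", "BOL5-4")
  expect_true(min(scores[surface]) >= scores[["Hla"]])
  expect_true(scores[["Hla"]] >= max(scores[subsurface]))
})

test_that("integrity score is linear in the weights", {
  vt <- table2Fixture()
  w <- integrityWeights()
  s1 <- integrityScore(vt, genePresent = c("BOL5-4" = FALSE), weights = w)
  s2 <- integrityScore(vt, genePresent = c("BOL5-4" = FALSE),
                       weights = 2 * w)
  expect_equal(s2, 2 * s1)
})

test_that("hydrogen-bond impacts feed the integrity score when supplied", {
  vt <- table2Fixture()
  mkImpact <- function(call, verdict)
    new("SubstitutionImpact", call = call, strain = NA_character_,
        before = phrscan:::emptyHbonds(), after = phrscan:::emptyHbonds(),
        verdict = verdict, partners = character(0))
  # cover every non-identical call with a no-change impact, then make the
  # BOL3-1 call a hydrogen-bond loss
  calls <- unique(unlist(lapply(strainIds(vt), function(st)
    diffCounts(vt, st, "NRC-1")$calls$notation)))
  impacts <- setNames(lapply(calls, mkImpact, verdict = "unchanged"),
                      calls)
  d <- diffCounts(vt, "BOL3-1", "NRC-1")
  expect_equal(d$calls$notation, "D385N")
  impacts[["D385N"]] <- mkImpact("D385N", "loss")
  sc <- integrityScore(vt, impacts = impacts)
  scNo <- integrityScore(vt)
  expect_equal(sc[["BOL3-1"]],
               scNo[["BOL3-1"]] - integrityWeights()[["hbondLost"]])
  expect_equal(sc[["JOR-1"]], scNo[["JOR-1"]])  # unchanged verdicts add 0
  expect_error(integrityScore(vt, impacts = list()),
               "missing substitution impact")
})
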