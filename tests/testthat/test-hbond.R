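test_that("planted donor-acceptor geometries are detected exactly", {
  sim <- simStructure(nRes = 6, sequence = c("2" = "S", "4" = "R"),
    hbondPartners = data.frame(
      resno = c(2, 4, 4), res_atom = c("OG", "NH1", "NH2"),
      ligand = c("DNA", "HDF", "HDF"), partner_element = c("N", "O", "O"),
      distance = c(2.9, 3.0, 3.5)))
  g <- classifyLigands(sim$model)
  hb2 <- detectHbonds(sim$model, 2, g["DNA"])
  expect_equal(nrow(hb2), 1L)
  expect_equal(hb2$distance, 2.9, tolerance = 1e-9)
  expect_equal(hb2$strength, "strong")
  hb4 <- detectHbonds(sim$model, 4, g["HDF"])
  expect_equal(nrow(hb4), 2L)
  expect_setequal(hb4$strength, c("strong", "weak"))
})

test_that("distant partners and apolar residues yield no bonds", {
  sim <- simStructure(nRes = 4, sequence = c("2" = "S"),
    contacts = data.frame(resno = 3, ligand = "DNA", distance = 8))
  g <- classifyLigands(sim$model)
  expect_equal(nrow(detectHbonds(sim$model, 2, g["DNA"])), 0L)
  expect_warning(hb <- detectHbonds(sim$model, 3, g["DNA"]),
                 "no polar side-chain atoms")
  expect_equal(nrow(hb), 0L)
})

test_that("acceptor-acceptor pairs are not bonds (capability chemistry)", {
  # ASP side-chain oxygens only accept; a ligand O (acceptor) cannot pair
  sim <- simStructure(nRes = 4, sequence = c("2" = "D"),
    hbondPartners = data.frame(resno = 2, res_atom = "OD2",
                               ligand = "DNA", partner_element = "O",
                               distance = 3.0))
  g <- classifyLigands(sim$model)
  expect_equal(nrow(detectHbonds(sim$model, 2, g["DNA"])), 0L)
  # but a ligand N (donor-capable) can donate to it
  sim2 <- simStructure(nRes = 4, sequence = c("2" = "D"),
    hbondPartners = data.frame(resno = 2, res_atom = "OD2",
                               ligand = "DNA", partner_element = "N",
                               distance = 3.0))
  g2 <- classifyLigands(sim2$model)
  hb <- detectHbonds(sim2$model, 2, g2["DNA"])
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$donor, "ligand")
})

test_that("detection is rigid-motion invariant and monotone in d_weak", {
  sim <- simStructure(nRes = 5, sequence = c("2" = "K"),
    hbondPartners = data.frame(resno = 2, res_atom = "NZ", ligand = "DNA",
                               partner_element = "O", distance = 3.45))
  g <- classifyLigands(sim$model)
  base <- detectHbonds(sim$model, 2, g["DNA"])
  s2 <- rigidTransform(sim$model)
  g2 <- classifyLigands(s2)
  moved <- detectHbonds(s2, 2, g2["DNA"])
  expect_equal(moved$distance, base$distance, tolerance = 1e-6)
  expect_equal(moved$strength, base$strength)
  # shrinking the weak window below the planted distance removes the bond;
  # enlarging it never does
  narrow <- detectHbonds(sim$model, 2, g["DNA"],
                         criteria = hbondCriteria(dWeak = 3.4))
  wide <- detectHbonds(sim$model, 2, g["DNA"],
                       criteria = hbondCriteria(dWeak = 4.0))
  expect_equal(nrow(narrow), 0L)
  expect_equal(nrow(wide), 1L)
})

test_that("verdict classification is a pure function of bond sets", {
  mk <- function(...) {
    rows <- list(...)
    if (!length(rows)) return(phrscan:::emptyHbonds())
    do.call(rbind, lapply(rows, function(r) data.frame(
      res_atom = "X", partner = r[[1]], partner_resid = r[[1]],
      partner_resno = 1L, partner_atom = "O1", distance = 3.0,
      strength = r[[2]], donor = "residue", stringsAsFactors = FALSE)))
  }
  cases <- list(
    list(mk(), mk(), "unchanged"),
    list(mk(list("DNA", "strong")), mk(list("DNA", "strong")), "unchanged"),
    list(mk(list("DNA", "strong")), mk(), "loss"),
    list(mk(), mk(list("DNA", "weak")), "gain"),
    list(mk(list("DNA", "strong")), mk(list("DNA", "weak")), "weakened"),
    list(mk(list("DNA", "weak")), mk(list("DNA", "strong")),
         "strengthened"),
    list(mk(list("DNA", "strong"), list("FAD", "weak")),
         mk(list("FAD", "weak")), "loss"),
    list(mk(list("DNA", "strong")),
         mk(list("DNA", "weak"), list("FAD", "strong")), "mixed"),
    list(mk(list("DNA", "strong"), list("FAD", "strong")), mk(), "loss"),
    list(mk(list("DNA", "weak")),
         mk(list("DNA", "weak"), list("FAD", "weak")), "gain"),
    # multiple bonds to one partner: best strength wins
    list(mk(list("DNA", "strong"), list("DNA", "weak")),
         mk(list("DNA", "strong")), "unchanged"))
  for (cs in cases) {
    v <- hbondVerdict(cs[[1]], cs[[2]])
    expect_equal(as.character(v), cs[[3]])
  }
})

test_that("identity substitution changes nothing", {
  sim <- simStructure(nRes = 5, sequence = c("2" = "R"),
    hbondPartners = data.frame(resno = 2, res_atom = "NH1",
                               ligand = "HDF", partner_element = "O",
                               distance = 2.9))
  g <- classifyLigands(sim$model, cofactors = c(HDF = "HDF"))
  s2 <- substituteResidue(sim$model, 2, "R")
  expect_equal(atoms(s2), atoms(sim$model))
  im <- assessSubstitution(sim$model, "R2R", g)
  expect_equal(im@verdict, "unchanged")
})

test_that("substitution to Gly removes the side chain, backbone intact", {
  sim <- simStructure(nRes = 5, sequence = c("3" = "K"))
  s2 <- substituteResidue(sim$model, 3, "G")
  a0 <- atoms(sim$model); a2 <- atoms(s2)
  r2 <- a2[a2$resno == 3, ]
  expect_setequal(r2$elety, c("N", "CA", "C", "O"))
  for (nm in c("N", "CA", "C", "O")) {
    expect_equal(as.numeric(r2[r2$elety == nm, c("x", "y", "z")]),
                 as.numeric(a0[a0$resno == 3 & a0$elety == nm,
                               c("x", "y", "z")]), tolerance = 1e-9)
  }
})

test_that("substitution to Ala places CB at the idealized bond length", {
  sim <- simStructure(nRes = 5, sequence = c("3" = "W"))
  s2 <- substituteResidue(sim$model, 3, "A")
  a <- atoms(s2)
  r <- a[a$resno == 3, ]
  ca <- as.numeric(r[r$elety == "CA", c("x", "y", "z")])
  cb <- as.numeric(r[r$elety == "CB", c("x", "y", "z")])
  expect_equal(sqrt(sum((ca - cb)^2)), 1.52, tolerance = 0.05)
})

test_that("chi angles are copied from the wild type where the tree allows", {
  sim <- simStructure(nRes = 5, sequence = c("3" = "K"))
  a <- atoms(sim$model)
  wt <- a[a$resno == 3, ]
  chiWt <- phrscan:::measureChis(wt)
  s2 <- substituteResidue(sim$model, 3, "R")
  mut <- atoms(s2)[atoms(s2)$resno == 3, ]
  chiMut <- phrscan:::measureChis(mut)
  expect_equal(chiMut[1:3], chiWt[1:3], tolerance = 1e-6)
})

test_that("substitution verdicts reproduce planted gain and loss", {
  sim <- simStructure(nRes = 6, sequence = c("3" = "D", "5" = "K"),
    hbondPartners = data.frame(resno = c(3, 5), res_atom = c("OD2", "NZ"),
                               ligand = "DNA", partner_element = "O",
                               distance = c(3.0, 2.9)))
  g <- classifyLigands(sim$model)
  expect_equal(assessSubstitution(sim$model, "D3N", g)@verdict, "gain")
  expect_equal(assessSubstitution(sim$model, "K5T", g)@verdict, "loss")
  expect_error(assessSubstitution(sim$model, "W3N", g),
               "the call states")
})

test_that("impact reports tabulate and round-trip through CSV", {
  sim <- simStructure(nRes = 6, sequence = c("3" = "D", "5" = "K"),
    hbondPartners = data.frame(resno = c(3, 5), res_atom = c("OD2", "NZ"),
                               ligand = "DNA", partner_element = "O",
                               distance = c(3.0, 2.9)))
  g <- classifyLigands(sim$model)
  impacts <- list(assessSubstitution(sim$model, "D3N", g),
                  assessSubstitution(sim$model, "K5T", g))
  rep <- impactReport(impacts)
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$call, sort(rep$call))
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rep, csv, row.names = FALSE, na = "")
  back <- utils::read.csv(csv, stringsAsFactors = FALSE, na.strings = "")
  expect_equal(back$call, rep$call)
  expect_equal(back$verdict, rep$verdict)
  expect_equal(impactReport(list()),
               impactReport(list())) # header-only, stable
  expect_equal(nrow(impactReport(list())), 0L)
})
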