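flatRecords <- function(strain = "S", conds = c("light", "dark"),
                        doses = c(0, 24, 48), cfu = 100, dilution = 100) {
  expand.grid(strain = strain, condition = conds, dose = doses,
              replicate = 1:2, stringsAsFactors = FALSE) |>
    transform(dilution = dilution, cfu = cfu)
}

test_that("equal counts at all doses give a flat 100 percent curve", {
  sd <- percentSurvival(flatRecords())
  expect_true(all(abs(survivalCurves(sd)$percent - 100) < 1e-9))
})

test_that("survival is invariant to uniform rescaling of counts", {
  rec <- flatRecords(cfu = 100)
  rec$cfu <- rec$cfu * ifelse(rec$dose > 0, 0.5, 1)  # 50 percent kill
  s1 <- survivalCurves(percentSurvival(rec))
  rec2 <- rec; rec2$cfu <- rec2$cfu * 7
  s2 <- survivalCurves(percentSurvival(rec2))
  expect_equal(s1$percent, s2$percent)
})

test_that("dose-0-only data yields the single 100 percent point", {
  rec <- data.frame(strain = "S", condition = "light", dose = 0,
                    replicate = 1, dilution = 10, cfu = 50)
  s <- survivalCurves(percentSurvival(rec))
  expect_equal(nrow(s), 1L)
  expect_equal(s$percent, 100)
})

test_that("missing dose 0 and negative counts are rejected", {
  rec <- data.frame(strain = "S", condition = "light", dose = 24,
                    replicate = 1, dilution = 10, cfu = 50)
  expect_error(percentSurvival(rec), "missing dose 0")
  rec2 <- flatRecords(); rec2$cfu[3] <- -1
  expect_error(percentSurvival(rec2), "negative CFU")
})

test_that("all-zero counts at a dose hit the censoring floor", {
  rec <- flatRecords(conds = "light", doses = c(0, 24))
  rec$cfu[rec$dose == 24] <- 0
  s <- survivalCurves(percentSurvival(rec))
  at24 <- s[s$dose == 24, ]
  expect_true(at24$censored)
  expect_gt(at24$percent, 0)
  expect_equal(at24$percent, 100 * (0.5 * 100) / (100 * 100))
})

test_that("known exponential kill is recovered as a log-linear slope", {
  k <- 0.03
  sim <- simSurvival(preset = "custom",
                     rates = data.frame(strain = "S", k_light = k,
                                        k_dark = k),
                     cv = 0, seed = 1)
  sd <- percentSurvival(sim$records)
  sm <- doseResponseSummary(sd)
  expect_equal(sm$slope, rep(-k / log(10), 2), tolerance = 1e-9)
  expect_false(any(sm$positive_slope))
})

test_that("photoreactivation benefit has the closed-form slope", {
  kL <- 0.01; kD <- 0.02
  sim <- simSurvival(preset = "custom",
                     rates = data.frame(strain = "S", k_light = kL,
                                        k_dark = kD),
                     cv = 0, seed = 1)
  ben <- photoreactivationBenefit(percentSurvival(sim$records), "S")
  # benefit(d) = (kD - kL) d / ln 10
  expect_equal(ben$perDose$benefit,
               (kD - kL) * ben$perDose$dose / log(10), tolerance = 1e-9)
  expect_gt(ben$summary, 0)
})

test_that("benefit is zero for identical curves and antisymmetric", {
  rec <- flatRecords()
  rec$cfu <- rec$cfu * 0.5^(rec$dose / 24)
  sd <- percentSurvival(rec)
  ben <- photoreactivationBenefit(sd, "S")
  expect_true(all(abs(ben$perDose$benefit) < 1e-9))
  rec2 <- rec
  rec2$cfu[rec2$condition == "dark"] <-
    rec$cfu[rec$condition == "dark"] * 0.25^(rec$dose[rec$condition ==
                                                        "dark"] / 24)
  sdA <- percentSurvival(rec2)
  rec3 <- rec2
  rec3$condition <- ifelse(rec2$condition == "light", "dark", "light")
  sdB <- percentSurvival(rec3)
  bA <- photoreactivationBenefit(sdA, "S")$perDose$benefit
  bB <- photoreactivationBenefit(sdB, "S")$perDose$benefit
  expect_equal(bA, -bB)
})

test_that("a strain without dark data errors as missing condition", {
  rec <- flatRecords(conds = "light")
  expect_error(photoreactivationBenefit(percentSurvival(rec), "S"),
               "missing condition 'dark'")
})

test_that("planted orderings are recovered by the strain ranking", {
  sim <- simSurvival(preset = "custom",
                     rates = data.frame(strain = c("good", "mid", "bad"),
                                        k_light = c(0.003, 0.02, 0.06),
                                        k_dark = c(0.05, 0.05, 0.06)),
                     cv = 0.1, seed = 4)
  rk <- rankStrains(percentSurvival(sim$records))
  expect_equal(rk$strain, c("good", "mid", "bad"))
})

test_that("ties are broken lexicographically and flagged", {
  rec <- rbind(flatRecords("A"), flatRecords("B"))
  rk <- rankStrains(percentSurvival(rec))
  expect_equal(rk$strain, c("A", "B"))
  expect_true(all(rk$tied))
})

test_that("Spearman rho hits the concordant/discordant extremes", {
  x <- 1:5
  expect_equal(spearmanPermutation(x, x * 2)$rho, 1)
  expect_equal(spearmanPermutation(x, -x)$rho, -1)
})

test_that("exact permutation p equals the brute-force enumeration at n=6", {
  set.seed(9)
  x <- c(3.2, 1.5, 4.8, 2.2, 5.9, 0.7)
  y <- c(2.8, 1.9, 3.9, 3.1, 5.2, 1.1)
  sp <- spearmanPermutation(x, y)
  expect_equal(sp$method, "exact")
  expect_equal(sp$nPerm, factorial(6))
  expect_equal(sp$p, bruteForceSpearmanP(x, y), tolerance = 1e-12)
  expect_gt(sp$p, 0)
  expect_lte(sp$p, 1)
})

test_that("Monte-Carlo p agrees with the exact p within 3 SE", {
  x <- c(3.2, 1.5, 4.8, 2.2, 5.9, 0.7)
  y <- c(2.8, 1.9, 3.9, 3.1, 5.2, 1.1)
  pExact <- spearmanPermutation(x, y)$p
  # force the Monte-Carlo path by embedding in a 9-point problem is not
  # comparable; instead call the internal machinery at n = 6 via sampling
  set.seed(123)
  rx <- rank(x); ry <- rank(y)
  rhoObs <- stats::cor(rx, ry)
  rhos <- replicate(4000, stats::cor(rx, ry[sample.int(6)]))
  pMc <- (1 + sum(abs(rhos) >= abs(rhoObs) - 1e-12)) / 4001
  se <- sqrt(pExact * (1 - pExact) / 4000)
  expect_lt(abs(pMc - pExact), 3 * se + 1e-3)
})

test_that("slope recovery under noise: median error below 10 percent", {
  set.seed(2024)
  n <- 100
  k <- stats::runif(n, 0.005, 0.06)
  rates <- data.frame(strain = sprintf("s%03d", seq_len(n)),
                      k_light = k, k_dark = k)
  sim <- simSurvival(preset = "custom", rates = rates, cv = 0.2,
                     seed = 2024)
  sm <- doseResponseSummary(percentSurvival(sim$records))
  sm <- sm[sm$condition == "light", ]
  truth <- -k[match(sm$strain, rates$strain)] / log(10)
  relErr <- abs(sm$slope - truth) / abs(truth)
  expect_lt(stats::median(relErr), 0.10)
})

test_that("genotype-phenotype correlation needs four shared strains", {
  scores <- c(A = 0, B = -1, C = -2)
  vals <- c(A = 90, B = 50, C = 10)
  expect_error(genotypePhenotypeCorrelation(scores, vals),
               "at least four")
  scores <- c(scores, D = -3); vals <- c(vals, D = 1)
  out <- genotypePhenotypeCorrelation(scores, vals)
  expect_equal(out$rho, 1)
  expect_equal(out$n, 4L)
})
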