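#' Percent survival from colony-count dose-response records
#'
#' Converts raw colony counts to percent survival per (strain, condition,
#' dose). Counts are dilution-corrected to titers, replicates are averaged
#' on the linear scale, and survival is expressed relative to the dose-0
#' titer of the same strain and condition. When every replicate at a dose
#' yields zero colonies, survival is set to the detection floor (half a
#' colony at the deepest plated dilution, relative to the dose-0 titer) and
#' flagged censored so downstream log-scale summaries stay finite.
#'
#' @param records data.frame with columns \code{strain}, \code{condition}
#'   ("light"/"dark"), \code{dose} (J/m2), \code{replicate},
#'   \code{dilution} (fold dilution of the plated sample; titer =
#'   cfu x dilution) and \code{cfu}.
#' @return A \linkS4class{SurvivalDataset}.
#' @examples
#' rec <- data.frame(strain = "S", condition = "light",
#'                   dose = c(0, 24), replicate = 1, dilution = 1e4,
#'                   cfu = c(200, 100))
#' survivalCurves(percentSurvival(rec))
#' @export
percentSurvival <- function(records) {
  need <- c("strain", "condition", "dose", "replicate", "dilution", "cfu")
  if (!all(need %in% names(records)))
    stop("records needs columns: ", paste(need, collapse = ", "))
  if (any(records$cfu < 0)) stop("negative CFU count")
  if (any(records$dose < 0)) stop("negative dose")
  records$titer <- records$cfu * records$dilution

  out <- list()
  for (grp in split(records,
                    list(records$strain, records$condition), drop = TRUE)) {
    strain <- grp$strain[1L]; cond <- grp$condition[1L]
    z <- grp[grp$dose == 0, , drop = FALSE]
    if (!nrow(z))
      stop("missing dose 0 for ", strain, "/", cond)
    n0 <- mean(z$titer)
    if (n0 <= 0)
      stop("dose-0 titer is zero for ", strain, "/", cond)
    for (d in sort(unique(grp$dose))) {
      sub <- grp[grp$dose == d, , drop = FALSE]
      titer <- mean(sub$titer)
      censored <- FALSE
      if (titer == 0) {
        titer <- 0.5 * min(sub$dilution)
        censored <- TRUE
      }
      pct <- if (d == 0) 100 else 100 * titer / n0
      out[[length(out) + 1L]] <- data.frame(
        strain = strain, condition = cond, dose = d, percent = pct,
        censored = censored, stringsAsFactors = FALSE)
    }
  }
  surv <- do.call(rbind, out)
  surv <- surv[order(surv$strain, surv$condition, surv$dose), , drop = FALSE]
  rownames(surv) <- NULL
  new("SurvivalDataset", raw = records[, need], survival = surv)
}

#' Log-linear dose-response summaries per strain and condition
#'
#' Fits log10(percent survival) against dose by least squares for each
#' (strain, condition), giving the log-kill slope per J/m2, the dose at 10
#' percent survival from the fit (flagged extrapolated when beyond the dose
#' range), and the log-kill at the maximum dose. A positive slope (survival
#' rising with dose) triggers a warning flag, not an error.
#'
#' @param sd A \linkS4class{SurvivalDataset}.
#' @return data.frame: \code{strain}, \code{condition}, \code{slope}
#'   (log10 per J/m2), \code{intercept}, \code{d10}, \code{d10_extrapolated},
#'   \code{max_dose}, \code{max_dose_log_kill}, \code{n_censored},
#'   \code{positive_slope}.
#' @export
doseResponseSummary <- function(sd) {
  s <- survivalCurves(sd)
  out <- list()
  for (grp in split(s, list(s$strain, s$condition), drop = TRUE)) {
    fit <- stats::lm(log10(percent) ~ dose, data = grp)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
    d10 <- if (abs(slope) > 1e-12) (1 - intercept) / slope else NA_real_
    maxd <- max(grp$dose)
    out[[length(out) + 1L]] <- data.frame(
      strain = grp$strain[1L], condition = grp$condition[1L],
      slope = slope, intercept = intercept, d10 = d10,
      d10_extrapolated = is.na(d10) | d10 > maxd | d10 < 0,
      max_dose = maxd,
      max_dose_log_kill = 2 - log10(grp$percent[grp$dose == maxd][1L]),
      n_censored = sum(grp$censored),
      positive_slope = slope > 0, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$strain, res$condition), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Photoreactivation benefit of a strain
#'
#' Per-dose difference in log10 survival between the light and dark
#' conditions; positive values mean photoreactivating light improved
#' survival. Censored points in either condition propagate a censored flag.
#'
#' @param sd A \linkS4class{SurvivalDataset}.
#' @param strain Strain id.
#' @return List with \code{perDose} (data.frame \code{dose},
#'   \code{benefit}, \code{censored}) and \code{summary} (mean benefit over
#'   positive doses).
#' @export
photoreactivationBenefit <- function(sd, strain) {
  s <- survivalCurves(sd)
  s <- s[s$strain == strain, , drop = FALSE]
  if (!nrow(s)) stop("unknown strain: ", strain)
  for (cond in c("light", "dark"))
    if (!cond %in% s$condition)
      stop("missing condition '", cond, "' for strain ", strain)
  li <- s[s$condition == "light", ]
  da <- s[s$condition == "dark", ]
  doses <- intersect(li$dose, da$dose)
  perDose <- data.frame(
    dose = doses,
    benefit = log10(li$percent[match(doses, li$dose)]) -
      log10(da$percent[match(doses, da$dose)]),
    censored = li$censored[match(doses, li$dose)] |
      da$censored[match(doses, da$dose)])
  pos <- perDose$dose > 0
  list(perDose = perDose,
       summary = if (any(pos)) mean(perDose$benefit[pos]) else NA_real_)
}

#' Rank strains by UV survival
#'
#' Deterministic ranking, best first. The default metric is light-condition
#' percent survival at the maximum dose shared by all strains; ties are
#' broken by mean photoreactivation benefit, then lexicographically by
#' strain id, and flagged.
#'
#' @param sd A \linkS4class{SurvivalDataset}.
#' @param metric "light-survival" (default) or "benefit" (mean
#'   photoreactivation benefit).
#' @return data.frame \code{rank}, \code{strain}, \code{metric},
#'   \code{tied}.
#' @export
rankStrains <- function(sd, metric = c("light-survival", "benefit")) {
  metric <- match.arg(metric)
  s <- survivalCurves(sd)
  strains <- sort(unique(s$strain))
  if (length(strains) < 2L) stop("need at least two strains")
  common <- Reduce(intersect, lapply(strains, function(st)
    s$dose[s$strain == st]))
  common <- common[common > 0]
  if (!length(common)) stop("no positive dose common to all strains")
  maxd <- max(common)
  val <- vapply(strains, function(st) {
    sub <- s[s$strain == st & s$dose == maxd, , drop = FALSE]
    sub <- if ("light" %in% sub$condition)
      sub[sub$condition == "light", ] else sub
    mean(sub$percent)
  }, numeric(1L))
  ben <- vapply(strains, function(st) {
    b <- tryCatch(photoreactivationBenefit(sd, st)$summary,
                  error = function(e) NA_real_)
    if (is.na(b)) 0 else b
  }, numeric(1L))
  primary <- if (metric == "light-survival") val else ben
  ord <- order(-primary, -ben, strains)
  data.frame(rank = seq_along(strains), strain = strains[ord],
             metric = primary[ord],
             tied = duplicated(primary[ord]) |
               duplicated(primary[ord], fromLast = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman rank correlation with a permutation p-value
#'
#' The correlation is Spearman's rho (average ranks for ties). For eight or
#' fewer observations the two-sided p-value is exact, computed by
#' enumerating every permutation of one variable; above that it is a
#' seeded Monte-Carlo estimate (the identity permutation is included, so p
#' is never zero).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param nPerm Number of Monte-Carlo permutations when n > 8 (default
#'   10000); set the RNG seed beforehand for reproducibility.
#' @return List \code{rho}, \code{p}, \code{method} ("exact"/"monte-carlo"),
#'   \code{nPerm}.
#' @export
spearmanPermutation <- function(x, y, nPerm = 10000L) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  spearOf <- function(perm) stats::cor(rx, ry[perm])
  if (n <= 8L) {
    perms <- allPermutations(n)
    rhos <- vapply(perms, spearOf, numeric(1L))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    list(rho = rho, p = p, method = "exact", nPerm = length(perms))
  } else {
    rhos <- vapply(seq_len(nPerm - 1L),
                   function(i) spearOf(sample.int(n)), numeric(1L))
    p <- (1 + sum(abs(rhos) >= abs(rho) - 1e-12)) / nPerm
    list(rho = rho, p = p, method = "monte-carlo", nPerm = nPerm)
  }
}

allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (i in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = i - 1L)
  }
  out
}

#' Correlate photolyase integrity scores with survival phenotype
#'
#' Spearman rank correlation (with permutation p-value) between per-strain
#' integrity scores and a survival metric, the formal version of asking
#' whether strains with more intact photolyases survive UV better.
#'
#' @param scores Named numeric vector of integrity scores (see
#'   \code{\link{integrityScore}}).
#' @param sd A \linkS4class{SurvivalDataset} covering the same strains, or a
#'   named numeric vector of metric values.
#' @param metric Passed to \code{\link{rankStrains}} when \code{sd} is a
#'   dataset.
#' @param nPerm See \code{\link{spearmanPermutation}}.
#' @return List \code{rho}, \code{p}, \code{method}, \code{n},
#'   \code{strains}.
#' @export
genotypePhenotypeCorrelation <- function(scores, sd,
                                         metric = "light-survival",
                                         nPerm = 10000L) {
  if (is(sd, "SurvivalDataset")) {
    rk <- rankStrains(sd, metric)
    vals <- setNames(rk$metric, rk$strain)
  } else vals <- sd
  shared <- intersect(names(scores), names(vals))
  if (length(shared) < 4L)
    stop("need at least four strains with both score and phenotype")
  sp <- spearmanPermutation(scores[shared], vals[shared], nPerm)
  c(sp, list(n = length(shared), strains = shared))
}
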