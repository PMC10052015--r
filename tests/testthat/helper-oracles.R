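# Independent oracles used by the property tests. These deliberately use
# naive algorithms (exhaustive enumeration, all-pairs scans) so they stay
# independent of the implementation paths they check.

## Exhaustive global-alignment optimum under affine gaps: a gap run of
## length L costs open + L * ext (end gaps penalized). Enumerates every
## monotone alignment path.
bruteForceAlignScore <- function(a, b, mat, open, ext) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  best <- -Inf
  rec <- function(i, j, score, lastMove) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1L, j + 1L, score + mat[ca[i], cb[j]], "M")
    if (i <= length(ca))     # gap in b
      rec(i + 1L, j, score - ext - if (lastMove == "I") 0 else open, "I")
    if (j <= length(cb))     # gap in a
      rec(i, j + 1L, score - ext - if (lastMove == "D") 0 else open, "D")
  }
  rec(1L, 1L, 0, "start")
  best
}

## Spearman rho without cor(): 1 - 6 sum d^2 / (n(n^2-1)); assumes no ties.
spearmanFormula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

## Exhaustive two-sided permutation p for Spearman, via a simple recursive
## permutation generator and the closed-form rho.
bruteForceSpearmanP <- function(x, y) {
  n <- length(x)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  obs <- abs(spearmanFormula(x, y))
  hits <- vapply(perms(seq_len(n)), function(p)
    abs(spearmanFormula(x, y[p])) >= obs - 1e-12, logical(1L))
  mean(hits)
}

## All-pairs minimum heavy-atom distance per (protein residue, group),
## nested loops, no vectorization.
bruteForceShell <- function(s, groups, threshold) {
  a <- atoms(s)
  rows <- list()
  for (g in groups) {
    gi <- g@atomIdx[a$element[g@atomIdx] != "H"]
    prot <- which(a$entity == "protein" & a$element != "H")
    for (res in unique(a$resno[prot])) {
      ri <- prot[a$resno[prot] == res]
      dmin <- Inf
      for (i in ri) for (j in gi) {
        d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                    (a$z[i] - a$z[j])^2)
        dmin <- min(dmin, d)
      }
      if (dmin <= threshold)
        rows[[length(rows) + 1L]] <- data.frame(pos = res,
                                                ligand = g@label,
                                                min_distance_A = dmin)
    }
  }
  if (!length(rows)) return(data.frame(pos = integer(),
                                       ligand = character(),
                                       min_distance_A = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$pos, out$ligand), , drop = FALSE]
}

## Rigid-body transform of a StructureModel (rotation + translation).
rigidTransform <- function(s, angles = c(0.3, 0.7, 1.1),
                           shift = c(5, -3, 2)) {
  rot <- function(t, i, j) {
    R <- diag(3)
    R[i, i] <- cos(t); R[j, j] <- cos(t)
    R[i, j] <- -sin(t); R[j, i] <- sin(t)
    R
  }
  R <- rot(angles[1L], 1L, 2L) %*% rot(angles[2L], 2L, 3L) %*%
    rot(angles[3L], 1L, 3L)
  a <- atoms(s)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1L] + shift[1L]
  a$y <- xyz[, 2L] + shift[2L]
  a$z <- xyz[, 3L] + shift[3L]
  new("StructureModel", atoms = a, chains = s@chains, source = s@source)
}

## Toy scoring matrix over a reduced alphabet.
toyMatrix <- function(alphabet = c("A", "C", "D", "E"),
                      match = 2, mismatch = -1) {
  m <- matrix(mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}
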