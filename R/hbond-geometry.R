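# Idealized side-chain geometry: internal-coordinate templates per amino
# acid and a deterministic builder. Bond lengths (A) and angles (degrees)
# are idealized single-conformer values; torsion fields are either numeric
# (fixed) or chi references ("chi1", "chi2+120", ...), resolved from the
# wild-type residue where possible, else from the default rotamer.

scRow <- function(atom, refs, bond, angle, tors)
  list(atom = atom, refs = refs, bond = bond, angle = angle, tors = tors)

CB <- scRow("CB", c("N", "C", "CA"), 1.53, 110.5, -122.6)

SIDECHAIN_TEMPLATES <- list(
  GLY = list(),
  ALA = list(CB),
  SER = list(CB, scRow("OG",  c("N", "CA", "CB"), 1.42, 110.8, "chi1")),
  CYS = list(CB, scRow("SG",  c("N", "CA", "CB"), 1.81, 114.0, "chi1")),
  THR = list(CB, scRow("OG1", c("N", "CA", "CB"), 1.43, 109.5, "chi1"),
             scRow("CG2", c("N", "CA", "CB"), 1.52, 110.5, "chi1-120")),
  VAL = list(CB, scRow("CG1", c("N", "CA", "CB"), 1.52, 110.5, "chi1"),
             scRow("CG2", c("N", "CA", "CB"), 1.52, 110.5, "chi1+122")),
  ILE = list(CB, scRow("CG1", c("N", "CA", "CB"), 1.53, 110.5, "chi1"),
             scRow("CG2", c("N", "CA", "CB"), 1.53, 110.5, "chi1-122"),
             scRow("CD1", c("CA", "CB", "CG1"), 1.52, 114.0, "chi2")),
  LEU = list(CB, scRow("CG",  c("N", "CA", "CB"), 1.53, 116.3, "chi1"),
             scRow("CD1", c("CA", "CB", "CG"), 1.52, 110.5, "chi2"),
             scRow("CD2", c("CA", "CB", "CG"), 1.52, 110.5, "chi2+122")),
  MET = list(CB, scRow("CG",  c("N", "CA", "CB"), 1.52, 114.0, "chi1"),
             scRow("SD",  c("CA", "CB", "CG"), 1.80, 112.7, "chi2"),
             scRow("CE",  c("CB", "CG", "SD"), 1.79, 100.9, "chi3")),
  PRO = list(CB, scRow("CG",  c("N", "CA", "CB"), 1.50, 104.5, "chi1"),
             scRow("CD",  c("CA", "CB", "CG"), 1.51, 106.1, "chi2")),
  ASP = list(CB, scRow("CG",  c("N", "CA", "CB"), 1.52, 112.6, "chi1"),
             scRow("OD1", c("CA", "CB", "CG"), 1.25, 118.4, "chi2"),
             scRow("OD2", c("CA", "CB", "CG"), 1.25, 118.4, "chi2+180")),
  ASN = list(CB, scRow("CG",  c("N", "CA", "CB"), 1.52, 112.6, "chi1"),
             scRow("OD1", c("CA", "CB", "CG"), 1.23, 120.8, "chi2"),
             scRow("ND2", c("CA", "CB", "CG"), 1.33, 116.4, "chi2+180")),
  GLU = list(CB, scRow("CG",  c("N", "CA", "CB"), 1.52, 114.0, "chi1"),
             scRow("CD",  c("CA", "CB", "CG"), 1.52, 112.6, "chi2"),
             scRow("OE1", c("CB", "CG", "CD"), 1.25, 118.4, "chi3"),
             scRow("OE2", c("CB", "CG", "CD"), 1.25, 118.4, "chi3+180")),
  GLN = list(CB, scRow("CG",  c("N", "CA", "CB"), 1.52, 114.0, "chi1"),
             scRow("CD",  c("CA", "CB", "CG"), 1.52, 112.6, "chi2"),
             scRow("OE1", c("CB", "CG", "CD"), 1.23, 120.8, "chi3"),
             scRow("NE2", c("CB", "CG", "CD"), 1.33, 116.4, "chi3+180")),
  LYS = list(CB, scRow("CG",  c("N", "CA", "CB"), 1.52, 114.0, "chi1"),
             scRow("CD",  c("CA", "CB", "CG"), 1.52, 111.3, "chi2"),
             scRow("CE",  c("CB", "CG", "CD"), 1.52, 111.3, "chi3"),
             scRow("NZ",  c("CG", "CD", "CE"), 1.49, 111.9, "chi4")),
  ARG = list(CB, scRow("CG",  c("N", "CA", "CB"), 1.52, 114.0, "chi1"),
             scRow("CD",  c("CA", "CB", "CG"), 1.52, 111.3, "chi2"),
             scRow("NE",  c("CB", "CG", "CD"), 1.46, 112.0, "chi3"),
             scRow("CZ",  c("CG", "CD", "NE"), 1.33, 124.2, "chi4"),
             scRow("NH1", c("CD", "NE", "CZ"), 1.33, 120.0, 0),
             scRow("NH2", c("CD", "NE", "CZ"), 1.33, 120.0, 180)),
  HIS = list(CB, scRow("CG",  c("N", "CA", "CB"), 1.50, 113.8, "chi1"),
             scRow("ND1", c("CA", "CB", "CG"), 1.38, 122.7, "chi2"),
             scRow("CD2", c("CA", "CB", "CG"), 1.36, 131.1, "chi2+180"),
             scRow("CE1", c("CB", "CG", "ND1"), 1.32, 109.2, 180),
             scRow("NE2", c("CG", "ND1", "CE1"), 1.32, 108.2, 0)),
  PHE = list(CB, scRow("CG",  c("N", "CA", "CB"), 1.50, 113.8, "chi1"),
             scRow("CD1", c("CA", "CB", "CG"), 1.39, 120.8, "chi2"),
             scRow("CD2", c("CA", "CB", "CG"), 1.39, 120.8, "chi2+180"),
             scRow("CE1", c("CB", "CG", "CD1"), 1.39, 120.8, 180),
             scRow("CE2", c("CB", "CG", "CD2"), 1.39, 120.8, 180),
             scRow("CZ",  c("CG", "CD1", "CE1"), 1.39, 120.0, 0)),
  TYR = list(CB, scRow("CG",  c("N", "CA", "CB"), 1.50, 113.8, "chi1"),
             scRow("CD1", c("CA", "CB", "CG"), 1.39, 120.8, "chi2"),
             scRow("CD2", c("CA", "CB", "CG"), 1.39, 120.8, "chi2+180"),
             scRow("CE1", c("CB", "CG", "CD1"), 1.39, 120.8, 180),
             scRow("CE2", c("CB", "CG", "CD2"), 1.39, 120.8, 180),
             scRow("CZ",  c("CG", "CD1", "CE1"), 1.39, 120.0, 0),
             scRow("OH",  c("CD1", "CE1", "CZ"), 1.38, 120.0, 180)),
  TRP = list(CB, scRow("CG",  c("N", "CA", "CB"), 1.50, 113.8, "chi1"),
             scRow("CD1", c("CA", "CB", "CG"), 1.37, 126.9, "chi2"),
             scRow("CD2", c("CA", "CB", "CG"), 1.43, 126.7, "chi2+180"),
             scRow("NE1", c("CB", "CG", "CD1"), 1.38, 110.2, 180),
             scRow("CE2", c("CB", "CG", "CD2"), 1.40, 107.2, 180),
             scRow("CE3", c("CB", "CG", "CD2"), 1.40, 133.9, 0),
             scRow("CZ2", c("CG", "CD2", "CE2"), 1.40, 122.4, 180),
             scRow("CZ3", c("CG", "CD2", "CE3"), 1.39, 118.6, 180),
             scRow("CH2", c("CD2", "CE2", "CZ2"), 1.37, 117.5, 0)))

## chi dihedral atom quadruples per residue type.
CHI_ATOMS <- list(
  SER = list(c("N", "CA", "CB", "OG")),
  CYS = list(c("N", "CA", "CB", "SG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")))

## Packaged default rotamer (used when a chi cannot be copied from the
## wild-type residue). Proline uses a ring-compatible pucker.
defaultChi <- function(resid3, k) {
  if (resid3 == "PRO") return(c(-25, 35)[min(k, 2L)])
  c(-65, 180, 180, 180)[min(k, 4L)]
}

## Measure the chi angles of a residue present in an atom table (rows of
## one residue). Returns numeric vector, NA where atoms are missing.
measureChis <- function(resAtoms) {
  resid3 <- resAtoms$resid[1L]
  defs <- CHI_ATOMS[[resid3]]
  if (is.null(defs)) return(numeric(0L))
  vapply(defs, function(q) {
    idx <- match(q, resAtoms$elety)
    if (anyNA(idx)) return(NA_real_)
    xyz <- as.matrix(resAtoms[idx, c("x", "y", "z")])
    torsionAngle(xyz[1L, ], xyz[2L, ], xyz[3L, ], xyz[4L, ])
  }, numeric(1L))
}

resolveTorsion <- function(tors, chis) {
  if (is.numeric(tors)) return(tors)
  m <- regmatches(tors, regexec("^chi([0-9])([+-][0-9.]+)?$", tors))[[1L]]
  k <- as.integer(m[2L])
  offset <- if (nzchar(m[3L])) as.numeric(m[3L]) else 0
  chis[k] + offset
}

## Build idealized side-chain coordinates for residue type `resid3` on a
## backbone given as a named list of coordinates (N, CA, C). `chis` is a
## fully resolved numeric chi vector.
buildSidechain <- function(resid3, backbone, chis) {
  tmpl <- SIDECHAIN_TEMPLATES[[resid3]]
  if (is.null(tmpl)) stop("no side-chain template for ", resid3)
  coords <- backbone
  out <- list()
  for (row in tmpl) {
    refs <- lapply(row$refs, function(nm) {
      if (is.null(coords[[nm]])) stop("missing reference atom ", nm)
      coords[[nm]]
    })
    xyz <- placeAtom(refs[[1L]], refs[[2L]], refs[[3L]], row$bond,
                     row$angle, resolveTorsion(row$tors, chis))
    coords[[row$atom]] <- xyz
    out[[row$atom]] <- xyz
  }
  out
}

## Number of chi angles a residue type uses.
nChi <- function(resid3) length(CHI_ATOMS[[resid3]] %||% list())

#' Model a single residue substitution on a structure
#'
#' Replaces the side chain of one protein residue with an idealized side
#' chain of the new amino acid. Backbone atoms (N, CA, C, O, OXT) are kept
#' exactly; side-chain atoms are rebuilt from packaged internal-coordinate
#' templates. Chi angles are copied from the wild-type residue where the
#' atom tree allows (chi k is copied when both residue types define it and
#' the wild-type atoms are present), otherwise the packaged default rotamer
#' is used. The construction is fully deterministic; no rotamer search or
#' clash relief is performed. Substituting a residue by itself returns the
#' structure unchanged.
#'
#' @param s A \linkS4class{StructureModel}.
#' @param position Residue number in reference numbering.
#' @param newAa One-letter code of the replacement residue.
#' @param chain Chain id (default: first chain containing the position).
#' @param numberingOffset Added to \code{position} to obtain the structure's
#'   residue number (0 when the structure is already in reference
#'   numbering).
#' @return A \linkS4class{StructureModel} with the modeled residue.
#' @export
substituteResidue <- function(s, position, newAa, chain = NULL,
                              numberingOffset = 0L) {
  a <- atoms(s)
  resno <- position + numberingOffset
  sel <- a$entity == "protein" & a$resno == resno
  if (!is.null(chain)) sel <- sel & a$chain == chain
  if (!any(sel)) stop("no protein residue at position ", position)
  ch <- a$chain[sel][1L]
  sel <- sel & a$chain == ch
  res <- a[sel, , drop = FALSE]
  old3 <- res$resid[1L]
  new3 <- aa3(newAa)
  if (new3 == old3) return(s)

  bbNames <- c("N", "CA", "C", "O", "OXT")
  bb <- lapply(c("N", "CA", "C"), function(nm) {
    i <- match(nm, res$elety)
    if (is.na(i)) stop("residue ", position, " lacks backbone atom ", nm,
                       " required for side-chain placement")
    as.numeric(res[i, c("x", "y", "z")])
  })
  names(bb) <- c("N", "CA", "C")

  wtChis <- measureChis(res)
  chis <- vapply(seq_len(max(nChi(new3), 1L)), function(k) {
    if (k <= length(wtChis) && !is.na(wtChis[k]) && k <= nChi(new3))
      wtChis[k] else defaultChi(new3, k)
  }, numeric(1L))

  sc <- buildSidechain(new3, bb, chis)

  keep <- a[!sel | a$elety %in% bbNames, , drop = FALSE]
  keep$resid[keep$entity == "protein" & keep$resno == resno &
               keep$chain == ch] <- new3
  newRows <- if (length(sc)) data.frame(
    eleno = 0L, elety = names(sc), element = substr(names(sc), 1L, 1L),
    resid = new3, resno = resno, chain = ch, insert = "",
    x = vapply(sc, `[`, numeric(1L), 1L),
    y = vapply(sc, `[`, numeric(1L), 2L),
    z = vapply(sc, `[`, numeric(1L), 3L),
    o = 1, alt = "", entity = "protein", stringsAsFactors = FALSE)
  else keep[0L, ]

  ins <- max(which(keep$entity == "protein" & keep$resno == resno &
                     keep$chain == ch))
  out <- rbind(keep[seq_len(ins), , drop = FALSE], newRows,
               keep[-seq_len(ins), , drop = FALSE])
  out$eleno <- seq_len(nrow(out))
  rownames(out) <- NULL
  new("StructureModel", atoms = out, chains = s@chains,
      source = paste0(s@source, " [", aa1(old3), position, newAa, "]"))
}
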