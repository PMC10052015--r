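# Geometric hydrogen-bond detection between a protein residue's polar
# side-chain atoms and ligand-group atoms. The criterion is distance-only:
# the structures of interest lack hydrogens, so no angle term is applied
# (documented limitation; thresholds are configurable).

## Donor/acceptor capability of protein side-chain atoms.
## "D" can donate, "A" can accept, "DA" both.
SIDECHAIN_POLAR <- list(
  SER = c(OG = "DA"), THR = c(OG1 = "DA"), TYR = c(OH = "DA"),
  CYS = c(SG = "DA"),
  ASN = c(OD1 = "A", ND2 = "D"), GLN = c(OE1 = "A", NE2 = "D"),
  ASP = c(OD1 = "A", OD2 = "A"), GLU = c(OE1 = "A", OE2 = "A"),
  LYS = c(NZ = "D"),
  ARG = c(NE = "D", NH1 = "D", NH2 = "D"),
  HIS = c(ND1 = "DA", NE2 = "DA"),
  TRP = c(NE1 = "D"),
  MET = c(SD = "A"))

## Ligand atoms carry no hydrogens in the structures considered; without
## protonation assignment the element-level default is: N both donor and
## acceptor, O acceptor, S acceptor. (Ribityl/hydroxyl ligand oxygens can
## in reality donate; that case is not modeled - documented.)
ligandCapability <- function(element) {
  switch(element, N = "DA", O = "A", S = "A", "")
}

#' Hydrogen-bond geometry criteria
#'
#' @param dMin Minimum donor-acceptor distance (A); pairs closer than this
#'   are treated as clashes, not bonds. Default 2.4.
#' @param dStrong Upper bound of the strong-bond window (default 3.3).
#' @param dWeak Upper bound of the weak-bond window (default 3.6). Strong
#'   bonds lie in [dMin, dStrong], weak bonds in (dStrong, dWeak].
#' @return List of criteria for \code{\link{detectHbonds}}.
#' @export
hbondCriteria <- function(dMin = 2.4, dStrong = 3.3, dWeak = 3.6) {
  stopifnot(dMin < dStrong, dStrong <= dWeak)
  list(dMin = dMin, dStrong = dStrong, dWeak = dWeak)
}

#' Detect hydrogen bonds between one residue and ligand groups
#'
#' Enumerates (donor, acceptor) pairs between the residue's polar
#' side-chain atoms (per the packaged capability table) and ligand N/O/S
#' atoms, classifying each in-window pair as a strong or weak bond by
#' distance.
#'
#' @param s A \linkS4class{StructureModel}.
#' @param position Residue number in reference numbering.
#' @param partners List of \linkS4class{LigandGroup}.
#' @param criteria See \code{\link{hbondCriteria}}.
#' @param chain Optional chain id.
#' @param numberingOffset Added to \code{position} to get the structure's
#'   residue number.
#' @return data.frame with columns \code{res_atom}, \code{partner},
#'   \code{partner_resid}, \code{partner_resno}, \code{partner_atom},
#'   \code{distance}, \code{strength} ("strong"/"weak"), \code{donor}
#'   ("residue" or "ligand"). Zero rows when the residue has no polar
#'   side-chain atoms (with a warning) or no partner within the window.
#' @export
detectHbonds <- function(s, position, partners,
                         criteria = hbondCriteria(), chain = NULL,
                         numberingOffset = 0L) {
  if (!length(partners)) stop("no partner groups supplied")
  a <- atoms(s)
  resno <- position + numberingOffset
  sel <- a$entity == "protein" & a$resno == resno
  if (!is.null(chain)) sel <- sel & a$chain == chain
  if (!any(sel)) stop("no protein residue at position ", position)
  sel <- sel & a$chain == a$chain[sel][1L]
  res <- a[sel, , drop = FALSE]
  cap <- SIDECHAIN_POLAR[[res$resid[1L]]]
  polar <- res[res$elety %in% names(cap), , drop = FALSE]
  if (!nrow(polar)) {
    warning("residue ", res$resid[1L], position,
            " has no polar side-chain atoms")
    return(emptyHbonds())
  }
  out <- list()
  for (g in partners) {
    gi <- g@atomIdx[a$element[g@atomIdx] %in% c("N", "O", "S")]
    gi <- setdiff(gi, which(sel))
    if (!length(gi)) next
    d <- crossDist(as.matrix(polar[, c("x", "y", "z")]),
                   as.matrix(a[gi, c("x", "y", "z")]))
    hit <- which(d >= criteria$dMin & d <= criteria$dWeak, arr.ind = TRUE)
    for (r in seq_len(nrow(hit))) {
      i <- hit[r, 1L]; j <- hit[r, 2L]
      rcap <- cap[[polar$elety[i]]]
      lcap <- ligandCapability(a$element[gi[j]])
      resDonates <- grepl("D", rcap) && grepl("A", lcap)
      ligDonates <- grepl("D", lcap) && grepl("A", rcap)
      if (!resDonates && !ligDonates) next
      out[[length(out) + 1L]] <- data.frame(
        res_atom = polar$elety[i], partner = g@label,
        partner_resid = a$resid[gi[j]], partner_resno = a$resno[gi[j]],
        partner_atom = a$elety[gi[j]], distance = d[i, j],
        strength = if (d[i, j] <= criteria$dStrong) "strong" else "weak",
        donor = if (resDonates) "residue" else "ligand",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(emptyHbonds())
  out <- do.call(rbind, out)
  out <- out[order(out$partner, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

emptyHbonds <- function()
  data.frame(res_atom = character(), partner = character(),
             partner_resid = character(), partner_resno = integer(),
             partner_atom = character(), distance = numeric(),
             strength = character(), donor = character(),
             stringsAsFactors = FALSE)

#' Classify the hydrogen-bond verdict of a substitution
#'
#' Pure, table-driven function of the before/after bond sets, evaluated at
#' the level of partner ligand labels with the best strength per partner
#' (strong beats weak). Per-partner transitions: loss (bonded before,
#' unbonded after), gain (the reverse), weakened (strong to weak),
#' strengthened (weak to strong), unchanged. The overall verdict is the
#' single transition category present, "unchanged" when all partners are
#' unchanged, or "mixed" when several categories occur.
#'
#' @param before,after Bond data.frames as returned by
#'   \code{\link{detectHbonds}}.
#' @return Character scalar with attribute \code{partners}: the labels whose
#'   bonding changed.
#' @export
hbondVerdict <- function(before, after) {
  best <- function(b) {
    if (!nrow(b)) return(character(0L))
    vapply(split(b$strength, b$partner),
           function(s) if ("strong" %in% s) "strong" else "weak",
           character(1L))
  }
  sb <- best(before); sa <- best(after)
  labels <- union(names(sb), names(sa))
  status <- vapply(labels, function(l) {
    b <- sb[l][[1]]; a <- sa[l][[1]]
    bHas <- l %in% names(sb); aHas <- l %in% names(sa)
    if (bHas && !aHas) "loss"
    else if (!bHas && aHas) "gain"
    else if (b == "strong" && a == "weak") "weakened"
    else if (b == "weak" && a == "strong") "strengthened"
    else "unchanged"
  }, character(1L))
  changed <- status[status != "unchanged"]
  verdict <- if (!length(changed)) "unchanged"
  else if (length(unique(changed)) == 1L) unique(changed)
  else "mixed"
  attr(verdict, "partners") <- if (length(changed)) names(changed)
                               else character(0L)
  verdict
}

#' Assess the hydrogen-bond impact of a residue substitution
#'
#' Detects bonds for the wild-type residue, models the substitution with
#' \code{\link{substituteResidue}}, re-detects, and classifies the verdict
#' with \code{\link{hbondVerdict}}.
#'
#' @param s A \linkS4class{StructureModel}.
#' @param call Substitution in from-position-to notation (e.g. "R50V") or a
#'   list with elements \code{from}, \code{pos}, \code{to}, optionally
#'   \code{strain}.
#' @param partners List of \linkS4class{LigandGroup}.
#' @param criteria See \code{\link{hbondCriteria}}.
#' @param chain,numberingOffset Passed through to detection/substitution.
#' @return A \linkS4class{SubstitutionImpact}. Errors when the call's "from"
#'   residue does not match the structure at that position (a guard against
#'   numbering mistakes).
#' @export
assessSubstitution <- function(s, call, partners,
                               criteria = hbondCriteria(), chain = NULL,
                               numberingOffset = 0L) {
  if (is.character(call)) call <- parseCall(call)
  a <- atoms(s)
  resno <- call$pos + numberingOffset
  sel <- a$entity == "protein" & a$resno == resno
  if (!is.null(chain)) sel <- sel & a$chain == chain
  if (!any(sel)) stop("no protein residue at position ", call$pos)
  found <- aa1(a$resid[sel][1L])
  if (found != toupper(call$from))
    stop("structure has ", found, " at position ", call$pos,
         ", but the call states ", call$from,
         " (check numbering offsets)")
  before <- detectHbonds(s, call$pos, partners, criteria, chain,
                         numberingOffset)
  s2 <- substituteResidue(s, call$pos, call$to, chain, numberingOffset)
  # atom indices shift when the modeled side chain changes size
  partners2 <- lapply(partners, regroupLigand, s = s2)
  after <- suppressWarnings(
    detectHbonds(s2, call$pos, partners2, criteria, chain, numberingOffset))
  v <- hbondVerdict(before, after)
  new("SubstitutionImpact",
      call = paste0(toupper(call$from), call$pos, toupper(call$to)),
      strain = if (is.null(call$strain)) NA_character_ else call$strain,
      before = before, after = after, verdict = as.character(v),
      partners = attr(v, "partners"))
}

## Re-resolve a ligand group's atom indices against another structure
## sharing the same residue identifiers.
regroupLigand <- function(g, s) {
  a <- atoms(s)
  key <- paste(a$chain, a$resno, a$resid)
  want <- paste(g@residues$chain, g@residues$resno, g@residues$resid)
  idx <- which(key %in% want)
  new("LigandGroup", label = g@label, residues = g@residues,
      atomIdx = idx)
}

parseCall <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x))[[1L]]
  if (length(m) != 4L) stop("cannot parse substitution call: ", x)
  list(from = m[2L], pos = as.integer(m[3L]), to = m[4L])
}

#' Tabulate substitution impacts
#'
#' @param impacts List of \linkS4class{SubstitutionImpact}.
#' @return data.frame with one row per substitution: \code{strain},
#'   \code{call}, \code{verdict}, \code{partners} (comma-joined),
#'   \code{n_bonds_before}, \code{n_bonds_after}, \code{min_distance_before},
#'   \code{min_distance_after}; ordered by call. CSV round-trips losslessly.
#' @export
impactReport <- function(impacts) {
  if (!length(impacts))
    return(data.frame(strain = character(), call = character(),
                      verdict = character(), partners = character(),
                      n_bonds_before = integer(), n_bonds_after = integer(),
                      min_distance_before = numeric(),
                      min_distance_after = numeric(),
                      stringsAsFactors = FALSE))
  rows <- lapply(impacts, function(im) data.frame(
    strain = im@strain, call = im@call, verdict = im@verdict,
    partners = paste(im@partners, collapse = ","),
    n_bonds_before = nrow(im@before), n_bonds_after = nrow(im@after),
    min_distance_before = if (nrow(im@before)) min(im@before$distance)
                          else NA_real_,
    min_distance_after = if (nrow(im@after)) min(im@after$distance)
                         else NA_real_,
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$call), , drop = FALSE]
  rownames(out) <- NULL
  out
}
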