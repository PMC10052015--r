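#' Reference-numbered positions repeatedly reported as key for photolyase
#' function: the HDF-binding arginine (50), the DNA-binding loop position
#' (149), the FAD/DNA-proximal glutamate (282), the FAD-binding asparagine
#' (385), the DNA-proximal aspartate (398) and the DNA-binding lysine (413).
#'
#' @return Integer vector of reference-numbered positions.
#' @export
keyPositions <- function() c(50L, 149L, 282L, 385L, 398L, 413L)

#' Packaged key-residue variant table
#'
#' The packaged transcription of the published key-residue comparison:
#' 15 contact-shell positions (reference numbering, initiator Met excluded)
#' at which at least one haloarchaeal Phr2 differs from the reference
#' cyanobacterial photolyase, with the residue observed in each strain and
#' the ligand class assigned to each position. Two provenance caveats are
#' documented in the fixture header (position 282's interaction label, and
#' the BOL3-1 residue at position 385) and travel with the object's
#' provenance field.
#'
#' @return A \linkS4class{VariantTable} with structural reference "SEL" and
#'   functional reference "NRC-1".
#' @examples
#' vt <- table2Fixture()
#' diffCounts(vt, "BOL5-1", "NRC-1")$total
#' @export
table2Fixture <- function() {
  path <- system.file("extdata", "table2_phr2_residues.tsv",
                      package = "phrscan", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, setdiff(names(tab), c("pos", "interaction"))])
  rownames(m) <- NULL
  new("VariantTable", positions = as.integer(tab$pos),
      interaction = tab$interaction, residues = m,
      structuralRef = "SEL", functionalRef = "NRC-1",
      provenance = "packaged fixture (published key-residue table)")
}

#' Build a cross-strain variant table from a contact shell and position maps
#'
#' Rows are contact-shell positions (reference numbering); the reference
#' column comes from the shell's residue identities and each strain column
#' from its position map. The interaction label per position is the ligand
#' of minimum distance in the shell (ties: the lexicographically first label
#' of the tied set, all tied labels recorded in provenance), or can be
#' overridden with an explicit annotation.
#'
#' @param shell A \linkS4class{ContactShell} on the reference structure.
#' @param maps Named list of \linkS4class{PositionMap} (reference to each
#'   strain), as from \code{\link{familyMaps}}.
#' @param refId Structural reference id (default "SEL").
#' @param functionalRef Strain used as phenotype comparison reference
#'   (default "NRC-1").
#' @param interactionOverride Optional data.frame \code{pos},
#'   \code{interaction} replacing the shell-derived labels.
#' @param variantOnly Keep only rows where at least one strain differs from
#'   the reference (default FALSE).
#' @return A \linkS4class{VariantTable}.
#' @export
buildVariantTable <- function(shell, maps, refId = "SEL",
                              functionalRef = "NRC-1",
                              interactionOverride = NULL,
                              variantOnly = FALSE) {
  if (is.null(names(maps)) || anyDuplicated(names(maps)))
    stop("maps must be a uniquely named list of PositionMap objects")
  e <- shellEntries(shell)
  if (!nrow(e)) stop("empty contact shell")
  pos <- sort(unique(e$pos))

  interaction <- vapply(pos, function(p) {
    sub <- e[e$pos == p, , drop = FALSE]
    sub$ligand[order(sub$min_distance_A, sub$ligand)][1L]
  }, character(1L))
  prov <- "interaction = ligand of minimum distance in contact shell"
  if (!is.null(interactionOverride)) {
    idx <- match(pos, interactionOverride$pos)
    interaction[!is.na(idx)] <-
      interactionOverride$interaction[idx[!is.na(idx)]]
    prov <- "interaction labels supplied by annotation override"
  }

  refAa <- vapply(pos, function(p) e$aa[e$pos == p][1L], character(1L))
  cols <- lapply(maps, function(pm) {
    hit <- mapPosition(pm, pos)
    ifelse(is.na(hit$query_pos) & hit$query_aa == "-", "-", hit$query_aa)
  })
  m <- cbind(refAa, do.call(cbind, cols))
  colnames(m) <- c(refId, names(maps))
  rownames(m) <- NULL

  if (variantOnly) {
    keep <- apply(m, 1L, function(r) any(r != r[[1L]]))
    m <- m[keep, , drop = FALSE]
    pos <- pos[keep]
    interaction <- interaction[keep]
  }
  new("VariantTable", positions = as.integer(pos),
      interaction = interaction, residues = m, structuralRef = refId,
      functionalRef = functionalRef, provenance = prov)
}

#' Rows of a variant table where any strain differs from the reference
#'
#' @param vt A \linkS4class{VariantTable}.
#' @param ref Reference column for flagging (default the structural
#'   reference).
#' @return Integer vector of variant positions (reference numbering).
#' @export
variantPositions <- function(vt, ref = vt@structuralRef) {
  m <- vt@residues
  if (!ref %in% colnames(m)) stop("unknown reference strain: ", ref)
  vt@positions[apply(m != m[, ref], 1L, any)]
}

#' Count residue differences between two strains of a variant table
#'
#' @param vt A \linkS4class{VariantTable}.
#' @param strain,vs Strain ids to compare (cells differing between the two
#'   columns are counted; \code{vs} is the "from" side of the reported
#'   substitution calls).
#' @return List with \code{total}, \code{byInteraction} (named integer
#'   vector over the table's ligand classes) and \code{calls}, a data.frame
#'   of \code{pos}, \code{from}, \code{to}, \code{notation} (e.g. "R50V"),
#'   \code{interaction}, \code{conservativeness}, \code{chargeChange} in
#'   position order.
#' @export
diffCounts <- function(vt, strain, vs) {
  m <- vt@residues
  for (id in c(strain, vs))
    if (!id %in% colnames(m)) stop("unknown strain id: ", id)
  diff <- m[, strain] != m[, vs]
  pos <- vt@positions[diff]
  from <- m[diff, vs]
  to <- m[diff, strain]
  cls <- classifySubstitution(from, to)
  calls <- data.frame(pos = pos, from = from, to = to,
                      notation = paste0(from, pos, to),
                      interaction = vt@interaction[diff],
                      conservativeness = as.character(cls),
                      chargeChange = attr(cls, "chargeChange"),
                      strain = rep(strain, sum(diff)),
                      stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  by <- table(factor(calls$interaction, levels = sort(unique(vt@interaction))))
  list(total = sum(diff), byInteraction = c(unclass(by)), calls = calls)
}

## Default physicochemical partition used to call a substitution
## conservative. The published analysis never defines "non-conservative";
## this partition reproduces its stated classifications (T/S conservative;
## K/E, R/V, D/N changes non-conservative).
DEFAULT_AA_CLASSES <- list(
  aliphatic = c("A", "G", "V", "L", "I", "P", "M"),
  aromatic = c("F", "W", "Y"),
  hydroxyl = c("S", "T"),
  amide = c("C", "N", "Q"),
  acidic = c("D", "E"),
  basic = c("K", "R", "H"))

#' Classify a residue substitution as identical, conservative or
#' non-conservative
#'
#' Conservative means both residues fall in the same physicochemical class
#' of the configured partition. The charge-change flag is set when the
#' substitution moves between the acidic and basic classes or between a
#' charged and an uncharged class.
#'
#' @param from,to One-letter residues (vectorized).
#' @param classes Partition of the 20 amino acids (list of character
#'   vectors); the default is documented in
#'   \code{phrscan:::DEFAULT_AA_CLASSES}.
#' @return Character vector ("identical"/"conservative"/"non-conservative")
#'   with attribute \code{chargeChange} (logical vector).
#' @examples
#' classifySubstitution("T", "S")  # conservative
#' classifySubstitution("K", "E")  # non-conservative, charge change
#' @export
classifySubstitution <- function(from, to, classes = DEFAULT_AA_CLASSES) {
  from <- toupper(from); to <- toupper(to)
  lookup <- unlist(lapply(names(classes), function(n)
    setNames(rep(n, length(classes[[n]])), classes[[n]])))
  valid <- c(names(lookup), "-")
  bad <- setdiff(c(from, to), valid)
  if (length(bad)) stop("invalid amino acid letter: ",
                        paste(unique(bad), collapse = ", "))
  cf <- lookup[from]; ct <- lookup[to]
  out <- ifelse(from == to, "identical",
                ifelse(!is.na(cf) & !is.na(ct) & cf == ct,
                       "conservative", "non-conservative"))
  charged <- c("acidic", "basic")
  cc <- (from != to) & (
    (!is.na(cf) & !is.na(ct) & cf %in% charged & ct %in% charged & cf != ct) |
      xor(!is.na(cf) & cf %in% charged, !is.na(ct) & ct %in% charged))
  attr(out, "chargeChange") <- unname(cc)
  out
}

#' Default integrity-score weights
#'
#' Penalties (positive numbers, subtracted from the score): per non-identical
#' substitution relative to the functional reference; an additional penalty
#' when the substitution is non-conservative at one of the
#' \code{\link{keyPositions}}; hydrogen-bond loss and weakening penalties
#' applied when substitution impacts are available; and a flat gene-absent
#' penalty large enough to rank a missing photolyase below any variant one.
#'
#' @return Named numeric vector.
#' @export
integrityWeights <- function()
  c(substitution = 1, nonConservativeKey = 1, hbondLost = 2,
    hbondWeakened = 1, geneAbsent = 50)

#' Photolyase integrity score per strain
#'
#' Formalizes "how intact is this strain's photolyase" as a weighted penalty
#' sum: the functional reference scores 0 (best); every penalty lowers the
#' score; a strain lacking the gene receives the flat gene-absent penalty.
#' The score is linear in the weights, so doubling every weight doubles
#' each strain's distance from the best score.
#'
#' @param vt A \linkS4class{VariantTable}.
#' @param impacts Optional named list of \linkS4class{SubstitutionImpact}
#'   (names = substitution notation, e.g. "R50V") supplying hydrogen-bond
#'   verdicts. When given, every non-identical call of every scored strain
#'   must be covered or an error is raised; when NULL, the hydrogen-bond
#'   terms are omitted (genotype-only scoring).
#' @param genePresent Named logical vector; strains absent from the variant
#'   table can still be scored here (FALSE = gene lost).
#' @param vs Functional reference strain (default from the table).
#' @param weights See \code{\link{integrityWeights}}.
#' @return Named numeric vector of scores (0 = best).
#' @export
integrityScore <- function(vt, impacts = NULL, genePresent = NULL,
                           vs = vt@functionalRef,
                           weights = integrityWeights()) {
  strains <- setdiff(colnames(vt@residues), vt@structuralRef)
  if (is.null(genePresent))
    genePresent <- setNames(rep(TRUE, length(strains)), strains)
  all <- union(strains, names(genePresent))
  key <- keyPositions()
  score <- setNames(numeric(length(all)), all)
  for (id in all) {
    present <- if (id %in% names(genePresent)) genePresent[[id]] else TRUE
    if (!isTRUE(present)) {
      score[id] <- -weights[["geneAbsent"]]
      next
    }
    if (!id %in% strains) stop("strain '", id, "' has no variant data")
    d <- diffCounts(vt, id, vs)
    pen <- weights[["substitution"]] * d$total +
      weights[["nonConservativeKey"]] *
        sum(d$calls$conservativeness == "non-conservative" &
              d$calls$pos %in% key)
    if (!is.null(impacts)) {
      missing <- setdiff(d$calls$notation, names(impacts))
      if (length(missing))
        stop("missing substitution impact for: ",
             paste(missing, collapse = ", "))
      verdicts <- vapply(d$calls$notation,
                         function(n) impacts[[n]]@verdict, character(1L))
      pen <- pen + weights[["hbondLost"]] * sum(verdicts == "loss") +
        weights[["hbondWeakened"]] * sum(verdicts == "weakened")
    }
    score[id] <- -pen
  }
  score
}

`%||%` <- function(a, b) if (is.null(a)) b else a
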