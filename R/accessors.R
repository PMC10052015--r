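# Accessors and show methods for the core containers.

#' Atom table of a structure model
#'
#' @param x A \linkS4class{StructureModel}.
#' @return data.frame of atoms.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "StructureModel", function(x) x@atoms)

#' Entries of a contact shell
#'
#' @param x A \linkS4class{ContactShell}.
#' @return data.frame with one row per (residue, ligand) contact.
#' @export
setGeneric("shellEntries", function(x) standardGeneric("shellEntries"))

#' @rdname shellEntries
#' @export
setMethod("shellEntries", "ContactShell", function(x) x@entries)

#' Percent-survival table of a survival dataset
#'
#' @param x A \linkS4class{SurvivalDataset}.
#' @return data.frame strain/condition/dose/percent/censored.
#' @export
setGeneric("survivalCurves", function(x) standardGeneric("survivalCurves"))

#' @rdname survivalCurves
#' @export
setMethod("survivalCurves", "SurvivalDataset", function(x) x@survival)

#' Gene table of a neighborhood
#'
#' @param x A \linkS4class{GeneNeighborhood}.
#' @return data.frame of genes.
#' @export
setGeneric("neighborhoodGenes", function(x) standardGeneric("neighborhoodGenes"))

#' @rdname neighborhoodGenes
#' @export
setMethod("neighborhoodGenes", "GeneNeighborhood", function(x) x@genes)

#' Residue matrix of a variant table
#'
#' @param x A \linkS4class{VariantTable}.
#' @return character matrix, positions x strains.
#' @export
setGeneric("variantResidues", function(x) standardGeneric("variantResidues"))

#' @rdname variantResidues
#' @export
setMethod("variantResidues", "VariantTable", function(x) {
  m <- x@residues
  rownames(m) <- x@positions
  m
})

#' Strain identifiers of a variant table
#'
#' @param x A \linkS4class{VariantTable}.
#' @return character vector of strain ids (columns).
#' @export
setGeneric("strainIds", function(x) standardGeneric("strainIds"))

#' @rdname strainIds
#' @export
setMethod("strainIds", "VariantTable", function(x) colnames(x@residues))

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno, a$insert))), "residues,",
      length(object@chains), "chain(s)\n")
  cat("  entities:",
      paste(names(table(a$entity)), table(a$entity), collapse = ", "), "\n")
  cat("  source:", object@source, "\n")
})

setMethod("show", "LigandGroup", function(object) {
  cat("LigandGroup", object@label, "-", nrow(object@residues),
      "residue(s),", length(object@atomIdx), "atoms\n")
})

setMethod("show", "ContactShell", function(object) {
  cat("ContactShell: threshold", object@threshold, "A,",
      nrow(object@entries), "entries,", object@unionCount,
      "distinct residues (", object@atomScope, ")\n")
})

setMethod("show", "AlignmentPair", function(object) {
  cat("AlignmentPair", object@refId, "vs", object@queryId,
      sprintf("- score %.1f, identity %.1f%%, %d columns\n",
              object@score, object@percentIdentity,
              nchar(object@alignedRef)))
})

setMethod("show", "PositionMap", function(object) {
  cat("PositionMap", object@refId, "->", object@queryId, ":",
      nrow(object@table), "reference positions,",
      sum(is.na(object@table$query_pos)), "gapped\n")
})

setMethod("show", "VariantTable", function(object) {
  cat("VariantTable:", length(object@positions), "positions x",
      ncol(object@residues), "strains; structural ref",
      object@structuralRef, "; functional ref", object@functionalRef, "\n")
})

setMethod("show", "SubstitutionImpact", function(object) {
  cat("SubstitutionImpact", object@call, "->", object@verdict,
      if (length(object@partners)) paste0("(", paste(object@partners,
                                                     collapse = ","), ")"),
      "\n")
})

setMethod("show", "SurvivalDataset", function(object) {
  s <- object@survival
  cat("SurvivalDataset:", length(unique(s$strain)), "strain(s),",
      length(unique(s$dose)), "dose(s),",
      paste(unique(s$condition), collapse = "/"), "\n")
})

setMethod("show", "GeneNeighborhood", function(object) {
  cat("GeneNeighborhood", object@strain, "-", nrow(object@genes),
      "genes; anchor", object@anchor,
      if (object@anchor %in% object@genes$label) "(present)" else "(ABSENT)",
      "\n")
})
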