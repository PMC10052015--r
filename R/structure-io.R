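#' Read a macromolecular structure from a PDB file
#'
#' Parses a PDB file (via \pkg{bio3d}), selects one model, resolves
#' alternate locations and classifies each residue into an entity class:
#' protein, nucleic, cofactor, ion or water. Nonstandard residue names for
#' modified nucleotides (such as a cyclobutane pyrimidine dimer analog in a
#' photolyase-DNA co-crystal) are not hard-coded; declare them with
#' \code{nucleicExtra}.
#'
#' @param path Path to a PDB file.
#' @param modelIndex Model to extract from a multi-model file (default 1).
#' @param altlocPolicy How to resolve alternate locations: "occupancy"
#'   keeps the highest-occupancy conformer (ties broken alphabetically by
#'   alt-loc id), "first" keeps the first conformer encountered.
#' @param keepWaters Keep water molecules (default FALSE).
#' @param nucleicExtra Character vector of additional residue names to class
#'   as nucleic (e.g. names used for a thymine-dimer analog).
#'
#' @return A \linkS4class{StructureModel}.
#' @examples
#' pdb <- system.file("examples", "1hel.pdb", package = "bio3d")
#' s <- readStructure(pdb)
#' s
#' @export
readStructure <- function(path, modelIndex = 1L,
                          altlocPolicy = c("occupancy", "first"),
                          keepWaters = FALSE, nucleicExtra = character()) {
  altlocPolicy <- match.arg(altlocPolicy)
  if (!file.exists(path)) stop("structure file not found: ", path)
  multi <- modelIndex > 1L
  pdb <- bio3d::read.pdb(path, multi = multi, verbose = FALSE)
  a <- pdb$atom
  if (multi) {
    if (is.null(dim(pdb$xyz)) || nrow(pdb$xyz) < modelIndex)
      stop("model index ", modelIndex, " not present (",
           if (is.null(dim(pdb$xyz))) 1L else nrow(pdb$xyz), " models)")
    xyz <- matrix(pdb$xyz[modelIndex, ], ncol = 3L, byrow = TRUE)
    a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
  }
  if (nrow(a) == 0L) stop("no atoms in ", path)
  structureFromAtoms(a, source = path, altlocPolicy = altlocPolicy,
                     keepWaters = keepWaters, nucleicExtra = nucleicExtra)
}

## Build a StructureModel from a bio3d-style atom data.frame.
structureFromAtoms <- function(a, source = "memory",
                               altlocPolicy = "occupancy",
                               keepWaters = FALSE,
                               nucleicExtra = character()) {
  a$alt[is.na(a$alt)] <- ""
  a$insert[is.na(a$insert)] <- ""
  a$chain[is.na(a$chain)] <- " "
  a$o[is.na(a$o)] <- 1
  if (is.null(a$elesy) || all(is.na(a$elesy)) || all(a$elesy == "")) {
    a$elesy <- guessElement(a$elety)
  } else {
    miss <- is.na(a$elesy) | a$elesy == ""
    a$elesy[miss] <- guessElement(a$elety[miss])
  }

  key <- paste(a$chain, a$resno, a$insert, a$elety)
  if (anyDuplicated(key)) {
    keep <- logical(nrow(a))
    for (idx in split(seq_len(nrow(a)), key)) {
      if (length(idx) == 1L) { keep[idx] <- TRUE; next }
      if (altlocPolicy == "first") {
        keep[idx[1L]] <- TRUE
      } else {
        o <- a$o[idx]
        best <- idx[o == max(o)]
        keep[best[order(a$alt[best])][1L]] <- TRUE
      }
    }
    a <- a[keep, , drop = FALSE]
  }

  resid <- toupper(a$resid)
  entity <- rep("cofactor", nrow(a))
  entity[resid %in% names(AA3)] <- "protein"
  entity[resid %in% c(NUCLEIC_RESID, toupper(nucleicExtra))] <- "nucleic"
  entity[resid %in% ION_RESID & a$elety %in% ION_RESID] <- "ion"
  entity[resid %in% WATER_RESID] <- "water"

  atoms <- data.frame(eleno = a$eleno, elety = a$elety,
                      element = toupper(a$elesy), resid = resid,
                      resno = a$resno, chain = a$chain, insert = a$insert,
                      x = a$x, y = a$y, z = a$z, o = a$o, alt = a$alt,
                      entity = entity, stringsAsFactors = FALSE)
  if (!keepWaters) atoms <- atoms[atoms$entity != "water", , drop = FALSE]
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms, chains = unique(atoms$chain),
      source = source)
}

guessElement <- function(elety) {
  e <- sub("^[0-9]+", "", trimws(elety))
  two <- toupper(substr(e, 1L, 2L))
  out <- toupper(substr(e, 1L, 1L))
  out[two %in% c("CL", "BR", "FE", "MG", "ZN", "MN", "NA", "SE")] <-
    two[two %in% c("CL", "BR", "FE", "MG", "ZN", "MN", "NA", "SE")]
  out
}

#' Write a structure model to a PDB file
#'
#' @param s A \linkS4class{StructureModel}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(s, path) {
  a <- atoms(s)
  het <- a$entity %in% c("cofactor", "ion", "water")
  bio3d::write.pdb(file = path,
                   type = ifelse(het, "HETATM", "ATOM"),
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   resid = a$resid, chain = a$chain, resno = a$resno,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   o = a$o, b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

#' Group ligand atoms of a structure into labelled ligand groups
#'
#' Pools all nucleic-entity residues into one DNA group and creates one
#' group per matched cofactor residue name. Groups are disjoint by
#' construction (an atom is either nucleic or a cofactor heteroatom).
#'
#' @param s A \linkS4class{StructureModel}.
#' @param cofactors Named character vector or list mapping group label to
#'   residue name(s), e.g. \code{c(FAD = "FAD", HDF = "HDF")}. An
#'   explicitly requested label whose residue names are absent from the
#'   structure raises an error listing the heteroresidues actually present;
#'   with the default map, absent cofactors are simply skipped.
#' @param dnaLabel Label for the pooled nucleic group (default "DNA").
#' @param includeIons Include monoatomic ions as a group (default FALSE;
#'   ions are otherwise ignored).
#'
#' @return A list of \linkS4class{LigandGroup} objects. Empty (with a
#'   warning) for a protein-only structure when no cofactors are requested
#'   or present.
#' @export
classifyLigands <- function(s, cofactors = c(FAD = "FAD", HDF = "HDF"),
                            dnaLabel = "DNA", includeIons = FALSE) {
  requireAll <- !missing(cofactors)
  a <- atoms(s)
  groups <- list()

  nuc <- which(a$entity == "nucleic")
  if (length(nuc)) {
    res <- unique(a[nuc, c("chain", "resno", "resid")])
    rownames(res) <- NULL
    groups[[dnaLabel]] <- new("LigandGroup", label = dnaLabel,
                              residues = res, atomIdx = nuc)
  }

  hetResid <- unique(a$resid[a$entity == "cofactor"])
  for (label in names(cofactors)) {
    wanted <- toupper(unlist(cofactors[[label]]))
    idx <- which(a$entity == "cofactor" & a$resid %in% wanted)
    if (!length(idx)) {
      if (!requireAll) next
      stop("cofactor '", label, "' (residue name ",
           paste(wanted, collapse = "/"), ") not found; heteroresidues ",
           "present: ",
           if (length(hetResid)) paste(hetResid, collapse = ", ")
           else "none")
    }
    res <- unique(a[idx, c("chain", "resno", "resid")])
    rownames(res) <- NULL
    groups[[label]] <- new("LigandGroup", label = label,
                           residues = res, atomIdx = idx)
  }

  if (includeIons) {
    idx <- which(a$entity == "ion")
    if (length(idx)) {
      res <- unique(a[idx, c("chain", "resno", "resid")])
      rownames(res) <- NULL
      groups[["ION"]] <- new("LigandGroup", label = "ION",
                             residues = res, atomIdx = idx)
    }
  }

  if (!length(groups))
    warning("no ligand groups found (protein-only structure?)")
  groups
}
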