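#' @import methods
NULL

#' Parsed macromolecular structure model
#'
#' One model from a PDB file after alt-loc resolution, with every atom
#' assigned to an entity class (protein, nucleic, cofactor, ion or water).
#'
#' @slot atoms data.frame with one row per atom: \code{eleno}, \code{elety}
#'   (atom name), \code{element}, \code{resid} (residue name), \code{resno},
#'   \code{chain}, \code{insert}, \code{x}, \code{y}, \code{z}, \code{o}
#'   (occupancy), \code{alt}, \code{entity}.
#' @slot chains character, chain identifiers in file order.
#' @slot source character, provenance of the model (file path or generator).
#'
#' @exportClass StructureModel
setClass("StructureModel",
  representation(atoms = "data.frame", chains = "character",
                 source = "character"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("eleno", "elety", "element", "resid", "resno", "chain",
            "insert", "x", "y", "z", "o", "alt", "entity")
  if (!all(need %in% names(a)))
    return(paste("atoms lacks columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) && !all(is.finite(c(a$x, a$y, a$z))))
    return("non-finite coordinates")
  key <- paste(a$chain, a$resno, a$insert, a$elety)
  if (anyDuplicated(key))
    return("duplicate atom after alt-loc resolution (chain/resno/icode/name)")
  if (!all(a$entity %in% c("protein", "nucleic", "cofactor", "ion", "water")))
    return("unknown entity class")
  TRUE
})

#' Ligand group of a structure
#'
#' A labelled set of heteroatoms or nucleic-acid residues used as one side of
#' contact-shell and hydrogen-bond calculations (e.g. the pooled DNA duplex,
#' or the FAD or HDF cofactor).
#'
#' @slot label character scalar, e.g. "DNA", "FAD", "HDF".
#' @slot residues data.frame with columns \code{chain}, \code{resno},
#'   \code{resid}.
#' @slot atomIdx integer indices into the atom table of the parent
#'   \linkS4class{StructureModel}.
#'
#' @exportClass LigandGroup
setClass("LigandGroup",
  representation(label = "character", residues = "data.frame",
                 atomIdx = "integer"))

#' Contact shell of protein residues around ligand groups
#'
#' @slot threshold numeric, distance cutoff in Angstrom.
#' @slot atomScope character, "all-heavy" or "side-chain-heavy".
#' @slot entries data.frame: \code{pos} (reference numbering), \code{aa},
#'   \code{ligand}, \code{min_distance_A}, \code{atom_i} (protein atom name),
#'   \code{atom_j} (ligand atom name), \code{chain}, \code{resno}.
#' @slot unionCount integer, number of distinct residues in at least one shell.
#'
#' @exportClass ContactShell
setClass("ContactShell",
  representation(threshold = "numeric", atomScope = "character",
                 entries = "data.frame", unionCount = "integer"))

setValidity("ContactShell", function(object) {
  e <- object@entries
  if (nrow(e)) {
    if (any(e$min_distance_A > object@threshold + 1e-9))
      return("entry distance exceeds threshold")
    if (anyDuplicated(paste(e$pos, e$ligand)))
      return("duplicate (position, ligand) entry")
  }
  TRUE
})

#' Pairwise global alignment of a homolog against the reference
#'
#' @slot refId,queryId character, record identifiers.
#' @slot alignedRef,alignedQuery character, gapped aligned strings of equal
#'   length ('-' for gaps, never gap against gap).
#' @slot score numeric, alignment score.
#' @slot matrix character, substitution matrix name.
#' @slot gapOpening,gapExtension numeric, affine gap penalties.
#' @slot percentIdentity numeric, identical columns / aligned columns.
#'
#' @exportClass AlignmentPair
setClass("AlignmentPair",
  representation(refId = "character", queryId = "character",
                 alignedRef = "character", alignedQuery = "character",
                 score = "numeric", matrix = "character",
                 gapOpening = "numeric", gapExtension = "numeric",
                 percentIdentity = "numeric"))

setValidity("AlignmentPair", function(object) {
  a <- object@alignedRef; b <- object@alignedQuery
  if (nchar(a) != nchar(b)) return("aligned strings differ in length")
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  if (any(ca == "-" & cb == "-")) return("gap aligned against gap")
  TRUE
})

#' Residue position map between reference and query numbering
#'
#' Positions are in biological numbering: reference positions exclude the
#' initiator methionine when \code{refOffset} is 1 (and likewise for the
#' query), mirroring the SEL photolyase numbering convention.
#'
#' @slot refId,queryId character.
#' @slot table data.frame: \code{ref_pos}, \code{ref_aa}, \code{query_pos}
#'   (NA when the reference position is deleted in the query), \code{query_aa}
#'   ("-" when gapped).
#' @slot refOffset,queryOffset integer, 1 when the underlying sequence carries
#'   an initiator Met excluded from numbering, else 0.
#'
#' @exportClass PositionMap
setClass("PositionMap",
  representation(refId = "character", queryId = "character",
                 table = "data.frame", refOffset = "integer",
                 queryOffset = "integer"))

#' Cross-strain variant table at contact-shell positions
#'
#' The computational analogue of a published key-residue table: rows are
#' reference-numbered positions, columns are strains, cells are one-letter
#' residues (or "-" for a gap).
#'
#' @slot positions integer, reference numbering, ascending.
#' @slot interaction character, ligand class per position (HDF/DNA/FAD).
#' @slot residues matrix (character), positions x strains.
#' @slot structuralRef character, strain id used for variant flagging (SEL).
#' @slot functionalRef character, strain id used for phenotype comparisons
#'   (NRC-1).
#' @slot provenance character, where the interaction labels came from.
#'
#' @exportClass VariantTable
setClass("VariantTable",
  representation(positions = "integer", interaction = "character",
                 residues = "matrix", structuralRef = "character",
                 functionalRef = "character", provenance = "character"))

setValidity("VariantTable", function(object) {
  if (length(object@positions) != nrow(object@residues))
    return("positions and residue rows disagree")
  if (length(object@interaction) != length(object@positions))
    return("one interaction label required per position")
  if (is.unsorted(object@positions, strictly = TRUE))
    return("positions must be strictly ascending")
  if (!all(object@residues %in% c(LETTERS, "-")))
    return("cells must be one-letter residues or '-'")
  if (!object@structuralRef %in% colnames(object@residues))
    return("structural reference strain missing from columns")
  TRUE
})

#' Impact of a single residue substitution on hydrogen bonding
#'
#' @slot call character, substitution in from-position-to notation (e.g.
#'   "R50V").
#' @slot strain character, strain carrying the substitution (may be NA).
#' @slot before,after data.frame of hydrogen bonds (see
#'   \code{\link{detectHbonds}}) for the wild-type and modeled residue.
#' @slot verdict character, one of gain, loss, weakened, strengthened,
#'   unchanged, mixed.
#' @slot partners character, ligand labels whose bonding changed.
#'
#' @exportClass SubstitutionImpact
setClass("SubstitutionImpact",
  representation(call = "character", strain = "character",
                 before = "data.frame", after = "data.frame",
                 verdict = "character", partners = "character"))

#' UV dose-response survival dataset
#'
#' Raw colony counts plus derived percent survival per strain, light/dark
#' condition and dose.
#'
#' @slot raw data.frame: \code{strain}, \code{condition} ("light"/"dark"),
#'   \code{dose}, \code{replicate}, \code{dilution}, \code{cfu}.
#' @slot survival data.frame: \code{strain}, \code{condition}, \code{dose},
#'   \code{percent}, \code{censored} (TRUE when the zero-count detection
#'   floor was applied).
#'
#' @exportClass SurvivalDataset
setClass("SurvivalDataset",
  representation(raw = "data.frame", survival = "data.frame"))

setValidity("SurvivalDataset", function(object) {
  r <- object@raw
  if (any(r$dose < 0)) return("negative dose")
  if (any(r$cfu < 0)) return("negative CFU count")
  s <- object@survival
  z <- s[s$dose == 0, ]
  if (nrow(z) && any(abs(z$percent - 100) > 1e-9))
    return("percent survival at dose 0 must be 100")
  TRUE
})

#' Gene neighborhood around an anchor gene
#'
#' @slot strain character.
#' @slot genes data.frame: \code{id}, \code{label}, \code{start}, \code{end}
#'   (1-based inclusive), \code{strand} ("+"/"-"), sorted by start.
#' @slot anchor character, anchor gene label (presence is not required; an
#'   absent anchor models gene loss).
#' @slot segments data.frame of declared homologous segments (\code{name},
#'   \code{start}, \code{end}) used for coordinate-level indel detection;
#'   may be empty.
#'
#' @exportClass GeneNeighborhood
setClass("GeneNeighborhood",
  representation(strain = "character", genes = "data.frame",
                 anchor = "character", segments = "data.frame"))

setValidity("GeneNeighborhood", function(object) {
  g <- object@genes
  if (!all(c("id", "label", "start", "end", "strand") %in% names(g)))
    return("genes needs columns id, label, start, end, strand")
  if (nrow(g)) {
    if (any(g$start > g$end)) return("gene start > end")
    if (is.unsorted(g$start)) return("genes must be sorted by start")
    if (!all(g$strand %in% c("+", "-"))) return("strand must be + or -")
  }
  TRUE
})
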