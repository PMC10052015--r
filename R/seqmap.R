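#' Global pairwise alignment of a homolog against the reference
#'
#' Needleman-Wunsch global alignment with affine gap penalties, computed
#' with \pkg{Biostrings}. The alignment score equals the exhaustive optimum
#' over all global alignments under the convention that a gap of length L
#' costs \code{gapOpening + L * gapExtension}.
#'
#' @param ref,query Named character scalars (names are used as record ids)
#'   or plain strings of one-letter amino acids.
#' @param matrix Substitution matrix: the name of a matrix shipped with
#'   \pkg{Biostrings} (default "BLOSUM62") or a numeric matrix.
#' @param gapOpening,gapExtension Affine gap penalties (defaults 10 and 1).
#'
#' @return An \linkS4class{AlignmentPair}. Percent identity is defined as
#'   identical columns divided by aligned columns (no column is gap/gap in a
#'   pairwise global alignment); this definition is fixed here because
#'   published identity percentages rarely state one.
#' @examples
#' globalAlign(c(A = "HEAGAWGHEE"), c(B = "PAWHEAE"))
#' @export
globalAlign <- function(ref, query, matrix = "BLOSUM62",
                        gapOpening = 10, gapExtension = 1) {
  refId <- if (!is.null(names(ref))) names(ref)[1L] else "ref"
  queryId <- if (!is.null(names(query))) names(query)[1L] else "query"
  ref <- toupper(unname(ref[1L])); query <- toupper(unname(query[1L]))
  if (!nzchar(ref) || !nzchar(query)) stop("empty sequence")
  if (is.character(matrix)) {
    matName <- matrix
    matrix <- getSubstitutionMatrix(matrix)
  } else matName <- "custom"
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref), Biostrings::AAString(query),
    substitutionMatrix = matrix, gapOpening = gapOpening,
    gapExtension = gapExtension, type = "global")
  ar <- as.character(Biostrings::alignedPattern(pa))
  aq <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(ar, "")[[1L]]; cb <- strsplit(aq, "")[[1L]]
  pid <- 100 * sum(ca == cb & ca != "-") / length(ca)
  new("AlignmentPair", refId = refId, queryId = queryId,
      alignedRef = ar, alignedQuery = aq, score = Biostrings::score(pa),
      matrix = matName, gapOpening = gapOpening,
      gapExtension = gapExtension, percentIdentity = pid)
}

getSubstitutionMatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Percent identity of an alignment pair
#'
#' @param ap An \linkS4class{AlignmentPair}.
#' @return Numeric scalar in [0, 100].
#' @export
percentIdentity <- function(ap) ap@percentIdentity

#' Pairwise percent-identity matrix for a set of sequences
#'
#' @param seqs Named character vector of protein sequences (ids must be
#'   unique).
#' @param ... Passed to \code{\link{globalAlign}}.
#' @return Symmetric numeric matrix with 100 on the diagonal.
#' @export
identityMatrix <- function(seqs, ...) {
  if (length(seqs) < 2L) stop("need at least two sequences")
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids)) stop("sequences need unique names")
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    # canonical pair order so the matrix is permutation-equivariant
    pair <- if (ids[i] <= ids[j]) c(i, j) else c(j, i)
    pid <- percentIdentity(globalAlign(seqs[pair[1L]], seqs[pair[2L]], ...))
    m[i, j] <- pid; m[j, i] <- pid
  }
  m
}

#' Residue-position map between reference and query numbering
#'
#' Builds the bidirectional position map implied by a pairwise global
#' alignment, in biological (offset-corrected) numbering. An offset of 1
#' means the record's FASTA sequence begins with an initiator methionine
#' that is excluded from the numbering frame, mirroring the reference
#' photolyase convention; position 1 then refers to the second FASTA
#' residue.
#'
#' @param ap An \linkS4class{AlignmentPair}.
#' @param refOffset,queryOffset Integer numbering offsets (0 or 1).
#' @return A \linkS4class{PositionMap}.
#' @export
positionMap <- function(ap, refOffset = 0L, queryOffset = 0L) {
  ca <- strsplit(ap@alignedRef, "")[[1L]]
  cb <- strsplit(ap@alignedQuery, "")[[1L]]
  rpos <- cumsum(ca != "-")          # 1-based FASTA positions
  qpos <- cumsum(cb != "-")
  keep <- ca != "-"
  refNum <- rpos[keep] - refOffset   # biological numbering
  queryNum <- ifelse(cb[keep] == "-", NA_integer_,
                     qpos[keep] - queryOffset)
  tab <- data.frame(ref_pos = refNum, ref_aa = ca[keep],
                    query_pos = queryNum, query_aa = cb[keep],
                    stringsAsFactors = FALSE)
  tab <- tab[tab$ref_pos >= 1L, , drop = FALSE]
  # a residue aligned to the query's excluded initiator Met has no number
  tab$query_pos[!is.na(tab$query_pos) & tab$query_pos < 1L] <- NA_integer_
  rownames(tab) <- NULL
  new("PositionMap", refId = ap@refId, queryId = ap@queryId, table = tab,
      refOffset = as.integer(refOffset), queryOffset = as.integer(queryOffset))
}

#' Map a reference-numbered position into a query sequence
#'
#' @param pm A \linkS4class{PositionMap}.
#' @param refPos Reference-numbered position (scalar or vector).
#' @return data.frame with columns \code{ref_pos}, \code{ref_aa},
#'   \code{query_pos} (NA when the position is gapped in the query) and
#'   \code{query_aa} ("-" when gapped).
#' @export
mapPosition <- function(pm, refPos) {
  tab <- pm@table
  idx <- match(refPos, tab$ref_pos)
  if (anyNA(idx))
    stop("position(s) out of reference range: ",
         paste(refPos[is.na(idx)], collapse = ", "))
  out <- tab[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Invert a position map
#'
#' @param pm A \linkS4class{PositionMap}.
#' @return A \linkS4class{PositionMap} from query to reference numbering.
#' @export
invertMap <- function(pm) {
  tab <- pm@table
  mapped <- tab[!is.na(tab$query_pos), , drop = FALSE]
  inv <- data.frame(ref_pos = mapped$query_pos, ref_aa = mapped$query_aa,
                    query_pos = mapped$ref_pos, query_aa = mapped$ref_aa,
                    stringsAsFactors = FALSE)
  inv <- inv[order(inv$ref_pos), , drop = FALSE]
  rownames(inv) <- NULL
  new("PositionMap", refId = pm@queryId, queryId = pm@refId, table = inv,
      refOffset = pm@queryOffset, queryOffset = pm@refOffset)
}

#' Position maps for a family of homologs against one reference
#'
#' @param seqs Named character vector of protein sequences including the
#'   reference.
#' @param refId Name of the reference record.
#' @param offsets Named integer vector of numbering offsets (default 0 for
#'   every record); see \code{\link{positionMap}}.
#' @param ... Passed to \code{\link{globalAlign}}.
#' @return Named list of \linkS4class{PositionMap}, one per non-reference
#'   record.
#' @export
familyMaps <- function(seqs, refId, offsets = NULL, ...) {
  if (!refId %in% names(seqs)) stop("reference '", refId, "' not in seqs")
  if (is.null(offsets)) offsets <- setNames(rep(0L, length(seqs)), names(seqs))
  others <- setdiff(names(seqs), refId)
  maps <- lapply(others, function(id) {
    positionMap(globalAlign(seqs[refId], seqs[id], ...),
                refOffset = offsets[[refId]], queryOffset = offsets[[id]])
  })
  names(maps) <- others
  maps
}
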