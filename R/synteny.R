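#' Construct a gene neighborhood
#'
#' @param strain Strain id.
#' @param genes data.frame with columns \code{id}, \code{label},
#'   \code{start}, \code{end} (1-based inclusive), \code{strand}
#'   ("+"/"-"); rows are sorted by start.
#' @param anchor Anchor gene label (default "phr2"); it need not be present
#'   (an absent anchor models gene loss).
#' @param segments Optional data.frame (\code{name}, \code{start},
#'   \code{end}) of declared homologous segments used by
#'   \code{\link{indelDetect}}.
#' @return A \linkS4class{GeneNeighborhood}.
#' @export
geneNeighborhood <- function(strain, genes, anchor = "phr2",
                             segments = NULL) {
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  if (is.null(segments))
    segments <- data.frame(name = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
  new("GeneNeighborhood", strain = strain, genes = genes, anchor = anchor,
      segments = segments)
}

#' Read a gene neighborhood from TSV or GFF3
#'
#' The native format is a 6-column TSV (\code{id}, \code{label},
#' \code{start}, \code{end}, \code{strand}, optional \code{segment});
#' GFF3 gene features (with a \code{label} or \code{Name} attribute) are
#' supported through \pkg{rtracklayer} when installed.
#'
#' @param path File path (.tsv/.txt or .gff3/.gff).
#' @param strain Strain id (default: file base name).
#' @param anchor Anchor gene label (default "phr2").
#' @return A \linkS4class{GeneNeighborhood}.
#' @export
readNeighborhood <- function(path, strain = NULL, anchor = "phr2") {
  if (is.null(strain))
    strain <- tools::file_path_sans_ext(basename(path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    md <- as.data.frame(gr)
    lab <- if ("label" %in% names(md)) md$label else md$Name
    genes <- data.frame(id = if ("ID" %in% names(md)) md$ID else lab,
                        label = lab, start = md$start, end = md$end,
                        strand = as.character(md$strand),
                        stringsAsFactors = FALSE)
  } else {
    genes <- utils::read.delim(path, comment.char = "#",
                               stringsAsFactors = FALSE)
  }
  seg <- NULL
  if ("segment" %in% names(genes)) {
    segRows <- genes[genes$segment %in% c(TRUE, "TRUE", "yes"), ]
    if (nrow(segRows))
      seg <- data.frame(name = segRows$id, start = segRows$start,
                        end = segRows$end, stringsAsFactors = FALSE)
    genes <- genes[!genes$segment %in% c(TRUE, "TRUE", "yes"),
                   setdiff(names(genes), "segment")]
  }
  geneNeighborhood(strain, genes, anchor, seg)
}

## Longest common subsequence length over label+strand tokens.
lcsLength <- function(a, b) {
  n <- length(a); m <- length(b)
  if (!n || !m) return(0L)
  prev <- integer(m + 1L)
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    for (j in seq_len(m))
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
                     else max(cur[j], prev[j + 1L])
    prev <- cur
  }
  prev[m + 1L]
}

revcompTokens <- function(labels, strands)
  list(labels = rev(labels),
       strands = rev(ifelse(strands == "+", "-", "+")))

#' Synteny score and report for two gene neighborhoods
#'
#' Order conservation is the length of the longest common subsequence of
#' (functional label, strand) tokens, normalized by the longer neighborhood.
#' A neighborhood and its reverse complement are equivalent: the better of
#' the forward and reverse-complement comparisons is taken, so the score is
#' 1 exactly when the label sequences (including strands) are identical up
#' to reverse complement. Homology is label-based (functional annotation
#' equivalence classes), not sequence-based.
#'
#' @param a,b \linkS4class{GeneNeighborhood} objects.
#' @return List: \code{score} in [0,1], \code{lcs}, \code{sharedLabels}
#'   (count of distinct labels in both), \code{anchorPresent} (named logical
#'   for both strains), \code{orientation} ("forward"/"revcomp").
#' @export
syntenyScore <- function(a, b) {
  ga <- neighborhoodGenes(a); gb <- neighborhoodGenes(b)
  if (!nrow(ga) || !nrow(gb)) stop("empty neighborhood")
  ta <- paste(ga$label, ga$strand)
  tbF <- paste(gb$label, gb$strand)
  rc <- revcompTokens(gb$label, gb$strand)
  tbR <- paste(rc$labels, rc$strands)
  lf <- lcsLength(ta, tbF)
  lr <- lcsLength(ta, tbR)
  lcs <- max(lf, lr)
  list(score = lcs / max(length(ta), length(tbF)),
       lcs = lcs,
       sharedLabels = length(intersect(ga$label, gb$label)),
       anchorPresent = setNames(c(a@anchor %in% ga$label,
                                  b@anchor %in% gb$label),
                                c(a@strain, b@strain)),
       orientation = if (lf >= lr) "forward" else "revcomp")
}

#' Genes between the anchor and another labelled gene
#'
#' @param n A \linkS4class{GeneNeighborhood}.
#' @param anchor Anchor label (default the neighborhood's anchor).
#' @param other Second label.
#' @return List: \code{absent} (TRUE with \code{missing} naming the absent
#'   label(s) when either is not in the neighborhood - gene loss is a
#'   result, not an exception) or \code{between}, the ordered data.frame of
#'   intervening genes (exclusive).
#' @export
anchorContext <- function(n, anchor = n@anchor, other) {
  g <- neighborhoodGenes(n)
  missing <- setdiff(c(anchor, other), g$label)
  if (length(missing))
    return(list(absent = TRUE, missing = missing))
  i <- which(g$label == anchor)[1L]
  j <- which(g$label == other)[1L]
  lo <- min(i, j); hi <- max(i, j)
  between <- if (hi - lo <= 1L) g[0L, ] else g[(lo + 1L):(hi - 1L), ]
  rownames(between) <- NULL
  list(absent = FALSE, between = between)
}

#' Detect insertions and deletions between two homologous regions
#'
#' Compares the region between two shared flanking genes. When declared
#' homologous segments are available (see
#' \code{\link{geneNeighborhood}}), segments present in \code{a} but absent
#' from \code{b} are reported as deletions (and the reverse as insertions),
#' each with its exact length in bp; shared segments of unequal length
#' contribute the length difference. Without segment annotations, the net
#' difference of the inter-flank spans is reported as a single indel.
#'
#' @param a,b \linkS4class{GeneNeighborhood} objects.
#' @param flanks Character vector of two gene labels present in both
#'   neighborhoods.
#' @return data.frame \code{type} ("deletion"/"insertion"; relative to
#'   \code{a}, i.e. a deletion means \code{b} lacks the sequence),
#'   \code{length_bp}, \code{segment}. Zero rows when the spans agree.
#' @export
indelDetect <- function(a, b, flanks) {
  stopifnot(length(flanks) == 2L)
  ga <- neighborhoodGenes(a); gb <- neighborhoodGenes(b)
  if (!all(flanks %in% ga$label) || !all(flanks %in% gb$label))
    stop("flanking genes not shared: ",
         paste(setdiff(flanks, intersect(ga$label, gb$label)),
               collapse = ", "))
  span <- function(g) {
    i <- range(c(which(g$label == flanks[1L])[1L],
                 which(g$label == flanks[2L])[1L]))
    c(lo = g$end[i[1L]], hi = g$start[i[2L]])
  }
  sa <- span(ga); sb <- span(gb)

  segA <- a@segments; segB <- b@segments
  inSpan <- function(seg, sp)
    seg[seg$start >= sp["lo"] & seg$end <= sp["hi"], , drop = FALSE]
  if (nrow(segA) || nrow(segB)) {
    segA <- inSpan(segA, sa); segB <- inSpan(segB, sb)
    out <- list()
    for (nm in union(segA$name, segB$name)) {
      la <- if (nm %in% segA$name)
        segA$end[segA$name == nm] - segA$start[segA$name == nm] + 1L else 0L
      lb <- if (nm %in% segB$name)
        segB$end[segB$name == nm] - segB$start[segB$name == nm] + 1L else 0L
      if (la == lb) next
      out[[length(out) + 1L]] <- data.frame(
        type = if (lb < la) "deletion" else "insertion",
        length_bp = abs(la - lb), segment = nm, stringsAsFactors = FALSE)
    }
    res <- if (length(out)) do.call(rbind, out) else
      data.frame(type = character(), length_bp = integer(),
                 segment = character(), stringsAsFactors = FALSE)
    res <- res[order(res$type, res$segment), , drop = FALSE]
    rownames(res) <- NULL
    return(res)
  }

  delta <- (sb["hi"] - sb["lo"]) - (sa["hi"] - sa["lo"])
  if (delta == 0)
    return(data.frame(type = character(), length_bp = integer(),
                      segment = character(), stringsAsFactors = FALSE))
  data.frame(type = if (delta < 0) "deletion" else "insertion",
             length_bp = abs(as.integer(delta)),
             segment = "inter-flank span", stringsAsFactors = FALSE)
}
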