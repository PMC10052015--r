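#' Pairwise distance between two aligned nucleotide sequences
#'
#' Sites with a gap in either sequence are excluded pairwise. The p-distance
#' is the mismatch proportion over compared sites; the Jukes-Cantor distance
#' corrects it as -(3/4) ln(1 - 4p/3) and errors at saturation (p >= 0.75)
#' rather than returning infinity.
#'
#' @param a,b Aligned sequences (equal-length strings; gaps "-" or ".").
#' @param model "p" or "JC".
#' @return Numeric distance.
#' @examples
#' seqDistance(strrep("A", 10), paste0(strrep("A", 9), "C"), "p")
#' @export
seqDistance <- function(a, b, model = c("p", "JC")) {
  model <- match.arg(model)
  ca <- strsplit(toupper(a), "")[[1L]]
  cb <- strsplit(toupper(b), "")[[1L]]
  if (length(ca) != length(cb)) stop("sequences differ in aligned length")
  keep <- !(ca %in% c("-", ".")) & !(cb %in% c("-", "."))
  if (!any(keep)) stop("no comparable sites (all-gap overlap)")
  p <- sum(ca[keep] != cb[keep]) / sum(keep)
  if (model == "p") return(p)
  if (p >= 0.75)
    stop("Jukes-Cantor distance undefined at saturation (p = ",
         signif(p, 4), " >= 0.75)")
  -0.75 * log(1 - 4 * p / 3)
}

#' Distance matrix for a set of aligned sequences
#'
#' @param seqs Named character vector of aligned sequences.
#' @param model See \code{\link{seqDistance}}.
#' @return Symmetric numeric matrix with zero diagonal and attribute
#'   \code{model}.
#' @export
distanceMatrix <- function(seqs, model = c("p", "JC")) {
  model <- match.arg(model)
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids)) stop("sequences need unique names")
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    d <- seqDistance(seqs[[i]], seqs[[j]], model)
    m[i, j] <- d; m[j, i] <- d
  }
  attr(m, "model") <- model
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' The agglomerative algorithm of Saitou and Nei with the standard
#' Q-criterion and branch-length formulas, authored here so that its
#' behaviour is exactly specified: ties in Q are broken by the lowest pair
#' of current node indices, and negative branch-length estimates are
#' clamped to zero (recorded in the \code{clamped} attribute). On an
#' additive distance matrix the generating topology and branch lengths are
#' recovered exactly.
#'
#' @param dm Symmetric distance matrix with taxon names (>= 3 taxa).
#' @return An unrooted \code{ape::phylo} tree; attribute \code{clamped}
#'   gives the number of negative length estimates clamped to zero.
#' @export
neighborJoining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <-
      paste0("t", seq_len(n))
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix not symmetric")
  labels <- rownames(dm)
  node <- as.list(labels)        # newick fragment per active node
  D <- dm
  clamped <- 0L
  fmt <- function(x) sprintf("%.10g", x)

  while (length(node) > 3L) {
    m <- nrow(D)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m))
      if (Q[i, j] < best[1L] - 1e-12) best <- c(Q[i, j], i, j)
    i <- best[2L]; j <- best[3L]
    li <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { clamped <- clamped + 1L; lj <- lj + li; li <- 0 }
    if (lj < 0) { clamped <- clamped + 1L; li <- li + lj; lj <- 0 }
    merged <- paste0("(", node[[i]], ":", fmt(li), ",",
                     node[[j]], ":", fmt(lj), ")")
    dNew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
                c(dNew[keep], 0))
    D <- D2
    node <- c(node[keep], merged)
  }

  d12 <- D[1L, 2L]; d13 <- D[1L, 3L]; d23 <- D[2L, 3L]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  ls <- c(l1, l2, l3)
  clamped <- clamped + sum(ls < 0)
  ls[ls < 0] <- 0
  nwk <- paste0("(", node[[1L]], ":", fmt(ls[1L]), ",",
                node[[2L]], ":", fmt(ls[2L]), ",",
                node[[3L]], ":", fmt(ls[3L]), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Neighbor-joining tree from aligned sequences
#'
#' Convenience wrapper: \code{\link{distanceMatrix}} then
#' \code{\link{neighborJoining}}.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param model Distance model (default "JC").
#' @return An \code{ape::phylo} tree.
#' @export
njTree <- function(seqs, model = "JC")
  neighborJoining(distanceMatrix(seqs, model))

#' Monophyly report for labelled groups on a tree
#'
#' Roots the tree at the given outgroup and reports, per group, whether its
#' members form a monophyletic clade.
#'
#' @param tree An \code{ape::phylo} tree.
#' @param groups Named character vector mapping leaf label to group name
#'   (every non-outgroup leaf must be assigned).
#' @param outgroup Leaf label used to root the tree.
#' @return data.frame \code{group}, \code{n}, \code{monophyletic}.
#' @export
clusterCheck <- function(tree, groups, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' not in tree")
  rest <- setdiff(tree$tip.label, outgroup)
  un <- setdiff(rest, names(groups))
  if (length(un))
    stop("leaves without a group: ", paste(un, collapse = ", "))
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  gs <- sort(unique(groups[rest]))
  data.frame(
    group = gs,
    n = vapply(gs, function(g) sum(groups[rest] == g), integer(1L)),
    monophyletic = vapply(gs, function(g)
      ape::is.monophyletic(rooted, names(groups[rest])[groups[rest] == g]),
      logical(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Read/write helpers for Newick trees
#'
#' Thin wrappers over \pkg{ape} kept for a uniform package surface.
#'
#' @param tree An \code{ape::phylo} object.
#' @param path File path.
#' @return \code{readNewick} returns an \code{ape::phylo};
#'   \code{writeNewick} returns \code{path} invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) ape::read.tree(path)
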