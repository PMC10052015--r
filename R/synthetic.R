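# Seed-deterministic generators for every pipeline input class, each
# emitting a machine-readable ground-truth record consumed directly by the
# test suite (tests never re-derive truth from outputs).

#' Generate a synthetic protein-ligand structure with planted geometry
#'
#' Builds a mini protein on an idealized extended backbone (residues spaced
#' so side chains cannot collide) and places pseudo-ligand atoms at exact
#' requested distances from designated residue atoms. Ligand atoms are
#' placed along a direction in which the designated atom is the nearest
#' protein atom; if no such direction exists the geometry request is
#' infeasible and an error is raised. Useful for exact-oracle testing of
#' contact shells and hydrogen-bond detection.
#'
#' @param nRes Number of residues (default 20; all alanine unless
#'   overridden).
#' @param sequence Optional named character vector, residue number to
#'   one-letter code, overriding the default alanines (e.g.
#'   \code{c("5" = "R")}).
#' @param contacts Optional data.frame \code{resno}, \code{ligand},
#'   \code{distance}: plant one ligand atom (carbon) at exactly
#'   \code{distance} Angstrom from the nearest atom of that residue.
#' @param hbondPartners Optional data.frame \code{resno}, \code{res_atom},
#'   \code{ligand}, \code{partner_element} ("N"/"O"), \code{distance}:
#'   plant a polar ligand atom at exactly \code{distance} from the named
#'   side-chain atom.
#' @param seed Unused by the construction (it is fully deterministic) but
#'   accepted for interface uniformity with the other generators.
#' @param out Optional directory: writes \code{structure.pdb} and
#'   \code{structure.pdb.truth.json}.
#' @return List: \code{model} (\linkS4class{StructureModel}), \code{truth}
#'   (planted contacts and hydrogen-bond geometries with achieved
#'   distances), \code{files}.
#' @export
simStructure <- function(nRes = 20L, sequence = NULL, contacts = NULL,
                         hbondPartners = NULL, seed = 1L, out = NULL) {
  aaByRes <- setNames(rep("A", nRes), seq_len(nRes))
  if (!is.null(sequence)) aaByRes[names(sequence)] <- toupper(sequence)

  rows <- list()
  addAtom <- function(elety, element, resid, resno, chain, xyz, entity) {
    rows[[length(rows) + 1L]] <<- data.frame(
      eleno = 0L, elety = elety, element = element, resid = resid,
      resno = resno, chain = chain, insert = "", x = xyz[1L], y = xyz[2L],
      z = xyz[3L], o = 1, alt = "", entity = entity,
      stringsAsFactors = FALSE)
  }

  spacing <- 14  # A between residue origins; beyond any side-chain reach
  for (i in seq_len(nRes)) {
    base <- c(spacing * (i - 1L), 0, 0)
    N <- base
    CA <- base + c(1.458, 0, 0)
    C <- CA + 1.525 * c(cos(69 * pi / 180), sin(69 * pi / 180), 0)
    O <- placeAtom(N, CA, C, 1.23, 120.5, 180)
    res3 <- aa3(aaByRes[[as.character(i)]])
    addAtom("N", "N", res3, i, "A", N, "protein")
    addAtom("CA", "C", res3, i, "A", CA, "protein")
    addAtom("C", "C", res3, i, "A", C, "protein")
    addAtom("O", "O", res3, i, "A", O, "protein")
    chis <- vapply(seq_len(max(nChi(res3), 1L)),
                   function(k) defaultChi(res3, k), numeric(1L))
    sc <- buildSidechain(res3, list(N = N, CA = CA, C = C), chis)
    for (nm in names(sc))
      addAtom(nm, substr(nm, 1L, 1L), res3, i, "A", sc[[nm]], "protein")
  }
  prot <- do.call(rbind, rows)

  ligRows <- list()
  ligCounter <- new.env()
  addLigAtom <- function(ligand, element, xyz) {
    k <- (get0("n", envir = ligCounter, ifnotfound = 0L)) + 1L
    assign("n", k, envir = ligCounter)
    resid <- if (ligand == "DNA") "DA" else ligand
    entity <- if (ligand == "DNA") "nucleic" else "cofactor"
    ligRows[[length(ligRows) + 1L]] <<- data.frame(
      eleno = 0L, elety = paste0(element, k), element = element,
      resid = resid, resno = 1000L + k, chain = "L", insert = "",
      x = xyz[1L], y = xyz[2L], z = xyz[3L], o = 1, alt = "",
      entity = entity, stringsAsFactors = FALSE)
    paste0(element, k)
  }

  pcoord <- as.matrix(prot[, c("x", "y", "z")])
  placeAt <- function(target, d) {
    dirs <- list(c(0, 0, 1), c(0, 0, -1), c(0, 1, 0), c(0, -1, 0),
                 c(0, 1, 1) / sqrt(2), c(0, -1, 1) / sqrt(2))
    for (u in dirs) {
      p <- target + d * u
      dmin <- min(sqrt(colSums((t(pcoord) - p)^2)))
      if (abs(dmin - d) < 1e-9) return(p)
    }
    stop("infeasible geometry request: no direction keeps the designated ",
         "atom nearest at ", d, " A")
  }

  truthContacts <- NULL
  if (!is.null(contacts)) {
    got <- list()
    for (r in seq_len(nrow(contacts))) {
      resno <- contacts$resno[r]
      ri <- which(prot$resno == resno)
      if (!length(ri)) stop("contact requested for absent residue ", resno)
      # designate the residue's last side-chain atom (falls back to CA)
      ti <- ri[length(ri)]
      target <- as.numeric(prot[ti, c("x", "y", "z")])
      p <- placeAt(target, contacts$distance[r])
      nm <- addLigAtom(contacts$ligand[r], "C", p)
      got[[r]] <- data.frame(resno = resno, ligand = contacts$ligand[r],
                             distance = contacts$distance[r],
                             ligand_atom = nm, stringsAsFactors = FALSE)
    }
    truthContacts <- do.call(rbind, got)
  }

  truthHb <- NULL
  if (!is.null(hbondPartners)) {
    got <- list()
    for (r in seq_len(nrow(hbondPartners))) {
      h <- hbondPartners[r, ]
      ti <- which(prot$resno == h$resno & prot$elety == h$res_atom)
      if (!length(ti))
        stop("no atom ", h$res_atom, " in residue ", h$resno)
      target <- as.numeric(prot[ti[1L], c("x", "y", "z")])
      p <- placeAt(target, h$distance)
      nm <- addLigAtom(h$ligand, h$partner_element, p)
      got[[r]] <- data.frame(resno = h$resno, res_atom = h$res_atom,
                             ligand = h$ligand, partner_atom = nm,
                             partner_element = h$partner_element,
                             distance = h$distance, stringsAsFactors = FALSE)
    }
    truthHb <- do.call(rbind, got)
  }

  allAtoms <- rbind(prot, if (length(ligRows)) do.call(rbind, ligRows))
  allAtoms$eleno <- seq_len(nrow(allAtoms))
  rownames(allAtoms) <- NULL
  model <- new("StructureModel", atoms = allAtoms,
               chains = unique(allAtoms$chain), source = "simStructure")
  truth <- list(nRes = nRes, sequence = aaByRes, contacts = truthContacts,
                hbonds = truthHb)
  files <- NULL
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    pdbPath <- file.path(out, "structure.pdb")
    writeStructure(model, pdbPath)
    jsonlite::write_json(truth, paste0(pdbPath, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(pdbPath, paste0(pdbPath, ".truth.json"))
  }
  list(model = model, truth = truth, files = files)
}

#' Generate a synthetic photolyase homolog family with planted substitutions
#'
#' Draws a random reference sequence and derives one homolog per strain by
#' applying planted substitutions at known reference-numbered positions.
#' The "table2" preset reproduces the packaged key-residue table exactly:
#' the reference carries the SEL column at the table's 15 positions, each
#' strain its own column, and a gene-absent strain (the BOL5-4 analog) is
#' flagged in the truth record and omitted from the sequence set.
#'
#' @param preset "table2" or "custom".
#' @param length Reference length in residues (default 480, about the
#'   photolyase length).
#' @param substitutions For "custom": named list, strain id to data.frame
#'   \code{pos}, \code{aa}.
#' @param absentStrains Strains flagged as lacking the gene (for "custom";
#'   "table2" uses BOL5-4).
#' @param withMet Prepend an initiator methionine excluded from numbering
#'   (records then carry numbering offset 1; default TRUE).
#' @param seed RNG seed for the reference sequence.
#' @param out Optional directory: writes \code{family.faa} (FASTA) and
#'   \code{family.faa.truth.json}.
#' @return List: \code{seqs} (named character, FASTA-frame sequences),
#'   \code{offsets} (named integer), \code{refId}, \code{truth}
#'   (substitution lists per strain, gene presence, pairwise identity to
#'   the reference), \code{files}.
#' @export
simSequences <- function(preset = c("table2", "custom"), length = 480L,
                         substitutions = NULL,
                         absentStrains = character(), withMet = TRUE,
                         seed = 1L, out = NULL) {
  preset <- match.arg(preset)
  set.seed(seed)
  aaPool <- names(AA1TO3)
  refSeq <- sample(aaPool, length, replace = TRUE)

  if (preset == "table2") {
    vt <- table2Fixture()
    pos <- vt@positions
    if (max(pos) > length) stop("length too short for the fixture positions")
    m <- variantResidues(vt)
    refSeq[pos] <- m[, "SEL"]
    strains <- setdiff(colnames(m), "SEL")
    substitutions <- lapply(strains, function(st) {
      d <- m[, st] != m[, "SEL"]
      data.frame(pos = pos[d], aa = m[d, st], stringsAsFactors = FALSE)
    })
    names(substitutions) <- strains
    absentStrains <- "BOL5-4"
  }
  if (is.null(substitutions)) substitutions <- list()

  mk <- function(subs) {
    s <- refSeq
    if (nrow(subs)) {
      if (any(subs$pos < 1L | subs$pos > length))
        stop("substitution position out of range")
      s[subs$pos] <- subs$aa
    }
    paste(s, collapse = "")
  }
  seqs <- c(SEL = paste(refSeq, collapse = ""),
            vapply(substitutions, mk, character(1L)))
  if (withMet) seqs <- vapply(seqs, function(s) paste0("M", s),
                              character(1L))
  offsets <- setNames(rep(if (withMet) 1L else 0L, length(seqs)),
                      names(seqs))
  genePresent <- setNames(rep(TRUE, length(seqs)), names(seqs))
  if (length(absentStrains))
    genePresent[absentStrains] <- FALSE

  identity <- vapply(names(substitutions), function(st)
    100 * (1 - nrow(substitutions[[st]]) / length), numeric(1L))
  truth <- list(refId = "SEL", length = length,
                substitutions = lapply(substitutions, function(d)
                  paste0(d$aa, "@", d$pos)),
                genePresent = as.list(genePresent),
                identityToRef = as.list(identity))
  files <- NULL
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out, "family.faa")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), fa)
    jsonlite::write_json(truth, paste0(fa, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(fa, paste0(fa, ".truth.json"))
  }
  list(seqs = seqs, offsets = offsets, refId = "SEL",
       genePresent = genePresent, truth = truth, files = files)
}

## Kill rates (per J/m2) defining the paper-shaped survival preset: surface
## brine/salt-crust strains photoreactivate well (low light-condition kill),
## the sediment strain is intermediate, subsurface-halite strains barely
## photoreactivate, and dark-condition kill is uniformly substantial
## (several logs at the top dose) except for the most dark-repair-proficient
## model strain.
paperSurvivalRates <- function() data.frame(
  strain = c("NRC-1", "BOL4-2", "GSL-19", "JOR-1", "BOL3-1",
             "Hla", "BOL5-1", "BOL6-1", "BOL5-4"),
  habitat = c("surface", "surface", "surface", "surface", "surface",
              "sediment", "subsurface", "subsurface", "subsurface"),
  k_light = c(0.002, 0.003, 0.004, 0.004, 0.005,
              0.020, 0.065, 0.055, 0.070),
  k_dark = c(0.015, 0.055, 0.055, 0.050, 0.045,
             0.050, 0.070, 0.065, 0.075),
  stringsAsFactors = FALSE)

#' Generate synthetic UV dose-response colony counts
#'
#' Colony counts follow noisy exponential kill: the expected titer at dose
#' d is N0 exp(-k d); plated counts are drawn with multiplicative lognormal
#' noise of the given coefficient of variation and a dilution chosen to
#' keep expected plate counts countable. With \code{cv = 0} the counts are
#' exact (left unrounded), so recovered slopes match the planted rates to
#' floating-point accuracy.
#'
#' @param preset "paper" uses \code{phrscan:::paperSurvivalRates}; "custom"
#'   requires \code{rates}.
#' @param rates data.frame \code{strain}, \code{k_light}, \code{k_dark}.
#' @param doses UV-C doses in J/m2 (default 0, 24, 48, 96, 144).
#' @param replicates Plates per dose/condition (default 2).
#' @param cv Lognormal coefficient of variation of counts (default 0.2).
#' @param n0 Unirradiated titer (default 1e7).
#' @param seed RNG seed.
#' @param out Optional directory: writes \code{counts.csv} and
#'   \code{counts.csv.truth.json}.
#' @return List: \code{records} (data.frame for
#'   \code{\link{percentSurvival}}), \code{truth} (planted rates and the
#'   habitat ordering), \code{files}.
#' @export
simSurvival <- function(preset = c("paper", "custom"), rates = NULL,
                        doses = c(0, 24, 48, 96, 144), replicates = 2L,
                        cv = 0.2, n0 = 1e7, seed = 1L, out = NULL) {
  preset <- match.arg(preset)
  if (preset == "paper") rates <- paperSurvivalRates()
  if (is.null(rates)) stop("custom preset requires rates")
  if (any(c(rates$k_light, rates$k_dark) < 0)) stop("kill rates must be >= 0")
  set.seed(seed)
  sigma <- sqrt(log(1 + cv^2))
  rows <- list()
  for (r in seq_len(nrow(rates))) for (cond in c("light", "dark")) {
    k <- if (cond == "light") rates$k_light[r] else rates$k_dark[r]
    for (d in doses) for (rep in seq_len(replicates)) {
      titer <- n0 * exp(-k * d)
      dilution <- 10^max(0, ceiling(log10(max(titer, 1) / 200)))
      expected <- titer / dilution
      cfu <- if (cv > 0) {
        stats::rlnorm(1L, meanlog = log(expected) - sigma^2 / 2,
                      sdlog = sigma)
      } else expected
      if (cv > 0) cfu <- round(cfu)
      rows[[length(rows) + 1L]] <- data.frame(
        strain = rates$strain[r], condition = cond, dose = d,
        replicate = rep, dilution = dilution, cfu = cfu,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  truth <- list(rates = rates, doses = doses, cv = cv, n0 = n0,
                logSlopePerJ = stats::setNames(-rates$k_light / log(10),
                                               rates$strain))
  files <- NULL
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(out, "counts.csv")
    utils::write.csv(records, csv, row.names = FALSE)
    jsonlite::write_json(truth, paste0(csv, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    files <- c(csv, paste0(csv, ".truth.json"))
  }
  list(records = records, truth = truth, files = files)
}

#' Evolve aligned sequences along a known tree
#'
#' Simulates nucleotide sequences under the Jukes-Cantor model along a
#' stated tree (via \pkg{phangorn}), returning the alignment together with
#' the generating topology, so neighbor-joining reconstruction can be
#' checked against known truth. The "clades3" preset mirrors a
#' three-order-plus-outgroup structure: three well-separated clades of
#' three taxa and a distant outgroup "Tko".
#'
#' @param preset "clades3" or "custom" (supply \code{tree}).
#' @param tree An \code{ape::phylo} or Newick string (for "custom").
#' @param length Alignment length in bp (default 1200, 16S-like).
#' @param seed RNG seed.
#' @param out Optional directory: writes \code{aln.fasta},
#'   \code{tree.nwk} and \code{aln.fasta.truth.json}.
#' @return List: \code{seqs} (named character, aligned), \code{tree}
#'   (generating \code{ape::phylo}), \code{groups} (named character:
#'   taxon to clade), \code{outgroup}, \code{files}.
#' @export
simTreeSequences <- function(preset = c("clades3", "custom"), tree = NULL,
                             length = 1200L, seed = 1L, out = NULL) {
  preset <- match.arg(preset)
  groups <- NULL; outgroup <- NULL
  if (preset == "clades3") {
    nwk <- paste0(
      "(((A1:0.02,A2:0.02):0.01,A3:0.03):0.12,",
      "((B1:0.02,B2:0.03):0.01,B3:0.03):0.12,",
      "(((C1:0.02,C2:0.02):0.01,C3:0.03):0.12,Tko:0.5):0.05);")
    tree <- ape::read.tree(text = nwk)
    groups <- c(A1 = "A", A2 = "A", A3 = "A", B1 = "B", B2 = "B",
                B3 = "B", C1 = "C", C2 = "C", C3 = "C")
    outgroup <- "Tko"
  } else {
    if (is.character(tree)) tree <- ape::read.tree(text = tree)
    if (is.null(tree)) stop("custom preset requires a tree")
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length")
  set.seed(seed)
  dat <- phangorn::simSeq(tree, l = length, type = "DNA")
  m <- toupper(as.character(dat))
  seqs <- apply(m, 1L, paste, collapse = "")
  files <- NULL
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out, "aln.fasta")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa)
    nwkPath <- file.path(out, "tree.nwk")
    ape::write.tree(tree, nwkPath)
    jsonlite::write_json(
      list(newick = ape::write.tree(tree), groups = as.list(groups),
           outgroup = outgroup),
      paste0(fa, ".truth.json"), auto_unbox = TRUE, digits = NA)
    files <- c(fa, nwkPath, paste0(fa, ".truth.json"))
  }
  list(seqs = seqs, tree = tree, groups = groups, outgroup = outgroup,
       files = files)
}

#' Generate synthetic gene neighborhoods around the phr2 anchor
#'
#' The "paper" preset emulates the published gene-organization comparison:
#' three strains sharing the reference arrangement with the anchor adjacent
#' to sod2; one strain with two hypothetical genes inserted between the
#' anchor and sod2; two strains with a distinct arrangement lacking sod2;
#' two related subsurface strains with their own shared arrangement; and
#' one strain lacking the anchor entirely, carrying a planted 1727 bp
#' deletion and a 237 bp insertion relative to its closest relative,
#' declared as homologous segments between shared flanking genes.
#'
#' @param preset Currently "paper".
#' @param seed Unused (the construction is deterministic); kept for
#'   interface uniformity.
#' @param out Optional directory: writes one TSV per strain plus
#'   \code{neighborhoods.truth.json}.
#' @return List: \code{neighborhoods} (named list of
#'   \linkS4class{GeneNeighborhood}), \code{truth}, \code{files}.
#' @export
simNeighborhoods <- function(preset = "paper", seed = 1L, out = NULL) {
  mkGenes <- function(labels, strands = NULL, width = 900L, gap = 120L) {
    n <- length(labels)
    if (is.null(strands)) strands <- rep("+", n)
    start <- 1L + (seq_len(n) - 1L) * (width + gap)
    data.frame(id = paste0("g", seq_len(n)), label = labels,
               start = start, end = start + width - 1L,
               strand = strands, stringsAsFactors = FALSE)
  }
  haloLayout <- c("coa_ligase", "sulfatase", "thioesterase", "phr2",
                  "sod2", "hypothetical")
  jorLayout <- c("coa_ligase", "sulfatase", "thioesterase", "phr2",
                 "hypothetical", "hypothetical", "sod2")
  rubrumLayout <- c("mbl_hydrolase", "cupin", "phr2", "thy_synthase",
                    "dead_helicase")
  natriLayout <- c("ghmp_kinase", "duf115", "phr2", "cell_division",
                   "sugar_isomerase")

  nb <- list(
    "NRC-1" = geneNeighborhood("NRC-1", mkGenes(haloLayout)),
    "BOL4-2" = geneNeighborhood("BOL4-2", mkGenes(haloLayout)),
    "GSL-19" = geneNeighborhood("GSL-19", mkGenes(haloLayout)),
    "JOR-1" = geneNeighborhood("JOR-1", mkGenes(jorLayout)),
    "Hla" = geneNeighborhood("Hla", mkGenes(rubrumLayout)),
    "BOL3-1" = geneNeighborhood("BOL3-1", mkGenes(rubrumLayout)),
    "BOL5-1" = geneNeighborhood("BOL5-1",
      mkGenes(c("ghmp_kinase", "phr2", "duf115", "cell_division"),
              strands = c("+", "-", "+", "+"))))

  # BOL6-1: anchor present inside a declared 1727 bp homologous segment
  # between the shared flanks duf115 and cell_division (the inter-flank
  # span is wide enough to hold the full segment).
  g6 <- data.frame(
    id = paste0("g", 1:5), label = natriLayout,
    start = c(1L, 1021L, 2100L, 3750L, 4770L),
    end = c(900L, 1920L, 3000L, 4650L, 5670L),
    strand = "+", stringsAsFactors = FALSE)
  seg6 <- data.frame(name = "phr2_region", start = 1970L,
                     end = 1970L + 1726L, stringsAsFactors = FALSE)
  nb[["BOL6-1"]] <- geneNeighborhood("BOL6-1", g6, segments = seg6)

  # BOL5-4: same arrangement minus the anchor; carries a 237 bp insertion
  # segment instead.
  g54 <- data.frame(
    id = paste0("g", 1:4), label = setdiff(natriLayout, "phr2"),
    start = c(1L, 1021L, 2300L, 3320L),
    end = c(900L, 1920L, 3200L, 4220L),
    strand = "+", stringsAsFactors = FALSE)
  seg54 <- data.frame(name = "orf_insert", start = 1960L,
                      end = 1960L + 236L, stringsAsFactors = FALSE)
  nb[["BOL5-4"]] <- geneNeighborhood("BOL5-4", g54, segments = seg54)

  truth <- list(
    anchorAbsent = "BOL5-4",
    syntenyWithNRC1 = c("BOL4-2", "GSL-19"),
    interveningJOR1 = 2L,
    indels = data.frame(type = c("deletion", "insertion"),
                        length_bp = c(1727L, 237L),
                        stringsAsFactors = FALSE),
    indelPair = c(a = "BOL6-1", b = "BOL5-4"),
    flanks = c("duf115", "cell_division"))
  files <- NULL
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    files <- character(0L)
    for (nm in names(nb)) {
      g <- neighborhoodGenes(nb[[nm]])
      g$segment <- FALSE
      seg <- nb[[nm]]@segments
      if (nrow(seg))
        g <- rbind(g, data.frame(id = seg$name, label = "segment",
                                 start = seg$start, end = seg$end,
                                 strand = "+", segment = TRUE))
      f <- file.path(out, paste0(nm, ".tsv"))
      utils::write.table(g, f, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      files <- c(files, f)
    }
    tj <- file.path(out, "neighborhoods.truth.json")
    jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    files <- c(files, tj)
  }
  list(neighborhoods = nb, truth = truth, files = files)
}
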