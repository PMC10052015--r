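#' Run the variant-to-phenotype analysis pipeline
#'
#' Orchestrates the full analysis: contact shell (or the packaged
#' key-residue table when no structure is supplied), cross-strain variant
#' table, substitution hydrogen-bond impacts (structure mode only),
#' photolyase integrity scores, survival summaries and ranking, and the
#' genotype-phenotype rank correlation. Optional phylogeny and synteny
#' stages run when their inputs are present. Stages that cannot run are
#' skipped and named in the report, never silently.
#'
#' @param config A list (or path to a YAML/JSON file):
#' \describe{
#'   \item{structure}{Path to a PDB file, or a
#'     \linkS4class{StructureModel}; omit to use the packaged key-residue
#'     table ("fixture mode").}
#'   \item{cofactors}{Cofactor name map for \code{\link{classifyLigands}}.}
#'   \item{contactThreshold}{Contact cutoff in Angstrom (default 2.8).}
#'   \item{sequences}{Named character vector of protein sequences, or a
#'     FASTA path (structure mode).}
#'   \item{offsets}{Named numbering offsets for \code{sequences}.}
#'   \item{genePresent}{Named logical, FALSE for strains lacking the gene.}
#'   \item{survival}{data.frame of colony-count records or a CSV path.}
#'   \item{structuralRef, functionalRef}{Reference ids (defaults "SEL",
#'     "NRC-1").}
#'   \item{weights}{Integrity-score weights.}
#'   \item{metric}{Ranking metric (default "light-survival").}
#'   \item{aln16s, phyloGroups, outgroup}{Aligned 16S sequences (named
#'     vector or FASTA path), group map, outgroup leaf for the phylogeny
#'     stage.}
#'   \item{neighborhoods}{Named list of \linkS4class{GeneNeighborhood} for
#'     the synteny stage.}
#'   \item{seed}{Seed for the permutation p-value (default 1).}
#'   \item{outDir}{Optional output directory for the JSON report.}
#' }
#' @return List: \code{configHash}, \code{stages} (run/skipped with
#'   reasons), \code{variantTable}, \code{diffs} (per strain vs the
#'   functional reference), \code{impacts}, \code{scores},
#'   \code{survivalSummary}, \code{ranking}, \code{correlation},
#'   \code{phylo}, \code{synteny}.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- readConfig(config)
  stopifnot(is.list(config))
  cfg <- config
  cfg$structuralRef <- cfg$structuralRef %||% "SEL"
  cfg$functionalRef <- cfg$functionalRef %||% "NRC-1"
  cfg$contactThreshold <- cfg$contactThreshold %||% 2.8
  cfg$metric <- cfg$metric %||% "light-survival"
  cfg$seed <- cfg$seed %||% 1L

  stages <- list()
  note <- function(stage, status, reason = NULL)
    stages[[stage]] <<- list(status = status, reason = reason)

  # --- variant table ---------------------------------------------------
  impacts <- NULL
  if (!is.null(cfg$structure)) {
    s <- if (is(cfg$structure, "StructureModel")) cfg$structure
         else readStructure(cfg$structure,
                            nucleicExtra = cfg$nucleicExtra %||% character())
    groups <- classifyLigands(s, cfg$cofactors %||% c(FAD = "FAD",
                                                      HDF = "HDF"))
    shell <- contactShell(s, groups, threshold = cfg$contactThreshold)
    seqs <- cfg$sequences
    if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs)) {
      ss <- Biostrings::readAAStringSet(seqs)
      seqs <- setNames(as.character(ss), names(ss))
    }
    if (is.null(seqs)) stop("structure mode requires sequences")
    maps <- familyMaps(seqs, cfg$structuralRef,
                       offsets = cfg$offsets)
    vt <- buildVariantTable(shell, maps, refId = cfg$structuralRef,
                            functionalRef = cfg$functionalRef,
                            variantOnly = TRUE)
    note("contacts", "run")
    note("variants", "run")

    # impacts: substitute each divergent strain residue into the
    # reference structure (keyed by the functional-reference notation so
    # the scores can consume them)
    impacts <- list()
    strains <- setdiff(strainIds(vt),
                       c(cfg$structuralRef))
    for (st in setdiff(strains, cfg$functionalRef)) {
      d <- diffCounts(vt, st, cfg$functionalRef)
      for (i in seq_len(nrow(d$calls))) {
        nota <- d$calls$notation[i]
        if (!is.null(impacts[[nota]])) next
        pos <- d$calls$pos[i]
        structAa <- variantResidues(vt)[match(pos, vt@positions),
                                        cfg$structuralRef]
        if (d$calls$to[i] == "-" || structAa == "-") next
        impacts[[nota]] <- assessSubstitution(
          s, list(from = structAa, pos = pos, to = d$calls$to[i],
                  strain = st),
          groups, cfg$hbondCriteria %||% hbondCriteria())
      }
    }
    note("impacts", "run")
  } else {
    vt <- table2Fixture()
    note("contacts", "skipped", "no structure supplied (fixture mode)")
    note("variants", "run", "packaged key-residue table")
    note("impacts", "skipped", "no structure supplied")
  }

  strains <- setdiff(strainIds(vt), vt@structuralRef)
  diffs <- lapply(setdiff(strains, cfg$functionalRef), function(st)
    diffCounts(vt, st, cfg$functionalRef))
  names(diffs) <- setdiff(strains, cfg$functionalRef)

  scores <- integrityScore(vt, impacts = impacts,
                           genePresent = unlist(cfg$genePresent) %||% NULL,
                           vs = cfg$functionalRef,
                           weights = cfg$weights %||% integrityWeights())
  note("scores", "run")

  # --- survival --------------------------------------------------------
  survivalSummary <- NULL; ranking <- NULL; correlation <- NULL
  if (!is.null(cfg$survival)) {
    rec <- cfg$survival
    if (is.character(rec)) rec <- utils::read.csv(rec)
    sd <- percentSurvival(rec)
    survivalSummary <- doseResponseSummary(sd)
    ranking <- rankStrains(sd, cfg$metric)
    note("survival", "run")
    shared <- intersect(names(scores), unique(ranking$strain))
    if (length(shared) >= 4L) {
      set.seed(cfg$seed)
      correlation <- genotypePhenotypeCorrelation(scores, sd,
                                                  metric = cfg$metric)
      note("correlation", "run")
    } else note("correlation", "skipped",
                "fewer than 4 strains with both genotype and phenotype")
  } else {
    note("survival", "skipped", "no survival records supplied")
    note("correlation", "skipped", "no survival records supplied")
  }

  # --- phylogeny -------------------------------------------------------
  phylo <- NULL
  if (!is.null(cfg$aln16s)) {
    aln <- cfg$aln16s
    if (is.character(aln) && length(aln) == 1L && file.exists(aln)) {
      ss <- Biostrings::readDNAStringSet(aln)
      aln <- setNames(as.character(ss), names(ss))
    }
    tree <- njTree(aln, model = cfg$distanceModel %||% "JC")
    mono <- if (!is.null(cfg$phyloGroups) && !is.null(cfg$outgroup))
      clusterCheck(tree, unlist(cfg$phyloGroups), cfg$outgroup) else NULL
    phylo <- list(newick = ape::write.tree(tree), monophyly = mono)
    note("phylo", "run")
  } else note("phylo", "skipped", "no 16S alignment supplied")

  # --- synteny ---------------------------------------------------------
  synteny <- NULL
  if (!is.null(cfg$neighborhoods)) {
    nbs <- cfg$neighborhoods
    refNb <- cfg$functionalRef
    if (refNb %in% names(nbs)) {
      others <- setdiff(names(nbs), refNb)
      synteny <- data.frame(
        strain = others,
        score = vapply(others, function(x)
          syntenyScore(nbs[[refNb]], nbs[[x]])$score, numeric(1L)),
        anchorPresent = vapply(others, function(x)
          nbs[[x]]@anchor %in% neighborhoodGenes(nbs[[x]])$label,
          logical(1L)),
        row.names = NULL, stringsAsFactors = FALSE)
    }
    note("synteny", "run")
  } else note("synteny", "skipped", "no neighborhoods supplied")

  report <- list(configHash = configHash(cfg), stages = stages,
                 variantTable = vt, diffs = diffs, impacts = impacts,
                 scores = scores, survivalSummary = survivalSummary,
                 ranking = ranking, correlation = correlation,
                 phylo = phylo, synteny = synteny)
  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(reportJson(report),
                         file.path(cfg$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", force = TRUE)
  }
  report
}

readConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

## Stable hash of the semantic configuration (output location excluded).
configHash <- function(cfg) {
  cfg$outDir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

## JSON-serializable view of a pipeline report.
reportJson <- function(report) {
  list(configHash = report$configHash, stages = report$stages,
       variantPositions = report$variantTable@positions,
       diffs = lapply(report$diffs, function(d)
         list(total = d$total, byInteraction = as.list(d$byInteraction))),
       impacts = if (length(report$impacts))
         impactReport(report$impacts) else NULL,
       scores = as.list(report$scores),
       survivalSummary = report$survivalSummary,
       ranking = report$ranking,
       correlation = report$correlation[c("rho", "p", "method", "n")],
       phylo = report$phylo, synteny = report$synteny)
}
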