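# Study-level report: Table-1-style metrics, pairwise synteny, core
# genes and the Dollo loss table for a set of genomes.

#' Run the full comparative study on a set of genomes
#'
#' Computes, for every genome, the architecture metrics table; for every
#' genome pair, colinear-block counts and shared-gene percentages; the
#' core-gene set; and, when a tree is supplied, the per-gene Dollo loss
#' table. A genome failing a stage is dropped from that table with a
#' logged reason, never silently.
#'
#' @param genomes named list of \linkS4class{ChloroGenome}s, or a
#'   directory containing gene-order TSVs (\code{*.tsv}) and/or GenBank
#'   flatfiles (\code{*.gb}, \code{*.gbk}).
#' @param tree optional rooted \code{phylo} tree (or newick path) whose
#'   leaves cover the genome ids; enables the Dollo loss table.
#' @param minLen,maxGap,collapseIr conventions for the gene-order
#'   comparison, see [colinearBlocks()] and [extractSignedOrder()].
#' @param outgroups outgroup ids for the Dollo gain policy.
#' @param irMinLen minimum IR length for detection.
#' @return list of class \code{"StudyReport"} with elements
#'   \code{metrics}, \code{synteny}, \code{coreGenes}, \code{lossTable},
#'   \code{dropped} and \code{provenance}.
#' @export
runStudy <- function(genomes, tree = NULL, minLen = 2L, maxGap = 0L,
                     collapseIr = TRUE, outgroups = character(0),
                     irMinLen = 1000L) {
  if (is.character(genomes) && length(genomes) == 1L && dir.exists(genomes)) {
    genomes <- .readGenomeDir(genomes)
  }
  if (length(genomes) < 2L) stop("need at least two genomes")
  ids <- vapply(genomes, genomeId, character(1))
  names(genomes) <- ids
  if (is.character(tree)) tree <- readSpeciesTree(tree)
  dropped <- list()
  note <- function(id, stage, why) {
    dropped[[length(dropped) + 1L]] <<- data.frame(
      id = id, stage = stage, reason = conditionMessage(why),
      stringsAsFactors = FALSE)
    message("dropping '", id, "' from ", stage, ": ", conditionMessage(why))
  }

  metrics <- do.call(rbind, lapply(ids, function(id) {
    tryCatch(genomeMetrics(genomes[[id]], irMinLen = irMinLen),
             error = function(e) { note(id, "metrics", e); NULL })
  }))

  orders <- lapply(ids, function(id) {
    tryCatch(extractSignedOrder(genomes[[id]], collapseIr = collapseIr,
                                irMinLen = irMinLen),
             error = function(e) { note(id, "gene_order", e); NULL })
  })
  names(orders) <- ids
  okOrd <- ids[!vapply(orders, is.null, logical(1))]
  syn <- NULL
  if (length(okOrd) >= 2L) {
    pairs <- utils::combn(okOrd, 2L)
    syn <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      bl <- suppressWarnings(colinearBlocks(orders[[a]], orders[[b]],
                                            minLen = minLen, maxGap = maxGap))
      stt <- syntenyStats(bl, orders[[a]], orders[[b]])
      data.frame(genome1 = a, genome2 = b, nBlocks = stt$nBlocks,
                 nBlockGenes = stt$nBlockGenes, pctOfG1 = stt$pctOfG1,
                 pctOfG2 = stt$pctOfG2,
                 largestBlock = length(stt$largestBlock),
                 stringsAsFactors = FALSE)
    }))
  }

  pam <- buildPresenceMatrix(genomes)
  core <- coreGenes(pam, setdiff(colnames(presenceStates(pam)), outgroups))

  lossTable <- NULL
  if (!is.null(tree)) {
    missing <- setdiff(ids, tree$tip.label)
    if (length(missing))
      stop("tree lacks leaves for: ", paste(missing, collapse = ", "))
    sub <- if (length(setdiff(tree$tip.label, ids)))
      ape::keep.tip(tree, ids) else tree
    lossTable <- dolloLossTable(pam, sub, outgroups = outgroups)
  }

  structure(list(
    metrics = metrics, synteny = syn, coreGenes = core,
    lossTable = lossTable,
    dropped = if (length(dropped)) do.call(rbind, dropped) else NULL,
    provenance = list(
      package = "plastarch",
      version = as.character(utils::packageVersion("plastarch")),
      nGenomes = length(ids),
      settings = list(minLen = minLen, maxGap = maxGap,
                      collapseIr = collapseIr, irMinLen = irMinLen))
  ), class = "StudyReport")
}

.readGenomeDir <- function(dir) {
  tsv <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  # only files carrying the gene-order header are genome inputs
  tsv <- tsv[vapply(tsv, function(f)
    grepl("^#id ", readLines(f, n = 1L, warn = FALSE)[1]), logical(1))]
  gb <- list.files(dir, pattern = "\\.(gb|gbk|genbank)$", full.names = TRUE)
  gs <- c(lapply(tsv, readGeneOrderTsv), lapply(gb, readGenomeRecord))
  if (!length(gs)) stop("no parsable genomes in ", dir)
  gs
}

#' Write a study report as a TSV set plus one JSON summary
#'
#' Deterministic: re-running on the same inputs yields identical bytes.
#'
#' @param report a \code{StudyReport} from [runStudy()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeStudyReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) {
    if (!is.null(df))
      utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
  }
  wt(report$metrics, "metrics.tsv")
  wt(report$synteny, "synteny.tsv")
  wt(report$lossTable, "dollo_losses.tsv")
  writeLines(report$coreGenes, file.path(dir, "core_genes.txt"))
  jsonlite::write_json(
    list(provenance = report$provenance, coreGenes = report$coreGenes,
         dropped = report$dropped),
    file.path(dir, "report.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(dir)
}

#' @export
print.StudyReport <- function(x, ...) {
  cat("StudyReport:", x$provenance$nGenomes, "genomes\n")
  cat("  metrics rows:", if (is.null(x$metrics)) 0 else nrow(x$metrics), "\n")
  cat("  synteny pairs:", if (is.null(x$synteny)) 0 else nrow(x$synteny), "\n")
  cat("  core genes:", length(x$coreGenes), "\n")
  if (!is.null(x$lossTable))
    cat("  characters mapped:", nrow(x$lossTable), "\n")
  invisible(x)
}

# --- shipped study inputs ----------------------------------------------

#' Shipped prasinophyte species tree
#'
#' The rooted backbone topology of the twelve prasinophyte chloroplast
#' genomes plus the two streptophyte outgroups (Mesostigma, Chlorokybus),
#' with the Prasinococcales as the earliest chlorophyte branch. Tip
#' labels are the standard study abbreviations (PCUS, PRMA, MBIC, PYRA,
#' MONO, MICR, OSTR, NAST, NOLI, PYCN, PICO, CCMP1205, MESO, CHLO).
#'
#' @return a \code{phylo} tree.
#' @export
prasinophyteTree <- function() {
  readSpeciesTree(system.file("extdata", "prasinophyte_tree.nwk",
                              package = "plastarch", mustWork = TRUE))
}

#' Shipped lineage map of the study taxa
#'
#' @return data.frame with columns \code{taxon}, \code{lineage},
#'   \code{group} (\code{"prasinophyte"} or \code{"outgroup"}).
#' @export
prasinophyteLineages <- function() {
  utils::read.delim(system.file("extdata", "prasinophyte_lineages.tsv",
                                package = "plastarch", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Reported presence patterns of selected characters
#'
#' Presence/absence, across the study taxa, of the six chloroplast genes
#' restricted to the Prasinococcales among chlorophytes (ndhJ, rbcR,
#' rpl21, rps15, rps16, ycf66) and of the inverted repeat, as reported
#' for the sequenced genomes. Used to map loss events on the shipped
#' species tree without genome downloads.
#'
#' @return data.frame, one row per character, one 0/1 column per taxon.
#' @export
reportedPresencePatterns <- function() {
  utils::read.delim(system.file("extdata", "reported_presence_patterns.tsv",
                                package = "plastarch", mustWork = TRUE),
                    stringsAsFactors = FALSE, check.names = FALSE)
}
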