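#' @import methods
NULL

#' ChloroGenome: an annotated circular chloroplast genome
#'
#' Container for one annotated circular genome: its identifier, length,
#' optional nucleotide sequence and strand-aware gene features. Coordinates
#' are 0-based half-open on the circle; a feature that wraps the origin is
#' stored as two (or more) spans.
#'
#' The \code{features} slot is a \code{data.frame} with one row per gene
#' occurrence (inverted-repeat duplicates are separate rows) and columns:
#' \describe{
#'   \item{name}{normalized gene symbol, e.g. \code{"psbA"}, \code{"trnL-uaa"}}
#'   \item{category}{one of \code{"protein"}, \code{"tRNA"}, \code{"rRNA"},
#'     \code{"orf"}, \code{"other"}}
#'   \item{strand}{integer, \code{+1} or \code{-1}}
#'   \item{conserved}{logical; member of the conserved-gene catalog}
#'   \item{pseudo}{logical; annotated as a pseudogene}
#'   \item{intervals}{list column; each element an integer matrix with
#'     columns \code{start}, \code{end} (0-based half-open spans, in order
#'     along the feature)}
#' }
#'
#' @slot id character(1), taxon or accession label.
#' @slot length integer(1), genome size in bp.
#' @slot sequence character(1); \code{""} when the sequence is absent.
#' @slot features data.frame as described above.
#'
#' @seealso [readGenomeRecord()], [readGeneOrderTsv()], [genomeMetrics()]
#' @exportClass ChloroGenome
setClass("ChloroGenome",
  representation(
    id = "character",
    length = "integer",
    sequence = "character",
    features = "data.frame"
  ),
  prototype(id = NA_character_, length = 0L, sequence = "",
            features = emptyFeatureTable())
)

setValidity("ChloroGenome", function(object) {
  msgs <- character(0)
  if (length(object@id) != 1L) msgs <- c(msgs, "id must be a single string")
  if (length(object@length) != 1L || is.na(object@length) || object@length < 0L)
    msgs <- c(msgs, "length must be a single non-negative integer")
  if (nzchar(object@sequence) && nchar(object@sequence) != object@length)
    msgs <- c(msgs, "sequence length does not equal genome length")
  ft <- object@features
  need <- c("name", "category", "strand", "conserved", "pseudo", "intervals")
  if (!all(need %in% names(ft)))
    msgs <- c(msgs, paste("features must have columns:",
                          paste(need, collapse = ", ")))
  else if (nrow(ft)) {
    if (any(!nzchar(ft$name))) msgs <- c(msgs, "feature names must be non-empty")
    if (!all(ft$strand %in% c(1L, -1L)))
      msgs <- c(msgs, "feature strand must be +1 or -1")
    for (i in seq_len(nrow(ft))) {
      iv <- ft$intervals[[i]]
      if (!is.matrix(iv) || ncol(iv) != 2L || nrow(iv) < 1L) {
        msgs <- c(msgs, sprintf("feature %d: intervals must be an n x 2 matrix", i))
        next
      }
      if (any(iv[, 1] < 0L) || any(iv[, 1] >= pmax(object@length, 1L)) ||
          any(iv[, 2] <= 0L) || any(iv[, 2] > object@length) ||
          any(iv[, 2] <= iv[, 1]))
        msgs <- c(msgs, sprintf(
          "feature %d (%s): spans must satisfy 0 <= start < end <= length",
          i, ft$name[i]))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' SignedGeneOrder: circular signed gene order of a genome
#'
#' The circular sequence of signed gene symbols of one genome, ordered by
#' ascending feature midpoint on the circle; the sign is the coding strand.
#' This is the substrate of all gene-order comparisons.
#'
#' @slot id character(1), source genome id.
#' @slot elements data.frame with columns \code{name}, \code{sign}
#'   (integer +1/-1), \code{midpoint} (numeric, genome coordinate) and
#'   \code{feature} (integer index into the source genome's feature table).
#'
#' @seealso [extractSignedOrder()], [adjacencyPairs()], [colinearBlocks()]
#' @exportClass SignedGeneOrder
setClass("SignedGeneOrder",
  representation(id = "character", elements = "data.frame"))

setValidity("SignedGeneOrder", function(object) {
  el <- object@elements
  if (!all(c("name", "sign") %in% names(el)))
    return("elements must have columns name, sign")
  if (nrow(el) && !all(el$sign %in% c(1L, -1L)))
    return("sign must be +1 or -1")
  TRUE
})

#' QuadripartiteStructure: IR/LSC/SSC partition of a circular genome
#'
#' Result of inverted-repeat detection: the two IR copies (ira and its
#' reverse-complement copy irb) and the two single-copy regions (lsc the
#' longer, ssc the shorter). Spans are 0-based half-open \code{c(start, end)}
#' on the circle; \code{end} may exceed the genome length to denote a span
#' that wraps the origin (positions are taken modulo the length).
#'
#' @slot ira,irb,lsc,ssc integer(2) spans.
#' @slot rrnOrientation character(1): \code{"toward_ssc"},
#'   \code{"toward_lsc"} or \code{"absent"}.
#' @slot irLength integer(1), length of one IR copy in bp.
#' @slot genomeLength integer(1).
#'
#' @seealso [detectInvertedRepeat()], [partitionConformity()]
#' @exportClass QuadripartiteStructure
setClass("QuadripartiteStructure",
  representation(
    ira = "integer", irb = "integer", lsc = "integer", ssc = "integer",
    rrnOrientation = "character", irLength = "integer",
    genomeLength = "integer"
  ))

#' PresenceAbsenceMatrix: conserved genes (or binary characters) by taxa
#'
#' Character states are \code{"present"}, \code{"pseudogene"} or
#' \code{"absent"}. Pseudogenes are treated as absent for parsimony by
#' default but kept distinct in reports.
#'
#' @slot states character matrix, rows = characters, columns = taxa.
#' @seealso [buildPresenceMatrix()], [coreGenes()], [dolloMap()]
#' @exportClass PresenceAbsenceMatrix
setClass("PresenceAbsenceMatrix", representation(states = "matrix"))

setValidity("PresenceAbsenceMatrix", function(object) {
  st <- object@states
  if (!is.character(st)) return("states must be a character matrix")
  if (length(st) && !all(st %in% c("present", "pseudogene", "absent")))
    return("states must be 'present', 'pseudogene' or 'absent'")
  if (is.null(rownames(st)) || is.null(colnames(st)))
    return("states must have row (character) and column (taxon) names")
  TRUE
})

#' DolloReconstruction: single-gain, minimum-loss history of one character
#'
#' Under Dollo parsimony a binary character is gained exactly once and can
#' only be lost thereafter; the reconstruction reports the gain node, the
#' minimal set of loss edges (each identified by its child node) and the
#' inferred state at every node.
#'
#' @slot character character(1), the character (gene) name.
#' @slot gainNode integer(1), ape node number of the single gain.
#' @slot lossEdges integer vector of child-node numbers of loss edges.
#' @slot lossCount integer(1).
#' @slot nodeStates logical vector indexed by ape node number.
#' @slot tree the \code{phylo} tree used.
#' @seealso [dolloMap()], [irLossEvents()]
#' @exportClass DolloReconstruction
setClass("DolloReconstruction",
  representation(
    character = "character", gainNode = "integer", lossEdges = "integer",
    lossCount = "integer", nodeStates = "logical", tree = "ANY"
  ))

#' SimulationConfig: parameters of the chloroplast-genome simulator
#'
#' @slot nGenes integer, conserved gene count of the ancestor.
#' @slot genomeBp integer, target genome size (bp).
#' @slot irLength integer, length of one IR copy (0 = no IR).
#' @slot irRrn character vector of rRNA genes placed inside the IR.
#' @slot nInversions,nLosses integer, events applied per branch.
#' @slot pIrLoss numeric in [0,1], per-branch probability of losing one
#'   IR copy.
#' @slot intergenicTargetPct,atPct numeric, targets for the intergenic
#'   fraction and A+T content of the ancestor (percent).
#' @slot seed integer, fixes all randomness.
#' @seealso [simulationConfig()], [simulateAncestor()], [evolveClade()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nGenes = "integer", genomeBp = "integer", irLength = "integer",
    irRrn = "character", nInversions = "integer", nLosses = "integer",
    pIrLoss = "numeric", intergenicTargetPct = "numeric", atPct = "numeric",
    seed = "integer"
  ))

setValidity("SimulationConfig", function(object) {
  msgs <- character(0)
  if (object@nGenes < 0L) msgs <- c(msgs, "nGenes must be >= 0")
  if (object@genomeBp < 0L) msgs <- c(msgs, "genomeBp must be >= 0")
  if (object@irLength < 0L) msgs <- c(msgs, "irLength must be >= 0")
  if (object@irLength > 0L && object@irLength >= object@genomeBp / 2)
    msgs <- c(msgs, "irLength must be < genomeBp/2")
  if (object@nInversions < 0L || object@nLosses < 0L)
    msgs <- c(msgs, "per-branch event counts must be >= 0")
  if (object@pIrLoss < 0 || object@pIrLoss > 1)
    msgs <- c(msgs, "pIrLoss must be in [0,1]")
  if (object@atPct < 0 || object@atPct > 100 ||
      object@intergenicTargetPct < 0 || object@intergenicTargetPct > 100)
    msgs <- c(msgs, "percent targets must be in [0,100]")
  if (length(msgs)) msgs else TRUE
})

#' SimulatedClade: a tree of simulated genomes with its event log
#'
#' @slot tree the \code{phylo} species tree.
#' @slot ancestor the root \linkS4class{ChloroGenome}.
#' @slot genomes named list of leaf \linkS4class{ChloroGenome}s.
#' @slot eventLog named list (by child node label/number) of per-branch
#'   event lists; replaying the log from the ancestor reproduces each leaf.
#' @seealso [evolveClade()], [replayEvents()]
#' @exportClass SimulatedClade
setClass("SimulatedClade",
  representation(tree = "ANY", ancestor = "ANY", genomes = "list",
                 eventLog = "list"))
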