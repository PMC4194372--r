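# Constructors, accessors and show methods.

#' Construct a ChloroGenome
#'
#' @param id taxon/accession label.
#' @param length genome size in bp.
#' @param features feature table (see \linkS4class{ChloroGenome}); built
#'   with the package's readers or the simulator in normal use.
#' @param sequence optional nucleotide string of length \code{length};
#'   \code{""} when absent.
#' @return a \linkS4class{ChloroGenome}.
#' @export
chloroGenome <- function(id, length, features = emptyFeatureTable(),
                         sequence = "") {
  new("ChloroGenome", id = as.character(id), length = as.integer(length),
      sequence = toupper(sequence), features = features)
}

#' @describeIn chloroGenome genome identifier.
#' @param x a ChloroGenome.
#' @export
genomeId <- function(x) x@id

#' @describeIn chloroGenome genome length in bp.
#' @export
genomeLength <- function(x) x@length

#' @describeIn chloroGenome feature table (one row per gene occurrence).
#' @export
genomeFeatures <- function(x) x@features

#' @describeIn chloroGenome nucleotide sequence; errors when absent unless
#'   \code{required = FALSE}.
#' @param required error when the sequence is missing?
#' @export
genomeSequence <- function(x, required = TRUE) {
  if (!nzchar(x@sequence) && required)
    stop("sequence absent for genome '", x@id, "'")
  x@sequence
}

#' @describeIn chloroGenome number of unique conserved gene names (IR and
#'   tRNA duplicates collapsed, fragmented genes counted once).
#' @export
nConservedGenes <- function(x) {
  ft <- x@features
  length(unique(baseGeneName(ft$name[ft$conserved])))
}

setMethod("show", "ChloroGenome", function(object) {
  ft <- object@features
  cat(sprintf("ChloroGenome '%s': %s bp (circular), %d features (%d conserved, %d unique conserved genes)\n",
              object@id, format(object@length, big.mark = ","), nrow(ft),
              sum(ft$conserved), nConservedGenes(object)))
  if (!nzchar(object@sequence)) cat("  sequence: absent\n")
})

#' Elements of a signed gene order
#'
#' @param x a \linkS4class{SignedGeneOrder}.
#' @return data.frame with columns \code{name}, \code{sign}.
#' @export
orderElements <- function(x) x@elements

setMethod("show", "SignedGeneOrder", function(object) {
  el <- object@elements
  cat(sprintf("SignedGeneOrder '%s': %d elements (circular)\n",
              object@id, nrow(el)))
  if (nrow(el)) {
    lab <- paste0(ifelse(el$sign > 0, "+", "-"), el$name)
    n <- min(8L, length(lab))
    cat("  ", paste(lab[seq_len(n)], collapse = " "),
        if (length(lab) > n) "..." else "", "\n")
  }
})

setMethod("show", "QuadripartiteStructure", function(object) {
  cat(sprintf("QuadripartiteStructure: IR %s bp, rRNA operon %s\n",
              format(object@irLength, big.mark = ","), object@rrnOrientation))
  cat(sprintf("  IRa [%d,%d)  IRb [%d,%d)  LSC [%d,%d)  SSC [%d,%d)\n",
              object@ira[1], object@ira[2], object@irb[1], object@irb[2],
              object@lsc[1], object@lsc[2], object@ssc[1], object@ssc[2]))
})

#' State matrix of a presence/absence matrix
#'
#' @param x a \linkS4class{PresenceAbsenceMatrix}.
#' @return character matrix of states.
#' @export
presenceStates <- function(x) x@states

#' Logical presence matrix
#'
#' @param x a \linkS4class{PresenceAbsenceMatrix}.
#' @param pseudoAsPresent count pseudogenes as present? Default FALSE: a
#'   pseudogene is a loss-in-progress for gene-content purposes.
#' @return logical matrix.
#' @export
isPresent <- function(x, pseudoAsPresent = FALSE) {
  ok <- c("present", if (pseudoAsPresent) "pseudogene")
  matrix(x@states %in% ok, nrow = nrow(x@states),
         dimnames = dimnames(x@states))
}

setMethod("show", "PresenceAbsenceMatrix", function(object) {
  st <- object@states
  cat(sprintf("PresenceAbsenceMatrix: %d characters x %d taxa (%d pseudogene cells)\n",
              nrow(st), ncol(st), sum(st == "pseudogene")))
})

setMethod("show", "DolloReconstruction", function(object) {
  cat(sprintf("DolloReconstruction '%s': gain at node %d, %d loss(es)\n",
              object@character, object@gainNode, object@lossCount))
})

#' Loss count of a Dollo reconstruction
#' @param x a \linkS4class{DolloReconstruction}.
#' @return integer.
#' @export
lossCount <- function(x) x@lossCount

#' Loss edges of a Dollo reconstruction
#'
#' Edges are identified by their child node; leaf children are reported by
#' label.
#' @param x a \linkS4class{DolloReconstruction}.
#' @return character vector of edge labels.
#' @export
lossEdges <- function(x) {
  tr <- x@tree
  vapply(x@lossEdges, function(v) {
    if (v <= length(tr$tip.label)) tr$tip.label[v]
    else paste0("node", v)
  }, character(1))
}

setMethod("show", "SimulatedClade", function(object) {
  cat(sprintf("SimulatedClade: %d leaves, %d logged branches\n",
              length(object@genomes), length(object@eventLog)))
})

#' Leaf genomes of a simulated clade
#' @param x a \linkS4class{SimulatedClade}.
#' @return named list of \linkS4class{ChloroGenome}s.
#' @export
cladeGenomes <- function(x) x@genomes

#' Event log of a simulated clade
#' @param x a \linkS4class{SimulatedClade}.
#' @return named list of per-branch event lists.
#' @export
cladeEventLog <- function(x) x@eventLog
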