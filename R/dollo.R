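# Conserved-gene repertoire comparison and Dollo most-parsimonious loss
# mapping on a fixed rooted species tree.

#' Build the presence/absence matrix of conserved genes across genomes
#'
#' A cell is \code{"present"} when the genome has at least one conserved
#' feature with that base name (IR and tRNA duplicates collapse to one;
#' fragmented genes count their base name once), \code{"pseudogene"} when
#' all such features are annotated pseudogenes, else \code{"absent"}.
#'
#' @param genomes list of \linkS4class{ChloroGenome}s.
#' @param catalog optional catalog restricting the gene universe (default:
#'   the union of conserved genes seen in the genomes).
#' @return a \linkS4class{PresenceAbsenceMatrix}.
#' @export
buildPresenceMatrix <- function(genomes, catalog = NULL) {
  ids <- vapply(genomes, genomeId, character(1))
  perGenome <- lapply(genomes, function(g) {
    ft <- genomeFeatures(g)
    ft <- ft[ft$conserved, , drop = FALSE]
    base <- baseGeneName(ft$name)
    list(present = unique(base[!ft$pseudo]),
         pseudo = unique(base[ft$pseudo]))
  })
  genes <- sort(unique(unlist(lapply(perGenome, function(p)
    c(p$present, p$pseudo)))))
  if (!is.null(catalog)) genes <- intersect(genes, catalog$name)
  st <- matrix("absent", nrow = length(genes), ncol = length(ids),
               dimnames = list(genes, ids))
  for (k in seq_along(perGenome)) {
    st[intersect(genes, perGenome[[k]]$pseudo), k] <- "pseudogene"
    st[intersect(genes, perGenome[[k]]$present), k] <- "present"
  }
  new("PresenceAbsenceMatrix", states = st)
}

#' Core genes shared by a set of taxa
#'
#' @param pam a \linkS4class{PresenceAbsenceMatrix}.
#' @param taxa taxa to intersect over (default: all columns).
#' @param pseudoAsPresent count pseudogenes as present?
#' @return sorted character vector of genes present in every listed taxon.
#' @export
coreGenes <- function(pam, taxa = colnames(presenceStates(pam)),
                      pseudoAsPresent = FALSE) {
  st <- presenceStates(pam)
  unknown <- setdiff(taxa, colnames(st))
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  pres <- isPresent(pam, pseudoAsPresent)[, taxa, drop = FALSE]
  sort(rownames(pres)[rowSums(pres) == length(taxa)])
}

# Fast tree bookkeeping shared by dolloMap: parent vector, postorder
# edge list, per-node all-absent flags.
.treeIndex <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tree$tip.label)
  par <- integer(nt + tree$Nnode)
  par[po$edge[, 2]] <- po$edge[, 1]
  root <- nt + 1L
  par[root] <- 0L
  list(edgePost = po$edge, par = par, ntips = nt, root = root)
}

#' Dollo most-parsimonious loss mapping of a binary character
#'
#' Under the Dollo model the character is gained exactly once; the
#' reconstruction places the gain (at the root, or at the last common
#' ancestor of the present leaves) and returns the minimal set of loss
#' edges: the maximal all-absent subtrees under the gain node. On a
#' polytomy each lost child subtree counts as its own loss (edges, not
#' nodes, carry events).
#'
#' @param tree rooted \code{phylo} tree (polytomies allowed).
#' @param presenceVector logical (or 0/1) vector named by leaf labels.
#' @param gainPolicy \code{"lca_of_present"} (default) or \code{"root"};
#'   \code{"root"} suits characters known to be ancestral (e.g. present
#'   in outgroups).
#' @param character name of the character, for reporting.
#' @return a \linkS4class{DolloReconstruction}.
#' @export
dolloMap <- function(tree, presenceVector,
                     gainPolicy = c("lca_of_present", "root"),
                     character = NA_character_) {
  gainPolicy <- match.arg(gainPolicy)
  nt <- length(tree$tip.label)
  pv <- presenceVector[tree$tip.label]
  if (anyNA(pv))
    stop("presence vector missing leaves: ",
         paste(tree$tip.label[is.na(pv)], collapse = ", "))
  pv <- as.logical(pv)
  idx <- .treeIndex(tree)
  nn <- nt + tree$Nnode
  allAbs <- c(!pv, rep(TRUE, tree$Nnode))
  ep <- idx$edgePost
  for (e in seq_len(nrow(ep))) {
    allAbs[ep[e, 1]] <- allAbs[ep[e, 1]] && allAbs[ep[e, 2]]
  }
  if (gainPolicy == "lca_of_present") {
    if (!any(pv)) stop("character never present (gain policy lca_of_present)")
    gain <- .mrca(idx$par, which(pv), idx$root)
  } else {
    gain <- idx$root
  }
  under <- logical(nn)
  under[gain] <- TRUE
  for (e in rev(seq_len(nrow(ep)))) {         # preorder
    if (under[ep[e, 1]]) under[ep[e, 2]] <- TRUE
  }
  par <- idx$par
  cand <- which(under & allAbs)
  cand <- cand[cand != gain]
  loss <- cand[par[cand] == gain | !allAbs[par[cand]]]
  lost <- logical(nn)
  for (e in rev(seq_len(nrow(ep)))) {
    if (under[ep[e, 1]]) {
      lost[ep[e, 2]] <- lost[ep[e, 1]] || ep[e, 2] %in% loss
    }
  }
  new("DolloReconstruction", character = as.character(character),
      gainNode = as.integer(gain), lossEdges = as.integer(sort(loss)),
      lossCount = length(loss), nodeStates = under & !lost, tree = tree)
}

# MRCA of a set of tips, via parent-pointer climbing.
.mrca <- function(par, tips, root) {
  if (length(tips) == 1L) return(tips)
  chain <- integer(0)
  v <- tips[1]
  while (v != 0L) { chain <- c(chain, v); v <- par[v] }
  anc <- chain
  for (t in tips[-1]) {
    v <- t
    while (!(v %in% anc)) v <- par[v]
    anc <- anc[which(anc == v):length(anc)]
  }
  anc[1]
}

#' Inverted-repeat loss events on a species tree
#'
#' Dollo mapping of IR presence with the gain fixed at the root (the IR
#' is ancestral for green plants): the loss count is the minimum number
#' of independent IR losses explaining the observed distribution.
#'
#' @param tree rooted \code{phylo} tree.
#' @param irPresenceVector logical (or 0/1) vector named by leaf labels.
#' @return a \linkS4class{DolloReconstruction}.
#' @export
irLossEvents <- function(tree, irPresenceVector) {
  dolloMap(tree, irPresenceVector, gainPolicy = "root", character = "IR")
}

#' Per-character Dollo loss table
#'
#' Maps every character of a presence/absence matrix on the tree and
#' tabulates loss counts. The gain policy per character follows the
#' ancestral-state convention: root when the character is present in at
#' least one of the given outgroup taxa, LCA of present leaves otherwise.
#'
#' @param pam a \linkS4class{PresenceAbsenceMatrix} whose columns are tree
#'   leaves.
#' @param tree rooted \code{phylo} tree covering the matrix columns.
#' @param outgroups outgroup taxon ids (may be empty).
#' @param pseudoAsPresent count pseudogenes as present?
#' @return data.frame with columns \code{character}, \code{gainPolicy},
#'   \code{lossCount}, \code{lossEdges} (comma-separated edge labels).
#' @export
dolloLossTable <- function(pam, tree, outgroups = character(0),
                           pseudoAsPresent = FALSE) {
  pres <- isPresent(pam, pseudoAsPresent)
  missingLeaves <- setdiff(tree$tip.label, colnames(pres))
  if (length(missingLeaves))
    stop("matrix lacks tree leaves: ", paste(missingLeaves, collapse = ", "))
  rows <- lapply(rownames(pres), function(g) {
    pv <- pres[g, tree$tip.label]
    if (!any(pv)) return(NULL)
    pol <- if (length(outgroups) && any(pv[intersect(outgroups, names(pv))]))
      "root" else "lca_of_present"
    rec <- dolloMap(tree, pv, gainPolicy = pol, character = g)
    data.frame(character = g, gainPolicy = pol, lossCount = lossCount(rec),
               lossEdges = paste(lossEdges(rec), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(character = character(0),
                                      gainPolicy = character(0),
                                      lossCount = integer(0),
                                      lossEdges = character(0))
  rownames(out) <- NULL
  out
}
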