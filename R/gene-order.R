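# Signed gene-order comparison: adjacency pairs, ancestral-pair selection,
# colinear synteny blocks and synteny statistics.

#' PairConservationMatrix: conserved signed adjacency pairs across genomes
#'
#' @slot presence logical matrix, rows = canonical pair keys, columns =
#'   genome ids; \code{TRUE} iff the pair is an adjacency of that genome.
#' @slot members data.frame (key, gene1, sign1, gene2, sign2) giving one
#'   reading of each canonical pair.
#' @slot selection character vector per pair: \code{"A"}, \code{"B"} or
#'   \code{NA} (rule that selected the pair as ancestral, if any).
#' @slot cells character matrix parallel to \code{presence}:
#'   \code{"present"}, \code{"absent_gene_loss"} (a member gene is missing
#'   from that genome's repertoire) or \code{"absent_rearranged"}.
#' @seealso [pairConservationMatrix()], [selectAncestralPairs()]
#' @exportClass PairConservationMatrix
setClass("PairConservationMatrix",
  representation(presence = "matrix", members = "data.frame",
                 selection = "character", cells = "matrix"))

setMethod("show", "PairConservationMatrix", function(object) {
  cat(sprintf("PairConservationMatrix: %d pairs x %d genomes (%d selected)\n",
              nrow(object@presence), ncol(object@presence),
              sum(!is.na(object@selection))))
})

#' Extract the circular signed gene order of a genome
#'
#' Conserved gene occurrences sorted by ascending feature midpoint on the
#' circle (wrap-aware); the sign of each element is its coding strand.
#'
#' @param genome a \linkS4class{ChloroGenome} with at least one conserved
#'   feature.
#' @param collapseIr drop the second IR copy's features before extracting
#'   the order (the IR is drawn once per comparison)? Requires \code{quad}
#'   or a sequence to detect it from.
#' @param quad optional precomputed \linkS4class{QuadripartiteStructure}.
#' @param irMinLen minimum IR length when detecting for \code{collapseIr}.
#' @return a \linkS4class{SignedGeneOrder}.
#' @export
extractSignedOrder <- function(genome, collapseIr = FALSE, quad = NULL,
                               irMinLen = 1000L) {
  ft <- genomeFeatures(genome)
  idx <- which(ft$conserved)
  if (!length(idx)) stop("no conserved features in genome '", genomeId(genome), "'")
  n <- genomeLength(genome)
  if (collapseIr && is.null(quad)) {
    if (nzchar(genome@sequence)) {
      rrn <- ft[ft$category == "rRNA", , drop = FALSE]
      quad <- detectInvertedRepeat(genome@sequence, minLen = irMinLen,
                                   requireRrn = if (nrow(rrn)) rrn)
    }
  }
  mids <- vapply(idx, function(i) spanMidpoint(ft$intervals[[i]], n), numeric(1))
  if (collapseIr && !is.null(quad)) {
    inIrb <- vapply(mids, function(m) circContains(quad@irb, m, n), logical(1))
    idx <- idx[!inIrb]
    mids <- mids[!inIrb]
  }
  o <- order(mids)
  new("SignedGeneOrder", id = genomeId(genome),
      elements = data.frame(name = ft$name[idx][o],
                            sign = ft$strand[idx][o],
                            midpoint = mids[o], feature = idx[o],
                            stringsAsFactors = FALSE))
}

# Canonical key of one signed adjacency: invariant under reading the
# circle in the opposite direction with flipped signs.
.pairKey <- function(na, sa, nb, sb) {
  enc <- function(n1, s1, n2, s2) {
    paste0(n1, if (s1 > 0) "+" else "-", "|", n2, if (s2 > 0) "+" else "-")
  }
  fwd <- enc(na, sa, nb, sb)
  rev <- enc(nb, -sb, na, -sa)
  if (fwd <= rev) fwd else rev
}

#' Signed adjacency pairs of a circular gene order
#'
#' One pair per circular adjacency, canonicalized so that
#' \code{key((a,sa),(b,sb)) == key((b,-sb),(a,-sa))}. Orders with fewer
#' than two elements yield an empty set.
#'
#' @param order a \linkS4class{SignedGeneOrder}.
#' @return data.frame with columns \code{key}, \code{gene1}, \code{sign1},
#'   \code{gene2}, \code{sign2} (one canonical reading per pair), one row
#'   per distinct pair.
#' @export
adjacencyPairs <- function(order) {
  el <- orderElements(order)
  m <- nrow(el)
  empty <- data.frame(key = character(0), gene1 = character(0),
                      sign1 = integer(0), gene2 = character(0),
                      sign2 = integer(0), stringsAsFactors = FALSE)
  if (m < 2L) return(empty)
  nxt <- c(seq_len(m)[-1], 1L)
  keys <- character(m)
  g1 <- character(m); s1 <- integer(m); g2 <- character(m); s2 <- integer(m)
  for (i in seq_len(m)) {
    j <- nxt[i]
    keys[i] <- .pairKey(el$name[i], el$sign[i], el$name[j], el$sign[j])
    g1[i] <- el$name[i]; s1[i] <- el$sign[i]
    g2[i] <- el$name[j]; s2[i] <- el$sign[j]
  }
  keep <- !duplicated(keys)
  data.frame(key = keys[keep], gene1 = g1[keep], sign1 = s1[keep],
             gene2 = g2[keep], sign2 = s2[keep], stringsAsFactors = FALSE)
}

#' Build the pair-conservation matrix over a set of genomes
#'
#' @param orders named list of \linkS4class{SignedGeneOrder}s (names =
#'   genome ids; unnamed lists take the orders' own ids).
#' @return a \linkS4class{PairConservationMatrix} (selection flags unset;
#'   see [selectAncestralPairs()]).
#' @export
pairConservationMatrix <- function(orders) {
  ids <- names(orders)
  if (is.null(ids)) ids <- vapply(orders, function(o) o@id, character(1))
  pairSets <- lapply(orders, adjacencyPairs)
  allPairs <- do.call(rbind, pairSets)
  allPairs <- allPairs[!duplicated(allPairs$key), , drop = FALSE]
  allPairs <- allPairs[order(allPairs$key), , drop = FALSE]
  presence <- vapply(pairSets, function(ps) allPairs$key %in% ps$key,
                     logical(nrow(allPairs)))
  presence <- matrix(presence, nrow = nrow(allPairs),
                     dimnames = list(allPairs$key, ids))
  cells <- matrix(ifelse(presence, "present", "absent_rearranged"),
                  nrow = nrow(presence), dimnames = dimnames(presence))
  new("PairConservationMatrix", presence = presence, members = allPairs,
      selection = rep(NA_character_, nrow(allPairs)), cells = cells)
}

#' Select ancestral gene pairs
#'
#' Flags the adjacency pairs regarded as ancestral, by two rules applied
#' to a pair-conservation matrix over ingroup (prasinophyte) genomes and
#' outgroup genomes:
#' \describe{
#'   \item{rule A}{the pair is present in at least two ingroup genomes
#'     from distinct lineages and in at least one outgroup;}
#'   \item{rule B}{a member gene of the pair is absent from at least two
#'     ingroup lineages or from both outgroups, and the pair is present in
#'     at least one ingroup lineage (outgroup presence not required).}
#' }
#' Cells where the pair is absent are classified as
#' \code{"absent_gene_loss"} when a member gene is missing from that
#' genome's repertoire, else \code{"absent_rearranged"}.
#'
#' @param pcm a \linkS4class{PairConservationMatrix}.
#' @param lineageMap named character vector mapping each ingroup genome id
#'   to its lineage label.
#' @param outgroupIds character vector of outgroup genome ids (columns of
#'   \code{pcm}).
#' @param repertoires a \linkS4class{PresenceAbsenceMatrix} (or logical
#'   matrix genes x taxa) giving gene presence per genome.
#' @return the matrix with \code{selection} flags and cell classes filled.
#' @export
selectAncestralPairs <- function(pcm, lineageMap, outgroupIds, repertoires) {
  pres <- pcm@presence
  ids <- colnames(pres)
  ingroup <- setdiff(ids, outgroupIds)
  unmapped <- setdiff(ingroup, names(lineageMap))
  if (length(unmapped))
    stop("genome id(s) not in lineage map: ", paste(unmapped, collapse = ", "))
  rep <- if (is(repertoires, "PresenceAbsenceMatrix"))
    isPresent(repertoires) else repertoires
  lin <- lineageMap[ingroup]
  lineages <- unique(lin)
  sel <- rep(NA_character_, nrow(pres))
  cells <- pcm@cells
  hasGene <- function(gene, taxon) {
    g <- baseGeneName(gene)
    g %in% rownames(rep) && taxon %in% colnames(rep) && rep[g, taxon]
  }
  for (p in seq_len(nrow(pres))) {
    g1 <- pcm@members$gene1[p]; g2 <- pcm@members$gene2[p]
    inPres <- pres[p, ingroup]
    linWithPair <- unique(lin[inPres])
    outPres <- any(pres[p, intersect(outgroupIds, ids)])
    # lineages where a member gene is absent from every genome of the
    # lineage; outgroups lacking a member gene
    lineageLacks <- vapply(lineages, function(L) {
      tax <- ingroup[lin == L]
      any(vapply(c(g1, g2), function(g)
        all(!vapply(tax, function(tx) hasGene(g, tx), logical(1))),
        logical(1)))
    }, logical(1))
    outLacks <- all(vapply(intersect(outgroupIds, colnames(rep)),
                           function(tx) !hasGene(g1, tx) || !hasGene(g2, tx),
                           logical(1))) && length(outgroupIds) > 0
    if (sum(inPres) >= 2 && length(linWithPair) >= 2 && outPres) {
      sel[p] <- "A"
    } else if ((sum(lineageLacks) >= 2 || outLacks) &&
               length(linWithPair) >= 1) {
      sel[p] <- "B"
    }
    for (tx in ids) {
      if (!pres[p, tx]) {
        cells[p, tx] <- if (!hasGene(g1, tx) || !hasGene(g2, tx))
          "absent_gene_loss" else "absent_rearranged"
      }
    }
  }
  new("PairConservationMatrix", presence = pres, members = pcm@members,
      selection = sel, cells = cells)
}

# Reduce two signed orders to the genes occurring exactly once in each.
.reduceShared <- function(el1, el2) {
  c1 <- table(el1$name); c2 <- table(el2$name)
  shared <- intersect(names(c1)[c1 == 1], names(c2)[c2 == 1])
  skipped <- setdiff(union(el1$name, el2$name), shared)
  list(r1 = el1[el1$name %in% shared, , drop = FALSE],
       r2 = el2[el2$name %in% shared, , drop = FALSE],
       skipped = skipped)
}

#' Colinear synteny blocks between two circular signed gene orders
#'
#' Both orders are first reduced to genes occurring exactly once in each
#' (duplicated names - second IR copies, duplicated tRNAs - are excluded
#' from matching); blocks are maximal runs of shared genes that are
#' consecutive in both reduced circular orders, in identical or globally
#' reversed-and-sign-flipped orientation. Blocks may wrap the origin.
#'
#' @param order1,order2 \linkS4class{SignedGeneOrder}s.
#' @param minLen minimum number of genes per reported block (default 2:
#'   the gene-pair baseline; singletons are not blocks).
#' @param maxGap tolerated displacement (in genes, along the reduced
#'   partner order) between consecutive block members; 0 = strictly
#'   colinear.
#' @return data.frame with one row per block, ordered by position in
#'   \code{order1}: \code{n} (gene count), \code{orientation}
#'   (\code{"same"}/\code{"inverted"}), \code{genes} (list column, gene
#'   names in order1 order), \code{start1}, \code{start2} (1-based
#'   indices into the reduced orders). Attribute \code{"skipped"} lists
#'   gene names excluded as duplicates or unshared.
#' @export
colinearBlocks <- function(order1, order2, minLen = 2L, maxGap = 0L) {
  red <- .reduceShared(orderElements(order1), orderElements(order2))
  r1 <- red$r1; r2 <- red$r2
  m <- nrow(r1)
  empty <- data.frame(n = integer(0), orientation = character(0),
                      genes = I(list()), start1 = integer(0),
                      start2 = integer(0), stringsAsFactors = FALSE)
  attr(empty, "skipped") <- red$skipped
  if (m == 0L) {
    warning("no shared single-copy genes between '", order1@id, "' and '",
            order2@id, "'")
    return(empty)
  }
  pos2 <- match(r1$name, r2$name)
  rel <- r1$sign * r2$sign[pos2]
  if (m == 1L) {
    blocks <- if (minLen <= 1L)
      data.frame(n = 1L, orientation = ifelse(rel > 0, "same", "inverted"),
                 genes = I(list(r1$name)), start1 = 1L, start2 = pos2,
                 stringsAsFactors = FALSE)
      else empty
    attr(blocks, "skipped") <- red$skipped
    return(blocks)
  }
  nxt <- c(seq_len(m)[-1], 1L)
  step <- (pos2[nxt] - pos2) %% m
  linked <- (rel == rel[nxt]) &
    ((rel > 0 & step >= 1L & step <= 1L + maxGap) |
     (rel < 0 & (m - step) %% m >= 1L & (m - step) %% m <= 1L + maxGap))
  blocks <- list()
  if (all(linked)) {
    blocks[[1]] <- seq_len(m)
  } else {
    startIdx <- which(!linked[c(m, seq_len(m - 1L))])  # i with i-1 not linked
    for (s in startIdx) {
      run <- s
      i <- s
      while (linked[i]) {
        i <- nxt[i]
        run <- c(run, i)
      }
      blocks[[length(blocks) + 1L]] <- run
    }
  }
  rows <- lapply(blocks, function(run) {
    if (length(run) < minLen) return(NULL)
    data.frame(n = length(run),
               orientation = if (rel[run[1]] > 0) "same" else "inverted",
               genes = I(list(r1$name[run])),
               start1 = run[1], start2 = pos2[run[1]],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(out)) out <- out[order(out$start1), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- red$skipped
  out
}

#' Synteny statistics for a pair of genomes
#'
#' @param blocks result of [colinearBlocks()] for the two orders.
#' @param order1,order2 the \linkS4class{SignedGeneOrder}s compared.
#' @param nGenes1,nGenes2 denominators: unique conserved gene counts of
#'   the two genomes (default: unique base names in each order).
#' @return list with \code{nBlocks}, \code{nBlockGenes} (unique gene names
#'   across blocks), \code{pctOfG1}, \code{pctOfG2} (integer percents) and
#'   \code{largestBlock} (gene names of the maximal block; ties broken by
#'   position in \code{order1}).
#' @export
syntenyStats <- function(blocks, order1, order2,
                         nGenes1 = NULL, nGenes2 = NULL) {
  if (is.null(nGenes1))
    nGenes1 <- length(unique(baseGeneName(orderElements(order1)$name)))
  if (is.null(nGenes2))
    nGenes2 <- length(unique(baseGeneName(orderElements(order2)$name)))
  genes <- unique(unlist(blocks$genes))
  largest <- if (nrow(blocks)) blocks$genes[[which.max(blocks$n)]] else character(0)
  list(
    nBlocks = nrow(blocks),
    nBlockGenes = length(genes),
    pctOfG1 = as.integer(roundHalfUp(100 * length(genes) / max(nGenes1, 1L), 0L)),
    pctOfG2 = as.integer(roundHalfUp(100 * length(genes) / max(nGenes2, 1L), 0L)),
    largestBlock = largest
  )
}
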