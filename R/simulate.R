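# Seeded simulator of chloroplast-like circular genomes evolving along a
# rooted tree by inversions, gene losses and inverted-repeat loss. Every
# event is logged with exact coordinates so leaves can be replayed and
# pipeline results checked against planted truth.

#' Simulation configuration
#'
#' Defaults emulate the architecture observed across sequenced
#' prasinophyte chloroplast genomes: ~60-200 kb circles carrying ~85-130
#' conserved genes on both strands, A+T around 58-68 percent, intergenic
#' fractions of roughly 10-45 percent, and (optionally) a large IR
#' containing the rRNA operon.
#'
#' @param nGenes conserved gene count of the ancestor.
#' @param genomeBp target genome size in bp.
#' @param irLength length of one IR copy in bp (0 = no IR); must exceed
#'   the rRNA operon it contains and stay below \code{genomeBp/2}.
#' @param irRrn rRNA genes placed inside the IR.
#' @param nInversions,nLosses events applied on every branch.
#' @param pIrLoss per-branch probability that one IR copy is deleted.
#' @param intergenicTargetPct,atPct ancestor targets (percent), each hit
#'   to within about one point.
#' @param seed integer seed fixing all randomness.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nGenes = 110L, genomeBp = 100000L,
                             irLength = 0L,
                             irRrn = c("rrs", "rrl", "rrf"),
                             nInversions = 3L, nLosses = 2L,
                             pIrLoss = 0.15,
                             intergenicTargetPct = 20, atPct = 62,
                             seed = 1L) {
  new("SimulationConfig", nGenes = as.integer(nGenes),
      genomeBp = as.integer(genomeBp), irLength = as.integer(irLength),
      irRrn = if (irLength > 0) irRrn else character(0),
      nInversions = as.integer(nInversions), nLosses = as.integer(nLosses),
      pIrLoss = pIrLoss, intergenicTargetPct = intergenicTargetPct,
      atPct = atPct, seed = as.integer(seed))
}

.rrnLengths <- c(rrs = 1491L, rrl = 2904L, rrf = 121L)

# Split `total` bp into `k` non-negative spacer widths (deterministic
# given the RNG state).
.splitSpacers <- function(total, k) {
  if (k == 0L) return(integer(0))
  if (total <= 0L) return(rep(0L, k))
  cuts <- sort(sample.int(total + k - 1L, k - 1L))
  as.integer(diff(c(0L, cuts, total + k)) - 1L)
}

#' Simulate an ancestral chloroplast-like genome
#'
#' Builds a circular genome with \code{nGenes} named conserved features
#' (names drawn from the shipped catalog), random strands, spacers tuned
#' to hit the intergenic target, an i.i.d. sequence at the configured A+T
#' bias, and optionally an exact IR containing the rRNA operon (layout
#' LSC-IRa-SSC-IRb; the operon is transcribed toward the SSC).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{ChloroGenome}.
#' @export
simulateAncestor <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@genomeBp
  if (config@nGenes == 0L)
    return(chloroGenome("ancestor", n, emptyFeatureTable(),
                        randomSeq(n, config@atPct)))
  cat <- conservedCatalog()
  irOn <- config@irLength > 0L
  rrn <- if (irOn) config@irRrn else character(0)
  pool <- setdiff(cat$name, rrn)
  nOther <- config@nGenes - length(rrn)
  if (nOther < 0L) stop("nGenes smaller than the IR rRNA gene set")
  if (nOther > length(pool)) stop("nGenes exceeds the catalog size")
  others <- sample(pool, nOther)
  catOf <- cat$category[match(c(others, rrn), cat$name)]
  names(catOf) <- c(others, rrn)
  rawLen <- vapply(others, function(g) {
    switch(catOf[[g]],
           tRNA = sample(72:90, 1L),
           rRNA = .rrnLengths[[g]],
           sample(300:2400, 1L))
  }, numeric(1))
  rrnSum <- if (irOn) sum(.rrnLengths[rrn]) else 0L
  if (irOn && config@irLength < rrnSum + length(rrn) + 1L)
    stop("irLength too small for the rRNA operon")
  genicTarget <- round(n * (1 - config@intergenicTargetPct / 100)) - 2L * rrnSum
  isP <- catOf[others] %in% c("protein", "other", "orf")
  fixed <- sum(rawLen[!isP])
  if (any(isP)) {
    scale <- max(0.1, (genicTarget - fixed) / sum(rawLen[isP]))
    rawLen[isP] <- pmax(90L, round(rawLen[isP] * scale))
  }
  geneLen <- as.integer(rawLen)
  names(geneLen) <- others
  # spacer budgets: IRa internal gaps sum to irLength - rrnSum; the rest
  # of the circle gets what remains of the size target
  scBudget <- n - 2L * config@irLength - sum(geneLen)
  if (scBudget < 0L) stop("genomeBp too small for the drawn gene lengths")
  scSpacers <- .splitSpacers(scBudget, nOther + 1L)
  irSpacers <- if (irOn)
    .splitSpacers(config@irLength - rrnSum, length(rrn) + 1L) else integer(0)
  # layout: [LSC: half the genes][IRa: rrn operon][SSC: rest][IRb]
  nLsc <- if (irOn) ceiling(nOther / 2) else nOther
  lscGenes <- others[seq_len(nLsc)]
  sscGenes <- if (nLsc < nOther) others[(nLsc + 1L):nOther] else character(0)
  pos <- 0L
  k <- 0L
  feats <- list()
  addGene <- function(g, strand, len) {
    feats[[length(feats) + 1L]] <<- list(
      name = g, category = unname(catOf[[g]]), strand = strand,
      intervals = span(pos, pos + len))
    pos <<- pos + len
  }
  for (g in lscGenes) {
    k <- k + 1L; pos <- pos + scSpacers[k]
    addGene(g, sample(c(1L, -1L), 1L), geneLen[[g]])
  }
  ira <- NULL
  if (irOn) {
    iraStart <- pos
    for (j in seq_along(rrn)) {
      pos <- pos + irSpacers[j]
      addGene(rrn[j], 1L, .rrnLengths[[rrn[j]]])
    }
    pos <- pos + irSpacers[length(irSpacers)]
    ira <- c(iraStart, pos)
    stopifnot(pos - iraStart == config@irLength)
  }
  for (g in sscGenes) {
    k <- k + 1L; pos <- pos + scSpacers[k]
    addGene(g, sample(c(1L, -1L), 1L), geneLen[[g]])
  }
  k <- k + 1L; pos <- pos + scSpacers[k]
  uniqueLen <- pos
  sq <- randomSeq(uniqueLen, config@atPct)
  if (irOn) {
    irbStart <- uniqueLen
    irbSeq <- revcompStr(substr(sq, ira[1] + 1L, ira[2]))
    sq <- paste0(sq, irbSeq)
    # break the bases flanking the two copies so the planted IR is the
    # exactly maximal reverse-complement pair
    total0 <- nchar(sq)
    comp1 <- c(A = "T", C = "G", G = "C", T = "A")
    fixFlank <- function(s, i, partner) {
      # make base at 0-based i mismatch the revcomp extension partner
      if (substr(s, i + 1L, i + 1L) == comp1[[substr(s, partner + 1L, partner + 1L)]]) {
        cur <- substr(s, i + 1L, i + 1L)
        repl <- setdiff(c("A", "C", "G", "T"),
                        c(cur, comp1[[substr(s, partner + 1L, partner + 1L)]]))[1]
        substr(s, i + 1L, i + 1L) <- repl
      }
      s
    }
    sq <- fixFlank(sq, ira[1] - 1L, 0L)                  # left of IRa vs past IRb
    sq <- fixFlank(sq, ira[2], irbStart - 1L)            # right of IRa vs before IRb
    for (f in feats[vapply(feats, function(f) f$name %in% rrn, logical(1))]) {
      s <- f$intervals[1, 1]; e <- f$intervals[1, 2]
      feats[[length(feats) + 1L]] <- list(
        name = f$name, category = f$category, strand = -f$strand,
        intervals = span(irbStart + (ira[2] - e), irbStart + (ira[2] - s)))
    }
  }
  total <- nchar(sq)
  ord <- order(vapply(feats, function(f) f$intervals[1, 1], numeric(1)))
  feats <- feats[ord]
  nms <- vapply(feats, `[[`, character(1), "name")
  ft <- makeFeatureTable(
    name = nms,
    category = vapply(feats, `[[`, character(1), "category"),
    strand = vapply(feats, `[[`, integer(1), "strand"),
    conserved = TRUE, pseudo = FALSE,
    intervals = lapply(feats, `[[`, "intervals"))
  chloroGenome("ancestor", total, ft, sq)
}

# --- event application (shared by evolveClade and replayEvents) ---------

# Internal mutable genome state: seq (string), ft (feature table),
# ira/irb (linear spans or NULL).
.stateFromGenome <- function(g, ira = NULL, irb = NULL) {
  list(seq = genomeSequence(g, required = TRUE), ft = genomeFeatures(g),
       ira = ira, irb = irb)
}

.stateToGenome <- function(st, id) {
  chloroGenome(id, nchar(st$seq), st$ft, st$seq)
}

.shiftSpan <- function(s, at, by) {
  # shift coordinates >= at by `by` (deletion upstream)
  ifelse(s >= at, s + by, s)
}

.applyLoss <- function(st, geneIndex) {
  iv <- st$ft$intervals[[geneIndex]]
  stopifnot(nrow(iv) == 1L)
  s <- iv[1, 1]; e <- iv[1, 2]
  w <- e - s
  st$seq <- paste0(substr(st$seq, 1, s), substr(st$seq, e + 1L, nchar(st$seq)))
  st$ft <- st$ft[-geneIndex, , drop = FALSE]
  st$ft$intervals <- lapply(st$ft$intervals, function(m) {
    m[] <- .shiftSpan(m, e, -w); m
  })
  for (arc in c("ira", "irb")) {
    if (!is.null(st[[arc]])) st[[arc]] <- .shiftSpan(st[[arc]], e, -w)
  }
  rownames(st$ft) <- NULL
  st
}

.applyIrLoss <- function(st) {
  stopifnot(!is.null(st$irb))
  s <- st$irb[1]; e <- st$irb[2]
  w <- e - s
  inside <- vapply(st$ft$intervals, function(m)
    m[1, 1] >= s && m[nrow(m), 2] <= e, logical(1))
  st$seq <- paste0(substr(st$seq, 1, s), substr(st$seq, e + 1L, nchar(st$seq)))
  st$ft <- st$ft[!inside, , drop = FALSE]
  st$ft$intervals <- lapply(st$ft$intervals, function(m) {
    m[] <- .shiftSpan(m, e, -w); m
  })
  st$ira <- NULL
  st$irb <- NULL
  rownames(st$ft) <- NULL
  st
}

.applyInversion <- function(st, b1, b2) {
  seg <- substr(st$seq, b1 + 1L, b2)
  st$seq <- paste0(substr(st$seq, 1, b1), revcompStr(seg),
                   substr(st$seq, b2 + 1L, nchar(st$seq)))
  flip <- function(sp) c(b1 + b2 - sp[2], b1 + b2 - sp[1])
  inSeg <- vapply(st$ft$intervals, function(m)
    m[1, 1] >= b1 && m[nrow(m), 2] <= b2, logical(1))
  for (i in which(inSeg)) {
    st$ft$intervals[[i]] <- span(flip(c(st$ft$intervals[[i]][1, 1],
                                        st$ft$intervals[[i]][1, 2]))[1],
                                 flip(c(st$ft$intervals[[i]][1, 1],
                                        st$ft$intervals[[i]][1, 2]))[2])
    st$ft$strand[i] <- -st$ft$strand[i]
  }
  for (arc in c("ira", "irb")) {
    a <- st[[arc]]
    if (!is.null(a) && a[1] >= b1 && a[2] <= b2) st[[arc]] <- flip(a)
  }
  if (!is.null(st$ira) && !is.null(st$irb) && st$ira[1] > st$irb[1]) {
    tmp <- st$ira; st$ira <- st$irb; st$irb <- tmp
  }
  ord <- order(vapply(st$ft$intervals, function(m) m[1, 1], numeric(1)))
  st$ft <- st$ft[ord, , drop = FALSE]
  rownames(st$ft) <- NULL
  st
}

# Candidate loss targets: conserved, single-occurrence, non-rRNA,
# single-span, outside the IR copies.
.lossCandidates <- function(st) {
  ft <- st$ft
  counts <- table(ft$name)
  ok <- ft$conserved & ft$category != "rRNA" &
    counts[ft$name] == 1L &
    vapply(ft$intervals, nrow, integer(1)) == 1L
  if (!is.null(st$ira)) {
    inIr <- vapply(ft$intervals, function(m) {
      (m[1, 1] >= st$ira[1] && m[1, 2] <= st$ira[2]) ||
        (m[1, 1] >= st$irb[1] && m[1, 2] <= st$irb[2])
    }, logical(1))
    ok <- ok & !inIr
  }
  which(ok)
}

# Cut points usable as inversion breakpoints: positions that split no
# feature and no IR copy.
.cutPoints <- function(st) {
  n <- nchar(st$seq)
  bad <- logical(n + 1L)
  mark <- function(s, e) if (e - s > 1L) bad[(s + 2L):e] <<- TRUE
  for (m in st$ft$intervals) for (r in seq_len(nrow(m)))
    mark(m[r, 1], m[r, 2])
  if (!is.null(st$ira)) { mark(st$ira[1], st$ira[2]); mark(st$irb[1], st$irb[2]) }
  which(!bad[seq_len(n)]) - 1L   # cut before position p (0-based), p in 0..n-1
}

#' Evolve an ancestral genome along a rooted tree
#'
#' Walks the tree from the root; on every branch applies, in order:
#' \code{nLosses} gene losses (uniform over current single-copy conserved
#' genes, never an rRNA gene or an IR resident), loss of one IR copy with
#' probability \code{pIrLoss}, then \code{nInversions} random segment
#' reversals with sign flips (breakpoints never split a feature or an IR
#' copy). Every event is logged with exact coordinates; replaying the log
#' from the ancestor reproduces each leaf byte for byte
#' ([replayEvents()]).
#'
#' @param ancestor a \linkS4class{ChloroGenome} with sequence (typically
#'   from [simulateAncestor()]).
#' @param tree rooted \code{phylo} tree; its tips name the leaf genomes.
#' @param config a \linkS4class{SimulationConfig}; the RNG stream is
#'   seeded from \code{config@seed}.
#' @return a \linkS4class{SimulatedClade}.
#' @export
evolveClade <- function(ancestor, tree, config) {
  set.seed(config@seed + 1L)
  quad <- if (config@irLength > 0L)
    detectInvertedRepeat(genomeSequence(ancestor),
                         minLen = max(30L, min(1000L, config@irLength))) else NULL
  rootState <- .stateFromGenome(
    ancestor,
    ira = if (!is.null(quad)) c(quad@ira[1], quad@ira[2]),
    irb = if (!is.null(quad)) c(quad@irb[1], quad@irb[2]))
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  nt <- length(tree$tip.label)
  states <- vector("list", nt + tree$Nnode)
  states[[nt + 1L]] <- rootState
  log <- list()
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; child <- edges[e, 2]
    st <- states[[par]]
    events <- list()
    for (l in seq_len(config@nLosses)) {
      cand <- .lossCandidates(st)
      if (!length(cand)) stop("loss count exceeds available genes")
      pick <- cand[sample.int(length(cand), 1L)]
      events[[length(events) + 1L]] <- list(
        type = "loss", gene = st$ft$name[pick],
        start = st$ft$intervals[[pick]][1, 1],
        end = st$ft$intervals[[pick]][1, 2])
      st <- .applyLoss(st, pick)
    }
    if (!is.null(st$irb) && stats::runif(1) < config@pIrLoss) {
      events[[length(events) + 1L]] <- list(
        type = "ir_loss", start = st$irb[1], end = st$irb[2])
      st <- .applyIrLoss(st)
    }
    for (iv in seq_len(config@nInversions)) {
      cuts <- .cutPoints(st)
      if (length(cuts) < 2L) break
      b <- NULL
      for (try in 1:25) {
        bb <- sort(sample(cuts, 2L))
        if (bb[2] - bb[1] < 1L || bb[2] - bb[1] >= nchar(st$seq)) next
        # a segment holding exactly one IR copy would turn the IR into a
        # direct repeat; keep both copies in or both out
        inSeg <- vapply(list(st$ira, st$irb), function(a)
          !is.null(a) && a[1] >= bb[1] && a[2] <= bb[2], logical(1))
        if (sum(inSeg) == 1L) next
        b <- bb
        break
      }
      if (is.null(b)) next
      events[[length(events) + 1L]] <- list(
        type = "inversion", start = b[1], end = b[2])
      st <- .applyInversion(st, b[1], b[2])
    }
    states[[child]] <- st
    lab <- if (child <= nt) tree$tip.label[child] else paste0("node", child)
    log[[lab]] <- events
  }
  genomes <- lapply(seq_len(nt), function(i)
    .stateToGenome(states[[i]], tree$tip.label[i]))
  names(genomes) <- tree$tip.label
  new("SimulatedClade", tree = tree, ancestor = ancestor,
      genomes = genomes, eventLog = log)
}

#' Simulate a clade in one call
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param tree rooted \code{phylo} tree.
#' @return a \linkS4class{SimulatedClade}.
#' @export
simulateClade <- function(config, tree) {
  evolveClade(simulateAncestor(config), tree, config)
}

#' Replay a simulated event log
#'
#' Applies the logged events branch by branch from the ancestor; the
#' result must equal the simulated leaves exactly (this is the
#' simulator's own consistency invariant).
#'
#' @param clade a \linkS4class{SimulatedClade}.
#' @return named list of replayed leaf \linkS4class{ChloroGenome}s.
#' @export
replayEvents <- function(clade) {
  tree <- clade@tree
  nt <- length(tree$tip.label)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  states <- vector("list", nt + tree$Nnode)
  states[[nt + 1L]] <- .stateFromGenome(clade@ancestor)
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; child <- edges[e, 2]
    st <- states[[par]]
    lab <- if (child <= nt) tree$tip.label[child] else paste0("node", child)
    for (ev in clade@eventLog[[lab]]) {
      st <- switch(ev$type,
        loss = {
          hit <- which(st$ft$name == ev$gene &
                       vapply(st$ft$intervals, function(m)
                         m[1, 1] == ev$start, logical(1)))
          .applyLoss(st, hit[1])
        },
        ir_loss = {
          st$irb <- c(ev$start, ev$end)
          .applyIrLoss(st)
        },
        inversion = .applyInversion(st, ev$start, ev$end))
    }
    states[[child]] <- st
  }
  out <- lapply(seq_len(nt), function(i)
    .stateToGenome(states[[i]], tree$tip.label[i]))
  names(out) <- tree$tip.label
  out
}
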