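# Per-genome architecture metrics and inverted-repeat / quadripartite
# structure detection.

# All circular k-mer start positions 0..n-1 of a sequence (doubled string).
.circKmers <- function(s, k) {
  n <- nchar(s)
  s2 <- paste0(s, substr(s, 1, k - 1))
  substring(s2, seq_len(n), seq_len(n) + k - 1)
}

#' A+T content of a sequence
#'
#' @param sequence nucleotide string over A, C, G, T, N (case-insensitive);
#'   N is excluded from the denominator.
#' @return percent, rounded to one decimal (half-up).
#' @examples
#' atContent("ATAT")   # 100
#' atContent("GCGC")   # 0
#' @export
atContent <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("empty sequence")
  f <- Biostrings::letterFrequency(Biostrings::DNAString(toupper(sequence)),
                                   c("A", "C", "G", "T"))
  denom <- sum(f)
  if (denom == 0) stop("sequence contains no A/C/G/T")
  roundHalfUp(100 * (f[["A"]] + f[["T"]]) / denom, 1L)
}

# Total circular overlap (bp) of two arcs given as c(start, end) with end
# possibly exceeding n.
.circOverlapLen <- function(a, b, n) {
  la <- circToLinear(a, n)
  lb <- circToLinear(b, n)
  tot <- 0L
  for (i in seq_len(nrow(la))) for (j in seq_len(nrow(lb))) {
    tot <- tot + max(0L, min(la[i, 2], lb[j, 2]) - max(la[i, 1], lb[j, 1]))
  }
  tot
}

# Circular extent span of a feature's interval matrix.
.featCircSpan <- function(iv, n) {
  if (nrow(iv) == 1L) return(c(iv[1, 1], iv[1, 2]))
  if (iv[1, 1] > iv[nrow(iv), 1]) {           # wraps the origin
    c(iv[1, 1], iv[nrow(iv), 2] + n)
  } else {
    c(iv[1, 1], iv[nrow(iv), 2])
  }
}

# All maximal circular reverse-complement self-matches of S, via k-mer
# seeds merged along diagonals. Returns a data.frame i, j, len (arc1 =
# [i, i+len), arc2 = [j, j+len), 0-based, possibly wrapping).
.revcompMatches <- function(s, minLen) {
  n <- nchar(s)
  k <- min(minLen, 24L)
  A <- .circKmers(s, k)
  R <- revcompStr(s)
  B <- .circKmers(R, k)
  posB <- split(seq_len(n) - 1L, B)
  hit <- match(A, names(posB))
  ii <- which(!is.na(hit))
  if (!length(ii)) return(NULL)
  reps <- lengths(posB[hit[ii]])
  i <- rep(ii - 1L, reps)
  p <- unlist(posB[hit[ii]], use.names = FALSE)
  d <- (i - p) %% n
  o <- order(d, i)
  i <- i[o]; p <- p[o]; d <- d[o]
  newRun <- c(TRUE, !(d[-1] == d[-length(d)] & i[-1] == i[-length(i)] + 1L))
  runId <- cumsum(newRun)
  starts <- tapply(seq_along(i), runId, min)
  ends <- tapply(seq_along(i), runId, max)
  runs <- data.frame(d = d[starts], i0 = i[starts], m = i[ends] - i[starts] + 1L)
  # join runs that wrap the seed circle (i = n-1 -> i = 0 on one diagonal)
  byD <- split(seq_len(nrow(runs)), runs$d)
  drop <- logical(nrow(runs))
  for (ix in byD) {
    if (length(ix) < 2) next
    r <- runs[ix, ]
    first <- ix[which(r$i0 == 0L)]
    last <- ix[which(r$i0 + r$m == n)]
    if (length(first) == 1L && length(last) == 1L && first != last) {
      runs$i0[last] <- runs$i0[last]
      runs$m[last] <- min(n, runs$m[last] + runs$m[first])
      drop[first] <- TRUE
    }
  }
  runs <- runs[!drop, , drop = FALSE]
  L <- pmin(runs$m + k - 1L, n)
  i0 <- runs$i0 %% n
  p0 <- (runs$i0 - runs$d) %% n
  j <- (n - p0 - L) %% n
  data.frame(i = i0, j = j, len = L)
}

#' Detect the inverted repeat and quadripartite structure
#'
#' Finds the maximal-length pair of disjoint exact reverse-complement
#' segments of a circular sequence (exact matches, seed-and-extend on
#' k-mer anchors; ties broken by the smallest IRa start). The two gaps
#' between the copies are the single-copy regions, LSC the longer.
#'
#' @param sequence circular nucleotide string.
#' @param minLen minimum IR copy length to report (bp, >= 30).
#' @param requireRrn optional feature table (rows with \code{name},
#'   \code{intervals}, \code{strand}) of rRNA genes: only candidate IRs
#'   whose two copies each contain all listed rRNA genes qualify; also
#'   used to orient the rRNA operon relative to the SC regions.
#' @return a \linkS4class{QuadripartiteStructure}, or \code{NULL} when no
#'   qualifying repeat exists.
#' @export
detectInvertedRepeat <- function(sequence, minLen = 1000L, requireRrn = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence absent")
  minLen <- as.integer(minLen)
  if (minLen < 30L) stop("minLen must be >= 30")
  n <- nchar(sequence)
  if (n < 2L * minLen) return(NULL)
  cand <- .revcompMatches(toupper(sequence), minLen)
  if (is.null(cand)) return(NULL)
  cand <- cand[cand$len >= minLen, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  # trim arcs that overlap (e.g. one long hairpin) down to the largest
  # disjoint prefix/suffix pair
  res <- vector("list", nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]; L <- cand$len[r]
    if (L > floor(n / 2)) L <- floor(n / 2)
    repeat {
      a1 <- c(i, i + L)
      a2 <- c((j + cand$len[r] - L) %% n, (j + cand$len[r] - L) %% n + L)
      v <- .circOverlapLen(a1, a2, n)
      if (v == 0L || L < minLen) break
      L <- L - max(1L, ceiling(v / 2))
    }
    if (L >= minLen && v == 0L) res[[r]] <- c(i = a1[1], j = a2[1], len = L)
  }
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res) || !nrow(res)) return(NULL)
  res <- as.data.frame(res)
  # canonical copy order: ira = copy with the smaller start
  sw <- res$j < res$i
  tmp <- res$i[sw]; res$i[sw] <- res$j[sw]; res$j[sw] <- tmp
  res <- unique(res)
  if (!is.null(requireRrn) && nrow(requireRrn)) {
    ok <- vapply(seq_len(nrow(res)), function(r) {
      .irContainsRrn(res[r, ], requireRrn, n)
    }, logical(1))
    res <- res[ok, , drop = FALSE]
    if (!nrow(res)) return(NULL)
  }
  res <- res[order(-res$len, res$i), , drop = FALSE]
  best <- res[1, ]
  ira <- c(best$i, best$i + best$len)
  irb <- c(best$j, best$j + best$len)
  g1 <- (irb[1] - ira[2]) %% n   # gap after ira
  g2 <- (ira[1] - irb[2]) %% n   # gap after irb
  s1 <- c(ira[2] %% n, ira[2] %% n + g1)
  s2 <- c(irb[2] %% n, irb[2] %% n + g2)
  if (g1 >= g2) { lsc <- s1; ssc <- s2 } else { lsc <- s2; ssc <- s1 }
  orient <- .rrnOrientation(requireRrn, ira, irb, lsc, ssc, n)
  new("QuadripartiteStructure",
      ira = as.integer(ira), irb = as.integer(irb),
      lsc = as.integer(lsc), ssc = as.integer(ssc),
      rrnOrientation = orient, irLength = as.integer(best$len),
      genomeLength = as.integer(n))
}

.irContainsRrn <- function(candRow, rrn, n) {
  arcs <- list(c(candRow$i, candRow$i + candRow$len),
               c(candRow$j, candRow$j + candRow$len))
  nms <- unique(rrn$name)
  all(vapply(arcs, function(a) {
    all(vapply(nms, function(nm) {
      idx <- which(rrn$name == nm)
      any(vapply(idx, function(f) {
        sp <- .featCircSpan(rrn$intervals[[f]], n)
        w <- sp[2] - sp[1]
        ((sp[1] - a[1]) %% n) + w <= (a[2] - a[1])
      }, logical(1)))
    }, logical(1)))
  }, logical(1)))
}

# Orientation of the rRNA operon inside the IR: transcription of rrs
# proceeds toward the SC region it exits the IR copy into.
.rrnOrientation <- function(rrn, ira, irb, lsc, ssc, n) {
  if (is.null(rrn) || !nrow(rrn)) return("absent")
  idx <- which(rrn$name == "rrs")
  if (!length(idx)) return("absent")
  for (f in idx) {
    mid <- spanMidpoint(rrn$intervals[[f]], n)
    for (arc in list(ira, irb)) {
      if (circContains(arc, mid, n)) {
        # probe the first base past the IR copy in the direction of
        # transcription; the SC region it lands in names the orientation
        probe <- if (rrn$strand[f] > 0) arc[2] %% n else (arc[1] - 1L) %% n
        towardLsc <- circContains(lsc, probe, n)
        towardSsc <- circContains(ssc, probe, n)
        if (!towardLsc && !towardSsc) next
        return(if (towardLsc) "toward_lsc" else "toward_ssc")
      }
    }
  }
  "absent"
}

#' Intergenic fraction of a genome
#'
#' Percent of the genome not covered by conserved-gene features (introns
#' count as genic, since merged features cover exons and introns;
#' free-standing ORFs count as intergenic). Overlapping features are
#' counted once.
#'
#' @param genome a \linkS4class{ChloroGenome} with features.
#' @return percent, rounded to one decimal (half-up).
#' @export
intergenicFraction <- function(genome) {
  ft <- genomeFeatures(genome)
  n <- genomeLength(genome)
  if (n == 0L) stop("zero-length genome")
  cons <- ft$intervals[ft$conserved]
  covered <- if (length(cons)) sum(coverageMask(cons, n)) else 0L
  roundHalfUp(100 * (n - covered) / n, 1L)
}

# Delete the circular arc `arc` (c(start,end), end may exceed n) from a
# sequence, returning the remaining circular sequence anchored at arc end.
.deleteArc <- function(s, arc, n) {
  keepLen <- n - (arc[2] - arc[1])
  if (keepLen <= 0) return("")
  s2 <- paste0(s, s)
  substr(s2, arc[2] %% n + 1L, arc[2] %% n + keepLen)
}

#' Repeat fraction of a genome sequence
#'
#' Finds all bases covered by an exact repeated segment of at least
#' \code{minLen} bp, in forward or reverse-complement (palindromic)
#' orientation, on the circular working sequence, and reports the masked
#' percentage. When a quadripartite structure is supplied, one full IR
#' copy is removed first so the IR itself is not counted as a repeat.
#'
#' A position is masked exactly when some \code{minLen}-mer covering it is
#' repeated, which is equivalent to masking all maximal repeats of length
#' at least \code{minLen}.
#'
#' @param sequence circular nucleotide string.
#' @param quad optional \linkS4class{QuadripartiteStructure}; its irb copy
#'   is removed before scanning.
#' @param minLen minimum repeat length (bp).
#' @return percent of the working sequence masked, rounded to one decimal.
#' @export
repeatFraction <- function(sequence, quad = NULL, minLen = 30L) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence absent")
  s <- toupper(sequence)
  n <- nchar(s)
  if (!is.null(quad)) {
    s <- .deleteArc(s, quad@irb, n)
    n <- nchar(s)
  }
  k <- as.integer(minLen)
  if (n < k) return(0)
  Kf <- .circKmers(s, k)
  dup <- duplicated(Kf) | duplicated(Kf, fromLast = TRUE)
  Kr <- .circKmers(revcompStr(s), k)
  pal <- Kf %in% Kr
  hitStarts <- which(dup | pal) - 1L
  if (!length(hitStarts)) return(0)
  mask <- logical(n)
  for (i in hitStarts) mask[(i + seq_len(k) - 1L) %% n + 1L] <- TRUE
  roundHalfUp(100 * sum(mask) / n, 1L)
}

#' Conformity of gene partitioning to a reference quadripartite layout
#'
#' Fraction of the genome's conserved genes located in the compartment
#' (LSC, SSC or IR) that a reference partition assigns them; genes absent
#' from the reference are skipped. Used to test whether a genome's
#' single-copy gene content conforms to the ancestral partitioning
#' pattern.
#'
#' @param genome a \linkS4class{ChloroGenome}.
#' @param quad the genome's \linkS4class{QuadripartiteStructure}.
#' @param referencePartition named character vector mapping gene names to
#'   \code{"LSC"}, \code{"SSC"} or \code{"IR"}.
#' @return fraction in [0,1], or \code{NA} when no genome gene occurs in
#'   the reference.
#' @export
partitionConformity <- function(genome, quad, referencePartition) {
  if (is.null(quad)) stop("no quadripartite structure (quad is NULL)")
  ft <- genomeFeatures(genome)
  ft <- ft[ft$conserved, , drop = FALSE]
  n <- genomeLength(genome)
  comp <- vapply(seq_len(nrow(ft)), function(i) {
    mid <- spanMidpoint(ft$intervals[[i]], n)
    if (circContains(quad@ira, mid, n) || circContains(quad@irb, mid, n))
      "IR"
    else if (circContains(quad@lsc, mid, n)) "LSC"
    else "SSC"
  }, character(1))
  genes <- baseGeneName(ft$name)
  perGene <- tapply(comp, genes, function(v) {
    if (any(v == "IR")) "IR" else v[1]
  })
  keep <- names(perGene) %in% names(referencePartition)
  if (!any(keep)) return(NA_real_)
  mean(unlist(perGene[keep]) == referencePartition[names(perGene)[keep]])
}

#' Architecture metrics of one genome
#'
#' Assembles the standard per-genome summary: total size, IR copy length
#' (0 when no IR is detected), A+T percent, unique conserved gene count,
#' conserved gene occurrence count (IR and tRNA duplicates included),
#' intergenic percent and repeat percent of the IR-collapsed sequence.
#' Sequence-dependent fields are \code{NA} when the sequence is absent.
#'
#' @param genome a \linkS4class{ChloroGenome}.
#' @param irMinLen minimum IR length passed to [detectInvertedRepeat()].
#' @param repeatMinLen minimum repeat length for [repeatFraction()].
#' @param requireRrn require the IR to contain the genome's annotated
#'   rRNA genes (recommended: the IR of interest is the rRNA-operon IR)?
#' @return one-row data.frame.
#' @export
genomeMetrics <- function(genome, irMinLen = 1000L, repeatMinLen = 30L,
                          requireRrn = TRUE) {
  ft <- genomeFeatures(genome)
  hasSeq <- nzchar(genome@sequence)
  quad <- NULL
  if (hasSeq) {
    rrn <- ft[ft$category == "rRNA", , drop = FALSE]
    quad <- detectInvertedRepeat(genome@sequence, minLen = irMinLen,
                                 requireRrn = if (requireRrn && nrow(rrn)) rrn)
  }
  data.frame(
    id = genomeId(genome),
    totalBp = genomeLength(genome),
    irBp = if (!hasSeq) NA_integer_ else if (is.null(quad)) 0L else quad@irLength,
    atPct = if (hasSeq) atContent(genome@sequence) else NA_real_,
    nGenes = nConservedGenes(genome),
    nGeneOccurrences = sum(ft$conserved),
    intergenicPct = intergenicFraction(genome),
    repeatPct = if (hasSeq) repeatFraction(genome@sequence, quad,
                                           repeatMinLen) else NA_real_,
    stringsAsFactors = FALSE
  )
}
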