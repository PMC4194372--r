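# Independent brute-force oracles. Each re-derives its quantity from the
# definition by a route different from the package implementation.

# --- colinear blocks: enumerate every circular substring -----------------

# All maximal common circular signed substrings (>= minLen genes) between
# two signed orders, as a sorted list of sorted gene-name vectors.
oracleBlockSets <- function(el1, el2, minLen = 2L) {
  c1 <- table(el1$name); c2 <- table(el2$name)
  shared <- intersect(names(c1)[c1 == 1], names(c2)[c2 == 1])
  r1 <- el1[el1$name %in% shared, , drop = FALSE]
  r2 <- el2[el2$name %in% shared, , drop = FALSE]
  m <- nrow(r1)
  if (m == 0L) return(list())
  enc <- function(name, sign) paste0(ifelse(sign > 0, "+", "-"), name)
  s1 <- enc(r1$name, r1$sign)
  s2 <- enc(r2$name, r2$sign)
  flipv <- function(v) rev(ifelse(substr(v, 1, 1) == "+",
                                  sub("^\\+", "-", v), sub("^-", "\\+", v)))
  d2 <- c(s2, s2)
  found <- list()
  for (L in seq.int(min(minLen, m), m)) {
    if (L < minLen) next
    win2 <- vapply(seq_len(m), function(s)
      paste(d2[s:(s + L - 1)], collapse = "\r"), character(1))
    for (s in seq_len(m)) {
      idx <- (s - 1L + 0:(L - 1L)) %% m + 1L
      sub <- s1[idx]
      if (paste(sub, collapse = "\r") %in% win2 ||
          paste(flipv(sub), collapse = "\r") %in% win2)
        found[[length(found) + 1L]] <- sort(unique(idx))
    }
  }
  if (!length(found)) return(list())
  found <- unique(found)
  keep <- vapply(seq_along(found), function(i) {
    !any(vapply(seq_along(found), function(j) {
      i != j && length(found[[j]]) > length(found[[i]]) &&
        all(found[[i]] %in% found[[j]])
    }, logical(1)))
  }, logical(1))
  sets <- lapply(found[keep], function(idx) sort(r1$name[idx]))
  sets[order(vapply(sets, paste, character(1), collapse = ","))]
}

blockSetsOf <- function(blocks) {
  sets <- lapply(blocks$genes, sort)
  sets[order(vapply(sets, paste, character(1), collapse = ","))]
}

# --- Dollo: minimal loss count by subset enumeration ---------------------

# Per-node descendant-leaf bitmasks of a rooted tree (<= 30 leaves).
treeLeafMasks <- function(tree) {
  nt <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  mask <- c(bitwShiftL(1, seq_len(nt) - 1L), rep(0L, tree$Nnode))
  for (e in seq_len(nrow(po)))
    mask[po[e, 1]] <- bitwOr(mask[po[e, 1]], mask[po[e, 2]])
  mask
}

# Minimum number of loss edges explaining `pv` under a single gain.
oracleDolloCount <- function(tree, pv, gainPolicy, masks = treeLeafMasks(tree)) {
  nt <- length(tree$tip.label)
  pv <- as.logical(pv[tree$tip.label])
  pmask <- 0L
  for (i in which(pv)) pmask <- bitwOr(pmask, bitwShiftL(1, i - 1L))
  nn <- length(masks)
  if (gainPolicy == "root") {
    gain <- nt + 1L
  } else {
    sup <- which(vapply(seq_len(nn), function(v)
      bitwAnd(masks[v], pmask) == pmask, logical(1)))
    gain <- sup[which.min(vapply(sup, function(v)
      sum(bitwAnd(masks[v], bitwShiftL(1, seq_len(nt) - 1L)) > 0), numeric(1)))]
  }
  absentMask <- bitwAnd(masks[gain], bitwNot(pmask))
  if (absentMask == 0L) return(0L)
  # candidate loss edges: nodes under the gain whose subtree is all-absent
  underGain <- vapply(seq_len(nn), function(v)
    v != gain && bitwAnd(masks[v], masks[gain]) == masks[v], logical(1))
  # strict descendant test: masks subset AND not an unrelated equal-mask node
  cand <- which(underGain &
                vapply(seq_len(nn), function(v)
                  bitwAnd(masks[v], pmask) == 0L, logical(1)))
  for (k in seq.int(0L, length(cand))) {
    if (k == 0L) next
    combs <- utils::combn(cand, k, simplify = FALSE)
    for (cc in combs) {
      u <- 0L
      for (v in cc) u <- bitwOr(u, masks[v])
      if (u == absentMask) return(k)
    }
  }
  stop("oracle: no loss set found")
}

# --- inverted repeat: exhaustive diagonal-chain scan ---------------------

# Longest pair of disjoint exact reverse-complement arcs (>= minLen) of a
# circular sequence, or NULL. Scans every complementary diagonal and every
# sub-window of every chain.
oracleIrLength <- function(s, minLen) {
  x <- strsplit(toupper(s), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  n <- length(x)
  best <- 0L
  for (cdiag in 0:(n - 1)) {
    e <- vapply(0:(n - 1), function(t)
      x[t + 1] == comp[[x[(cdiag - t) %% n + 1]]], logical(1))
    # circular runs of TRUE
    if (all(e)) {
      runs <- list(c(0L, n))
    } else {
      r <- rle(e[c(which(!e)[1]:n, seq_len(which(!e)[1] - 1))])
      shift <- which(!e)[1] - 1L
      pos <- cumsum(c(0L, r$lengths))
      runs <- lapply(which(r$values), function(k)
        c((pos[k] + shift) %% n, r$lengths[k]))
    }
    for (run in runs) {
      t0 <- run[1]; R <- run[2]
      if (R < minLen) next
      for (L in seq.int(minLen, min(R, floor(n / 2)))) {
        for (d in 0:(R - L)) {
          a1 <- (t0 + d) %% n                     # arc1 = [a1, a1+L)
          b1 <- (cdiag - (t0 + d + L - 1L)) %% n  # arc2 = [b1, b1+L)
          gap1 <- (b1 - (a1 + L)) %% n
          gap2 <- (a1 - (b1 + L)) %% n
          if (a1 != b1 && gap1 + gap2 == n - 2L * L && gap1 >= 0 && gap2 >= 0) {
            if (L > best) best <- L
          }
        }
      }
    }
  }
  if (best >= minLen) best else NULL
}

# --- repeat masking: shift scan over forward and palindromic matches -----

# Percent of circular sequence covered by exact repeats >= minLen (forward
# or reverse-complement), by scanning every shift / complementary diagonal.
oracleRepeatPct <- function(s, minLen) {
  x <- strsplit(toupper(s), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(x)
  mask <- logical(n)
  circRuns <- function(e) {
    if (all(e)) return(list(c(0L, n)))
    if (!any(e)) return(list())
    first0 <- which(!e)[1]
    r <- rle(e[c(first0:n, seq_len(first0 - 1))])
    pos <- cumsum(c(0L, r$lengths))
    lapply(which(r$values), function(k)
      c((pos[k] + first0 - 1L) %% n, r$lengths[k]))
  }
  markRun <- function(t0, len) {
    idx <- (t0 + 0:(len - 1L)) %% n + 1L
    mask[idx] <<- TRUE
  }
  for (d in 1:(n - 1)) {           # forward repeats at shift d
    e <- x == x[(seq_len(n) - 1L + d) %% n + 1L]
    for (run in circRuns(e)) {
      if (run[2] >= minLen) {
        markRun(run[1], run[2])
        markRun((run[1] + d) %% n, run[2])
      }
    }
  }
  for (cdiag in 0:(n - 1)) {       # palindromic matches on each diagonal
    e <- vapply(0:(n - 1), function(t)
      x[t + 1] == comp[[x[(cdiag - t) %% n + 1]]], logical(1))
    for (run in circRuns(e)) {
      if (run[2] >= minLen) {
        markRun(run[1], run[2])
        markRun((cdiag - (run[1] + run[2] - 1L)) %% n, run[2])
      }
    }
  }
  floor(100 * sum(mask) / n * 10 + 0.5) / 10
}

# --- adjacency pairs: literal enumeration over both readings -------------

oracleAdjacencyKeys <- function(el) {
  m <- nrow(el)
  if (m < 2) return(character(0))
  enc <- function(n1, s1, n2, s2)
    paste0(n1, ifelse(s1 > 0, "+", "-"), "|", n2, ifelse(s2 > 0, "+", "-"))
  keys <- character(0)
  readings <- list(
    list(name = el$name, sign = el$sign),
    list(name = rev(el$name), sign = -rev(el$sign)))
  for (r in readings) {
    for (i in seq_len(m)) {
      j <- if (i == m) 1L else i + 1L
      k1 <- enc(r$name[i], r$sign[i], r$name[j], r$sign[j])
      k2 <- enc(r$name[j], -r$sign[j], r$name[i], -r$sign[i])
      keys <- c(keys, min(k1, k2))
    }
  }
  sort(unique(keys))
}

# Signed adjacency breakpoint count between two orders on the same genes.
breakpointCount <- function(o1, o2) {
  k1 <- adjacencyPairs(o1)$key
  k2 <- adjacencyPairs(o2)$key
  length(setdiff(k1, k2))
}

# Order-level random inversion (reverse + sign-flip a run of elements).
invertOrderSegment <- function(el, i, j) {
  idx <- i:j
  el$name[idx] <- rev(el$name[idx])
  el$sign[idx] <- -rev(el$sign[idx])
  el
}
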