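# Low-level helpers shared across the package. This file collates first.

# Empty feature table with the canonical column set.
emptyFeatureTable <- function() {
  data.frame(
    name = character(0), category = character(0), strand = integer(0),
    conserved = logical(0), pseudo = logical(0),
    intervals = I(list()), stringsAsFactors = FALSE
  )
}

# Build a feature table row-wise from parallel vectors; `intervals` is a
# list of n x 2 integer matrices (0-based half-open spans).
makeFeatureTable <- function(name, category, strand, conserved, pseudo,
                             intervals) {
  stopifnot(length(name) == length(intervals))
  data.frame(
    name = as.character(name), category = as.character(category),
    strand = as.integer(strand), conserved = as.logical(conserved),
    pseudo = as.logical(pseudo), intervals = I(intervals),
    stringsAsFactors = FALSE
  )
}

span <- function(start, end) {
  matrix(as.integer(c(start, end)), ncol = 2L,
         dimnames = list(NULL, c("start", "end")))
}

# Round half away from zero (Table-style rounding), vectorised.
roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Sum of span widths of a feature's interval matrix.
spanWidth <- function(iv) sum(iv[, 2] - iv[, 1])

# Genome coordinate of the midpoint of a (possibly origin-wrapping)
# feature: the position reached after floor(width/2) bases walked from the
# feature start along its spans.
spanMidpoint <- function(iv, genomeLength) {
  w <- iv[, 2] - iv[, 1]
  half <- floor(sum(w) / 2)
  for (k in seq_len(nrow(iv))) {
    if (half < w[k]) return((iv[k, 1] + half) %% genomeLength)
    half <- half - w[k]
  }
  iv[nrow(iv), 2] %% genomeLength
}

# Logical coverage vector (length = genomeLength) of a list of interval
# matrices.
coverageMask <- function(intervalList, genomeLength) {
  mask <- logical(genomeLength)
  for (iv in intervalList) {
    for (k in seq_len(nrow(iv))) {
      mask[(iv[k, 1] + 1L):iv[k, 2]] <- TRUE
    }
  }
  mask
}

# Normalize a circular span c(start, end) (end may exceed len to denote a
# wrap) to a list of linear 0-based half-open spans.
circToLinear <- function(s, len) {
  start <- s[1] %% len
  width <- s[2] - s[1]
  stopifnot(width >= 0, width <= len)
  if (width == 0) return(span(integer(0), integer(0))[0, , drop = FALSE])
  if (start + width <= len) span(start, start + width)
  else rbind(span(start, len), span(0, start + width - len))
}

# Does circular span a (c(start,end), end possibly > len) contain circular
# position p?
circContains <- function(a, p, len) {
  w <- a[2] - a[1]
  ((p - a[1]) %% len) < w
}

# Do two circular spans overlap?
circOverlaps <- function(a, b, len) {
  pa <- (a[1] + seq_len(a[2] - a[1]) - 1L) %% len
  pb <- (b[1] + seq_len(b[2] - b[1]) - 1L) %% len
  length(intersect(pa, pb)) > 0
}

revcompStr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

randomSeq <- function(n, atPct = 50) {
  pat <- atPct / 200
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(pat, pat, 0.5 - pat, 0.5 - pat)), collapse = "")
}
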