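# Fixture builders: everything is generated in code at test time.

# Build a ChloroGenome from a compact feature spec:
# list(name, strand, start, end [, conserved, category, pseudo]) or, for a
# wrapping feature, `spans = rbind(c(s1,e1), c(s2,e2))`.
mkGenome <- function(id, len, feats = list(), sequence = "") {
  ivs <- lapply(feats, function(f) {
    if (!is.null(f$spans)) {
      m <- matrix(as.integer(f$spans), ncol = 2)
      colnames(m) <- c("start", "end")
      m
    } else {
      matrix(as.integer(c(f$start, f$end)), ncol = 2,
             dimnames = list(NULL, c("start", "end")))
    }
  })
  nms <- vapply(feats, `[[`, character(1), "name")
  ft <- data.frame(
    name = nms,
    category = vapply(feats, function(f)
      if (is.null(f$category)) "protein" else f$category, character(1)),
    strand = vapply(feats, function(f)
      if (is.null(f$strand)) 1L else as.integer(f$strand), integer(1)),
    conserved = vapply(feats, function(f)
      if (is.null(f$conserved)) TRUE else f$conserved, logical(1)),
    pseudo = vapply(feats, function(f)
      if (is.null(f$pseudo)) FALSE else f$pseudo, logical(1)),
    intervals = I(ivs), stringsAsFactors = FALSE)
  chloroGenome(id, len, ft, sequence)
}

# A SignedGeneOrder built directly from name/sign vectors.
mkOrder <- function(id, names, signs) {
  new("SignedGeneOrder", id = id,
      elements = data.frame(name = names, sign = as.integer(signs),
                            midpoint = seq_along(names),
                            feature = seq_along(names),
                            stringsAsFactors = FALSE))
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

revcomp <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))

# GenBank flatfile fixture: 5 gene occurrences (one origin-wrapping join,
# one IR-duplicated rRNA, one gene+CDS pair to merge), 4 unique names.
writeGbFixture <- function(path = tempfile(fileext = ".gb")) {
  writeLines(c(
    "LOCUS       TESTCP                  1000 bp    DNA     circular PLN 01-JAN-2000",
    "DEFINITION  synthetic test record.",
    "ACCESSION   TESTCP",
    "FEATURES             Location/Qualifiers",
    "     source          1..1000",
    "     gene            100..250",
    '                     /gene="psbA"',
    "     CDS             join(100..160,200..250)",
    '                     /gene="psbA"',
    "     gene            complement(300..380)",
    '                     /gene="trnL(UAA)"',
    "     tRNA            complement(300..380)",
    '                     /gene="trnL(UAA)"',
    "     rRNA            400..450",
    '                     /gene="rrn16"',
    "     rRNA            complement(600..650)",
    '                     /gene="rrn16"',
    "     gene            join(950..1000,1..30)",
    '                     /gene="ycf1"',
    "//"), path)
  path
}

writeGbTrnFixture <- function(path = tempfile(fileext = ".gb")) {
  writeLines(c(
    "LOCUS       TRNTEST                  500 bp    DNA     circular PLN 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     tRNA            10..90",
    '                     /gene="trnL(UAA)"',
    "     tRNA            complement(200..280)",
    '                     /gene="trnL(UAG)"',
    "//"), path)
  path
}

writeGbEmptyFixture <- function(path = tempfile(fileext = ".gb")) {
  writeLines(c(
    "LOCUS       EMPTY                  200 bp    DNA     circular PLN 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     source          1..200",
    "//"), path)
  path
}

# Plant an exact IR pair into a random circular sequence: copy of length
# irLen at posA, its reverse complement at posB; flanking bases are broken
# so the planted pair is exactly maximal.
plantIr <- function(n, irLen, posA, posB, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- strsplit(randomDna(n), "")[[1]]
  arm <- s[(posA + 1):(posA + irLen)]
  rc <- strsplit(revcomp(paste(arm, collapse = "")), "")[[1]]
  s[(posB + 1):(posB + irLen)] <- rc
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  fixPair <- function(i, j) {
    # i, j are 0-based positions that must NOT be revcomp partners
    ii <- i %% n + 1; jj <- j %% n + 1
    if (s[ii] == comp[[s[jj]]])
      s[ii] <<- setdiff(c("A", "C", "G", "T"), c(s[ii], comp[[s[jj]]]))[1]
  }
  fixPair(posA - 1, posB + irLen)
  fixPair(posA + irLen, posB - 1)
  paste(s, collapse = "")
}
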