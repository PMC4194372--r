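test_that("A+T content matches a direct per-base tally", {
  expect_equal(atContent("ATAT"), 100)
  expect_equal(atContent("GCGC"), 0)
  expect_error(atContent(""), "empty")
  set.seed(11)
  s <- randomDna(10000)
  x <- strsplit(s, "")[[1]]
  manual <- 100 * sum(x %in% c("A", "T")) / length(x)
  expect_equal(atContent(s), floor(manual * 10 + 0.5) / 10)
  # N excluded from the denominator
  expect_equal(atContent("ATGCNNNN"), 50)
  # complement of the G+C content
  gc <- 100 * sum(x %in% c("G", "C")) / length(x)
  expect_equal(atContent(s) + floor(gc * 10 + 0.5) / 10, 100)
})

test_that("inverted-repeat detection recovers planted copies exactly", {
  for (seed in 1:5) {
    s <- plantIr(50000, 5000, posA = 8000, posB = 30000, seed = seed)
    q <- detectInvertedRepeat(s, minLen = 1000)
    expect_false(is.null(q))
    expect_equal(q@irLength, 5000L)
    expect_equal(q@ira[1], 8000L)
    expect_equal(q@irb[1], 30000L)
    # the four spans partition the circle and the copies are revcomps
    widths <- c(q@ira[2] - q@ira[1], q@irb[2] - q@irb[1],
                q@lsc[2] - q@lsc[1], q@ssc[2] - q@ssc[1])
    expect_equal(sum(widths), 50000L)
    armA <- substr(s, q@ira[1] + 1, q@ira[2])
    armB <- substr(s, q@irb[1] + 1, q@irb[2])
    expect_identical(armB, revcomp(armA))
    expect_gte(q@lsc[2] - q@lsc[1], q@ssc[2] - q@ssc[1])
  }
  set.seed(99)
  expect_null(detectInvertedRepeat(randomDna(20000), minLen = 1000))
})

test_that("inverted-repeat detection agrees with the diagonal-scan oracle", {
  set.seed(202)
  for (rep in 1:12) {
    n <- sample(150:350, 1)
    s <- randomDna(n)
    if (rep %% 2 == 0) {   # plant a small IR in half the cases
      irLen <- sample(35:60, 1)
      posA <- sample(0:(n %/% 3), 1)
      posB <- posA + irLen + sample(5:20, 1)
      arm <- substr(s, posA + 1, posA + irLen)
      substr(s, posB + 1, posB + irLen) <- revcomp(arm)
    }
    q <- detectInvertedRepeat(s, minLen = 30)
    got <- if (is.null(q)) NULL else q@irLength
    expect_equal(got, oracleIrLength(s, 30), info = paste("rep", rep))
  }
})

test_that("rRNA-containing candidates are preferred when required", {
  # two planted pairs: a longer one without rRNA, a shorter one whose
  # copies carry an rrs span
  s <- plantIr(40000, 3000, posA = 2000, posB = 12000, seed = 31)  # long, no rrn
  # plant a second, shorter pair carrying rrs
  arm <- substr(s, 20001, 22000)
  substr(s, 30001, 32000) <- revcomp(arm)
  # break the flanks of the second pair so it is exactly 2000 bp
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  brk <- function(seqs, i, j) {
    a <- substr(seqs, i + 1, i + 1); b <- substr(seqs, j + 1, j + 1)
    if (a == comp[[b]])
      substr(seqs, i + 1, i + 1) <- setdiff(c("A","C","G","T"), c(a, comp[[b]]))[1]
    seqs
  }
  s <- brk(s, 19999, 32000)
  s <- brk(s, 22000, 29999)
  rrn <- data.frame(name = c("rrs", "rrs"), strand = c(1L, -1L),
                    stringsAsFactors = FALSE)
  rrn$intervals <- list(cbind(start = 20200L, end = 21700L),
                        cbind(start = 30300L, end = 31800L))
  free <- detectInvertedRepeat(s, minLen = 1000)
  expect_equal(free@irLength, 3000L)
  constrained <- detectInvertedRepeat(s, minLen = 1000, requireRrn = rrn)
  expect_false(is.null(constrained))
  expect_equal(constrained@irLength, 2000L)
  expect_true(constrained@rrnOrientation %in% c("toward_ssc", "toward_lsc"))
})

test_that("intergenic fraction counts overlapping conserved features once", {
  tiled <- mkGenome("t", 500, list(list(name = "psbA", start = 0, end = 500)))
  expect_equal(intergenicFraction(tiled), 0)
  bare <- mkGenome("b", 500, list(list(name = "orf1", start = 0, end = 400,
                                       conserved = FALSE, category = "orf")))
  expect_equal(intergenicFraction(bare), 100)
  twoGenes <- mkGenome("o", 1000, list(
    list(name = "psbA", start = 100, end = 500),
    list(name = "psbB", start = 300, end = 700)))
  expect_equal(intergenicFraction(twoGenes), 40)
  # monotone: adding a feature never increases the fraction
  set.seed(3)
  feats <- list()
  last <- 100
  for (i in 1:10) {
    s <- sample(0:900, 1)
    feats[[i]] <- list(name = paste0("psb", LETTERS[i]), start = s,
                       end = min(1000, s + sample(20:150, 1)))
    g <- mkGenome("m", 1000, feats)
    expect_lte(intergenicFraction(g), last)
    last <- intergenicFraction(g)
  }
})

test_that("repeat fraction masks planted repeats and matches the oracle", {
  expect_equal(repeatFraction("ACGT", minLen = 30), 0)
  set.seed(5)
  s <- randomDna(10000)
  s2 <- paste0(substr(s, 1, 5000), substr(s, 1001, 1100), substr(s, 5101, 10000))
  expect_equal(repeatFraction(s2), 2)          # 200 masked bases of 10 kb
  expect_equal(repeatFraction(s), 0)
  # rotation invariance on the circle
  rot <- function(x, k) paste0(substr(x, k + 1, nchar(x)), substr(x, 1, k))
  for (k in c(1, 517, 5050)) {
    expect_equal(repeatFraction(rot(s2, k)), repeatFraction(s2))
  }
  # diagonal-scan oracle on small sequences with planted forward and
  # palindromic repeats
  set.seed(77)
  for (rep in 1:6) {
    n <- 300
    x <- randomDna(n)
    if (rep <= 2) {
      substr(x, 101, 140) <- substr(x, 11, 50)                 # forward
    } else if (rep <= 4) {
      substr(x, 201, 240) <- revcomp(substr(x, 31, 70))        # palindromic
    }
    expect_equal(repeatFraction(x, minLen = 30), oracleRepeatPct(x, 30),
                 info = paste("rep", rep))
  }
})

test_that("one IR copy is removed before repeat scanning", {
  cfg <- simulationConfig(nGenes = 30, genomeBp = 40000, irLength = 5000,
                          seed = 13)
  g <- simulateAncestor(cfg)
  s <- genomeSequence(g)
  quad <- detectInvertedRepeat(s, minLen = 1000)
  expect_equal(quad@irLength, 5000L)
  expect_gt(repeatFraction(s), 10)             # the IR dominates otherwise
  expect_equal(repeatFraction(s, quad), 0)
})

test_that("partition conformity scores relocated genes", {
  # 30 genes laid out LSC/IRa/SSC/IRb on a 33 kb circle
  cfg <- simulationConfig(nGenes = 30, genomeBp = 33000, irLength = 6000,
                          seed = 21)
  g <- simulateAncestor(cfg)
  quad <- detectInvertedRepeat(genomeSequence(g), minLen = 1000)
  ft <- genomeFeatures(g)
  n <- genomeLength(g)
  compOf <- vapply(seq_len(nrow(ft)), function(i) {
    mid <- plastarch:::spanMidpoint(ft$intervals[[i]], n)
    if (plastarch:::circContains(quad@ira, mid, n) ||
        plastarch:::circContains(quad@irb, mid, n)) "IR"
    else if (plastarch:::circContains(quad@lsc, mid, n)) "LSC"
    else "SSC"
  }, character(1))
  ref <- tapply(compOf, baseGeneName(ft$name), function(v)
    if (any(v == "IR")) "IR" else v[1])
  ref <- stats::setNames(as.character(ref), names(ref))
  expect_equal(partitionConformity(g, quad, ref), 1.0)
  # relocate 3 of 30 genes in the reference: conformity drops to 0.9
  movable <- names(ref)[ref %in% c("LSC", "SSC")][1:3]
  ref2 <- ref
  ref2[movable] <- ifelse(ref[movable] == "LSC", "SSC", "LSC")
  expect_equal(partitionConformity(g, quad, ref2), 27 / 30)
  # reference sharing no genes: undefined
  expect_true(is.na(partitionConformity(g, quad, c(zzz = "LSC"))))
  expect_error(partitionConformity(g, NULL, ref), "quad")
})

test_that("genome metrics assemble the per-genome summary row", {
  cfg <- simulationConfig(nGenes = 25, genomeBp = 30000, irLength = 6000,
                          intergenicTargetPct = 15, atPct = 64, seed = 8)
  g <- simulateAncestor(cfg)
  m <- genomeMetrics(g)
  expect_equal(m$totalBp, genomeLength(g))
  expect_equal(m$irBp, 6000L)
  expect_equal(m$nGenes, 25L)
  expect_gte(m$nGeneOccurrences, m$nGenes)
  expect_equal(m$atPct, 64, tolerance = 0.02)
  expect_equal(m$intergenicPct, 15, tolerance = 0.1)
  expect_true(m$repeatPct >= 0 && m$repeatPct <= 100)
})
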