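test_that("signed orders sort by circular midpoint, wrap-aware", {
  g <- mkGenome("g", 1000, list(
    list(name = "psbC", start = 390, end = 410),
    list(name = "psbA", start = 40, end = 60),
    list(name = "psbB", start = 240, end = 260, strand = -1),
    list(name = "ycf1", spans = rbind(c(950, 1000), c(0, 30)))))
  el <- orderElements(extractSignedOrder(g))
  expect_equal(el$name, c("psbA", "psbB", "psbC", "ycf1"))
  expect_equal(el$sign, c(1L, -1L, 1L, 1L))
  expect_equal(el$midpoint[4], 990)
  one <- mkGenome("o", 100, list(list(name = "psbA", start = 10, end = 40)))
  expect_equal(orderElements(extractSignedOrder(one))$name, "psbA")
  none <- mkGenome("n", 100, list(list(name = "orf9", start = 10, end = 40,
                                       conserved = FALSE, category = "orf")))
  expect_error(extractSignedOrder(none), "no conserved features")
})

test_that("adjacency pairs are canonical and match brute-force enumeration", {
  two <- mkOrder("t", c("A", "B"), c(1, 1))
  ap <- adjacencyPairs(two)
  expect_equal(nrow(ap), 2L)     # a 2-element circle has 2 adjacencies
  # reverse-complement symmetry of the key
  k1 <- plastarch:::.pairKey("A", 1L, "B", -1L)
  k2 <- plastarch:::.pairKey("B", 1L, "A", -1L)
  expect_identical(k1, k2)
  expect_equal(nrow(adjacencyPairs(mkOrder("s", "A", 1))), 0L)
  set.seed(41)
  for (rep in 1:10) {
    nm <- sample(paste0("g", 1:20))
    sg <- sample(c(1L, -1L), 20, replace = TRUE)
    o <- mkOrder("r", nm, sg)
    expect_equal(sort(adjacencyPairs(o)$key), oracleAdjacencyKeys(orderElements(o)))
    # invariant under reading the circle backwards with flipped signs
    oRev <- mkOrder("rr", rev(nm), -rev(sg))
    expect_setequal(adjacencyPairs(o)$key, adjacencyPairs(oRev)$key)
  }
})

test_that("colinear blocks find inverted and origin-wrapping runs", {
  o1 <- mkOrder("g1", c("A", "B", "C", "D"), c(1, 1, 1, 1))
  o2 <- mkOrder("g2", c("A", "C", "B", "D"), c(1, -1, -1, 1))
  bl <- colinearBlocks(o1, o2)
  expect_equal(nrow(bl), 2L)
  sets <- blockSetsOf(bl)
  expect_equal(sets, list(c("A", "D"), c("B", "C")))
  expect_setequal(bl$orientation, c("inverted", "same"))
  # identical orders collapse to a single full-circle block
  nm <- paste0("g", 1:12)
  sg <- rep(c(1L, -1L), 6)
  same <- colinearBlocks(mkOrder("a", nm, sg), mkOrder("b", nm, sg))
  expect_equal(nrow(same), 1L)
  expect_equal(same$n, 12L)
  # empty shared set warns and returns nothing
  expect_warning(
    out <- colinearBlocks(mkOrder("a", c("X", "Y"), c(1, 1)),
                          mkOrder("b", c("P", "Q"), c(1, 1))),
    "no shared")
  expect_equal(nrow(out), 0L)
})

test_that("blocks are symmetric, disjoint and bounded by the shared set", {
  set.seed(57)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    nm <- paste0("g", 1:n)
    o1 <- mkOrder("a", sample(nm), sample(c(1L, -1L), n, TRUE))
    o2 <- mkOrder("b", sample(nm), sample(c(1L, -1L), n, TRUE))
    b12 <- colinearBlocks(o1, o2)
    b21 <- colinearBlocks(o2, o1)
    expect_equal(blockSetsOf(b12), blockSetsOf(b21))
    genes <- unlist(b12$genes)
    expect_equal(anyDuplicated(genes), 0L)
    expect_lte(length(genes), n)
    expect_equal(blockSetsOf(b12), oracleBlockSets(orderElements(o1),
                                                   orderElements(o2)))
  }
})

test_that("duplicated gene names are excluded from block matching", {
  o1 <- mkOrder("a", c("A", "B", "rrs", "C", "rrs"), c(1, 1, 1, 1, -1))
  o2 <- mkOrder("b", c("A", "B", "rrs", "C"), c(1, 1, 1, 1))
  bl <- colinearBlocks(o1, o2)
  expect_true("rrs" %in% attr(bl, "skipped"))
  expect_false("rrs" %in% unlist(bl$genes))
})

test_that("k random inversions leave at most 2k breakpoints", {
  set.seed(71)
  for (rep in 1:12) {
    n <- 30
    el <- data.frame(name = paste0("g", 1:n),
                     sign = sample(c(1L, -1L), n, TRUE),
                     stringsAsFactors = FALSE)
    o0 <- mkOrder("anc", el$name, el$sign)
    k <- sample(1:5, 1)
    el2 <- el
    for (i in seq_len(k)) {
      ij <- sort(sample(1:n, 2))
      el2 <- invertOrderSegment(el2, ij[1], ij[2])
    }
    o1 <- mkOrder("der", el2$name, el2$sign)
    expect_lte(breakpointCount(o0, o1), 2 * k)
    bl <- colinearBlocks(o0, o1, minLen = 1L)
    expect_gte(nrow(bl), 1L)
    expect_lte(nrow(bl), max(1L, 2L * k))
  }
})

test_that("synteny statistics summarise shared gene content", {
  nm <- paste0("g", 1:50)
  sg <- rep(1L, 50)
  o1 <- mkOrder("a", nm, sg); o2 <- mkOrder("b", nm, sg)
  st <- syntenyStats(colinearBlocks(o1, o2), o1, o2)
  expect_equal(st$nBlocks, 1L)
  expect_equal(st$nBlockGenes, 50L)
  expect_equal(st$pctOfG1, 100L)
  expect_equal(st$pctOfG2, 100L)
  expect_equal(sort(st$largestBlock), sort(nm))
})

test_that("ancestral pair selection applies both rules", {
  mk <- function(id, nm) mkOrder(id, nm, rep(1L, length(nm)))
  # lineage L1: two genomes; L2: one; two outgroups
  orders <- list(
    A1 = mk("A1", c("a", "b", "c", "d")),
    A2 = mk("A2", c("a", "b", "d", "c")),
    B1 = mk("B1", c("a", "b", "c", "d")),
    O1 = mk("O1", c("a", "b", "c", "d")),
    O2 = mk("O2", c("c", "a", "b", "d")))
  pcm <- pairConservationMatrix(orders)
  genes <- c("a", "b", "c", "d")
  repert <- matrix(TRUE, nrow = 4, ncol = 5,
                   dimnames = list(genes, names(orders)))
  lmap <- c(A1 = "L1", A2 = "L1", B1 = "L2")
  sel <- selectAncestralPairs(pcm, lmap, c("O1", "O2"), repert)
  key_ab <- plastarch:::.pairKey("a", 1L, "b", 1L)
  # a+|b+ is in A1, A2, B1 (two lineages) and both outgroups: rule A
  expect_equal(sel@selection[match(key_ab, rownames(sel@presence))], "A")
  # a pair present everywhere in the data but in one lineage only, with a
  # member gene deleted from both outgroups: rule B
  orders2 <- list(
    A1 = mk("A1", c("a", "b", "c", "d")),
    A2 = mk("A2", c("a", "b", "c", "d")),
    B1 = mk("B1", c("a", "c", "d")),
    O1 = mk("O1", c("a", "c", "d")),
    O2 = mk("O2", c("a", "c", "d")))
  rep2 <- repert
  rep2["b", c("B1", "O1", "O2")] <- FALSE
  pcm2 <- pairConservationMatrix(orders2)
  sel2 <- selectAncestralPairs(pcm2, lmap, c("O1", "O2"), rep2)
  i_ab <- match(key_ab, rownames(sel2@presence))
  expect_equal(sel2@selection[i_ab], "B")
  # absence cells distinguish gene loss from rearrangement
  expect_equal(sel2@cells[i_ab, "B1"], "absent_gene_loss")
  key_ac <- plastarch:::.pairKey("d", 1L, "a", 1L)
  expect_error(selectAncestralPairs(pcm2, c(A1 = "L1"), c("O1", "O2"), rep2),
               "not in lineage map")
})

test_that("ancestral pair selection equals a literal re-application", {
  set.seed(83)
  genes <- paste0("g", 1:8)
  for (rep in 1:10) {
    ids <- c("P1", "P2", "P3", "P4", "Q1", "Q2")
    lmap <- c(P1 = "L1", P2 = "L1", P3 = "L2", P4 = "L3")
    outg <- c("Q1", "Q2")
    repert <- matrix(stats::runif(length(genes) * 6) > 0.2, nrow = 8,
                     dimnames = list(genes, ids))
    orders <- lapply(ids, function(id) {
      has <- genes[repert[, id]]
      if (length(has) < 2) has <- genes[1:2]
      mkOrder(id, sample(has), sample(c(1L, -1L), length(has), TRUE))
    })
    names(orders) <- ids
    pcm <- pairConservationMatrix(orders)
    sel <- selectAncestralPairs(pcm, lmap, outg, repert)
    pres <- sel@presence
    for (p in seq_len(nrow(pres))) {
      g1 <- sel@members$gene1[p]; g2 <- sel@members$gene2[p]
      ing <- setdiff(ids, outg)
      linPres <- unique(lmap[ing[pres[p, ing]]])
      ruleA <- sum(pres[p, ing]) >= 2 && length(linPres) >= 2 &&
        any(pres[p, outg])
      lacks <- vapply(unique(lmap), function(L) {
        tax <- ing[lmap[ing] == L]
        any(!apply(repert[c(g1, g2), tax, drop = FALSE], 1, any))
      }, logical(1))
      outLacks <- all(vapply(outg, function(tx)
        !(repert[g1, tx] && repert[g2, tx]), logical(1)))
      ruleB <- (sum(lacks) >= 2 || outLacks) && length(linPres) >= 1
      want <- if (ruleA) "A" else if (ruleB) "B" else NA_character_
      expect_identical(sel@selection[p], want)
    }
  }
})
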