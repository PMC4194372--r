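# GenBank flatfile reader.
#
# A focused parser for annotated organelle records: LOCUS (id, length),
# the FEATURES table (gene/CDS/tRNA/rRNA keys, join/complement and
# origin-wrapping locations) and ORIGIN (sequence). GenBank 1-based closed
# locations are converted to 0-based half-open spans on read.

# Parse one location string into list(strand, spans) where spans is an
# ordered n x 2 matrix of 0-based half-open spans in feature order.
parseLocation <- function(loc, genomeLength, what = "feature") {
  s <- gsub("[[:space:]]", "", loc)
  strand <- 1L
  if (grepl("^complement\\(", s)) {
    strand <- -1L
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  if (grepl("^(join|order)\\(", s)) {
    s <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
  }
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  spans <- lapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("^complement\\(", p)) {
      # per-segment complement (rare); fold into outer strand handling
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
      span(ab[1] - 1L, ab[2])
    } else if (grepl("^[0-9]+$", p)) {
      a <- as.integer(p)
      span(a - 1L, a)
    } else {
      stop("unparseable location '", loc, "' in ", what)
    }
  })
  spans <- do.call(rbind, spans)
  if (strand < 0) spans <- spans[rev(seq_len(nrow(spans))), , drop = FALSE]
  if (any(spans[, 2] > genomeLength))
    stop("location '", loc, "' exceeds genome length in ", what)
  list(strand = strand, spans = spans)
}

# Circular extent (c(start, end), end may exceed len) covered by an
# occurrence's ordered spans, bridging internal gaps (introns).
.circExtent <- function(spans, strand, len) {
  if (strand < 0) spans <- spans[rev(seq_len(nrow(spans))), , drop = FALSE]
  start <- spans[1, 1]
  end <- spans[nrow(spans), 2]
  if (end <= start && nrow(spans) > 1) end <- end + len   # wraps the origin
  if (end <= start) end <- end + len
  c(start, end)
}

.readGbSections <- function(lines) {
  iFeat <- grep("^FEATURES", lines)[1]
  iOrig <- grep("^ORIGIN", lines)[1]
  iEnd <- grep("^//", lines)[1]
  if (is.na(iEnd)) iEnd <- length(lines) + 1L
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  if (is.na(locus)) stop("not a GenBank flatfile: no LOCUS line")
  len <- as.integer(sub(".*?([0-9]+)\\s+bp.*", "\\1", locus))
  id <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][1]
  acc <- grep("^VERSION|^ACCESSION", lines, value = TRUE)
  if (length(acc)) {
    tok <- strsplit(trimws(sub("^(VERSION|ACCESSION)", "", acc[1])), "\\s+")[[1]]
    if (length(tok) && nzchar(tok[1])) id <- tok[1]
  }
  featLines <- if (!is.na(iFeat)) {
    to <- min(c(iOrig, iEnd), na.rm = TRUE) - 1L
    if (to > iFeat) lines[(iFeat + 1L):to] else character(0)
  } else character(0)
  seqLines <- if (!is.na(iOrig) && iOrig + 1L < iEnd) {
    lines[(iOrig + 1L):(iEnd - 1L)]
  } else character(0)
  sq <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
  list(id = id, length = len, featureLines = featLines, sequence = sq)
}

# Split the FEATURES block into raw entries: key, location string, named
# qualifier list.
.parseFeatureEntries <- function(featLines) {
  entries <- list()
  cur <- NULL
  flush <- function() if (!is.null(cur)) entries[[length(entries) + 1L]] <<- cur
  for (ln in featLines) {
    if (grepl("^ {0,8}\\S", ln) && grepl("^\\s*[A-Za-z0-9_'-]+\\s+\\S", ln) &&
        !grepl("^\\s*/", ln) && substr(ln, 1, 1) == " " &&
        !grepl("^ {9,}", ln)) {
      flush()
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      cur <- list(key = tok[1], location = paste(tok[-1], collapse = ""),
                  qualifiers = list())
    } else if (!is.null(cur)) {
      t <- trimws(ln)
      if (startsWith(t, "/")) {
        q <- sub("^/", "", t)
        if (grepl("=", q, fixed = TRUE)) {
          nm <- sub("=.*$", "", q)
          val <- gsub('^"|"$', "", sub("^[^=]*=", "", q))
          cur$qualifiers[[nm]] <- val
        } else {
          cur$qualifiers[[q]] <- TRUE
        }
      } else if (nzchar(t) && length(cur$qualifiers) == 0L) {
        cur$location <- paste0(cur$location, t)   # continued location
      } else if (nzchar(t) && length(cur$qualifiers)) {
        # continued quoted qualifier value
        last <- length(cur$qualifiers)
        if (is.character(cur$qualifiers[[last]]))
          cur$qualifiers[[last]] <- paste(cur$qualifiers[[last]],
                                          gsub('"$', "", t))
      }
    }
  }
  flush()
  entries
}

#' Read an annotated genome record from a GenBank flatfile
#'
#' Produces one feature per annotated gene occurrence (inverted-repeat
#' duplicates yield two features). Gene names are normalized (see
#' [normalizeGeneName()]); gene/CDS/tRNA/rRNA entries describing the same
#' locus are merged into one feature covering exons and introns; the
#' conserved flag is set by catalog membership (free-standing ORFs are
#' never conserved).
#'
#' @param path path to a GenBank flatfile.
#' @param catalog conserved-gene catalog data.frame (default: shipped
#'   catalog, [conservedCatalog()]).
#' @return a \linkS4class{ChloroGenome}. The sequence slot is \code{""}
#'   when the record carries no ORIGIN block; metrics that need sequence
#'   will then signal "sequence absent".
#' @export
readGenomeRecord <- function(path, catalog = conservedCatalog()) {
  lines <- readLines(path, warn = FALSE)
  gb <- .readGbSections(lines)
  if (is.na(gb$length)) {
    if (nzchar(gb$sequence)) gb$length <- nchar(gb$sequence)
    else stop("cannot determine genome length from LOCUS line")
  }
  entries <- .parseFeatureEntries(gb$featureLines)
  keep <- c("gene", "CDS", "tRNA", "rRNA", "ncRNA", "tmRNA")
  occ <- list()
  for (e in entries) {
    if (!(e$key %in% keep)) next
    raw <- e$qualifiers$gene
    if (is.null(raw)) raw <- e$qualifiers$product
    if (is.null(raw)) raw <- e$qualifiers$locus_tag
    if (is.null(raw)) next
    loc <- parseLocation(e$location, gb$length,
                         what = paste0(e$key, " '", raw, "'"))
    nm <- normalizeGeneName(raw)
    category <- switch(e$key, CDS = "protein", tRNA = "tRNA", rRNA = "rRNA",
                       inferCategory(nm))
    if (grepl("^orf[0-9]+", nm)) category <- "orf"
    occ[[length(occ) + 1L]] <- list(
      name = nm, key = e$key, category = category, strand = loc$strand,
      spans = loc$spans, pseudo = isTRUE(e$qualifiers$pseudo),
      extent = .circExtent(loc$spans, loc$strand, gb$length)
    )
  }
  features <- .mergeOccurrences(occ, gb$length, catalog)
  chloroGenome(gb$id, gb$length, features, gb$sequence)
}

# Merge same-locus gene/CDS/tRNA/rRNA entries: occurrences with the same
# normalized name whose circular extents overlap are one locus; the merged
# feature covers the union extent (exons + introns). IR duplicates have
# disjoint extents and stay separate.
.mergeOccurrences <- function(occ, len, catalog) {
  if (!length(occ)) return(emptyFeatureTable())
  nms <- vapply(occ, `[[`, character(1), "name")
  out <- list()
  for (nm in unique(nms)) {
    idx <- which(nms == nm)
    grp <- rep(0L, length(idx))
    g <- 0L
    for (k in seq_along(idx)) {
      if (grp[k]) next
      g <- g + 1L
      grp[k] <- g
      for (j in seq_along(idx)) {
        if (grp[j]) next
        if (any(vapply(which(grp == g), function(m) {
          circOverlaps(occ[[idx[m]]]$extent, occ[[idx[j]]]$extent, len)
        }, logical(1)))) grp[j] <- g
      }
    }
    for (gg in seq_len(g)) {
      mem <- occ[idx[grp == gg]]
      exts <- do.call(rbind, lapply(mem, `[[`, "extent"))
      # union arc: anchor at the earliest member start, extend to the
      # farthest end reached walking forward
      starts <- exts[, 1] %% len
      anchor <- min(starts)
      endsRel <- ((exts[, 1] - anchor) %% len) + (exts[, 2] - exts[, 1])
      extent <- c(anchor, anchor + max(endsRel))
      keys <- vapply(mem, `[[`, character(1), "key")
      catKey <- setdiff(keys, "gene")
      category <- if (length(catKey)) mem[[which(keys == catKey[1])[1]]]$category
                  else mem[[1]]$category
      out[[length(out) + 1L]] <- list(
        name = nm, category = category, strand = mem[[1]]$strand,
        pseudo = any(vapply(mem, `[[`, logical(1), "pseudo")),
        intervals = circToLinear(extent, len), start = extent[1] %% len
      )
    }
  }
  ord <- order(vapply(out, `[[`, numeric(1), "start"))
  out <- out[ord]
  nmv <- vapply(out, `[[`, character(1), "name")
  makeFeatureTable(
    name = nmv,
    category = vapply(out, `[[`, character(1), "category"),
    strand = vapply(out, `[[`, integer(1), "strand"),
    conserved = isConservedGene(nmv, catalog) &
      !grepl("^orf[0-9]+", nmv),
    pseudo = vapply(out, `[[`, logical(1), "pseudo"),
    intervals = lapply(out, `[[`, "intervals")
  )
}
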