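# Gene-order TSV dialect and tree input.
#
# The TSV dialect allows download-free operation: it round-trips the
# ordered, strand-aware feature list of a genome without its sequence.
# Format: one header line "#id <id> length <bp>", then one tab-separated
# row per feature in genome order: name, strand (+/-), comma-separated
# spans ("start-end", 0-based half-open), conserved (0/1).

#' Write a genome's gene order to TSV
#'
#' @param genome a \linkS4class{ChloroGenome}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso [readGeneOrderTsv()]
#' @export
writeGeneOrderTsv <- function(genome, path) {
  ft <- genomeFeatures(genome)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#id %s length %d", genomeId(genome),
                     genomeLength(genome)), con)
  if (nrow(ft)) {
    rows <- vapply(seq_len(nrow(ft)), function(i) {
      iv <- ft$intervals[[i]]
      spans <- paste(sprintf("%d-%d", iv[, 1], iv[, 2]), collapse = ",")
      paste(ft$name[i], if (ft$strand[i] > 0) "+" else "-", spans,
            if (ft$conserved[i]) "1" else "0", sep = "\t")
    }, character(1))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a genome's gene order from TSV
#'
#' Inverse of [writeGeneOrderTsv()]: restores id, length and the ordered
#' feature list (name, strand, spans, conserved). The sequence is absent;
#' categories are inferred from the normalized names.
#'
#' @param path path to a gene-order TSV.
#' @return a \linkS4class{ChloroGenome} without sequence.
#' @export
readGeneOrderTsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^#id\\s+\\S+\\s+length\\s+[0-9]+\\s*$", lines[1]))
    stop("malformed gene-order TSV header (line 1): ", path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  id <- hdr[2]
  len <- as.integer(hdr[4])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  feats <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4L || !f[2] %in% c("+", "-") || !f[4] %in% c("0", "1"))
      stop("malformed gene-order TSV row at line ", i + 1L, ": ", body[i])
    spans <- strsplit(f[3], ",", fixed = TRUE)[[1]]
    iv <- do.call(rbind, lapply(spans, function(sp) {
      se <- suppressWarnings(as.integer(strsplit(sp, "-", fixed = TRUE)[[1]]))
      if (length(se) != 2L || anyNA(se))
        stop("malformed span '", sp, "' at line ", i + 1L)
      span(se[1], se[2])
    }))
    list(name = f[1], strand = if (f[2] == "+") 1L else -1L,
         conserved = f[4] == "1", intervals = iv)
  })
  nms <- vapply(feats, `[[`, character(1), "name")
  ft <- makeFeatureTable(
    name = nms, category = inferCategory(nms),
    strand = vapply(feats, `[[`, integer(1), "strand"),
    conserved = vapply(feats, `[[`, logical(1), "conserved"),
    pseudo = FALSE,
    intervals = lapply(feats, `[[`, "intervals")
  )
  chloroGenome(id, len, ft)
}

#' Read a rooted species tree from newick
#'
#' Thin wrapper around [ape::read.tree()] that enforces unique leaf
#' labels and preserves polytomies.
#'
#' @param path path to a newick file.
#' @return an \code{ape} \code{phylo} tree.
#' @export
readSpeciesTree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick tree: ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels in tree: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}
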