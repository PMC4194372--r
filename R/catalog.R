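# Conserved-gene catalog and gene-name normalization.
#
# Cross-record repertoire comparison needs a controlled vocabulary: every
# record's annotations are mapped onto canonical plastid gene symbols
# (lowercase-prefix symbols such as psbA; tRNAs as trn<AA>-<anticodon>;
# rRNAs rrs/rrl/rrf). Unknown names pass through lowercased and are
# flagged non-conserved.

.plastarchCache <- new.env(parent = emptyenv())

#' Conserved plastid gene catalog
#'
#' Returns the shipped catalog of conserved chloroplast genes (canonical
#' symbol and category). The catalog covers the conserved repertoire of
#' green-algal chloroplast genomes: photosystem, ATP synthase, cytochrome,
#' ribosomal-protein, RNA-polymerase, ndh and chl gene families, the three
#' rRNAs and the standard tRNA set with anticodon suffixes.
#'
#' @param path optional path to a two-column (name, category) TSV to use
#'   instead of the shipped catalog.
#' @return data.frame with columns \code{name}, \code{category}.
#' @export
conservedCatalog <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.plastarchCache$catalog)) {
      f <- system.file("extdata", "conserved_genes.tsv", package = "plastarch",
                       mustWork = TRUE)
      .plastarchCache$catalog <- utils::read.delim(f, stringsAsFactors = FALSE)
    }
    return(.plastarchCache$catalog)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

geneSynonyms <- function() {
  if (is.null(.plastarchCache$synonyms)) {
    f <- system.file("extdata", "gene_synonyms.tsv", package = "plastarch",
                     mustWork = TRUE)
    .plastarchCache$synonyms <- utils::read.delim(f, stringsAsFactors = FALSE)
  }
  .plastarchCache$synonyms
}

.aa3to1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V"
)

.normalizeTrn <- function(x) {
  # anticodon: a 3-letter [acgu] group in parentheses or after -/_
  anti <- NA_character_
  m <- regmatches(x, regexpr("\\(([ACGTUacgtu]{3})\\)", x))
  if (length(m) && nzchar(m)) anti <- gsub("[()]", "", m)
  if (is.na(anti)) {
    m <- regmatches(x, regexpr("[-_ ]([ACGTUacgtu]{3})\\b", x))
    if (length(m) && nzchar(m)) anti <- gsub("^[-_ ]", "", m)
  }
  body <- sub("\\(.*$", "", x)
  body <- sub("^t-?RNA[-_ ]?", "trn", body, ignore.case = TRUE)
  body <- sub("^trn", "", body, ignore.case = TRUE)
  body <- sub("[-_ ].*$", "", body)
  aa <- body
  # 3-letter amino-acid names (tRNA-Leu style)
  hit <- match(tolower(aa), tolower(names(.aa3to1)))
  if (!is.na(hit)) aa <- unname(.aa3to1[hit])
  # initiator methionine spellings
  if (tolower(aa) %in% c("fm", "fmet")) aa <- "Mf"
  if (nchar(aa) >= 1) {
    aa <- paste0(toupper(substr(aa, 1, 1)),
                 tolower(substr(aa, 2, nchar(aa))))
  }
  anti <- tolower(gsub("u", "u", gsub("t", "u", tolower(anti))))
  if (is.na(anti) || !nzchar(anti)) return(paste0("trn", aa))
  paste0("trn", aa, "-", anti)
}

#' Normalize a gene name to its canonical plastid symbol
#'
#' Maps annotation spellings onto the controlled vocabulary used throughout
#' the package: tRNAs become \code{trn<AA>-<anticodon>} (lowercase
#' anticodon; initiator methionine \code{trnMf-cau}, elongator
#' \code{trnMe-cau}), rRNA synonyms (\code{rrn16}, \code{16S}, ...) become
#' \code{rrs}/\code{rrl}/\code{rrf}, shipped synonyms (e.g.
#' \code{ycf9} -> \code{psbZ}) are resolved, and any name matching the
#' conserved catalog case-insensitively takes the catalog spelling.
#' Anything else passes through lowercased. The mapping is idempotent.
#'
#' @param x character vector of raw gene names.
#' @return character vector of normalized names.
#' @examples
#' normalizeGeneName(c("trnL(UAA)", "PsbA", "rrn16", "orf389"))
#' @export
normalizeGeneName <- function(x) {
  vapply(x, function(one) {
    s <- trimws(one)
    if (!nzchar(s)) return(s)
    syn <- geneSynonyms()
    hit <- match(tolower(s), tolower(syn$synonym))
    if (!is.na(hit)) return(syn$canonical[hit])
    if (grepl("^t-?rna", s, ignore.case = TRUE) ||
        grepl("^trn", s, ignore.case = TRUE)) {
      s2 <- .normalizeTrn(s)
      hit <- match(tolower(s2), tolower(syn$synonym))
      if (!is.na(hit)) return(syn$canonical[hit])
      cat <- conservedCatalog()
      hit <- match(tolower(s2), tolower(cat$name))
      if (!is.na(hit)) return(cat$name[hit])
      return(s2)
    }
    cat <- conservedCatalog()
    hit <- match(tolower(s), tolower(cat$name))
    if (!is.na(hit)) return(cat$name[hit])
    tolower(s)
  }, character(1), USE.NAMES = FALSE)
}

#' Base name of a possibly fragmented gene
#'
#' Trans-spliced or fragmented genes are stored as separate features
#' sharing one base name with a single-letter part suffix (e.g. Picocystis
#' \code{ycf3a} + \code{ycf3b}). For repertoire purposes the base name
#' counts once; gene order keeps each part as its own element.
#'
#' @param x character vector of normalized names.
#' @return character vector of base names.
#' @export
baseGeneName <- function(x) {
  cat <- conservedCatalog()
  vapply(x, function(s) {
    if (s %in% cat$name) return(s)
    stem <- sub("[a-b]$", "", s)
    if (stem != s && stem %in% cat$name) return(stem)
    s
  }, character(1), USE.NAMES = FALSE)
}

# Category guessed from a normalized name (used when reading the
# gene-order TSV, which does not carry categories).
inferCategory <- function(x) {
  cat <- conservedCatalog()
  vapply(x, function(s) {
    hit <- match(baseGeneName(s), cat$name)
    if (!is.na(hit)) return(cat$category[hit])
    if (grepl("^trn", s)) return("tRNA")
    if (s %in% c("rrs", "rrl", "rrf")) return("rRNA")
    if (grepl("^orf[0-9]+", s)) return("orf")
    "other"
  }, character(1), USE.NAMES = FALSE)
}

#' Is a (normalized) gene name in the conserved catalog?
#'
#' Free-standing ORFs and unrecognized names are non-conserved; they are
#' excluded from gene counts, pair/block analysis and the genic cover used
#' for the intergenic fraction.
#'
#' @param x character vector of normalized names.
#' @param catalog optional catalog data.frame, see [conservedCatalog()].
#' @return logical vector.
#' @export
isConservedGene <- function(x, catalog = conservedCatalog()) {
  baseGeneName(x) %in% catalog$name
}
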