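#' Construct a BarcodeSet
#'
#' @param sequences Character vector or \code{DNAStringSet} of nucleotide
#'   sequences (IUPAC codes; \code{-} gaps allowed; RNA \code{U} is mapped to
#'   \code{T} on ingestion).
#' @param accession Character vector of unique record identifiers; defaults to
#'   \code{names(sequences)}.
#' @param declaredTaxon Species label under which each record was deposited.
#' @param taxonGroup Higher group, e.g. "Gastrotricha"; defaults to
#'   \code{"unknown"} so screening never requires curated metadata.
#' @param geneLabel Free-text gene description as deposited.
#'
#' @return A \linkS4class{BarcodeSet}. The \code{aligned} flag is set iff all
#'   sequences have equal length.
#' @examples
#' bs <- barcodeSet(c(r1 = "ACGT-CA", r2 = "ACGAACA"),
#'                  declaredTaxon = "Branchipus schaefferi")
#' isAligned(bs)
#' @export
barcodeSet <- function(sequences, accession = names(sequences),
                       declaredTaxon = "unknown", taxonGroup = "unknown",
                       geneLabel = "") {
  if (is(sequences, "XStringSet")) sequences <- as.character(sequences)
  if (!length(sequences)) stop("no sequences supplied", call. = FALSE)
  if (is.null(accession)) stop("records need accessions", call. = FALSE)
  .checkAlphabet(sequences)
  sequences <- .normalizeSeq(sequences)
  dna <- Biostrings::DNAStringSet(sequences)
  names(dna) <- as.character(accession)
  n <- length(dna)
  meta <- S4Vectors::DataFrame(
    declared_taxon = rep_len(as.character(declaredTaxon), n),
    taxon_group = rep_len(as.character(taxonGroup), n),
    gene_label = rep_len(as.character(geneLabel), n)
  )
  rownames(meta) <- names(dna)
  aligned <- length(unique(Biostrings::width(dna))) <= 1L
  new("BarcodeSet", sequences = dna, meta = meta, aligned = aligned)
}

#' Accessors for BarcodeSet
#'
#' @param x A \linkS4class{BarcodeSet}.
#' @return \code{accessions}, \code{declaredTaxon}, \code{taxonGroup} and
#'   \code{geneLabels} return character vectors; \code{sequences} the
#'   underlying \code{DNAStringSet}; \code{isAligned} a logical scalar.
#' @name BarcodeSet-accessors
#' @aliases accessions declaredTaxon taxonGroup geneLabels isAligned sequences
NULL

#' @rdname BarcodeSet-accessors
#' @export
setMethod("accessions", "BarcodeSet", function(x) names(x@sequences))

#' @rdname BarcodeSet-accessors
#' @export
setMethod("declaredTaxon", "BarcodeSet", function(x) x@meta$declared_taxon)

#' @rdname BarcodeSet-accessors
#' @export
setMethod("taxonGroup", "BarcodeSet", function(x) x@meta$taxon_group)

#' @rdname BarcodeSet-accessors
#' @export
setMethod("geneLabels", "BarcodeSet", function(x) x@meta$gene_label)

#' @rdname BarcodeSet-accessors
#' @export
setMethod("isAligned", "BarcodeSet", function(x) x@aligned)

#' @rdname BarcodeSet-accessors
#' @export
setMethod("sequences", "BarcodeSet", function(x) x@sequences)

#' @export
setMethod("length", "BarcodeSet", function(x) length(x@sequences))

#' @export
setMethod("[", "BarcodeSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, accessions(x))
  new("BarcodeSet",
      sequences = x@sequences[i],
      meta = x@meta[i, , drop = FALSE],
      aligned = length(unique(Biostrings::width(x@sequences[i]))) <= 1L)
})

#' @export
setMethod("show", "BarcodeSet", function(object) {
  n <- length(object)
  w <- Biostrings::width(object@sequences)
  cat("BarcodeSet with", n, "record(s),",
      if (isAligned(object)) sprintf("aligned (width %d)", if (n) w[1] else 0L)
      else sprintf("unaligned (widths %d-%d)", min(w), max(w)), "\n")
  grp <- table(taxonGroup(object))
  cat("  taxon groups:",
      paste(sprintf("%s (%d)", names(grp), grp), collapse = ", "), "\n")
})

#' Read barcode records from FASTA (plus optional metadata TSV)
#'
#' FASTA headers are parsed as \code{accession<whitespace>description}; gap
#' characters are preserved and RNA \code{U} is mapped to \code{T}. When a
#' metadata table is supplied its \code{taxon_group} and \code{gene_label}
#' (and, if present, \code{declared_taxon}) columns are joined on accession;
#' records without a metadata row get \code{taxon_group = "unknown"}.
#'
#' @param path FASTA file.
#' @param meta Optional TSV with header
#'   \code{accession<TAB>taxon_group<TAB>gene_label}.
#' @return A \linkS4class{BarcodeSet}; its \code{aligned} flag is \code{TRUE}
#'   iff all entries have equal length.
#' @export
readBarcodeFasta <- function(path, meta = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (!length(nonEmpty))
    stop("empty FASTA file: ", path, call. = FALSE)
  if (!startsWith(trimws(lines[nonEmpty[1]]), ">"))
    stop("malformed FASTA at line ", nonEmpty[1],
         ": expected a '>' header", call. = FALSE)
  raw <- Biostrings::readBStringSet(path)
  if (!length(raw)) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(raw)
  acc <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(acc))
    stop("duplicate accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  bs <- barcodeSet(as.character(raw), accession = acc,
                   declaredTaxon = ifelse(nzchar(desc), desc, "unknown"))
  if (!is.null(meta)) {
    md <- readRecordMeta(meta)
    idx <- match(acc, md$accession)
    hit <- !is.na(idx)
    bs@meta$taxon_group[hit] <- md$taxon_group[idx[hit]]
    bs@meta$gene_label[hit] <- md$gene_label[idx[hit]]
    if ("declared_taxon" %in% colnames(md))
      bs@meta$declared_taxon[hit] <- md$declared_taxon[idx[hit]]
  }
  validObject(bs)
  bs
}

#' Read a record metadata TSV
#'
#' @param path TSV with required columns \code{accession}, \code{taxon_group},
#'   \code{gene_label}; extra columns are kept.
#' @return A data.frame.
#' @export
readRecordMeta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  md <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#")
  need <- c("accession", "taxon_group", "gene_label")
  if (!all(need %in% colnames(md)))
    stop("metadata TSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  md
}

#' Write a BarcodeSet to FASTA (and optionally its metadata TSV)
#'
#' Headers are \code{accession declared_taxon}; sequences (including gaps)
#' round-trip byte-exactly through \code{\link{readBarcodeFasta}}.
#'
#' @param x A \linkS4class{BarcodeSet}.
#' @param path Output FASTA path.
#' @param metaPath Optional path for a metadata TSV
#'   (\code{accession, taxon_group, gene_label, declared_taxon}).
#' @return \code{path}, invisibly.
#' @export
writeBarcodeFasta <- function(x, path, metaPath = NULL) {
  stopifnot(is(x, "BarcodeSet"))
  out <- x@sequences
  names(out) <- paste(accessions(x), declaredTaxon(x))
  Biostrings::writeXStringSet(out, filepath = path, width = 70L)
  if (!is.null(metaPath)) {
    md <- data.frame(accession = accessions(x),
                     taxon_group = taxonGroup(x),
                     gene_label = geneLabels(x),
                     declared_taxon = declaredTaxon(x),
                     stringsAsFactors = FALSE)
    write.table(md, metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Normalize free-text gene labels to a canonical COX token
#'
#' Public databases describe the same gene in several dialects ("COI" vs
#' "CO1", "cytochrome c oxidase" vs "cytochrome oxidase", roman vs arabic
#' subunit numbers). This maps any such description to one of
#' \code{COX1}, \code{COX2}, \code{COX3} or \code{OTHER}, case-insensitively.
#' Labels advertising a "COI-like" gene (a numt hallmark) keep their subunit
#' token but are flagged.
#'
#' @param x Character vector of gene labels.
#' @param detail If \code{TRUE}, return a data.frame with columns
#'   \code{label}, \code{token}, \code{like_gene}; otherwise just the token
#'   vector.
#' @return Character vector of tokens, or a data.frame when
#'   \code{detail = TRUE}.
#' @examples
#' normalizeGeneLabel(c("cytochrome c oxidase subunit I", "CO1", "ND5"))
#' normalizeGeneLabel("cytochrome c oxidase subunit I like (COI) gene",
#'                    detail = TRUE)
#' @export
normalizeGeneLabel <- function(x, detail = FALSE) {
  x <- as.character(x)
  s <- tolower(x)
  s <- gsub("[^a-z0-9]+", " ", s)
  s <- trimws(gsub("\\s+", " ", s))
  subunit3 <- grepl("(subunit (iii|3)\\b)|\\bco(x ?)?(iii|3)\\b", s)
  subunit2 <- grepl("(subunit (ii|2)\\b)|\\bco(x ?)?(ii|2)\\b", s)
  subunit1 <- grepl("(subunit (i|1)\\b)|\\bco(x ?)?(i|1)\\b", s)
  oxidase <- grepl("\\b(cytochrome )?(c )?oxidase\\b", s)
  token <- rep("OTHER", length(s))
  token[subunit1 | (oxidase & !subunit2 & !subunit3)] <- "COX1"
  token[subunit2 & !subunit3] <- "COX2"
  token[subunit3] <- "COX3"
  # bare "cytochrome oxidase" with no subunit stays OTHER unless nothing else
  bare <- oxidase & !subunit1 & !subunit2 & !subunit3
  token[bare] <- "COX1"
  like <- grepl("\\blike\\b", s)
  if (detail)
    data.frame(label = x, token = token, like_gene = like,
               stringsAsFactors = FALSE)
  else token
}

# Canonical boolean query template; the published rendering strips spaces
# (typesetting artifact), hence the compact form below.
.ENTREZ_TEMPLATE <- paste0(
  '(%s[Organism]) AND ("oxidase subunit I" OR "oxidase subunit 1" OR ',
  '"CO1" OR "COI")) NOT ("subunit II" OR "subunit 2" OR ',
  '"subunit III" OR "subunit 3")')

#' Build the COI database query string for a taxon
#'
#' Produces the boolean Entrez query matching all gene-name dialects of COI
#' while excluding subunits II and III, with the taxon substituted into the
#' organism clause. No network call is made; the string is returned for the
#' user to execute.
#'
#' @param taxonName Non-empty taxon name, e.g. "Gastrotricha".
#' @param compact If \code{TRUE}, return the space-stripped rendering.
#' @return The query string.
#' @examples
#' buildEntrezQuery("Gastrotricha")
#' @export
buildEntrezQuery <- function(taxonName, compact = FALSE) {
  if (length(taxonName) != 1L || is.na(taxonName) || !nzchar(trimws(taxonName)))
    stop("taxonName must be a non-empty string", call. = FALSE)
  q <- sprintf(.ENTREZ_TEMPLATE, trimws(taxonName))
  if (compact) gsub(" ", "", q, fixed = TRUE) else q
}
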