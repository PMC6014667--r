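# Nei-Kumar p-distance screening: the proportion of differing nucleotide
# sites between two aligned sequences, with pairwise deletion of any column
# holding a gap or ambiguity code in either sequence. Conspecific COI
# records sit around 2% p-distance; bacterial contaminants mislabeled as
# their metazoan "host" sit around 62-68%, which makes the distance a
# near-perfect contaminant detector.

# Encode an aligned character matrix as integers 1..4, NA = gap/ambiguity.
#' @noRd
.alignedIntMatrix <- function(x) {
  stopifnot(is(x, "BarcodeSet"))
  if (!isAligned(x))
    stop("records must be aligned (equal lengths) for distance computation",
         call. = FALSE)
  cm <- as.matrix(x@sequences)
  m <- matrix(match(cm, .BASES), nrow = nrow(cm), ncol = ncol(cm))
  rownames(m) <- accessions(x)
  m
}

#' Nei-Kumar p-distance between two aligned sequences
#'
#' @param a,b Aligned nucleotide strings of equal length (IUPAC; gaps
#'   allowed). Columns where either sequence carries a gap or ambiguity code
#'   are excluded (pairwise deletion).
#' @param minSites Minimum number of pairwise-comparable sites for a valid
#'   distance (default 100; the Folmer amplicon is ~658 bp, and tiny overlaps
#'   yield spurious distances).
#' @return A list: \code{distance} (proportion in [0,1]) and
#'   \code{comparableSites}.
#' @examples
#' pDistance("ACGT-CA", "ACGAACA", minSites = 1)  # 1 difference / 6 sites
#' @export
pDistance <- function(a, b, minSites = 100) {
  a <- .encodeSeq(as.character(a))
  b <- .encodeSeq(as.character(b))
  if (length(a) != length(b))
    stop("alignment error: sequences have unequal lengths", call. = FALSE)
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < minSites)
    stop(sprintf(
      "insufficient overlap: %d comparable site(s) < minSites = %d", n,
      as.integer(minSites)), call. = FALSE)
  list(distance = sum(a[ok] != b[ok]) / n, comparableSites = as.integer(n))
}

#' p-distance between two unaligned sequences via pairwise alignment
#'
#' Globally aligns the pair end to end (match +5, mismatch -4, gap opening
#' 100, gap extension 2) and computes the p-distance on the aligned strings.
#' Provided for two-record comparisons only; multi-record sets should be
#' aligned upstream. The scoring is deliberately gap-averse: two same-locus
#' amplicons differ by substitutions plus at most a few real indels, and at
#' cross-domain divergences (~62-68\%) permissive gap penalties let the
#' optimizer fabricate gap pairings that convert mismatches into matches and
#' deflate the distance. End gaps are penalized for the same reason: under
#' score maximization a free-end-gap alignment of such a pair collapses to a
#' near-empty overlap.
#'
#' @param a,b Unaligned nucleotide strings.
#' @param minSites Minimum comparable sites (see \code{\link{pDistance}}).
#' @return As \code{\link{pDistance}}.
#' @export
pairwisePDistance <- function(a, b, minSites = 100) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(gsub("-", "", .normalizeSeq(as.character(a)))),
    Biostrings::DNAString(gsub("-", "", .normalizeSeq(as.character(b)))),
    type = "global", substitutionMatrix = mat,
    gapOpening = 100, gapExtension = 2)
  pDistance(as.character(Biostrings::alignedPattern(aln)),
            as.character(Biostrings::alignedSubject(aln)),
            minSites = minSites)
}

#' Pairwise p-distance matrix for an aligned BarcodeSet
#'
#' @param x An aligned \linkS4class{BarcodeSet}.
#' @param minSites Minimum comparable sites per pair; pairs below the
#'   threshold get an \code{NA} distance.
#' @return A \linkS4class{PDistanceMatrix}.
#' @export
pDistanceMatrix <- function(x, minSites = 100) {
  m <- .alignedIntMatrix(x)
  n <- nrow(m)
  ok <- !is.na(m)
  vals <- matrix(0, n, n)
  sites <- matrix(0L, n, n)
  diag(sites) <- as.integer(rowSums(ok))
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        comp <- ok[i, ] & ok[j, ]
        s <- sum(comp)
        sites[i, j] <- sites[j, i] <- as.integer(s)
        vals[i, j] <- vals[j, i] <-
          if (s >= minSites) sum(m[i, comp] != m[j, comp]) / s else NA_real_
      }
    }
  }
  dimnames(vals) <- dimnames(sites) <- list(rownames(m), rownames(m))
  new("PDistanceMatrix", labels = rownames(m), values = vals, sites = sites,
      minSites = as.integer(minSites))
}

#' Accessors for PDistanceMatrix
#'
#' @param x A \linkS4class{PDistanceMatrix}.
#' @return \code{distanceValues} the numeric distance matrix;
#'   \code{comparableSites} the site-count matrix; \code{labels} the
#'   accessions.
#' @name PDistanceMatrix-accessors
#' @aliases distanceValues comparableSites
NULL

#' @rdname PDistanceMatrix-accessors
#' @export
setMethod("distanceValues", "PDistanceMatrix", function(x) x@values)

#' @rdname PDistanceMatrix-accessors
#' @export
setMethod("comparableSites", "PDistanceMatrix", function(x) x@sites)

#' @rdname PDistanceMatrix-accessors
#' @param object A \code{PDistanceMatrix}.
#' @export
setMethod("labels", "PDistanceMatrix", function(object, ...) object@labels)

#' @export
setMethod("show", "PDistanceMatrix", function(object) {
  n <- length(object@labels)
  off <- object@values[upper.tri(object@values)]
  cat(sprintf("PDistanceMatrix: %d records, min sites %d\n", n,
              object@minSites))
  if (length(off))
    cat(sprintf("  distances: %.3f-%.3f (mean %.3f), %d invalid pair(s)\n",
                min(off, na.rm = TRUE), max(off, na.rm = TRUE),
                mean(off, na.rm = TRUE), sum(is.na(off))))
})

#' Within- and between-group distance summaries
#'
#' Mean, minimum and maximum of within-group pairwise distances per group
#' (NA for singleton groups) and the mean between-group distance for every
#' group pair. This reproduces the clade-level summaries an audit reports:
#' conspecific clouds around 2%, within-bacteria spreads up to ~27%, and
#' cross-domain means around 65%.
#'
#' @param x A \linkS4class{PDistanceMatrix}.
#' @param groups Named character vector mapping accession to group, or an
#'   unnamed vector in matrix order.
#' @return A list with data.frames \code{within} (\code{group, n, mean, min,
#'   max}) and \code{between} (\code{group1, group2, mean}).
#' @export
groupDistanceSummary <- function(x, groups) {
  stopifnot(is(x, "PDistanceMatrix"))
  v <- x@values
  labs <- x@labels
  g <- if (!is.null(names(groups))) unname(groups[labs]) else
    rep_len(unname(groups), length(labs))
  if (anyNA(g)) stop("every accession needs a group", call. = FALSE)
  ug <- unique(g)
  if (length(ug) < 2) stop("need at least 2 groups", call. = FALSE)
  within <- do.call(rbind, lapply(ug, function(gr) {
    idx <- which(g == gr)
    d <- v[idx, idx, drop = FALSE][upper.tri(diag(length(idx)))]
    data.frame(group = gr, n = length(idx),
               mean = if (length(d)) mean(d, na.rm = TRUE) else NA_real_,
               min = if (length(d)) min(d, na.rm = TRUE) else NA_real_,
               max = if (length(d)) max(d, na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(ug, 2)
  between <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
    i <- which(g == pairs[1, p]); j <- which(g == pairs[2, p])
    data.frame(group1 = pairs[1, p], group2 = pairs[2, p],
               mean = mean(v[i, j, drop = FALSE], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(within = within, between = between)
}

# Distances from each query record to each reference, all pre-aligned to a
# common coordinate system (equal lengths).
#' @noRd
.queryRefDistances <- function(records, references, minSites) {
  mq <- .alignedIntMatrix(records)
  mr <- .alignedIntMatrix(references)
  if (ncol(mq) != ncol(mr))
    stop("records and references must share one alignment (equal widths)",
         call. = FALSE)
  d <- matrix(NA_real_, nrow(mq), nrow(mr),
              dimnames = list(rownames(mq), rownames(mr)))
  okq <- !is.na(mq); okr <- !is.na(mr)
  for (i in seq_len(nrow(mq))) {
    for (j in seq_len(nrow(mr))) {
      comp <- okq[i, ] & okr[j, ]
      s <- sum(comp)
      if (s >= minSites) d[i, j] <- sum(mq[i, comp] != mr[j, comp]) / s
    }
  }
  d
}

#' Classify barcode records against a labeled reference panel
#'
#' Applies the screening rules in fixed order, per record:
#' \describe{
#'   \item{R1}{distance to the nearest conspecific reference (same declared
#'     taxon) at most \code{tauSpecies}: \code{target}. Skipped (and noted in
#'     the rule trace) when no conspecific reference exists.}
#'   \item{R2}{translation not clean or gaps present, and nearest metazoan
#'     reference closer than \code{tauContam}: \code{numt_suspect} (a numt is
#'     a corrupted copy of the host's own gene, so it stays well inside the
#'     metazoan distance range).}
#'   \item{R3}{every metazoan reference at least \code{tauContam} away and
#'     some contaminant-panel (bacteria/fungi) reference closer than all
#'     metazoans: \code{bacterial_contaminant}.}
#'   \item{R4}{conspecific distance above \code{tauSpecies} (or no
#'     conspecific) but some other metazoan reference within
#'     \code{tauSpecies}: \code{other_metazoan}.}
#'   \item{R5}{otherwise \code{unresolved}.}
#' }
#'
#' @param records Aligned \linkS4class{BarcodeSet} of query records.
#' @param references Aligned \linkS4class{BarcodeSet} of references, same
#'   alignment width; \code{taxonGroup} must be one of \code{metazoa},
#'   \code{bacteria}, \code{fungi}.
#' @param flags Optional data.frame from \code{\link{screenFrames}} (computed
#'   here if missing).
#' @param tauSpecies Conspecific threshold (default 0.05, above the ~2\%
#'   conspecific expectation).
#' @param tauContam Cross-domain threshold (default 0.30, between the
#'   within-bacteria range and the ~62-68\% cross-domain distances).
#' @param minSites Minimum comparable sites per pair.
#' @param codeTable Genetic code for the frame screen when \code{flags} is
#'   missing.
#' @return A data.frame with one row per record: \code{accession},
#'   \code{verdict}, \code{d_conspecific}, \code{d_nearest_other},
#'   \code{rule_trace} (comma-separated ids of the rules evaluated; the last
#'   one fired).
#' @export
classifyRecords <- function(records, references, flags = NULL,
                            tauSpecies = 0.05, tauContam = 0.30,
                            minSites = 100, codeTable = 5) {
  stopifnot(is(records, "BarcodeSet"), is(references, "BarcodeSet"))
  refGroups <- tolower(taxonGroup(references))
  if (!all(refGroups %in% c("metazoa", "bacteria", "fungi")))
    stop("reference taxon_group must be metazoa, bacteria or fungi",
         call. = FALSE)
  if (is.null(flags)) flags <- screenFrames(records, codeTable = codeTable)
  flags <- flags[match(accessions(records), flags$accession), ]
  d <- .queryRefDistances(records, references, minSites)
  metaIdx <- which(refGroups == "metazoa")
  contamIdx <- which(refGroups != "metazoa")
  refTaxa <- declaredTaxon(references)
  out <- lapply(seq_len(length(records)), function(i) {
    di <- d[i, ]
    consIdx <- which(refTaxa == declaredTaxon(records)[i])
    dCons <- if (length(consIdx)) suppressWarnings(min(di[consIdx], na.rm = TRUE)) else NA_real_
    if (!is.finite(dCons)) dCons <- NA_real_
    otherIdx <- setdiff(seq_along(di), consIdx)
    dOther <- if (length(otherIdx)) suppressWarnings(min(di[otherIdx], na.rm = TRUE)) else NA_real_
    if (!is.finite(dOther)) dOther <- NA_real_
    dMeta <- suppressWarnings(min(di[metaIdx], na.rm = TRUE))
    dContam <- suppressWarnings(min(di[contamIdx], na.rm = TRUE))
    trace <- character()
    verdict <- NULL
    if (!length(consIdx) || is.na(dCons)) {
      trace <- c(trace, "R1:skipped_no_conspecific")
    } else {
      trace <- c(trace, "R1")
      if (dCons <= tauSpecies) verdict <- "target"
    }
    if (is.null(verdict)) {
      trace <- c(trace, "R2")
      if ((!flags$clean[i] || flags$has_gaps[i]) &&
          is.finite(dMeta) && dMeta < tauContam)
        verdict <- "numt_suspect"
    }
    if (is.null(verdict)) {
      trace <- c(trace, "R3")
      if (is.finite(dMeta) && dMeta >= tauContam &&
          is.finite(dContam) && dContam < dMeta)
        verdict <- "bacterial_contaminant"
    }
    if (is.null(verdict)) {
      trace <- c(trace, "R4")
      otherMetaIdx <- setdiff(metaIdx, consIdx)
      dOtherMeta <- suppressWarnings(min(di[otherMetaIdx], na.rm = TRUE))
      if ((is.na(dCons) || dCons > tauSpecies) &&
          is.finite(dOtherMeta) && dOtherMeta <= tauSpecies)
        verdict <- "other_metazoan"
    }
    if (is.null(verdict)) {
      trace <- c(trace, "R5")
      verdict <- "unresolved"
    }
    data.frame(accession = accessions(records)[i], verdict = verdict,
               d_conspecific = dCons, d_nearest_other = dOther,
               rule_trace = paste(trace, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' UPGMA tree from a distance matrix
#'
#' @param x A \linkS4class{PDistanceMatrix} with no invalid entries.
#' @return An \code{\link[ape]{as.phylo}}-converted UPGMA (average-linkage)
#'   tree.
#' @export
upgmaTree <- function(x) {
  stopifnot(is(x, "PDistanceMatrix"))
  if (anyNA(x@values))
    stop("distance matrix has invalid (insufficient-overlap) entries",
         call. = FALSE)
  hc <- hclust(as.dist(x@values), method = "average")
  ape::as.phylo(hc)
}

#' Two-cluster bipartition check
#'
#' Desk-scale stand-in for the domain-level split a phylogeny shows: builds a
#' UPGMA tree, cuts it at the deepest node into two clusters, and scores how
#' purely the clusters reproduce the true group labels (fraction of records
#' matching their cluster's majority label, maximized over labelings). A
#' clean Metazoa/bacteria data set at cross-domain distances yields purity 1.
#'
#' @param x A \linkS4class{PDistanceMatrix} of at least 4 records.
#' @param groups Named character vector (accession to true group) or unnamed
#'   vector in matrix order.
#' @return A list: \code{clusters} (named integer vector, 1 or 2),
#'   \code{purity}, \code{tie} (TRUE when all pairwise distances are equal,
#'   making the split arbitrary), \code{tree} (the UPGMA \code{phylo}).
#' @export
bipartitionCheck <- function(x, groups) {
  stopifnot(is(x, "PDistanceMatrix"))
  n <- length(x@labels)
  if (n < 4) stop("need at least 4 records", call. = FALSE)
  g <- if (!is.null(names(groups))) unname(groups[x@labels]) else
    rep_len(unname(groups), n)
  hc <- hclust(as.dist(x@values), method = "average")
  cl <- stats::cutree(hc, k = 2)
  off <- x@values[upper.tri(x@values)]
  tie <- isTRUE(all.equal(max(off), min(off)))
  purity <- sum(vapply(split(g, cl), function(z) max(table(z)), numeric(1))) / n
  list(clusters = cl, purity = purity, tie = tie, tree = ape::as.phylo(hc))
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param x A \linkS4class{PDistanceMatrix}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writePhylip <- function(x, path) {
  stopifnot(is(x, "PDistanceMatrix"))
  n <- length(x@labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", n), con)
  for (i in seq_len(n)) {
    writeLines(paste0(formatC(x@labels[i], width = -10),
                      paste(sprintf("%.6f", x@values[i, ]), collapse = "  ")),
               con)
  }
  invisible(path)
}
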