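#' BarcodeSet: a collection of barcode database records
#'
#' An ordered set of DNA barcode records, each carrying the fields a database
#' entry carries: accession, declared taxon (the species label under which the
#' sequence was deposited), higher taxon group, free-text gene label and the
#' nucleotide sequence (IUPAC codes, gaps permitted). Sequences are stored as
#' a \link[Biostrings]{DNAStringSet} named by accession; per-record metadata
#' live in a \link[S4Vectors]{DataFrame}.
#'
#' @slot sequences A \code{DNAStringSet}, names are accessions (unique).
#' @slot meta A \code{DataFrame} with columns \code{declared_taxon},
#'   \code{taxon_group} and \code{gene_label}, one row per record.
#' @slot aligned Logical; \code{TRUE} iff all sequences have equal length
#'   (gap columns included).
#'
#' @seealso \code{\link{barcodeSet}}, \code{\link{readBarcodeFasta}}
#' @export
setClass("BarcodeSet",
  representation(
    sequences = "DNAStringSet",
    meta = "DataFrame",
    aligned = "logical"
  )
)

setValidity("BarcodeSet", function(object) {
  msg <- character()
  acc <- names(object@sequences)
  if (length(object@sequences) > 0 && (is.null(acc) || any(!nzchar(acc))))
    msg <- c(msg, "every record needs a non-empty accession")
  if (anyDuplicated(acc))
    msg <- c(msg, "accessions must be unique within a BarcodeSet")
  if (length(object@sequences) > 0 && any(Biostrings::width(object@sequences) == 0))
    msg <- c(msg, "sequences must be non-empty")
  if (nrow(object@meta) != length(object@sequences))
    msg <- c(msg, "meta must have one row per sequence")
  need <- c("declared_taxon", "taxon_group", "gene_label")
  if (!all(need %in% colnames(object@meta)))
    msg <- c(msg, paste("meta must have columns:", paste(need, collapse = ", ")))
  if (length(object@aligned) != 1L || is.na(object@aligned))
    msg <- c(msg, "aligned must be TRUE or FALSE")
  else if (object@aligned && length(object@sequences) > 1 &&
           length(unique(Biostrings::width(object@sequences))) != 1L)
    msg <- c(msg, "aligned=TRUE but sequence lengths differ")
  if (length(msg)) msg else TRUE
})

#' PDistanceMatrix: pairwise p-distances with comparable-site counts
#'
#' Symmetric matrix of Nei-Kumar p-distances (proportion of differing sites
#' among pairwise-comparable sites) together with the number of comparable
#' sites used for each pair. Entries whose comparable-site count falls below
#' \code{minSites} are \code{NA} (not considered valid distances).
#'
#' @slot labels Character vector of accessions (row/column order).
#' @slot values Numeric symmetric matrix in [0,1], zero diagonal; \code{NA}
#'   where the pair had insufficient overlap.
#' @slot sites Integer matrix of pairwise-comparable site counts.
#' @slot minSites Minimum comparable sites required for a valid entry.
#'
#' @seealso \code{\link{pDistanceMatrix}}
#' @export
setClass("PDistanceMatrix",
  representation(
    labels = "character",
    values = "matrix",
    sites = "matrix",
    minSites = "integer"
  )
)

setValidity("PDistanceMatrix", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (!all(dim(object@values) == c(n, n)) || !all(dim(object@sites) == c(n, n)))
    msg <- c(msg, "values and sites must be n x n for n labels")
  v <- object@values
  if (n > 0) {
    if (any(abs(diag(v)) > 0, na.rm = TRUE))
      msg <- c(msg, "diagonal must be zero")
    if (!isTRUE(all.equal(v, t(v))) && !all(is.na(v) == is.na(t(v))))
      msg <- c(msg, "values must be symmetric")
    if (any(v < 0 | v > 1, na.rm = TRUE))
      msg <- c(msg, "distances must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' AuditObservation: one database sampling outcome
#'
#' The outcome of sampling a database group: \code{n} records sampled
#' uniformly at random, \code{k} of them found misidentified, out of
#' \code{nTotal} records the database holds for the group. This is the sole
#' input to all prevalence-estimation operations.
#'
#' @slot taxonGroup Group label (e.g. "Arthropoda").
#' @slot n Sample size (positive integer).
#' @slot k Number of misidentified records found, \code{0 <= k <= n}.
#' @slot nTotal Total database records for the group, \code{>= n}.
#'
#' @seealso \code{\link{auditObservation}}, \code{\link{auditEstimate}}
#' @export
setClass("AuditObservation",
  representation(
    taxonGroup = "character",
    n = "integer",
    k = "integer",
    nTotal = "integer"
  )
)

setValidity("AuditObservation", function(object) {
  msg <- character()
  if (length(object@n) != 1L || is.na(object@n) || object@n < 1L)
    msg <- c(msg, "n must be a positive integer")
  if (length(object@k) != 1L || is.na(object@k) || object@k < 0L ||
      object@k > object@n)
    msg <- c(msg, "k must satisfy 0 <= k <= n")
  if (length(object@nTotal) != 1L || is.na(object@nTotal) ||
      object@nTotal < object@n)
    msg <- c(msg, "nTotal must satisfy n <= nTotal")
  if (length(msg)) msg else TRUE
})

#' AuditEstimate: prevalence estimate for one audited group
#'
#' Point ratio \code{k/n}, exact (Clopper-Pearson) confidence interval,
#' percentiles of the beta-posterior absolute count of misidentified records,
#' and predictive beta-binomial counts for prospective sample sizes.
#'
#' @slot observation The \code{AuditObservation} the estimate derives from.
#' @slot pointRatio \code{k/n}.
#' @slot conf Confidence level of the interval.
#' @slot ciLow,ciHigh Exact binomial interval bounds.
#' @slot countPercentiles Named integer vector: posterior percentiles of the
#'   number of misidentified records in the whole group.
#' @slot predictiveCounts Integer matrix, one row per prospective sample size,
#'   one column per percentile.
#' @slot draws Number of Monte-Carlo draws used.
#' @slot seed Seed used for the stochastic parts (NA if none supplied).
#'
#' @seealso \code{\link{auditEstimate}}
#' @export
setClass("AuditEstimate",
  representation(
    observation = "AuditObservation",
    pointRatio = "numeric",
    conf = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    countPercentiles = "integer",
    predictiveCounts = "matrix",
    draws = "integer",
    seed = "integer"
  )
)

setValidity("AuditEstimate", function(object) {
  msg <- character()
  if (!(object@ciLow <= object@pointRatio + 1e-12 &&
        object@pointRatio <= object@ciHigh + 1e-12 &&
        object@ciLow >= 0 && object@ciHigh <= 1))
    msg <- c(msg, "interval must satisfy 0 <= low <= k/n <= high <= 1")
  cp <- object@countPercentiles
  if (length(cp) > 1 && any(diff(cp) < 0))
    msg <- c(msg, "count percentiles must be non-decreasing")
  if (length(msg)) msg else TRUE
})
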