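# Seeded synthetic barcode databases with a ground-truth table.
#
# The generator emulates the data-generating situation a database audit
# faces: a conspecific cloud of genuine records around a species' COI
# haplotype, bacterial contaminants deposited under the same species name at
# cross-domain divergence, numt-like records carrying a frame-disrupting
# indel plus internal stop codons, and records from a second metazoan
# species deposited under the wrong name.
#
# Substitution model: i.i.d. per-site substitutions with uniform choice
# among the 3 alternative bases (Jukes-Cantor-like). A site substituted at
# rate r always differs from the root, so the expected p-distance to the
# root equals r directly — no correction needed. For two independent
# derivations at rates r1 and r2 from one root, a site differs unless both
# kept the root base or both substituted to the same alternative, giving the
# composition ("saturation") formula
#     E[d] = r1 + r2 - (4/3) r1 r2 ,
# which the generator uses when reasoning about pairwise (record-to-record)
# distances. All internals run on integer matrices (1..4 = A,C,G,T, 5 = gap)
# for speed; sequences are decoded to a DNAStringSet at the end.

# ---- integer-sequence helpers ------------------------------------------

# Codon ids of the stop codons of a genetic code, in the package's own
# enumeration id = 16*(b1-1) + 4*(b2-1) + b3 over A,C,G,T.
#' @noRd
.stopIdSet <- function(code) {
  nm <- names(code)
  m <- matrix(match(unlist(strsplit(nm, "")), .BASES), nrow = 3)
  ids <- 16L * (m[1, ] - 1L) + 4L * (m[2, ] - 1L) + m[3, ]
  ids[unname(code) == "*"]
}

# Codon ids for frame +1 of integer rows (matrix n x L), first ncod codons.
#' @noRd
.codonIdMatrix <- function(M) {
  ncod <- ncol(M) %/% 3L
  i1 <- seq(1L, 3L * ncod, by = 3L)
  16L * (M[, i1, drop = FALSE] - 1L) +
    4L * (M[, i1 + 1L, drop = FALSE] - 1L) +
    M[, i1 + 2L, drop = FALSE]
}

# Random sequence with no stop codon in frame +1 (terminal included, for
# simplicity of the guarantee).
#' @noRd
.randomOrfRoot <- function(len, stopIds) {
  x <- sample.int(4L, len, replace = TRUE)
  ncod <- len %/% 3L
  repeat {
    M <- matrix(x, nrow = 1)
    bad <- which(.codonIdMatrix(M) %in% stopIds)
    if (!length(bad)) return(x)
    for (ci in bad) x[(3L * ci - 2L):(3L * ci)] <-
        sample.int(4L, 3L, replace = TRUE)
  }
}

# Derive n records from a root at substitution rate `rate`. Returns matrix.
#' @noRd
.deriveMatrix <- function(root, n, rate) {
  L <- length(root)
  M <- matrix(root, nrow = n, ncol = L, byrow = TRUE)
  if (rate > 0 && n > 0) {
    flip <- which(matrix(runif(n * L) < rate, n, L))
    if (length(flip))
      M[flip] <- ((M[flip] - 1L + sample.int(3L, length(flip),
                                             replace = TRUE)) %% 4L) + 1L
  }
  M
}

# Resample substituted bases inside any frame-+1 stop codon until the open
# reading frame is restored. Substituted positions stay substituted (still
# differ from the root), so the expected distance to the root is unchanged.
#' @noRd
.preserveOrf <- function(M, root, stopIds, maxIter = 200L) {
  ncod <- ncol(M) %/% 3L
  rows <- seq_len(nrow(M))
  for (iter in seq_len(maxIter)) {
    cid <- .codonIdMatrix(M[rows, , drop = FALSE])
    bad <- which(matrix(cid %in% stopIds, length(rows), ncod), arr.ind = TRUE)
    if (!nrow(bad)) return(M)
    bad[, 1L] <- rows[bad[, 1L]]
    for (j in 1:3) {
      pos <- (bad[, 2L] - 1L) * 3L + j
      idx <- cbind(bad[, 1L], pos)
      flipped <- M[idx] != root[pos]
      if (any(flipped)) {
        ii <- idx[flipped, , drop = FALSE]
        M[ii] <- ((root[ii[, 2L]] - 1L +
                     sample.int(3L, nrow(ii), replace = TRUE)) %% 4L) + 1L
      }
    }
    rows <- unique(bad[, 1L])
  }
  stop("failed to restore open reading frames", call. = FALSE)
}

# Deposit gene-orientation rows in the strand/offset implied by `frame`:
# translation of the deposited sequence at `frame` recovers the gene's
# frame +1. Prepends |frame|-1 random bases (same count for every record, so
# records stay column-aligned), and reverse-complements for negative frames.
#' @noRd
.depositMatrix <- function(M, frame) {
  pre <- abs(frame) - 1L
  n <- nrow(M)
  if (pre > 0L)
    M <- cbind(matrix(sample.int(4L, n * pre, replace = TRUE), n, pre), M)
  if (frame < 0L)
    M <- (5L - M)[, rev(seq_len(ncol(M))), drop = FALSE]
  M
}

# Internal-stop count of integer vector v (no gaps) in one frame.
#' @noRd
.frameInternalStops <- function(v, f, stopIds) {
  w <- if (f > 0L) v else 5L - rev(v)
  off <- abs(f) - 1L
  ncod <- (length(w) - off) %/% 3L
  if (ncod <= 1L) return(0L)
  i1 <- off + 3L * (seq_len(ncod - 1L) - 1L) + 1L  # exclude terminal codon
  cid <- 16L * (w[i1] - 1L) + 4L * (w[i1 + 1L] - 1L) + w[i1 + 2L]
  sum(cid %in% stopIds)
}

# Inject TAA codons (a stop in all supported code tables) into any reading
# frame that still translates without an internal stop, until none does.
#' @noRd
.disruptAllFrames <- function(v, stopIds, maxIter = 30L) {
  for (iter in seq_len(maxIter)) {
    stops <- vapply(.FRAMES, .frameInternalStops, integer(1), v = v,
                    stopIds = stopIds)
    clean <- .FRAMES[stops == 0L]
    if (!length(clean)) return(v)
    f <- clean[1L]
    w <- if (f > 0L) v else 5L - rev(v)
    off <- abs(f) - 1L
    ncod <- (length(w) - off) %/% 3L
    ci <- max(2L, ncod %/% 2L)
    w[off + 3L * (ci - 1L) + 1:3] <- c(4L, 1L, 1L)  # TAA
    v <- if (f > 0L) w else 5L - rev(w)
  }
  stop("failed to disrupt all reading frames", call. = FALSE)
}

# ---- public API ---------------------------------------------------------

#' Configuration for the synthetic database generator
#'
#' Defaults mirror the audited-census situation: a ~658 bp Folmer-length
#' amplicon, a conspecific cloud at ~2\% pairwise p-distance, contaminants at
#' ~65\% from the mislabeled host species, within-bacteria spread ~15\%,
#' records deposited reverse-complemented with a one-base offset (reading
#' frame -2), and a class mix of ~0.9\% contaminants (bacterial plus
#' fungal-as-contaminant) and ~6.06\% wrong-species metazoan records.
#'
#' @param nRecords Number of database records (default 363).
#' @param pContaminant,pNumt,pOtherMetazoan Class probabilities; the
#'   remainder are genuine target records.
#' @param dWithin Expected conspecific p-distance to the species root
#'   (default 0.02).
#' @param dContaminant Expected contaminant-to-host p-distance (default
#'   0.65).
#' @param dWithinBacteria Expected within-bacteria pairwise p-distance
#'   (default 0.15).
#' @param dNumt Expected numt-to-host p-distance (default 0.1).
#' @param dOtherMetazoan Divergence of the second metazoan species' root
#'   (default 0.2).
#' @param seqLength Amplicon length in bp (default 658).
#' @param depositFrame Reading frame in which deposited records translate
#'   (default -2).
#' @param codeTable Genetic code under which target ORFs are preserved
#'   (default 5).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return A validated list of class \code{SyntheticConfig}.
#' @export
syntheticConfig <- function(nRecords = 363, pContaminant = 0.009,
                            pNumt = 0, pOtherMetazoan = 0.0606,
                            dWithin = 0.02, dContaminant = 0.65,
                            dWithinBacteria = 0.15, dNumt = 0.1,
                            dOtherMetazoan = 0.2,
                            seqLength = 658, depositFrame = -2,
                            codeTable = 5, seed = 1) {
  cfg <- list(nRecords = as.integer(nRecords),
              pContaminant = pContaminant, pNumt = pNumt,
              pOtherMetazoan = pOtherMetazoan,
              dWithin = dWithin, dContaminant = dContaminant,
              dWithinBacteria = dWithinBacteria, dNumt = dNumt,
              dOtherMetazoan = dOtherMetazoan,
              seqLength = as.integer(seqLength),
              depositFrame = as.integer(depositFrame),
              codeTable = .checkCodeTable(codeTable),
              seed = as.integer(seed))
  if (cfg$nRecords < 1L) stop("nRecords must be positive", call. = FALSE)
  ps <- c(cfg$pContaminant, cfg$pNumt, cfg$pOtherMetazoan)
  if (any(ps < 0) || sum(ps) > 1)
    stop("class probabilities must be non-negative and sum to at most 1",
         call. = FALSE)
  ds <- c(cfg$dWithin, cfg$dContaminant, cfg$dWithinBacteria, cfg$dNumt,
          cfg$dOtherMetazoan)
  if (any(ds < 0 | ds > 0.75))
    stop("infeasible distance: expected p-distances must lie in [0, 0.75]",
         call. = FALSE)
  if (!cfg$depositFrame %in% .FRAMES)
    stop("depositFrame must be one of +1,+2,+3,-1,-2,-3", call. = FALSE)
  if (cfg$seqLength < 150L)
    stop("seqLength too short for a meaningful barcode", call. = FALSE)
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Generate a labeled synthetic barcode database
#'
#' Produces a column-aligned record set (equal widths; the numt class alone
#' carries a 1 bp deletion marked by a gap character), a ground-truth table,
#' and a three-sequence reference panel (conspecific root, second-species
#' root, bacterial root) labeled for \code{\link{classifyRecords}}. All
#' records are deposited under the same species name — contaminants, numts
#' and wrong-species records are mislabeled, as in a real database — and in
#' the strand/offset implied by \code{depositFrame}. Target (and
#' second-species) roots and records keep an open reading frame in the
#' designated frame under the configured genetic code; numts are guaranteed
#' to carry an internal stop in every frame.
#'
#' @param config A \code{\link{syntheticConfig}}.
#' @return A list: \code{records} (\linkS4class{BarcodeSet}),
#'   \code{truth} (data.frame \code{accession, true_class,
#'   distance_to_root}), \code{references} (\linkS4class{BarcodeSet}),
#'   \code{config}.
#' @examples
#' db <- generateDatabase(syntheticConfig(nRecords = 50, pContaminant = 0.1,
#'                                        seed = 7))
#' table(db$truth$true_class)
#' @export
generateDatabase <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  code <- .geneticCode(config$codeTable)
  stopIds <- .stopIdSet(code)
  .withSeed(config$seed, {
    n <- config$nRecords
    L <- config$seqLength
    classes <- sample(c("target", "bacterial_contaminant", "numt",
                        "other_metazoan"), n, replace = TRUE,
                      prob = c(1 - config$pContaminant - config$pNumt -
                                 config$pOtherMetazoan,
                               config$pContaminant, config$pNumt,
                               config$pOtherMetazoan))
    root <- .randomOrfRoot(L, stopIds)
    root2 <- .preserveOrf(.deriveMatrix(root, 1L, config$dOtherMetazoan),
                          root, stopIds)[1L, ]
    rootB <- .deriveMatrix(root, 1L, config$dContaminant)[1L, ]

    M <- matrix(0L, n, L)
    idxT <- which(classes == "target")
    idxC <- which(classes == "bacterial_contaminant")
    idxN <- which(classes == "numt")
    idxO <- which(classes == "other_metazoan")
    if (length(idxT))
      M[idxT, ] <- .preserveOrf(
        .deriveMatrix(root, length(idxT), config$dWithin), root, stopIds)
    if (length(idxO))
      M[idxO, ] <- .preserveOrf(
        .deriveMatrix(root2, length(idxO), config$dWithin), root2, stopIds)
    if (length(idxC))
      M[idxC, ] <- .deriveMatrix(rootB, length(idxC),
                                 config$dWithinBacteria / 2)
    if (length(idxN))
      M[idxN, ] <- .deriveMatrix(root, length(idxN), config$dNumt)

    D <- .depositMatrix(M, config$depositFrame)
    refRows <- .depositMatrix(rbind(root, root2, rootB), config$depositFrame)

    # numts: one 1 bp deletion (gap-marked, so columns stay aligned) plus
    # engineered stops so no reading frame of the degapped sequence is clean
    for (i in idxN) {
      pos <- sample(seq.int(ncol(D) %/% 3L, 2L * (ncol(D) %/% 3L)), 1L)
      v <- .disruptAllFrames(D[i, -pos], stopIds)
      D[i, ] <- append(v, .GAP_CODE, after = pos - 1L)
    }

    seqs <- vapply(seq_len(n), function(i) .decodeSeq(D[i, ]), character(1))
    acc <- sprintf("SYN%05d", seq_len(n))
    records <- barcodeSet(seqs, accession = acc,
                          declaredTaxon = "Target species",
                          taxonGroup = "Synthetica",
                          geneLabel = "cytochrome c oxidase subunit I")

    refSeqs <- vapply(1:3, function(i) .decodeSeq(refRows[i, ]), character(1))
    references <- barcodeSet(
      refSeqs, accession = c("REF_target", "REF_othermet", "REF_bacteria"),
      declaredTaxon = c("Target species", "Other species", "Bacterium sp."),
      taxonGroup = c("metazoa", "metazoa", "bacteria"),
      geneLabel = "cytochrome c oxidase subunit I")

    # realized p-distance of every record to the deposited conspecific root
    rootDep <- refRows[1L, ]
    dist2root <- vapply(seq_len(n), function(i) {
      a <- D[i, ]; b <- rootDep
      okp <- a <= 4L & b <= 4L
      sum(a[okp] != b[okp]) / sum(okp)
    }, numeric(1))

    truth <- data.frame(accession = acc, true_class = classes,
                        distance_to_root = dist2root,
                        stringsAsFactors = FALSE)
    list(records = records, truth = truth, references = references,
         config = config)
  })
}

#' Write a synthetic database to disk
#'
#' Emits the records FASTA, the truth TSV
#' (\code{accession<TAB>true_class<TAB>distance_to_root}), the reference
#' panel FASTA with its group TSV, and a JSON echo of the configuration.
#'
#' @param db Result of \code{\link{generateDatabase}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSyntheticDb <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBarcodeFasta(db$records, file.path(dir, "records.fasta"),
                    metaPath = file.path(dir, "records_meta.tsv"))
  write.table(db$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeBarcodeFasta(db$references, file.path(dir, "references.fasta"))
  refGroups <- data.frame(accession = accessions(db$references),
                          taxon_group = taxonGroup(db$references),
                          gene_label = geneLabels(db$references),
                          declared_taxon = declaredTaxon(db$references),
                          stringsAsFactors = FALSE)
  write.table(refGroups, file.path(dir, "reference_groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- unclass(db$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Draw an audit sample from a (synthetic) database
#'
#' Samples \code{nSample} records uniformly without replacement and counts
#' how many are misidentified — by ground truth (\code{mode = "truth"}) or by
#' the screening pipeline's verdicts (\code{mode = "blind"}).
#'
#' @param records A \linkS4class{BarcodeSet}.
#' @param truth Truth table from \code{\link{generateDatabase}} (used in
#'   truth mode).
#' @param nSample Sample size, at most the number of records.
#' @param seed Optional integer seed.
#' @param mode \code{"truth"} or \code{"blind"}.
#' @param verdicts Classification data.frame from
#'   \code{\link{classifyRecords}} (required in blind mode).
#' @param taxonGroup Group label for the resulting observation.
#' @return An \linkS4class{AuditObservation} with \code{nTotal} equal to the
#'   database size.
#' @export
sampleAudit <- function(records, truth = NULL, nSample, seed = NULL,
                        mode = c("truth", "blind"), verdicts = NULL,
                        taxonGroup = "Synthetica") {
  mode <- match.arg(mode)
  n <- length(records)
  nSample <- as.integer(nSample)
  if (nSample > n)
    stop("nSample exceeds the number of records", call. = FALSE)
  picked <- .withSeed(seed, sample(accessions(records), nSample))
  if (mode == "truth") {
    if (is.null(truth)) stop("truth table required in truth mode",
                             call. = FALSE)
    cls <- truth$true_class[match(picked, truth$accession)]
  } else {
    if (is.null(verdicts)) stop("verdicts required in blind mode",
                                call. = FALSE)
    cls <- verdicts$verdict[match(picked, verdicts$accession)]
  }
  if (anyNA(cls)) stop("sampled accession missing from the label table",
                       call. = FALSE)
  auditObservation(taxonGroup, n = nSample, k = sum(cls != "target"),
                   nTotal = n)
}
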