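# Six-frame translation integrity screen: numts and other pseudogene-like
# records betray themselves through frame-disrupting indels and internal
# stop codons. A genuine mitochondrial COI fragment translates cleanly in
# (at least) one of the six frames under the appropriate mitochondrial code.

.FRAMES <- c(1L, 2L, 3L, -1L, -2L, -3L)

# Reverse complement on a plain character string (IUPAC-aware).
#' @noRd
.revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Translate one reading frame
#'
#' Gaps are stripped before translation (they are recorded separately by
#' \code{\link{scanFrames}}). Frames +1/+2/+3 start at offsets 0/1/2 of the
#' sequence; frames -1/-2/-3 at offsets 0/1/2 of its reverse complement.
#' The trailing partial codon is ignored. Any codon containing an ambiguity
#' code translates to \code{'X'} — never to \code{'*'} — so ambiguous bases
#' cannot fabricate stop codons. A stop codon in the final translated
#' position is terminal, not internal: barcode amplicons may legitimately
#' end at a stop.
#'
#' @param sequence Nucleotide string (IUPAC; gaps allowed, stripped here).
#' @param frame Integer in \code{c(1, 2, 3, -1, -2, -3)}.
#' @param codeTable NCBI genetic code id; one of 1, 2, 4, 5, 11. Default 5
#'   (invertebrate mitochondrial), the code under which metazoan COI barcodes
#'   are screened.
#' @return A list of class \code{FrameReport}: \code{frame}, \code{protein}
#'   (amino acids, \code{X} for ambiguous codons, \code{*} for stops),
#'   \code{internal_stop_count}, \code{terminal_stop}.
#' @examples
#' translateFrame("ATGTGATAA", 1, codeTable = 5)  # TGA = Trp in table 5
#' translateFrame("ATGTGATAA", 1, codeTable = 1)  # TGA = stop in table 1
#' @export
translateFrame <- function(sequence, frame, codeTable = 5) {
  frame <- as.integer(frame)
  if (length(frame) != 1L || !frame %in% .FRAMES)
    stop("frame must be one of +1,+2,+3,-1,-2,-3", call. = FALSE)
  code <- .geneticCode(codeTable)
  s <- gsub("-", "", .normalizeSeq(as.character(sequence)), fixed = TRUE)
  if (frame < 0) s <- .revComp(s)
  offset <- abs(frame) - 1L
  nc <- (nchar(s) - offset) %/% 3L
  if (nc <= 0L) {
    protein <- ""
  } else {
    starts <- offset + 3L * (seq_len(nc) - 1L) + 1L
    codons <- substring(s, starts, starts + 2L)
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    protein <- paste(aa, collapse = "")
  }
  n <- nchar(protein)
  chars <- if (n) strsplit(protein, "")[[1]] else character()
  terminal <- n > 0 && chars[n] == "*"
  internal <- if (n > 1) sum(chars[-n] == "*") else 0L
  structure(
    list(frame = frame, protein = protein,
         internal_stop_count = as.integer(internal),
         terminal_stop = terminal),
    class = "FrameReport")
}

#' Scan all six reading frames of one record
#'
#' Translates the record in all six frames, picks the best frame (fewest
#' internal stops, ties broken in the order +1, +2, +3, -1, -2, -3) and
#' summarizes the integrity signals the numt screen uses: gaps in the raw
#' sequence, and whether any frame translates without internal stops.
#'
#' @param x Nucleotide string, a \code{DNAString}, or a single-record
#'   \linkS4class{BarcodeSet}.
#' @param codeTable NCBI genetic code id (default 5).
#' @return A list with \code{flags} (list of class \code{IntegrityFlags}:
#'   \code{best_frame}, \code{internal_stops_best}, \code{clean},
#'   \code{has_gaps}, \code{has_non_triplet_indel_signal},
#'   \code{low_information}) and \code{reports} (the six
#'   \code{FrameReport}s, named by frame).
#' @examples
#' scanFrames("ATGTGATAA")$flags$clean
#' @export
scanFrames <- function(x, codeTable = 5) {
  if (is(x, "BarcodeSet")) {
    stopifnot(length(x) == 1L)
    x <- as.character(sequences(x))
  }
  s <- as.character(x)
  if (!nzchar(s)) stop("sequence must be non-empty", call. = FALSE)
  reports <- lapply(.FRAMES, function(f) translateFrame(s, f, codeTable))
  names(reports) <- as.character(.FRAMES)
  stops <- vapply(reports, `[[`, integer(1), "internal_stop_count")
  best <- which.min(stops)  # first minimum = tie-break order +1,+2,+3,-1,-2,-3
  clean <- stops[best] == 0L
  bestProt <- reports[[best]]$protein
  lowInfo <- !grepl("[^X*]", bestProt)
  flags <- structure(
    list(best_frame = .FRAMES[best],
         internal_stops_best = as.integer(stops[best]),
         clean = clean,
         has_gaps = grepl("-", s, fixed = TRUE),
         has_non_triplet_indel_signal = !clean,
         low_information = lowInfo),
    class = "IntegrityFlags")
  list(flags = flags, reports = reports)
}

#' Frame-screen every record of a BarcodeSet
#'
#' @param x A \linkS4class{BarcodeSet}.
#' @param codeTable NCBI genetic code id (default 5).
#' @return A data.frame with one row per record: \code{accession},
#'   \code{best_frame}, \code{internal_stops_best}, \code{has_gaps},
#'   \code{clean}, \code{low_information}.
#' @seealso \code{\link{scanFrames}} for the per-record detail.
#' @export
screenFrames <- function(x, codeTable = 5) {
  stopifnot(is(x, "BarcodeSet"))
  seqs <- as.character(sequences(x))
  rows <- lapply(seq_along(seqs), function(i) {
    fl <- scanFrames(seqs[i], codeTable)$flags
    data.frame(accession = accessions(x)[i],
               best_frame = fl$best_frame,
               internal_stops_best = fl$internal_stops_best,
               has_gaps = fl$has_gaps,
               clean = fl$clean,
               low_information = fl$low_information,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.FrameReport <- function(x, ...) {
  cat(sprintf("FrameReport frame %+d: %d internal stop(s)%s\n  %s\n",
              x$frame, x$internal_stop_count,
              if (x$terminal_stop) ", terminal stop" else "",
              x$protein))
  invisible(x)
}

#' @export
print.IntegrityFlags <- function(x, ...) {
  cat(sprintf(
    "IntegrityFlags: best frame %+d (%d internal stops), clean=%s, gaps=%s\n",
    x$best_frame, x$internal_stops_best, x$clean, x$has_gaps))
  invisible(x)
}
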