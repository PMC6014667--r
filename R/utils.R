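# Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")
.GAP_CODE <- 5L
.BASES_GAP <- c(.BASES, "-")

# IUPAC nucleotide codes accepted in records (plus gap).
.IUPAC <- c("A","C","G","T","U","R","Y","S","W","K","M","B","D","H","V","N","-")

.SUPPORTED_TABLES <- c(1L, 2L, 4L, 5L, 11L)

#' @noRd
.checkCodeTable <- function(codeTable) {
  codeTable <- as.integer(codeTable)
  if (length(codeTable) != 1L || is.na(codeTable) ||
      !codeTable %in% .SUPPORTED_TABLES)
    stop("unsupported genetic code table; supported: ",
         paste(.SUPPORTED_TABLES, collapse = ", "), call. = FALSE)
  codeTable
}

#' @noRd
.geneticCode <- function(codeTable) {
  codeTable <- .checkCodeTable(codeTable)
  Biostrings::getGeneticCode(as.character(codeTable))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
#' @noRd
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv),
      add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-operation substream from one top-level seed.
# Kept below 2^31 - 1 so it is a valid R integer seed.
#' @noRd
.deriveSeed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((abs(as.numeric(seed)) * 7919 + stream * 104729) %% 2147483646) + 1L
}

# Uppercase, map RNA U to the internal DNA alphabet.
#' @noRd
.normalizeSeq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' @noRd
.checkAlphabet <- function(x, what = "sequence") {
  ch <- unique(strsplit(paste(.normalizeSeq(x), collapse = ""), "")[[1]])
  bad <- setdiff(ch, .IUPAC)
  if (length(bad))
    stop(what, " contains non-IUPAC characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# Character string -> integer codes 1..4 (A,C,G,T), NA for anything else.
#' @noRd
.encodeSeq <- function(x) {
  match(strsplit(.normalizeSeq(x), "")[[1]], .BASES)
}

#' @noRd
.decodeSeq <- function(v) {
  paste(.BASES_GAP[v], collapse = "")
}

#' @noRd
.isoTime <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
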