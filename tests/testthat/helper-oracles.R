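# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately written with naive, per-element logic so they do
# not share code paths with the package implementation.

randomDnaString <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Reverse complement written from scratch (no Biostrings).
revCompOracle <- function(s) {
  comp <- chartr("ACGTacgt", "TGCAtgca", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# Brute-force per-column p-distance: walk the columns one by one.
pDistanceOracle <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(ca) == length(cb))
  used <- 0L; diff <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] %in% c("A", "C", "G", "T") && cb[i] %in% c("A", "C", "G", "T")) {
      used <- used + 1L
      if (ca[i] != cb[i]) diff <- diff + 1L
    }
  }
  list(distance = if (used) diff / used else NA_real_, sites = used)
}

# Mutate a sequence at an exact number of uniformly chosen sites (always to
# a different base), so the realized p-distance is known by construction.
mutateExactly <- function(s, nSites) {
  ch <- strsplit(s, "")[[1]]
  idx <- sample(seq_along(ch), nSites)
  for (i in idx) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

# Two-group aligned toy set: nA sequences around rootA, nB around rootB.
makeTwoGroupSet <- function(nA, nB, len = 658, withinFlips = 6,
                            betweenFlips = round(0.65 * len)) {
  rootA <- randomDnaString(len)
  rootB <- mutateExactly(rootA, betweenFlips)
  seqs <- c(vapply(seq_len(nA), function(i) mutateExactly(rootA, withinFlips),
                   character(1)),
            vapply(seq_len(nB), function(i) mutateExactly(rootB, withinFlips),
                   character(1)))
  acc <- sprintf("S%03d", seq_len(nA + nB))
  groups <- c(rep("metazoa", nA), rep("bacteria", nB))
  list(set = barcodeSet(seqs, accession = acc, taxonGroup = groups),
       groups = stats::setNames(groups, acc))
}
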