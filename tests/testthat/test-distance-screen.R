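test_that("p-distance handles identity, gaps and insufficient overlap", {
  expect_equal(pDistance("ACGTACGT", "ACGTACGT", minSites = 1)$distance, 0)
  # gap column dropped: 6 comparable sites, 1 difference
  r <- pDistance("ACGT-CA", "ACGAACA", minSites = 1)
  expect_equal(r$comparableSites, 6L)
  expect_equal(r$distance, 1 / 6)
  expect_error(pDistance("ACGT", "ACG", minSites = 1), "unequal")
  expect_error(pDistance("ACGT", "ACGT", minSites = 100), "insufficient")
})

test_that("p-distance matches the brute-force per-column oracle", {
  set.seed(301)
  alpha <- c("A", "C", "G", "T", "A", "C", "G", "T", "N", "-", "R", "Y")
  for (i in 1:500) {
    n <- sample(40:120, 1)
    a <- randomDnaString(n, alphabet = alpha)
    b <- randomDnaString(n, alphabet = alpha)
    want <- pDistanceOracle(a, b)
    if (want$sites >= 10) {
      got <- pDistance(a, b, minSites = 10)
      expect_equal(got$distance, want$distance)
      expect_equal(got$comparableSites, want$sites)
    } else {
      expect_error(pDistance(a, b, minSites = 10), "insufficient")
    }
  }
})

test_that("adding a gap column never changes the distance on the rest", {
  set.seed(302)
  for (i in 1:50) {
    a <- randomDnaString(200)
    b <- mutateExactly(a, 30)
    base <- pDistance(a, b, minSites = 10)
    # insert a gap/ambiguity column: excluded pairwise, so neither the
    # comparable count nor the distance over the remaining columns changes
    pos <- sample(200, 1)
    ag <- paste0(substr(a, 1, pos - 1), "-", substr(a, pos, 200))
    bg <- paste0(substr(b, 1, pos - 1), "N", substr(b, pos, 200))
    d1 <- pDistance(ag, bg, minSites = 10)
    expect_identical(d1$comparableSites, base$comparableSites)
    expect_equal(d1$distance, base$distance)
    # masking an existing column drops exactly one comparable site
    ag2 <- a; substr(ag2, pos, pos) <- "-"
    d2 <- pDistance(ag2, b, minSites = 10)
    expect_identical(d2$comparableSites, base$comparableSites - 1L)
    expect_equal(d2$distance, pDistanceOracle(ag2, b)$distance)
  }
})

test_that("distance matrix is symmetric, zero-diagonal and bounded", {
  tg <- makeTwoGroupSet(6, 4, len = 300)
  dm <- pDistanceMatrix(tg$set)
  v <- distanceValues(dm)
  expect_identical(v, t(v))
  expect_true(all(diag(v) == 0))
  expect_true(all(v >= 0 & v <= 1))
  expect_identical(labels(dm), accessions(tg$set))
})

test_that("group summaries recover engineered within/between distances", {
  set.seed(303)
  tg <- makeTwoGroupSet(8, 6, len = 658, withinFlips = 13,
                        betweenFlips = round(0.65 * 658))
  dm <- pDistanceMatrix(tg$set)
  gs <- groupDistanceSummary(dm, tg$groups)
  expect_equal(gs$between$mean, 0.65, tolerance = 0.05)
  expect_lt(max(gs$within$max), 0.10)
  # one group duplicated as two labels: between-group mean equals the pooled
  # within-group mean
  g2 <- tg$groups
  half <- accessions(tg$set)[1:8]
  g2[half] <- rep(c("x", "y"), 4)
  dmA <- pDistanceMatrix(tg$set[1:8])
  vs <- distanceValues(dmA)
  gsA <- groupDistanceSummary(dmA, g2[half])
  pooledWithin <- mean(c(vs[g2[half] == "x", g2[half] == "x"][upper.tri(diag(4))],
                         vs[g2[half] == "y", g2[half] == "y"][upper.tri(diag(4))]))
  # identical generating distribution: between mean within sampling noise of
  # pooled within mean
  expect_equal(gsA$between$mean, pooledWithin, tolerance = 0.02)
  expect_error(groupDistanceSummary(dm, rep("one", 14)), "2 groups")
})

test_that("classifier reproduces the generator truth with default thresholds", {
  db <- generateDatabase(syntheticConfig(nRecords = 150, pContaminant = 0.1,
                                         pNumt = 0.06, pOtherMetazoan = 0.1,
                                         seed = 21))
  v <- classifyRecords(db$records, db$references)
  expect_identical(nrow(v), 150L)
  # verdicts partition the set: exactly one per record
  expect_identical(sort(v$accession), sort(db$truth$accession))
  truth <- db$truth$true_class[match(v$accession, db$truth$accession)]
  expect_identical(v$verdict[truth == "target"],
                   rep("target", sum(truth == "target")))
  expect_identical(v$verdict[truth == "bacterial_contaminant"],
                   rep("bacterial_contaminant",
                       sum(truth == "bacterial_contaminant")))
  expect_identical(v$verdict[truth == "numt"],
                   rep("numt_suspect", sum(truth == "numt")))
  expect_identical(v$verdict[truth == "other_metazoan"],
                   rep("other_metazoan", sum(truth == "other_metazoan")))
  expect_true(all(nzchar(v$rule_trace)))
  # determinism
  v2 <- classifyRecords(db$records, db$references)
  expect_identical(v, v2)
  # precision and recall of bacterial_contaminant are 1 under generator
  # separation
  expect_identical(sum(v$verdict == "bacterial_contaminant"),
                   sum(truth == "bacterial_contaminant"))
})

test_that("verdicts respect the conspecific threshold invariant", {
  db <- generateDatabase(syntheticConfig(nRecords = 80, pContaminant = 0.15,
                                         pOtherMetazoan = 0.15, seed = 22))
  v <- classifyRecords(db$records, db$references)
  flagged <- v$verdict == "target"
  expect_true(all(v$d_conspecific[flagged] <= 0.05))
  expect_true(all(v$d_conspecific[!flagged] > 0.05))
})

test_that("missing conspecific reference skips R1 and is traced", {
  db <- generateDatabase(syntheticConfig(nRecords = 20, seed = 23))
  refs <- db$references
  refs@meta$declared_taxon <- c("Foreign species", "Other species",
                                "Bacterium sp.")
  v <- classifyRecords(db$records, refs)
  expect_true(all(grepl("R1:skipped_no_conspecific", v$rule_trace)))
  expect_false(any(v$verdict == "target"))
})

test_that("bipartition check separates metazoa from bacteria", {
  set.seed(304)
  tg <- makeTwoGroupSet(10, 5, len = 658, withinFlips = 13)
  dm <- pDistanceMatrix(tg$set)
  bc <- bipartitionCheck(dm, tg$groups)
  expect_equal(bc$purity, 1.0)
  expect_false(bc$tie)
  # brute-force search over all 2-partitions: the minimum within-cluster
  # distance sum must be achieved by the true grouping
  v <- distanceValues(dm)
  n <- nrow(v)
  best <- NULL; bestScore <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    side <- c(TRUE, as.logical(bitwAnd(mask, 2^(0:(n - 2)))))
    if (all(side) || !any(side)) next
    score <- sum(v[side, side]) + sum(v[!side, !side])
    if (score < bestScore) { bestScore <- score; best <- side }
  }
  expect_identical(unname(split(seq_len(n), best)),
                   unname(split(seq_len(n), bc$clusters == bc$clusters[1])))
})

test_that("bipartition edge cases: identical pairs and homogeneous clouds", {
  s1 <- randomDnaString(200); s2 <- mutateExactly(s1, 100)
  quad <- barcodeSet(c(a = s1, b = s1, c = s2, d = s2))
  bc <- bipartitionCheck(pDistanceMatrix(quad),
                         c(a = "g1", b = "g1", c = "g2", d = "g2"))
  expect_equal(bc$purity, 1.0)
  # random labels on one homogeneous cloud: purity ~ max label frequency
  set.seed(305)
  cloud <- barcodeSet(vapply(1:20, function(i) mutateExactly(s1, 8),
                             character(1)),
                      accession = sprintf("c%02d", 1:20))
  glab <- sample(c("u", "v"), 20, replace = TRUE, prob = c(0.7, 0.3))
  bc2 <- bipartitionCheck(pDistanceMatrix(cloud),
                          stats::setNames(glab, accessions(cloud)))
  expect_gte(bc2$purity, max(table(glab)) / 20 - 0.15)
  expect_lte(bc2$purity, 1.0)
})

test_that("pairwise alignment distance recovers engineered divergence", {
  set.seed(306)
  root <- randomDnaString(658)
  # ragged, unaligned analogue of a contaminant pair at 62% divergence
  contam <- mutateExactly(root, round(0.62 * 658))
  a <- substr(root, 5, 650)
  b <- substr(contam, 1, 658)
  r <- pairwisePDistance(a, b)
  expect_equal(r$distance, 0.62, tolerance = 0.03)
  # and a conspecific pair at ~2%
  near <- mutateExactly(root, 13)
  expect_equal(pairwisePDistance(substr(root, 3, 658), near)$distance,
               13 / 658, tolerance = 0.01)
})

test_that("PHYLIP and Newick exports are readable round-trips", {
  tg <- makeTwoGroupSet(4, 3, len = 250)
  dm <- pDistanceMatrix(tg$set)
  f <- withr::local_tempfile(fileext = ".phylip")
  writePhylip(dm, f)
  lines <- readLines(f)
  expect_equal(as.integer(trimws(lines[1])), 7L)
  expect_length(lines, 8L)
  tr <- upgmaTree(dm)
  expect_s3_class(tr, "phylo")
  nf <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, nf)
  back <- ape::read.tree(nf)
  expect_setequal(back$tip.label, accessions(tg$set))
})
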