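test_that("generation is deterministic given the seed", {
  cfg <- syntheticConfig(nRecords = 100, pContaminant = 0.1, seed = 7)
  a <- generateDatabase(cfg)
  b <- generateDatabase(cfg)
  expect_identical(as.character(sequences(a$records)),
                   as.character(sequences(b$records)))
  expect_identical(a$truth, b$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSyntheticDb(a, d1); writeSyntheticDb(b, d2)
  expect_identical(readLines(file.path(d1, "records.fasta")),
                   readLines(file.path(d2, "records.fasta")))
  expect_identical(readLines(file.path(d1, "truth.tsv")),
                   readLines(file.path(d2, "truth.tsv")))
})

test_that("realized distances match the configured expectations", {
  cfg <- syntheticConfig(nRecords = 50, pContaminant = 0, pNumt = 0,
                         pOtherMetazoan = 0, dWithin = 0.02, seed = 31)
  db <- generateDatabase(cfg)
  d <- db$truth$distance_to_root
  # mean target-vs-root distance within 3 binomial standard errors of 0.02
  se <- sqrt(0.02 * 0.98 / 658) / sqrt(50)
  expect_lt(abs(mean(d) - 0.02), 3 * se)
  # contaminants land at the configured cross-domain distance
  dbc <- generateDatabase(syntheticConfig(nRecords = 60, pContaminant = 0.5,
                                          seed = 32))
  contam <- dbc$truth$true_class == "bacterial_contaminant"
  # 0.65 root offset composed with the 0.075 within-bacteria derivation:
  # 0.65 + 0.075 - 4/3 * 0.65 * 0.075 = 0.66
  expect_equal(mean(dbc$truth$distance_to_root[contam]), 0.66,
               tolerance = 0.03)
})

test_that("pairwise distances follow the substitution composition formula", {
  set.seed(33)
  comp <- function(r1, r2) r1 + r2 - 4 / 3 * r1 * r2
  cfg <- syntheticConfig(nRecords = 40, dWithin = 0.05, seed = 34)
  db <- generateDatabase(cfg)
  dm <- pDistanceMatrix(db$records)
  off <- distanceValues(dm)[upper.tri(diag(40))]
  want <- comp(0.05, 0.05)
  se <- sqrt(want * (1 - want) / 658)
  expect_lt(abs(mean(off) - want), 3 * se)
})

test_that("gaps occur only in numt records", {
  db <- generateDatabase(syntheticConfig(nRecords = 120, pContaminant = 0.1,
                                         pNumt = 0.1, pOtherMetazoan = 0.1,
                                         seed = 35))
  hasGap <- grepl("-", as.character(sequences(db$records)), fixed = TRUE)
  expect_identical(unname(hasGap),
                   db$truth$true_class == "numt")
})

test_that("class frequencies sit within binomial error of the configuration", {
  db <- generateDatabase(syntheticConfig(nRecords = 2000, pContaminant = 0.05,
                                         pNumt = 0.02, pOtherMetazoan = 0.1,
                                         seed = 36))
  tab <- table(factor(db$truth$true_class,
                      c("target", "bacterial_contaminant", "numt",
                        "other_metazoan")))
  for (cl in c("bacterial_contaminant", "numt", "other_metazoan")) {
    p <- c(bacterial_contaminant = 0.05, numt = 0.02,
           other_metazoan = 0.1)[[cl]]
    se <- sqrt(p * (1 - p) * 2000)
    expect_lt(abs(tab[[cl]] - 2000 * p), 4 * se)
  }
})

test_that("census sampling returns the exact non-target count", {
  db <- generateDatabase(syntheticConfig(nRecords = 80, pContaminant = 0.2,
                                         pOtherMetazoan = 0.1, seed = 37))
  obs <- sampleAudit(db$records, db$truth, nSample = 80, seed = 1)
  expect_identical(obs@k, sum(db$truth$true_class != "target"))
  expect_identical(obs@nTotal, 80L)
  expect_error(sampleAudit(db$records, db$truth, nSample = 81), "exceeds")
})

test_that("audit samples are unbiased for the configured prevalence", {
  # replicate databases at p_true = 0.05, sample 300 of 2000 without
  # replacement; mean k/n must sit within 3 standard errors of p_true
  reps <- 40
  ks <- vapply(seq_len(reps), function(s) {
    db <- generateDatabase(syntheticConfig(
      nRecords = 2000, pContaminant = 0.02, pNumt = 0.01,
      pOtherMetazoan = 0.02, seed = 5000 + s))
    sampleAudit(db$records, db$truth, nSample = 300, seed = 6000 + s)@k
  }, integer(1))
  pHat <- mean(ks) / 300
  se <- sqrt(0.05 * 0.95 / (300 * reps))
  expect_lt(abs(pHat - 0.05), 3 * se)
})

test_that("blind-mode sampling equals truth mode when the classifier is exact", {
  db <- generateDatabase(syntheticConfig(nRecords = 150, pContaminant = 0.08,
                                         pNumt = 0.05, pOtherMetazoan = 0.08,
                                         seed = 38))
  v <- classifyRecords(db$records, db$references)
  truthObs <- sampleAudit(db$records, db$truth, nSample = 100, seed = 99)
  blindObs <- sampleAudit(db$records, nSample = 100, seed = 99,
                          mode = "blind", verdicts = v)
  expect_identical(truthObs@k, blindObs@k)
})

test_that("infeasible configurations are rejected", {
  expect_error(syntheticConfig(dContaminant = 0.8), "infeasible")
  expect_error(syntheticConfig(pContaminant = 0.7, pOtherMetazoan = 0.5),
               "at most 1")
  expect_error(syntheticConfig(nRecords = 0), "positive")
  expect_error(syntheticConfig(depositFrame = 4), "depositFrame")
})
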