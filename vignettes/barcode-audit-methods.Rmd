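---
title: "Auditing COI barcode databases: methods and design choices"
author: "barcodeAudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing COI barcode databases: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeAudit)
```

## The problem

The ~658 bp Folmer fragment of mitochondrial cytochrome c oxidase subunit I
(COI) is the standard DNA barcode for animals. The "universal" primer pair
used to amplify it binds bacterial templates well — in some taxa better than
the intended metazoan template — and also co-amplifies nuclear copies of the
mitochondrial gene (numts). When such amplicons are sequenced and deposited
without scrutiny, public databases accumulate records that carry a metazoan
species name but a bacterial, fungal, numt or wrong-species sequence. Every
downstream identification that matches against those records inherits the
error.

`barcodeAudit` addresses two questions a curator or barcoding practitioner
asks:

1. **Is this record what its label claims?** Answered per record by a
   translation-integrity screen plus distance-based classification against a
   small labeled reference panel.
2. **How many records like it does the database hold?** Answered at the
   group level by a binomial sampling design: sample `n` records, find `k`
   misidentified, and propagate the uncertainty into ratios and absolute
   counts.

## Record screening

### Translation integrity

A genuine mitochondrial COI fragment translates without internal stop
codons in at least one of the six reading frames under the appropriate
mitochondrial genetic code. Numts accumulate frame-disrupting indels and
internal stops. `scanFrames()` translates all six frames and reports the
best frame (fewest internal stops), with these conventions:

* **Default code: NCBI translation table 5** (invertebrate mitochondrial);
  tables 1, 2, 4 and 11 are selectable. Bacterial contaminants are *not*
  detected by code choice — a protein-coding bacterial fragment often
  translates cleanly — but by distance (below).
* **Reverse frames −1/−2/−3 start at offsets 0/1/2 of the reverse
  complement.** Translation tools have used more than one historical
  numbering for reverse frames; this package pins one convention and the
  test suite pins it down. A record deposited reverse-complemented with a
  one-base offset therefore reports best frame −2.
* **A terminal stop codon is not internal.** An amplicon may legitimately
  end at a stop; only stops before the final translated position count
  against a record.
* **Ambiguity codes translate to `X`, never `*`** — even when the ambiguous
  codon could only encode stops. Stop calling is deliberately conservative:
  an `N`-rich record is flagged `low_information`, not corrupted.
* **Gaps are stripped before translation** but recorded as `has_gaps`,
  because alignment gaps in a deposited barcode are themselves a numt
  signal, independent of the stop-codon evidence.

### p-distance classification

Distances are Nei–Kumar p-distances: the proportion of differing sites
among sites where both sequences carry an unambiguous A/C/G/T. Columns with
a gap or ambiguity code in either sequence are excluded pair by pair
(**pairwise deletion**, the common default for barcode data, which also
tolerates ragged amplicon ends). A distance is only reported when at least
`minSites = 100` comparable positions remain — about one seventh of the
amplicon — which guards against spurious distances on tiny overlaps.

The empirical anchors for classification are: conspecific records differ by
about 2%; records of congeneric/confamilial metazoans by a few to ~20%; and
a bacterial sequence mislabeled as its metazoan "host" differs from the
host's genuine sequence by about 62–68%. Two thresholds, both exposed as
arguments, separate these regimes:

* `tauSpecies = 0.05` — generously above the ~2% conspecific expectation,
  below typical congeneric divergence.
* `tauContam = 0.30` — between the within-bacteria spread (~2–27%) and the
  cross-domain distances (~62–68%).

`classifyRecords()` applies fixed-order rules R1–R5 (conspecific → numt
suspect → bacterial contaminant → other metazoan → unresolved); each verdict
records the rule trace, and the rules partition the record set — exactly one
verdict per record, deterministically. Rule R2 (numt) fires only *below*
`tauContam`: a numt is a corrupted copy of the host's own gene and stays in
the metazoan distance range, whereas a clean-translating sequence at
cross-domain distance from every metazoan reference is a contaminant.

### Pairwise alignment for unaligned pairs

Multi-record sets are expected pre-aligned (any standard aligner). For the
occasional two-record comparison, `pairwisePDistance()` aligns the pair end
to end with deliberately gap-averse scoring (match +5, mismatch −4, gap
opening 100, gap extension 2). The scoring matters more than usual here:
at ~60% divergence a score-maximizing aligner with permissive gap penalties
fabricates gap pairings that convert mismatches into matches and deflates
the distance (we observed 0.62 collapse to 0.44 under unit match/mismatch
scores with light gaps, and free end gaps collapse the alignment to a
near-empty overlap). With the pinned scoring, substitution-only pairs align
gapless across the divergence range of interest while a genuine 1 bp indel
is still resolved.

### Domain bipartition check

As a desk-scale surrogate for the domain-level split a phylogeny of mixed
metazoan/bacterial records shows, `bipartitionCheck()` cuts a UPGMA tree
into two clusters and scores label purity. UPGMA is used because it is
deterministic and adequate for a two-cluster question at cross-domain
separation; it is *not* a claim of reproducing a maximum-likelihood
topology, and no model selection or bootstrap is attempted.

## Prevalence estimation

All estimation starts from an `AuditObservation` `(n, k, N_total)`.

* **Detection probability.** `P(X > 0) = 1 − (1 − p)^n` is the chance a
  sample of `n` records contains at least one misidentified record at
  population ratio `p`. Inverting at `P = 0.95`, `p = 0.01` gives
  `n = 299` (exact ceiling) or 300 when rounded to the next hundred —
  `requiredSampleSize()` offers both roundings because audit plans are
  quoted in round numbers.
* **Exact interval.** `exactBinomialCI()` is the Clopper–Pearson
  construction from beta quantiles, with the lower bound exactly 0 at
  `k = 0`. For `k = 1, n = 300` the lower bound is ≈ 1e−4; published
  audit summaries sometimes quote a larger lower bound for this case, but
  the standard construction is implemented as is.
* **Posterior counts.** Under a uniform prior the binomial proportion has
  posterior `Beta(k+1, n−k+1)`. `posteriorCountPercentiles()` draws 10,000
  probabilities, scales each by `N_total`, and reports percentiles —
  absolute numbers of suspect records, the quantity a curator budgets
  against. For `k = 0` the posterior quantile has the closed form
  `1 − (1−q)^{1/(n+1)}`, which the tests use as an oracle.
* **Predictive counts.** `predictiveSampleCounts()` compounds the same
  posterior draws through `Binomial(s, p)` for prospective sample sizes
  `s`, answering "how many errors would a new sample of size `s` contain".

Numerical conventions: percentiles use linear interpolation between order
statistics (R's default quantile type 7); posterior and predictive counts
are rounded to integers because they are counts of records; one top-level
seed drives each stochastic operation through deterministically derived
substreams, so a pipeline run is bit-reproducible while the two Monte-Carlo
stages remain independent.

## The synthetic database generator

Real misidentified records cannot ship with a package, so every stage is
exercised against `generateDatabase()`, which emulates the statistical
structure the screen relies on:

* a conspecific cloud at expected p-distance `dWithin = 0.02` from a root
  haplotype with a guaranteed open reading frame;
* bacterial contaminants: a bacterial root at `dContaminant = 0.65` from
  the target root, with records spread at `dWithinBacteria = 0.15`
  pairwise, all deposited under the *target* species name;
* numt-like records at `dNumt = 0.1` carrying one 1 bp deletion (marked by
  a gap so columns stay aligned) plus engineered stop codons guaranteeing
  no clean reading frame;
* wrong-species metazoan records from a second root at
  `dOtherMetazoan = 0.2`;
* all records deposited reverse-complemented with a one-base offset
  (`depositFrame = -2`), amplicon length 658 bp.

The default class mix (0.9% contaminant, 6.06% other-metazoan, database
size 363) mirrors the census composition of a small, fully auditable group;
every parameter is configurable. Substitutions are i.i.d. per site with
uniform choice among the three alternative bases; a site substituted at
rate `r` always differs from the root, so the expected root distance equals
`r` exactly, and two independent derivations at rates `r1`, `r2` sit at
`r1 + r2 − (4/3) r1 r2` — the saturation-corrected composition the tests
verify. ORF preservation resamples substitutions that would create an
in-frame stop; the resampled site remains substituted, leaving expected
distances unchanged.

**What passing tests do and do not show.** The generator produces
substitution-only divergence with sharply separated classes; real databases
add alignment uncertainty, chimeras, heteroplasmy, codon-usage structure,
numts *without* stops or indels (which this screen, like any
integrity-based screen, cannot flag), and contaminants of intermediate
divergence. Perfect classifier precision/recall on synthetic data therefore
validates the rule logic and thresholds under the stated separation — not a
claim about error-free screening of arbitrary real data.

## Reproducibility and problem sizes

The test suite regenerates all fixtures from code under fixed seeds. The
heavier statistical checks run at these sizes, chosen to make Monte-Carlo
error small relative to the tolerances while keeping a full test run in the
low minutes: 10,000 simulated experiments for interval coverage; 10,000
draws for posterior/predictive checks (the same number used for the
published quantities); 500 random pairs against the brute-force p-distance
oracle; 200 replicate synthetic databases of 2,000 records (300 sampled
each) for end-to-end coverage of the true prevalence.

## Known limitations

* Alignment is an input for multi-record sets; the built-in aligner is for
  pairs only, and no attempt is made to reproduce any particular aligner's
  output.
* Database query strings are constructed but never executed; how many
  records a live query returns, and BLAST identities of particular
  accessions, depend on the live databases and are out of scope.
* Numts lacking stops and indels pass the integrity screen and, if close
  to the conspecific cloud, classify as targets.
* The bipartition check is a clustering property, not phylogenetics; no
  ML tree, model selection or bootstrap support is computed.
* Estimation treats the sample as binomial; sampling 300 from a finite
  group is hypergeometric, which makes the intervals slightly
  conservative — the direction of error a curator prefers.
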