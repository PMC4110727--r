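---
title: "Evaluating error correction on heterozygous readsets"
author: "HetErrEval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating error correction on heterozygous readsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HetErrEval)
```

## The problem

Read error-correction tools were largely designed with homozygous data in
mind. On a diploid sample, a genuine heterozygous site looks — locally —
exactly like a sequencing error: a position where some reads say one base
and some say another. An aggressive corrector can therefore "fix" a true
variant away, converting a base to its homologous counterpart, or to
neither haplotype. When this happens at two or more heterozygous sites of
one read inconsistently, it produces a *chimeric read*: a read whose
heterozygous markers represent both haplotypes, which is biologically
impossible for a read sequenced from a single DNA fragment.

HetErrEval quantifies this failure mode. Because real data never reveal
the true source of a read, everything is built on simulation with a
complete truth ledger: a synthetic diploid genome whose heterozygous
sites are known exactly, and reads whose source haplotype, position,
strand and injected errors are all recorded. Any corrector — a built-in
control, the bundled k-mer-spectrum corrector, or an external tool run on
the exported FASTQ and re-ingested — can then be scored base by base.

## The evaluation model

Every base of the readset that is either an injected error or overlaps a
heterozygous site is classified into a stratum (heterozygous/homozygous
position × error/non-error base) and an outcome:

* **corrected correctly** — changed to the source genome's base;
* **not corrected** — an error base left as written;
* **corrected to the wrong haplotype** — changed to the homologous
  haplotype's base (a mis-correction that silently switches haplotype);
* **corrected to neither haplotype** — changed to a base neither
  haplotype carries;
* **unchanged** — a non-error base left alone (the desired outcome);
* **mis-corrected (homozygous)** — a homozygous-position base changed to
  anything but the source base;
* **trimmed** — the base was removed, either by end-trimming or because
  the whole read was discarded.

Three conventions deserve justification:

* *Unchanged precedes haplotype matching.* An error base that happens to
  equal the other haplotype's base and is left alone is **not corrected**,
  not "corrected to the wrong haplotype": non-modification is its own
  class, whatever the base's value.
* *Trimming is a separate class.* Correctors that trim remove errors and
  markers alike; folding those bases into "not corrected" would conflate
  two very different behaviours. Removed reads contribute all their
  classified bases to the trimmed class.
* *Undefined rates are `NA`.* A rate whose denominator is empty (e.g. a
  zero-heterozygosity genome) is reported as missing, never as 0 or 1, so
  degenerate configurations cannot masquerade as perfect scores.

From the stratified counts come three rate families: `rateOccurrence()`
(how all errors, heterozygous and homozygous pooled, were treated),
`rateCorrected()` (outcomes among heterozygous error bases only), and
`rateIntroduced()` (non-error heterozygous bases corrected to the wrong
or neither haplotype — errors the corrector *created*). At the read
level, `chimeraReport()` counts reads with more than one surviving
heterozygous marker and, among them, reads whose markers represent both
haplotypes.

### Trim inference

Corrected FASTQ carries no coordinates, so end-trimming is inferred: for
a length deficit ΔL, all ΔL+1 end splits are scored by Hamming distance
against the original read and the minimal one is taken, ties to the
smallest leading trim. Mis-inference is possible only when a substitution
sits exactly at a read end and ties the metric; the tie-break makes the
result deterministic. Interior deletions are out of model (end-trimming
is the behaviour class of k-spectrum tools).

### Markers and chimeras

A *heterozygous marker* is any surviving read position overlapping a
heterozygous site, whatever its base. A marker is assigned to haplotype A
or B when its (strand-corrected) base matches that haplotype, and
`NEITHER` otherwise. `NEITHER` markers count toward the "more than one
marker" denominator but represent no haplotype, so they can never make a
read chimeric; this is one consistent reading of "haplotypes
represented", and the marker table returned by `markerCalls()` lets users
apply a different rule if they prefer. Marker positions come from the
truth ledger, not re-alignment — the simulator knows where every read
came from, which is precisely the point of synthetic evaluation.

## The synthetic data generator

`introduceHeterozygosity()` duplicates a source sequence and plants
exactly `round(het_rate × length)` single-nucleotide differences
(positions uniform without replacement; substituted base uniform over the
three alternatives; round-half-even). An exact count, rather than
per-base Bernoulli sampling, makes the site count a testable invariant;
nothing downstream depends on the distinction. Only SNVs are modelled —
no indels, structural variants or ambiguity codes.

`simulateReads()` generates `round(coverage × L / read_length)`
fixed-length single-end reads, each from haplotype A or B with
probability 1/2, start uniform, strand uniform, with i.i.d. per-base
substitution errors. Coverage is *combined* over the haploid length, so
40x means about 20x per haplotype; all downstream rates are
count-normalised, so this convention affects no classification. The
defaults — 75 bp reads, 40x, error rates 3.7–7.3%, heterozygosity
0.2–10% in 0.2% steps (50 levels × 4 error rates = 200 datasets) — are
the study conditions this package exists to reproduce.

What the generator does *not* emulate: quality-profile error models
(errors here are uniform along the read), paired ends, indel errors, GC
or coverage bias, duplicate reads. Quality strings are constant Q40 and
ignored throughout. Consequently, passing tests demonstrate the
evaluation machinery and the haplotype-level phenomena; they do not
certify corrector performance on position-dependent real error profiles.

## The built-in k-spectrum corrector

`kspectrumCorrect()` is a deliberately minimal member of the k-mer
spectrum family, not a re-implementation of any published tool: count all
k-mers canonically (each pooled with its reverse complement, since reads
come from both strands), trust those seen at least `trustThreshold`
times, and for each read containing untrusted k-mers try every
single-base substitution at positions covered by untrusted k-mers,
applying the one that maximises the read's trusted k-mer count *only if
it makes every k-mer trusted* — otherwise the read is left alone. At most
one substitution per read per pass, up to two passes; ties break to the
smallest (position, base); the census is computed once from the input and
held fixed across passes (a pass-1 fix restores genuine genome k-mers
that the original census already trusts, so a second error can still be
fixed in pass 2). There is no quality model, no likelihood ranking and no
trimming.

This is enough to reproduce the phenomenon class under study. In a pooled
("heterozygous") dataset, both haplotypes' k-mers are trusted: an error
at a heterozygous site can be "corrected" to either haplotype, and at low
heterozygosity the two candidates tie, so about half of those corrections
switch haplotype. As heterozygosity rises, neighbouring heterozygous
sites fall inside the k-mer window and disambiguate the read's origin, so
accuracy at heterozygous errors *increases* with heterozygosity. In the
split ("homozygous") mode each half's census contains only its own
haplotype, the wrong-haplotype candidate is never trusted, and accuracy
dominates the pooled mode at every level — the package's acceptance tests
assert exactly these two trends.

Defaults `k = 15`, `trustThreshold = 2`: at the package's demo scale
(100 kb genome, 40x) a 15-mer census is essentially collision-free
(4^15 ≈ 10^9 ≫ genome size) while every genuine k-mer is sampled ~16
times per haplotype, making threshold 2 a safe trust cut-off. `k` is a
user parameter; no genome-size formula is applied.

## Numerical and design choices

* **Determinism.** Every stochastic step takes a seed; sweep cells derive
  seeds from the master seed with an order-insensitive integer mixing
  function (always < 2^31). The adversarial `flipMarkersCorrect()` draws
  its flips from per-read derived seeds so that correcting the pooled
  readset and correcting the haplotype halves commute — which the test
  suite asserts for all control correctors.
* **Mode pooling.** In homozygous mode the two halves are corrected and
  evaluated independently and their outcome *counts* summed; rates are
  computed from pooled counts, never averaged across halves.
* **Heterozygous vs homozygous mode equality at zero heterozygosity.**
  With no heterozygous sites the two modes differ only through census
  sampling. They produce *identical* reports only when no two erroneous
  reads share a corrupted k-mer (the pooled census would trust such a
  k-mer at threshold 2; a split census may not) and each half's coverage
  still trusts every genuine k-mer. The unit test asserts equality under
  such collision-free conditions (2 kb, 60x, error 2×10⁻⁴); at higher
  error rates the modes drift apart by a handful of events, which is a
  real census effect, not a bug.
* **Replicate pooling in the trend checks.** At the demo scale a 100 kb
  dataset at 0.2% heterozygosity holds only ~300 heterozygous error
  bases, so single-dataset rates carry sampling noise comparable to the
  trend being checked. The acceptance checks therefore pool outcome
  counts over four replicate datasets per heterozygosity level before
  computing rates. Problem sizes throughout (100 kb sweep genome, 50 kb
  fidelity checks, tiny brute-force instances) are the package's own
  desk-scale choices; the genome length is a configuration knob and a
  real reference FASTA can be supplied instead.
* **Degenerate inputs.** Ambiguity codes are rejected at genome
  construction; heterozygosity above 10% is out of the supported model;
  over-trimmed reads become removed records; corrected reads longer than
  their original are a hard error.

## A worked example

```{r example, eval = FALSE}
pair <- introduceHeterozygosity(randomReference(100000, seed = 1),
                                hetRate = 0.02, seed = 2)
rs   <- simulateReads(pair, readLength = 75, coverage = 40,
                      errorRate = 0.037, seed = 3)
verifyReadset(rs, pair)                 # TRUE: ledger reconstructs genome

ks   <- kspectrumCorrect(rs, k = 15, trustThreshold = 2)
ev   <- evaluateCorrections(rs, pair, ks)
rateCorrected(ev, "corrected_correctly")
rateCorrected(ev, "wrong_haplotype")
rateIntroduced(ev)
rateChimeric(chimeraReport(rs, pair, ks))

## the two dataset modes of the full design:
cfg <- sweepConfig(genomeLength = 100000, hetRates = c(0.002, 0.02, 0.10),
                   errorRates = 0.037)
res <- runConfig(cfg, 0.02, 0.037)
res$heterozygous.kspectrum$evaluation
res$homozygous.kspectrum$evaluation
```

## Known limitations

* The built-in corrector is a behaviour-class stand-in: conclusions about
  any specific published tool require running that tool on the exported
  FASTQ and re-ingesting with `loadExternalCorrected()`.
* Only single-base substitutions are modelled and analysed, on both the
  simulation and the correction side; indel-producing correctors violate
  the end-trimming model and are out of scope.
* Marker positions rely on simulated provenance; the package offers no
  alignment-based marker discovery for reads of unknown origin.
* The chimera statistic conditions on reads with >1 surviving marker; a
  heavily trimming corrector can look artificially good on it simply by
  destroying markers, which is why the marker-count rate
  (`rateMultimarker()`) is always reported alongside.
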