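---
title: "Assembly grading: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly grading: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(asmqc)
```

`asmqc` grades genome assemblies on continuity, base accuracy, completeness,
structural reliability and haplotype phasing, and summarizes the result in
the compact x.y.P.Q.C notation. This vignette is the package's own account
of the underlying models, the tunable parameters that matter, and the design
decisions taken where the problem left the design open. Every number quoted
here is computed by the test suite or the acceptance script; nothing is
asserted that the code does not measure.

## Assemblies, contigs and gaps

A scaffold is decomposed into contigs separated by gaps, where a gap is a
maximal run of at least `gap_min_run` `N` characters. The default is 10 N —
the common sequence-archive convention — although scaffolding tools often
insert fixed 100-N gaps; both are captured by the default, and the parameter
is exposed everywhere. Two boundary rules keep the statistics honest:

* terminal `N` runs of any length are reported as terminal gaps but never
  become contigs (they would otherwise inflate contig counts), and they are
  excluded from the interior gap count used for gaps/Gb;
* contig and gap intervals tile each scaffold exactly, so concatenating them
  reconstructs the scaffold byte-identically (a property the tests enforce).

Coordinates are 0-based half-open internally and in all BED output; only
human-readable reports use 1-based positions. NGx is computed by descending
cumulative sum; when an assembly cannot reach the target fraction of the
genome size, the statistic is reported as the sentinel 0 with a
`reached = FALSE` flag rather than an error, so grading of fragmented
assemblies still completes.

## The k-mer engine

All validation metrics run on canonical k-mers (the lexicographic minimum of
a k-mer and its reverse complement). The counter is C++ behind an R surface:
k-mers are 2-bit packed into 64-bit integers, which bounds k at 31 —
sufficient for the two defaults used throughout, k = 31 for genome profiling
and k = 21 for validation metrics, both exposed as parameters. K-mers
containing `N` (or any non-ACGT character) are skipped; lowercase soft
masking is preserved in sequences but invisible to every metric.

The error threshold separating sequencing-error k-mers from genomic ones is
the first local minimum of the (lightly smoothed) multiplicity histogram
between the error mass at multiplicity 1–2 and the main coverage peak. Two
edge rules matter: the descent must begin at the lowest multiplicities —
a histogram that opens by *rising* has no error mass, and its first peak may
legitimately be the haploid peak of a heterozygous genome — and when no
interior minimum exists the threshold falls back to 2. Error-free simulated
reads therefore get threshold 2, and completeness is unaffected.

## Genome profiling

The read k-mer histogram is summarized into genome size, heterozygosity and
repeat content by a peak/moment estimator. A full mixture-model fit (as in
dedicated profilers) is deliberately not reimplemented: downstream grading
consumes only the three point estimates, and a closed-form estimator is
auditable.

* **Coverage peak.** The diploid (homozygous) peak λ_d is located as the
  histogram mode above the error threshold, disambiguated against the
  haploid peak: when a comparable peak exists at twice the mode, the mode is
  the haploid peak of a highly heterozygous genome and λ_d is taken at 2×.
  The integer mode is then refined by truncated-Poisson moment matching in
  the window [0.75, 1.45]·λ_d — the λ whose truncated-Poisson mean over the
  window equals the observed window mean. The asymmetric window stays above
  the haploid peak while tolerating the heavy right tail that long,
  correlated reads produce; the mode alone is unreliable because depth is
  correlated over read-length scales, so single realizations of the
  histogram are much rougher than a Poisson ideal.
* **Genome size.** G = Σ_{m>t} m·hist[m] / λ_d: reliable k-mer instances
  divided by k-mer coverage. Over the test grid (G ∈ {0.5, 1, 2} Mb,
  heterozygosity ∈ {0, 0.5, 1}%, coverage ∈ {30, 60}×) recovery is within
  5%, and within 2% for the single homozygous 30× example.
* **Heterozygosity.** Distinct k-mers are split at 0.75·λ_d into a
  haploid-peak share and a diploid-peak share; the haploid share is
  corrected for the expected Poisson spill of homozygous k-mers below the
  split. A heterozygous site puts *two* distinct k-mer variants (one per
  haplotype) at half coverage, so a het k-mer pair is counted once when
  forming the heterozygous fraction of k-mer positions f_het, and the
  per-base rate is r = 1 − (1 − f_het)^(1/k). This pair-counted form is
  unbiased in the parameter-recovery tests (±0.3 percentage points across
  the grid; the alternative of counting each variant separately
  overestimates r by roughly a factor of two).
* **Repeat content.** The fraction of above-threshold k-mer instances at
  multiplicity above 2.5·λ_d. The cutoff is a configurable stand-in — the
  framework this mirrors defines repeat content through a model fit with no
  closed form — and reports label it as such.

A histogram whose mode sits at the threshold boundary (only error mass, no
sampling peak) is rejected as an unreliable profile rather than silently
fitted.

## QV, completeness, duplications

**QV.** With T total assembly k-mer instances and B instances whose
canonical k-mer never occurs in the reads, E = 1 − (1 − B/T)^(1/k) and
QV = −10·log10(E). One isolated substitution destroys exactly k k-mers, so
one error per 10 kb at k = 21 gives B/T ≈ 0.0021 and Q40.00; the tests
verify ±0.5 QV agreement with the planted rate at 10⁻³, 10⁻⁴ and 10⁻⁵, and
monotone decrease as errors accumulate. When B = 0 the error rate is 0 and
QV is reported at a cap of 99.9 with a `capped` flag — the framework being
mirrored has no cap rule, and an infinite QV would be unusable downstream.

**Completeness** is the fraction of reliable read k-mers (multiplicity
strictly above the error threshold) found in the assembly; a perfect
self-assembly against error-free reads scores exactly 100.

**False duplications.** Each assembly k-mer's expected copy number is its
read multiplicity divided by λ_d, rounded half away from zero and floored at
1; assembly instances in excess of that are falsely duplicated, reported as
a percent of T, optionally with the excess k-mer positions as BED. λ_d comes
from the global profile, not per-contig depth, so a collapsed contig cannot
mask a duplication elsewhere. A planted extra copy of a 50-kb unique segment
in a 1.05-Mb assembly measures 4.8%, matching the counting oracle.

## Coverage analysis

Depth tracks are built from PAF target intervals (per-base depth via
interval coverage, averaged in 1-kb windows by default), filtered by the
residue-match fraction PAF always carries (default ≥ 0.5) as a
mapping-quality proxy. Collapsed repeats are windows with depth strictly
above mean + 3 s.d., merged and length-filtered (1 kb default); copy number
is depth over the global mean. Because collapses themselves inflate the
plain s.d., a robust mode (median / 1.4826·MAD) is available and is what the
detector property tests use; plain mean/s.d. remains the default to match
the 3-s.d. convention. Reliable blocks are maximal intervals where ≥ 2
technologies provide spanning support, each alignment trimmed by 100 bp at
both ends and required to reach depth ≥ 3; optical-map or transcript
support can be supplied as pre-computed BED intervals since aligning those
data types is out of scope. The trimmed-spanning-depth definition is an
explicit operationalization — the original curation tooling never published
one — so edge behaviour may differ from that tooling.

Duplication candidates combine two signatures: heterotype candidates are
intervals at half coverage (|d − μ/2| ≤ 0.25·μ/2 by default) with a
self-alignment partner elsewhere; homotype candidates are self-alignment
pairs with one copy within two windows of a contig end and length within
[0.2, 3]× the read length — the classic boundary artifact of overlap-based
contigging.

## Purging

Coverage cutoffs are derived from the depth histogram (smoothed, moving
average width 3): low = max(2, λ_h/4) below which a contig is junk,
mid = (λ_h + λ_d)/2 bounding haplotig candidates, high = 3·λ_d above which
a contig is flagged as repeat but retained. A haplotig call additionally
requires ≥ 80% of the contig aligned to a longer retained contig — depth
alone never moves sequence; the 80% threshold is configurable since the
published purging tools do not document theirs. Junk goes to its own output,
never silently deleted; mutual (circular) haplotig evidence keeps the longer
contig and logs the tie-break. Scaffold-internal end-to-end duplications are
handled at contig granularity (the shorter end copy moves); the chaining
dynamic program of the dedicated purging tools is a non-goal. The tests
enforce exact base conservation
(primary + alternate + junk before = after), idempotence, ≥ 90% recall of
planted haplotig bases, and that the k-mer duplication rate never rises
after purging.

## Trio phasing

Hap-mers are k-mers confined to one parent's reads: own-parent multiplicity
within [error threshold + 1, 4·coverage peak] (excluding sequencing errors
below and repeats above) and absent from the other parent, optionally
intersected with the child's k-mers. Reads are binned by marker hits
normalized by marker-set size, ties and zero-hit reads unassigned. Phase
blocks scan ordered marker placements: opposite-parent runs of at most 10
markers spanning at most 20 kb are tolerated and each counts one switch
error; longer or wider runs terminate the block. These two tolerances are
the dominant determinant of phase block NG50 and are deliberately exposed;
the defaults are a package choice, not a published constant. Precision is
the fraction of in-block markers agreeing with the block's parent; recall is
in-block agreeing markers over the full marker-set size. These denominators
are stated explicitly because the published precision/recall figures this
mirrors never defined theirs precisely.

## The simulator

The fixture module emulates: a random-background diploid genome with
optional planted interspersed repeats (identical between haplotypes), SNV
heterozygosity at a stated percent (small indels optional and off by
default, so k-mer arithmetic stays exactly checkable), lognormal long reads
sampled uniformly with substitution errors only, and truth-tracked defect
injection in a fixed order (switches, collapses, duplications, gaps,
substitutions) with coordinates re-mapped to the final sequence. Read starts
are drawn over an extended range and clipped, so coverage is uniform to the
sequence ends — without this, end-ramp undercoverage leaves a few thousand
genomic k-mers unsampled at 30× and corrupts the perfect-assembly QV.
Substitution injection uses one random offset within regularly spaced slots,
which guarantees the planted errors stay isolated at the k-mer level.

What the simulator does *not* emulate — realistic long-read error profiles
(homopolymer indels), GC bias, optical maps, Hi-C — bounds what passing
tests show: the metrics are verified against their definitions and against
planted truth, not against the full messiness of real data. Study-scale
conditions (heterozygosity 0.1–1.1%, read lengths 10–35 kb, ≥ 60× combined
coverage) are mirrored at desk scale: genomes of 0.5–2 Mb, coverage 30–60×,
which the tests complete in minutes on one CPU.

## Grading

The notation floors everything: x = ⌊log10 contig NG50⌋ (in bases),
y = ⌊log10 scaffold NG50⌋, P likewise for phase blocks, Q = ⌊QV⌋,
C = ⌊assigned %⌋. Floor was chosen over rounding because the published
worked examples (a 10⁵-bp phase block NG50 printing as P5 against a
">100 kb" threshold) are only consistent with floor. Components that were
not assessed are omitted with their prefix, reproducing short forms like
`4.5.Q30`; missing values are never defaulted. A component renders as `c`
(chromosome-complete) only when the corresponding NG50 equals a
user-supplied chromosome NG50 — and for x, additionally zero gaps; without
that input `c` is never emitted. Q prints the measured floor, not the
threshold met — categories are reported separately, as the highest standard
whose threshold each metric meets. The assigned-percent row treats the
chromosome-assignment table as authoritative: N bases count by default
(configurable), and unlocalized scaffolds count only if chromosome-labelled,
both decisions the upstream convention leaves unstated.

## Known limitations

* Heterozygosity above ~2% would put the histogram mode at the haploid peak
  with the homozygous peak as a shoulder; the 2×-mode disambiguation handles
  the simulated range (≤ 1.6%) but extreme outbred genomes would need the
  mixture fit this package deliberately omits.
* The k-mer engine keeps count sets in memory; at vertebrate scale
  (≫ 10⁹ distinct k-mers) a disk-backed counter would be required. The
  module surface (sorted packed codes + merge joins) was chosen so such a
  backend could be swapped in without changing results.
* Repeat-content and reliable-block definitions are explicit stand-ins for
  upstream conventions that were never operationalized; both are labelled
  in output and configurable.
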