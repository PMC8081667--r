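# asmqc — genome assembly quality evaluation and grading

`asmqc` evaluates and grades genome assemblies with the metric framework
adopted by large vertebrate genome projects. It is aimed at anyone producing
or consuming de novo assemblies who needs to answer, with numbers: how
continuous is this assembly, how accurate is its consensus, how complete is
it, how much of it is falsely duplicated, and how well are the haplotypes
separated?

The package covers six metric families plus the machinery to test them:

* **Continuity** — contig/scaffold NG50 and N50, gap counts and gaps per Gb.
  NG50 is the weighted median of sequence lengths relative to the estimated
  genome size: the length `L` such that sequences of length ≥ `L` cover half
  the genome.
* **Base accuracy (QV)** — k-mer survival consensus quality. With `T` total
  assembly k-mer instances and `B` instances absent from the read set, the
  per-base error rate is `E = 1 − (1 − B/T)^(1/k)` and `QV = −10·log10(E)`.
  One error per 10 kb is 99.99% accuracy, Q40.
* **Completeness and false duplications** — the fraction of reliable read
  k-mers (above the error threshold of the read k-mer histogram) present in
  the assembly, and the fraction of assembly k-mer instances in excess of
  the copy number implied by read multiplicity over the coverage peak.
* **Genome profiling** — genome size, heterozygosity and repeat content
  estimated from the read k-mer histogram with a documented peak/moment
  estimator.
* **Structural reliability** — read-depth tracks from PAF alignments,
  collapsed-repeat detection (depth > mean + 3 s.d.), reliable blocks
  (spanning support by ≥ 2 technologies), coverage-based false-duplication
  candidates, and coverage-cutoff purging of haplotigs and junk contigs.
* **Haplotype phasing** — parent-specific marker k-mers (hap-mers), trio
  read binning, phase blocks with a bounded switch tolerance, switch
  errors, and phase block NG50.

Everything is aggregated into the compact **x.y.P.Q.C** notation
(`x` = floor log10 contig NG50 in bases, `y` = floor log10 scaffold NG50,
`P` = floor log10 phase block NG50, `Q` = floor QV, `C` = floor percent
assigned to chromosomes; `c` marks chromosome-complete components) and into
per-metric quality categories (Finished / VGP-2020 / VGP-2016 / B10K-2014 /
below).

A seeded simulator of diploid genomes, long reads and injected assembly
defects (substitutions, heterotype/homotype duplications, collapses, gaps)
ships as a first-class module, so every metric can be checked against known
truth without any external data.

## Worked example

```r
library(asmqc)

# simulate a 1-Mb genome and error-free 30x long reads
spec <- sim_spec(genome_size = 1e6, heterozygosity = 0, coverage = 30, seed = 42)
dip   <- simulate_diploid(spec)
reads <- simulate_reads(dip$maternal, spec)

# inject one substitution per 10 kb into the "assembly"
inj <- inject_defects(Assembly(dip$maternal),
                      defect_spec(substitutions = 1e-4, sub_spacing = 25))

rc <- count_kmers(reads$reads, 21, "reads")
ac <- count_kmers(inj$assembly, 21, "assembly")
estimate_qv(ac, rc)
#> QV 40.00 (k=21, 2100 of 999980 assembly k-mer instances absent from reads)

thr <- error_threshold(kmer_histogram(rc))
kmer_completeness(rc, ac, thr)
#> k-mer completeness 99.790% (997880 / 999980 reliable k-mers, threshold 2)
```

The 100 planted substitutions each erase k = 21 assembly k-mers, so
`B = 2100`, giving a measured error rate of 1.0 × 10⁻⁴ — Q40, the boundary
the x.y.P.Q.C notation renders as `Q40`. Completeness dips just below 100%
because the same substitutions delete genuine genomic k-mers from the
assembly.

Grading a metric set:

```r
b <- metrics_bundle(contig_ng50 = 1.2e6, scaffold_ng50 = 1.5e7,
                    phase_block_ng50 = 2e5, qv = 41.2, assigned_pct = 93.4)
notation(b)
#> [1] "6.7.P5.Q41.C93"
```

A thin command-line wrapper is installed at `inst/cli/asmqc`
(`asmqc stats|profile|qv|completeness|duprate|hapmers|bin|phase|depth|collapse|reliable|purge|grade|simulate|evaluate`),
and `evaluate()` runs the whole pipeline from a YAML config, marking stages
without inputs as "not assessed".

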