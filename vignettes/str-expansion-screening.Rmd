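---
title: "Screening long-read genomes for STR expansions with a population normal-range database"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening long-read genomes for STR expansions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strscreen)
```

## The problem and the model

Short tandem repeats (STRs) are tracts where a motif of 1–16 bp is
repeated consecutively. Repeat counts vary between individuals, and
expansions of particular STRs cause dominant and recessive disorders
(Huntington's disease, the spinocerebellar ataxias, fragile X syndrome,
Friedreich's ataxia, ...). Long reads span whole tracts, so a per-allele
repeat count is measurable from a BAM; the missing piece for genome-wide
discovery is a reference for what counts are *normal* at each locus.

`strscreen` builds that reference empirically. Per catalog locus, allele
counts from a panel of presumed-unaffected genomes are pooled — both
alleles of each diploid genome, one of each haploid genome, so a fully
called panel of 19 diploids and 2 haploids pools $N = 40$ counts
$c_1,\dots,c_N$. The locus's normal range is summarised as

* the minimum $\min_i c_i$,
* the 95th percentile $u$ (computed with linear interpolation between
  order statistics at index $h = 0.95\,(N-1)$ on the sorted pool), used
  instead of the maximum so that single panel outliers do not inflate the
  upper bound, and
* the sample standard deviation
  $s = \sqrt{\sum_i (c_i - \bar c)^2 / (N - 1)}$, computed over the full
  pool (values above $u$ are *not* excluded from $s$: the deviation
  describes the whole pool, the percentile bounds it).

A new observation $c$ at that locus gets the expansion score

$$ z = \frac{c - u}{s}, $$

and an allele is labelled *pathogenic* when $z$ strictly exceeds a
threshold; a subject is *affected* under the dominant model when at least
one allele is pathogenic. The model's central assumptions are that the
panel genomes are unaffected by repeat-expansion disorders, and that
pooled counts at a locus are unimodal enough for a location/scale summary
to be meaningful — both are assumptions about the reference panel, not
about the tested genome.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `threshold` (coding) | 2.0 | score (SD units) | allele label in exonic regions; strict `>` — a score exactly at the threshold is normal |
| `threshold_noncoding` | 10.0 | score | second-stage filter outside exons; non-coding regions tolerate far more repeat variability, so a much higher bar is needed |
| `sd_floor` | 5 (screening only) | repeat copies | floors $s$ so loci with tiny panel deviation cannot reach huge scores from a 1–2 copy excess; targeted single-locus scoring uses the raw $s$ |
| `min_genomes` | 10 | genomes | a locus scored against fewer contributing genomes is skipped — its range estimate is too unstable |
| `skip_poly_at` | TRUE | — | poly-A/poly-T tracts are skipped: their apparent length variation is dominated by homopolymer sequencing error |
| `min_reads` | 5 | spanning reads | below this support a locus is a distinct no-call rather than a genotype |
| `flank` | 50 | bp | a read must cover the tract plus this anchor on both sides to count as spanning |
| `set_size`, `time_budget`, `regroup_factor` | 100, none, 2 | loci, s, — | scan partitioning and kill/regroup behaviour |

Screening is two-stage, mirroring genome-wide practice: every candidate
must first clear the coding threshold, and non-exonic candidates must
additionally clear the non-coding one. Only `exonic` loci use the coding
threshold as final; all other region classes (UTRs, up/downstream,
ncRNA, intronic, intergenic, unknown) are treated as non-coding.

## Counting motif copies in noisy reads

The repeat tract of each spanning read is extracted through the
alignment's coordinate mapping (CIGAR walk; insertions at the exact tract
boundary are assigned to the flank). The tract is then aligned globally
against tandem arrays of the motif under unit costs (match +1,
mismatch/indel −1); the reported copy number is the array length $k$
maximising the alignment score. All $f(k)$ come from one dynamic-
programming table against a long array, read off at columns $k\,m$.

Ties in $f(k)$ are real and systematic: a substituted base scores the
same whether it is absorbed into a copy (mismatch) or treated as an
insertion, so always taking the smallest maximiser undercounts
homopolymer-period motifs by roughly one copy per substitution, while
always taking the largest overcounts insertion-induced ties on
mixed-base motifs. The package therefore resolves ties toward the $k$
closest to $\mathrm{len(segment)}/\mathrm{len(motif)}$ (smaller $k$ when
equidistant), which we measured to be near-unbiased (|bias| < 0.5
copies at a 10% error rate) across homopolymer, dinucleotide and longer
motifs. Exact tandem arrays have a unique maximiser and always return
exactly their copy number; the empty segment returns 0.

Per-read counts are clustered by a one-dimensional Gaussian mixture with
deterministic initialisation (component means at the 25th/75th
percentiles, common initial SD, iteration cap 200, tolerance $10^{-4}$),
choosing between one and two components by BIC; component means round
half-up to integer alleles, and a two-component fit whose rounded means
coincide collapses to a homozygote. Component SDs are floored at 0.25 so
that point masses (all reads identical) keep a finite likelihood; the
input is sorted first, making the call permutation-invariant. For a
collapsed homozygote the read support is recorded on the first allele
copy (second 0) so support never exceeds the read count.

## The scan driver

Genome-wide genotyping is partitioned into fixed-size tasks in catalog
order. A task exceeding its time budget is killed and its loci regrouped
into sets of `ceiling(size / regroup_factor)`, recursively, until tasks
are singletons; a killed singleton is dropped with a warning (or, on
request, retried once without a budget). A locus whose genotyping raises
an error is recorded as failed — distinct from dropped — and the scan
continues; a no-call is an ordinary result row, not a drop. Every scan
satisfies |results| + |dropped| + |failed| = |catalog|, and the combined
table is identical whatever the partitioning. Tests drive the budget
with an abstract per-locus cost function, which makes kill decisions
(and hence outputs) fully deterministic; production use falls back to
wall-clock accounting with kills at locus boundaries.

## What the simulator emulates — and what it does not

The generator's defaults encode the reference-panel conditions the
pipeline assumes: 21 genomes of which 2 are haploid (40-count pools at
fully called loci); per-locus base copy numbers uniform on [5, 35] with
per-allele jitter `round(N(0, 2))` truncated at 1; read depth 30 per
allele; a 10% per-base error rate split 60/20/20 between substitutions,
insertions and deletions; motif lengths 1–6 weighted
(.10, .25, .30, .20, .10, .05) to resemble the di-/tri-/tetranucleotide-
heavy spectrum of genomic STR catalogs. Reads are built with their exact
CIGARs, so simulated BAMs have perfect coordinate mappings by
construction.

It does **not** emulate: platform-specific error profiles (systematic
homopolymer undercalls of nanopore, PacBio CCS error clustering),
alignment ambiguity from a real aligner, reference mismapping in complex
or sub-telomeric regions, somatic mosaicism, or motif impurity
(interrupted repeats). Passing tests therefore demonstrate correctness
of the counting, fitting, scoring and orchestration logic under the
stated noise model — not calling accuracy on real instruments, which
depends on upstream alignment quality.

## Numerical and design choices

* **Coordinates** are BED 0-based half-open everywhere internally;
  UCSC simpleRepeat `chromStart` is already 0-based. Region labels join
  by the first interval in table order containing the locus start, with
  half-open semantics (a start equal to a region end does not match).
* **Percentile** is the linear-interpolation estimate (R's
  `quantile(type = 7)`); min/p95/SD are stored and serialized unrounded
  (15 significant digits), and any 1-decimal rounding happens only in
  reports. Classification always compares unrounded values.
* **Degenerate SD** (constant pool) is guarded: the score is ±Inf/0 and
  flagged, rather than NaN.
* **Strand**: catalog motifs are taken as reference-strand; reverse
  complements are not merged. Rotational variants can be pooled via
  `canonical_motif()` (lexicographically smallest rotation), but the
  poly-A/T skip tests the literal motif (homopolymers are
  rotation-invariant anyway).
* **Malformed catalog rows** are skipped with a warning, never fatal: a
  genome-wide scan should tolerate per-locus defects.
* **Which allele is scored**: screening scores the larger allele
  (expansion detection); targeted mode scores both and reports
  subject-level calls.
* **Problem sizes in the tests**: oracle agreement on 1,000 random pools
  and ~65 random noisy segments; exhaustive pure-array recovery for
  motif lengths 1–6 × 0–60 copies; allele recovery on 100 simulated loci
  at depth 30 and 10% error (allele separation ≥ 5); the full synthetic
  pipeline closure uses 20 loci × 5 genomes. These sizes exercise every
  code path while keeping the default suite fast.

## A complete synthetic run

```{r pipeline, eval = FALSE}
cfg <- sim_config(seed = 11, n_loci = 20, n_genomes = 5, n_haploid = 1,
                  read_depth = 12, read_error_rate = 0.05)
sim <- simulate_catalog(cfg)
pop <- simulate_population_counts(sim$catalog, cfg)

# "sequence" genome01 and scan its BAM over the catalog
bam  <- simulate_alignments(sim$catalog,
                            pop$calls$genome01[, c("allele1", "allele2")],
                            sim$ref_seq, cfg, sample_id = "genome01")
scan <- scan_genome(bam, sim$catalog, "genome01", set_size = 5)

# fit the normal-range database on the other genomes and screen
db   <- build_range_db(pop$calls[-1], pop$ploidies[-1], sim$catalog)
cand <- predict(db, scan$results, mode = "screen",
                catalog = sim$catalog, min_genomes = 3)
```

With no planted expansion the candidate list is empty; adding
`expansion_spike = list(locus = 3, count = 80)` to the configuration
makes locus 3 the top-ranked candidate of the spiked genome.

## Known limitations

* The repeat counter is a deliberately simple, fully specified
  edit-distance method; it does not perform split-and-align realignment
  or HMM-based error correction, and motif-impure or adjacent compound
  repeats will blur its estimates.
* The database summarises each locus marginally; linkage between loci
  and population structure in the panel are ignored.
* Scores are descriptive deviations, not calibrated p-values; candidate
  counts from screening are enrichment filters, not error-controlled
  discoveries, and region-dependent thresholds are conventions rather
  than fitted quantities.
* Haploid/diploid is the only ploidy model; X-linked loci in male
  samples should be passed as haploid.
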