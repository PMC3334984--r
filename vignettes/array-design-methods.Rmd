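---
title: "Methods: designing and evaluating a fixed-size SNP array from low-coverage resequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: designing and evaluating a fixed-size SNP array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snparray)
```

## The problem

Genotyping arrays for crop breeding are built by resequencing a panel of
breeding-relevant accessions at low depth, calling variants against a
reference assembly, and then filtering roughly a million raw candidate
SNPs down to the few thousand that fit on a fixed-size Infinium bead
pool. `snparray` implements that whole funnel — detection-stage
filtering, probe candidacy screening, design-stage filtering, even
physical spacing into bead slots, and post-hoc evaluation of the
resulting array — together with a synthetic-data module that generates
genomes, panels, call tables and genotype reports with the statistical
structure the pipeline assumes, so that every stage can be exercised and
checked without any external data.

## Detection-stage (Stage 1) filtering

Variant evidence arrives as per-accession records: chromosome, 1-based
position, reference and alternate allele, per-allele read depths, and a
caller quality score. Two filtering regimes are provided, reflecting the
two ways such call sets are typically produced:

* **Regime A** (deep pooled coverage): quality `>= 25` (inclusive);
  total site coverage — reads summed over the pool's accessions —
  between 30 reads and 2.5x the mean site coverage of the input; at
  least 5 reads supporting the minor allele; sites inside a supplied
  repeat-interval track removed.
* **Regime B** (shallow coverage): quality strictly `> 30`; the larger
  per-allele read total below the mean site total plus three standard
  deviations; at least 5 minor-allele reads with total coverage of at
  least 10; and average k-mer copy number of the +/-50 bp flanking
  region strictly below 2.

Several conventions here are deliberate package choices, because the
procedures that inspired them leave them open:

* *Coverage is pooled.* "Coverage" means reads at the site summed over
  the accessions of the pool; at ~2-4x per accession, a 30-161-read
  band is only meaningful pool-wise. `filter_stage1()` works on whatever
  subset of accessions it is given, so per-accession filtering is just a
  matter of passing one accession's records.
* *Coverage ceilings are data-derived.* The 2.5x-mean and mean+3SD
  ceilings are recomputed from the input call tables at run time; they
  are distributional rules, not fixed read counts.
* *The minor allele is read-defined.* At a site, the minor allele is the
  one with fewer supporting reads (ties go to the alternate allele). A
  site where one allele has no read support at all therefore fails the
  minor-allele rule: with no second observed allele there is no
  segregation evidence within the panel.
* *Quality boundaries.* Regime A's threshold is inclusive (`>= 25`),
  regime B's strict (`> 30`); both are tested at the boundary.
* *Genotypes are allele-presence sets.* At 0.2-8x coverage, diploid
  genotype calling is hopeless; an accession's genotype at a site is
  simply the set of alleles with at least one supporting read. Detection
  MAF is computed from these presence-based genotypes (both alleles seen
  = heterozygous), and accession support counts accessions with at least
  one minor-allele-supporting read.

The same presence-set convention drives `compare_callsets()`, which
classifies candidate positions covered by two independent call sets of
the same accession as genotype-identical, sharing one allele, or
sharing none — the cross-laboratory concordance check. With very shallow
data, most candidate positions are simply not covered by both sets, and
the report says so rather than hiding the denominator.

### K-mer copy number

`estimate_copy_number()` takes the +/-`flank_bp` window around a site
(truncated at chromosome ends), enumerates its k-mers (default k = 31),
and averages each k-mer's genome-wide occurrence count. Counting is
canonical: a k-mer and its reverse complement are the same word. Unique
sequence scores 1.0; a region duplicated exactly once elsewhere scores
2.0 and is excluded by the regime-B rule (`< 2`). Windows narrower than
k raise an error; windows with no ACGT-only k-mer (all-N sequence)
return `NA` with a warning. Matching runs through Biostrings
`PDict`/`vcountPDict` in one batch per call.

## Probe candidacy screening

Infinium chemistry drives three screens implemented in
`classify_infinium()`, `extract_probe_context()`,
`probe_tail_duplicated()` and `apply_score_filter()`:

* A/T and C/G SNPs (type I) need two bead types and are removed;
  everything else is type II.
* The probe bodies are the 50 bp immediately up- and downstream of the
  SNP. The "tail" — the 25 bases adjacent to the SNP, where extension
  happens — must be unique in the genome. Both possible probe sides are
  checked; a tail whose 25-mer occurs more than once (counting reverse
  complements by default; a switch disables that) flags the candidate.
  Probes truncated below 25 bp by a chromosome end are undetermined and
  conservatively flagged.
* Vendor design scores are proprietary and enter as an input column in
  `[0, 1]`; the default retention threshold is 0.9 for de-novo
  candidates and 0.6 for pre-validated markers. The simulator draws
  scores from a right-skewed Beta model and penalises candidates with
  another segregating site inside the probe footprint, mimicking the
  empirical observation that hidden flanking polymorphism is the main
  driver of probe failure.

`merge_dedup()` combines candidate sets from multiple detection sources.
Records identical in (chromosome, position, unordered allele pair)
collapse to one, pooling accession support (detection panels of the
sources are disjoint, so the sum is a union size) and concatenating
source tags. Same-position records with *conflicting* allele pairs are
dropped entirely and reported via the `"conflicts"` attribute: with no
principled way to arbitrate between callers, a contested site is not
array material.

## Design-stage (Stage 2) filtering and slot selection

`filter_stage2()` retains candidates supported by at least five
accessions, located in predicted coding exons, and anchored on a
chromosome-scale pseudomolecule, logging per-rule removal counts in
application order (`stage_log()`), so the whole funnel can be
reconstructed from any run.

`select_even_spacing()` fills a fixed number of bead slots. Pre-validated
markers are pinned first — they are always included, wherever they sit,
including unanchored scaffolds. Remaining slots are apportioned to
chromosomes by largest-remainder rounding proportional to their
candidate counts, so design density tracks discovery density. Within a
chromosome, ideal target positions spanning the candidate interval are
laid down in *bisection-refinement order*: the two endpoints first, then
interval midpoints level by level (1/2; 1/4, 3/4; 1/8, 3/8, ...). Each
pinned SNP consumes its nearest target point; every remaining target
point is then filled, in refinement order, by the nearest still-unused
candidate, ties going to the lower position.

The refinement ordering is the one genuinely open design choice here,
and it was made for two reasons. First, for slot counts of the form
2^m + 1 the target set is exactly the uniform ideal grid, and on small
instances the selection provably attains the exhaustive-search minimum
of the summed distance between grid points and their nearest selected
candidate (the test suite checks this against full subset enumeration).
Second, the target sets are *nested* as the slot count grows, which
guarantees that adding slots never widens the largest inter-SNP gap on a
chromosome — a property a plain left-to-right uniform-grid assignment
does not have (its selections for k and k+1 slots are not nested, and
sweeps show the largest gap jumping up by several kb when a slot is
added). One caveat is inherited from largest-remainder apportionment:
like all quota methods it is not house-monotone across chromosomes
(the Alabama paradox), so the no-widening guarantee is within a
chromosome, not across reallocations.

`apply_manufacturing_dropout()` models bead-synthesis loss, either as an
explicit id list or a seeded random rate.

## Array evaluation

`qc_genotypes()` fails a SNP unless its GenTrain score exceeds 0.4, its
10th-percentile GenCall score exceeds 0.2, and it produces calls for at
least half the samples. `classify_snps()` then splits passing SNPs into
monomorphic (observed MAF exactly 0) and polymorphic; `glance()` returns
the class proportions plus the fraction of polymorphic SNPs with
MAF > 0.10 and > 0.20. Two denominators are deliberately kept apart:
failure/polymorphism rates are reported against all SNPs on the array,
while a union-of-panels polymorphism rate uses the union of SNPs
polymorphic in either evaluation panel; both appear in the outputs under
their own names.

MAF is `min(p, 1 - p)` with `p` the B-allele fraction over called
samples, assuming autosomal biallelic diploid calls; null alleles
surface only as no-calls, never as a third allele. Gap statistics
(`gap_statistics()`) are distances between successive SNPs on the same
chromosome — the flank from the chromosome end to the outermost SNP is
not a gap — summarised per chromosome and pooled, with a count of gaps
above a threshold (default 150 kb). `crosstab_validation()` produces
validation-outcome proportion tables by any labelling columns;
proportions are printed half-up at 2 decimals (percentages at 1
decimal), the convention of published validation tables, with unrounded
fractions kept alongside. `compare_panels()`, `progeny_informativeness()`,
`coverage_accounting()`/`coverage_summary()` and `maf_concordance()`
cover panel sharing, progeny segregation summaries, sequencing-coverage
bookkeeping (coverage = reads x read length / effective genome size,
with flagged low-yield runs excluded from means but not totals), and
Pearson correlation of MAFs across sample groups (requiring at least 3
shared SNPs; zero-variance input yields `NA` with a warning).

## What the simulator emulates — and what it does not

`sim_config()` centralises every generator tunable. The defaults encode
the study conditions the pipeline was built around: a detection panel of
56 accessions in 12 pools, the last pool on a long-read low-yield
platform at ~0.2x coverage and the rest drawn uniformly from 0.2-8x;
true MAFs uniform on (0.05, 0.5]; Hardy-Weinberg genotypes
(alt dosage ~ Binomial(2, MAF)); per-site read depth Poisson with the
accession's coverage as mean; binomial allele split given the genotype
with a 0.005 per-read error rate; quality scores normal(32, 6) truncated
to [0, 40], placing mass on both sides of the 25 and 30 thresholds;
array reports with 5% forced-failure SNPs, 1% baseline no-calls, and 2%
null-allele-like samples at a 50% no-call rate. The toy genome default
is eight 1 Mb chromosomes plus two unanchored 50 kb scaffolds with 100
genes/Mb, 5% exactly-duplicated repeat blocks, and 4,000 planted SNPs
(a density chosen so that each filtering rule removes a visible
fraction); tests and the acceptance run scale n_chrom, chromosome
length and SNP count down (e.g. 2-4 chromosomes of 60-200 kb, a few
hundred to 2,500 SNPs, evaluation panels of 50-200 samples) — sizes
chosen so the suite exercises every rule at meaningful counts while
each property test stays in seconds.

Deliberately *not* emulated: read-level sequencing (FASTQ, alignment,
base-calling artifacts), pedigree structure in genotypes, linkage
disequilibrium between sites, caller-specific error models, and the
internals of vendor design scoring and genotype clustering (both enter
as score columns). Passing tests on this generator therefore show that
the filtering, selection and evaluation arithmetic is correct under the
stated sampling models — not that those models capture every failure
mode of real resequencing data, where alignment artifacts, paralogy
beyond exact duplication, and population structure all add noise the
generator does not produce.

A note on determinism: every generator call derives its RNG stream from
`config$seed` plus a fixed per-stage offset and restores the caller's
RNG state afterwards, so identical configurations give byte-identical
FASTA/GFF3/TSV outputs and repeated pipeline runs are reproducible
end to end.

## Numerical and boundary conventions

* Coordinates are 1-based inclusive everywhere internally (the VCF/GFF3
  convention); BED is converted at the read/write boundary.
* Rounding of published-style proportions is half away from zero
  (`0.1875 -> 0.19`), not banker's rounding.
* Ties in nearest-candidate selection go to the lower position; ties in
  largest-remainder apportionment go to the earlier chromosome.
* Degenerate inputs return empty results rather than errors where the
  empty case is meaningful (empty call tables, zero-SNP panels,
  zero-comparable concordance reports flag their zero denominator), and
  typed errors otherwise (`snparray_invalid_config`,
  `snparray_reference_mismatch`, `snparray_parse_error`, ...).
* All file writers are atomic (temp file + rename), so a crashed run
  never leaves a truncated manifest behind.

## Limitations

Beyond the simulator's scope above: the even-spacing selection optimises
spacing only, with no joint objective on MAF or information content; the
concordance report does not model genotyping error rates, only allele
sharing; and `coverage_accounting()` treats the effective genome size as
a constant supplied by the user. The detection filters operate on
site-level summaries, so callers that emit haplotype- or read-backed
evidence must be reduced to per-allele depths first.
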