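# snparray

Design and evaluate fixed-size Infinium-style SNP genotyping arrays from
low-coverage whole-genome resequencing of a breeding panel.

Crop genotyping arrays are built by resequencing a few dozen
breeding-relevant accessions at 0.2–8× depth, calling variants against a
reference assembly, and filtering on the order of a million raw
candidate SNPs down to the few thousand that fit on a bead pool. The
package implements that funnel end to end:

1. **Stage-1 (detection) filtering** — two regimes over per-accession
   call tables. A site survives if its caller quality passes the regime
   threshold (≥25 inclusive, or >30 strict), its pooled coverage lies in
   a data-derived band (min 30 reads and ≤2.5× the mean site coverage;
   or the larger per-allele total below mean + 3 SD with ≥10 reads), the
   minor allele has ≥5 supporting reads, and it is not repetitive
   (interval track, or mean flank k-mer copy number < 2 with k = 31 over
   ±50 bp).
2. **Probe screening** — removal of Infinium type I SNPs (A/T, C/G
   transversions), of probes whose terminal 25-mer is duplicated in the
   genome (canonical k-mer counting), and of candidates with vendor
   design score < 0.9 (< 0.6 for pre-validated markers); multi-source
   merge with conflict-aware deduplication.
3. **Stage-2 filtering and slot selection** — retain exonic,
   ≥5-accession, pseudomolecule-anchored candidates; pin pre-validated
   markers; fill the remaining slots for even physical spacing via
   per-chromosome largest-remainder allocation and nested
   bisection-refinement target points (nearest unused candidate per
   target, ties to the lower position); optional manufacturing dropout.
4. **Evaluation** — genotype QC (GenTrain > 0.4, GenCall-10% > 0.2,
   ≤50% no-calls), MAF = min(p, 1−p) over called samples,
   failed/monomorphic/polymorphic classification, MAF spectra,
   inter-marker gap statistics, two-panel comparison, validation
   cross-tabs, progeny informativeness, and sequencing-coverage
   accounting (coverage = reads × read length / genome size).

A first-class synthetic-data module (`sim_config()`, `simulate_*()`)
generates genomes with genic/repeat structure, Hardy–Weinberg diploid
panels, Poisson-depth call tables and array genotype reports, so the
whole pipeline runs and is tested without any external data.

## Worked example

```r
library(snparray)

cfg <- sim_config(seed = 42, n_chrom = 2, chrom_length = 1e5,
                  n_unanchored = 1, unanchored_length = 2e4,
                  n_snps = 800, n_accessions = 24, n_pools = 6,
                  gene_density = 250)
res <- run_pipeline(cfg, slots = 50, dropout_rate = 0.05)
res$funnel
#>    stage          rule                       removed remaining
#>  1 stage1_regimeA quality                          0       800
#>  2 stage1_regimeA cov_min                        364       436
#>  3 stage1_regimeA cov_max                          0       436
#>  4 stage1_regimeA minor_allele                   117       319
#>  5 stage1_regimeA repeat_track                     8       311
#>  6 stage1_regimeB quality                          0       800
#>  7 stage1_regimeB cov_min                          9       791
#>  8 stage1_regimeB cov_max                          0       791
#>  9 stage1_regimeB minor_allele                   284       507
#> 10 stage1_regimeB copy_number                     13       494
#> 11 merge          dedup                          219       586
#> 12 probe          infinium_II                    198       388
#> 13 probe          tail_duplicated                  5       383
#> 14 probe          design_score                   181       202
#> 15 stage2         accession_support               98       104
#> 16 stage2         exonic_restriction              79        25
#> 17 stage2         pseudomolecule_restriction       2        23
#> 18 selection      even_spacing                     0        23
#> 19 manufacturing  dropout                          1        22
```

Each row is one filtering rule with the candidates it removed and the
count surviving it: the two detection regimes see the same 800 planted
sites through different accession pools (regime A's 30-read pooled floor
is the harshest rule at this coverage), the merged 586 candidates lose a
third to the type-I chemistry screen and half of the rest to the 0.9
design-score threshold, and the exonic restriction dominates Stage 2.
The evaluation of the simulated genotype report on the 22 surviving
array SNPs:

```r
glance(res$classification)
#>       n n_failed n_monomorphic n_polymorphic prop_failed prop_monomorphic ...
#> 1    22        1             0            21      0.0455                0

res$gaps
#>   chrom n_snps n_gaps avg_gap_kb largest_gap_kb n_gaps_over
#> 1 chr1      11     10       8.70           26.9           0
#> 2 chr2      11     10       8.50           24.9           0
#> 3 total     22     20       8.60           26.9           0
```

One SNP fails cluster QC (the generator plants 5% forced failures), the
rest are polymorphic, and the design spaces 11 SNPs per 100 kb
chromosome at an 8.6 kb average gap. Individual stages are ordinary
functions over tibbles (`filter_stage1()`, `merge_dedup()`,
`filter_stage2()`, `select_even_spacing()`, `classify_snps()`, ...) and
chain with the pipe; `compute_maf(c(rep("AA", 6), rep("AB", 3), "NC"))`
returns `0.1667` (3 minor alleles among 18 called). A thin command-line
front end (`run_cli()`; installed at `inst/scripts/snparray`) exposes
`simulate`, `detect`, `design`, `evaluate` and `report` subcommands over
FASTA/GFF3/BED/TSV/VCF/CSV files.

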