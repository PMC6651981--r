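# bulkmark

Single-bulk sequence analysis for rapid discovery of trait-linked
markers from pooled genotyping-by-sequencing (GbS) data of a
mixed-ploidy F1 population — plus everything around it: flow-cytometry
ploidy classification, pooled variant filtering, segregation and
co-segregation statistics, cultivar variant association, and a synthetic
cross/GbS generator (including unreduced-gamete formation) so the whole
pipeline is testable without any external sequencing data.

It is written for plant geneticists and breeders working on
dominant-recessive traits in non-model species where a classical
mapping population fails — e.g. because a heterozygous parent produces
unreduced (2n) pollen and most offspring are triploid, or because GbS
coverage is too sparse for per-individual genotyping.

## The method

Let the trait be controlled by a single locus with recessive allele
*inf* (recessive homozygotes show the trait, e.g. mophead
inflorescences). A pseudo-backcross (mother *inf/inf* × father
*INF/inf*) segregates 1:1 in diploid offspring. Two read pools are
formed: a **reference pool** of diploid plants regardless of phenotype
and a **trait pool** of recessive-phenotype plants regardless of ploidy.
With per-position allele counts `c_a` and coverage `n`, allele
frequencies are `f_a = c_a / n`, and:

1. a position is evaluated only if `min_cov ≤ n ≤ 4 × mean
   coverage` (mean excluding zero-coverage positions; `min_cov` 15 for
   the reference and 8 for the trait pool); an allele is reported only
   if `c_a ≥ 3` and `f_a ≥ 0.18`; only positions with ≥ 2 reported
   alleles are polymorphic;
2. positions with reference-pool alternate frequency in the closed band
   **[0.25, 0.75]** (heterozygous signature) are kept;
3. each is annotated with the trait pool's major-allele frequency;
4. a contig is a **candidate** iff it has ≥ 2 evaluable such positions,
   mean reference-pool frequency inside the band, and mean trait-pool
   major-allele frequency **> 0.95** (near-fixation — the trait pool is
   monomorphic at the trait locus).

Downstream statistics: Pearson χ² segregation tests
(`chi_square_ratio()`), genotype–phenotype co-segregation percentages
under the coupling model valid at any ploidy
(`cosegregation_percent()`), non-flowering association, and cultivar
collection association (`associate_cultivar_variants()`). Ploidy is
classified from flow-cytometric 2C DNA content against a *Pisum
sativum* standard (2C = 9.09 pg): [4.1, 4.5] pg diploid, [6.4, 6.7] pg
triploid, ≥ 7.05 pg higher ploidy.

See the methods vignette (`vignettes/bulk-marker-discovery.Rmd`) for
the model, the synthetic generator's stated world, and all numerical
conventions.

## Worked example

Simulate the full study design — 422 offspring, ~75% triploid via
unreduced (SDR) pollen, one contig in coupling with the trait locus
among 29 unlinked contigs — then run the bulk analysis on the two
simulated pools:

```r
library(bulkmark)

contigs <- simulate_contig_set(n_contigs = 30, n_linked = 1, rng_seed = 101)
cfg     <- cross_config(n_offspring = 422,
                        marker_loci = contig_marker_loci(contigs),
                        rng_seed = 102)
plants  <- simulate_population(cfg)
table(ploidy = plants$ploidy, phenotype = as.character(plants$phenotype))
#>       phenotype
#> ploidy lacecap mophead non_flowering
#>      2      48      28            22
#>      3     154      93            77

pools <- define_pools(plants, rng_seed = 103)   # 99 diploid / 65 mophead
noise <- gbs_noise_model(coverage_mean = 45, coverage_dispersion = 0.8,
                         seq_error_rate = 0.003, dropout_rate = 0.1)
dip <- simulate_pool_pileup(plants[plants$plant_id %in% pools$diploid$plant_ids, ],
                            contigs, noise, rng_seed = 104)
mop <- simulate_pool_pileup(plants[plants$plant_id %in% pools$mophead$plant_ids, ],
                            contigs, noise, rng_seed = 105)

run_bulk_analysis(dip, mop)
#> <bulk_analysis>
#>   diploid pool : 159 positions, mean coverage 46.1
#>   trait pool   : 164 positions, mean coverage 45.9
#>   polymorphic positions (diploid)  : 94
#>   heterozygous-band positions      : 59
#>   evaluable in trait pool          : 42
#>   candidate contigs                : 1
#>
#>    contig n_positions mean_af_diploid mean_af_trait phase_consistent
#> 1 ctg0001           2       0.5518009             1             TRUE
```

The single candidate, `ctg0001`, is exactly the planted coupled contig:
its positions are heterozygous-band in the diploid pool (mean alternate
frequency 0.55) and fixed in the mophead pool (mean major-allele
frequency 1.0). Scoring its marker locus plant by plant:

```r
linked <- contigs$contigs[contigs$contigs$linked_to_inf, ]
cosegregation_percent(plants, linked$locus, "0")
#> [1] 99.7                       # one recombinant in ~350 flowering plants

chi_square_ratio(c(43, 36))     # diploid lacecap : mophead segregation
#> $chi2 0.6202532  $df 1  $p_value 0.4310759  $significant FALSE
```

A 1:1 ratio is not rejected (χ² = 0.62, α = 0.05), as expected for
monogenic dominant-recessive inheritance in the diploid fraction. The
packaged 56-variety collection at the A109A110 marker locus:

```r
path <- system.file("extdata", "cultivar_collection_a109a110.csv",
                    package = "bulkmark")
associate_cultivar_variants(read_cultivar_csv(path))[1:4]
#> $n_distinct  6
#> $variants    "B1" "B2" "B3" "B4" "B5" "B6"
#> $recessive_associated  "B1" "B2"
#> $conflicts   "B2"      # homozygous in 2 lacecap varieties: partial linkage
```

Six variants segregate at the marker; B1 and B2 are homozygous in
mophead varieties (recessive-associated), and B2 is flagged because two
lacecap varieties are also homozygous for it.

## Command line

```sh
Rscript -e 'quit(status = bulkmark::bulkmark_cli())' run-all \
    --seed 7 --out-dir results/run7
Rscript -e 'quit(status = bulkmark::bulkmark_cli())' associate \
    --cultivars inst/extdata/cultivar_collection_a109a110.csv --out assoc.json
```

Subcommands: `simulate`, `classify-ploidy`, `call-variants`, `select`,
`segregation`, `associate`, `run-all`. Logs go to stderr, results to
files; every run writes a `provenance.json` (version, seed, config
hash). Runs with the same seed are byte-identical.

## Pileup TSV format (v1)

```
#bulkmark-pileup-tsv v1
contig	pos	ref	counts
ctg0001	17	A	A:10;C:5
```

1-based positions; allele counts as `allele:count` pairs joined by `;`;
indel tokens allowed as atomic allele symbols. Readers/writers for
minimal VCF 4.2 (`write_vcf()`), BED candidate spans, population CSV and
cultivar CSV are included.
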