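---
title: "Single-bulk GbS marker discovery in mixed-ploidy F1 populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-bulk GbS marker discovery in mixed-ploidy F1 populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkmark)
```

## The problem

In an ornamental outcrosser such as *Hydrangea macrophylla*, the mophead
inflorescence is controlled recessively by a single locus (here called
*INF*): `inf/inf` plants are mophead, carriers of the dominant `INF`
allele are lacecap. Seedlings flower only in their second year, so a DNA
marker that predicts the phenotype (and the zygosity of parents) saves a
year of cultivation. A pseudo-backcross — homozygous-recessive mophead
mother × heterozygous lacecap father — segregates 1:1 at the trait locus
in diploid offspring.

Two complications shape this package. First, such crosses can yield
mostly **triploid** offspring when the father produces unreduced (2n)
pollen, which wrecks classical map construction but not pooled analysis.
Second, genotyping-by-sequencing (GbS) yields sparse, heavily
overdispersed coverage, so per-individual genotypes are unreliable while
**pooled allele frequencies** remain informative.

The pipeline therefore uses a *single trait bulk*: a reference pool of
diploid plants (any phenotype) is contrasted with a pool of mophead
plants (any ploidy). A marker in coupling with the recessive allele is
heterozygous-band in the reference pool and near-fixed in the trait
pool. No second, alternate-homozygote bulk exists in a backcross, so
two-bulk Δ-SNP-index statistics are deliberately out of scope.

## Pipeline and model

For a position with allele counts $c_a$ and coverage $n=\sum_a c_a$ the
allele frequency is $\hat f_a = c_a/n$ (denominator = total position
coverage, including sub-threshold alleles). The stages of
`run_bulk_analysis()` are:

1. **Variant gates** (`call_variants()`): evaluate a position only if
   $n_{\min} \le n \le k\,\bar n_{>0}$, where $\bar n_{>0}$ is the mean
   coverage excluding zero-coverage positions and $k = 4$; report an
   allele only if $c_a \ge 3$ and $\hat f_a \ge 0.18$; emit only
   positions with ≥ 2 reported alleles. Defaults $n_{\min}$ = 15
   (diploid pool) and 8 (trait pool).
2. **Heterozygosity band** (`select_heterozygous_positions()`): keep
   positions whose alternate-allele frequency in the diploid pool lies
   in the closed band $[0.25, 0.75]$.
3. **Trait-pool lookup** (`lookup_trait_pool_frequency()`): annotate
   each kept position with the trait pool's major-allele frequency;
   positions under the trait-pool coverage gate are *unevaluable* and
   excluded from contig means (requiring full coverage would select
   nothing at GbS sparsity).
4. **Contig selection** (`select_candidate_contigs()`): a contig is a
   candidate iff it has ≥ 2 evaluable positions, mean diploid-pool
   frequency inside the band, and mean trait-pool major-allele
   frequency strictly $> 0.95$.

Downstream, `cosegregation_percent()` scores a candidate marker on
individually genotyped plants: predicted mophead iff *every* allele of
the genotype equals the recessive-coupled allele — valid at any ploidy,
which is why the unknown dosage of heterozygous triploids (1/1/2 vs
1/2/2) never matters. `chi_square_ratio()` is the Pearson statistic
without continuity correction. `associate_cultivar_variants()`
summarizes a cultivar collection: variants homozygous in ≥ 1 mophead
cultivar are recessive-associated; those also homozygous in a lacecap
cultivar are flagged as conflicted (partial linkage).
`compute_2c()`/`classify_ploidy()` implement flow-cytometry 2C
estimation against a *Pisum sativum* standard (9.09 pg) with closed
class windows (diploid [4.1, 4.5] pg, triploid [6.4, 6.7] pg, higher
ploidy ≥ 7.05 pg).

## Why the band boundary matters

In a pseudo-backcross, a position with the *candidate signature*
(polymorphic in the diploid pool, monomorphic in the trait pool) forces
the mother to be homozygous for the recessive-coupled base, so its true
diploid-pool frequency is exactly **0.25 or 0.75 — on the closed band
boundary**. Observed frequencies scatter around the boundary, and
roughly half of the signature positions fall outside the band in any one
experiment. That is why the band is closed, why a candidate contig needs
only 2 of its positions inside, and why contigs with many linked SNPs
are recovered much more reliably than contigs with few. The synthetic
linked contig carries 12 signature positions by default — a
multi-kilobase contig in a strongly heterozygous outcrosser (the real
marker contigs were 0.7–5.3 kb and the published marker amplicon alone
held 6 SNPs), which keeps the probability that ≥ 2 positions survive
band sampling high without making the contig atypical.

## The synthetic cross: stated world and its limits

`cross_config()` defaults restate the study design rather than tuning
anything: 422 offspring; unreduced-pollen rate 0.75 (matching the 75.1%
triploid fraction; the paper cannot separate the pollen formation rate
from pollen competition, so this is treated as a free parameter);
restitution mode SDR (the observed triploid mopheads exclude FDR);
maternal gametes always reduced (triploidy was attributed to the male
side); marker–*INF* recombination 0.003 (one recombinant in ~350 plants
reproduces 99.7% co-segregation); a flowering locus at r = 0.10 from
*INF* with the non-flowering allele in coupling with `inf` and
penetrance 0.8, giving the observed excess of recessive-homozygous
non-flowering plants.

Gamete mechanics (`draw_gamete()`): reduced gametes pick a haplotype at
the *INF* anchor and every other locus follows it except with its
recombination fraction (a star topology around *INF* — the paper gives
no map, so no chain of map distances is pretended). Unreduced gametes:
FDR carries both parental alleles at every locus; SDR two copies of one
allele per locus (haplotype chosen with the same recombination
structure, so coupling persists); IMR retains heterozygosity per locus
with probability `imr_het_prob`. Enumerating these outcomes for the
default cross gives P(triploid ∧ mophead) = u/2 under SDR and exactly 0
under FDR; the observed 37/317 ≈ 12% triploid mopheads actually sits
between the SDR and FDR expectations, consistent with partial
heterozygosity retention — the simulator exposes IMR for exactly that
exploration, but SDR remains the default as the simplest mechanism
compatible with the data.

Coverage (`gbs_noise_model()`) is negative binomial with a zero atom.
The published coverage is 98.7 ± 596.76 excluding zeros; a negative
binomial **cannot** reach a conditional CV of 6 at that mean (the real
tail comes from collapsed repeats and wrong mappings), so the defaults
match the conditional mean (~99× over covered positions) and the
variance ≫ mean character, not the extreme tail. Sequencing error
substitutes a read's base uniformly among the other three bases at rate
0.003 by default. The generator emulates pool-level counts only — no
read-level artifacts, no restriction-site placement, no intermediate
phenotypes, no aneuploids. A green end-to-end test therefore
establishes that the *selection logic* behaves as specified under
realistic frequency/coverage noise; it cannot certify behaviour under
repeat-driven coverage blowups or mapping error, which the upper
coverage gate only heuristically removes.

## Numerical conventions

- Intervals: band and ploidy windows closed ("between ... and"),
  fixation strict (">95%"). The upper coverage gate uses the exact
  product 4 × mean, not its rounded instantiation.
- Reported percentages round half away from zero to 1 decimal
  (`round_half_up()`), matching the published 99.7 / 49.9 / 89.6 / 92.2
  convention; base R's banker's rounding is not used.
- Co-segregation denominators include only lacecap/mophead plants with
  genotypes. Including the 3 intermediate plants could not reproduce
  the printed 99.7% (351/355 ≈ 98.9%), so exclusion matches the
  published arithmetic.
- 2C values in the gaps (4.5, 6.4) and (6.7, 7.05) pg return
  `unclassified` with a warning — the study observed none, so any
  forced assignment would be invention.
- Candidate ordering: descending mean trait-pool frequency, then
  descending position count, then contig id — a pure function of input
  content, not row order.
- Frequency denominators always use total position coverage; whether
  the original tool excluded sub-threshold alleles is undocumented, so
  the simpler convention is used and stated.
- All coordinates are 1-based inclusive except BED output (0-based
  half-open at the single conversion point in
  `write_candidates_bed()`).

## Known limitations

- The negative-binomial coverage tail is lighter than real pooled GbS.
- Selection near the 0.25/0.75 boundary is conservative by design;
  contigs whose signature positions all scatter below the band in a
  given experiment are missed (the published pipeline had the same
  property — 69 candidates of which 35 verified).
- `reported_ploidy` is metadata only; no genotype likelihoods are
  computed from pools.
- The cultivar association treats variant labels as atomic; it does not
  model haplotype relationships among them.
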