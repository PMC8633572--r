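# xomap

Crossover detection and recombination-landscape analysis for selfing
populations genotyped on SNP arrays.

In inbreeding cereals such as barley, meiotic crossovers (COs) are scarce
and skewed to the ends of the chromosomes, which constrains breeding. A
standard way to measure how a mutation changes recombination is to self an
F1 hybrid to F2, select F2 plants by genotype class, self them again, and
genotype ~10 F3 plants per F2 family on a dense array: crossovers that
occurred in the F2 meioses segregate in the F3, but only at markers where
the parental F2 was heterozygous. `xomap` implements that analysis as a
tested pipeline:

* **Genotype input and QC** — A/H/B encoding from nucleotide calls given
  both parents' alleles; removal of monomorphic markers, markers with
  skewed allele frequencies (minor allele frequency < 0.10) or more than
  5% missing calls, and of hyper-recombinant individuals (validated CO
  count > 35, a signature of array artifacts).
* **Family masking** — per F3 family, only markers heterozygous in the
  parental F2 are informative; masks come from the F2's own genotypes or
  are inferred from the family's F3s.
* **Crossover calling with a three-marker validation rule** — a state
  switch (A↔H, B↔H single CO; A↔B double CO) is accepted only when the new
  call is maintained over the following three informative markers, which
  suppresses the isolated miscalls that otherwise inflate CO counts.
  Missing calls are skipped transparently.
* **Genetic maps** — per-interval recombination fractions
  (events / informative individuals), Kosambi distances
  d = 25·ln((1+2r)/(1−2r)) cM, per-chromosome and genome map lengths, and
  CO equivalents (genome cM / 50: a selfed individual unites two meiotic
  products).
* **Recombination landscapes** — distal / interstitial / pericentromeric
  zone summaries and 50-bin (~2% physical length) profiles aggregated
  genome-wide by relative position.
* **Population comparisons** — paired Wilcoxon signed-rank tests on
  per-chromosome map lengths (exact for few pairs), chi-squared tests on
  zone proportions, Welch t-tests on percent fertile florets.
* **A meiosis simulator** — forward simulation of the F1→F2→F3 selfing
  design (Poisson COs per gamete, distally weighted CO density, per-class
  rate scaling, genotyping error, missingness) with full truth tracking,
  used to validate the caller: zero false positives on error-free data and
  a ≥ 90% reduction of noise-driven events by the validation window.

## Worked example

Simulate a two-population study (a wild type and a mutant with 1.95× its
recombination rate, 10 F2 families × 10 F3 plants each, 4,000 markers on
seven chromosomes), add genotyping noise, and run the full pipeline:

```r
library(xomap)
library(dplyr)

genome <- sim_genome(n_chrom = 7, n_markers = 4000)
design <- sim_design(n_families = 10, n_f3_per_family = 10,
                     class_scaling = c(WT = 1, recql4 = 1.95), seed = 42)
study <- simulate_pedigree(genome, design)
obs <- inject_noise(study$genotypes, error_rate = 0.001,
                    missing_rate = 0.02, seed = 43)$genotypes

qc <- run_qc(obs, study$marker_map)
qc
#> Genotype QC
#>   markers:     4000 in, 3988 retained (0 monomorphic, 0 skewed, 12 missing-data)
#>   individuals: 200 in, 200 retained (0 hyper-recombinant removed)

masks <- build_family_masks(qc$genotypes, study$f2_genotypes)
events <- call_crossovers(qc$genotypes, study$marker_map, masks) |>
  filter_shared_doubles() |> getElement("events")

intervals <- interval_recombination_fractions(
  events, qc$genotypes, study$marker_map, masks,
  event_assignment = "span", on_high_r = "drop")
rec_map <- map_lengths(intervals)
rec_map
#> Recombination map
#>   WT            929.7 cM  (18.6 CO equivalents)
#>   recql4       1737.6 cM  (34.8 CO equivalents)
```

The mutant map is 1.87× the wild-type map, recovering the simulated 1.95×
rate within sampling error; the genome totals mean that a selfed wild-type
F2 transmits about 19 crossovers to an F3 offspring versus about 35 in the
mutant. The populations differ significantly chromosome by chromosome:

```r
compare_map_lengths(rec_map, "recql4", "WT")
#> # A tibble: 1 × 6
#>   comparison   n_pairs statistic p_value method significant
#>   <chr>          <int>     <dbl>   <dbl> <chr>  <lgl>
#> 1 recql4 vs WT       7        28  0.0156 exact  TRUE

zone_summaries(intervals, study$zone_scheme)
#> # A tibble: 6 × 6
#>   population  zone    cm n_events prop_cm prop_events
#>   <chr>      <int> <dbl>    <dbl>   <dbl>       <dbl>
#> 1 recql4         1 1256.    754.   0.723       0.706
#> 2 recql4         2  317.    208.   0.183       0.195
#> 3 recql4         3  164.    106.   0.0944      0.0991
#> 4 WT             1  665.    370.   0.716       0.711
#> 5 WT             2  155.     88.3  0.167       0.169
#> 6 WT             3  109.     62.3  0.117       0.120
```

Roughly 72% of recombination sits in the distal zone 1 in both
populations — increasing the rate does not move its distribution. Plot
methods are available for the fitted objects: `autoplot(rec_map)` draws
genetic-vs-physical curves per chromosome,
`autoplot(bin_landscape(intervals, chromosome_lengths(study$zone_scheme)))`
the genome-wide 2%-bin landscape, and `plot_zone_summary()` the zone
barplots. `tidy()` and `glance()` return the underlying tibbles.

Published genome map lengths can be fed directly to the arithmetic
helpers:

```r
co_equivalents(c(985.9, 1924.5))        # 19.7 38.5
percent_change(1924.5, 985.9)$pct_change  # 95.19525 -> +95.2%
```

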