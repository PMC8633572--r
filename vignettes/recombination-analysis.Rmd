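---
title: "Measuring meiotic recombination from selfed F3 families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring meiotic recombination from selfed F3 families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xomap)
```

# The measurement problem

`xomap` estimates meiotic crossover (CO) frequency and distribution from a
three-generation selfing design. An F1 hybrid between two inbred parents is
heterozygous at every polymorphic marker. Selfing it produces F2
individuals, each the union of two independent F1 meiotic products; selfing
selected F2s produces F3 families. Genotyping roughly ten F3 plants per F2
family on a dense SNP array reveals the crossovers that occurred in the
**F2 meioses** — but only inside the chromosomal regions where the parental
F2 was still heterozygous, because where the F2 is homozygous the two
haplotypes are identical and recombination between them changes nothing.
On average half the genome is informative in any one family, in long
blocks; pooling ten families per genotype class restores near-complete
coverage, at varying per-locus sample size.

This design is how the recombination effect of meiotic mutants is measured
in large-genome cereals, where crossovers are few (one to two per
chromosome pair per meiosis) and strongly skewed to the distal ends of the
chromosomes.

# From calls to crossovers

## Encoding and quality control

Nucleotide calls are recoded to `A` (homozygous for the first parent's
allele), `B` (second parent), `H` (heterozygous); anything else — third
alleles, or calls at markers where the parents share an allele — becomes
missing (`recode_nucleotides_to_abh()`). `run_qc()` then applies, in a
fixed order:

1. **Monomorphic markers** removed (no segregation, no information).
2. **Skewed markers** removed: the A-allele frequency of a marker is
   `(2 nA + nH) / (2 (nA + nH + nB))`; a biparental F2/F3 expects 0.5, so a
   minor allele frequency below the default 0.10 indicates a failed assay
   or clustering artifact rather than ordinary segregation distortion.
3. **Missing data**: markers with strictly more than 5% missing calls
   removed.
4. **Hyper-recombinant individuals** removed: a preliminary genome-wide
   validated CO count is computed per individual (no family masking), and
   individuals above 35 are discarded. Isolated miscalls mimic double
   crossovers; an individual with an abundance of them is better dropped
   than corrected. The count uses the same validated caller as the main
   analysis so that the filter is reproducible.

Removing individuals can newly expose monomorphic or skewed markers, so
the marker filters run once more afterwards; marker statistics are
per-column, so this always converges.

## Family masking

`build_family_masks()` restricts each family to its informative markers:
those called `H` in the parental F2's own array genotype. When the F2 was
not genotyped, informativeness is inferred from the family's F3s (a marker
with at least two distinct non-missing calls segregates); with six or more
clean F3s the inferred set is nearly exact, and inference can only miss
informative markers, never invent them. Masked markers are *excluded*
from an individual's call sequence — they do not break adjacency — so a
switch across a masked block is still a single event whose interval spans
the block.

## The three-marker validation rule

`call_crossovers()` scans each individual's retained (informative,
non-missing) calls per chromosome. A state switch at a marker is
**validated** only if the following `confirm_window` retained markers
(default 3) all carry the new state, i.e. the minimal validated run is
four markers. A validated A↔H or B↔H switch is one crossover; a direct
A↔B switch is a double crossover (multiplicity 2). An unvalidated short
run is treated as a miscall and masked, and scanning resumes from the
prior state. The event's interval runs from the last old-state marker to
the switch marker, even when missing or masked markers were skipped in
between; its physical position is the integer midpoint of that interval.

At a chromosome end, fewer than three confirming markers may remain. The
default `terminal_policy = "require_all_remaining"` accepts the switch if
every remaining marker (at least one) confirms it; `"reject"` would
silently zero out recombination exactly where it is most frequent, so it
is not the default. Setting `confirm_window = 0` disables validation — a
deliberately naive caller that scores every allele change, used to
quantify what the window buys: on simulated data with a realistic 0.002
per-call miscall rate, validation removes more than 90% of the
noise-driven events (the acceptance suite computes the exact figure).

The rule is conservative by construction and under-counts in two known
ways: crossovers within the window of an informative-region end can lack
confirming markers, and two true crossovers fewer than four informative
markers apart collapse or vanish. Both losses grow with the ratio of CO
density to informative-marker density — this matters when comparing
populations with very different recombination rates (below).

## Family-shared double crossovers are phase changes

One crossover in *each* F1 gamete inside the same marker interval leaves a
short homozygous sliver in the F2 and — crucially — swaps the phase of the
F2's haplotypes beyond it. Every homozygous F3 of that family then shows
the same validated hom↔hom switch between the same flanking markers. These
are genuine crossovers, but from the F1 meioses, not the F2 meioses being
measured. Because independent F2-meiosis double crossovers are private to
single individuals, a multiplicity-2 event recurring at identical flanks
in three or more family members is diagnostic of a phase change;
`filter_shared_doubles()` removes such groups. This is the programmatic
analog of curating such artifacts by hand, and without it both
populations' maps carry a class-independent contamination that biases
between-population ratios toward 1.

# From crossovers to a genetic map

## Recombination fractions

For a pair of adjacent markers, the recombination fraction is the number
of crossover events between them (a double counts 2) divided by the number
of individuals that could have revealed such an event
(`interval_recombination_fractions()`). Two conventions connect events to
intervals:

* **`"midpoint"`** (classical, the default): an event is assigned to the
  adjacent-marker interval containing its physical midpoint, and an
  individual counts toward an interval when both flanking markers are
  informative for its family and non-missing. Exact when informativeness
  is dense.
* **`"span"`** (recommended for family-masked data): the event's
  multiplicity is spread over the map intervals covered by its
  flanking-marker span, proportional to physical length, and an individual
  counts toward every interval its informative span covers. `n_events` may
  then be fractional.

The difference matters because family informativeness is blocky. With
midpoint assignment, all of a family's events across a wide uninformative
block (say, an F2 homozygous across the pericentromere) share one
midpoint, landing in a single central interval whose denominator counts
*other* families — the numerator and denominator describe different
individuals, and the convex Kosambi transform amplifies the spuriously
concentrated fractions. The span convention keeps numerator and
denominator referring to the same individuals and coincides with the
midpoint convention whenever the flanks are map-adjacent (i.e. almost
everywhere at array densities). The acceptance suite's parameter-recovery
check runs the span pipeline.

Fractions at or above 0.5 leave the domain of the Kosambi function. Under
the per-individual denominator (below) they can legitimately arise in
small samples over wide, hot intervals; `on_high_r` either stops
(default) or drops such intervals with a warning, the latter being the
scripted equivalent of manual curation.

## Kosambi distances and map lengths

Distances use the Kosambi map function, `d = 25·ln((1+2r)/(1−2r))` cM,
which accounts for moderate crossover interference and satisfies
`d → 100r` for small `r`; its inverse is `r = tanh(2d/100)/2`, and the
package round-trips the two to machine precision. Chromosome lengths are
interval sums, the genome length the chromosome sum (`map_lengths()`).

Two conventions follow the field's practice for this design and are kept
deliberately:

* `r` divides by **individuals**, not gametes. An F3 individual unites two
  meiotic products, so the resulting map is roughly twice the per-gamete
  map; this matches how such studies report totals. The consequence is
  that `r` is bounded by 1, not 0.5 — see `on_high_r` above.
* **Crossover equivalents** divide genome centiMorgans by 50, reported to
  one decimal: the expected crossover count transmitted to a selfed
  offspring through its two gametes.

`percent_change()` reports both the change `100·(a−b)/b` and the plain
ratio `100·a/b`, because published comparisons mix the two conventions.

## Landscapes

`zone_summaries()` totals centiMorgans and events in the three classical
compartments of large cereal genomes — distal zone 1, interstitial zone 2,
pericentromeric zone 3 — assigning each interval by its midpoint. Zone
boundaries are genome-version-specific and are therefore an input file
(BED-like), never hard-coded; `sim_zone_scheme()` writes a synthetic
symmetric scheme for simulated genomes. `bin_landscape()` divides each
chromosome into 50 equal physical bins (~2% each; edges `i·L/50`,
half-open with the last bin closed) and aggregates genome-wide by bin
index, i.e. by relative position, so chromosomes of unequal length align.
Both summaries conserve the genome total exactly; the tests assert
agreement to 1e−9.

# Population comparisons

`wilcoxon_paired()` compares two populations' per-chromosome map lengths
(the natural exchangeable pairing unit; seven pairs genome-wide, or
chromosome×zone via `compare_map_lengths(unit = "chromosome_zone")`). Zero
differences are dropped; with ≤ 25 untied pairs the exact signed-rank
distribution is used (the suite checks it against full enumeration of all
sign patterns), otherwise the normal approximation with continuity
correction. At seven pairs the smallest attainable two-sided p is
2/2⁷ ≈ 0.0156, and the realized type-I error at α = 0.05 is 6/128 ≈ 4.7%;
the acceptance suite verifies 5% ± 2% calibration over 2,000 null
replicates. `chisq_zone_proportions()` applies Pearson's chi-squared
(no continuity correction) to event *counts* — counts, not centiMorgans,
satisfy the test's sampling assumptions — warning when an expected cell
falls below 1. `fertility_ttest()` compares per-plant percent fertile
florets (mean over scored ears) with a two-sided Welch t-test. No
multiple-testing correction is applied by default, matching the reporting
convention of the studies this design comes from; adjust afterwards with
`p.adjust()` if desired.

# The meiosis simulator

`simulate_pedigree()` generates the full design forward: a fully
heterozygous F1; each F2 from two independent F1 gametes; each F3 from two
independent F2 gametes; genotypes read off at the marker panel, with every
true crossover position, every F2's informative set, and every phase flip
recorded in a truth object for `truth_match()`.

**Crossover model.** Counts per gamete per chromosome are Poisson with
mean (genetic length in cM)/100; positions are i.i.d. from a mixture
density placing `distal_weight` (default 0.7) of crossovers uniformly in
the two distal segments jointly covering `distal_frac` (default 0.25) of
the chromosome, the rest uniform — a deliberately simple emulation of the
distally skewed landscapes of large-genome cereals. There is no chromatid
or chiasma interference. An obligate-crossover floor (`obligate_co`)
exists but is **off by default**: with a floor, a class whose genetic
length is scaled by `s` has realized rate `sλ + e^{−sλ}` rather than `sλ`,
which destroys the proportional rate signature that the class scalings
exist to carry; since class scaling is the simulator's central purpose,
proportionality wins the default.

**Defaults as study conditions.** Seven chromosomes of 650 Mbp; 70 cM per
chromosome per gamete, so a wild-type-like genome reads ≈ 980 cM on the
per-individual scale the pipeline reports, matching the magnitude typical
of this design in barley; 10 families × 10 F3 per class (one of the four
genotype classes of a two-locus suppressor cross: wild type, an
anti-crossover helicase mutant at 1.95×, a crossover-maintenance mutant at
0.37×, their double at 1.71×); 12,000 markers placed uniformly (a
density-weighted placement is available; real arrays are denser in distal
gene space, but quantifying that gradient is out of scope); miscall rate
0.001 per call, dominantly homozygote→heterozygote (the artifact mode that
inflates naive CO counts; opposite-homozygote flips at a tenth of that)
and 2% missing calls. F1 meioses always run at the base rate — the F1 of
such a cross is heterozygous for the mutations and phenotypically normal.

**What it does not emulate.** Crossover interference; segregation
distortion; linkage drag around the selected loci (the real design loses
informativeness entirely near the selected genes); marker-density
gradients by default; tetrad-level simulation and mis-segregation; real
zone coordinates. Passing tests on simulated data therefore demonstrate
the pipeline's correctness under the stated generative model, not the
biological fidelity of that model.

# Known limitations and numerical choices

* **Distal observability.** Crossovers outside a family's outermost
  heterozygous markers are invisible to any estimator of this design, and
  window losses concentrate where crossovers do; the estimated distal
  (zone 1) share therefore sits a few points below the generating
  density's share under 50%-blocky masking. In the fully informative
  regime (an F2-generation population) the zone-1 share matches the
  generating density to well under a point, which is what the acceptance
  suite asserts.
* **Rate-dependent attenuation.** Pair-proximity losses of the validation
  window grow quadratically with the CO-to-informative-marker density
  ratio, so a high-recombination class is attenuated more than the wild
  type. At the full array density used by the acceptance checks
  (11,965 markers) a simulated twofold rate difference is recovered within
  the stated band; at a few thousand markers it lands visibly below two.
* **Determinism.** A seed plus a design reproduces simulations
  byte-identically; report writers emit bit-stable delimited text.
* **Problem sizes in the test suite** were chosen to exercise each claim
  at the smallest scale that keeps sampling noise well inside the asserted
  tolerances: 10,000 random vectors for caller–oracle equivalence,
  2,000-marker studies for false-positive properties, the full
  11,965-marker density for parameter recovery, 2,000 replicates for test
  calibration.
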