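---
title: "Methods: family-wide conserved-region scans, diversity statistics, and amino-acid change classification"
author: "famcons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-wide conserved-region scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`famcons` analyses panels of closely related species — a taxonomic family
such as the cats, great apes, or bovids — whose resequenced genomes have
all been mapped to a single family reference. Three questions are
addressed:

1. **Where is the family jointly depleted of variation?** Genomic windows
   in which all member species are homozygous more often than the
   chromosome as a whole point at regions under shared constraint
   ("highly conserved regions", HCRs).
2. **How diverse is each species?** Per-bp heterozygosity (nucleotide
   diversity) and a per-bp, per-million-year rate of fixed differences to
   the reference (genetic distance) summarise each species' standing
   variation and drift from the reference.
3. **Which protein changes track a phenotype shared across lineages?**
   Alignment columns where a target group of species carries one residue
   that no other species carries (group-specific amino-acid changes,
   AACs), columns where several independent clades converge on the same
   residue, and genes in which every member of a diet group carries a
   function-altering change while no species of another diet group does.

Everything below documents the exact statistical procedure, the tunable
parameters, the synthetic-data generator used to validate the pipeline,
and the numerical and design decisions taken where more than one sensible
choice existed.

## The conservation scan

### Window statistic

Each autosomal contig is tiled with overlapping windows of `bin_size`
(default 100 kb) whose starts sit on a `step_size` grid (default 10 kb).
Windows are anchored at offset 0 of the contig and only windows that fit
entirely inside the contig are tested; there are no partial terminal
windows.

A position is **covered** when it is callable in *every* species of the
panel (intersection of the per-species callable masks). A covered
position is **non-conserved** when at least one species carries a
heterozygous SNV there, and **conserved** otherwise, so that
`n_conserved + n_nonconserved = n_covered` always holds. Two deliberate
choices shape this definition:

* **Zygosity mode (default).** Homozygous-alternate calls do *not* break
  conservation: a site where every species is homozygous — whether for
  the reference base or an alternate — is a site without standing
  variation in the family. An optional **identity mode** additionally
  breaks conservation when species disagree in their homozygous allele
  (including disagreement with the reference); it is off by default and
  recorded in the output metadata when enabled.
* **Indels** are excluded from position counting by default because the
  per-position semantics of a multi-base event are ambiguous; a flag
  (`include_indels`) counts a heterozygous indel as one non-conserved
  position at its anchor base.

A window is **usable** when strictly more than `coverage_fraction`
(default 0.8) of its positions are covered; a window covered at exactly
80 % is excluded.

### Test, correction, calling

Each usable window is compared against its own chromosome with a
two-sided Fisher's exact test on the 2×2 table

|            | conserved | non-conserved |
|------------|-----------|---------------|
| window     | a         | b             |
| chromosome | c         | d             |

where `c`/`d` are position-wise totals over the whole contig, *including*
the tested window (no subtraction: the window is at most a fraction of a
percent of a chromosome, and leaving it in keeps the background identical
for all windows of a contig). The per-chromosome background — rather than
a genome-wide one — absorbs chromosome-scale differences in diversity.

P values from all usable windows of all autosomes are corrected **once,
family-wide** with the Benjamini–Hochberg step-up procedure; applying one
correction matches the single significance rule used to call regions. A
window is called when its adjusted P is strictly below `alpha_adj`
(default 1e-4) *and* — because a two-sided test is also significant for
windows with elevated variation — its non-conserved fraction lies below
the chromosome's (`require_reduced`, on by default; both the sidedness
and the direction filter are recorded in the output metadata).

From each called window `[s, s + bin_size)` only the **middle tile**
`[s + (bin_size − step_size)/2, s + (bin_size + step_size)/2)` (10 kb at
the defaults) enters the HCR set; overlapping and adjacent tiles are
merged. Total HCR length is therefore always a multiple of `step_size`
and invariant to window processing order. Both the merged total and the
unmerged `n_called × step_size` sum are reported, since the two differ
once neighbouring windows are called together.

### Numerical details

* The exact test sums all hypergeometric point probabilities not
  exceeding the observed table's, with the conventional `1 + 1e-7`
  relative tolerance against floating-point ties (the same convention as
  `stats::fisher.test`, with which the implementation agrees to ~1e-14).
  Because the pmf is log-concave, the qualifying cells form two
  contiguous tails; their boundaries are located by binary search and
  summed with `phyper`, making the cost per table O(log support) rather
  than O(support). This matters because a genome scan tests thousands of
  windows whose support reaches 1e5.
* Degenerate tables (any zero margin) return P = 1 instead of erroring,
  so a scan never aborts mid-genome on an empty window or contig; a
  contig with no jointly covered positions is reported with a warning and
  its windows are untestable.
* BH ties are handled by the standard min-cummin step-up formulation
  (deterministic); the implementation delegates to `stats::p.adjust`.

## Diversity statistics

For one species with `n_het` heterozygous SNVs and `n_hom`
homozygous-alternate SNVs on autosomes,

* nucleotide diversity = `n_het / G`
* genetic distance = `n_hom / (G × T)`

with `G` the genome size in bp and `T` the divergence time in million
years. `G` defaults to the summed autosomal contig length — the quantity
is not standardised, so a configuration override is provided. `T` is a
configuration input (crown ages such as 15.9 MY for the cat family,
15.8 MY for the great apes, and 26 MY for bovids are typical values from
divergence-time databases; either a family crown age or a per-species
split time may be supplied). Family summaries are plain arithmetic means
over member species. Heterozygous indels are excluded unless requested.

## Amino-acid change classification

Input is one consensus protein sequence per species per gene, aligned;
within-species polymorphism is assumed resolved upstream. Columns
containing a gap or ambiguity symbol in any involved species are skipped
entirely — the definitions below presume an aligned residue in every
species. Internally columns are 0-based; all reported positions are
1-based to match the "269th residue" convention.

* **Group-specific AAC:** every target species carries the same residue
  `r` and no background species carries `r`. Note the definition is
  symmetric in an absolute sense: when every species *outside* a group
  has moved away from an ancestral residue, the untouched group itself
  becomes "specific" for the ancestral state. This is intended — the
  statistic flags the column, not the direction of change.
* **Convergent AAC:** the union of several pairwise-disjoint target
  clades is unanimous for `r`. By default the stricter reading is used —
  `r` must additionally be absent from all background species — with a
  flag to relax to unanimity only, since unanimity without background
  exclusion is a much weaker notion of convergence.
* **Function-altered gene (per diet group):** every species of the group
  has at least one function-altering AAC anywhere in the gene and every
  species of the other diet groups has none. Function-altering calls are
  consumed from an upstream effect-predictor table (any
  deleterious/damaging call from any tool sets the flag); no prediction
  is performed here.

## The synthetic-data generator

The generator emulates exactly the statistical structure the scan
consumes, with truth files for recovery scoring:

* Per species, each site independently draws a heterozygous SNV with rate
  `het_rate` and a homozygous-alternate SNV with rate `hom_rate`
  (defaults 0.002 and 0.005; within-family resequencing panels show
  per-bp heterozygosities in the 5e-4 to 2.5e-3 range, and the default
  sits in its upper half so that window counts are well away from the
  sparse regime).
* Planted intervals multiply `het_rate` by a suppression factor
  `f ∈ [0, 1)` jointly in all species — the family-shared depletion the
  scan targets.
* Callable masks drop `mask_block`-sized blocks (default 10 kb)
  independently per species at rate `mask_dropout` (default 0.02). With
  five species this yields roughly 75 % usable windows under the strict
  >80 % joint-coverage filter, so the filter is genuinely exercised.
* Protein panels start every column from a shared ancestral residue, add
  independent per-species substitution noise (default 0.01), and plant
  group-specific, convergent, and function-altered-gene columns whose
  residues are chosen absent from all other species; planted columns are
  kept noise-free so the emitted truth is exact by construction. Decoy
  function-altering flags are scattered over non-planted genes but are
  never allowed to complete a full group pattern.

All generators are pure functions of their seed and parameters: reruns
are byte-identical, and every emitted file parses back through the
package's own readers.

**What the generator does not emulate:** linkage disequilibrium (sites
are independent — sufficient because the scan statistic consumes only
per-position zygosity), coalescent genealogies, recombination or
demographic history, alignment error, and depth-dependent callability.
Passing recovery tests on this generator therefore validates the
statistical machinery, not robustness to mapping artefacts or LD
structure in real panels.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:
position-by-position counting loops for the window statistic, full
hypergeometric enumeration and `stats::fisher.test` for the exact test,
the direct step-up formula for BH, per-column brute-force checkers for
the AAC definitions, and planted truth for end-to-end recovery. Scan
validation runs on panels of 5 species × 20 Mb (~1,991 windows at the
default grid — large enough for the family-wide correction to be
meaningful, small enough for a minutes-scale suite); diversity recovery
uses 10-Mb genomes at rates 0.0005–0.0025; protein panels use 50 genes ×
200 columns.

A null panel (no planted intervals, homogeneous rates) yields no windows
with adjusted P < 1e-4, confirming calibration. On panels with 20 planted
200-kb intervals suppressed to `f = 0.05` (placed deterministically at
1-Mb spacing on the step grid), nucleotide-level sensitivity is ~0.8.
Precision settles near ~0.85, and the shortfall from 1 is structural
rather than noise: with ~90k covered positions per window the exact test
is powerful enough to call windows that only partially overlap a
suppressed interval, and the middle tile of such a boundary window can
lie mostly outside it. Every false-positive base in these runs sits
immediately adjacent to a planted interval. The practical reading: HCR
*boundaries* are soft by up to roughly half a window minus half a tile,
while HCR *interiors* and totals are reliable.

## Known limitations

* The middle-tile extraction trades boundary sharpness for simplicity;
  regions shorter than the window size are recovered only partially, and
  edges smear as described above.
* The coverage filter is binary per window; no attempt is made to model
  partially covered positions or depth.
* Identity mode compares homozygous alleles as strings; it does not
  attempt to reconcile multi-allelic representation differences between
  VCFs.
* The per-chromosome background assumes chromosomes are internally
  homogeneous apart from the signal being scanned for; strong megabase-
  scale diversity gradients would locally miscalibrate the test.
* Cross-family gene comparisons rely on a user-supplied shared gene key
  (symbol); no orthology inference is performed.
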