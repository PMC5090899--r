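# famcons

Family-level comparative genomics from multi-species variant panels:
detection of family-wide **highly conserved regions** (HCRs), per-species
**nucleotide diversity** and **genetic distance**, and classification of
**group-specific / convergent / function-altering amino-acid changes**
(AACs) — with a synthetic-data generator that plants known signal so that
every stage can be validated against truth.

## Who this is for

You have several species of one taxonomic family (cats, great apes,
bovids, ...) resequenced and mapped to a single family reference, with
per-species variant calls (VCF) and callable-region masks (BED). You want
to know where the whole family is jointly depleted of heterozygosity, how
diverse each member species is, and which protein changes are private to
a group of species sharing a phenotype such as diet.

## The statistics

**Conservation scan.** Each autosomal contig is tiled with 100-kb windows
on a 10-kb grid. Within a window, a position is *covered* if callable in
every species and *non-conserved* if at least one species is heterozygous
there. Windows covered at more than 80 % are tested against their
chromosome's position-wise totals with a two-sided Fisher's exact test on

```
            conserved  non-conserved
window          a            b
chromosome      c            d
```

P values are Benjamini–Hochberg corrected once across all usable windows
of the family; windows with adjusted P < 1e-4 *and* reduced variation
relative to the chromosome are called, and only the middle 10 kb of each
called window enters the HCR set (merged over windows). Genes overlapping
HCRs by ≥ 1 bp can be partitioned into family-shared and family-specific
sets across several families.

**Diversity.** For a species with `n_het` heterozygous and `n_hom`
homozygous-alternate SNVs on autosomes of total length `G` and divergence
time `T` (MYA):

```
nucleotide diversity = n_het / G
genetic distance     = n_hom / (G * T)
```

**Amino-acid changes.** On one aligned consensus protein per species per
gene: a column is a *group-specific AAC* when all target species share a
residue absent from every background species; a *convergent AAC* when
several disjoint clades are unanimous for a residue absent from the
background; a gene is *function-altered for a diet group* when every
group member has ≥ 1 function-altering AAC in it (flags consumed from an
upstream effect-predictor table) and no other-diet species has any.

## Worked example

Simulate a 5-species panel on a 10-Mb contig with eight planted 200-kb
intervals in which heterozygosity is suppressed to 5 % of background,
then scan it and score recovery against the planted truth:

```r
library(famcons)

starts  <- 4e5 + (0:7) * 1.2e6
planted <- data.frame(contig = "chr1", start = starts, end = starts + 2e5,
                      f = 0.05)
params  <- sim_panel_params(n_species = 5, contig_lengths = c(chr1 = 1e7),
                            het_rate = 0.002, hom_rate = 0.005,
                            planted = planted, seed = 7)
panel   <- simulate_panel(params)
panel
#> <sim_panel> 5 species, 1 contig(s), 1e+07 bp; 8 planted interval(s)

windows <- scan_family(panel$species, panel$contigs)
hcr     <- call_hcrs(windows)
hcr
#> <hcr_set> 12 merged intervals, 1,620,000 bp total (162 windows called;
#> unmerged 1,620,000 bp)
score_recovery(hcr, panel$truth)
#> sensitivity   precision
#>   0.8437500   0.8333333

div <- do.call(rbind, lapply(panel$species, function(cs)
  species_diversity(cs, panel$contigs, divergence_mya = 15.9)))
family_summary(div, "sim_family", divergence_mya = 15.9)
#> <family_diversity> sim_family (5 species)
#>   mean nucleotide diversity: 0.0016966
#>   mean genetic distance:     0.00031431
```

Reading the numbers: 162 windows reach family-wide significance and their
merged middle tiles recover 84 % of the planted bases; precision is
bounded below 1 because windows that only partially overlap a planted
interval are still significant and their middle tiles can stick out past
its edge (see the methods vignette). The mean diversity 0.0017 is the
simulated per-site rate 0.002 diluted by the suppressed intervals, and
the distance 0.00031 is `0.005 / 15.9`.

The same stages run from a YAML configuration over real VCF/BED/FASTA
inputs via `validate_config()` + `run_all()`, or from a shell through the
thin front end `inst/cli/famcons` (subcommands `simulate`, `scan`,
`diversity`, `aac`, `run-all`).

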