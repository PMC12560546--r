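---
title: "Selecting complementary pairs to resynthesize a heterozygous elite genotype"
author: "resyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting complementary pairs to resynthesize a heterozygous elite genotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resyn)
```

## The problem

Many crops — F1 hybrid vegetables, clonal fruit trees, ornamentals — are
grown as a single, partly heterozygous elite genotype.  The resynthesis
breeding strategy reconstructs such a genotype from scratch: self the elite
individual, genotype a large F2 (or later selfing generation) with a modest
panel of well-spaced SNPs, and find two individuals that are (i) highly
homozygous and (ii) genotypically *complementary* — where one is fixed `A`,
the other is fixed `B`.  Crossing such a pair restores heterozygosity
genome-wide, yielding progeny nearly identical to the original elite plant,
into which new traits can meanwhile have been introgressed.

Doing this selection by eye over thousands of individuals is slow and
error-prone.  `resyn` automates it: it screens every pair of individuals in
an ABH-coded genotype matrix, scores each pair's complementarity locus by
locus, filters on heterozygosity and invariable sites, and reports the
ranked candidates together with diagnostics.

## The scoring model

Genotypes are coded per marker as `A` and `B` (the two parental
homozygotes), `H` (heterozygous) and `-` (missing).  For a pair of
individuals, each locus falls into one of ten unordered combination
classes: `A/B`, `A/H`, `B/H`, `H/H`, `A/A`, `B/B`, `A/-`, `B/-`, `H/-`,
`-/-`.  A score table maps every class to a value in $[0, 1]$ and the
pair's **final score** is the sum over the panel:

$$ S(i, j) \;=\; \sum_{m = 1}^{M} w\big(\mathrm{class}(g_{im}, g_{jm})\big). $$

The **ideal score** is the score of a perfectly complementary pair,
$M \cdot w(A/B)$; with all built-in tables $w(A/B) = 1$, so the ideal score
equals the marker count.

Three built-in tables are provided (`score_table("SET1")`, `"SET2"`,
`"SET3"`):

```{r}
dplyr::bind_cols(
  score_table("SET1")["combo"],
  SET1 = score_table("SET1")$score,
  SET2 = score_table("SET2")$score,
  SET3 = score_table("SET3")$score
)
```

`SET1` gives missing-data classes no credit, `SET2` down-weights
heterozygous combinations, and `SET3` — the default — is tolerant of both.
`SET1` and `SET3` differ only on classes involving `-`, so on missing-free
data they induce exactly the same ranking; this identity is exercised in
the test suite.  Note that `SET1` assigns `H/-` the value 0.5 even though it
is the missing-intolerant set; the published table is adopted verbatim
rather than "corrected".  Users can supply any other table as a two-column
TSV via `read_score_table()`.

## Filters

The pipeline applies three filters, in this order:

1. **Individual heterozygosity** (`max_het`, default 0.5).  An F2 is on
   average 50% heterozygous, so the default discards roughly half of the
   population and keeps the most fixed individuals.  The rate is the H
   count divided by the number of *non-missing* calls by default; the
   alternative convention (divide by all markers) is available as
   `het_denominator = "all"`, since published analyses do not always state
   which is used.
2. **Score threshold** (`min_score_fraction`, default 0.8).  Pairs scoring
   below this fraction of the ideal score are discarded immediately,
   before any further annotation, which keeps large runs fast.  The 0.8
   default is chosen so that, e.g., on a 62-marker panel the acceptance
   boundary sits at a score of 49.6.
3. **Invariable sites** (`max_invariable_fraction`, default 0.1).  A locus
   where both members carry the same homozygote (`A/A` or `B/B`) is fixed
   in all their progeny and unrecoverable.  Typical caps range from 0
   (no invariable marker tolerated) to 0.1; note that with a 62-marker
   panel a 1% cap already forces zero invariable loci.  The fraction is
   taken over the full panel size.

All boundaries are inclusive on the accepting side: a rate exactly at
`max_het`, a score exactly at the threshold, or a fraction exactly at the
cap is accepted.  Score comparisons carry a $10^{-9}$ absolute guard so a
boundary like $0.8 \times 62 = 49.6$ is not lost to floating-point
representation of the threshold fraction.  Every discarded individual or
pair is recorded with its reason (`HET_RATE`, `LOW_SCORE`,
`INVARIABLE_EXCESS`), the observed value and the threshold; when the pair
count exceeds `low_score_cap` (default $10^6$) the low-score rejections are
aggregated into a count, because enumerating tens of millions of discarded
pairs serves no one.

## Similarity range

For an accepted pair the similarity range bounds how closely the
resynthesized progeny can match the original hybrid.  With $M$ markers,
$I$ invariable loci and $U$ loci where at least one member is
heterozygous (a heterozygous parent transmits either allele, so the
outcome there is uncertain):

$$ \mathrm{upper} = \frac{(M - I) \cdot 100}{M}, \qquad
   \mathrm{lower} = \frac{(M - I - U) \cdot 100}{M}. $$

For example `similarity_range(50, 4, 10)` gives 72–92%.  A locus counts
once towards $U$ even if both members are heterozygous.

## Recombination counting

When the genotype data are phased along each chromosome (`phased = TRUE` —
a user assertion, since ABH coding cannot certify phase by itself), the
package estimates each individual's recombination-event count and the pair
total.  A genotype sequence constrains the two haplotypes: `A` and `B` fix
both, `H` leaves the orientation free.  The reported count is the *minimum*
total number of haplotype-origin switches over all orientations of the `H`
loci, computed per chromosome.  This reduces to per-transition costs
between consecutive non-missing calls — `A`↔`B` costs 2 (both haplotypes
switch), `A`↔`H` and `B`↔`H` cost 1, equal classes including runs of `H`
cost 0 — with nothing counted across chromosome boundaries and missing
calls skipped.  The reduction is verified in the test suite against an
exhaustive enumeration oracle on all sequences up to 12 markers.  Counting
`A`↔`B` as two events follows from summing over both haplotypes of the
pair; pairs with the fewest total events are preferable among equal
scores, because every breakpoint implies a homozygous segment in the
resynthesized hybrids.

## The F2 simulator

`simulate_f2()` generates the study conditions end to end so the whole
pipeline is testable without external data.  Each individual is the union
of two independent gametes from a fully heterozygous F1.  Meiosis follows
the Haldane model: the crossover count on a chromosome of length $L$ cM is
Poisson with mean $L/100$, crossover positions are uniform, the starting
parental origin is fair, and the origin flips at each crossover — no
interference and no obligate chiasma, the standard no-assumption default.
Adjacent-marker recombinant fractions therefore follow the Haldane map
function $r = (1 - e^{-2d})/2$, and per-marker genotypes segregate 1:2:1.
Markers are equidistant at positions $(i + 0.5)/m \cdot L$, leaving no
marker exactly on a chromosome end where position ties would arise.  The
reference configuration mirrors a realistic scale-up scenario: 10
chromosomes of 100 cM carrying 50 markers each, populations up to 10,000
individuals, optionally with 5% of calls masked as missing
(`inject_missing()`).  The exact phased gametes are returned, so simulated
crossovers can be compared against genotype-based recombination estimates.

What the simulator does *not* emulate: genotyping errors other than
missingness, segregation distortion, crossover interference, non-uniform
marker spacing, and selfing generations beyond the F2.  Green tests on
simulated data therefore validate the machinery and its statistical
behaviour under Mendelian assumptions, not the idiosyncrasies of any real
population.

## The pair engine and determinism

All $k(k-1)/2$ pairs of retained individuals are evaluated.  Internally the
genotype matrix is expanded into per-class indicator matrices so that pair
scores, invariable counts and heterozygous-union counts reduce to a handful
of matrix products — a 12.7-million-pair run over 500 markers completes in
well under a minute on one core.  The pair-index space is split into
contiguous chunks of roughly `total / (8 * workers)` pairs; chunks are
evaluated independently (forked workers when `workers > 1`), and since the
chunk results are concatenated in index order and the final ranking is a
global sort, the output is bit-identical for any worker count or chunking.
Ties on the final score are broken by ascending total recombination count
(phased runs), then by the canonical pair label (`id1 < id2`,
C-locale ordering).

## Outputs

`write_selection()` produces the four run products under one prefix: the
accepted-pairs TSV (8 columns, or 11 when phased: ids, final score,
invariable count, per-member heterozygosity, similarity bounds,
recombination counts), the annotated discards TSV, a human-readable log
that restates every applied argument including defaults, and a
genotype-profile figure of the top ten pairs (`.png` and `.pdf`), with
markers grouped into chromosome panels and cells coloured by call class.
A thin command-line wrapper with `select`, `simulate` and `score-pair`
subcommands ships in `inst/cli/resyn.R`.

## Numerical and design choices

* Problem sizes in the test suite are the package's own choices for quick,
  reliable statistical checks: full 10,000-individual simulations are used
  where only counting or filtering is involved, pair evaluation properties
  are checked on a 1,000-individual subsample, and Monte-Carlo checks use
  10,000 gametes with 3-standard-error bands (4 when hundreds of
  per-marker checks run simultaneously).  The acceptance script runs the
  full 10,000-individual evaluation.
* The genotype file's header row is mandatory; the marker file may carry
  an optional header, detected by checking whether the first line's
  chromosome label ever reappears.
* Degenerate inputs fail loudly: empty matrices, all-missing individuals
  (heterozygosity undefined), unknown call symbols (including lowercase),
  duplicated ids, ragged rows, split chromosome blocks, and marker-order
  disagreements between the two input files are all hard errors naming the
  offending position.

## Limitations

The package selects *pairs within one genotyped generation*; the
surrounding breeding scheme — advancing selfing generations, introgression
backcrosses, linkage-map construction, phasing, and imputation of missing
calls — is out of scope.  Missing data degrade selection quality; if the
missing fraction is substantial, impute before running the pipeline.
Recombination counts are minimal estimates from marker data: double
crossovers between adjacent markers are invisible, which is why marker
panels should cover chromosomes at 10–15 cM spacing.
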