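---
title: "Pedigree-aware phasing and crossover detection in multiparental populations"
author: "magicphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-aware phasing and crossover detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magicphase)
```

## The problem

Multiparental (MAGIC) populations descend from a panel of inbred, homozygous
founder lines through a fully recorded pedigree. Because every individual's
parents are known and genotyped, the two allele sequences each individual
inherited can be reconstructed deterministically, and every switch between
the grandparental haplotypes along a homolog marks a recombination event in
one specific meiosis. The difficulty in practice is genotyping error: a
single miscalled SNP can fabricate a spurious haplotype block and with it a
pair of false crossovers. `magicphase` implements a forward,
generation-by-generation pipeline that phases by family-trio Mendelian
segregation and then defends the inferred haploblocks against genotyping
error by requiring a minimum number of *informative* alleles per block.

## The pipeline

**Phasing.** Founders (G0) are required to be homozygous; a heterozygous
founder locus is a hard error naming the individual and marker. G1 phases
follow directly from the founder genotypes: the paternal allele is the
father's allele, the maternal allele the mother's, and a locus with a
missing founder genotype is wholly unresolved (`MD`) — we deliberately do
not phase one homolog of a half-known locus, since the trio machinery
downstream needs complete allele pairs. From G2 on, each offspring genotype
is compared with its parents' genotypes: a homozygous offspring a/a is
phased when both parents can transmit a, otherwise flagged as a Mendelian
error (`ME`); a heterozygous offspring is phased when exactly one assignment
of its two alleles to the parents is Mendelian-consistent; when all three
genotypes are heterozygous the locus is a triple heterozygote (`TH`), and
any missing genotype gives `MD`. These three states are data, not errors —
they propagate into the origin mosaic as unresolved symbols.

Mendelian consistency is checked against parental *genotypes*, not phases.
Where a parent's genotype is missing but its phase was completed by
imputation in the previous generation, the phase-derived allele pair stands
in for the genotype; this is precisely how phase imputation benefits later
generations.

**Grandparental origins.** Each phased allele of an offspring homolog is
compared with the transmitting parent's phase. If the parent is
heterozygous and phased there, the allele identifies the parental homolog it
came from — origin `P` (the parent's own paternal homolog) or `M` — and the
locus is *informative*. Alleles descending from a homozygous parent are
noninformative (`*`); unphased offspring loci are `?` (TH/MD) or `!` (ME).
Only directly assigned loci ever count as informative; imputed origins never
do, which is what gives the filter below its meaning.

**Haploblock completion and filtering.** Runs of noninformative loci flanked
by the same origin adopt that origin; runs at a chromosome border adopt the
single adjacent origin; runs between different origins stay unassigned and
become the reported recombination interval. The filter then removes every
haploblock with fewer than `min` informative alleles, re-completes from the
surviving informative loci, and repeats until no block falls below the
threshold. We iterate to this fixpoint deliberately: removing a block can
merge its two neighbours into a new block whose own count has never been
checked, and a single pass would leave the result dependent on scan order.
At the fixpoint the operation is idempotent (property-tested), and `min = 1`
is exactly the identity. A removed block flanked by two different origins
leaves its loci permanently unassigned, which widens the event interval
rather than inventing an origin.

**Imputation and correction.** Once a locus's origin is known, the allele
carried by the parent's haplotype of that origin can fill the unresolved
phase: `imputeTHonly` fills only TH loci, `imputeAll` also MD and ME,
`imputeNot` nothing. Imputation can contradict the observed genotype —
deliberately so at ME loci, where the genotype itself is suspect, and
accidentally at TH loci whose origin was bridged across an undetected
double crossover. The corrections target the accidental case:
`correctFalseHom` undoes the two imputations at any locus whose genotype is
heterozygous but whose homologs were imputed to the same allele, and
`reImpute` fills a heterozygous-genotype locus with exactly one resolved
homolog using the remaining genotype allele. `correctAll` chains both;
`imputeNot` forces `correctNot`. When `cor` is omitted we default to the
recommended companions (`imputeTHonly`/`correctFalseHom`,
`imputeAll`/`correctAll`).

A consequence worth stating precisely: the invariant "resolved allele pairs
equal the genotype" holds unconditionally for directly resolved loci at
every stage, and for imputed loci after correction on error-free data; on
data with genotyping errors, imputed pairs at former ME loci may differ from
the (erroneous) observed genotype — that is the error robustness working as
intended, and the pipeline's internal consistency assertion excludes exactly
those loci.

**Events, classification, founders.** Adjacent blocks of different origins
yield one event spanning from the last locus of the left block to the first
locus of the right block (closed interval), so the true breakpoint lies
strictly inside the reported bp interval. With a physical threshold
`thr > 0`, an event is a gene conversion when the *smaller* of its two
flanking block lengths is below `thr` — a conversion tract manifests as one
short interior block, and taking the minimum flags both of the transitions
that delimit it; `thr = 0` classifies everything as crossover. Finally,
origins are lifted recursively through the pedigree (an origin-`P` allele
maps to the father's paternal homolog at the same locus, bottoming out in
the founder lines at G1), so every assigned allele traces to a founder.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min` | 1 | minimum informative alleles per haploblock; scalar or per-generation map (`"2/5/3"` = G2:2, G3:5, G4:3). 1 disables filtering; higher values trade recall for precision and are worth raising in generations with high Mendelian-error rates |
| `imp` | `imputeNot` | phase imputation of unresolved loci (`imputeTHonly`, `imputeAll`) |
| `cor` | companion of `imp` | post-imputation correction of triple heterozygotes |
| `thr` | 0 bp | flanking-block length below which an event is a gene conversion |

## The simulator

`simulatePopulation()` generates the study conditions the package is tested
under: homozygous founders with per-locus minor-allele frequencies drawn
uniformly from 0.1–0.5 (independent across loci), a circular chain-crossing
pedigree in which cross j of each generation mates an offspring of cross j
with one of cross j+1 — founder genomes accumulate along the chain and mates
are never full sibs, as in real chain-crossed MAGIC designs — and meioses
with a Poisson number of crossovers (default mean 1.5 per chromosome, within
the 0.7–1.5 range reported for *Brassica napus*) placed uniformly in bp
without interference. Genotyping errors flip one uniformly chosen allele of
a genotype with the configured per-generation probability, by default in
G2 and later (G0/G1 calls derive from inbred founders and are clean by
construction). Every meiosis records its true breakpoints and every homolog
its true founder of origin.

What the simulator does *not* emulate: linkage disequilibrium among
founders (alleles are i.i.d. across loci — irrelevant to trio phasing,
which is per-locus), crossover interference and position hotspots, locus
dropout/missingness patterns of real arrays, and error modes that are
correlated between markers (e.g. sample swaps). Passing tests therefore
demonstrate correctness of the phasing/origin/filter logic and robustness
to *independent* miscalls, not performance under structured artefacts.

Two idealizations matter when reading the test results. First, a double
crossover falling entirely inside a noninformative run is invisible; the
completion step imputes the flanking origin across it, so founder
assignments agree with the simulated truth at ≥98% of assigned loci rather
than all of them, and such pairs of breakpoints depress recall slightly.
Second, crossovers of founder (G0) meioses occur between identical
homozygous homologs and are biologically undetectable; evaluation therefore
scores the meioses producing G2+ individuals only.

## Numerical and degenerate-input choices

* Half-missing genotypes (one allele 0) are promoted to fully missing.
* Map rows out of bp order are sorted with a warning; ties on one
  chromosome are rejected.
* Completion and filtering never cross chromosome boundaries.
* A homolog with no informative locus stays wholly unassigned.
* Zero detected events make resolution (and the filtered percentage when
  the raw run is empty) `NA`, never a division by zero.
* Matching of true breakpoints to detected intervals uses closed-interval
  inclusion; breakpoints are continuous, so boundary equality has measure
  zero in simulation but the convention matters for replicated runs.
* Event intervals report `end_idx - start_idx` SNP intervals — the number
  of candidate breakpoint positions — as the denominator of resolution.

## Problem sizes

The shipped tests run populations of 8 founders, chain-crossed to G3
(56 individuals) with 300–500 loci on one chromosome: 50 replicates for the
stage-by-stage consistency property, 20 for each of the precision/recall,
monotonicity and filtering-gain properties, 10^4 meioses for the Poisson
calibration, and exhaustive enumeration of all single-locus trio-chain
genotype configurations and all origin sequences up to length 6 against
brute-force oracles. These sizes were chosen as the smallest at which the
stochastic properties are stable across seeds.

## Limitations

* Both parents must be genotyped (or founders): half-sib families and
  single-parent duos are skipped with a warning, not phased.
* Strictly biallelic markers on the 0/1/2 code; no VCF or binary PLINK.
* No probabilistic origin posteriors: origins are hard assignments, and
  confidence comes from the informative-allele filter rather than from a
  recombination probability.
* No genetic-map (cM) estimation; the crossover map is a per-SNP-interval
  count table.
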