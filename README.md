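# magicphase

Pedigree-aware phasing and crossover detection in multiparental (MAGIC)
populations, robust to genotyping errors.

## What it does

MAGIC populations descend from a panel of inbred, homozygous founder lines
through a fully recorded pedigree. With SNP genotypes for parents and
offspring, each individual's two homologs can be reconstructed
deterministically by family-trio Mendelian segregation, and every switch in
*grandparental origin* along a homolog marks a crossover (CO) in one
specific meiosis. The catch is genotyping error: one miscalled SNP can
fabricate a spurious haploblock and two false crossovers.

`magicphase` implements the full forward pipeline:

1. **Phasing** generation by generation: founders (G0) must be homozygous,
   G1 phases follow directly from the founder genotypes, later generations
   are phased by trio segregation. Unresolvable loci are tagged `TH`
   (all three trio members heterozygous), `MD` (missing data) or `ME`
   (Mendelian error).
2. **Origin inference**: each phased allele is assigned to the transmitting
   parent's paternal (`P`) or maternal (`M`) homolog where that parent is
   heterozygous and phased — an *informative* allele.
3. **Haploblock completion and filtering**: noninformative runs between
   same-origin anchors are imputed; every haploblock with fewer than `min`
   informative alleles is removed and the mosaic re-imputed, iterated to a
   fixpoint. This is the error defence: false blocks from miscalls rarely
   accumulate `min` informative alleles.
4. **Optional phase imputation/correction** (`imputeTHonly`/`imputeAll` +
   `correctFalseHom`/`reImpute`/`correctAll`) so resolved phases benefit the
   next generation.
5. **Event detection and classification**: origin transitions become
   recombination events with closed SNP/bp intervals, classified CO vs gene
   conversion by a flanking-block length threshold `thr`; alleles are traced
   back to founder lines.

Detection quality is scored as precision = m/d and recall = m/t, where d is
the number of detected events, t the number of simulated breakpoints and m
the number of detected events containing at least one true breakpoint
(an event containing two counts once), F1 = 2PR/(P+R), resolution =
1/median(SNP intervals per event) and adjusted resolution = precision x
resolution. A meiosis-level simulator (Poisson crossovers, allele-flip
genotyping errors, full truth) makes the whole method testable without any
external data, and a Mendelian-error/genotyping-error calibration curve
links the two rates.

## Worked example

```r
library(magicphase)

sim <- simulatePopulation(seed = 42, depth = 3, nLoci = 500, geRates = 0.05)
sim$geno
#> MagicGeno: 56 individuals, 500 loci on 1 chromosome(s)
#>   generations: G0=8 G1=16 G2=16 G3=16
#>   missing genotypes: 0.00%

res <- phasePopulation(sim$geno, magicConfig(min = 3, imp = "imputeTHonly"))
res
#> MagicResult: 56 phased individuals, 88 recombination events
#>   settings: min=3 imp=imputeTHonly cor=correctFalseHom thr=0
#>   classes: CO=88

head(events(res)[, c("id", "homolog", "start_marker", "end_marker",
                     "start_bp", "end_bp", "class", "founder_left",
                     "founder_right")], 3)
#>       id homolog start_marker end_marker start_bp end_bp class founder_left founder_right
#> 1 G2_1_2       P     snp00141   snp00142   252651 257965    CO           F2            F1
#> 2 G2_1_2       P     snp00331   snp00335   627937 636968    CO           F1            F2
#> 3 G2_1_2       M     snp00088   snp00093   145786 163234    CO           F3            F2

raw <- phasePopulation(sim$geno, magicConfig(1, "imputeNot"))
round(performanceReport(res, sim$truth, raw), 3)
#>   precision recall    f1 resolution adjusted_resolution n_detected n_true n_matched pct_filtered
#> 1     0.807  0.664 0.728      0.154               0.124         88    107        71       85.761
```

Read: at a 5% genotyping-error rate in G2/G3, the `min = 3` filter discarded
85.8% of the raw detected events; of the 88 events kept, 71 contain a true
simulated breakpoint (precision 0.81), covering 66% of the 107 true
crossovers; a typical reported interval spans ~6.5 SNP intervals
(resolution 0.154). Each event row names the meiosis (individual plus
paternal/maternal homolog), the flanking markers and the founder lines on
either side of the transition. The same run with `min = 1` has precision
0.14 here — the filter is what makes detection usable at realistic error
rates.

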