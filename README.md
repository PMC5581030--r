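# melanochip

Computational pipeline for a low-density **hydrogel biochip** that genotypes
39 recurrent somatic driver mutations in melanoma — hotspots of *BRAF*,
*NRAS*, *KIT*, *GNAQ*, *GNA11*, *MAP2K1* and *MAP2K2* — from
allele-specific hybridization images. The wet assay combines a locked
nucleic acid (LNA) PCR clamp, which suppresses wild-type amplification and
so enriches the mutant allele, with hybridization of fluorescently labeled
PCR product to duplicated allele-specific gel-drop probes. This package
implements everything downstream of (and, via simulation, upstream of) the
scanner: the mutation panel and its HGVS-level validation, a ground-truthed
forward simulator of clamped PCR, probe hybridization and 16-bit chip
images, marker-based grid location and spot quantification, the
signal-normalization and mutation-calling rule, limit-of-detection (LoD)
estimation from dilution series, and cohort-level frequency, cross-method
concordance and association statistics.

It is intended for developers and evaluators of clamp-enriched
hybridization genotyping assays who need a fully testable in-silico version
of the analysis chain.

## The model

Each gel spot *m* yields an interior intensity *I*<sub>m</sub> (mean pixel
value over the spot interior), a local background *B*<sub>m</sub> (median
over a surrounding annulus) and the camera dark current *I*<sub>0</sub>.
The normalized signal is

> *J*<sub>m</sub> = (*I*<sub>m</sub> − *I*<sub>0</sub>) / (*B*<sub>m</sub> − *I*<sub>0</sub>)

Duplicate spots of the same probe are averaged, and signals are compared
within a **locus group** — the wild-type probe plus the mutant probes of
one clamped amplicon. A mutation is assigned when

> *J*<sub>mut</sub> > *J*<sub>wt</sub>  and  *J*<sub>mut</sub> ≥ 2,

the second condition being the signal-to-background criterion (threshold
exposed as `min_sbr`). Among multiple qualifying probes the maximal-*J*
probe wins; exact ties are no-calls. The LoD of a dilution series is the
smallest mutant fraction called in every replicate, with no false call
allowed in the 0% replicates.

The simulator models the clamp as capped geometric growth with
allele-specific per-cycle efficiencies (mutant ≫ clamped wild type), probe
signals as a linear gain over product copies with within-group
cross-hybridization, and spots as soft-edged disks with multiplicative
log-normal spot noise plus additive Gaussian pixel noise. See the methods
vignette (`vignettes/biochip-genotyping.Rmd`) for parameter meanings,
defaults and calibration rationale.

## Worked example

Simulate a 5% *BRAF* V600K sample, render the chip, and call it:

```r
library(melanochip)
panel  <- defaultPanel()
layout <- buildLayout(panel)
truth    <- sampleTruth(genotype = "mut03", mutant_fraction = 0.05) # BRAF V600K
products <- simulateClampPcr(truth, panel)
spots    <- simulateSpotTruth(products, layout, hybParams(), seed = 11)
chip     <- renderChipImage(spots, layout, imageParams(seed = 12))
chip
#> ChipImage: 201 x 261 px, 16-bit, range [487, 34015]
report <- callChip(chip, layout, panel, sample_id = "demo")
report
#> SampleReport demo - 11 groups; called: BRAF V600K
calledMutations(report)
#>   gene protein_change           cdna_change group_id probe_id   margin
#> 1 BRAF          V600K c.1798_1799delGTinsAA BRAF_600    mut03 4.893784
```

The chip was located by its four corner markers, each of the 104 occupied
spots quantified, probe duplicates averaged, and the V600K probe cleared
both parts of the calling rule in the BRAF group with a margin
*J*<sub>mut</sub> − *J*<sub>wt</sub> ≈ 4.9; the other ten groups stayed
wild type.

Cohort accounting over the packaged 253-patient record reconstruction:

```r
summarizeCohort(referenceCohort(), method = "biochip")
#> Cohort summary (biochip): 253 samples, 177 (70.0%) mutated, 76 (30.0%) WT
#>    gene   n  pct
#>    BRAF 129 51.0
#>    NRAS  45 17.8
#>     KIT   6  2.4
#>    GNAQ   4  1.6
#>   GNA11   2  0.8
#>  MAP2K1   2  0.8
```

A command-line wrapper with `simulate`, `quantify`, `call`, `lod`,
`summarize`, `concord` and `validate-panel` subcommands is installed at
`inst/scripts/melanochip`.

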