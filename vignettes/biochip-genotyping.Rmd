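---
title: "Methods: hydrogel-biochip genotyping of melanoma driver mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrogel-biochip genotyping of melanoma driver mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melanochip)
```

## The assay and what this package computes

The assay genotypes 39 recurrent somatic hotspot mutations of *BRAF*,
*NRAS*, *KIT*, *GNAQ*, *GNA11*, *MAP2K1* and *MAP2K2* on a low-density
microarray of polyacrylamide gel drops, each drop carrying one immobilized
allele-specific oligonucleotide probe. Sensitivity to low mutant-allele
fractions comes from a locked nucleic acid (LNA) PCR clamp: a
non-extendable oligomer complementary to the wild-type sequence that
suppresses wild-type amplification, so mutant template is preferentially
amplified before it ever reaches the chip. Fluorescently labeled product
hybridizes to the probes; a CCD image of the chip is the raw measurement.

`melanochip` implements the computational chain around that measurement:

1. **panel** — the 39-mutation catalog, its HGVS coding-change grammar and
   codon-level label validation, and the deterministic chip layout;
2. **synthsim** — a ground-truthed forward simulator (clamped PCR →
   hybridization → 16-bit image) so that every downstream stage is testable
   without instrument data;
3. **imaging** — marker-based grid location and per-spot quantification;
4. **calling** — the normalized-signal decision rule and limit-of-detection
   (LoD) estimation;
5. **cohort** — frequency accounting, cross-method concordance with
   arbitration, and association statistics;
6. a thin CLI chaining the stages reproducibly.

## Panel and layout

Panel entries are rows of `inst/extdata/panel.tsv` (gene, protein change,
HGVS c. change, locus group). The HGVS subset in use — single-base
substitutions, deletion–insertions (also in the `c.625_626CA>TT` range
spelling, which is canonicalized to `delins` form), and insertions — is
parsed by `parseHgvsC()`; `parseHgvsC()` then `formatHgvsC()` is the
identity on all packaged strings.

`validateEntry()` checks that each entry's coding change, applied to a
packaged coding-strand reference window and translated with the standard
genetic code, reproduces the protein label (reference amino acid, codon
number, alternate amino acid). The windows in
`inst/extdata/codon_contexts.tsv` are short frame-aligned CDS fragments
around the interrogated codons; the BRAF 594–604, NRAS 8–17 and KIT
555–578 windows follow the real coding sequences, while flanking codons of
the shorter windows are synthetic filler chosen to be consistent with every
panel label. They exist to validate labels, not to serve as a reference
genome.

Locus groups pair one wild-type probe with the mutant probes of one clamped
amplicon. The published assay description enumerates the amplified loci but
not an explicit group list, so the package fixes eleven groups (BRAF 600, NRAS
12/13, NRAS 61, KIT 557/559, KIT 576, KIT 642, KIT 816, GNAQ 209, GNA11
209, MAP2K1 121/124, MAP2K2 57/60), one wild-type probe each. `buildLayout()`
duplicates every probe onto two consecutive spots (2 × (39 + 11) = 100
spots), adds four bright corner markers, and fills a configurable grid —
default 9 × 12, pitch 20 px, spot radius 6 px — giving 104 occupied spots.
The published figure's exact drop coordinates are not reproduced; the
layout is a package convention, serialized to a JSON manifest.

## The forward simulator

**Clamped PCR.** No kinetic parameters are published, so the simplest
monotone two-efficiency model is used: after $c$ cycles a locus group
carrying the spiked mutation at template fraction $f$ with input $N_0$
copies yields

$$\mathrm{mut} = \min\!\big(\mathrm{cap},\; f N_0 (1+e_m)^c\big), \qquad
  \mathrm{wt} = \min\!\big(\mathrm{cap},\; (1-f) N_0 (1+e_w)^c\big),$$

with mutant efficiency $e_m$ strictly above the clamped wild-type
efficiency $e_w$. Groups whose locus is wild type in the sample see the
full template as wild type. Defaults: $N_0 = 10^4$ template copies,
$c = 35$ cycles, $e_m = 0.9$, $e_w = 0.2$, cap $10^{12}$ copies. For any
$f \in (0,1)$ the product ratio strictly exceeds the template ratio — the
clamp enriches — and this is tested as a property.

**Hybridization.** A probe's noiseless signal above the optical background
$\bar B$ is $\mathrm{gain} \times \sum_a w_{pa}\,\mathrm{copies}_a$, where
$w$ is 1 for the probe's own allele, `crosshyb` (default 0.05) for other
alleles of the same group, and 0 across groups. The nested second-round
PCR and Cy5-dUTP label incorporation of the wet protocol are absorbed into
the single `gain` parameter (default $2 \times 10^{-9}$ counts/copy)
rather than modeled separately. Spot-to-spot variability is multiplicative
log-normal with CV 10% — standard array noise structure — applied to the
background-subtracted hybridization component (it models probe-density and
drop-volume variation, which scale the amount of bound material, not the
optical background). Duplicated spots draw independently.

**Imaging.** Spots are soft-edged disks (edge 1 px) whose interior equals
the assigned intensity before additive Gaussian pixel noise (sd 3 counts);
background pixels sit at $\bar B = 500$ counts with dark current
$I_0 = 100$ counts; corner markers are fixed at 30000 counts; images are
16-bit with clipping warnings. Every stochastic step demands a seed and
records it in the image metadata and truth manifest.

**Calibration.** The only quantitative sensitivity constraint published
for the assay is its 0.5% LoD on a *BRAF* V600E dilution series (0, 0.25,
0.5, 1, 5, 10, 50, 100%, triplicate). The default `gain` is therefore set
so that the expected dark-corrected spot signal is about 1.4× the
dark-corrected background at the 0.25% fraction and about 2.85× at 0.5%.
Against the calling threshold $J \ge 2$ this places both fractions ≈3.5
standard deviations of the 10% spot noise away from the decision boundary
— on the failing and passing side respectively — so the simulated series
reproduces a 0.5% LoD with very high probability for any seed, while 0.25%
essentially never passes in all three replicates. This is a repository
convention calibrated to the printed LoD, not a fit to published signal
magnitudes (none are printed; the published sensitivity figure is
graphical).

The cohort generator (`generateCohort()`) draws one driver from the
mutually exclusive genes (*BRAF*/*NRAS*/*KIT*/*GNAQ*/*GNA11*) per patient
at the published per-variant frequencies, lets *MAP2K1/2* variants ride on
*BRAF* carriers, thins true calls into per-method observed calls with a
configurable false-negative rate, and draws covariates from a simple model
(sex ~ Bernoulli(140/237 female), age ~ Normal(53.7, 16.4) years, subtype
categorical at the published margins).

**What the simulator does not emulate:** FFPE degradation artifacts,
multiplex primer interactions, probe thermodynamics and LNA placement,
spatial gradients or flat-field error, comet/doughnut spot morphologies,
and inter-chip batch effects. Passing tests therefore demonstrate the
correctness of the computational chain under a clean forward model, not
the wet-lab performance of the assay on real tissue.

## Grid location and quantification

`locateGrid()` thresholds at half the image maximum (halving further if a
saturated spot swamps the markers), labels connected bright components
(EBImage), assigns one blob to each image corner, and least-squares fits an
affine map from grid (row, col) to pixel coordinates through the four
marker centroids. The fit residual is reported; above 2 px all spots are
flagged `weak-marker`. Fewer than four assignable blobs is a grid failure.

The scanner software's internal region and background definitions are not
published, so the package fixes: interior = disk of 0.6 × nominal radius
(mean), background = annulus 1.2–1.8 × radius (median, robust to neighbor
bleed), excluding pixels inside a neighboring spot's nominal disk. Dark
current comes from image metadata when present, else the mean of the
darkest 1% of pixels (dark current is a camera property, not a spot
property). Saturation is flagged when more than 1% of interior pixels sit
at the bit-depth maximum; `B_m ≤ I0` flags the spot unusable. On noiseless
synthetic images the render→quantify round trip recovers assigned
intensities within 2% (tested; in practice it is exact up to integer
rounding).

## Calling rule and LoD

Per spot, $J_m = (I_m - I_0)/(B_m - I_0)$; per probe, $J$ is the mean over
surviving duplicates; per group, $J$ values are also reported normalized to
the group maximum (the display convention of the assay's histograms). The
published rule assigns a mutation when $J_{mut} > J_{wt}$ and
"$J_{mut}/B_m \ge 2$". The second expression as printed divides a
dimensionless ratio by a raw intensity, which cannot be meant literally;
since $J$ is itself the signal-to-background ratio, the package reads it
as $J_{mut} \ge 2$, i.e. $(I_m - I_0) \ge 2 (B_m - I_0)$, preserving the
evident intent and the printed constant. The threshold is exposed as
`min_sbr` (default 2, dimensionless).

Within a group, the maximal-$J$ qualifying probe is called (consistent
with the max-normalized display); exact ties are no-calls with an
ambiguity flag, since the assay description never adjudicates ties. A
failed wild-type probe makes the group a no-call — the rule is
inapplicable without its reference — which is this package's convention
for dim chips. Variants absent from the panel are structurally invisible:
the caller never emits off-panel verdicts. A sample report warns (never
errors) when two of the mutually exclusive genes carry calls;
*BRAF* + *MAP2K1/2* co-occurrence is expected and silent.

`estimateLod()` takes replicate reports over a fraction grid: the LoD is
the smallest fraction detected in all replicates (policy `"all"`;
`"majority"` selectable). Specificity is a hard constraint: any mutant
call in a 0% replicate leaves the LoD undefined (error). If no fraction is
fully detected the result is "above the tested range" rather than a
number. Scale invariance holds throughout: multiplying every pixel and
$I_0$ by $g > 0$ leaves all $J$, all calls and the LoD unchanged (tested).

## Cohort statistics

Method calls are canonical `gene:HGVS-c` token sets. Frequency summaries
count patients per gene (de-duplicated: a double-mutant patient counts
once for the gene) and events per variant; a variant's share uses the
gene's event total as denominator, which is how the published shares (e.g.
V600E as 111/134 = 82.8%) are constructed. Concordance marks a record
discordant when two methods' token sets differ, optionally after
restriction to panel-representable variants; arbitration labels each
discordant record by exact token-set equality with the arbiter
(`confirms-a` / `confirms-b` / `confirms-neither` / `unresolved`). An
arbiter reporting only an off-panel variant against a wild-type chip call
is `confirms-neither` — this is exactly how the two rare-variant samples
in the ARMS comparison land, yielding the published 8-of-10 arbitration in
the biochip's favor. Cell lines are flagged and excluded from
patient-sample counts by default (the published "4 samples detected only
by the biochip" excludes a cell line that behaves the same way).

Association tests build the per-gene mutation indicator (any variant, any
method by default), drop records with missing covariates pairwise (the
published denominators, e.g. 140 + 97 = 237 of 253 for sex, imply the
same), and apply the two-sided Fisher exact test by default, with
Yates-corrected chi-square, uncorrected chi-square and Mann–Whitney
(numeric covariates) selectable. The published p-values do not state which
test produced each number; the sex × *BRAF* contingency (85/140 vs 46/97,
printed p = 0.047) is matched by Fisher (0.0472), while the printed
nodular-vs-superficial *NRAS* p = 0.0367 corresponds to the uncorrected
chi-square (Fisher gives 0.0441) — both routes are available and tested as
computed.

`referenceCohort()` reconstructs a 253-record cohort whose every marginal
matches the published accounting (variant counts, 177 positive / 76 wild
type, sex and subtype margins and their gene cross-tabs, the five rare
BRAF and one rare GNAQ sequencing-only variants, the NRAS double mutant).
The published per-gene counts over the mutually exclusive genes sum to 186
against 177 positive patients; the 9-patient excess is absorbed as
BRAF∩NRAS co-occurrences, the exclusivity pattern being described as
holding only "in general". The per-patient arrangement beneath the
marginals is synthetic and documented as such; ages are left `NA` because
only cohort-level age summaries were published. Similarly, the published
"185/253 mutated by any method" cannot be reconstructed from printed
increments (they sum to 183) and is deliberately not asserted anywhere.

## Numerical and testing choices

Pixel coordinates are 0-based (row, col) with continuous spot centers; CDS
coordinates are 1-based on the coding strand with codon $c$ spanning
$3c-2..3c$. J is `NA` (never `Inf`) when $B_m \le I_0$. Duplicate
averaging drops QC-failed spots and keeps the survivor. All randomness
flows from explicit seeds; per-replicate seeds are derived from the master
seed via one `sample.int` draw, keeping them below $2^{31}$. Output JSON
embeds the tool version and the verbatim configuration (rather than a hash)
so deterministic runs are byte-reproducible.

Problem sizes in the test-suite and acceptance runs — a 9 × 12 grid at 20
px pitch (201 × 261 px images), 24-chip dilution series, an exhaustive
calling-rule grid of several hundred cases and a few hundred Fisher tables
— were chosen as the smallest sizes at which every published quantity and
every invariant is exercised end to end; all are package defaults, and all
independent oracles in the tests (brute-force rule evaluation, closed-form
product amounts, hypergeometric enumeration, hand-coded codon
translations) are separate code paths from the implementation.

## Known limitations

* The clamp model is phenomenological; it reproduces enrichment and the
  calibrated LoD but not real PCR kinetics, competition or stochastic
  early-cycle effects.
* Grid location assumes four visible corner markers and an affine
  deformation; rotated-beyond-affine or partially cropped chips fail
  loudly rather than being rescued.
* The cohort fixtures reproduce published marginals, not the unpublished
  per-patient data; conclusions beyond those marginals (e.g. multivariable
  associations) cannot be drawn from them.
* Quantitative allele-fraction estimation from $J$ and probabilistic
  genotype likelihoods are out of scope; the caller is deliberately the
  published threshold rule.
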