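---
title: "Methods: population genetics and spectral analysis of opsin alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genetics and spectral analysis of opsin alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opsinadapt)
```

## Scope and scientific setting

`opsinadapt` implements the computational chain used to study depth-related
adaptation of visual opsin genes (the long-wavelength-sensitive cone opsin
*LWS* and the rod opsin *RH1*) in closely related fish populations:

1. haplotypes are collapsed into **amino-acid allele groups** (synonymous
   variants are functionally identical);
2. polymorphic sites are tabulated with synonymous/nonsynonymous labels, and
   allele frequencies are stratified by species, locality and depth;
3. coding diversity is summarised by mean **Nei–Gojobori Ds/Dn** distances;
4. selection on a gene region is tested with the **Hudson–Kreitman–Aguadé
   (HKA)** polymorphism/divergence test against flanking regions;
5. population structure is screened with **Hudson's FST**;
6. allele genealogies are reconstructed by **neighbor joining** with
   bootstrap supports; and
7. visual pigment absorbance spectra are analysed: peak wavelength
   (λmax) estimation, standard template construction, and estimation of the
   **A1/A2 chromophore ratio** of a photoreceptor by template mixture
   fitting to microspectrophotometric (MSP) curves.

Because raw sequence chromatograms and measured absorbance curves of such
studies are rarely deposited in machine-readable form, the package treats its
synthetic-data generators as first-class, tested components: every downstream
stage can be validated against planted ground truth.

## The two-region coalescent simulator

`simulate_two_region_data()` draws, independently per region, a standard
n-sample coalescent genealogy (exponential waiting times; for `k` active
lineages the coalescence rate is `k(k-1)/2` per `2N` generations). Mutations
fall on branches as a Poisson process with rate θ/2 per unit branch length,
so the expected number of segregating sites is `E[S] = θ a_n` with
`a_n = Σ_{j<n} 1/j` (Watterson). A standard coalescent rather than a star
approximation is used because the HKA variance formula's `b_n = Σ 1/j²` term
assumes it.

Divergence is generated by a single outgroup lineage that split `T` coalescent
units ago (time in units of `2N` generations) and coalesces with the ingroup
ancestral lineage after an additional `Exp(1)` time, giving
`E[D] = θ(T + 1)` where `D` is the mean number of differences between an
ingroup sequence and the outgroup. A per-region `divergence_inflation`
multiplier on `T` is the alternative-hypothesis knob emulating directional
selection on one region. Mutations occupy distinct sites (infinite-sites
behaviour on a finite grid); requesting more mutations than sites is an
explicit error, never a recurrent hit.

Defaults mirror the study conditions the package is calibrated under:
θ = 5 per region, T = 2, n = 20 ingroup haplotypes, region lengths 1932 and
1286 bp (an upstream flanking gene and a gene body from exon 2 to exon 5);
the third demo region uses the 1928 bp downstream flank.

## The HKA test: estimator, statistic, and honest calibration

For two regions with observed segregating sites `S_i` and mean outgroup
divergence `D_i`, the neutral model has per-region mutation parameters θ_i
and one shared divergence time `T`:

- `E[S_i] = θ_i a_n`, `Var[S_i] = θ_i a_n + θ_i² b_n`
- `E[D_i] = θ_i (T + 1)`, `Var[D_i] = E[D_i] + θ_i²`

(single outgroup lineage; the population-size ratio `f` is fixed at 1
because a single outgroup allele class leaves it unidentifiable). The
method-of-moments estimator matches total polymorphism, total divergence and
per-region totals; the system is exactly identified for two regions and is
solved by bounded least squares on the (symmetric) moment residuals, so
degenerate inputs such as a region with `S = 0` go through the same
machinery with θ bounded below at 1e-9 and `T ≥ 0`. The goodness-of-fit
statistic

&nbsp;&nbsp;`X² = Σ_i (S_i − ÊS_i)²/VarS_i + (D_i − ÊD_i)²/VarD_i`

is referred to χ² with one degree of freedom. The solver is verified in the
test suite against a brute-force Nelder–Mead minimisation over
(θ₁, θ₂, T) to 1e-4 (agreement is in practice ~1e-6).

**Calibration, measured honestly.** Under the default study conditions the
χ²(1) reference is conservative: over thousands of neutral replicates the
rejection rate at α = 0.05 is ≈ 0.03, and the power against five-fold
divergence inflation of one region is ≈ 0.55. Three causes are measurable:
(i) the prescribed `Var[D]` describes the divergence of a *single* sequence
pair, while the counted observable is the *mean* pairwise divergence of the
sample, whose true variance is smaller (≈ 35.6 versus 40 at θ = 5, T = 2,
n = 20); (ii) `S` and `D` share the mutations on each tip's path to the
ingroup ancestor (correlation ≈ 0.15), which the model treats as
independent; (iii) parameters and variances are plugged in from the same
data. These are properties of the classical test as defined, and the
formulas are kept in their classical form rather than adjusted. When
calibrated inference matters, `hka_test(..., sim_reps = )` provides a
simulation p-value: the null X² distribution is re-simulated at the fitted
(θ̂₁, θ̂₂, T̂) with the package's own coalescent generator. For large counts
the two p-values agree closely; for mid-range p the χ² value is the larger
(more conservative) of the two.

## Nei–Gojobori Ds/Dn

Site counts follow the classic rule: at each codon position the fraction of
the three possible changes that are synonymous contributes to the
synonymous site count, so syn + nonsyn = 3 per codon exactly (changes to
stop codons count as nonsynonymous). For codons differing at more than one
position, all minimal substitution pathways are weighted equally — including
pathways through stop codons, which keeps the counting rule uniform — and
synonymous/nonsynonymous steps are averaged over pathways. Proportions are
corrected with Jukes–Cantor, `d = −(3/4) ln(1 − 4p/3)`; `p ≥ 3/4` is
reported as undefined and flagged, never as an infinite distance. Codons
containing gaps or ambiguity in either sequence, and stop codons, are
skipped pairwise with per-pair site totals. The implementation is held to
*exact* agreement with an independent recursive pathway-enumeration oracle
over all unordered non-stop codon pairs; because counting is per-codon
independent, that exhaustive set covers every pathway topology that longer
sequences can produce.

## Allele grouping and site tables

`translate_cds()` expands IUPAC ambiguity codes per codon: if all
expansions agree the codon translates to that residue, else to `X`;
internal stop codons warn but do not abort. `group_alleles()` partitions
haplotypes by exact protein identity. Haplotypes whose translation contains
`X` (direct-sequencing heterozygotes, Ns) are assigned only when exactly
one known protein — observed clean groups plus optional user-supplied
reference proteins, which also carry the field's allele names — is
compatible at all unambiguous positions; otherwise they are reported
unresolved. This compatibility rule is a declared convention: source
studies rarely state how heterozygous direct reads were resolved into
allele calls. A polymorphic column is labelled `"s"` only when every
observed variant leaves the translation of every observed codon background
unchanged, `"n"` otherwise, `"noncoding"` outside the CDS.

## Spectral analysis and A1/A2 unmixing

The generative shape is the standard unimodal visual-pigment alpha-band
template of the vision literature (Govardovskii-type), parameterised by
λmax with separate constants for A1 (11-cis retinal) and A2
(3-dehydroretinal) chromophores; the A2 template for the same opsin peaks at
a longer wavelength and is broader. The beta band is deliberately not
modelled. The default wavelength grid is 350–750 nm at 1 nm, spanning all
opsin peaks considered (457–611 nm) with margin for the shoulders.

- **λmax estimation**: the vertex of a quadratic fitted over a 20 nm window
  around the grid argmax (robust to 1 nm quantisation); replicate curves
  give a mean and a standard error of the mean, mirroring repeated
  spectrophotometric measurements. A peak on the grid boundary is an error
  (not bracketed).
- **Standard templates**: replicate curves are unit-peak normalised,
  translated onto a peak-relative grid, averaged, smoothed with a centred
  moving average (default 5 nm — the construction is described in the
  source literature only as "averaged and then smoothed", so the window is
  exposed), re-centred and re-normalised.
- **Mixture fitting**: an MSP curve of one photoreceptor is modelled as
  `(1−φ)·A1 + φ·A2`; φ is searched on a 0.01 grid. `peak-match` (default)
  matches the mixture's λmax to the observed peak — this mirrors adjusting
  the mixture until it fits the reported MSP peak — while `curve-match`
  minimises full-curve least squares after unit-peak rescaling and is the
  stricter option. Observed peaks outside the template interval are clamped
  to φ = 0 or 1 with a warning. Both modes are implemented because the
  source description of the fit is ambiguous between them. A possible
  confound noted in the field — coexpression of a second opsin mimicking an
  A1/A2 mixture — is not modelled; three-component unmixing is out of scope.

## FST and trees

`pairwise_fst()` is Hudson's `1 − Hw/Hb` with `Hw` the average of the two
within-population mean pairwise difference counts and `Hb` the
between-population mean; gap/ambiguity columns are dropped pairwise, and
negative estimates are reported as computed with a flag rather than
truncated. `min_fst_partner()` breaks ties lexicographically (declared).

`neighbor_joining()` is a from-scratch Saitou–Nei agglomeration with two
declared conventions: ties in the Q criterion are joined at the
lexicographically smallest pair of representative taxon labels (making the
result independent of input order), and negative branch lengths are clamped
to zero with the excess transferred to the sister branch. Distances are
Jukes–Cantor (the distance model is a declared choice). `bootstrap_support()`
resamples columns, rebuilds NJ trees and reports the percentage of
replicates containing each internal bipartition of the point tree; 1000
replicates by default. Heterozygous flanking sequences are expanded into two
allele sequences per individual (`expand_heterozygotes()`), assigning the
first-listed IUPAC base to allele 1 — a stated convention, not a phase
inference — and concatenated across regions before tree building.

## What the synthetic data do and do not show

The generators emulate: neutral and selection-inflated
polymorphism/divergence at linked regions; codon alignments with exact
planted amino-acid and synonymous differences; depth-stratified allele
counts with each species dominated by one allele; and noisy mixed-chromophore
absorbance curves with known φ. They do **not** emulate recombination,
demography, selection with linkage, baseline drift or instrument-specific
artefacts in spectra, or sequencing error. Passing tests therefore
demonstrate correctness of the computations under the stated models, not
robustness of the biological conclusions to violations of those models.

## Problem sizes and numerical choices

Calibration experiments in the test suite and acceptance script use 1000
neutral and 500 alternative HKA replicates at the default study conditions,
100 noisy replicates per A2 fraction, 100 random 8-taxon additive matrices,
and 200 panmictic FST replicates — sizes chosen so the full suite documents
the package's statistical behaviour in a few minutes on one CPU. Numerical
conventions worth knowing: the moment solver refines a closed-form solution
by bounded L-BFGS-B and conserves `Σ(ÊS + ÊD) = Σ(S + D)` to 1e-8;
undefined distances (Jukes–Cantor at `p ≥ 3/4`, FST at `Hb = 0`) are
flagged `NA`, and tree building refuses matrices containing them; all
generators are deterministic given their seed, and `run_pipeline()` is
byte-identical under a repeated seed.

## Worked demo

```{r, eval = FALSE}
out <- run_pipeline(default_run_config(seed = 1), "demo_out")
read.csv(file.path("demo_out", "hka_panel.csv"))
read.csv(file.path("demo_out", "a1_a2_unmixing.csv"))
```

The demo simulates six allele groups in ten-ish species' worth of samples,
a three-region locus with five-fold gene-region divergence inflation, and
MSP curves at known A2 fractions, then runs every stage end to end; the HKA
panel flags the gene-involving pairs and the unmixing stage recovers the
planted fractions within the φ grid step.

## Known limitations

- The HKA χ² p-value is conservative at small-to-moderate counts (see
  above); use `sim_reps` for calibrated p-values.
- Only two-region HKA contrasts are provided (pairwise panels over more
  regions), not a joint multi-locus test.
- Mixture unmixing assumes exactly two components with known template
  shapes and a common opsin.
- NJ is the only tree method; parsimony and likelihood methods are standard
  territory of dedicated phylogenetics packages.
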