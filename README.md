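# opsinadapt

Population-genetic and spectral analysis of visual opsin adaptation.

Closely related fish species living along a depth gradient often carry
different alleles of the long-wavelength-sensitive cone opsin (*LWS*) and the
rod opsin (*RH1*), tuned to the ambient light of their habitat. Testing
whether selection — rather than drift — fixed those alleles, and measuring
what the encoded pigments actually absorb, takes a chain of computations
that this package implements as tested, reusable R functions:

- **Allele groups**: haplotypes are translated and partitioned into
  amino-acid allele classes (synonymous variants collapsed), with
  polymorphic-site tables labelled synonymous (`s`) / nonsynonymous (`n`)
  and allele frequencies stratified by species, locality and depth.
- **Ds/Dn**: mean pairwise Nei–Gojobori synonymous/nonsynonymous distances
  with equal pathway weighting and Jukes–Cantor correction.
- **HKA test**: the Hudson–Kreitman–Aguadé polymorphism/divergence test
  between genomic regions. With segregating sites `S_i` and mean outgroup
  divergence `D_i` per region, the neutral model `E[S_i] = θ_i a_n`,
  `E[D_i] = θ_i (T + 1)` is fitted by the method of moments and
  `X² = Σ (S−ÊS)²/VarS + (D−ÊD)²/VarD` is referred to χ²(1); a
  coalescent simulation p-value is available.
- **FST**: Hudson's `1 − Hw/Hb` between labelled populations, plus
  minimum-FST partner identification.
- **Allele trees**: neighbor joining (from-scratch Saitou–Nei with declared
  deterministic tie-breaks) on Jukes–Cantor distances, with column-resampling
  bootstrap supports; heterozygous sequences are expanded into two allele
  sequences and concatenated across regions first.
- **Spectra**: visual-pigment absorbance templates (Govardovskii-type alpha
  band, A1 and A2 chromophores), λmax estimation with standard errors,
  empirical standard-template construction, and estimation of the A1/A2
  chromophore ratio φ of a photoreceptor by fitting the mixture
  `(1−φ)·A1 + φ·A2` to a microspectrophotometry curve (peak-match or
  curve-match mode).
- **Simulators**: a standard-coalescent two-region generator with tunable θ,
  divergence time and per-region divergence inflation; a codon-alignment
  generator with planted allele groups; and a noisy spectrum generator with
  known mixing fraction — so every stage is testable without external data.

## Worked example

Simulate a locus whose gene body diverged five times faster than its
upstream flank, then test for heterogeneity:

```r
library(opsinadapt)

sim <- simulate_two_region_data(sim_sequence_params(
  theta_per_region = 5, divergence_time = 2, n_ingroup = 20,
  region_lengths = c(1932L, 1286L), divergence_inflation = c(1, 5), seed = 42))
up   <- region_counts(sim$regions[[1]]$ingroup, sim$regions[[1]]$outgroup, "up(SWS2A)")
gene <- region_counts(sim$regions[[2]]$ingroup, sim$regions[[2]]$outgroup, "gene")
hka_test(up, gene)
#> HKA test of polymorphism/divergence heterogeneity
#>     region  S    D    E_S   E_D  Var_S  Var_D
#>  up(SWS2A) 11 10.0  7.729 13.27  15.29  18.02
#>       gene 24 50.1 27.271 46.83 121.44 105.92
#> theta_hat = (2.1785, 7.6869), T_hat = 5.0920
#> X2 = 1.4829, df = 1, p(chi2) = 0.2233
```

`S` and `D` are the observed polymorphism and mean divergence per region and
`E_S`/`E_D` their fitted neutral expectations; here the excess gene-region
divergence is visible (50.1 observed) but this particular replicate does not
reach significance — the χ² reference is conservative at these counts (see
the methods vignette), and `hka_test(..., sim_reps = 1000)` gives a
simulation-calibrated p-value.

Estimate the A2 chromophore fraction of a simulated photoreceptor whose true
mixing fraction is 0.6, with pure templates at 544 nm (A1) and 595 nm (A2):

```r
g  <- 400:750
a1 <- spectrum_curve(g, pigment_template(g, 544, "A1"))
a2 <- spectrum_curve(g, pigment_template(g, 595, "A2"))
obs <- simulate_spectrum(sim_spectrum_params(544, 595, a2_fraction = 0.6,
                                             noise_sd = 0.005, seed = 7))
fit_a1_a2_mixture(obs, a1, a2, mode = "curve-match")
#> A1/A2 mixture fit (curve-match): A2 fraction = 0.60 (60%), mixture peak = 576.8 nm
```

The recovered fraction (60%) matches the planted truth to the φ grid step,
and the fitted mixture peak (576.8 nm) agrees with the observed curve's
estimated λmax (576.7 nm).

The whole chain — allele grouping, frequencies, Ds/Dn, HKA panel, FST
screen, bootstrap NJ tree, spectral unmixing — runs end to end on synthetic
demo data with one call:

```r
run_pipeline(default_run_config(seed = 1), "demo_out")
```

A thin command-line front end over the same functions lives at
`inst/cli/opsinadapt.R` (subcommands `run`, `simulate`, `alleles`, `dsdn`,
`hka`, `fst`, `tree`, `lmax`, `unmix`).

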