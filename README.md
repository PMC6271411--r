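# duplexmelt

Thermodynamic analysis of short DNA duplex melting, in R.

Hybridization assays — SNP probes, degenerate primers, oligonucleotide
therapeutics — stand or fall on small free-energy differences between matched
and mismatched base pairs, and those differences shift with the ionic and
solvent environment. `duplexmelt` implements the full analysis chain used to
quantify this for short (here 13-mer) non-self-complementary DNA duplexes,
including duplexes carrying the non-canonical nucleotides inosine (I) and
2,6-diaminopurine (D) and the G·T wobble pair:

1. **Two-state melting-curve analysis.** A UV melting curve at 260 nm is
   modelled as a population-weighted mix of two linear baselines,
   `A(T) = f(T)·(b_ds + m_ds·T) + (1 − f(T))·(b_ss + m_ss·T)`, where the
   duplexed fraction `f` obeys bimolecular mass action
   `K·Ct·(1 − f)² = 2f` with `K = exp(−ΔG°(T)/RT)` and
   `ΔG°(T) = ΔH° − TΔS°`. Nonlinear least squares recovers
   (ΔH°, Tm) plus four baseline coefficients; ΔS° and ΔG°₃₇ follow.
2. **van't Hoff concentration dependence.** For a heteroduplex with total
   strand concentration Ct (each strand at Ct/2), `Tm⁻¹` is linear in
   `log₁₀(Ct/4)` with slope `2.303·R/ΔH°`; regression over a concentration
   series gives a second, independent (ΔH°, ΔS°) estimate. Agreement of the
   two estimates is the operational test of two-state melting, and their
   average is the reported parameter set.
3. **Salt dependence and counterion uptake.** Duplex stability is regressed
   on `log₁₀[M]`; the slope converts into the net number of cations taken up
   on duplex formation, `Δn = slope/(2.303·α·R·T)` (α = 0.9 for Na⁺,
   0.88 for Mg²⁺), or equivalently from `δ(Tm⁻¹)/δlog[M] = 2.303·α·R·Δn/ΔH°`.
4. **Nearest-neighbor prediction.** The embedded unified Watson–Crick
   parameter set plus the internal G·T wobble set predict duplex
   thermodynamics by summing dinucleotide steps and initiation terms, and a
   trinucleotide-core decomposition isolates the contribution of the two
   steps flanking a central (possibly non-canonical) pair from measured
   whole-duplex parameters.
5. **A synthetic melting-curve generator** with the same generative
   structure (two-state transition, sloping baselines, Gaussian photometric
   noise, seedable) stands in for raw absorbance data in validation and
   parameter-recovery studies.

Units throughout: ΔH° and ΔG°₃₇ in kcal·mol⁻¹, ΔS° in cal·mol⁻¹·K⁻¹,
R = 1.987 cal·mol⁻¹·K⁻¹, temperatures in Kelvin internally (°C at I/O),
`Ct` always the **total** strand concentration.

## Worked example

Simulate a concentration series for an A·T-variant 13-mer duplex
(ΔH° = −92, ΔG°₃₇ = −10.4), fit every curve, and consolidate with the
van't Hoff plot:

```r
library(duplexmelt)

cfg <- sim_config(dH = -92, dG37 = -10.4, noise_sd = 0.002, seed = 7)
curves <- generate_ct_series(cfg)
fits <- lapply(curves, fit_two_state)
vh <- vant_hoff_regression(data.frame(Ct = sapply(fits, `[[`, "Ct"),
                                      Tm = sapply(fits, `[[`, "Tm")))
consolidate_parameters(fits, vh)
#> Consolidated over 6 curve fits + van't Hoff (two-state: yes):
#> Duplex formation thermodynamics:
#>   dH   =   -91.67 kcal/mol
#>   dS   =   -262.1 cal/(mol K)
#>   dG37 =   -10.38 kcal/mol
```

The consolidated enthalpy is within 0.4% of the simulation truth and the
two independent estimates agree, flagging two-state behaviour. The G·T
wobble core and the Na⁺ uptake of the most stable duplex:

```r
nn_trinucleotide("CGC", "GTG")
#> Duplex formation thermodynamics:
#>   dH   =    -8.50 kcal/mol
#>   dS   =    -24.0 cal/(mol K)
#>   dG37 =    -1.06 kcal/mol

ion_uptake_from_dg(3.91, alpha = 0.9)
#> Counterion uptake (from_dG, alpha = 0.90): dn = 3.1 ions/duplex (3.0616)
```

The full six-duplex study (G·C, D·T, I·C, A·T, G·T, I·T variants of
`5'-TTTGTATCXCAAT-3'/5'-ATTGYGATACAAA-3'`) runs end to end with
`run_pipeline(run_config(seed = 42))`, reproducing the stability ordering
G·C > D·T ≈ I·C > A·T > G·T > I·T, uptake numbers ordered with the salt
slopes (3.1 ions for G·C down to 2.0 for I·T), and the match/mismatch
discrimination table (e.g. ΔΔG°₃₇ = 3.37 kcal·mol⁻¹ and ΔTm = 11.0 K for
G·C vs G·T at 2 µM strands). A thin command-line wrapper with
`simulate / fit / vanthoff / salt / nn / pipeline` subcommands lives at
`inst/cli/duplexmelt.R`.

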