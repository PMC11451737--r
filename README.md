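# llpsnmr

Quantitative comparison of conformational distributions in frozen protein
solutions from 2D solid-state NMR crosspeaks.

## What it is for

Disordered, low-complexity protein domains — the package ships the
S/T/Q/Y/G-rich N-terminal 163 residues of human FUS as its worked example —
can be frozen either from a homogeneous solution or from a liquid–liquid
phase-separated one, and low-temperature 2D ssNMR spectra of the two states
show broad crosspeaks whose lineshapes encode the conformational distribution
of the chain. `llpsnmr` answers two questions about such spectrum pairs:

1. **Do the two conformational distributions differ?** Matched 1D slices are
   scaled onto each other by least squares (with a 30 ppm diagonal exclusion
   band), the residual is quantified as a fraction of the crosspeak area
   against its analytic noise floor, and crosspeak centers of mass are
   compared with noise-injection uncertainties and a conservative
   mirror-symmetry criterion.
2. **How large a population change could hide below the noise?** Conformer
   ensembles are reweighted toward beta-strand-like torsions by a factor
   ε_β with exact crosspeak-volume conservation; because the simulated
   difference is exactly proportional to ε_β − 1, an observed (or
   noise-limited) difference level converts linearly into a detectability
   bound on the beta-population enhancement.

A synthetic generator (torsion-basin ensembles, surrogate shift mapping,
spectrum rendering with realistic 6.5–8 ppm linewidths, optional diagonal /
sideband / t1-noise artifacts) closes the loop: it lets the whole pipeline be
validated against known injected truths, which is exactly what the test suite
does.

## Worked example

Simulate a paired experiment (condition A: original ensemble; condition B:
the same ensemble with beta conformers enhanced by ε_β = 1.2), then run the
comparison pipeline on it:

```r
library(llpsnmr)

ens <- ensemble_spec(fus_sequence(), n_frames = 100)
pe <- paired_experiment(ens, eps_beta = 1.2, residue_type = "T",
                        shift_pair = "CA_CB", snr = 100, seed = 1)
pe$spec_a
#> <spectrum2d> 187 x 187 (indirect x direct)
#>   direct  : 13C, 42.5 .. 89 ppm
#>   indirect: 13C, 42.5 .. 89 ppm
#>   noise_rms: 0.01

ref <- extract_slice(pe$spec_a, 70, "direct")
oth <- extract_slice(pe$spec_b, 70, "direct")
pair <- optimal_scale(ref, oth, diag_ppm = ref$fixed_ppm,
                      exclusion_halfwidth_ppm = 5)
pair
#> <scaled_pair> scale = 1.034514, 148/187 points in fit (exclusion halfwidth 5 ppm about 70 ppm)

d <- difference_spectrum(pair)
quantify_difference(d, ref, roi_ppm = c(50, 70),
                    noise_rms = sqrt(2) * pe$spec_a$noise_rms)
#> <difference_report> |diff|/|ref| = 0.04335 over [50, 70] ppm (noise floor 0.02896)
```

The measured 4.3% difference sits above its 2.9% noise floor: the injected
reweighting is detected. On the ensemble side, the same reweighting looks
like this:

```r
rw <- reweight_crosspeak(pe$table, "T", "CA_CB",
                         spec = reweight_spec(epsilon_beta = 1.2))
rw
#> <reweight_result> eps_beta = 1.2: N_beta = 260 of N_T = 1000 (non-beta factor 0.92973)
#>   difference extremes: 8.66% / -7.03% of original crosspeak maximum
```

And the closed-loop detectability workflow — inject ε_β = 1.1 at a peak
signal-to-noise ratio of 50, run the full slice-comparison pipeline, and
convert the pooled noise-debiased difference into an enhancement bound —
recovers the injected 10%:

```r
detectability_workflow(ens, eps_injected = 1.1, eps_ref = 1.2, snr = 50,
                       seed = 1)
#> # A tibble: 1 × 7
#>   bound_pct observed_magnitude simulated_magnitude eps_injected eps_ref   snr  seed
#>       <dbl>              <dbl>               <dbl>        <dbl>   <dbl> <dbl> <dbl>
#> 1      8.73              0.188               0.430          1.1     1.2    50     1
```

All result objects are tibble-native: `tidy()` gives long tables for plotting,
`glance()` one-row summaries, and `autoplot()` ggplot2 graphics
(`autoplot(pe$spec_a)`, `autoplot(rw)`).

I/O: `load_spectrum()` reads a dependency-free plain text dialect and
single-file NMRPipe 2D spectra (`dialect = "nmrpipe"`); `parse_conformer_table()`
reads a long TSV dialect and per-frame prediction-style tables
(`dialect = "spartaplus"`).

Command line: `run_workflow()` drives the `compare`, `simulate` and `bound`
workflows from a YAML configuration and writes outputs plus a hash manifest;
`inst/scripts/llpsnmr.R` wraps it for `Rscript`.

## Reproduction

```sh
# full test suite, including the acceptance criteria
Rscript -e 'testthat::test_dir("tests/testthat", package = "llpsnmr", load_package = "installed")'

# recompute the headline quantities into a JSON report
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The acceptance report includes the residue-count totals (e.g. 12997 Ser and
3170 Thr records for 163 residues x 317 frames), the exact proportionality
and volume-conservation deviations (~1e-15), the center-of-mass and
optimal-scale oracle agreements, the noise-injection uncertainty doubling
ratio, the 20-seed median detectability bound (~10% for an injected 10%
enhancement), and the `compare_com` false-positive rate at ε_β = 1 (~1%).

See `vignettes/methods.Rmd` for the model, the numerical choices, and the
generator's realism limits.
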