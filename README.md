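# toccsl

Single-molecule brightness analysis of membrane-protein subunit
stoichiometry in live cells, for researchers doing TIRF microscopy of
GFP-tagged transporters and receptors.

At physiological surface densities, diffraction-limited imaging cannot
distinguish a monomer from an oligomer. The TOCCSL protocol ("thinning
out clusters while conserving stoichiometry of labeling") photobleaches
an aperture-confined membrane region and lets intact, unbleached
oligomers diffuse back in, so that for a short window each
diffraction-limited spot is one oligomer. Its integrated brightness
*B* then reports the number of active fluorophores it carries.

The core statistical model: with ρ₁(B) the measured single-fluorophore
brightness density, an *n*-mer's density is the *n*-fold autoconvolution
ρₙ = ρ₁ ∗ ⋯ ∗ ρ₁, and the observed spot-brightness density is the
constrained mixture

    ρ(B) = Σₙ αₙ ρₙ(B),   αₙ ≥ 0,  Σₙ αₙ = 1

whose weights αₙ are the oligomer fractions (average oligomeric state
⟨n⟩ = Σₙ n·αₙ). The package implements:

- **Synthetic data** (`sim_*`): seeded generators for single-fluorophore
  brightness, mixed-order spot populations, rendered 16-bit camera
  frames (integrated Gaussian PSF, shot + read noise), full TOCCSL runs
  with aperture bleaching and Brownian re-entry, repeated-run series
  with or without subunit exchange, and FRAP traces.
- **Image analysis**: photon conversion (`counts_to_photons`),
  matched-filter spot detection (`detect_spots`), integrated-Gaussian
  spot fitting (`fit_gaussian_spot`), brightness tables
  (`extract_brightness_table`), and surface-density estimation
  (`estimate_surface_density`).
- **Brightness mixture**: KDE monomer density (`estimate_monomer_pdf`),
  autoconvolution (`autoconvolve_pdf`, plus a brute-force oracle),
  maximum-likelihood simplex fit (`fit_mixture`, with a
  least-squares-on-histogram cross-check `fit_mixture_lsq`), and 50%/100-rep
  bootstrap SDs (`bootstrap_fractions`).
- **Kinetics and exchange**: one-phase association FRAP fits
  (`fit_frap`, I(t)/I₀ = mf·(1 − e^(−Kt))), the bleach-state exchange
  model (`predict_apparent_fractions`), active-fluorophore decline, and
  Friedman/Dunn repeated-run statistics (`exchange_test`).
- **Pipeline + CLI**: `run_pipeline()` drives simulate/convert/detect/
  fit/bootstrap/report from a JSON config with full seeded determinism;
  `toccsl_cli()` (wrapper script in `inst/exec/toccsl`) exposes
  `simulate`, `detect`, `fit-mixture`, `frap`, `exchange`, `pipeline`,
  and `report` subcommands. Minimal 16-bit grayscale TIFF I/O is built
  in (`write_tiff16` / `read_tiff16`).

## Worked example

Recover a 60:40 monomer:dimer composition from synthetic brightness
data, then fit a noisy FRAP trace:

```r
library(toccsl)

gt   <- ground_truth(fractions = c(0.6, 0.4),
                     monomer_median = 100, monomer_gsd = 1.4)
mono <- sim_monomer_brightness(gt, 5000, seed = 1)   # calibration set
rho1 <- estimate_monomer_pdf(mono, n_max = 3)
spots <- sim_mixture_spots(gt, 5000, seed = 2)
bootstrap_fractions(spots$brightness[spots$visible], rho1,
                    n_max = 3, seed = 3)
#> <oligomer_distribution> n_max = 3  n_samples = 5000
#>   alpha_1 = 0.5962 (sd 0.0085)
#>   alpha_2 = 0.4038 (sd 0.0085)
#>   alpha_3 = 0.0000 (sd 0.0001)
#>   average oligomeric state <n> = 1.4038

trace <- sim_frap_trace(mf = 0.89, K = 0.02, noise_sd = 0.02, seed = 4)
fit_frap(trace)
#> <frap_fit> mf = 0.8950 [0.8880, 0.9020], K = 0.02057 /s, rss = 0.0112
```

The fitted α₁/α₂ recover the simulation truth (60%/40%) within the
bootstrap SD, and the mobile fraction recovers 89% within its 95% CI.
The full image-level pipeline (render frames → detect → fit → mixture)
runs from a config:

```r
run_pipeline(system.file("extdata", "example-config.json",
                         package = "toccsl"))
```

which writes `brightness.csv`, `cells.csv`, `aggregate.csv`, and
`report.md` (each stamped with the config hash and seed) into the
config's `out_dir`.

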