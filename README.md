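# sptlock

Single-molecule tracking, dual-color co-tracking and confinement
analysis for membrane receptor mobility, with a synthetic-data
generator that makes every stage verifiable without microscopy data.

## The problem

Multivalent binders (biparatopic DARPins, antibody combinations) can
crosslink cell-surface receptors such as HER2 into oligomers and nearly
abolish their lateral diffusion ("lockdown").  Quantifying this from
dual-color single-molecule localization microscopy requires a chain of
statistical steps, each with calibrated error rates:

1. **Detection** of single-molecule spots at a fixed per-pixel
   false-positive rate (default 10⁻⁶, 9 × 9 px evaluation box) by a
   matched-filter GLRT against the local noise, followed by
   **sub-pixel Gaussian localization** (fixed PSF width, ~10–20 nm
   precision) and a particle-density QC gate (< 1 µm⁻² per channel).
2. **Immobile clustering**: transient immobilization events as
   spatiotemporal clusters (> 20 frames within a 120 nm radius of a
   running centroid), yielding the per-frame immobile fraction.
3. **Trajectory linking** of the mobile localizations (optimal per-frame
   assignment, adaptive gates, ≤ 3-frame gap bridging) and diffusion
   estimation by weighted fits of the exposure- and noise-corrected MSD
   model `MSD = 4Dτ − 4/3·D·Δt + 4ε²` over the first 5 lags.
4. **Co-tracking**: affine channel registration from bead calibrations,
   then per-frame optimal pairing of the two channels; ≥ 10 consecutive
   co-localized frames within 150 nm define a co-locomoting complex.
5. **Confinement analysis**: a Simson–Sheetz confinement index along
   trajectories (> 100 frames, 10-frame windows) thresholded at a level
   calibrated on simulated free Brownian motion (false-positive rate
   10⁻³), maximum-likelihood two-state transition probabilities, and a
   nanodomain-size estimate from the MSD plateau of arrested segments
   (`diameter = 2·√(plateau − 4ε²)`).
6. **FRAP**: per-cell normalization
   `(F(t) − F(0)) / (<F_pre> − F(0))`, exponential acquisition-bleach
   correction, a ≥ 40% bleach-depth QC, and recovery metrics.

The synthetic-data module simulates freely diffusing receptors
(D = 0.19 µm² s⁻¹, 32 ms frames), transient trapping in ~35 nm
nanodomains with two-state switching, oligomers with stochastic
two-color subunit labeling, rendered EMCCD movies, and FRAP curves with
known mobile fractions — so all of the above have parameter-recovery
tests.

## Worked example

```r
library(sptlock)

sc <- sim_scenario(density = 0.5, n_frames = 300, fov = c(15, 15),
                   boundary = "reflecting",
                   oligomer_size_dist = c("2" = 1), p_label = 0.4,
                   trap = trap_model(0.01, 0.01), seed = 1)
res <- run_pipeline(sc)
str(res$summary)
#> List of 12
#>  $ seed                         : int 1
#>  $ n_localizations              : int 32400
#>  $ density_per_um2              :List of 2
#>   ..$ A: num 0.227
#>   ..$ B: num 0.253
#>  $ immobile_fraction            :List of 2
#>   ..$ A: num 0.485
#>   ..$ B: num 0.537
#>  $ median_D_um2_s               :List of 2
#>   ..$ A: num 0.17
#>   ..$ B: num 0.182
#>  $ dual_fraction_mobile         : num 0.133
#>  $ n_colocalized_immobile_events: int 20
#>  $ dual_fraction_total          : num 0.195
#>  $ confined_fraction            : num 0.0833
#>  $ p_arrest                     : num 0.000459
#>  $ p_release                    : num 0.0938
#>  $ domain_diameter_nm           : num 0
```

Reading the output: the scenario simulates dimers at 0.5 observable
particles/µm² with half-arrested kinetics
(`p_arrest = p_release = 0.01`), so roughly half of all localizations
fall into immobilization events (`immobile_fraction` ≈ 0.49/0.54 per
channel), the mobile remainder diffuses near the input 0.19 µm² s⁻¹
(`median_D_um2_s`), and 13% of mobile localizations co-locomote in both
colors (`dual_fraction_mobile`), rising to 19.5% when co-localized
immobile events are included (`dual_fraction_total`).  The confinement
module analyzes the *mobile* trajectories; long arrests were already
removed by clustering, so the confined fraction is small here and too
few arrested frames remain for a domain-size estimate
(`domain_diameter_nm = 0`).  Use `analyze_confinement()` on unfiltered
trajectories (see the vignette) to study trapping itself.

A thin CLI over the same functions is in
`inst/scripts/sptlock-cli.R` (subcommands `simulate`, `localize`,
`cluster`, `track`, `cotrack`, `confine`, `frap`, `run`, each taking
`--config`, `--seed`, `--out`).

## Documentation

Every exported function carries roxygen documentation; the methods
vignette (`vignettes/sptlock-methods.Rmd`) describes the models,
assumptions, numerical choices and limitations in detail.
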