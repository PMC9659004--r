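# virocount

Quantitative image analysis for counting kinesin-1 motors on vaccinia
virions and measuring virion motility on microtubules.

Vaccinia virus produces two morphologically distinct infectious particles —
intracellular mature virions (IMVs, single-membraned) and intracellular
enveloped virions (IEVs, additionally wrapped in Golgi-derived membrane) —
and both are transported toward microtubule plus ends by kinesin-1. Two
quantitative questions drive the analyses here: *how many* motor complexes
does each virion carry, and *how* do virions move, in cells and in
reconstituted in vitro assays. This package implements both measurement
pipelines end to end, together with synthetic-scene generators that provide
complete ground truth, so that every stage can be validated without any
microscope data. It is aimed at cell biologists and microscopists doing
fluorescence molecule counting or single-particle motility analysis.

## What it computes

**Motor counting.** Spot intensities are measured with the concentric-ROI
scheme: the integrated counts over an 8-pixel-diameter disc, minus the
annulus background (10-pixel outer disc) scaled to the inner pixel area,

    I = I_inner − (I_outer − I_inner) · A_in / (A_out − A_in).

Intensities of protein-nanocage standards carrying defined fluorophore
copy numbers (24/60/120/180-mers) give a through-origin calibration line
`I = s·N` with `s = Σ N·Ī_N / Σ N²`; virion intensities then convert to
molecules `N = I/s`, to motor complexes `N/2` (two tagged heavy chains per
kinesin-1), and to expression-corrected counts `round(mean complexes × f)`
where `f` is the parental/knock-in antibody intensity ratio. Virion surface
areas come from the Thomsen ellipsoid approximation
`S = 4π(((ab)^p + (ac)^p + (bc)^p)/3)^{1/p}`, `p = 1.6075`, and motor
densities from `⌊S / n⌋`.

**Motility.** Per-frame Laplacian-of-Gaussian detections are linked with a
simple LAP tracker (0.8 µm linking, 5-frame gap closing, >1 µm displacement
filter), and each track is segmented into active transport, normal
diffusion, subdiffusion or confined motion from windowed MSD slope,
straightness, and segment-scale confinement statistics; active segments
report velocity (net displacement / duration) and run length. In vitro
movies are analysed by projection onto microtubule paths and piecewise
constant-velocity run extraction (the kymograph image itself is also
reconstructed), with motility rates normalised per minute per millimetre of
microtubule, and directionality scored against microtubule polarity.

## Worked example

```r
library(virocount)

rep <- run_motor_counting(analysis_config(seed = 1),
                          n_virions = 40, n_spots_per_species = 50)
print(rep$calibration)
#> Through-origin calibration curve
#>   slope: 99.92 counts per fluorophore (r^2 = 1.0000, species-mean fit)
#>  copy_number n_spots mean_intensity        sd
#>           24      50       2406.451  97.93945
#>           60      50       5991.641 111.66701
#>          120      50      11973.896 141.00801
#>          180      50      17996.142 173.81919
```

The simulated optics deliver 100 photons per fluorophore, and the fitted
slope recovers 99.9 counts per fluorophore from the four nanocage species.
The virion cohorts (planted at 139 and 320 true motor complexes, rendered
at knock-in expression levels) come back as:

```r
rep$imv[c("mean_molecules", "mean_complexes", "fold_estimate",
          "corrected_mean_complexes", "area_per_motor_nm2")]
#> IMV: 129.7 molecules -> 64.9 complexes; fold 2.14 -> 139 corrected
#>      (area per motor 1715 nm^2)
#> IEV: 230.3 molecules -> 115.1 complexes; fold 2.78 -> 320 corrected
#>      (area per motor 1264 nm^2)
```

i.e. the full chain — detection, background-subtracted intensity,
calibration, expression correction, surface-density arithmetic — recovers
the planted motor numbers. An in vitro motility experiment planted at
0.66 µm/s:

```r
iv <- simulate_invitro_experiment(n_runs = 20, speed_um_s = 0.66,
                                  config = analysis_config(seed = 1))
#> 20 runs, 0.660 ± 0.001 µm/s, 100% plus-end directed
```

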