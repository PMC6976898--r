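# palight

Voxel Monte Carlo simulation of light delivery for combined
ultrasound/photoacoustic (US/PA) probes — a linear transducer array with
external fiber-bundle illumination — for researchers designing such probes or
assessing how results obtained in mice translate to humans.

Photoacoustic signal strength is proportional to the optical fluence at the
absorber, so the probe geometry (the lateral offset `D` between the fiber
footprint and the transducer's imaging plane, and the emission angle `theta`)
directly controls sensitivity. The dominant confounder is the skin: a ~0.3 mm
mouse skin layer leaves a collimated beam largely ballistic, while ~2 mm of
human skin diffuses it completely. `palight` quantifies the consequences: the
optimal emission angle shifts from intermediate values (thin skin) to shallow
ones (thick skin), and an identical probe delivers severalfold less fluence in
the human configuration.

## What it computes

Photon packets are launched from a collimated rectangular emitter (25 mm x
1.4 mm footprint, offset `D`, tilt `theta`) into a voxelized cube: a skin (or
milk) layer over homogeneous bulk tissue, each voxel class carrying the
optical quadruple (mu_a, mu_s, g, n) from a bundled database (700–1064 nm;
fatty/fibrous mixtures are convex combinations of the endpoint rows).
Transport uses free paths drawn from mu_s, continuous absorption weighting
exp(-mu_a l) with an exponentially weighted track-length fluence tally,
Henyey–Greenstein scattering, Snell/Fresnel refraction at internal
refractive-index interfaces, and Russian roulette termination. The tallied
fluence (per unit launched energy, 1/mm^2, mirror-averaged across the imaging
plane) is reduced to:

* **depth profiles** — mean fluence in a 0.5 mm x 20 mm region centered on
  the imaging plane, per depth;
* **peak fluence** over emission-angle (20–70 degrees) and offset
  (5–13 mm) sweeps;
* **mouse/human maximum-fluence ratios** per tissue and wavelength;
* **kernel SNR** convergence scores;
* a **milk/gelatin phantom pipeline** with a synthetic graphite-rod scan
  generator and the square-root ultrasound normalization used to compare
  model and experiment.

## Worked example

Compare the optimal emission angle for a fibrous bulk under mouse-like
(0.3 mm) and human-like (2 mm) skin, at reduced problem size:

```r
library(palight)

plan <- study_plan("desk", n_photons = 2e5, master_seed = 1)
mouse <- run_angle_sweep(plan, tissue_spec("fibrous", 700), 0.3)
human <- run_angle_sweep(plan, tissue_spec("fibrous", 700), 2.0)
mouse
human
species_ratio(mouse$peak_value, human$peak_value)
```

```
sweep_table: fibrous@700, skin 0.3 mm
 angle_deg  peak_value peak_depth_mm       seed
      20.0 0.002126878         3.825  122662268
      32.5 0.002283866         4.275 1914356774
      45.0 0.002251230         3.675  122662335
      57.5 0.001986405         3.225 1914421161
      70.0 0.001600994         3.975  122662423
sweep_table: fibrous@700, skin 2 mm
 angle_deg   peak_value peak_depth_mm      seed
      20.0 0.0009623464         4.275 129870865
      32.5 0.0009947211         4.575 251883975
      45.0 0.0009191725         3.825 129870932
      57.5 0.0007690084         5.025 251948362
      70.0 0.0006517095         4.275 129871020
[1] 2.295986
```

Reading: `peak_value` is the maximum of the ROI-averaged normalized fluence
(1/mm^2 per unit delivered energy) over depth. With thin skin the peak is
maximized at an intermediate angle (32.5 and 45 degrees differ by ~1.4%,
inside the Monte Carlo noise at this budget), fluence collapses at steep
angles, and the thin-skin configuration delivers ~2.3x more peak fluence
than the thick-skin one, whose optimum sits at the shallow end (20–32.5
degrees). The peaks lie at 3–5 mm depth. `run_full_study()` runs the
whole tissue-by-wavelength factorial and emits the ratio matrix;
`simulate_phantom_fluence()`, `generate_synthetic_scan()` and
`us_normalize()` stage the phantom validation; `write_outputs()` serializes
profiles, ratio tables and a reproducibility manifest, and
`inst/cli/palight.R` wraps it all for the shell.

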