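# e2edose

End-to-end (E2E) geometric accuracy analysis for MR-guided radiotherapy
dose delivery.

An E2E test of an MR-linac runs the entire online adaptive treatment chain
on a phantom — imaging, registration, plan adaptation, delivery — and
measures whether the dose landed where it was planned. A 3D polymer-gel
dosimeter (or 2D radiochromic film as reference) records the delivered
dose; the residual rigid displacement between the planned dose and the
readout is the geometric error of the chain, and a global gamma analysis
quantifies dosimetric agreement. `e2edose` implements that analysis as a
reusable, fully tested pipeline for medical physicists and QA developers:

* **Dose grids** — axis-aligned 3D dose volumes in the IEC 61217 frame
  (mm, Gy) with trilinear resampling, rigid transforms, validity masks,
  ROI construction, and NIfTI I/O.
* **Synthetic phantom** — the dual-cone test plan (two mirrored truncated
  cones, tip 0.5 cm, base 3.0 cm, length 4.6 cm; PTV maximum 11 Gy, 6 Gy
  cap outside; 1 mm or 3 mm lattices) with known ground-truth
  displacements and calibrated noise, so every stage is checkable against
  exact expectations.
* **Gel chain** — R2 relaxation-rate readout simulation, multi-echo R2
  fitting, and linear R2-to-dose conversion normalised to the maximum
  calculated dose.
* **Film chain** — net-optical-density calibration curves
  (`D = b·netOD + c·netOD^2.5`), dose conversion, marker-based
  orthogonal-Procrustes registration, and exact 3D film placement.
* **Registration** — the shift estimator: Hooke–Jeeves pattern search
  maximising the correlation ratio η² between readout and resampled plan
  inside a PTV region of interest,

  η² = 1 − E[Var(measured | planned-dose bin)] / Var(measured),

  reported as per-axis shifts (dx, dy, dz), planar and 3D displacement
  vectors, and session mean ± SD.
* **Gamma analysis** — global 3D gamma index,
  γ(r) = min over p of √[(‖p − r‖/Δd)² + ((D_eval(p) − D_ref(r))/ΔD)²],
  at 3%/3 mm with a 20% dose threshold, with a lossless pruned search, an
  exhaustive brute-force oracle, and a film-plane restricted variant.
* **Pipeline** — `run_e2e_experiment()` reproduces a full measurement
  session (simulate, read out, register, gamma, aggregate) from one config
  and one seed, byte-reproducibly.

## Worked example

Recover a known 2.3 mm displacement through the full gel chain:

```r
library(e2edose)

spec  <- plan_spec(noise_sd_fraction = 0)      # 1 mm dual-cone plan
plan  <- generate_plan_dose(spec)
truth <- rigid_transform(c(1.0, -0.5, 2.0))    # ground-truth shift, mm

measured <- apply_known_shift(plan$dose, truth)
gel      <- simulate_gel(measured, noise_sd = 0.044, seed = 7)  # ~1% noise
readout  <- gel_to_dose(gel, reference_max_dose = max(plan$dose$values))

fit <- fit_dose_to_readout(plan$dose, readout, ptv_roi_boxes(plan))
fit
#> fit_result: shift (1.000, -0.516, 2.000) mm, eta^2 = 0.99870 (96 evaluations, converged)

displacement_vectors(fit$shift)
#>     v_xy     v_xz     v_yz     v_3d
#> 1.125109 2.236068 2.065398 2.294748

gamma_map(plan$dose, readout)
#> gamma_result: pass rate 100.0% (382720 voxels evaluated, global 3%/3 mm, threshold 20%)
```

The fitted shift reproduces the ground truth to 0.016 mm per axis despite
the gel lattice change (0.78 × 0.78 × 2.0 mm readout), the renormalisation,
and the readout noise — the correlation ratio is invariant to the linear
intensity map, and the pattern search resolves to its 0.01 mm minimum
step. `v_3d` is the 3D displacement vector magnitude (mm); the gamma pass
rate is the percentage of evaluated voxels with γ ≤ 1. A whole session is
one call:

```r
report <- run_e2e_experiment(e2e_config("gel", n_measurements = 5, seed = 1))
report$aggregates     # per-axis and vector mean ± SD, mean gamma pass rate
```

A thin command-line wrapper with `simulate`, `register`, `gamma`, and
`e2e` subcommands is installed under `inst/cli/e2edose.R`.

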