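# spinlyo

Intra-vial primary-drying kinetics of spin freeze-dried vials from
time-resolved (4D) micro-computed tomography.

## The problem

In continuous spin freeze-drying, a vial is rotated about its long axis
while frozen, so the formulation solidifies as a thin annular layer on the
inner wall. During primary drying the sublimation front moves radially
outward through this layer, and the local drying rate is governed by the
**dried-product mass-transfer resistance** `Rp` — a lumped property of the
dried cake's pore size and tortuosity. Conventional techniques measure one
`Rp` per vial or per batch. Time-resolved micro-CT of a drying vial,
segmented on a cylindrical `(r, Φ, h)` grid, resolves the frozen-layer
thickness — and hence `Rp` — *per azimuth-height coordinate*, exposing
intra-vial inhomogeneity (thickness gradients, cracks, freezing
artefacts) that drives a broad distribution of local drying endpoints.

`spinlyo` implements that analysis chain for process scientists and
imaging groups:

1. **phantom** — a synthetic 4D-µCT generator (annular frozen layer with
   gradients, eccentricity, cracks, cavities, gripper spots; partial-volume
   greyscale; seeded noise) with known ground truth, so the whole chain is
   testable without scanner data;
2. **tomogeometry** — cartesian→cylindrical re-gridding, vial-axis
   estimation, Otsu ice segmentation, extraction of the front radius
   `r_p(t, Φ, h)`, layer thickness `L_ice = r_vial − r_p`, the integrated
   ice length `L_ice′`, and the sublimation-direction diagnostic
   `(L_ice − L_ice′)/L_ice`;
3. **physics** — vapour pressure of ice
   `P_i = exp(α − β/T_i + γ ln T_i − δ T_i)`, latent heat of sublimation
   `ΔH_sub(T_i)`, and the vial-level heat balance
   `P_tot = A_p,vial (P_i − P_c)/R_p,vial · ΔH_sub/M` solved for `T_i` by
   bracketed bisection;
4. **resistance** — per-coordinate regression
   `R_p = A_p (P_i − P_c) / ṁ_sub` with Savitzky–Golay (degree 3, window
   15) smoothing/differentiation of `L_ice(t)`, segment volumes
   `V = π h_vial/(n·m) (r_vial² − r_p²)`, and binning of `(L_dr, R_p)`
   into 38 bins over 0–2.5 mm;
5. **endpoint** — a coupled heat/mass-balance time stepper that predicts
   the per-coordinate primary-drying endpoint `t_end` from the regressed
   profiles and initial thickness field;
6. **thermal** — an emulated thermal-imaging verification: field of view
   `HFOV = 2 d_w tan(α/2)`, rotation-synchronised movie unwrapping,
   per-pixel endpoint detection, and endpoint-distribution comparison;
7. **pipeline** — JSON-configured orchestration with reproducible CSV/JSON
   artifacts.

## Worked example

```r
library(spinlyo)

# vial-level heat balance at the reference process point
hb <- solve_interface_temperature(P_tot = 1.2, A_p_vial = 2.24e-4,
                                  R_p_vial = 1e5, P_c = 10)
hb$T_i; hb$P_i
#> 260.16 K; 198.75 Pa

# synthetic vial with a 20% top-bottom thickness gradient and 5% eccentricity
geom <- scan_geometry(voxel_size = 1e-4, dims = c(248, 248, 40),
                      n_radial = 124, n_phi = 16, n_h = 10,
                      r_vial = 10.9e-3, h_vial = 4e-3, scan_interval = 50)
th0   <- thickness_field(geom, base = 2e-3, gradient_frac = 0.2,
                         eccentricity = 0.05)
truth <- ground_truth(function(L) rep(1e5, length(L)), th0, geom)
cfg   <- simulation_config(P_c = 10, P_tot = 1.2, dt = 10)
sim   <- simulate_series(phantom_spec(seed = 1, scan_interval = 50),
                         geom, truth, cfg)

series <- extract_layer_series(sim$frames, geom)
series
#> <layer_series> 23 scans, 16 x 10 coordinates, t in [0, 1100] s

trace  <- process_trace(sim$truth$T_i_trace$t, sim$truth$T_i_trace$T_i,
                        P_c = 10)
binned <- bin_profiles(resistance_profile(series, trace, geom))
binned
#> <rp_profile_field, binned> 38 bins x 16 x 10 coordinates; 33% bins populated

em <- predict_endpoints(binned, matrix(series$L_ice[1, , ], 16, 10),
                        cfg, geom)
em
#> <endpoint_map> 16 x 10 coordinates; t_end 5/50/95%: 0.25 / 0.28 / 0.29 h

compare_endpoint_maps(em, sim$truth$endpoints)
#> <endpoint_comparison> r = 0.938; max CDF distance = 0.112; median |dt| = 0.004 h
```

The thicker bottom of the vial dries last (0.29 h vs 0.25 h); predicted
endpoints agree with the generator's realized ground truth to a median
0.004 h, i.e. the regression closed the loop on a vial it had only seen
through rendered greyscale volumes.

The bundled demo pipeline runs the same chain end to end and writes CSV
artifacts plus metadata:

```r
run_pipeline(system.file("extdata", "demo_config.json", package = "spinlyo"),
             outdir = "demo_run")
```

## Layout

- `R/` — implementation; `tests/testthat/` — unit, property and acceptance
  suites (phantom fixtures are generated in code at test time);
- `vignettes/spinlyo-methods.Rmd` — the model, its assumptions, numerical
  choices and limitations;
- `scripts/acceptance.R` — the acceptance report.
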