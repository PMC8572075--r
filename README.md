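# scoutrange

Automated craniocaudal scan-range delimitation for chest CT, with
radiation-dose accounting.

## The problem

Before a helical chest CT, the technologist marks the scan range on a 2D
scout (localizer) image. In routine practice that range is almost always
generous — the costophrenic recesses are faint on a scout, and missing
lung is a worse failure than a few extra centimetres — so most chest CTs
*overscan*, irradiating the thyroid, liver and other organs outside the
lungs for no diagnostic benefit. `scoutrange` implements an automated
alternative and the machinery to quantify what overscanning costs:

1. **Scout synthesis** — sum-projection of a 3D volume into AP and lateral
   scout-like images (attenuation-weighted so air contributes zero), with
   an exact affine mapping from image rows to patient z that survives
   normalization, resizing and magnification distortion.
2. **2D lung segmentation** — a residual dilated convolutional network
   (20 conv layers, residual connections every two layers, per-block
   dilation factors, Dice + cross-entropy loss; forward/backward passes
   implemented in this package and verified against numeric gradients),
   plus a deterministic classical segmenter used as a training-free
   oracle/fallback.
3. **Range selection** — small-component removal, first/last occupied row
   with an optional one-voxel safety margin, AP/lateral combination, and
   signed overscan errors (positive = overscan, negative = missed lung).
4. **Dosimetry** — effective diameter `sqrt(D_AP x D_Lat)`, SSDE via the
   published size-conversion fit `f(D) = 3.704369 exp(-0.03671937 D)`
   (32-cm phantom, valid 6–55 cm), per-region tube-current averaging,
   regional DLP, a declared simplified organ-dose surrogate (in-field
   regional SSDE + exponential out-of-field tail), and ICRP-103 effective
   dose, compared across *exact*, *human-selected* and *predicted*
   range scenarios.

A synthetic chest-phantom generator (body + two lungs with tapered apices
and slanted costophrenic recesses, vertebral column, consolidation, noise,
tube-current modulation, simulated operator-selected ranges) makes the
whole pipeline testable end to end with no external data.

## Worked example

```r
library(scoutrange)

ph <- generate_phantom(phantom_config(), seed = 7)
ph$volume
#> <ct_volume> 96 x 96 x 64 voxels @ (3.75, 3.75, 2.50) mm, CTDIvol 6.00 mGy
ph$range                      # ground truth from the 3D lung mask
#> <scan_range exact> [28.75, 123.75] mm (length 95.00 mm)

human <- simulate_human_range(ph$range, seed = 7)
human                         # a simulated operator selection
#> <scan_range human> [-18.29, 136.72] mm (length 155.01 mm)

pr  <- normalize_resize(project_volume(ph$volume, "AP"),
                        project_mask(ph$mask, "AP"), 256)
seg <- postprocess_mask(classical_segment(pr$projection))
dice(seg, pr$mask)
#> [1] 0.982
dl <- mask_to_range(seg, margin_voxels = 1, provenance = "DL_AP")
overscan_error(dl, ph$range)
#> <overscan_report DL_AP> superior +1.56 mm, inferior +1.56 mm
overscan_error(human, ph$range)
#> <overscan_report human> superior +47.04 mm, inferior +12.97 mm

dm  <- measure_body_diameters(ph$volume, ph$mask)
inp <- dose_inputs(dm["d_ap"], dm["d_lat"], ctdi_vol = ph$volume$ctdi_vol,
                   tcm = ph$volume$tcm)
scenario_dose(human, ph$range, inp, "human")
#> <dose_report human> length 15.5 cm, SSDE 8.33 mGy, DLP 94.3 mGy cm, ED 4.731 mSv
scenario_dose(dl, ph$range, inp, "DL")
#> <dose_report DL> length 9.8 cm, SSDE 8.33 mGy, DLP 57.0 mGy cm, ED 3.559 mSv
```

Reading the numbers: the automated range tracks the true lung limits to
within ~1.6 mm on each side (the +1.56 mm is dominated by the deliberate
one-voxel safety margin), while the simulated operator overscans by 47 mm
superiorly and 13 mm inferiorly; with the package's simplified dose
surrogate that overscan costs about 25% of the scan's effective dose
(`compare_scenarios()` reports the reduction and its superior/inferior
decomposition).

`run_pipeline(run_config(output_dir = "out"))` chains all stages
(simulate → project → segment → range → dose → evaluate), writes every
intermediate as NIfTI/PNG/CSV/JSON with a checksummed manifest, and is
bit-reproducible per seed. `inst/cli/scoutrange` exposes the stages as
shell subcommands (`simulate`, `project`, `segment-train`,
`segment-predict`, `range`, `dose`, `evaluate`, `run`).

The methods vignette (`vignettes/scan-range-delimitation.Rmd`) documents
the model assumptions, parameter choices, what the phantom does and does
not emulate, and known limitations.

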