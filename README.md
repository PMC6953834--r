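# ioertdose

Dose-scenario comparison for intraoperative electron radiation therapy
(IOERT) on paired pre/intraoperative CT.

In IOERT, a rigid bevelled applicator docked to the LINAC collimates a
single electron beam (4–20 MeV) onto the surgically exposed tumour bed. The
beam energy is chosen under the conventional assumption of a flat,
water-equivalent medium starting at the applicator's exit face — but the
real field has an **air gap** between the bevel and the irregular
post-resection surface, and **heterogeneous tissue** below it. This package
rebuilds the analysis that separates the two factors: from a registered
pre/intraoperative CT pair it constructs five dose-calculation scenarios on
one 1.5 mm grid,

* `intraCT` — the intraoperative scan, the gold standard;
* `preCT_water` — the conventional assumption (water half-space at the
  bevel plane);
* `preCT` — the registered preoperative CT (heterogeneity, no gap);
* `preCT_water_air` — water plus the segmented air gap;
* `preCT_air` — preoperative CT plus the segmented air gap,

computes a 3D electron dose on each with a divergent pencil-beam engine
(percent depth dose PDD(z_we) on radiological depth, erf aperture edge,
inverse square from a virtual source; pluggable for a Monte Carlo engine),
and gamma-compares each scenario against `intraCT` at **3%/3 mm, global
normalisation**, for reference doses above 10% and 70%, excluding non-tissue
voxels. The per-voxel gamma index is

γ(v) = min over sample points u of √( (|v−u|/3 mm)² + ((D_eval(u) −
D_ref(v)) / (3% · D_max))² ),

a voxel passing when γ ≤ 1. The chain in between — rigid registration of
the preoperative CT by normalised mutual information evaluated over
segmented bone, region-growing segmentation of bone / air gap (−500 HU
limit) / applicator wall / body, and applicator pose recovery (axis, bevel
centre, bevel roll) from the wall mask — is implemented and validated on a
synthetic CT phantom generator with exact ground truth (known pose, motion,
masks and a closed-form cavity floor giving an analytic maximum air gap).

## Worked example

```r
library(ioertdose)

cfg <- phantomConfig(seed = 82L, target_gap_mm = 14.5,
                     spec = applicatorSpec(5, 15))   # 5 cm aperture, 15° bevel
ph  <- generatePhantom(cfg)
report <- runCase(caseConfig(ph@preop, ph@intraop,
                             beamSpec(6, cfg@spec, ph@truth$pose),
                             seed = 82L))
report
#> IOERT case report: gamma pass rates (%)
#>                 dose>10% dose>70% average
#> preCT_water         64.8     49.5    57.2
#> preCT               65.9     49.5    57.7
#> preCT_water_air    100.0    100.0   100.0
#> preCT_air          100.0    100.0   100.0
#> RMS HU difference (tissue, dose extent): 85.0 HU
#> Maximum air-gap distance: 14.4 mm
```

Reading the table: with a 14.4 mm maximum air gap, doses computed under the
conventional water assumption (`preCT_water`) or from the registered
preoperative CT (`preCT`) agree with the intraoperative gold standard at
only ~57% of voxels — and using the preoperative CT (which adds tissue
heterogeneity) buys almost nothing over plain water. Once the segmented air
gap enters the calculation (`preCT_water_air`, `preCT_air`), agreement is
complete: the air gap, not heterogeneity, drives the dose error. The RMS HU
difference quantifies how far the registered preoperative image is from the
intraoperative one over tissue inside the dose extent.

A thin CLI wraps the same functions: `exec/ioert phantom ...` writes a
phantom with its ground truth, `exec/ioert run ...` runs a case from two
NIfTI files.

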