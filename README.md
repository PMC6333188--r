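# vsmlc

Analytic virtual-source photon-fluence model for a 6 MV linac with a
rotated-leaf ("defocused") multi-leaf collimator, for medical physicists
studying why small-field dose calculations go wrong.

Small fields — a single open 5 mm leaf between closed neighbours is the
extreme case — are dominated by source occlusion (the collimator hides
part of the finite focal spot), by the exact leaf-bank geometry, and by
leaf transmission.  `vsmlc` models the beam with two virtual photon
sources ray-traced through a polygonal leaf bank:

* **primary source**: Gaussian focal spot, FWHM 1.05 mm, at the distal
  side of the target (`Z = 1.1` cm), mean energy 1.6 MeV;
* **secondary source**: broad head-scatter source at the distal plane of
  the flattening filter (`Z = 15.9` cm), mean energy 0.7 MeV;
* **MLC**: 5 mm leaves (projected at the isocenter, `Z = 100` cm) with
  interleaf air gap, optional tongue-and-groove step, and a leaf-bank
  rotation `LBROT` that shifts the field centre by
  `shift = h · sin(LBROT) / 2` for leaf height `h`;
* **attenuation**: exponential, `T = exp(-μ L)` along each ray's chord
  `L` through leaf material, with μ from packaged XCOM-style mass
  attenuation tables for the 96/3/1 W/Ni/Fe alloy at 18.5 g/cm³.

The in-line fluence at isocenter position `y` is the source-plane
integral `F(y) = Σ_s w_s ∫ S_s(y_s) A_s(y_s→y) exp(-μ L(y_s→y)) dy_s`.
Profiles are compared with percent differences, distance-to-agreement at
the 50% penumbra level, and a 1D global gamma index
`γ(y) = min_e sqrt((ΔD / (d% · D_max))² + (Δy / dmm)²)`.

## Worked example

Sweep the leaf-bank rotation around its fitted 9 mrad value and compare
each profile against the nominal one:

```r
library(vsmlc)

mlc_shift(height = 90, lbrot = 9)
#> [1] 0.4049945          # mm field-centre shift at the MLC plane

prof <- profile_from_config(nominal_config())
prof
#> Fluence profile: 301 points on [-15, 15] mm, max 0.04735 at 1.2 mm (unit integral)

run_sweep("lbrot", c(0, 9, 12))
#>   parameter value rel_max_fluence rel_integral   dta_avg
#> 1     lbrot     0       1.0346277    1.2349069 1.3999633
#> 2     lbrot     9       1.0000000    1.0000000 0.0000000
#> 3     lbrot    12       0.9577436    0.8544893 0.3810507
```

Reading the output: the 0.405 mm bank shift projects to ≈1.2 mm at the
isocenter, which is where the nominal profile peaks.  Removing the
rotation (`lbrot = 0`) raises the peak fluence by 3.5% and the profile
integral by 23% (no flank wedges eroding the aperture, and the open
interleaf gaps leak), while over-rotating to 12 mrad costs 4.2% of the
peak; the 50% penumbra moves by 1.40 mm and 0.38 mm respectively.
Ratios are computed on unnormalized fluence — normalizing to unit
integral would cancel exactly the integral changes being measured.

Named sensitivity scenarios wrap the common perturbations:

```r
run_scenario("exclude_secondary")
#>                name rel_max_fluence rel_integral     dta_avg  pct_max pct_integral
#> 1 exclude_secondary       0.9974859    0.9815799 0.002920732 -0.25141    -1.842013
```

A thin command-line front end lives in `inst/cli/vsm.R`
(`profile`, `scenario`, `sweep`, `compare`, `generate` subcommands).

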