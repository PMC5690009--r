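# brachyqa

Commissioning tools for the TG-43 dose calculation of high-dose-rate (HDR)
brachytherapy treatment planning systems (TPS), written for the medical
physicist who has to decide whether the anisotropy tables a vendor shipped
with a planning system can be trusted.

## The problem

TPS dose engines for sealed HDR sources implement the AAPM TG-43
line-source formalism

    D(r,θ) = Sk · Λ · G_L(r,θ)/G_L(r0,θ0) · g_L(r) · F(r,θ)

driven entirely by tabulated source data: the dose-rate constant Λ, the
radial dose function g_L(r), and the 2D anisotropy function F(r,θ). The
vendor input data (VID) tables are finite subsamples of published Monte
Carlo data sets. Cable-driven Ir-192 sources have steep F gradients within
~15° of both poles (steeper on the cable side), and a VID table with no
angular samples inside those bands forces the TPS to interpolate linearly
across them. The resulting *outcome discrepancies due to interpolation*
(ODIN) can exceed 15% locally — well past the 2% investigation and 5%
intervention levels used in commissioning — while transverse-axis point
checks, ABS-style reporting points, and even gamma analysis at clinical
criteria all look clean.

`brachyqa` implements the full analysis chain:

- a TG-43 line-source dose engine with explicit interpolation /
  extrapolation policies (`tg43_engine()`, `dose_rate()`,
  `geometry_factor()`, `radial_dose()`, `anisotropy_lookup()`,
  `pole_extrapolate()`);
- anisotropy-table comparison with bidirectional bilinear resampling and
  ODIN detection against the 2%/5% action levels (`resample_table()`,
  `compare_tables()`, `odin_detect()`);
- extraction of F(r,θ) from along–away dose-rate tables via the formal
  TG-43 definition (`extract_anisotropy()`);
- dose-plane superposition for standard clinical dwell configurations —
  single dwell, short/long applicators, Fletcher tandem + ovoids,
  multi-applicator implants (`make_setup()`, `compute_dose_plane()`,
  `percent_diff_plane()`);
- 2D gamma-index analysis with local dose normalisation and criteria
  sweeps (`gamma_2d()`, `gamma_sweep()`);
- QA point patterns, including the half-star pattern whose free rays sit
  inside the pole-gradient zones that legacy array patterns miss
  (`half_star_pattern()`, `legacy_pattern()`, `evaluate_pattern()`);
- a synthetic-data generator that emulates reference/vendor table pairs
  with realistic pole gradients so the entire pipeline is testable without
  proprietary data (`synthetic_anisotropy_spec()`,
  `make_reference_anisotropy()`, `subsample_vendor()`,
  `make_alongaway()`).

Reading and writing use plain-text CSV dialects (`read_anisotropy_csv()`
and friends) and versioned JSON reports. A thin command-line front end
with subcommands (`synth`, `tables-compare`, `plan-compute`, `diff`,
`gamma`, `qa-pattern`, `pipeline`) ships in `inst/cli/brachyqa.R`; exit
codes 0/3/4 signal clean / investigation-level / intervention-level
findings so it can gate a commissioning workflow.

## Worked example

Generate the synthetic study conditions (a dense reference table and its
sparse vendor-style subsample), detect ODIN regions, and evaluate the
half-star QA pattern:

```r
library(brachyqa)

spec   <- synthetic_anisotropy_spec(seed = 1)
dense  <- make_reference_anisotropy(spec)
vendor <- subsample_vendor(dense)

src <- source_model()                      # L = 0.5 cm, Λ = 1.101 cGy/h/U
g   <- make_radial_model("polynomial")
eng_ref <- tg43_engine(src, g, dense,  label = "reference")
eng_vid <- tg43_engine(src, g, vendor, label = "vendor")

back <- resample_table(vendor, dense$radii, dense$angles, "reference")
odin_detect(compare_tables(dense, back, denominator = "a"))
#> ODIN report (investigation > 2%, intervention > 5%)
#>   flagged cells      : 135 (108 at intervention level)
#>   angular band       : [3.0, 24.0] deg
#>   angular band       : [159.0, 177.0] deg
#>   angular coverage   : 21.7% of [0, 180] deg (7.5% solid angle)
#> percent differences over 531 cells:
#>   amplitude [-17.625, 0.000] %
#>   mean -2.490 %  SD 4.794 %
#>   quartiles -2.200 / -0.021 / -0.001 %
```

Every cell beyond the 2% level lies inside the vendor table's two angular
sampling gaps; the worst linear-interpolation underestimate is −17.6%.
The half-star pattern sees it, because its free rays (7° and 172° by
default) sit inside those gaps:

```r
star <- evaluate_pattern(half_star_pattern(), eng_ref, eng_vid)
subset(as.data.frame(star), r == 2)
#>    r theta    dose_a    dose_b      diff_pct        level
#> 7  2     0 0.1547731 0.1547731   0.000000000           ok
#> 8  2     7 0.2376731 0.1992793 -16.154028760 intervention
#> 9  2    45 0.2850870 0.2850752  -0.004122251           ok
#> 10 2    90 0.2822441 0.2822441   0.000000000           ok
#> 11 2   135 0.2847119 0.2846910  -0.007369408           ok
#> 12 2   172 0.2397667 0.2126761 -11.298736232 intervention
attr(star, "exit_status")
#> [1] 4
```

The dose rates are per unit Sk (cGy h⁻¹ U⁻¹); the 0° row is clean because
vendor pole entries match the same linear extrapolation the reference
engine uses, which is exactly why pole-only checks miss the defect. The
legacy array patterns (no ray inside (0°, 15°)) return exit status 0 on
the same engine pair. A full run — difference planes for the clinical
setups, a 3×3 gamma-criteria sweep, all QA patterns, CSV/JSON outputs —
is one call: `run_pipeline(out_dir = "out", seed = 1)`.

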