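# carpetFCS

Image-correlation spectroscopy for quantifying intracellular transport
from confocal **line-scan carpets** — with pair-correlation (pCF)
analysis across the nuclear envelope, single-component FCS diffusion
fitting, number-and-brightness (N&B) moment analysis, 3D watershed
particle segmentation and two-channel co-transport detection. A
Brownian-dynamics simulator with known ground truth (diffusion
coefficients, brightness, barrier permeability, co-transport fraction)
backs every analysis stage, so the whole chain is testable without
access to live-cell recordings.

Intended users: microscopists and image-analysis people working with
scanning-FCS / pCF data — e.g. tracking fluorescent virus capsids or
other cargo moving through the cytoplasm, across the nuclear envelope
(NE) and into the nucleoplasm.

## The quantities computed

For a carpet `F(t, r)` (lines × pixels, each column a time trace):

* **pCF** between pixels a distance `d` apart,

  ```
  pCF(tau, d) = <F(t, 0) F(t + tau, d)> / (<F(t, 0)> <F(t, d)>) - 1
  ```

  on a multi-tau log lag grid (`d = 0` gives the ACF; different spectral
  channels give the cross-channel pCF used for co-transport). A delayed
  positive pCF peak means molecules travel between the two pixels; its
  absence across a line reveals a barrier such as the NE.
* **FCS fit** per column: `G(tau) = G0 / ((1 + tau/tau_D) sqrt(1 +
  tau/(kappa^2 tau_D))) + Ginf`, with `D = w0^2 / (4 tau_D)`, chi-square
  validation, an admissible range of 0–100 um^2/s, and classification
  into fast (`D > 2 um^2/s`) and slow movement.
* **N&B**: apparent number `N = <k>^2 / sigma^2` and brightness
  `B = sigma^2 / <k>` under a dual fast/slow segmentation scheme
  (300-line raw segments vs 100-line-averaged series).
* **Zones**: the lamina is located from its marker channel and columns
  are partitioned into cytoplasm / NE / nucleoplasm for all aggregates.
* **3D segmentation**: distance-transform-seeded watershed on fixed-cell
  stacks; per-object volume, intensity, centre of mass and distance to
  the nucleus edge, binned in 0.5 um distance bins.

## Worked example

Simulate a two-channel line scan across the NE (lamina stripe in channel
1, a D = 3.5 um^2/s species in channel 2, 32,000 lines), then run the
carpet chain:

```r
library(carpetFCS)

cfg <- simulation_config(
  species = list(species_spec(3.5, 4, 200, channel_weights = c(0, 1))),
  lamina = lamina_spec(64, 3, 20, channel = 1),
  n_pixels = 128, n_lines = 32000, seed = 1)
carp <- simulate_carpet(cfg)
carp
#> line_scan_carpet: 32000 lines x 128 px x 2 channel(s); 41 nm px, 1.500 ms/line

lam <- detect_lamina(carp, lamin_channel = 1)
zones <- assign_zones(lam, ne_half_width_px = 11,
                      orientation = "cyto_left",
                      n_pixels = 128, pixel_size_nm = 41)
zones
#> zone_map: lamina at column 64, NE half-width 11 px (cyto_left);
#>   53 cytoplasm / 23 NE / 52 nucleoplasm columns

fits <- fit_carpet_acf(carp, fcs_model_config(), channel = 2)
zone_statistics(fits, zones)
#>          zone  n mean_D  sem_D median_D q25_D q75_D
#> 1   cytoplasm 53   3.21 0.0503     3.14  2.99  3.46
#> 2          NE 23   3.89 0.0832     3.74  3.59  4.19
#> 3 nucleoplasm 52   4.00 0.0658     3.96  3.65  4.34

pcf_carpet(carp, d = 20, channel_a = 2)
#> correlation_carpet (pair): 128 columns x 78 lags, d = 20 px (820 nm), 108 valid
```

The zone table is the boxplot-ready per-zone summary (n, mean ± SEM,
median, quartiles) of the fitted diffusion coefficients; here all
columns carry the same single species, and the pooled median fitted D is
3.63 um^2/s against a ground truth of 3.5 (the simulation has no barrier,
so the three zones differ only by sampling noise). The pCF carpet pairs
pixels 20 columns (820 nm) apart; columns whose partner falls outside
the field are flagged invalid rather than NaN-filled.

The same chain runs from one YAML config via `run_pipeline()` (modes
`simulate`, `carpet`, `seg3d`, `imagepcf`), writing CSV tables, float
TIFF correlation carpets and a manifest; `report_run()` renders the
standard figures. A thin command-line wrapper lives at
`inst/cli/carpetfcs.R`.

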