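# rhizopH

Quantification of *root-surface pH* from dual-excitation ratiometric
fluorescence images.

Plant roots shape the pH of their immediate surroundings: growing
*Arabidopsis* roots show an alkaline domain on the surface of the
transition zone, flanked by acidic domains at the very tip and in the
late elongation/maturation zone, and this zonation rearranges within
minutes during gravitropic bending. A membrane-impermeant,
pH-sensitive fluorescein-family dye dissolved in the growth medium
reports this surface pH: the dye stains the medium and the root
surface but not the root tissue, and the ratio of its fluorescence
under 488 nm and 405 nm excitation (**F488/405**) rises monotonically
with pH while cancelling dye concentration, layer thickness and
illumination.

`rhizopH` turns such two-channel images into longitudinal pH profiles
and downstream physiology metrics:

- **Segmentation & geometry** — the root is the dark (dye-excluded)
  object in bright medium; the mask is Otsu-thresholded from the summed
  channels, the midline is a pruned skeleton with arc length from the
  tip, and the tip and its tangent are located automatically.
- **Surface band** — the medium pixels 10–25 px off the root (exact
  Euclidean distance transform), each carrying its distance from the
  tip along the midline and a left/right side label.
- **Profiles** — the band is binned every 20 px of arc length (15 × 20
  px bins with the default band width); the per-bin ratio is
  Σ I488 / Σ I405. Optional calibration against (pH, ratio) standards
  maps bin ratios to pH through a monotone Hyman spline (or a
  4-parameter logistic).
- **Kinetics** — per-frame tracking, elongation rate (length increment
  between first and last frame over elapsed minutes), tip-angle series,
  lower/upper flank asymmetry in the transition-zone window during
  gravistimulation, and oscillation traces with periodogram peaks.
- **Statistics** — per-position Brunner–Munzel rank comparison of
  profile groups (relative effect P(X<Y) + ½P(X=Y)), many-to-one
  comparisons with Holm adjustment, alkalinization-factor curves with
  bootstrap bands, alkaline-domain descriptors (peak position,
  amplitude, FWHM), and mesh-penetration efficiencies normalized per
  replicate to a reference variant.
- **Synthetic phantoms** — a fully ground-truthed generator (geometry,
  programmed pH field, forward optics, shared illumination fields,
  Poisson + Gaussian noise, growth/bending/flank dynamics) that makes
  every stage testable without microscope data.

## Worked example

Simulate a root with the default alkaline halo (centered 350 µm from
the tip, +0.5 pH over a 5.2 baseline, σ = 60 µm), run the pipeline, and
describe the recovered domain:

```r
library(rhizopH)

spec <- phantomSpec(seed = 21)        # 1024 x 256 px, 0.65 um/px
ph   <- makePhantom(spec)

cfg  <- runConfig()                   # band 10-25 px, 20 px bins
fr   <- getFrame(ph$stack, 1)
geom <- rootGeometry(fr$I488, fr$I405, cfg, pixelSize(ph$stack))
band <- extractSurfaceBand(geom, fr$I488, fr$I405, cfg)
prof <- binProfile(band, cfg, phantomCalibration(spec))

dom <- detectAlkalineDomain(prof, windowUm = c(150, 550))
str(dom[c("peakPositionUm", "amplitude", "fwhmUm")])
#> List of 3
#>  $ peakPositionUm: num 344
#>  $ amplitude     : num 0.49
#>  $ fwhmUm        : num 141
```

The programmed halo (350 µm, 0.5 pH, FWHM 2.355·60 ≈ 141 µm) is
recovered within half a bin in position and a few percent in amplitude
and width, through the full segmentation → band → binning →
calibration chain under shot noise.

A command-line driver wrapping the same functions ships in
`inst/cli/rhizoph.R` (subcommands `profile`, `gravitropy`,
`oscillations`, `compare`, `calibrate`, `penetration`, `simulate`;
each run writes its outputs plus a `manifest.json` with input hashes
and the seed).

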