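# hawkmanr

Multi-scale structural error mapping for single-molecule localisation
microscopy (SMLM) reconstructions.

## What it is for

SMLM images are computed, not observed: fluorophore positions are fitted
frame by frame and rendered onto a sub-diffraction pixel grid.  At high
emitter densities overlapping fluorophores are localised towards their
mutual centre, which *reduces* the scatter of the fitted positions — the
image looks sharper while being biased ("artificial sharpening").  Line
pairs merge, adjacent filaments collapse into one, hollow structures fill
in.

`hawkmanr` is a quality-control tool for people who make or review such
reconstructions.  It compares a **test** image against a **reference**
reconstruction of the same raw data (e.g. one made with HAWK temporal
preprocessing, which trades a little precision for unbiased positions, or
a low-density acquisition) across a Gaussian scale space, and reports
*where* and *at which length scale* the two disagree structurally —
without assuming the two intensity scales are comparable.

## The method in brief

Both images are intensity-capped at the 98th percentile of their nonzero
pixels.  Then, for every integer length scale *s* (a Gaussian blur of
FWHM *s* reconstruction pixels, from 1 px up to the instrument PSF), each
blurred, max-normalised image is binarised against the Wellner-style
adaptive threshold

P<sup>thr</sup> = C<sub>b</sub>·mean<sub>r</sub>(P) +
0.1·mean<sub>r′</sub>(P) + C<sub>a</sub>,
  r = ⌈s/2⌉ − 1,  r′ = ⌈s<sub>PSF</sub>/2⌉ − 1

twice: with (C<sub>b</sub>, C<sub>a</sub>) = (0.7, 0.04) for the
**sharpening map** (agreement yellow, test-only magenta, reference-only
cyan) and with (0.85, 0.02) followed by Zhang–Suen skeletonisation and
re-blurring at the current scale for the **structure map**, which catches
the collapse of adjacent structures.  Windowed Pearson correlations of
the two representations combine into the per-pixel confidence

S<sub>conf</sub> = ½·min(1, PCC<sup>sharp</sup>/0.85) +
½·min(1, PCC<sup>str</sup>/0.85)   (terms clamped to [0, 1]),

rendered red (0) → cyan (1) over the combined image brightness.  The
**artefact scale map** records, per pixel, the smallest scale with
S<sub>conf</sub> ≥ 0.9: the local length scale above which the
reconstruction can be trusted.  Each scale also yields whole-frame
correlations of the two maps (PCC sharpening / PCC structure).

A synthetic generator (`generate_fixture()`) produces paired
test/reference reconstructions from emitters placed on known geometry
(line pairs, crossings, rings, sarcomere-like thick lines), with Poisson
blink statistics, Gaussian localisation error, and a controllable
density-bias emulation that pulls close same-frame localisations toward
their mutual midpoint — so the whole pipeline is testable without any
external data.

## Worked example

Simulate a 100 nm line pair whose test channel suffers strong sharpening
bias (80% of close same-frame pairs pulled toward their midpoint), then
compare test against reference:

```r
library(hawkmanr)

cfg <- simulation_config(struct_line_pair(separation_nm = 100),
                         bias_fraction = 0.8, seed = 1)
fx  <- generate_fixture(cfg)
res <- run_hawkman(fx$test, fx$reference,
                   threshold_params(psf_scale_no = 27),
                   max_scale_no = 12)
summary(res)
```

```
Multi-scale comparison: 'test' (test) vs 'reference' (reference)

 scale_no fwhm_nm pcc_sharp pcc_str mean_conf
        1      10    0.4025  0.4371    0.1773
        2      20    0.7123  0.5992    0.4271
        3      30    0.7533  0.6824    0.5322
        4      40    0.8294  0.8645    0.7440
        5      50    0.8639  0.8962    0.8027
        6      60    0.9006  0.9310    0.8518
        7      70    0.9106  0.9152    0.8582
        8      80    0.9168  0.8787    0.8814
        9      90    0.9250  0.9714    0.8843
       10     100    0.9281  0.9741    0.9014
       11     110    0.9263  0.9948    0.9329
       12     120    0.9353  0.9873    0.9391

<artefact_scale_map> 200 x 200 px, scales 1..12, threshold 0.9
  9583 px reach confidence (median scale 7); 30417 never do
```

Read this as: at fine scales the two reconstructions disagree (the biased
test image has partially collapsed the pair toward its centre line), and
agreement — both the global correlations and the mean confidence — climbs
as the analysis scale approaches and passes the 100 nm separation.  On an
unbiased pair the confidence is high from a few pixels upward;
`plot(res, scale_no = 9)` shows the colour maps, with the collapsed
midline magenta in the sharpening map and red in the confidence map at
scales below the separation.

The same analysis runs file-to-file from a shell:

```sh
Rscript inst/scripts/hawkman.R simulate --config inst/extdata/example_sim.cfg --out sim
Rscript inst/scripts/hawkman.R run --test sim/test.tif --ref sim/reference.tif \
        --pixel-size 10 --psf-fwhm 270 --max-scale 12 --out out
Rscript inst/scripts/hawkman.R report out --scales 2,6,12
```

writing per-scale `sharpening_sNN.png` / `structure_sNN.png` /
`confidence_sNN.png`, `artefact_scale.png`, `metrics.csv`,
`metrics.json`, and a `manifest.json` that makes the run reproducible
bit-for-bit.

## Scope

The tool consumes rendered reconstructions (TIFF/PNG) or localisation
tables (CSV, x/y in nm).  It does not perform HAWK preprocessing, fitting,
drift correction, 3D/bi-plane handling, or raw-frame simulation with
camera noise; see the methods vignette (`vignettes/hawkman-methods.Rmd`)
for the model, parameter guidance and known limitations.
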