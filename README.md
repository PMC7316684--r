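# fluoropose

Pose estimation of small surgical fiducials and instruments from a single
X-ray-like image, for researchers in image-guided minimally invasive
surgery (temporal-bone interventions: cochlear implantation, vestibular
schwannoma removal) who need sub-millimeter instrument localization without
line-of-sight tracking or intra-operative CT.

## What it does

Given one radiograph, a projection geometry and a rough initial guess,
`fluoropose` estimates the five recoverable pose parameters of a small
radio-opaque object (screw fiducial, drill tip, miniature drilling robot):

```
theta = (x, y, alpha, tau, d)
```

in-plane position `(x, y)` [px], forward angle `alpha` (projected axis vs
image x-axis) [deg], projection angle `tau` (out-of-plane tilt; only |tau|
is observable from one view) [deg], and depth `d` (source-object distance)
[mm]. The pipeline is modular:

1. **Appearance normalization** — a 92 x 48 patch is resampled around the
   prior guess so the instrument always appears in a *standard pose*
   (fixed anchor, axis along patch x, z-scored intensities).
2. **Pseudo-landmark regression** — a small VGG-style CNN (implemented
   from scratch in single-precision C++, trained with Adam/MSE under a
   staged learning-rate schedule) predicts six geometrically defined
   landmarks arranged in a metric cross (15 mm spacing; 3+1 along the
   instrument axis, 2+1 orthogonal to it):

   `p_i = (x, y) + 1/(c_d2p d) * R(alpha) (x_lp cos(tau), y_lp)`,
   with `c_d2p = delta_ds / d_SDD`.
3. **Geometric reconstruction** — total-least-squares lines through the two
   legs of the cross invert that projection in closed form: the line
   intersection gives `(x, y)`, the axis-leg slope gives `alpha`, the
   orthogonal leg's image spacing gives `d` (magnification), the axis leg's
   foreshortening gives `|tau|` (`cos tau`).

The estimate is iterated (3x by default): each reconstruction re-centers
the next patch. A built-in simulator (ray-traced parametric fiducial meshes
over Gaussian-random-field "anatomy", Beer-Lambert compositing, exact pose
export) makes the whole pipeline trainable and testable with no external
data.

## Worked example

```r
library(fluoropose)

geom <- projection_geometry(d_sdd = 1000, delta_ds = 0.5,
                            width = 256, height = 256)
screw <- make_fiducial("screw")
truth <- pose(130.4, 121.7, alpha = 35, tau = 40, d = 900)
img <- render_radiograph(screw, truth, geom)

# perfect-landmark oracle: isolates the geometry from the learning
oracle <- oracle_regressor(landmarks_from_pose(truth, geom))
init <- pose(134, 118, alpha = 15, tau = 0, d = 900)   # coarse prior
estimate_pose_iterative(img, init, oracle, geom, n_iter = 3)
```

```
<iteration trace>  3 of 3 iterations
  init x= 134.000 y= 118.000 alpha=  15.000 tau=  0.000 d=  900.00
  it 1 x= 130.400 y= 121.700 alpha=  35.000 tau= 40.000 d=  900.00
  it 2 x= 130.400 y= 121.700 alpha=  35.000 tau= 40.000 d=  900.00
  it 3 x= 130.400 y= 121.700 alpha=  35.000 tau= 40.000 d=  900.00
```

The oracle recovers the generating pose exactly in one iteration (the sign
of `tau` is unrecoverable by design) and stays at that fixed point — the
geometric inversion is exact; everything beyond it is learned.

The full learned pipeline at desk scale — simulate 1500 training images,
train the compact reference CNN for 12 epochs, evaluate 3-iteration
estimation from 2 random initial guesses on 200 held-out images (cases with
|tau| > 80 deg excluded):

```r
bm <- run_reference_benchmark(seed = 1)
print(bm$experiment)
```

```
<experiment>  model landmark_cnn, k = 2 initial poses, 3 iterations, seed 5
<error report>  368 cases evaluated (32 filtered at |tau| > 80 deg, 0 failed)
                              mean      sd   median     q95     max
position_error_mm           0.0563  0.0273   0.0534  0.1051  0.1487
position_error_px           0.1248  0.0594   0.1224  0.2296  0.3021
forward_angle_error_deg    -0.1112  2.1434  -0.1225  2.9285 13.6861
projection_angle_error_deg  3.3131  3.3511   1.8632 10.7038 13.5464
depth_error_mm             -9.1526 18.1450 -11.6964 20.6386 67.2715
```

Read: on clean synthetic images the desk-scale model localizes the screw to
a fraction of a pixel on average (sub-0.1 mm in the fiducial plane), the
forward-angle error is centered on zero, and the out-of-plane quantities
are — as expected from a single view — an order of magnitude less precise
than the in-plane ones. Training at full scale (200k patches, 80 epochs)
tightens all of these substantially; see the methods vignette
(`vignettes/fluoropose-methods.Rmd`) for what the desk scale does and does
not establish.

## Command line

```sh
inst/scripts/fluoropose simulate --out data/train --n 1500 --seed 1
inst/scripts/fluoropose train    --data data/train --out models/ref --seed 1
inst/scripts/fluoropose evaluate --data data/test --model models/ref --out results/
```

## Acceptance script

`scripts/acceptance.R` re-runs the reference benchmark end to end —
simulates fresh training and test data, trains the compact CNN from
scratch, runs the 3-iteration estimator and applies the projection-angle
filter — and writes the mean in-plane position error (mm) and the maximum
per-case position error (px) as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
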