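# swarmcut

Seeded 3D liver segmentation from contrast-enhanced CT by a
swarm-modulated graph cut, with the standard five-metric evaluation stack
(VOE, RVD, ASD, RMSD, MSD) and a deterministic synthetic phantom for
testing without clinical data.

## Who this is for

Medical-image-analysis researchers and engineers who need an interactive
(seed-based) liver segmentation whose energy is robust to the two classic
failure modes of plain graph cuts on abdominal CT: nearly iso-intense
adjacent organs (heart, stomach, kidney) and blurred boundaries.

## The model

Segmentation is a binary min-cut labeling over the 6-connected voxel
lattice:

    E(C) = sum_u D_u(w_u) + lambda * sum_{(u,v)} B_{u,v} K_{u,v} [w_u != w_v]

* `D_u(w) = -log Pr(x_u | w)` — likelihoods grow from the user's object and
  background seeds by best-first path-connectivity expansion,
  `exp(-Iw * mu * (Int - IntBar)^2 / (dis + Dis))` per step with a
  weakest-step path composition, where `Iw` is an HU-interval prior weight
  (liver parenchyma band, damped with exponent `q < 0`).
* `K(u,v) = exp(-(I_u - I_v)^2 / (2 sigma^2))` — the Gaussian boundary
  affinity (`sigma = 10` HU).
* `B_{u,v} = 1 - tau_{u,v}` — the swarm factor. `tau in [0.001, 0.999]` is
  a per-pixel pheromone field from a variant ant-colony optimization run on
  a per-slice enhanced image (intensity + local-binary-pattern appearance
  profiles compared with a seed-derived global model through the
  1-Wasserstein distance). High pheromone marks confident boundaries and
  makes cuts along them cheap.

Defaults follow the standard parameterization: `lambda = 0.15`, `mu1 = 12`,
`mu2 = 8`, `sigma = 10`; ACO with `alpha = 1`, `beta = 2`, `tau0 = 1e-6`,
`phi = 0.2`, `rho = 0.3`. The min cut is solved by a Boykov–Kolmogorov
max-flow implemented in C++ (sub-second on 64^3 grids).

Scores use the linear calibration in which zero error is worth 100 points
per metric and the reference manual-segmentation errors (6.4 %, 4.7 %,
1.0 mm, 1.8 mm, 19 mm) are worth 75:
`score = max(0, 100 - 25 * error / reference)`.

## Worked example

```r
library(swarmcut)

# deterministic synthetic abdomen: lobed liver + adjacent organ at +60 HU,
# 1 mm boundary blur, 10 HU correlated noise, auto-placed seeds
ph <- generate_phantom(phantom_spec(dim = c(64, 64, 64), seed = 1))

res <- segment_volume(ph$volume, ph$seeds, pipeline_config(seed = 1),
                      reference = ph$truth)
res$report
```

```
<score_report>
  voe   error    5.468  score  78.64
  rvd   error    5.257  score  72.04
  asd   error    1.965  score  50.88
  rmsd  error    5.194  score  27.86
  msd   error   19.339  score  74.55
  total score 60.80
```

The liver is recovered with a 5.5 % volumetric overlap error (the `voe`
row; values under 10 % are good at this noise level); the surface rows are
in mm, and each score interpolates between the 100-point ideal and the
75-point reference error. Rerunning with `aco_enabled = FALSE` and
`intensity_weight = FALSE` gives the plain graph-cut baseline for A/B
comparisons.

A thin CLI wraps the same functions:

```sh
exec/swarmcut phantom --out /tmp/ph --dim 64,64,64
exec/swarmcut segment --volume /tmp/ph/volume.nii.gz \
    --seeds /tmp/ph/seeds.nii.gz --out /tmp/mask.nii.gz --seed 1
exec/swarmcut evaluate --pred /tmp/mask.nii.gz --ref /tmp/ph/truth.nii.gz
```

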