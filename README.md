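# polysomix

Reciprocal neighbourhood analysis of ribosome particle fields from
cryo-electron tomography.

After subtomogram averaging, every ribosome in a tomogram carries a 3D
position, a rigid-body orientation (ZYZ Euler angles), a translational-state
class (decoding, pre+, rotated, hibernating, ...) and a translocon-population
class (SEC61–TRAP–OSTA, SEC61–TRAP, multipass, soluble, ...). polysomix
answers the question these metadata pose: **which ribosomes are organised
into polysomes, and which states and populations take part?** It is aimed at
structural biologists analysing ER-bound (or cytosolic) ribosome fields from
particle metadata alone — no maps or images are needed.

## Method

For each ribosome the vectors to its *n* = 4 nearest neighbours within
100 Å are rotated into the particle's own reference frame (for a
membrane-bound ribosome the *xy* plane is the ER membrane) and binned on a
15³ Å³-voxel histogram normalised by the number of analysed neighbours, so
voxel values are probabilities of finding a neighbour there. Thresholding
(P > 5×10⁻⁴ membrane-bound, P > 3×10⁻⁴ soluble), 26-connected cluster
extraction, direction assignment and two-voxel dilation produce a dataset
*trailing* mask and *leading* mask; a polysome link i→j is confirmed only
reciprocally (j in i's trailing region **and** i in j's leading region).
Confirmed links are assembled into chains and per-tomogram event
frequencies.

State–polysome association is then estimated with a multinomial
mixed-effects logistic regression,

    log P(Y = k) / P(Y = ref) = β[k, state] + u[k, tomogram],
    u[k, t] ~ N(0, σ²_k),

with the tomogram as random intercept (absorbing sample and imaging
variability), fitted by a per-tomogram Laplace approximation (adaptive
Gauss–Hermite available for binary outcomes). The package reports predicted
probabilities with 95% delta-method confidence intervals, two-sided Wald
contrasts with Hochberg adjustment, and fold increases over the
random-association probability (the outcome's fractional abundance).

A synthetic-scene generator builds spherical ER vesicles carrying
membrane-bound ribosomes with planted polysome chains, plus a soluble pool
and per-tomogram random effects, so the whole pipeline is testable with
known ground truth.

## Worked example

Twenty synthetic tomograms (~35,000 ribosomes) generated, analysed and
modelled end to end:

```r
library(polysomix)
cfg <- pipeline_config(output_dir = "run",
                       scene = scene_config(n_tomograms = 20, seed = 1),
                       seed = 1)
res <- run_pipeline(cfg)
res$fit
#> multinomial mixed-effects logistic regression (laplace)
#>   35480 observations, 20 tomograms, 5 states, 2 outcome categories (reference 'none')
#>   random-intercept sd: in-polysome 0.333
#>       state     outcome   mean ci_low ci_high
#> 2  decoding in-polysome 0.5778  0.539  0.6153
#> 4      NR-H in-polysome 0.0852  0.073  0.0992
#> 6      post in-polysome 0.5422  0.504  0.5803
#> 8      pre+ in-polysome 0.5926  0.556  0.6284
#> 10      R-H in-polysome 0.0823  0.070  0.0966
#>   (rows for the reference outcome omitted here)
```

The elongating states (pre+, decoding, post) sit in polysomes with
probability ≈0.54–0.59 while the hibernating classes (NR-H, R-H) are
strongly depleted (≈0.08) — the modelled means are conditional on a typical
tomogram, and the per-tomogram scatter is visible in `res$frequencies`:

```r
head(res$frequencies, 4)
#>   tomogram_id    group n_total n_in_polysome frequency
#> 1    tomo_001 decoding     278           176 0.6330935
#> 2    tomo_001     NR-H     355            44 0.1239437
#> 3    tomo_001     post     310           201 0.6483871
#> 4    tomo_001     pre+     581           374 0.6437177
```

Fold increases over random association (fractional membership abundance):

```r
res$fold[res$fold$outcome == "in-polysome", ]
#>       state  fold fold_ci_low fold_ci_high
#>  decoding   1.427       1.332        1.520
#>  NR-H       0.210       0.180        0.245
#>  post       1.339       1.244        1.433
#>  pre+       1.463       1.373        1.552
#>  R-H        0.203       0.173        0.239
```

A fold of 1 means "as often as chance"; hibernating ribosomes are ~5-fold
depleted from polysomes. Of the 9,885 planted trailing→leading links in this
scene, 9,853 edges are confirmed (99.6% recovery, <0.1% spurious), forming
4,514 chains. The run directory contains every intermediate artifact
(particles.star, neighbors.tsv, histogram CSVs, masks.json, links.tsv,
chains.tsv, frequencies.tsv, association.tsv, fold_increase.tsv) and a
hashed manifest; reruns with the same config and seed reproduce identical
hashes.

A thin CLI over the same functions ships in
`inst/scripts/polysomix-pipeline` (subcommands `simulate`, `neighbors`,
`histogram`, `masks`, `links`, `stats`, `run-all`).

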