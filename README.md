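# PetriReg

Predicting the accuracy of intrasubject rigid/affine MRI registration
*before it runs*, with a calibrated Petri net.

## The problem

Serial MRI of a single subject (say a T1- and a T2-weighted scan, or
follow-up scans months apart) must be registered to subvoxel precision
before changes can be read clinically. Accuracy is usually validated *a
posteriori* with surrogate metrics. PetriReg implements the complementary
approach: model the registration workflow as a Petri net whose transitions
are the selectable processing choices — transform model (rigid/affine),
optimizer (regular-step gradient descent / (1+1) evolutionary), and
interpolator (NN / trilinear / cubic B-spline), with mutual information as
the fixed multimodal metric — and let each transition deposit an
inaccuracy weight (in mm) into a dedicated *inaccuracy counter* place as
the token game fires along a path. The counter total for a path is the
predicted registration error of that pipeline configuration, available a
priori and monitorable at run time.

It is intended for image-analysis methodologists who need to choose or
audit a registration pipeline, and it runs out of the box with no external
data: a built-in generator produces multi-tissue T1/T2 phantoms,
thin-plate-spline anatomical jitter, protocol-range rigid misalignments,
landmarks, and Rician magnitude noise (with a moment-matching estimator of
the noise parameters from image backgrounds).

## The model

With 2 transforms x 2 optimizers x 3 interpolators there are 12 paths
through the net and 7 weighted transitions. Measuring the landmark-based
maximum geometric error

$$\mathrm{MGE} = \max_i \, D_E\!\left(x_i,\; \hat T(y_i)\right)$$

for every configuration on training data gives one observed cost per path.
The weights solve the inverse shortest path problem as a linear
least-squares system $A x = b$, where $A$ is the binary 12 x 7
path-by-transition design matrix (row sums 3, rank 5) and $b$ the per-path
MGE averaged over training datasets. Because $A$ is rank deficient, $x =
A^{+} b$ is taken via the Moore–Penrose pseudoinverse: path sums (the
predictions) are uniquely determined even though individual weights are
only identified up to per-stage shifts — which is also why calibrated
weights can be negative. Prediction quality is the Pearson correlation $P
= \mathrm{corr}(\sum_{\mathrm{path}} w_i, \mathrm{MGE}_i)$ on held-out
data; robustness $\rho$ correlates weight vectors calibrated on different
training sets.

## Worked example

```r
library(PetriReg)

# six synthetic subjects: T1 fixed volume, misaligned noisy T2 moving
# volume, reference + misaligned landmarks, ground-truth transform
datasets <- lapply(1:6, function(k)
  simulateDataset(seed = k, gridShape = c(64, 64, 64), spacing = c(2, 2, 2),
                  transMax = 10, rotMax = 5, tpsMax = 2, noiseSigma = 8))

# run all 12 pipeline configurations on every dataset (72 registrations)
records <- evaluateDatasets(datasets, seed = 1)

# split 3/3, calibrate on the training half, predict the testing half
report <- calibrateAndReport(records, splitSeed = 1)
round(report$weights, 3)
#>   t_rigid  t_affine    t_rsgd     t_evo  t_linear      t_nn t_bspline
#>     0.022     1.649     0.512     1.159     0.081     1.677    -0.087

net <- applyCalibration(buildRegistrationNet(), report$calibration)
predictInaccuracy(net, pipelineConfig("rigid", "RSGD", "linear"))
#> [1] 0.614
predictInaccuracy(net, pipelineConfig("affine", "EO", "NN"))
#> [1] 4.485
```

The weight table reads stage by stage: NN interpolation carries ~1.6 mm
more predicted error than trilinear, the stochastic evolutionary optimizer
~0.6 mm more than deterministic RSGD, and rigid beats affine on these
rigidly misaligned volumes. The two predictions bracket the pipeline
space: the recommended configuration (rigid, RSGD, linear) is predicted at
0.61 mm — subvoxel for 2 mm voxels — while the worst (affine, EO, NN) is
predicted at 4.49 mm. Held-out agreement for this split: median
per-dataset predictive power `report$medianP` = 0.897, and weights
recalibrated on the disjoint testing half correlate with the training
weights at `report$rho` = 0.989. Negative weights (B-spline) are a
known artefact of the minimum-norm pseudoinverse solution, not evidence
that a step removes error; only within-stage differences and path sums are
identified.

A thin CLI over the same functions is installed at
`inst/cli/petrireg` (subcommands `simulate`, `evaluate`, `calibrate`,
`predict`; `predict --threshold` activates the token-game early abort).
Real NIfTI volume pairs drop into the same dataset layout
(`fixed.nii.gz`, `moving.nii.gz`, landmark CSVs) in place of phantoms.

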