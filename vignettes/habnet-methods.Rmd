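---
title: "Modelling mosquito habitability from daily climate sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mosquito habitability from daily climate sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modelling problem

habnet estimates the relative risk of observing a vector mosquito at a
given place and date from daily gridded climate alone. The approach is a
presence/pseudo-absence species distribution model: dated, geolocated
occurrence records (e.g. community-science exports) supply the positive
class; synthetic background points drawn over land supply the negative
class; and a feedforward neural network (FFNN) learns to separate the two
from the recent climate history of each point. Because raw classifier
scores depend strongly on modelling choices -- above all on how many
background points accompany each presence -- maps are reported on a
calibrated scale, the false negative rate (FNR), described below.

The pipeline has five stages, each exposed as ordinary functions and as a
`run_pipeline()` stage: covariate derivation, dataset construction,
training, calibration and map prediction, and downstream analytics
(seasonality, historical change, and population-at-risk burden).

## Derived daily covariates

Five covariates are computed per cell per day from the raw reanalysis
fields:

* **temperature range** `tmax - tmin` (deg C), floored at zero;
* **mean temperature** (deg C) -- the daily-mean 2-m air temperature is
  used as the central-temperature covariate;
* **relative humidity** (%) from the August-Roche-Magnus form,
  `RH = 100 exp(17.625 Td / (243.04 + Td)) / exp(17.625 Tm / (243.04 + Tm))`,
  with dew point `Td` and mean temperature `Tm` in deg C. RH is *not*
  clipped at 100: reanalysis fields occasionally imply supersaturation,
  and the z-score normalization downstream absorbs the scale;
* **total precipitation** (mm/day), 24 times the average hourly rate,
  with negative reanalysis artifacts clamped to zero and counted;
* **wind speed** (m/s), the magnitude of the u/v components.

Surface pressure, though present in the raw inputs, does not enter the
model; it is carried through I/O for completeness only.

A model input is the flattened sequence of these covariates over the
`seq_len` days strictly *before* the observation date (the observation
day itself is excluded), day-major with the oldest day first. The layout
is recorded inside every `trained_model` so checkpoints cannot be applied
to incompatibly assembled features. `seq_len` may be anything from 30 to
365 days; 365 is the scientific default, while the bundled synthetic
experiments use 60 to keep the full chain fast on one CPU.

## Dataset construction

Pseudo-absences are drawn with a date uniform over the presence window
and a land cell drawn with probability proportional to the cosine of the
cell-center latitude, which makes the background approximately uniform
per unit area on a regular lat/lon grid. A draw is rejected outright if
its cell contains *any* presence record (rejection is by shared grid
cell, not exact coordinates), and dates that do not leave `seq_len` days
of climate history are redrawn. The **absence ratio** is the
presence : pseudo-absence count ratio: the default 0.2 yields five
background points per presence (`round(n_presence / 0.2)` in total).

Two split protocols are provided: a random 80/20 split, and a
chronological split reserving the newest 20% of presences -- both pair
the test presences with an equal number of randomly chosen
pseudo-absences, so test AUC is computed on balanced classes.
Stratified k-fold assignment (default k = 5) supports cross-validation;
folds are stratified because the classes are deliberately imbalanced.

## Network, loss, and early stopping

The classifier is a fully connected ReLU network with hidden sizes
128/64/32 on the standardized flattened sequence, a single logit output,
and the numerically stable fused binary cross-entropy-with-logits loss.
Optimization is Adam (learning rate 0.001, standard moment constants) on
minibatches of 256, with z-score normalization fitted on the training
split only. Early stopping monitors validation AUC and returns the
weights of the *best* epoch, not the last: patience is 10 epochs during
cross-validation and 100 during final training, with a cap of 1000
epochs. Weight initialization is seeded uniform fan-in; a fixed seed
makes training bit-reproducible (single-threaded deterministic kernels).
There is no retraining on train+validation after the stopping epoch: the
best epoch's weights are final.

Choices the method leaves open, fixed here: batch size 256, 1000-epoch
cap, standard Adam constants, and the validation carve-out for final
training described in the next section. All of them are recorded in the
model checkpoint.

## FNR calibration

Raw scores are converted to false negative rates through the empirical
CDF of presence scores: `FNR(s)` is the fraction of reference presences
scoring strictly below `s` -- the fraction of known presences that would
be missed if `s` were the detection threshold. Ties count as detected
(the conservative direction), the step function is used as-is (no
smoothing or interpolation), and the sorted reference is stored inside
the model checkpoint. Being a monotone transform, the FNR preserves
ranking, so ROC/AUC computed on FNR maps equals ROC/AUC on raw scores;
an FNR map is therefore a "risk percentile" map whose values are
comparable across models with different hyperparameters.

**Reference population.** The percentile reading requires the reference
scores to be exchangeable with the scores of genuinely new presences.
Presences the optimizer has gradient-fit do not satisfy this: on the
bundled synthetic world their score distribution sits visibly above that
of fresh presences (two-sample Kolmogorov-Smirnov D around 0.25), which
would bias every FNR downward. habnet therefore carves a seeded fraction
of the presences (`calibration_fraction`, default 0.4, paired with an
equal number of pseudo-absences) out of the training split before
gradient descent; this carve serves as the early-stopping validation set
and, scored by the final weights, as the calibration reference. The
carve stays inside the training split -- test data never touches the
reference -- and `calibration_on = "training"` restores the naive
variant for comparison. Out-of-fold pooling across cross-validation
models was considered and rejected: scores from differently trained
networks live on different scales, and pooling them degrades the
calibration as badly as the naive choice.

`uniformity_check()` packages the diagnostic: on held-out presences the
FNR values should be approximately Uniform(0, 1) (one-sample KS test).

## Evaluation and ablation

AUC is the rank-based (Mann-Whitney) statistic with half-credit for
ties. The ablation harness retrains the model for the full covariate
set, every leave-one-out subset, and every leave-two-out subset --
1 + 5 + 10 = 16 subsets for the five base variables -- for each requested
sequence length (30/60/90/365 by convention) and split protocol, reusing
one pseudo-absence pool and one split per sequence length so that AUC
differences reflect covariates rather than resampling noise. Subsets are
ranked by their best AUC across sequence lengths; ties break
lexicographically by subset label. Some descriptions of the method count
"four" climate variables while five are listed; the harness takes the
base set as an argument (default: all five) rather than resolving the
discrepancy silently.

Binarized risk maps are compared by Jaccard similarity (intersection
over union of the cells meeting an FNR threshold), including the full
threshold-by-threshold comparison matrix. Two empty exceedance sets
compare as identical (similarity 1). Any externally produced raster on
the same grid -- for example a MaxEnt cumulative-output map, whose
native scale is already an FNR -- can be read through the I/O layer and
compared; no MaxEnt reimplementation is included.

## Seasonality analytics

Daily FNR stacks support period averages, season averages (MAM/JJA/SON/
DJF, with December assigned to the following year's winter), transition
maps (differences of successive seasons), and historical difference
maps. Change in transition *strength*
(`|transition| recent - |transition| baseline`) is signed so that
negative values mean temporal homogenization and positive values
temporal diversification.

The **season diameter** `d` of a location is the length of the shortest
contiguous window of days containing 95% of the year's cumulative FNR
mass, computed on the circular year (windows may wrap December into
January, so a southern-hemisphere season is not artificially split);
**seasonality** is `1/d`. The production implementation is a two-pointer
sweep over the doubled series; the test suite proves it equal to an
exhaustive search over all 365 starts and lengths. Ties break toward the
earliest starting day. The **season midpoint** is the first day within
the diameter window at which the cumulative mass from the window start
reaches half of the year's total -- the day splitting the location's
cumulative FNR into halves, placed inside the window so that wrap-around
seasons get midpoints near New Year rather than mid-year artifacts.
All-zero series are degenerate: they get no season and are excluded
downstream. Series are always length 365: in leap years Feb 29 is
averaged into the day-59 bucket. For multi-year summaries the per-year
diameters are averaged; the bundled analyses use single years.

For map rendering only, `exclusion_mask()` masks locations whose season
midpoint falls within 10 days (circularly) of January 1 -- these are
near-polar locations with negligible cumulative FNR whose "season" is an
artifact -- and reports the 2nd/98th percentile clip range of the
remaining seasonality values (type-7 quantiles, R's default). The mask
feeds no other computation.

## Burden of disease

Person-days at risk is the sum over cells and days of the cell
population wherever FNR meets the threshold (inclusive, default 0.5).
Population rasters are stored as persons per cell and resampled between
grids by area-weighted sums so persons are conserved; census years are
interpolated linearly per cell, as are daily FNR values between modeled
years (paired by day of year). Yearly burden series get an ordinary
least-squares trend with a t-based 90% prediction interval. Region masks
may be arbitrary lat/lon boxes or rasters; ocean cells are masked before
aggregation. The estimate is exposure risk only -- no vector population
size and no transmission model.

## The synthetic world

Because the real inputs (reanalysis archives, occurrence databases,
census rasters) are far too large for a test suite, the package ships a
generator for a structurally analogous planet:

* climate: mean temperature = 28 degC at the equator minus a 45 degC
  equator-to-pole gradient, plus a 10 degC seasonal sinusoid in
  hemisphere antiphase and iid daily noise (sd 1.5 degC); max/min
  temperatures sit half a diurnal range (8 degC) either side; dew point
  is the mean minus a noisy ~4 degC depression; precipitation follows a
  wet-season sinusoid; two rectangular continents form the land mask;
* habitability: a logistic law on the 30-day trailing means of mean
  temperature and daily precipitation,
  `logit(h) = 1.0 - 0.08 (T30 - 26)^2 + 0.15 (P30 - 3)`,
  i.e. a quadratic thermal niche around 26 degC with a mild wet bias --
  deterministic given the climate, so it can be recovered and scored;
* observations: a thinned point process, one Bernoulli trial per land
  cell-day with probability `effort x habitability`, jittered within the
  cell; the default effort (0.007) yields roughly 500 presences over the
  final simulated year, a deliberately sparse, community-science-sized
  sample;
* population: a smooth two-hotspot density at two census years with
  configured totals.

The default world is a 40 x 80 global grid over two simulated years
(the first year exists to provide climate history). Under these
reference conditions -- seed 1, sequence length 60, absence ratio 0.2,
random split, default training configuration -- the trained model
reaches held-out AUC around 0.87, Spearman correlation around 0.9
between the annual-mean FNR map and the annual-mean true habitability,
and held-out presence FNRs that pass the KS uniformity check; the
acceptance tests assert AUC >= 0.85, Spearman >= 0.7, and KS p > 0.01 at
n = 200. The full chain (world, training, a year of daily maps,
seasonality, burden) runs in about two minutes on one CPU.

What the synthetic world does *not* emulate: spatial autocorrelation of
weather beyond the smooth latitudinal laws, observation effort gradients
(effort is spatially uniform unless configured), taxonomic reporting
biases, coastline geometry, and interannual climate trends. Passing
tests therefore demonstrate that the machinery recovers a known signal
under honest sampling -- not that any particular real-world map is
correct.

## Numerical and I/O choices

* Grids are regular lat/lon with cell-center registration; nearest-cell
  snapping uses plain lat/lon Euclidean distance with a deterministic
  tie-break (lower row, then lower column). Longitudes normalize to
  [-180, 180).
* Kelvin inputs convert to Celsius only when units metadata says "K" --
  never by value heuristics.
* Rasters persist as per-day float32 GeoTIFFs (written by a minimal
  built-in encoder, since no available R package writes float TIFF
  samples; read back through libtiff) with a JSON sidecar for grid
  geometry and units, plus long-format CSV. NetCDF is not supported in
  this build and is reported as such rather than silently remapped.
* Model checkpoints are single RDS archives (weights, scaler,
  calibration reference, config, training log); reload is bit-exact.
* The loss is evaluated in the fused softplus form, stable for logits of
  either sign and any magnitude.
* Ocean cells receive predictions by default and are masked only on
  output/visualization; this is configurable at the masking step.

## Known limitations

* Training is plain R matrix algebra: fine for the bundled scales
  (thousands of examples, a few hundred features) but not for decades of
  global daily prediction, which is the realm of the original GPU
  pipelines.
* The FNR transform calibrates marginally, not regionally: uniformity of
  held-out presence FNRs is a global property and can hide compensating
  regional biases.
* Pseudo-absence sampling implements the cosine-latitude scheme only; no
  target-group background or environmental stratification.
* The chronological split pairs newest presences with *randomly* dated
  pseudo-absences, so temporal covariate drift affects only the presence
  side of the test set.
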