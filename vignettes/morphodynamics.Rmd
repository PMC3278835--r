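---
title: "Models and methods behind morphodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind morphodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`morphodyn` turns time-lapse movies of motile cells into two coupled feature
sets — whole-cell motility and membrane (edge) dynamics — and provides the
statistical machinery to discover subpopulations in them and to quantify how
they co-vary. This vignette documents the models, the tunable parameters and
the numerical choices, including the places where a design decision was
genuinely open and we had to pick.

## The persistent random walk and its eight features

Cell velocity is modelled as a 2-D Ornstein–Uhlenbeck process with
root-mean-square speed $S$ (µm/h) and correlation time $P$ (h), so the mean
squared displacement of the centroid is

$$\mathrm{MSD}(t) = 2 S^2 P \left[ t - P\left(1 - e^{-t/P}\right) \right],$$

ballistic ($S^2t^2$) below $P$ and diffusive ($2S^2Pt$) above it.
`computeMSD()` averages over all overlapping interval pairs (lag $k$ has
$T-k$ pairs) and `fitPRW()` fits the closed form by weighted nonlinear least
squares (Levenberg–Marquardt, via minpack.lm), weighting each lag by its
pair count — the sampling variance of a time-averaged MSD point scales
inversely with the number of pairs, so short lags carry more weight.

Two numerical choices matter here:

* **Lag truncation.** By default only the shortest
  $\max(5, 0.25\,(T-1))$ lags enter the fit. Long-lag points of a
  single-track MSD are dominated by realization noise (at lag $T-1$ a single
  pair remains), and including them destabilizes the fit through the
  $S$–$P$ exchange degeneracy: an underestimated $P$ can be compensated by
  an inflated $S$ on the diffusive branch. Fitting the early curve is the
  standard remedy; `lagFrac = 1` restores the full-curve fit.
* **Fundamental limit of single-track estimates.** A track of duration $T$
  contains only $\approx T/P$ independent velocity samples, so the relative
  standard deviation of any estimator of $S$ is about $\tfrac12\sqrt{P/T}$.
  For a 100-frame track at 10-minute intervals with $P = 2$ h this floor is
  ~17 % (≈ 12 % median absolute error), which our simulations reproduce.
  Single-cell $\hat S$ values should be read with that granularity in mind;
  class means are correspondingly tighter.

The eight features per cell are $S$, $P$, the chemotactic index
$CI = TD/TPL$, total path length $TPL$ (sum of step lengths), total
displacement $TD$, random motility coefficient $RMC = S^2P/2$ (the long-time
2-D diffusion coefficient of the PRW), mean path length $MPL = TPL/(T-1)$
and persistence length $PrL = S \cdot P$. The published per-class reference
table that ships with the package satisfies $PrL = S \cdot P$ exactly in all
four classes, which pins down that identity; the remaining definitions
($CI$, $RMC$, $MPL$) are declared package conventions — standard in the
motility literature, but not uniquely recoverable from class-averaged
numbers, so each is kept as a separate documented function of the fitted
parameters. When the fit does not converge the features fall back to the
mean frame-to-frame speed and one frame interval, flagged `fallback`; a
fitted $P$ beyond ten observation windows is flagged `ballistic` because the
data only bound it from below.

## Edge prints

For each complete track the boundary polygon at every frame is resampled
onto $M$ equiangular polar markers about that frame's own centroid
(translation is thereby removed; rotation is deliberately **not**
compensated, a documented caveat). The signed radial displacement
$\Delta_m = r_m(t+\tau) - r_m(t)$ of each marker is split into its positive
and negative parts:

$$p_t = \frac{1}{M\tau}\sum_m \max(\Delta_m, 0), \qquad
  r_t = \frac{1}{M\tau}\sum_m \max(-\Delta_m, 0),$$

yielding $2(T-1)$ features (22 for $T = 12$) in µm/min. Choices:

* $M = 360$ by default (1° resolution) — finer than any boundary feature at
  0.707 µm pixels; halving or doubling $M$ changes a smooth print by < 2 %,
  which is why we normalize by $M$ (the un-normalized displacement sum is
  available with `normalize = FALSE`).
* $\tau$ defaults to one frame interval (adjacent frames).
* Non-star-shaped outlines: each ray keeps the **outermost** intersection
  with the polygon, which preserves protruding tips and is deterministic.
* Positive $\Delta_m$ is protrusion, negative is retraction; both features
  are non-negative by construction, and a rigidly translated cell has an
  all-zero print.

## Segmentation and tracking

Frames are segmented by the two-phase piecewise-constant (Chan–Vese) energy
$$E(\Omega, c_1, c_2) = \sum_{p\in\Omega}(I_p-c_1)^2 +
  \sum_{p\notin\Omega}(I_p-c_2)^2 + \mu\,\mathrm{Per}(\Omega),$$
whose region terms make it independent of initialization and of edge
gradients. We minimize the discrete energy directly: exact updates of
$c_1, c_2$ alternate with checkerboard sweeps of single-pixel moves, each
accepted only when it lowers $E$, so the energy is provably non-increasing —
a property an explicit level-set PDE discretization does not guarantee — and
iteration stops when the relative change drops below `tol` (default 1e-6).
The single regularization parameter is the length weight $\mu$; its default
$0.1 \times (\text{intensity range})^2$ scales the penalty to the image's
dynamic range so one mis-labelled bright pixel (data cost
$\sim \text{range}^2$) outweighs its perimeter cost. Touching cells are then
split by watershed on a Gaussian-smoothed ($\sigma = 2$ px) distance
transform, whose regional maxima act as shape markers; components with a
single marker pass through unchanged, and the foreground union is never
altered. Regions smaller than 50 px are discarded as noise specks at the
stated pixel size. Boundaries are traced at the 0.5 iso-level of the label
indicator (sub-pixel, counter-clockwise, (row, col) 0-based).

Frame-to-frame linking minimizes the total cost
$w_{pos}\,d/g + w_{size}\,|\Delta A|/A_{\max} + w_{int}\,|\Delta I|/I_{\max}$
over one-to-one assignments (Hungarian algorithm, via clue), gated at
centroid displacement $g$ (50 px default — mask overlap between frames is
deliberately not assumed). The weight defaults (0.5, 0.25, 0.25) encode that
position dominates at 10-minute sampling; the upstream reference settings
are not published, so the weights are exposed in the configuration. Near-tie
candidates within 1.5× the assigned cost create one-to-many links, resolved
by the three-frame heuristic: a one-to-two link is a DIVISION only if both
children have their own matches one frame later, otherwise the fragments are
re-merged as an OVERSEG (from the label masks when available, else by
area-weighted pooling); at the movie's final transition, where no third
frame exists, the conservative default is a plain match, logged. A division
closes the parent track and opens two children, so complete-track filtering
excludes divided lineages — consistent with requiring cells observed over
the entire period.

## Mixture modelling, MDL and two-phase K-means

Motility features are standardized (they span three orders of magnitude) and
modelled as a $K$-component full-covariance Gaussian mixture fitted by EM
from a K-means partition. Every covariance update receives a ridge of
$10^{-6}\times$ the mean feature variance so degenerate components stay
positive definite; the log-likelihood is non-decreasing by construction and
convergence is declared at a relative change of $10^{-5}$. A run is
re-attempted with fresh initial conditions (up to 5 times) until it
converges; the alternative best-of-all-restarts policy is available as
`restartPolicy = "best"`. The model order minimizes

$$\mathrm{MDL}(K) = -\log L(\hat\Theta_K) + \tfrac12 L_p \log(Nn), \qquad
  L_p = K\left(1 + n + \tfrac{n(n+1)}{2}\right) - 1,$$

where the penalty argument includes the feature count $n$; the classical
$\log N$ form is one configuration switch away. Edge prints inside each
class are subclustered by two-phase K-means: a first K-means pass on a
uniform 10 % subsample (5 random starts — the subsample is small, so extra
starts are cheap insurance) supplies the initial centroids of the full-data
pass, sidestepping K-means' initialization sensitivity; up to 1000
iterations per phase. The number of edge subclusters defaults to the
MDL-selected order on the class's edge prints when the class is large
enough, with a fixed-$K$ override. Normality diagnostics (probability-plot
coordinates with midpoints $(j-0.5)/N$ and a first/third-quartile reference
line, and a chi-square GOF test with equal-probability bins and $n_{bins}-3$
degrees of freedom) are provided to justify the Gaussian mixture; following
the original practice, features failing normality are flagged but never
dropped automatically.

## Correlation, jackknife and factor analysis

Edge prints are time-averaged into two scalars (mean protrusion and mean
retraction velocity) and joined with the eight motility features. Spearman
rank correlations get two-sided p-values from
$t = \rho\sqrt{(N-2)/(1-\rho^2)}$ on $N-2$ d.f. — within 0.02 of the exact
permutation p-value at the class sizes where we could enumerate all $N!$
permutations — flagged at raw $p < 0.05$ (the conventional report), with
Benjamini–Hochberg-adjusted flags emitted alongside. Multiple correlation is
the OLS $R^2$ of speed on all remaining features. The leave-one-out
jackknife reports the mean ± sd of delete-one correlations per (motility,
edge) pair, exposing influence of single cells; it defaults to Spearman for
consistency with the main analysis. Factor analysis extracts principal axes
from the feature **covariance** matrix (loadings = eigenvectors scaled by
root eigenvalues, matching the convention of covariance-based loading
tables) while the Kaiser retention rule is applied to the eigenvalues of the
**correlation**-scaled matrix, its standard home; retained loadings are
varimax-rotated (the sparse published loading structure indicates rotation)
and magnitudes below 0.4 are suppressed in the report view, with the full
matrix always emitted alongside. Per-class matrices and a pooled matrix are
both produced, since class-wise analyses and a single pooled loading table
are both plausible readings of the original report.

## The synthetic generator: what it emulates, and what not

`simulateCellMovie()` renders each cell as a star-shaped region
$r(\theta, t) = R + \sum_j A_j \sin(f_j\theta + \psi_j + \omega_j t)$
centred on an exact integrated-OU track (the joint Gaussian transition of
position and velocity is sampled exactly, so the ensemble MSD matches the
PRW closed form at every lag, not only asymptotically). Defaults emulate the
imaging conditions the pipeline targets: 12 frames at 10 min, 0.707 µm
pixels, 12-bit range, bright cells (3000) on dark background (200) with
additive Gaussian noise (sd 50), radius 12 µm, speed 10 µm/h, persistence
2 h — speeds and persistences in the range of cultured macrophage-like
cells. The three default boundary modes give per-marker displacements of
~1–2 µm per interval, the magnitude of lamellipodial ruffling. Ground-truth
boundaries are evaluated analytically and resampled on the same equiangular
grid the edge module uses, about the polygon's own centroid, so recovered
and true prints are comparable without resampling error. Cells are placed on
a jittered grid with margins covering 1.5× their RMS travel; configurations
that cannot be placed without overlap are rejected. One optional division
event (cell 1 splits into two √2-smaller children) exists solely to exercise
the tracker's division branch.

What the generator does **not** emulate: photon statistics and camera noise,
intensity gradients inside cells, rotation, shape changes that are not
radial about the centroid, cell–cell adhesion or crowding, and focus drift.
Passing the closed-loop tests therefore demonstrates correctness of the
algorithms under the stated model, not robustness to every artefact of real
microscopy; on real data the segmentation (`lengthWeight`) and gating
parameters are the knobs to revisit first.

## Problem sizes used in the shipped checks

The test-suite simulations are sized to exercise each claim at its stated
tolerance: 2000 tracks for the ensemble-MSD comparison (5 %), 20 seeds ×
2000 samples for MDL order recovery over $K = 2..10$, 500 noisy 100-frame
tracks for single-track speed recovery, movies of 4–10 cells at 384–512 px
for the imaging loop, and full $N!$ permutation enumeration at $N = 7..8$
for the Spearman oracle. CSV intermediates are written with 17 significant
digits so a resumed run reproduces downstream fits bit for bit.

## Known limitations

* Rotation of non-circular cells appears as spurious protrusion/retraction
  (inherent to radial markers with centroid-only alignment).
* Gap closing across more than one missing frame is out of scope; a cell
  lost for one frame starts a new track.
* The chi-square GOF test uses moment estimates inside equal-probability
  bins; with very heavy tails the moment fit itself is fragile.
* Single-track $\hat S$, $\hat P$ carry the sampling floor discussed above;
  interpret per-cell values through class aggregates.
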