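---
title: "The persistent random deformation model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The persistent random deformation model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prdcell)
```

`prdcell` implements a shape-based description of crawling cells: the outline
of a cell is reduced to a few complex Fourier modes, the centroid velocity is
tied to the *rates of change* of those modes by a bilinear migration law, and
a stochastic model built on that law (the persistent random deformation, PRD,
model) reproduces the statistics of persistent, back-and-forth migration on
elastic substrates. This vignette records the model, the conventions, the
numerical choices, and the reasoning behind every place where the design was
genuinely open.

## Shape modes

For each frame the cell outline (a closed polygon in micrometres) is reduced
to the radial profile $R(\theta)$ — the distance from the area centroid to
the rim along the ray at angle $\theta$, measured counterclockwise from the
$x$ axis on a uniform grid (default 360 samples). The profile is averaged
over $\theta \pm 6^\circ$ (a circular 13-sample window at the default grid)
to suppress segmentation noise, and projected on circular harmonics:

$$C_n = \langle R(\theta)\, e^{i n \theta} \rangle_\theta , \qquad
R(\theta) \approx R_0 + \sum_{n\ge 2} \left( C_n e^{-i n \theta} +
\bar C_n e^{i n \theta} \right).$$

$|C_2|$ measures elongation, $|C_3|$ triangularity, and the phase
$\phi_n = \arg(C_n)/n$ (reduced to $[0, 2\pi/n)$) is the direction of
maximum deformation. Two sign conventions exist for the kernel; they differ
only in which member of the conjugate pair is called $C_n$. We use the
$e^{+in\theta}$ kernel because it is the one under which (i) $\phi_n$ points
at the deformation maximum, and (ii) a rigid rotation of the cell by
$\theta_0$ multiplies $C_n$ by $e^{in\theta_0}$, so that the bilinear
migration law below transforms exactly like a velocity. Under the opposite
kernel the predicted velocity would rotate *against* the cell, which is
unphysical.

Mode $n = 1$ encodes residual displacement of the centroid; since the
centroid is recomputed per frame it is close to zero, and it is retained
only as a quality diagnostic (`fourier_modes()$c1`). For non-star-convex
outlines the outermost ray crossing is used, which preserves protrusion
signal; if the centroid falls outside the outline the frame is rejected with
an explicit error. The $\pm 6^\circ$ average is applied to $R(\theta)$
*after* centroid computation (the centroid is a polygon-area property and
should not depend on the angular resampling).

A practical consequence worth knowing: the angular box average attenuates
$|C_n|$ by a factor $\tfrac{1}{13}\sum_{s=-6}^{6}\cos(n s^\circ)$
($\approx 0.99$ for $n = 2$, $0.98$ for $n = 3$). Mobility coefficients
fitted on smoothed modes are therefore inflated by a few percent relative to
the generating values; the test suite pins this down on noise-free synthetic
contour movies.

## Observation pipeline

Positions and modes are sampled every $\tau = 5$ min. Before any rate is
computed, each series is smoothed with a centred 3-point moving average
(ends shrink symmetrically to the available window — the scheme is then
exact for linear trends at the ends); rates are forward differences
$(s_{k+1} - s_k)/\tau$ expressed per hour and aligned to the left sample.
A centred (rather than trailing) average was chosen because the analysis is
retrospective and a trailing window would bias rate estimates by half a
sample. All trajectory statistics in the package operate on the smoothed
positions, consistently with the velocities derived from them.

## The migration law

Writing the velocity as $v_1 = v_x + i v_y$ (µm/h), the law is

$$v_1 = \beta_1 \dot{\bar C}_2 C_3 - \beta_2 \bar C_2 \dot C_3 ,$$

with mobilities $\beta_1, \beta_2$ (µm$^{-1}$). Both terms have rotation
order $-2 + 3 = 1$, so the law is rotation-equivariant, and it is odd under
time reversal: retracing a shape change backwards retraces the path. A
static shape implies a motionless cell. The general form
(`predict_velocity_general()`) adds $\beta_c \bar C_2 C_3$, the
shape-determined (keratocyte-type) term; $\beta_c = 0$ recovers the
deformation-rate law.

`fit_mobility()` minimizes $S = \sum |V - v|^2$ by stacking real and
imaginary parts and solving the normal equations in closed form (QR). The
fit pools all samples across cells — a population-level estimate. 95%
intervals come from the standard linear-model covariance with
$\hat\sigma^2 = S/(2n - k)$; this is the natural interval for a
least-squares fit and the only reasonable reading of a least-squares
procedure with reported confidence bounds. Samples whose regressors both
vanish carry no information and are dropped with a message. An AIC,
$n\ln(\mathrm{RSS}/n) + 2k$ on the stacked residuals, is attached for
comparing candidate laws on identical data.

Note that when the regressors are built from *noisy* observed modes, the
usual errors-in-variables attenuation applies: mobilities estimated from
observation-noise-laden data are biased toward zero relative to the
generative values. This is expected and visible when fitting the law to the
simulator's noisy output.

## The PRD model

The modes evolve under restoring forces, motion couplings and fluctuating
internal force multipoles:

$$\dot C_2 = -\kappa_2 C_2 - \alpha_2 \bar v_1 C_3 + F_2, \qquad
\dot C_3 = -K_3 C_3 - \alpha_3 v_1 C_2 + \beta_3 \bar C_3 F_6 + F_3,$$
$$K_3 = \kappa_3 + \gamma_3 |C_3|^2, \qquad
\dot F_i = \kappa_f (-F_i + \sigma_i \xi_i), \quad i = 2, 3, 6,$$
$$\Gamma_v v_1 = \alpha_v \bar v_1 C_2 + \beta_1 \dot{\bar C}_2 C_3
- \beta_2 \bar C_2 \dot C_3, \qquad \Gamma_v = 1 + \gamma_v |C_2|^2 .$$

Every coupling obeys the rotation-order selection rule (the factor orders
must sum to the order of the left-hand side; `validate_coupling_term()`).
The forces are red noise — Ornstein–Uhlenbeck processes with cut-off rate
$\kappa_f$ and stationary per-component spread $\sigma_i\sqrt{\kappa_f/2}$ —
because the internal force distribution rearranges slowly compared to the
frame rate. $\alpha_v > 0$ steers motion along the elongation axis and,
near its stability boundary, amplifies speeds multiplicatively, which is
what produces the exponential (heavier-than-Gaussian) velocity tails;
$\gamma_v$ bounds that amplification. $\beta_3 \bar C_3 F_6$ acts as
multiplicative noise on the triangular mode (fattening its distribution
tail) and $\gamma_3$ keeps it from diverging.

**Velocity solve.** Because $\dot C_2$ and $\dot C_3$ themselves contain
$v_1$, the velocity equation is a conjugate-linear system
$A v_1 - \alpha_v C_2 \bar v_1 = b$ with
$A = \Gamma_v + \beta_1\alpha_2 |C_3|^2 - \beta_2\alpha_3 |C_2|^2$ and
$b = \beta_1(-\kappa_2 \bar C_2 + \bar F_2) C_3 - \beta_2 \bar C_2
(-K_3 C_3 + \beta_3 \bar C_3 F_6 + F_3)$, solved exactly:
$v_1 = (A b + \alpha_v C_2 \bar b) / (A^2 - \alpha_v^2 |C_2|^2)$.
The default scheme uses this simultaneous solve each step — it is
well-defined at any step size and avoids an undocumented one-step lag — and
a `lagged` scheme (previous step's velocity in the couplings) is provided;
the two converge to each other as $\mathrm{d}t \to 0$, which the tests
check on frozen noise paths. A denominator below $10^{-10}$ raises a
singular-velocity error naming the state: it signals parameters beyond the
amplification stability bound
$\gamma_v - \beta_2\alpha_3 > \alpha_v^2/4$ (the condition for
$A > \alpha_v |C_2|$ at every $|C_2|$ when $\alpha_2$ is small).

**Integration.** Euler–Maruyama with $\Delta t = 0.5$ min (forces advance
as $F' = F - \kappa_f F \Delta t + \kappa_f \sigma \xi \sqrt{\Delta t}$,
then the velocity solve, then the Euler update of $C_2$, $C_3$, $x$, $y$) —
first-order, verified by step-halving on frozen noise. Cells start from the
zero state and a 5-hour burn-in is discarded so recorded series are
stationary (the slowest relaxation, $1/\kappa_2 \approx 2.6$ h, is well
inside that window). States are sampled every 5 min; independent Gaussian
observation noise ($\sigma_0 = 1$ µm by default, the scale of typical
image-processing error) is added to $x$, $y$ and to the real and imaginary
part of each mode; the observation pipeline above is then applied verbatim.
Each cell consumes an independent noise substream derived from the master
seed, in a fixed documented order (per step $F_2, F_3, F_6$; then the
observation noise), so ensembles are bitwise reproducible and cell $k$ does
not depend on how many cells are requested.

## Parameters

Three presets carry the published per-substrate estimates, with the noise
scales back-computed from the non-dimensional forces
$\sigma_n / (R_0 \kappa_n)$ and the printed mean radii:

| preset | $\beta_1$ | $\beta_2$ | $\kappa_2$ | $\kappa_3$ | $R_0$ | $\sigma_2/(R_0\kappa_2)$ | $\sigma_3/(R_0\kappa_3)$ |
|---|---|---|---|---|---|---|---|
| `table2_35kPa` | 1.21 | 0.24 | 0.38 | 1.55 | 23.9 | 0.66 | 0.026 |
| `table2_120kPa` | 0.83 | 0.15 | 0.40 | 1.11 | 26.6 | 0.64 | 0.036 |
| `table2_410kPa` | 0.59 | 0.07 | 0.40 | 0.51 | 27.2 | 0.67 | 0.076 |

(units: µm$^{-1}$, h$^{-1}$, µm). The remaining coefficients are not
published in the main text; this package ships one set of calibrated
defaults, chosen once so that the 35 kPa ensemble reproduces the qualitative
statistics of the system — exponential-tailed velocity components,
shape-autocorrelation times of a few hours exceeding the velocity
correlation time, back-and-forth motion (rotation angles peaked at 180°)
and a short-lag MSD exponent in the superdiffusive 1.6–1.7 range — and not
revisited thereafter:

| parameter | default | units | role |
|---|---|---|---|
| $\alpha_v$ | 0.5 | µm$^{-1}$ | motion along the elongation axis; speed amplification |
| $\gamma_v$ | 0.0669 | µm$^{-2}$ | just above the stability bound $\alpha_v^2/4 + \beta_2\alpha_3$ for all presets |
| $\kappa_f$ | 0.75 | h$^{-1}$ | force memory ($\sim$ 80 min), sets stroke duration |
| $\alpha_2, \alpha_3$ | 0.01 | µm$^{-1}$ | weak shape response to motion |
| $\gamma_3$ | 0.3 | µm$^{-2}$ h$^{-1}$ | bounds the multiplicatively pumped $C_3$ |
| $\beta_3$ | 0.3 | µm$^{-1}$ | multiplicative $C_3$–$F_6$ coupling (tail fattening) |
| $\sigma_6$ | $0.25\,\sigma_3$ | µm h$^{-1}$ | hexapole force scale |
| $\sigma_0$ | 1 | µm | observation noise |

Placing $\gamma_v$ close to its bound is deliberate: the near-singular
amplification is the mechanism behind the heavy velocity tails, and backing
it off visibly lightens them. The trade-off is a velocity-component excess
kurtosis well above the Laplace value of 3, i.e. the default tails are
somewhat heavier than a pure exponential.

## Trajectory and shape statistics

* **MSD** — time-averaged per cell over all start points, then an
  unweighted ensemble mean (tracks of unequal duration then contribute one
  curve each rather than in proportion to their length). Computed on the
  smoothed positions, consistent with the rest of the pipeline. The
  short-lag exponent is the log–log slope over 10–60 min by default; the
  window is configurable and reported alongside.
* **Autocorrelations** — per track after per-track mean subtraction,
  normalized at lag zero, then equal-weight ensemble averaging; for complex
  series the real part of $\langle a(t+\tau) \bar a(t)\rangle$. Note the
  finite-track bias of mean subtraction ($\approx -2 t_c / T$), which is
  why observed and simulated summaries must use matching track lengths
  when compared (see the fitting section).
* **Symmetrized densities** — by isotropy the real and imaginary components
  of $v_1$, $C_2$, $C_3$ share one distribution; both components are pooled
  into a single density histogram with bins centred on zero.
* **Persistence** — $CV(t) = v_x(t+\Delta t) v_x(t) + v_y(t+\Delta t)
  v_y(t)$ with $\Delta t = 10$ min; a sample is persistent when $CV$
  exceeds $2/3$ of its per-track median, and maximal persistent runs form
  segments. A segment's span includes the displacement step of its last
  velocity sample, so even one-sample runs have a direction; its length is
  the summed step length (never less than the net displacement).
* **Rotation angles** — the unsigned angle between net-displacement vectors
  of successive segments, in $[0^\circ, 180^\circ]$, with $180^\circ$ =
  reversal. This folding makes the statistic invariant under time reversal
  of the track. Histogramming uses bins centred at multiples of
  $20^\circ$; the end bins at $0^\circ$ and $180^\circ$ cover half the
  width and are density-corrected (`modal_rotation_bin()`), which is
  exactly equivalent to binning the symmetric full-circle distribution on
  $[0^\circ, 360^\circ)$.
* **Persistent-length CCDF** — the empirical $P(X > x)$ at the sorted
  sample points; an exponential tail appears as a straight line on a log
  ordinate.
* Tracks shorter than 8.3 h are excluded (with a log message) before any
  population statistic, mirroring the study's inclusion filter.

## Fitting the model to summary statistics

The ERR objective compares eight summaries: quantile–quantile $R^2$ (99
interior percentiles) for the symmetrized component distributions of $v_1$,
$C_2$, $C_3$ and for the two phase differences
$\arg v_1 - \arg(\dot{\bar C}_2 C_3)$ and
$\arg v_1 - \arg(\bar C_2 \dot C_3)$, plus curve $R^2$ for the
autocorrelations of $v_1$, $C_2$, $C_3$ on the common lag grid;
$\mathrm{ERR} = \sum_i (1 - R_i^2)$, itemized per component so a mismatch
can be attributed.

`fit_prd()` minimizes ERR over a chosen parameter subset in two stages: a
seeded random multiplicative scan (default ±50%) around the initial values
— standing in for the study's manual pre-search, whose ranges are not
published — and then 20 Nelder–Mead restarts in log-parameter space from
jittered starts. Each restart evaluates all its candidates with one fixed
simulation seed (common random numbers), making the per-restart objective
deterministic; the restart-to-restart spread then measures the residual
simulation noise, and results are reported as mean ± sd across restarts
with the best-ERR set attached. Because of the ACF mean-subtraction bias,
the fitting simulations use the same per-cell duration as the observed
ensemble; ignoring this drags relaxation-rate estimates low. With a
24-cell × 16 h budget per evaluation and 180-min ACF lags, the restricted
$(\kappa_2, \sigma_2)$ fit in the acceptance suite recovers the generating
values within the across-restart spread in a few minutes of CPU time.

The PRW baseline uses the two-dimensional Fürth form with an additive
observation-noise offset, $\mathrm{MSD}(t) = 4D\,(t - P(1 - e^{-t/P})) +
4\sigma_0^2$ (our choice of dialect; the study's exact expression is in its
supplement), fitted by Nelder–Mead on weighted residuals with weights
$1/n_\mathrm{pairs}$ per lag, from several deterministic starts.

## The synthetic-data module

`mode_program()` / `generate_contour_movie()` render contour movies from
prescribed mode trajectories (ramps, sinusoids, or PRD output) with
per-vertex radial noise, alongside the ground-truth mode table — so every
pipeline stage (contours → profiles → modes → rates → law fit) can be
scored against a known answer without re-simulation. The generator emulates
what the analysis consumes: star-convex outlines with band-limited radial
shape and white vertex noise. It does **not** emulate segmentation
artifacts (merged cells, dropped frames), pixelation, non-radial boundary
noise, or shapes whose centroid leaves the outline; passing tests therefore
validate the analysis chain, not robustness to those real-data failure
modes, which the inclusion filters upstream are assumed to remove.

## Sizes, tolerances and other numerical choices

* Test and acceptance ensembles use 100 cells × 16 h (the scale of the
  experimental cohorts); the fit demonstration uses a 60-cell observed
  ensemble and 24-cell evaluation budget. These sizes are the package's
  choice of a demonstration scale with stable statistics.
* Singular-velocity guard $10^{-10}$ on the solve denominator; ray–edge
  intersections accept $s \in [-10^{-9}, 1 + 10^{-9}]$ so rays through a
  polygon vertex are kept; degenerate (zero-area) polygons are rejected.
* A zero mode amplitude has no phase: `phase_decomposition()` flags it
  rather than returning an arbitrary angle; joint-phase statistics use
  $\arg C_n$ directly (not the folded $\phi_n$) to avoid branch artifacts.
* Zero-net-displacement segments are skipped (and counted) in rotation
  angles; empty histogram bins are omitted from binned outputs.
* CSV files carry a `#prdcell,v1,<kind>` header line; angles are degrees in
  files and radians in memory; complex columns are stored as `_re`/`_im`
  pairs.

## Known limitations

* The simulator truncates the mode hierarchy at $n = 3$ (the evolution
  equations for higher modes live in the study's supplement and are not
  reproduced here). The integrator's state layout accepts additional force
  multipoles, but shape reconstruction from simulations is limited to
  modes 2–3.
* The calibrated defaults for the unpublished coefficients are one
  qualitative operating point, not fitted values; per-substrate differences
  in those coefficients are not represented.
* The ERR objective implements the components named in the study's methods;
  any supplementary-only extras (e.g. persistent-length terms) are not
  included, though the itemized design makes them easy to add.
* `fit_prd()` is a local, stochastic-objective optimizer: it documents
  spread across restarts but offers no global-optimality or posterior
  guarantees.
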