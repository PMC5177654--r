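---
title: "Methods: encoding models, unscented Kalman decoding, and the synthetic session harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encoding models, unscented Kalman decoding, and the synthetic session harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the models it
implements, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical and design choices made where
the design was genuinely open. Everything quantitative stated here is
computed by the test suite or `scripts/acceptance.R`; nothing is quoted
from elsewhere.

## The decoding problem

An intracortical BMI observes spike counts of $n$ units in 50 ms bins and
must estimate the user's intended 2D cursor kinematics bin by bin. We treat
this as state estimation: a latent kinematic state $x_t$ evolves under a
linear-Gaussian transition, and the binned count of unit $i$ is a noisy
observation,

$$fr_{i,t} \approx c^\top \phi(x_t) + \text{(history terms)} + \varepsilon_i,$$

where $\phi$ collects the encoding features and $fr_{i,t}$ is mean-centred.
The decoder inverts this generative model with a Kalman filter; when
$\phi$ is nonlinear (magnitudes, interactions, target–cursor distance) the
unscented Kalman filter (UKF) propagates sigma points through $\phi$
instead of linearising by hand. The filter algorithm itself is standard;
all of the modelling lives in the observation model and in post-processing
of the filter output.

### State layouts and taps

A *tap* is a copy of the kinematic variables at a fixed bin offset kept in
the state, so the observation model can express tuning at several
latencies at once. The layouts are: position–velocity at a single tap
(dimension 4, the classical Kalman decoder); position–velocity at ten taps
$t+5 \dots t-4$ (dimension 40); and position, velocity, acceleration and
target position at five taps $t+2 \dots t-2$ (dimension 40). Only the
leading tap receives new dynamics each step; every other tap shifts — the
value at tap $k$ becomes, one step later, the value at tap $k-1$, exactly.
This shift identity is asserted in the tests.

### Encoding feature groups

Per tap: `P` = $(px, py, \sqrt{px^2+py^2})$; `V`, `A` analogously for
velocity and acceleration; `PVI` = $(px\,vx,\; py\,vy)$, a multiplicative
gain-field term motivated by velocity tuning that changes with limb
posture; `T` = $(tx, ty, \sqrt{(tx-px)^2+(ty-py)^2})$, target position and
target–cursor distance. `SH` adds the previous bin's spike counts of the
population — exactly one past bin, since longer history buys little per
added parameter. History scopes `self`, `others` and `population` restrict
which units' lagged counts each unit may use; they are implemented as
per-unit column restrictions at fitting time. The feature-count identities
(4 for the linear model, 60 for the ten-tap model, $70+n$ for the
five-tap model with history) are fixed by these definitions and asserted
structurally.

## Model fitting

Targets are mean-centred counts; features are standardised to zero mean
and unit variance internally (coefficients are stored in standardised
space with the scalers), which makes a single ridge penalty meaningful
across features measured in cm, cm/s, cm/s², and counts. The penalty is
chosen from 25 log-spaced values spanning $[10^{-6}, 10^{6}]$ times the
mean diagonal of $X^\top X$, by summed held-out MSE on the last 20% of the
training rows, followed by a refit on all rows; one penalty is shared by
all units of a model. Constant feature columns are dropped with a warning
and their coefficients reported as zero. The sample covariance of the
training residuals becomes the observation noise $R$, diagonally loaded
with $10^{-6}$ times its mean diagonal so duplicated units cannot make it
singular. Predictions are deliberately not clipped at zero: the model
class is linear-Gaussian and the filter consumes raw linear predictions.

Offline, the transition is a first-order ridge regression from one tap of
kinematics to the next (using all ten taps as regressors destabilises the
fitted model). When the layout carries target variables they form a
separate regression block: the target is decoded, but it does not directly
affect the dynamics of the other variables. In closed loop the transition
is built from physical laws — position integrates velocity; velocity
decays with friction $c_v = 0.85$ and integrates acceleration;
acceleration decays with $c_a = 0.75$ and is attracted toward the decoded
target with gain $c_g = 0.01$ (in units of cm/s² per cm of target–cursor
error, scaled by $1/dt^2$) — and only the noise covariance is fitted, as
the sample covariance of one-step residuals of the deterministic part.
With position-as-feedback (the FIT-style Kalman variant) the positional
rows and columns of that covariance are exactly zero *and* the predicted
position covariance is zeroed each step, so the decoded position is a
deterministic integral of the decoded velocity; intention estimation
re-aims training velocities at the current target preserving speed and
zeroes them inside the target, before the observation-model fit.

## Control refinements (closed loop only)

* **Future tap.** The cursor is driven from the $t+2$ tap (+100 ms),
  consistent with motor cortex leading movement.
* **Movement threshold.** With velocity belief $(\bar v, C_v)$,
  $X = \bar v^\top C_v^{-1} \bar v \sim \chi^2(2)$ under the null of zero
  intended velocity; the cursor moves only when the survival probability
  falls below $\alpha$. $\alpha$ is the false-positive move rate — the
  calibration is checked by simulation at $\alpha \in \{0.1, 0.3, 0.5\}$
  with $10^5$ draws. Default $\alpha = 0.3$, configurable per run; held
  bins swap in a transition whose leading position row drops the velocity
  term, the filter update still runs, and the velocity state is never
  zeroed so evidence accumulates across held bins.
* **Mixing.** $\bar x_t = \bar x_{t-1} + c_m\,dt\,\bar v_t +
  (1-c_m)\,dt\,\frac{\lVert\bar v_t\rVert}{\lVert\bar e_t\rVert}\bar e_t$
  with $\bar e_t = \bar p_t - \bar x_{t-1}$ and $c_m = 0.5$. At
  $\lVert\bar e_t\rVert = 0$ the position term is defined as zero
  (removable singularity). The cursor is clamped to a ±12 cm workspace
  with a message.

## Unscented transform settings

Scaled symmetric sigma points ($2d+1$) with $\alpha = 10^{-3}$,
$\beta = 2$, $\kappa = 0$. For observation models linear in the state the
update coincides with the linear Kalman update regardless of $\alpha$ up
to rounding — the suite asserts agreement to $10^{-8}$ over 100 random
systems, which doubles as the central correctness oracle. For the
magnitude nonlinearity the sigma-point update is second-order accurate:
the tests verify posterior moments against a $10^6$-sample Monte-Carlo
moment-matching oracle to 2% in a mildly curved regime (speed well away
from zero relative to its uncertainty). Near the cone point of
$\lVert v\rVert$ no second-order method matches exact moment matching
closely; this is an inherent approximation of the filter class, not a
tuning issue. Covariances are resymmetrised every step and negative
eigenvalues below $-10^{-9}$ (relative) are an error; small negatives are
floored at zero. Sigma-point factorisation uses Cholesky with an
eigendecomposition fallback for semidefinite matrices.

The initial belief replicates the last training bin's kinematics across
taps with covariance $10\,Q$: a benign burn-in, since the first 30 s of
every session are discarded anyway.

## The synthetic session harness

The generator emulates the experimental conditions the decoders are meant
for: a screen-centred workspace of roughly ±10 cm, 50 ms bins, center-out
trials with a 5 cm target alternating between the center and peripheral
locations at uniform random angle and 8–10 cm distance with 500 ms holds,
and pursuit variants (Lissajous, default $x = 8\sin(3\omega t)$,
$y = 8\sin(4\omega t)$, $\omega = 0.25$ rad/s; and smoothed random
point-to-point). The cursor is logically a point: acquisition means the
cursor center is inside the target circle.

The *hand* is a second-order servo — commanded acceleration
$k_p(\text{target} - p) - k_d v$ plus Gaussian motor noise, with
acceleration and speed caps. Defaults $k_p = 20\,\mathrm{s^{-2}}$,
$k_d = 9\,\mathrm{s^{-1}}$ sit near critical damping and settle a reach in
about a second, matching the intended reach tempo; noise 15 cm/s², caps
40 cm/s and 300 cm/s². Positions are integrated and velocity/acceleration
re-derived by the package's own central-difference scheme, so generated
sessions are exactly self-consistent under it.

The *population* draws per-unit coefficients group by group. A group's
scale parameter is the standard deviation (counts/bin) of that group's
total rate contribution for a tuned unit; per-coefficient SDs are derived
from reference feature magnitudes of a typical session. Defaults
(P 0.15, V 0.25, A 0.12, PVI 0.08, T 0.12, SH 0.3 counts/bin, 10% of
units untuned, baselines 5–25 Hz) make velocity the dominant kinematic
signal with meaningful contributions from every group the richer models
exploit. The spiking-history coupling matrix is rescaled to spectral
radius 0.5 (< 1 guarantees a stable count autoregression; verified by
eigendecomposition). Counts are `max(0, round(rate + N(0, σ)))` by
default — matching the linear-Gaussian assumptions of the filters — with
a Poisson option for robustness studies.

In closed loop, the simulated user runs the same servo on the *decoded*
cursor; position and target features of the generative model are evaluated
at the actual cursor and target (sensory feedback), velocity and
acceleration features at the user's intended values, and future taps use a
deterministic forward rollout of the servo — the user's short-horizon
movement plan. These conventions mirror the brain-control-with-visual-
feedback situation; they are simulator conventions, not claims about
cortex.

**What passing tests do and do not show.** The generator produces
stationary, correctly specified sessions: the generative model family
equals the fitted family, there is no electrode drift, no unit loss, no
nonstationarity across a session, and noise is Gaussian-plus-rounding
rather than genuinely spiking. Results on it validate the machinery
(fitting, inference, control logic, metrics) and directional claims
(richer generative structure rewards richer observation models); they do
not predict absolute performance on cortical recordings.

## Conditions chosen for the heavier checks

Problem sizes were chosen as the smallest that make the statistical
assertions stable. Parameter recovery uses a 20,000-bin (~16.7 min)
point-to-point pursuit session — pursuit samples the position/velocity
space far more thoroughly than center-out — with 25 units, single-tap
tuning, baselines 60–100 Hz and rate-noise σ = 0.5. Three identifiability
facts shaped this condition, each diagnosed with an independent
ordinary-least-squares oracle: (1) strong tuning over low baselines drives
rates below zero, and the floor-at-zero biases every coefficient, so the
recovery population fires at multiunit-like 60–100 Hz; (2) Gaussian noise
below σ ≈ 0.4 cannot dither integer rounding (the rounding bias decays as
$e^{-2\pi^2\sigma^2}$), so σ = 0.5; (3) target features are structurally
collinear with position whenever the hand tracks the target, and lagged
population counts duplicate slowly varying position information, so
per-coefficient recovery is asserted on a kinematics-only population
(P/V/A/PVI) while the full history-bearing population is checked by
coefficient sign agreement. "Strongly tuned" means a rate contribution of
at least 0.2 counts/bin (4 Hz) per feature SD — a level a physiologist
would call clear modulation.

The decoder-ordering check uses five independent 8-minute, 40-unit
center-out sessions (the recorded populations this emulates are several
times larger; 40 units is the smallest population for which the ordering
was stable across seeds). The closed-loop check trains on 10 minutes of
hand control from a 40-unit, low-noise (σ = 0.15), fully tuned population
and runs 52 trials with an 8 s timeout. Movement-threshold calibration
uses $10^5$ draws.

## Design choices where the design was open

* Derivatives use central differences (interior) with one-sided edges; the
  simulator uses the same scheme, making round-trips exact.
* The training split discards 30 s, then takes 10 min if at least 12.5 min
  of hand control exist, else 5 min; the boundary case (exactly 12.5 min)
  takes the long split — the short split is read as a strict "less than".
* Acceleration series are smoothed with a 5-bin (250 ms) centred moving
  average before fitting acceleration-bearing models: raw double-differenced
  acceleration is dominated by bin-to-bin noise, and smoothing is what makes
  acceleration tuning usable. Window configurable; 1 disables.
* Intention estimation re-aims velocity and zeroes it inside the target;
  positions and accelerations are left unchanged. This is one reasonable
  reading of the FIT-style refinement, flagged as such.
* During held (thresholded) bins the filter continues to assimilate
  observations; only the cursor and the position integration are held.
  Freezing the whole filter would defeat the evidence build-up that the
  no-zeroing rule exists for.
* The Fitts index of difficulty is $\log_2(D/W + 1)$ with $D$ the
  commanded reach distance and $W$ the full target diameter (point
  cursor); movement time ends at the first bin of the hold that ultimately
  succeeds. Both conventions are configurable inputs to `trial_metrics`.
* One global seed fans out to named substreams (task, hand, population,
  counts, user) so each component is independently reproducible.

## Known limitations

* The UKF covariance approximation is second order; in strongly curved
  regimes (decoded speed comparable to its uncertainty) its posterior
  moments deviate from exact moment matching.
* Self-consistency of offline reconstruction is bounded by integer count
  quantisation, and on center-out tasks by transients after target jumps
  (the decoded target needs a few bins to catch up); the near-ideal
  (> 0.99 CC) regime is reached on smooth-pursuit sessions with strong
  high-rate populations.
* Per-coefficient identifiability of target tuning from tracking behaviour
  is structurally poor (see above); the package fits such models happily,
  but interpreting individual target coefficients from behavioural data
  alone is not supported by the data.
* The simulator does not model spike waveforms, sorting errors, electrode
  drift, or cross-session nonstationarity.
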