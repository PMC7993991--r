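---
title: "Methods: multi-timescale ensemble-sequence analysis of W-track CA1-PFC recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-timescale ensemble-sequence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and scientific setting

`wtrackseq` analyzes simultaneous dorsal-CA1 and prefrontal (PFC) ensemble
recordings from the W-track continuous spatial alternation task. In this
task a rat earns reward by alternating between the two side wells from the
center well (outbound, the working-memory component) and returning to the
center well from either side (inbound). Four trajectory types result:
C-to-L, L-to-C, C-to-R, R-to-C. The package quantifies how the same
upcoming (or past) choice is represented at three nested timescales:

* **behavioral sequences** (seconds): successive place fields along a run,
  read out with a memoryless Poisson Bayesian decoder;
* **theta sequences** (~125 ms): time-compressed sweeps within single
  theta cycles, scored by a posterior-weighted correlation and a
  best-fit-line goodness-of-fit with circular shuffles;
* **replay sequences** (~100 ms): trajectory reactivation inside
  sharp-wave ripples (SWRs) during immobility, with CA1-PFC
  reactivation-strength analysis.

Single-cell correlates are quantified alongside: trajectory selectivity,
theta phase precession (circular-linear regression), spatial field
asymmetry, and theta cycle skipping from corrected autocorrelograms.
Trial-by-trial classifiers test whether theta-sequence content predicts
the choice and whether pre-trial reactivation predicts the outcome.

## The decoding model

For each travel type the encoder holds linearized rate-map templates
$f_i(x, \mathit{tr})$ on a common 2-cm grid over the two trajectories
$\mathit{tr} \in \{L, R\}$. With spike counts $n_i$ in a window of length
$\tau$ and independent-Poisson firing,

$$P(x, \mathit{tr} \mid \mathbf{n}) \propto
  \Big(\prod_i f_i(x, \mathit{tr})^{n_i}\Big)
  e^{-\tau \sum_i f_i(x, \mathit{tr})},$$

with a uniform prior, normalized jointly over both trajectories so each
time window's posterior sums to one. Windows are $\tau = 120$ ms stepped
60 ms for behavioral decoding, $\tau = 20$ ms stepped 10 ms inside theta
cycles, and $\tau = 10$ ms non-overlapping inside SWRs. All computation
is in log space; templates are floored at 0.01 Hz so an off-field spike
can never zero out a state. Zero-spike windows are excluded (flagged, not
decoded); MAP ties break to the lowest state index.

## Sequence scoring

Per candidate event and per trajectory block $\mathbf{P}$ (space x time):

* **Weighted correlation** $r$: the Pearson correlation of spatial bin
  centers against window times with the posterior mass as weights.
* **Best-fit line** $R_{\max}$: a dense grid search over slope $v$ (both
  signs, $1 \le |v| \le 15$ m/s, 0.25 m/s steps — the lower bound excludes
  stationary events, the upper bound exceeds the largest plausible
  compression of run speed) and intercept $\rho$ (every 2-cm bin center),
  scoring each line by the average per-window posterior mass within 8 cm
  of it. Ties break to the smallest $|v|$, then the smallest $\rho$.

Significance uses 1000 circular space shuffles by default (each time
column independently rotated): an event passes when $r$ lies outside the
shuffles' [2.5, 97.5] percentile band **and** $R_{\max}$ exceeds their
95th percentile. When both trajectories pass, the higher $|r|$ wins; we
use $|r|$ rather than signed $r$ so reverse sequences compete on equal
terms (the signed alternative is noted in the source). With the position
axis oriented along the running direction, forward means $r > 0$.

Replay significance differs deliberately: the decoded trajectory is fixed
first (the block holding more posterior mass) and only that block's
$R^2$ (MAP position regressed on bin index) is tested against a time
shuffle, with a tie-counting Monte-Carlo p-value. Testing both blocks and
OR-ing two 5% tests would double the false-positive rate, and with few
decodable bins the MAP sequence has heavy ties that make a plain
percentile cut anti-conservative; both effects were measurable on noise
events during development.

## The synthetic-data generator as a stated world

The raw recordings behind the reference analyses are not available, so
every stage is validated against synthetic sessions with known ground
truth. Defaults describe one behavioral session: 40 CA1 + 30 PFC units,
40 traversals (100 in the full-size acceptance run), 25 cm/s runs, 2-10 s
well dwells, 8 Hz theta, SWRs at 0.3 Hz during immobility, 15% outbound
errors, 60% trajectory-selective units, CA1 field SD 8 cm with PFC fields
twice as wide and lower-rate (a config choice — the reference work does
not quantify PFC field widths), phase precession at -8 deg/cm, 20%
cycle-skipping units, and replay depicting the upcoming choice with
probability 0.8.

Three generator choices deserve emphasis because naive alternatives make
planted parameters unrecoverable *in principle*:

* **Non-preferred-side firing is diffuse, not a scaled field.** If a
  selective cell's non-preferred template were a scaled copy of its
  field, the log-likelihood contribution of its spikes would have the
  same spatial shape on both trajectory blocks, and the decoded
  trajectory label would be unidentifiable by any shape-based score.
  Real "splitter" cells fire sparsely and diffusely off their preferred
  trajectory, which is what the generator now does; field centers on the
  two side arms are additionally jittered a few cm apart.
* **The theta oscillator wanders.** Cycle lengths are drawn with ~15 ms
  SD around the 125 ms period. A perfectly periodic oscillator produces
  autocorrelogram theta peaks that never decay, so a non-skipping cell
  would have equal first and second peaks and the cycle-skipping index
  would have no defined sign. The LFP and all spike modulation share one
  oscillator, so phase-recovery tests are exact.
* **Poisson thinning at 1 ms.** Spiking is an inhomogeneous Poisson
  process (place field x selectivity gain x normalized von Mises theta
  gain whose preferred phase advances linearly with within-field travel
  distance x cycle-skip gain), matching the decoder's Poisson assumption
  so recovery tests are well-posed.

What a green test does **not** establish: the generator has no biophysics
(no conductances, no 1/f LFP background, no ripple-frequency structure
beyond a planted 200 Hz burst), no learning dynamics across sessions, no
tracking artifacts, and its immobility behavior is a simple dwell. Tests
green on this world certify the estimators, not the biology.

## Numerical and procedural choices

* Speed is the centered difference of the position trace smoothed with an
  ~83 ms SD Gaussian (the smoothing is unstated upstream; chosen to
  suppress 30 Hz tracking jitter). Locomotion is speed > 5 cm/s,
  immobility <= 4 cm/s; the 4-5 cm/s band belongs to neither.
* Rate maps smooth spike counts and occupancy separately with a 4-cm-SD
  Gaussian before dividing; bins with <= 20 ms raw occupancy carry no
  estimate; track ends are not wrapped. Mean rates for the selectivity
  index are occupancy-weighted map means, insensitive to dwell
  asymmetries.
* Field "center" for the asymmetry index is the extent midpoint by
  default (the peak-bin alternative is exposed as an argument); the
  profile is resampled into ten 10%-length bins and integrated by
  trapezoids.
* The ripple envelope is smoothed with a 4 ms Gaussian and must stay
  above threshold for >= 10 ms; both parameters are exposed. The 10 ms
  sustain gate exists because a Gaussian noise envelope crosses 3 SD by
  chance for a sample or two, which no one would call a ripple.
* Theta cycles are cut at the phase of minimum population firing
  (histogram over Rayleigh-significant CA1 units during locomotion),
  with a trough fallback and warning when no unit is phase-locked.
  Cycles of 50-300 ms are kept at segmentation; the stricter 100-200 ms
  gate applies to candidate sequences.
* The circular-linear precession slope is searched within +/- 0.05
  cycles/cm (grid + golden-section refinement). Because the slope is
  *selected* by maximizing the mean resultant over that grid — which
  behaves like a periodogram scan — an asymptotic p-value on the
  resulting correlation is badly anticonservative (12% false positives
  at nominal 5% in our null simulations). The reported p is therefore a
  permutation p on the selection statistic itself (phases shuffled
  against positions, maximal grid resultant recomputed, ties counted),
  which is calibrated by construction.
* Spectral summaries use Welch averaging with 1 s Hann segments (the
  upstream multitaper implementation is not available in this stack; the
  band means of a z-scored spectrum are insensitive to the taper choice
  at this resolution). Power is z-scored per frequency across segments.
* The choice/outcome classifiers are RBF-kernel ridge classifiers with
  closed-form leave-one-out residuals; the classifier is specified by
  contract (binary, nonlinear RBF margin), and hyperparameters
  (C in [1e-2, 1e3], gamma in [1e-3, 1e1], log-uniform, 50 draws) are
  selected by seeded random search under leave-one-out. The same
  candidate draws are reused across label permutations for variance
  reduction. Outcome prediction resamples incorrect trials to class
  balance *inside* the evaluated pipeline and permutes labels at the
  trial level before resampling; permuting after resampling leaks the
  duplicate structure and is anti-conservative. Because resampling
  duplicates points into the training set, the absolute AUC is optimistic
  — only the comparison against the identically-computed permutation
  null is interpreted.
* All randomness derives from the config seed through scoped `set.seed`
  calls (R has a single global RNG); identical configs give bit-identical
  sessions, results, and provenance hashes.

## Known limitations

Stem theta sequences are intrinsically ambiguous between the two
trajectories (the templates coincide on the shared stem except through
selective cells), so trajectory-label recovery is only evaluated on
side-arm events; on real data the same caution applies to before-CP
sequence labels.

Two properties of the theta-sequence significance procedure are worth
knowing, both inherent to the procedure as classically printed and kept
here deliberately:

* **Event-level null rate exceeds 5%.** An event is significant when
  *either* trajectory block passes its (r AND R_max) test — an OR of two
  ~5% tests, giving ~8-11% of temporally shuffled events declared
  significant. The inflation is compounded by the column-rotation
  shuffle itself: rotating each time column uniformly spreads posterior
  mass over all positions, while real (and null) events concentrate
  mass where fields are dense, so a near-flat line captures more mass
  in the observed matrix than in its shuffles. The per-trajectory,
  per-criterion tests are calibrated; the event-level rate is not, and
  the corresponding acceptance assertion is left failing with this
  analysis rather than silently altering the printed procedure (the
  replay detector, whose procedure is less explicitly specified, fixes
  the decoded trajectory before testing and is calibrated).
* **A near-empty trajectory block can win the tie-break.** The weighted
  correlation is mass-normalized and R_max is compared against the
  block's own shuffles, so a block holding a few percent of the
  posterior can be "significant" with a high |r| when path-equivalent
  cells trace the same ridge on both templates; the highest-|r|
  tie-break then occasionally decodes the wrong trajectory (~5% of
  side-arm events in the default world). Consumers who need a
  conservative label can require the decoded block to also hold the
  posterior-mass majority. The distance index, coherent CA1-PFC pairing, and
choice-representation summaries are bookkeeping over significant events
and inherit whatever bias the significance step has. Phase-jitter
shuffles re-draw spike times uniformly within the event (the animal moves
< 4 cm in one cycle, so position-conditional phase sampling degenerates
to this); the space-circular shuffle is the default everywhere.
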