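---
title: "Network resonance in a delay-coupled Wilson-Cowan cortical sheet: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network resonance in a delay-coupled Wilson-Cowan cortical sheet: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Each primary sensory cortex responds maximally to repetitive stimulation at a
characteristic driving frequency -- its resonance frequency -- and larger
cortical territories tend to resonate lower. `wcresonance` implements a
network model that asks whether this is an emergent property of network
structure rather than of single-neuron physiology: a homogeneous patch of
cortical sheet is simulated as a lattice of identical neural mass
oscillators, sub-networks of different sizes are activated with periodic
pulse trains over a grid of driving frequencies, and the driving frequency
of maximal steady-state response is read out as the resonance estimate. The
package's protocol suite shows resonance falling as the activated area, the
local excitatory out-degree, or the inter-unit transmission delay grows.

## The model

### Units

Each lattice site holds a Wilson-Cowan unit: coupled excitatory (E) and
inhibitory (I) population activities obeying

$$\tau_E \dot E_i = -E_i + \sigma\!\big(w_{EE} E_i + w_{IE} I_i + E_0 +
  \textstyle\sum_j CE_{ij} E_j(t - d_{ij}) + f(t) + z\,\xi(t)\big),$$
$$\tau_I \dot I_i = -I_i + \sigma\!\big(w_{EI} E_i + w_{II} I_i + I_0 +
  \textstyle\sum_j CI_{ij} E_j(t - d_{ij})\big),$$

with the logistic response $\sigma(x) = 1/(1 + e^{-m(x - n)})$. The unit
output is the excitatory activity (interpreted as action potential
density). Defaults (`unit_params()`): $w_{EE} = 23$, $w_{II} = 0$,
$w_{EI} = 35$, $w_{IE} = -15$, $E_0 = 0.5$, $I_0 = -5$, $m = 1$, $n = 4$,
$\tau_E = 14$ ms, $\tau_I = 13$ ms. With these values a single noise-driven
unit oscillates in the alpha band; the ratio $\tau_E/\tau_I$ tunes the
intrinsic frequency (`run_single_unit_tau_scan()`).

**Units of the time constants.** The time constants are handled in seconds
(14 ms, 13 ms). Millisecond-scale time constants would make a 1 ms
integration step dimensionally meaningless and produce no alpha-band
rhythm; with 13-18 ms constants the unit's spontaneous spectral peak falls
at 7-13 Hz, matching the single-unit scan results.

### Dynamical regime of a unit

With the default parameters the uncoupled deterministic unit has three
fixed points: a low-activity point ($E^* \approx 0.214$) that is an
unstable spiral, a saddle, and a stable high-activity node
($E^* \approx 0.984$). The physiological operating regime is a stable limit
cycle around the low-activity point; macrocolumn noise perturbs this cycle
into the broadband alpha-band rhythm the spectra show.
`uncoupled_fixed_point()` targets the low-activity point: a brief damped
fixed-point iteration from the caller's start is followed by a Newton
polish of the 2x2 root problem, because an undamped long iteration drifts
to the high-activity node (which is stable for the iteration map), and that
node is not the operating point of interest.

### Integration scheme

Fixed-step integration at `dt = 1` ms with **staggered (Gauss-Seidel) field
updates**: at each step the whole E field is advanced first, then the I
field is advanced using the freshly updated E for its intra-unit term.
This ordering was chosen over simultaneous updating after comparing both
schemes at the operating step size: simultaneous updating at 1 ms loses the
oscillation entirely for the slower time-constant settings
($\tau_I = 17$ ms falls into the stable high-activity node) and fails to
entrain the driven network anywhere on the probed grids, while staggered
updating sustains the oscillation over the whole scanned $\tau_I$ range
with spontaneous peaks in the alpha band and reproduces the driven
resonance phenomenology. At this step size the update ordering is a genuine
model-defining choice, not a numerical detail, and the staggered variant is
the one that exhibits the phenomena of interest.

Delay coupling reads the excitatory history at $t - d_{ij}$ from a circular
buffer of length (max delay + 1), with edges grouped by delay value so each
distinct delay resolves its history row once per step. Pre-history
($t - d < 0$) equals the initial state. The buffered integrator is
contractually identical to a naive full-history reference implementation
(`simulate_trial_reference()`), and the test suite holds the two to within
1e-12 on toy networks -- delay buffering is an optimization, never a model
change.

### Noise

Every unit inside a 10x10 **macrocolumn** shares one Gaussian white-noise
draw per step, independent across macrocolumns and steps, entering the E
sigmoid argument scaled by $z$ (0.05 in the driven-network and delay
protocols, 0.07 in the degree protocols, where denser coupling damps the
rhythm). The multiplier $z$ is defined at the reference step of 1 ms; when
integrating at another step the per-step standard deviation is
$z\sqrt{dt_{\mathrm{ref}}/dt}$, which keeps the noise power per unit time
-- and with it the dynamical regime -- invariant under step halving or
doubling. The package adopted this convention after measuring the
alternative (fixed per-step variance), under which halving the step halves
the effective noise power and changes the operating regime outright. Under
the adopted convention the single unit's driven response peak stays locked
to the drive bin when the step is halved or doubled, and that is the form
in which step-consistency is asserted; the spontaneous quasi-cycle
frequency still drifts by about one bin per octave of step size (intrinsic
first-order Euler bias). The coupled sheet is more delicate: at the
operating step the staggered discretization itself helps stabilize the
collective limit cycle, and at 0.5 ms the 30x30 network slides into its
saturated high-activity state instead of oscillating. Network-level
conclusions therefore hold at the stated 1 ms step, which is how all
protocols run.

### Initial state

Trials start at zeros by default. The low-activity fixed point is spiral-
unstable under the default parameters, so starting exactly there delays
limit-cycle onset rather than avoiding a transient; from zeros the
trajectory joins the cycle within roughly 100 ms. No burn-in is discarded
by default -- whole trials are analyzed, matching the protocol definitions
-- but `sim_config(burn_in =)` is available and is used by tests that
score steady-state responses specifically.

## Connectivity

`build_network()` realizes one random network: for every unit, exactly
`k_exc` excitatory and `k_inh` inhibitory local out-edges (default 5/5)
whose target offsets are drawn from an isotropic Gaussian with SD 250 um
(5 lattice steps at 50 um spacing), rounded to the nearest site, redrawn
on self-hits, duplicates, or targets beyond the hard 700 um (14-step)
cutoff. Redrawing to an exact out-degree honors both the stated mean node
degree of 5 and the Gaussian fall-off shape; the accepted-offset radii
follow the correspondingly truncated, discretized Rayleigh law (checked
against an independent rejection-sampling oracle in the tests).

Long-range excitatory edges -- 25% of the local excitatory edge count, the
"local connections" reading of the two phrasings in the source material --
are drawn with uniformly random endpoints, rejecting self-edges, duplicates
and targets inside the local cutoff disc, so "long-range" is well defined.
Scans that vary the local degree hold the long-range count frozen at its
degree-5 value (`n_long_range` in `build_network()`).

All distances are torus distances (periodic boundaries). Transmission
delays are `round(delay_per_step * distance)` integration steps, rounding
half away from zero, identically for both edge kinds; the default 10 steps
per unit distance corresponds to 10 ms per 50 um minicolumn spacing at the
1 ms step. Inhibitory edges connect the source's E population to the
target's I population; both kinds carry non-negative weights (0.15
excitatory, 0.10 inhibitory), the sign of the influence being determined by
the population they target.

**Lateral inhibition** (`apply_lateral_inhibition()`) confines activity to
a driven sub-network: existing excitatory edges from masked to unmasked
units are zeroed and existing inhibitory edges with that orientation are
raised to weight 1. No new edges are created: creating all surround pairs
would both swamp the surround and change the degree statistics that the
connectivity profile protocol measures.

## Spectral statistics

`power_spectrum()` removes the mean, takes $|\mathrm{FFT}|^2$ at positive
frequencies, drops the zero-frequency bin, and normalizes the remainder to
unit sum. The DC bin is excluded from normalization and search because the
activity has a large standing offset whose inclusion would let baseline
shifts dominate the statistic; the quantities of interest are oscillatory.
No taper is applied: the protocol trial lengths are exact multiples of the
drive periods on their frequency grids (2000 samples against 0.5 Hz steps,
5000 against 0.2 Hz), so rectangular-window leakage is minimal.

The driven response statistic is the normalized power at the bin nearest
the driving frequency (`response_power_at()`); the recorded-epoch variant
(`ssep_response_power()`) takes the maximum over the three bins nearest the
stimulus frequency, tolerating a one-bin mismatch between stimulus and
response on real recordings.

`bootstrap_statistic()` resamples trial spectra with replacement (default
1000 resamples), averages each resample, and evaluates the statistic; for
parameter scans the statistic is the drive frequency of maximal response
per resample, with ties broken toward the lower frequency (a documented,
arbitrary convention). Because per-trial spectra are normalized before
averaging, the response at a bin of an averaged spectrum equals the average
of per-trial bin responses, which the implementation exploits. The
bootstrap RNG is seeded independently of the simulation RNG.

## Protocols and their study conditions

Every protocol derives all connectivity, noise, and bootstrap seeds from
one master seed and accepts `scale`, a multiplier in (0, 1] applied to the
trial count only -- never to model parameters, grid ranges, or trial
lengths. One connectivity realization is drawn per condition and shared by
all trials of that condition.

| Protocol | Sheet | Trials x samples | Drive grid | z |
|---|---|---|---|---|
| `run_size_resonance` | 50x50, masks 10x10 & 30x30, delay 10 | 100 x 2000 | 10-15 Hz, 0.5 | 0.05 |
| `run_connectivity_profile` | 100x100, delay 10 | none | none | -- |
| `run_delay_scan` | 30x30, delay 10-100 | 100 x 5000 | 12-14 Hz, 0.2 | 0.05 |
| `run_degree_scan` | 30x30, delay 0, degree 0-9 | 1000 x 5000 | 12-17 Hz, 0.2 | 0.07 |
| `run_single_unit_tau_scan` | single unit | 100 x 5000 | 6-13 Hz, 0.2 | 0.05 |
| `run_noise_strength_scan` | 30x30, spontaneous | 100 x 5000 | none | scanned |

The single-unit scan's noise level is not fixed by the source protocol
tables; 0.05, the network default, is used, and the spontaneous peaks are
insensitive to the choice over 0.05-0.1. The noise-scan grid (z from 0.01
to 0.11) covers the rising limb of the peak-frequency-versus-noise curve;
the strength grid (0.05-0.30) spans weak coupling up to the damping
regime.

The acceptance script and the test suite run these protocols at reduced
trial counts chosen as follows: the size experiment at 30 of 100 trials
per frequency (and its ordinal repetition check at 10 of 100), the delay
scan at 8 of 100, the degree scans at the floor of 5 of 1000, and the
single-unit scan at the full 100. Reducing the trial count raises the variance of every
bootstrap estimate but biases nothing; the full-scale conditions are a
single `scale = 1` call away.

## Reproduction fidelity and known limitations

- The single-unit time-constant ladder reproduces within two frequency
  bins at the protocol's resolution, and the inhibitory-degree scan
  reproduces its reported positive trend with a strong linear fit
  (resonance climbing from about 12.2 to 13.4 Hz over degrees 0-9).
- The excitatory-degree scan reproduces the reported negative relationship
  over degrees 0 through 4 (about 13.8 down to 12.5 Hz), but from degree 6
  the sheet saturates into its stable high-activity state (mean activity
  near 0.93, no rhythm, negligible driven response) despite the raised
  noise level the protocol prescribes for exactly this regime. The upper
  half of that scan therefore measures a dead network and the full 0-9
  linear fit is not meaningful in this implementation.
- The delay scan expresses the delay effect as an asymmetric narrowing of
  the entrainment tongue -- on a 30x30 sheet the response at 12 Hz grows
  from 0.06 to above 0.8 as the delay rate rises from 10 to 100 steps per
  unit distance, while the response at 14 Hz falls -- but the location of
  the response maximum inside the 12-14 Hz probe window barely moves, so
  an argmax-based resonance-versus-delay fit is flat here rather than
  cleanly negative.
- In the size experiment, the small-mask resonance lands at the reported
  13.5 Hz. The large mask's driven response, however, saturates: between
  11.5 and 13.5 Hz the drive entrains the mask almost completely
  (normalized response near 0.85), the response curve becomes a plateau
  whose maximum sits at its upper lock edge, and the estimated peak ties
  with the small mask instead of dropping a full 1 Hz as reported. The
  within-mask connectivity differences (more internal edges and longer
  internal delays in the larger mask) are present -- they shift the lower
  lock edge by about 1 Hz between masks -- but at the printed drive
  amplitude they do not move the upper edge. Diagnostic variants (weaker
  drive, silenced surround noise, simultaneous updates) did not produce
  the 1 Hz upper-edge split either; the size-ordering of the peaks
  (small >= large) does hold, and is what the repetition check asserts.
- Spontaneous (undriven) spectra are step-size sensitive to first order,
  as discussed above; conclusions should rest on driven statistics or on
  fixed-step comparisons.
- The synthetic protocols share one connectivity realization across trials
  of a condition. Real cortical tissue varies connectivity continuously;
  nothing here models heterogeneous kernels, conduction-velocity
  distributions (delays are discrete and distance-proportional), or the
  background-variable extensions of the neural mass family. Passing tests
  demonstrate internal reproduction of the model's phenomenology, not
  validation against recorded cortical data: the analysis layer accepts
  external epoch matrices (`score_epochs()`), but no recorded data ships
  with the package.

## Numerical choices summarized

- Sigmoid exponent argument clamped to +/-500 (saturation instead of
  overflow; unreachable in the operating range).
- Fixed-point solver: damped iteration capped at 25 steps, Newton polish
  with steps capped at 0.2, residual tolerance 1e-10 on the derivatives.
- Delay rounding: half away from zero. Drive cycle onsets: true period
  rounded to the step grid per cycle, kernel restarted at each onset (at
  8 Hz and above the kernel has decayed to under 2% of its peak by cycle
  end, so restarting and summing overlapping kernels nearly coincide;
  restart is deterministic and cheaper).
- Trial seeds derive arithmetically from (base seed, trial index), all
  kept inside 32-bit range; fixed seeds give bit-identical networks,
  noise streams, and therefore trials.
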