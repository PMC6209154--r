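---
title: "Methods: phase-synchronization networks and dynamic functional states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-synchronization networks and dynamic functional states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the model at
each stage, the parameters that matter, what the synthetic generator does
and does not emulate, and the numerical decisions taken where the design
was genuinely open.

## The analysis problem

Repeated practice of a demanding visuomotor task (the motivating setting
is simulator-based robot-assisted-surgery training over six sessions
spread across a year) reorganizes the brain's functional coupling. The
package quantifies that reorganization from 20-channel scalp recordings
on the 10–20 montage: it builds per-frequency-band synchronization
networks, segments them into functional communities, tracks how strongly
the predefined motor (F3, Fz, F4, F7, F8, C3, Cz, C4), cognitive (Fp1,
Fp2, P3, Pz, P4, POz) and visual (O1, O2) systems cohere (recruitment) or
mix (integration) across sessions, and correlates those dynamics with
practice time, practice gaps and behavioral performance.

## Preprocessing

- **Band-pass 0.5–128 Hz.** Implemented as a cascade of 4th-order
  Butterworth high- and low-pass halves, each applied forward-backward
  (zero phase). The cascade is used instead of a single band-pass design
  because the band spans nearly the whole Nyquist range at a 256 Hz
  sampling rate and the cascade stays numerically stable there; channel
  means are subtracted first, which removes DC exactly and avoids
  start-up transients. When the upper edge reaches Nyquist it is clipped
  to 0.99 × Nyquist with a warning.
- **Notch 60 Hz.** A second-order IIR biquad with quality factor 30
  (≈ 2 Hz −3 dB bandwidth), forward-backward. Frequencies 5 Hz away are
  attenuated by well under 3 dB.
- **Blink handling.** The original acquisition chain used a proprietary
  discriminant-function blink classifier that cannot be reproduced
  without its trained coefficients. The package ships an
  amplitude-threshold stand-in: windows of 400 ms (default) around any
  sample where a frontal lead (Fp1, Fp2, F3, F4) exceeds 100 µV
  (default) are excised from all channels and the surviving segments
  concatenated. The excised fraction is recorded; recordings losing more
  than half their samples are flagged `excessive_artifact`. This is a
  stand-in: it preserves the pipeline contract (artifact-reduced signal)
  without pretending to replicate a classifier.
- No ICA, no epoching: each recording is treated as one segment.

## Band phase and the synchronization index

Instantaneous phase per band comes from convolution with a complex
Morlet wavelet centred at the band midpoint (θ 6 Hz, α 10 Hz, β 23.5 Hz,
γ 47.5 Hz) with a width of 6 cycles. Samples within one wavelet support
(3.5 temporal standard deviations) of either end lie inside the cone of
influence and are excluded from all synchronization sums.

For channels x, y the index over the P~s~ usable samples is

$$\Gamma_{xy} = \frac{\left(\sum_t \cos \Delta\varphi_{xy}(t)\right)^2 +
\left(\sum_t \sin \Delta\varphi_{xy}(t)\right)^2}{P_s^2},$$

the squared length of the resultant of the phase-difference unit
vectors. It is 1 under perfect locking (any constant offset), has
expectation 1/P~s~ for independent uniform phase differences, and is
invariant to a common phase shift of both channels.

Two deliberate conventions:

- **Normalization.** Dividing the resultant by P~s~ only (the
  `"literal"` convention, kept available) yields an index that equals
  P~s~ under perfect locking; downstream use of Γ as a bounded
  connectivity weight (probabilities, averaged strengths) presumes the
  P~s~² normalization, which is the default.
- **Signed phase difference.** The phase difference can be folded to its
  absolute value, but the fold rectifies the sine term: for completely
  independent phases E[sin|Δφ|] = 1/π, so the folded index converges to
  ≈ 1/π² ≈ 0.10 instead of 0 as P~s~ grows. The implementation therefore
  computes the resultant over the signed wrapped difference (the cosine
  term is unaffected, cosine being even), which is the standard
  phase-locking statistic and vanishes for unrelated channels.
  `phase_difference()` still exposes the absolute-value series (range
  [0, 2π), optionally normalized by its 2π range) for inspection.
- **Stationary-point restriction.** An optional mode restricts the sum
  to samples where the central-difference derivative of Δφ is below a
  tolerance (default 0.05 rad/sample) — the "phase-locked time points"
  reading. The default sums over all usable samples; both modes are
  available because the role of stationary points in the index is
  ambiguous in the source description, and neither is labelled
  authoritative.

The 190 unique pairs are computed once and mirrored; the diagonal is
structurally zero (self-synchronization carries no information).

## Community detection

Partitions maximize

$$Q(\gamma) = \sum_{i \ne j} \left[\Gamma_{ij} - \gamma \frac{k_i k_j}{2m}\right]
\delta(g_i, g_j),$$

with node strengths $k_i = \sum_j \Gamma_{ij}$, total weight
$m = \tfrac12 \sum_i k_i$ (the Newman–Girvan null) and resolution γ. The
sum runs over ordered pairs with the diagonal excluded, so this Q is the
conventional modularity scaled by 2m; the argmax is identical.

The maximizer is a greedy Louvain scheme written for determinism on
small dense networks: greedy single-node moves from singletons (ties
broken toward the highest gain, then the lowest community id), then
iterated community-aggregation moves and node-level refinement until a
full cycle stops improving Q. The refinement guarantees the returned
partition is a local maximum under single-node moves on the original
matrix. The node visiting order — the only stochastic element — is drawn
from a seed, so a (matrix, γ, seed) triple is fully reproducible.

**Resolution selection.** γ is swept over 0.5–2.0 in steps of 0.05
(defaults; the range spans merge-all to fragmented regimes on 20-node
synchronization matrices) with 20 random-order restarts per γ, keeping
the best Q. Among grid points whose best partition has at most 6
communities, the maximum-Q partition is returned (ties toward smaller
γ). The cap of 6 reflects the montage's six anatomical groupings;
finer partitions of a 20-node network degenerate into singletons. If no
grid point satisfies the cap, the fewest-community partition is returned
flagged `constraint_unmet`.

Validation uses an exhaustive-partition oracle: on 7-node random
weighted graphs the Louvain result never exceeds the brute-force optimum
over all 877 partitions and attains it in ≥ 90% of instances.
Permutation stability (best-of-20 restarts invariant to node order to
1e-9) is asserted on community-structured matrices — the regime the
pipeline actually produces; on dense i.i.d.-uniform matrices the
modularity landscape is degenerate and no restart budget makes greedy
maximization reproducible there.

## Allegiance, integration, recruitment

Partitions are pooled per (session, band) across all subjects and
recordings of that session — the granularity at which the session-level
correlation analyses operate (six observations per band). The module
allegiance matrix entry MAM~ij~ is the fraction of pooled partitions
assigning channels i and j to the same community.

- **Recruitment** of a system: mean MAM over its unordered within-system
  pairs, diagonal excluded (it is identically 1 and would inflate the
  statistic).
- **Integration** of two systems: mean MAM over cross-system pairs, each
  unordered pair counted once; symmetric by construction.

Both lie in [0, 1]. The temporal channels ("other") participate in
partitions but are not part of any reported system statistic.

## Features

| feature | definition | units / range | notes |
|---|---|---|---|
| CT | samples / sampling rate | s | exact |
| D | MD + PD + TD + E | 4–80 | performance and frustration indices excluded (trainee self-ratings of outcome are unreliable) |
| performance | 100 − mean(8 FSRS scores) | ≤ 100 | NA if any score missing |
| complexity | fixed task lookup {1:2, 2:4, 3:5, 4:3, 5:1} | 1–5 | curriculum-assigned |
| strength | mean Γ over within-system pairs (self-pairs excluded) | [0,1] | see below |
| communication | mean Γ over cross-system pairs | [0,1] | |
| AI | (L−R)/(L+R), L/R = summed α-power ranges at F3+F7 / F4+F8 | [−1,1] | 0 with a flag when both ranges vanish |
| APA | mean over α, β(13–30 Hz) and C3/Cz/C4 of (P~base~−P~move~)/P~base~ | — | positive = desynchronization |

Choices worth stating:

- **Self-pairs in strength.** Reducing the communication formula to a
  single system divides by |S|², which includes self-pairs whose Γ is
  structurally zero here; a system of m channels has m(m−1)/2
  informative pairs, so within-system averages exclude i = j. Applied
  consistently, the within-system statistic is then the self-pair-free
  cross formula, which the tests assert.
- **Spectral windows.** Band powers use Welch estimation: 2 s Hamming
  segments, 50% overlap, and the band power is the *integral* of the
  periodogram over the band (sum × bin width), so estimates from
  different segment lengths are comparable. AI takes the max−min range
  of per-segment α power within the recording (the source does not
  define the range window; per-segment ranges are the natural reading).
- **APA windows and electrodes.** "Spatially enhanced" is not further
  specified; the central motor-relevant subset C3, Cz, C4 is used, with
  the first 10% of the recording as the default aiming/baseline window.
  APA's β is 13–30 Hz — deliberately different from the connectivity β
  (12–35 Hz); each is used only in its own context.
- **Pass-through cognitive scores.** Mental workload, engagement and
  distraction estimates require proprietary discriminant-function
  baselines; the reports accept them as externally supplied columns and
  never compute them.

## Correlation reports

All reports use the sample Pearson correlation with the two-tailed
p-value from $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on n−2 df
(indistinguishable from the exact test at n = 260 and consistent with
printed session-level (r, p) pairs at n = 6, e.g. r = −0.84 → p ≈ 0.036).
A cell is significant when |r| > 0.2 **and** p < 0.05 jointly; at n = 6
the p gate dominates (critical |r| ≈ 0.811), at n = 260 the |r| gate
does. **No multiple-testing correction is applied** — the reports mirror
tables that apply none, and users should treat cell-level significance
accordingly. Missing data are handled by pairwise-complete deletion,
which is what produces recording-level analyses at n ≈ 260 of ~524
recordings when tool-based scores are unavailable for unfinished tasks.
Constant series and pools with fewer than three finite pairs yield
flagged NA cells rather than errors.

## The synthetic generator

Per coupled band b with couplings (κ_in, κ_out), κ_out ≤ κ_in, each
channel's phase is

$$\varphi_c(t) = 2\pi f_b t + \kappa_{out}\, u_g(t) +
(\kappa_{in} - \kappa_{out})\, u_{m(c)}(t) + (1 - \kappa_{in})\, p_c(t),$$

where u_g, u_m, p_c are independent Ornstein–Uhlenbeck perturbations
(stationary sd π, mean-reversion timescale 1 s, simulated as stationary
AR(1)) shared globally, per planted module, and privately. The signal is
the sum over bands of unit-amplitude cosines plus white noise
(default sd 0.5). Within-module pairs share the global *and* module
processes, so their phase-difference spread scales with (1 − κ_in) while
between-module spread scales with (κ_in − κ_out) as well — the expected
synchronization margin is monotone in the coupling gap, which the tests
verify, and κ_in = κ_out makes within and between statistically
identical. Session trends add a per-session increment to the couplings
(clipped to keep 0 ≤ κ_out ≤ κ_in ≤ 1), which is how a practice-driven
decline of cross-module integration is planted.

Defaults: 256 Hz sampling (satisfies Nyquist for the 60 Hz band edge
with margin), 60 s per recording, 27 subjects × 6 sessions × 5 tasks,
sessions at days 0, 7, 30, 90, 180, 365. The source study states neither
sampling rate nor durations; these are desk-scale artifact choices, not
facts about the original data.

Behavioral tables are drawn from a Gaussian copula: a latent correlation
matrix carries the requested pairwise effect sizes (rejected with a
diagnostic if not positive semidefinite), and affine maps put each
variable on a realistic scale — FSRS scores nonnegative around 8 ± 3,
NASA-TLX indices clipped to [1, 20], CT around 90 ± 25 s. Targets on the
derived difficulty D are spread over its four components at half the
requested correlation (the four-component sum then carries the full
value). Task 5 never has FSRS scores and tasks 1–4 lose them
independently with probability 0.6, reproducing the ≈ 260-complete /
≈ 650-candidate ratio of the study design. Accumulated practice time is
the within-subject cumulative completion time; session gaps follow the
session calendar.

**What the generator does not emulate:** volume conduction and common
reference effects (which inflate neighbour synchronization in real EEG),
1/f spectral background, realistic blink/EMG morphology (the artifact
injector used in tests is a rectangular frontal transient),
between-subject amplitude differences, and any genuine coupling between
the signal recordings and the behavioral tables beyond shared
bookkeeping. Passing recovery tests therefore demonstrates that the
pipeline measures what it claims on signals with known phase structure —
not that real-EEG confounds are overcome.

## Validation problem sizes

The test-suite and acceptance script run scaled study conditions chosen
as the package's own validation design: planted three-module recovery
uses single recordings of 60 s at 256 Hz (κ_in = 0.9, κ_out = 0.1,
noise sd 0.5) over 20 replicates with the full default γ grid; the
planted practice-decline study uses 4 subjects × 6 sessions × 2 tasks at
15 s per recording (α κ_in = 0.7, κ_out = 0.55 − 0.11/session,
noise sd 0.5) with a 3-point γ grid and 5 restarts, 10 seeds; null
report calibration uses the full 27 × 6 × 5 feature-table design over 20
seeds. The decline conditions deliberately sit in the noisy-transition
regime: with a large κ_in − κ_out margin partitions split from session
one and integration is ≈ 0 throughout, while with κ_out close to κ_in
everything merges and integration saturates at 1 — both regimes flatten
the planted trend. The chosen margin lets the merge probability fall
gradually across sessions, which is the phenomenon the session-level
correlation is supposed to detect.

## Known limitations

- Only the one synchronization index is implemented; coherence,
  imaginary coherence or PLI variants (more robust to volume conduction)
  are out of scope by design.
- Single-layer detection per recording; no multilayer temporal coupling
  between sessions.
- The blink stand-in removes any high-amplitude frontal window, blink or
  not.
- Exact reproduction of the published correlation tables requires the
  study's supplementary session-level and recording-level CSVs, which
  cannot ship with the package
  (see `inst/extdata/supplementary/README.md` for the expected layout);
  without them that check reports failure rather than silently passing.
- Published session-level visual–cognitive integration correlations are
  identical across all four bands, which suggests a band-collapsed
  computation somewhere upstream in the original analysis; this package
  computes every statistic per band.
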