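---
title: "A discrete-time Conscious Turing Machine: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete-time Conscious Turing Machine: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctmsim)
```

## The model

`ctmsim` simulates a Conscious Turing Machine (CTM): a Global-Workspace-style
architecture given as the seven-tuple *⟨STM, LTM, Up Tree, Down Tree, Links,
Input, Output⟩*. Short-term memory (STM) is a stage holding a single *chunk*;
long-term memory is a bank of N autonomous processors, each of which submits
one chunk to a tournament every tick and receives every winner back by global
broadcast. Conscious content is whatever occupies the slot; conscious
awareness is its reception by all processors; the time-ordered broadcast
sequence is the machine's stream of consciousness.

A chunk is the six-tuple ⟨address, t, gist, weight, intensity, mood⟩. The
gist is an opaque, bounded, modality-tagged payload in the machine's inner
language; the simulator represents gists but never interprets them —
scenarios attach meaning. The weight is the valence its producer assigns; at
submission intensity = |weight| and mood = weight. As a chunk rises through
the Up Tree, its address, t, gist and weight are frozen while intensity and
mood become subtree sums, so |mood| ≤ intensity always holds (triangle
inequality, by induction over merges), and the root chunk reports the whole
machine's summed intensity and mood while naming exactly one winner.
`mood_readout()` exposes the consequence: machine mood at slot tick *t*
equals the sum of all moods submitted at *t − h*, and mood/N is the average
submitted mood — a machine-wide optimism/pessimism gauge.

### The probabilistic tournament

Each internal tree node holds a coin-flip neuron: given child scores (a, b)
it picks the left child with probability a/(a+b), or 1/2 when both are zero.
Scores come from a competition function f mapping chunks to non-negative
reals; the bundled family is f = intensity + c·mood with c ∈ [−1, 1], which
is *additive*: f of a merged chunk is the sum of f over its parts. For
additive f the winner distribution has the closed form f_i / Σf —
every submission gets slot time proportional to its importance, any leaf with
positive score has positive probability, and the assignment of processors to
leaves is irrelevant. `exact_win_probabilities()` verifies all of this
without using the closed form: it is a dynamic program over winner-identity
distributions, exact for arbitrary (including non-additive) f, exploiting
the fact that merged intensity and mood at a node are fixed subtree sums.
The classic counterexample f = |mood| breaks both additivity and permutation
invariance, and the oracle exhibits the violation on a 4-leaf instance with
moods (+1, −1, +2, −2).

### Learning, links, memory

Processors calibrate how loudly they speak with a Sleeping-Experts rule
acting multiplicatively on the magnitude of emitted weights: *embolden*
(multiply the scale by β) after losing while holding content more valuable
than the broadcast; *hush* (divide by β) after winning with content less
valuable than some loser's. Value comes from a scenario-supplied
ground-truth evaluator, and the machine computes the best losing value from
the archived submissions of the same competition. The rule states directions
only; the multiplicative form with clipping is the canonical
multiplicative-weights choice, default β = 2 on [0.01, 100]. Whether the
embolden comparison should use the broadcast or all competitors is
interpretive; we use broadcast-for-embolden and best-loser-for-hush.

Links form from repeated usefulness: k acknowledgments within a w-tick
window (defaults 3 in 50) create a bidirectional edge; each further k
strengthen it. Link traffic is unconscious — it never touches the slot — and
takes one tick, the same latency as a broadcast, keeping a single global
time semantics. The architecture describes strengthening only, so there is
no decay. Whether broadcasts alone should count toward linking is left open
in the source model; we require explicit acknowledgments tied to task
benefit.

Each processor archives, per tick, its submission, the broadcast received,
and the single largest-|weight| link/input chunk (plus anything surprising)
— its high-level story. Pruning keeps entries with |weight| above a salience
threshold or flagged surprising (prediction errors mark their tick salient),
never reordering and never resurrecting.

## Timing

The faithful mode is pipelined: one tree level per tick, so a competition
submitted at t produces its root at t + h and is received at t + h + 1, with
h competitions in flight and exactly one broadcast per tick once warm. The
source model fixes awareness of the slot's mood at one tick after slot
occupancy; whether reception could be same-tick is not stated, so reception
at root-tick + 1 is the default and a collapsed debug mode (resolution
within the submission tick, reception at t + 1) exists for unit tests. The
intra-tick phase order is fixed: sensors → deliveries and learning feedback
→ processor steps and submissions → tournament → actuators. Sleeping-Experts
feedback and link acknowledgments reference the submission tick carried
inside each chunk, so pipeline latency never misattributes outcomes.

## Determinism

All randomness derives from one master seed via independent L'Ecuyer-CMRG
streams — one per tree node, one per processor, one for the environment —
spawned in a fixed order. Traces written twice under the same configuration
and seed are byte-identical (JSON-lines with fixed field order and
full-precision numbers); this is the "deterministic machine" operating mode
in which all apparent randomness is pseudorandomness. Floating-point ties in
the tournament are resolved by the coin flip itself; no epsilon tie-breaking
is added.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n` | 16 | number of processors (leaves); non-powers of two are padded with null chunks |
| `h` | ⌈log₂ n⌉ | tree height; also the pipeline latency in ticks |
| `c` | 0 | competition-function coefficient, in [−1, 1] |
| `b_gist` | 256 bytes | gist serialized-size bound (per-node compute limits imply a bound; the value is ours) |
| `k_link`, `w_link` | 3, 50 ticks | acknowledgments per window to form a link |
| `beta_sea` | 2 | Sleeping-Experts multiplicative factor |
| `scale_min`, `scale_max` | 0.01, 100 | clip bounds of the Sleeping-Experts scale |
| `pipelined` | TRUE | one level per tick vs collapsed debug mode |

Padding with null chunks (empty gist, weight 0) keeps the tree full; under
additive f a null never beats a positive-score chunk, so the proportional
law over real leaves is untouched. An all-zero competition can put the null
chunk in the slot — an empty broadcast — which follows the coin-flip rule
rather than special-casing, and is exactly the sleeping machine's state.

## Scenarios: what they emulate, and what they do not

The scenarios are synthetic micro-environments that make the architecture's
qualitative predictions assertable. They emulate the *structures* the model
assumes — every processor submits every tick, sensory input arrives as
chunks at designated processors, ground-truth gist values exist for
learning feedback — not the richness of real perception: gists here are
short strings, "scenes" are labels, and no video, audio or language
processing of any kind occurs. Passing tests therefore show the model's
internal logic is implemented correctly; they are not evidence about human
vision or sleep.

* **Blindsight** — vision processors are lesioned out of the competition but
  a pre-formed link still carries visual chunks to the walk processor:
  vision-guided fetching succeeds with zero vision-origin broadcasts.
* **Inattentional blindness** — 15 task processors at weight 10 vs one
  "gorilla" at weight 1: the gorilla's broadcast share is its proportional
  share 1/151 ≈ 0.66%, computed by the exact oracle and confirmed by
  Monte-Carlo tournament sampling.
* **Change blindness** — when the gist encoder describes the pre- and
  post-change scenes with the same gist, the comparison processor (which
  reports a change iff consecutive scene gists differ) reports nothing; a
  finer encoder that encodes the swapped prop restores detection.
* **Sleep/dream** — a Sleep processor accumulates need (+1 per awake tick,
  −5 asleep; thresholds 100/40/10 — the mechanism of intensity domination is
  the model's, this schedule is ours) and floods the tournament with
  weight-10⁶ empty-gist chunks while choking sensors and blocking actuators;
  as need decays its weight drops to the need itself and a Dream Creator
  re-submits high-weight gists seeded deterministically from the salient
  entries of its archived daytime broadcasts, rerouted by the inner-speech
  pathway to the outer-speech recipient. A loud-noise detector is exempt
  from gating (weight 10¹² ≫ 10⁶), so a noise during sleep is broadcast.
  Single sleep→dream→wake cycles are implemented; multi-cycle alternation is
  a human detail left out.
* **Self-attribution** — "immediately followed" is operationalised as
  exactly one tick (the actuator latency), and "consistently and repeatedly"
  as 5 consecutive command→action pairings with misses resetting the streak;
  entities that act but never in step with a command are tagged not-self.
  Earned self tags never flip without contrary evidence. The broader
  Model-of-the-World machinery (imaginings, planning) is out of scope, not
  approximated.

## Problem sizes and numerical choices

All checks run desk-scale: the architecture's guarantees are scale-free, so
machines of 2–16 processors, runs of 40–1000 ticks, 10⁵ Monte-Carlo
tournaments and 100-seed learning replications exercise the same logic as
astronomically larger configurations. Tolerances: the oracle is compared to
the closed form at 10⁻¹², conservation at 10⁻⁹ (floating summation), and
Monte-Carlo frequencies at three binomial standard errors. The additivity
checker is a randomized necessary-condition sampler — exact for linear
forms, and a certain rejector of |mood| in the limit of many trials.

## Known limitations

Gists carry no semantics; the competition function may inspect the whole
chunk but the bundled family reads only intensity and mood; link capacity is
unbounded per tick (only chunk size is bounded); there is no link decay, no
hardware-level circuit timing (the one-level-per-tick constraint is
scheduling, not electronics), and no claim that any of this *feels* like
anything.
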