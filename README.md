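# ctmsim

A discrete-time simulator of the **Conscious Turing Machine (CTM)** — a
formal Global-Workspace-style cognitive architecture — for researchers in
computational cognitive science who want the architecture's qualitative
claims as executable, assertable code.

The machine is the seven-tuple *⟨STM, LTM, Up Tree, Down Tree, Links,
Input, Output⟩*: N long-term-memory processors each submit one *chunk*
⟨address, t, gist, weight, intensity, mood⟩ per tick into a binary
tournament tree of height h. Each internal node runs a local competition
with a **coin-flip neuron** — given child scores (a, b) it selects the
first with probability a/(a+b), or 1/2 when both vanish — scored by a
competition function f(chunk); the chunk moving up keeps the winner's
identity but carries the *sum* of its children's intensities and moods.
The root chunk occupies the single short-term-memory slot and is broadcast
to all N processors: the machine's conscious content. For **additive** f
(the bundled family f = intensity + c·mood, c ∈ [−1, 1]) every submission
wins the slot with probability exactly

&nbsp;&nbsp;&nbsp;&nbsp;P(chunk *p* reaches STM) = f(chunk_p) / Σ_p′ f(chunk_p′),

independent of the leaf assignment. The package implements this machine in
full: an exact dynamic-programming win-probability oracle valid for
arbitrary (also non-additive) f, Hebbian-style link formation carrying
unconscious processor-to-processor traffic, Sleeping-Experts
(embolden/hush) intensity calibration, salience-pruned memory archives,
mood readouts, byte-exact replayable JSON-lines traces, and executable
scenarios for blindsight, inattentional blindness, change blindness,
sleep/dream creation and self/not-self attribution.

## Worked example

Eight processors chatter with constant weights 1..8; under f = intensity
the slot time each receives is proportional to its weight.

```r
library(ctmsim)
cfg <- machine_config(n = 8, master_seed = 7)
cfg
#> CTM configuration: N=8 processors, tree height h=3, T=10000 ticks
#>   competition f = intensity + 0*mood; gist bound 256 bytes
#>   links: k=3 acks in 50 ticks; SEA beta=2, scale in [0.01, 100]
#>   mode: pipelined (one tree level per tick); master seed 7

beh <- lapply(1:8, function(i) list(
  emit = function(proc, inbox, tick, ctx)
    list(gist = gist(paste0("idea-", proc$address), tags = "query"),
         weight = proc$address + 1)))
trace <- run_ctm(ctm(cfg, beh), ticks = 200)
b <- trace_broadcasts(trace)
round(table(b$address) / nrow(b), 3)
#>     0     1     2     3     4     5     6     7
#> 0.031 0.036 0.112 0.107 0.153 0.128 0.194 0.240
```

The empirical broadcast shares track the proportional law (weights 1..8 sum
to 36, so processor 7 should win 8/36 ≈ 0.222 of the ticks). The exact
oracle confirms the law to machine precision:

```r
exact_win_probabilities(
  lapply(1:8, function(i) chunk(i - 1L, 0L, gist_empty(), i)),
  competition_function(0))
#> Up-Tree win probabilities under f = intensity + 0 * mood
#>  leaf address f_value probability
#>     0       0       1  0.02777778
#>     1       1       2  0.05555556
#>     2       2       3  0.08333333
#>     3       3       4  0.11111111
#>     4       4       5  0.13888889
#>     5       5       6  0.16666667
#>     6       6       7  0.19444444
#>     7       7       8  0.22222222

mood_readout(trace, 10)
#> mood at tick 10: 36 (avg 4.5 per processor, intensity 36) — optimism/happiness
```

The mood readout illustrates conservation: whoever wins, the root chunk's
mood is the sum of all submitted moods (here all weights are positive, so
the machine reads out optimism).

Scenarios run from a single seed and return their trace plus the quantities
their claim is about, e.g. `scenario_blindsight(seed = 1)` (zero
vision-origin broadcasts, yet successful vision-guided fetches via links)
or `scenario_sleep_dream(seed = 1)` (empty-gist broadcasts while asleep,
Dream-Creator content while dreaming, a loud noise cutting through). A thin
command-line front end lives at `inst/cli/ctm`
(`ctm run`, `ctm verify-theorem`, `ctm scenario`, `ctm mood`).

See the vignette in `vignettes/ctm-architecture.Rmd` for the model, its
parameters and the package's design choices.

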