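# Shared fixture builders: all inputs are generated in code from fixed seeds.

# leaf chunks with given weights (addresses 0..n-1, tick t)
make_leaves <- function(weights, t = 0L, g = gist_empty()) {
  lapply(seq_along(weights), function(i) chunk(i - 1L, t, g, weights[i]))
}

# constant-emission behaviour
const_behaviour <- function(payload, weight, tags = "query") {
  force(payload); force(weight); force(tags)
  list(emit = function(proc, inbox, tick, ctx)
    list(gist = gist(payload, tags = tags), weight = weight))
}

# small machine emitting deterministic distinct weights per processor
toy_machine <- function(n = 8L, seed = 1L, ...) {
  beh <- lapply(seq_len(n), function(i)
    const_behaviour(paste0("p", i - 1L), (i %% 5L) + 0.5))
  ctm(machine_config(n = n, master_seed = seed, ...), beh)
}
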