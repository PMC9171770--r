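test_that("pipelined cadence: first reception at h + 1, then one per tick", {
  m <- toy_machine(n = 8L, seed = 2L)            # h = 3
  trace <- run_ctm(m, 40L)
  b <- trace_broadcasts(trace)
  expect_identical(min(b$tick), 4)               # t=0 root at 3, received at 4
  expect_identical(b$tick, as.numeric(4:39))     # exactly one per tick after
  expect_identical(b$stm_tick, b$tick - 1)
  expect_identical(as.integer(b$t), as.integer(b$stm_tick - 3L))
})

test_that("collapsed debug mode receives at t + 1", {
  beh <- lapply(1:8, function(i) const_behaviour(paste0("p", i), i / 4))
  m <- ctm(machine_config(n = 8L, master_seed = 2L, pipelined = FALSE), beh)
  b <- trace_broadcasts(run_ctm(m, 20L))
  expect_identical(min(b$tick), 1)
  expect_identical(as.integer(b$t), as.integer(b$tick - 1L))
})

test_that("broadcast mood equals the submitted mood sum h ticks earlier", {
  n <- 8L
  beh <- lapply(seq_len(n), function(i) list(
    emit = function(proc, inbox, tick, ctx)
      list(gist = gist("m", tags = "query"),
           weight = (-1)^(proc$address + tick) * (proc$address + 1) / 3)
  ))
  m <- ctm(machine_config(n = n, master_seed = 6L), beh)
  trace <- run_ctm(m, 60L)
  b <- trace_broadcasts(trace)
  h <- trace$config$h
  for (k in seq_len(nrow(b))) {
    subs <- trace$submissions[[b$stm_tick[k] - h + 1L]]
    expect_equal(b$mood[k], sum(vapply(subs, `[[`, numeric(1), "mood")),
                 tolerance = 1e-9)
    expect_equal(b$intensity[k],
                 sum(vapply(subs, function(ch) ch$intensity, numeric(1))),
                 tolerance = 1e-9)
  }
  mr <- mood_readout(trace, b$stm_tick[5L])
  expect_equal(mr$mood, b$mood[5L])
  expect_equal(mr$average_mood, mr$mood / n)
  expect_error(mood_readout(trace, 0L), "no broadcast")
})

test_that("mood readout recovers the worked sign cases", {
  mk <- function(weights) {
    beh <- lapply(seq_along(weights), function(i)
      const_behaviour("m", weights[i]))
    run_ctm(ctm(machine_config(n = length(weights), master_seed = 8L), beh), 20L)
  }
  # moods (1, -2, 0.5, 0.5): cancellation, machine mood 0 whoever wins
  tr <- mk(c(1, -2, 0.5, 0.5))
  b <- trace_broadcasts(tr)
  expect_true(all(abs(b$mood) < 1e-12))
  r <- mood_readout(tr, b$stm_tick[1L])
  expect_equal(r$average_mood, 0)
  # all positive: optimism readout
  tr2 <- mk(c(1, 2, 0.5, 0.5))
  expect_true(all(trace_broadcasts(tr2)$mood == 4))
})

test_that("machine construction validates scenario size and sensor wiring", {
  beh <- lapply(1:4, function(i) const_behaviour("x", 1))
  expect_error(ctm(machine_config(n = 8L), beh), "mismatch")
  cfg <- machine_config(n = 4L)
  expect_error(
    attach_io(cfg, sensors = list(list(name = "eye", to = "STM",
                                       sense = function(s, t) NULL))),
    "never the short-term-memory slot")
  expect_error(
    attach_io(cfg, sensors = list(list(name = "eye", to = 9L,
                                       sense = function(s, t) NULL))),
    "invalid processor")
  # closed-box machine (no sensors/actuators) is valid and dream-capable
  io <- attach_io(cfg)
  expect_false("env_to_ltm" %in% io$kinds)
  io2 <- attach_io(cfg,
                   sensors = list(list(name = "eye", to = c(2L, 3L),
                                       sense = function(s, t) NULL)),
                   actuators = list(list(name = "leg", from = 1L,
                                         act = function(s, g, t) s)))
  expect_setequal(io2$kinds, c("env_to_ltm", "ltm_to_stm", "stm_to_ltm",
                               "ltm_to_ltm", "ltm_to_env"))
})

test_that("traces replay byte-identically under the same seed and differ across seeds", {
  t1 <- run_ctm(toy_machine(n = 8L, seed = 12L), 40L)
  t2 <- run_ctm(toy_machine(n = 8L, seed = 12L), 40L)
  t3 <- run_ctm(toy_machine(n = 8L, seed = 13L), 40L)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  f3 <- withr::local_tempfile()
  write_trace(t1, f1); write_trace(t2, f2); write_trace(t3, f3)
  b1 <- readBin(f1, "raw", file.size(f1) + 10)
  expect_identical(b1, readBin(f2, "raw", file.size(f2) + 10))
  expect_false(identical(b1, readBin(f3, "raw", file.size(f3) + 10)))
  rt <- read_trace(f1)
  expect_identical(rt$header$n, 8L)
  expect_identical(length(rt$events), length(t1$events))
})

test_that("the trace audit passes on a healthy run", {
  trace <- run_ctm(toy_machine(n = 8L, seed = 1L), 60L)
  expect_true(audit_trace(trace))
  kinds <- unique(vapply(trace$events, `[[`, character(1), "kind"))
  expect_true(all(c("submission", "broadcast") %in% kinds))
})

test_that("distinct master seeds give distinct broadcast sequences", {
  a <- trace_broadcasts(run_ctm(toy_machine(n = 8L, seed = 21L), 60L))
  b <- trace_broadcasts(run_ctm(toy_machine(n = 8L, seed = 22L), 60L))
  expect_false(identical(a$address, b$address))
})
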