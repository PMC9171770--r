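empty_inbox <- list(broadcast = NULL, links = list(), inputs = list())

test_that("processor steps scale the emitted weight and always submit one chunk", {
  cfg <- machine_config(n = 2L)
  p <- processor(0L, const_behaviour("hello", 1.0), sea_scale = 2.0, config = cfg)
  ch <- proc_step(p, empty_inbox, 0L, rng_stream(1L))
  expect_equal(ch$intensity, 2.0)       # |1.0 * 2.0|
  expect_equal(ch$weight, 2.0)
  # silent behaviour: the null chunk is still submitted (mandatory submission)
  q <- processor(1L, list(emit = function(proc, inbox, tick, ctx) NULL),
                 config = cfg)
  ch2 <- proc_step(q, empty_inbox, 0L, rng_stream(1L))
  expect_true(is_empty_gist(ch2$gist))
  expect_identical(ch2$weight, 0)
  expect_identical(ch2$address, 1L)
  # negative weights keep their sign under scaling
  r <- processor(0L, const_behaviour("bad news", -1.5), sea_scale = 2.0,
                 config = cfg)
  ch3 <- proc_step(r, empty_inbox, 0L, rng_stream(1L))
  expect_equal(ch3$weight, -3.0)
  expect_equal(ch3$intensity, 3.0)
})

test_that("the archive stores the broadcast received alongside the submission", {
  cfg <- machine_config(n = 2L)
  p <- processor(0L, const_behaviour("x", 1), config = cfg)
  bc <- chunk(1L, 0L, gist("broadcast content", tags = "answer"), 4)
  proc_step(p, list(broadcast = bc, links = list(), inputs = list()), 3L,
            rng_stream(1L))
  entry <- p$memory[[1L]]
  expect_identical(entry$t, 3L)
  expect_true(gist_equal(entry$received_broadcast$gist, bc$gist))
  expect_true(gist_equal(entry$submitted$gist, gist("x", tags = "query")))
})

test_that("Sleeping-Experts updates embolden, hush, or leave the scale alone", {
  cfg <- machine_config(beta_sea = 2, scale_min = 0.01, scale_max = 100)
  p <- processor(0L, const_behaviour("x", 1), sea_scale = 1.0, config = cfg)
  # lost with more valuable content -> embolden
  sea_update(p, won = FALSE, own_value = 1.0, broadcast_value = 0.2)
  expect_equal(p$sea_scale, 2.0)
  # won with less valuable content than the best loser -> hush
  p$sea_scale <- 1.0
  sea_update(p, won = TRUE, own_value = 0.2, broadcast_value = 0.2,
             best_loser_value = 1.0)
  expect_equal(p$sea_scale, 0.5)
  # won with the highest value -> unchanged
  p$sea_scale <- 1.0
  sea_update(p, won = TRUE, own_value = 1.0, broadcast_value = 1.0,
             best_loser_value = 0.5)
  expect_equal(p$sea_scale, 1.0)
  # lost against better content -> unchanged
  sea_update(p, won = FALSE, own_value = 0.1, broadcast_value = 0.9)
  expect_equal(p$sea_scale, 1.0)
})

test_that("the Sleeping-Experts scale never leaves its bounds", {
  cfg <- machine_config(beta_sea = 3, scale_min = 0.5, scale_max = 4)
  p <- processor(0L, const_behaviour("x", 1), sea_scale = 1, config = cfg)
  for (i in 1:10) sea_update(p, FALSE, 1, 0)
  expect_equal(p$sea_scale, 4)
  for (i in 1:10) sea_update(p, TRUE, 0, 0, best_loser_value = 1)
  expect_equal(p$sea_scale, 0.5)
})

test_that("prediction scoring flags surprises and requires a registration", {
  cfg <- machine_config()
  p <- processor(0L, const_behaviour("x", 1), config = cfg)
  g1 <- gist("sun rises", tags = "vision")
  g2 <- gist("sun sets", tags = "vision")
  predict_register(p, 5L, g1)
  res <- predict_and_score(p, 5L, g1)
  expect_equal(res$error, 0)
  expect_false(res$surprise)
  predict_register(p, 6L, g1)
  res2 <- predict_and_score(p, 6L, g2)
  expect_equal(res2$error, 1)
  expect_true(res2$surprise)
  expect_error(predict_and_score(p, 7L, g2), "no prediction")
})

test_that("surprising ticks are marked salient in the archive", {
  cfg <- machine_config()
  p <- processor(0L, const_behaviour("x", 0.0), config = cfg)
  proc_step(p, empty_inbox, 0L, rng_stream(1L))
  predict_register(p, 0L, gist("expected", tags = "vision"))
  predict_and_score(p, 0L, gist("unexpected", tags = "vision"))
  expect_true(p$memory[[1L]]$surprise)
  # zero-weight but surprising: survives pruning at any threshold
  prune_memory(p, 10)
  expect_identical(length(p$memory), 1L)
})

test_that("memory pruning filters on |weight|, keeps order, never resurrects", {
  cfg <- machine_config()
  p <- processor(0L, list(emit = function(proc, inbox, tick, ctx)
    list(gist = gist("x", tags = "query"), weight = c(0.1, 0.9, 0.5)[tick + 1L])),
    config = cfg)
  for (t in 0:2) proc_step(p, empty_inbox, t, rng_stream(1L))
  prune_memory(p, 0)                     # threshold 0: unchanged
  expect_identical(length(p$memory), 3L)
  prune_memory(p, 0.4)
  expect_identical(length(p$memory), 2L)
  expect_identical(vapply(p$memory, `[[`, integer(1), "t"), c(1L, 2L))
  prune_memory(p, 0.4)                   # idempotent: nothing resurrected
  expect_identical(length(p$memory), 2L)
})

test_that("each processor submits exactly once per tick across a whole run", {
  trace <- run_ctm(toy_machine(n = 8L, seed = 4L), 50L)
  subs <- Filter(function(e) e$kind == "submission", trace$events)
  tab <- table(tick = vapply(subs, `[[`, numeric(1), "tick"),
               origin = vapply(subs, `[[`, numeric(1), "origin"))
  expect_true(all(tab == 1L))
  expect_identical(dim(tab), c(50L, 8L))
})

test_that("a starved reliable expert recovers the majority of broadcasts", {
  res <- sea_two_expert(seed = 1L, ticks = 200L)
  expect_true(res$majority)
  expect_gt(res$reliable_wins / res$total_broadcasts, 0.75)
  # its scale has grown off the floor; the unreliable expert has been hushed
  expect_gt(res$final_scales[1L], res$final_scales[2L])
})
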