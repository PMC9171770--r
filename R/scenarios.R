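# Executable scenarios: synthetic environments and special processors that
# turn the architecture's qualitative predictions into assertable traces.
# Each scenario runs from a single seed, needs no external data, and returns
# its trace together with the quantities its claim is about. None of them
# says anything about human vision or sleep; they verify the model's internal
# logic only.

#' Blindsight: seeing without conscious sight
#'
#' Vision processors receive visual input but are lesioned out of the
#' tournament (they submit only null chunks), so no vision-origin chunk is
#' ever broadcast — the machine is never conscious of what it sees. A
#' pre-formed link from a vision processor to the walk processor still
#' carries the visual chunks unconsciously, and the walk processor drives the
#' leg actuator to fetch the seen object successfully. The control run
#' (lesioned = FALSE) restores competitive submission and vision content
#' reaches the broadcast.
#'
#' @param seed master seed.
#' @param ticks run length (default 120).
#' @param lesioned disable competitive submission from vision processors.
#' @return list with \code{trace}, \code{vision_broadcasts} (count of
#'   broadcast chunks originating at a vision processor),
#'   \code{fetch_successes}, \code{summary} (a one-row data frame), and the
#'   scenario parameters.
#' @export
scenario_blindsight <- function(seed = 1L, ticks = 120L, lesioned = TRUE) {
  n <- 8L
  vision_addrs <- c(0L, 1L)
  walk_addr <- 2L
  objects <- c("ball", "cup", "key")

  vision_behaviour <- function(can_link) list(emit = function(proc, inbox, tick, ctx) {
    seen <- Filter(function(ch) "vision" %in% ch$gist$tags, inbox$inputs)
    if (length(seen)) {
      proc$state$last <- seen[[1L]]$gist
      if (can_link) ctx$send_link(walk_addr, proc$state$last, 1.0)
    }
    if (lesioned || is.null(proc$state$last)) return(NULL)
    list(gist = proc$state$last, weight = 2.0)
  })
  walk_behaviour <- list(emit = function(proc, inbox, tick, ctx) {
    vis <- Filter(function(ch) "vision" %in% ch$gist$tags, inbox$links)
    if (!length(vis)) return(NULL)
    obj <- sub("^see ", "", vis[[1L]]$gist$payload)
    cmd <- gist(paste("fetch", obj), tags = "command")
    ctx$act("legs", cmd)
    ctx$acknowledge(vis[[1L]]$address)
    list(gist = cmd, weight = 0.2)
  })
  chatter_behaviour <- list(emit = function(proc, inbox, tick, ctx)
    list(gist = gist("hum", tags = "query"), weight = 0.5))

  behaviours <- c(list(vision_behaviour(TRUE), vision_behaviour(FALSE),
                       walk_behaviour),
                  rep(list(chatter_behaviour), n - 3L))
  sensors <- list(list(
    name = "eyes", to = vision_addrs,
    sense = function(state, tick)
      list(gist = gist(paste("see", state$object), tags = "vision"), weight = 1.5)
  ))
  actuators <- list(list(
    name = "legs", from = walk_addr,
    act = function(state, g, tick) {
      if (identical(sub("^fetch ", "", g$payload), state$object)) {
        state$fetched <- state$fetched + 1L
        state$object <- objects[(tick %/% 20L) %% length(objects) + 1L]
      }
      state
    }
  ))
  cfg <- machine_config(n = n, master_seed = seed, ticks = max(ticks, 8L))
  m <- ctm(cfg, behaviours, env_state = list(object = objects[1L], fetched = 0L),
           sensors = sensors, actuators = actuators,
           prelinked = list(c(0L, walk_addr)))
  trace <- run_ctm(m, ticks)
  b <- trace_broadcasts(trace)
  vb <- sum(!is.na(b$address) & b$address %in% vision_addrs & b$weight != 0)
  fetched <- m$env_state$fetched
  list(trace = trace, machine = m,
       vision_broadcasts = vb, fetch_successes = fetched,
       lesioned = lesioned,
       summary = data.frame(lesioned = lesioned, vision_broadcasts = vb,
                            fetch_successes = fetched,
                            total_broadcasts = nrow(b)))
}

#' Inattentional blindness: the unnoticed gorilla
#'
#' A task instruction makes the task processors assign high weight
#' (\code{ratio}) to task-relevant gists while one processor carries the
#' irrelevant "gorilla" gist at weight 1. Under an additive competition
#' function the gorilla's broadcast share is exactly its proportional share
#' f/sum(f) — near zero for large ratios, so the unexpected content rarely
#' reaches the conscious slot. The scenario computes the share three ways:
#' the exact oracle, a large Monte-Carlo tournament sample, and the broadcast
#' share of a (shorter) full machine run.
#'
#' @param seed master seed.
#' @param n_task number of task processors (default 15).
#' @param ratio task-to-gorilla weight ratio (default 10; \code{ratio = 1}
#'   removes the task and shares become uniform).
#' @param mc_runs Monte-Carlo tournaments (default 1e5).
#' @param machine_ticks full machine run length for the trace (default 300).
#' @return list with \code{oracle_share}, \code{mc_share}, \code{mc_se},
#'   \code{z}, \code{trace_share}, \code{trace}, \code{table} (per-class
#'   shares) and parameters.
#' @export
scenario_inattentional <- function(seed = 1L, n_task = 15L, ratio = 10,
                                   mc_runs = 1e5L, machine_ticks = 300L) {
  n <- n_task + 1L
  gorilla_addr <- n_task          # last address
  task_gist <- gist("white-shirt pass", tags = "vision")
  gorilla_gist <- gist("gorilla", tags = "vision")
  leaf <- c(lapply(seq_len(n_task) - 1L, function(a)
    chunk(a, 0L, task_gist, ratio)),
    list(chunk(gorilla_addr, 0L, gorilla_gist, 1)))
  f <- competition_function(0)
  tab <- exact_win_probabilities(leaf, f)
  oracle_share <- sum(tab$probability[tab$address %in% gorilla_addr],
                      na.rm = TRUE)
  rng <- rng_stream(seed)
  counts <- simulate_win_counts(leaf, f, mc_runs, rng)
  mc_share <- counts[gorilla_addr + 1L] / mc_runs
  mc_se <- sqrt(oracle_share * (1 - oracle_share) / mc_runs)

  mk_b <- function(g, w) list(emit = function(proc, inbox, tick, ctx)
    list(gist = g, weight = w))
  behaviours <- c(rep(list(mk_b(task_gist, ratio)), n_task),
                  list(mk_b(gorilla_gist, 1)))
  cfg <- machine_config(n = n, master_seed = seed)
  trace <- run_ctm(ctm(cfg, behaviours), machine_ticks)
  b <- trace_broadcasts(trace)
  trace_share <- if (nrow(b)) mean(b$gist_payload == "gorilla") else NA_real_
  list(oracle_share = oracle_share, mc_share = mc_share, mc_se = mc_se,
       z = (mc_share - oracle_share) / mc_se,
       mc_runs = mc_runs, trace_share = trace_share, trace = trace,
       n_task = n_task, ratio = ratio,
       table = data.frame(class = c("task", "gorilla"),
                          oracle_share = c(1 - oracle_share, oracle_share),
                          mc_share = c(1 - mc_share, mc_share)))
}

#' Change blindness: equal gists hide the change
#'
#' The environment shows scene A, cuts away to a suspect close-up, then
#' returns to a modified scene A'. Under the coarse gist encoder the same
#' gist describes A and A' equally well, so the comparison processor — which
#' reports a change iff consecutive scene gists differ — reports nothing.
#' A finer encoder that includes the swapped prop in the payload makes the
#' gists unequal and the change is reported.
#'
#' @param seed master seed.
#' @param encoder \code{"coarse"} or \code{"fine"}.
#' @param identical_scenes present A twice with no change (control: zero
#'   reports under any encoder).
#' @return list with \code{trace}, \code{change_reports}, \code{encoder},
#'   \code{summary}.
#' @export
scenario_change_blindness <- function(seed = 1L, encoder = c("coarse", "fine"),
                                      identical_scenes = FALSE) {
  encoder <- match.arg(encoder)
  n <- 4L
  scene_payload <- function(variant) {
    base <- "scene: living room, detective, butler, maid, body"
    if (encoder == "fine")
      paste0(base, "; trenchcoat-", if (variant == "A2") "white" else "dark")
    else base
  }
  stage_at <- function(tick) {
    if (tick < 10L) "A" else if (tick < 20L) "cut" else "A2"
  }
  sensors <- list(list(
    name = "camera", to = 0L,
    sense = function(state, tick) {
      st <- stage_at(tick)
      if (st == "cut")
        return(list(gist = gist("cut: maid close-up", tags = "vision"),
                    weight = 2))
      v <- if (identical_scenes) "A" else st
      list(gist = gist(scene_payload(v), tags = "vision"), weight = 2)
    }
  ))
  vision_behaviour <- list(emit = function(proc, inbox, tick, ctx) {
    if (!length(inbox$inputs)) return(NULL)
    list(gist = inbox$inputs[[1L]]$gist, weight = 3)
  })
  comparator_behaviour <- list(
    on_broadcast = function(proc, ch, tick, ctx) {
      if (startsWith(ch$gist$payload, "scene:")) {
        last <- proc$state$last_scene
        if (!is.null(last) && !gist_equal(last, ch$gist)) {
          proc$state$reports <- (if (is.null(proc$state$reports)) 0L
                                 else proc$state$reports) + 1L
          proc$state$flag <- TRUE
        }
        proc$state$last_scene <- ch$gist
      }
    },
    emit = function(proc, inbox, tick, ctx) {
      if (isTRUE(proc$state$flag)) {
        proc$state$flag <- FALSE
        return(list(gist = gist("scene changed", tags = "answer"), weight = 2))
      }
      NULL
    }
  )
  chatter <- list(emit = function(proc, inbox, tick, ctx)
    list(gist = gist("hum", tags = "query"), weight = 0.1))
  cfg <- machine_config(n = n, master_seed = seed)
  m <- ctm(cfg, list(vision_behaviour, comparator_behaviour, chatter, chatter),
           env_state = list(), sensors = sensors)
  trace <- run_ctm(m, 40L)
  reports <- m$procs[[2L]]$state$reports
  if (is.null(reports)) reports <- 0L
  list(trace = trace, change_reports = reports, encoder = encoder,
       identical_scenes = identical_scenes,
       summary = data.frame(encoder = encoder,
                            identical_scenes = identical_scenes,
                            change_reports = reports))
}

#' Sleep and dream creation
#'
#' A Sleep processor accumulates a need for sleep while awake (+1 per tick);
#' past the sleep threshold it floods the tournament with enormous-weight
#' empty-gist chunks — the machine broadcasts emptiness and is barely
#' conscious — while choking sensor intensities to zero and blocking actuator
#' commands. As the need decays (-5 per sleeping tick) below the dream
#' threshold, the Sleep processor's weight drops to the need itself and a
#' Dream Creator becomes active, re-submitting high-weight gists seeded from
#' the salient entries of its archived daytime broadcasts; an inner-speech
#' processor reroutes the dreamt speech to the outer-speech recipient, so
#' dreamt speech arrives by the same path as heard speech. Below the wake
#' threshold the choke hold is released. A loud-noise detector is exempt from
#' the gating: a sufficiently heavy noise input during sleep is broadcast.
#'
#' @param seed master seed.
#' @param ticks run length (default 160: one full awake/sleep/dream/wake
#'   cycle under the default thresholds).
#' @param theta_sleep,theta_dream,theta_wake need thresholds (100/40/10).
#' @param noise_tick tick at which a loud noise arrives (default 105, inside
#'   the sleep phase; \code{NULL} for no noise).
#' @return list with \code{trace}, \code{phases} (per-tick phase labels),
#'   per-phase broadcast classifications and the scenario's headline counts.
#' @export
scenario_sleep_dream <- function(seed = 1L, ticks = 160L,
                                 theta_sleep = 100, theta_dream = 40,
                                 theta_wake = 10, noise_tick = 105L) {
  n <- 8L
  sleep_addr <- 0L; creator_addr <- 1L; ear_addr <- 2L; inner_addr <- 3L
  speech_recipient <- 4L
  sh <- new.env(parent = emptyenv())
  sh$phase <- "awake"; sh$need <- 0; sh$gate <- 1
  sh$phase_log <- character(ticks)

  sleep_behaviour <- list(emit = function(proc, inbox, tick, ctx) {
    if (sh$phase == "awake") sh$need <- sh$need + 1 else sh$need <- sh$need - 5
    if (sh$phase == "awake" && sh$need >= theta_sleep) sh$phase <- "sleep"
    else if (sh$phase == "sleep" && sh$need <= theta_dream) sh$phase <- "dream"
    else if (sh$phase == "dream" && sh$need <= theta_wake) {
      sh$phase <- "awake"; sh$need <- max(sh$need, 0)
    }
    sh$gate <- if (sh$phase == "awake") 1 else 0
    sh$phase_log[tick + 1L] <- sh$phase
    switch(sh$phase,
           awake = NULL,
           sleep = list(gist = gist_empty(), weight = 1e6),
           dream = list(gist = gist_empty(), weight = sh$need))
  })
  creator_behaviour <- list(emit = function(proc, inbox, tick, ctx) {
    if (sh$phase != "dream") return(NULL)
    salient <- Filter(function(e) !is.null(e$received_broadcast) &&
                        abs(e$received_broadcast$weight) >= 2,
                      proc$memory)
    seedling <- if (length(salient)) {
      k <- (tick %% length(salient)) + 1L
      salient[[k]]$received_broadcast$gist$payload
    } else "nothing in particular"
    list(gist = gist(paste("dream of", seedling),
                     tags = c("speech", "vision"), note = "dream"),
         weight = 500)
  })
  ear_behaviour <- list(emit = function(proc, inbox, tick, ctx) {
    loud <- Filter(function(ch) ch$weight >= 1e9, inbox$inputs)
    if (!length(loud)) return(NULL)
    list(gist = loud[[1L]]$gist, weight = 1e12)
  })
  inner_behaviour <- list(
    on_broadcast = function(proc, ch, tick, ctx) {
      for (d in inner_speech_route(ch, speech_recipient)) {
        ctx$send_link(d$to, d$chunk$gist, 1.0)
      }
    },
    emit = function(proc, inbox, tick, ctx) NULL
  )
  day_behaviour <- function(addr) list(emit = function(proc, inbox, tick, ctx) {
    if (addr == speech_recipient && sh$gate == 1 && tick %% 7L == 0L)
      ctx$act("hand", gist("wave", tags = "command"))
    w <- if (tick %% 10L == addr %% 10L) 3 else 1
    list(gist = gist(paste0("daytime-", addr, "-", tick %/% 10L),
                     tags = if (addr == speech_recipient) "speech" else "vision"),
         weight = w)
  })
  behaviours <- c(list(sleep_behaviour, creator_behaviour, ear_behaviour,
                       inner_behaviour),
                  lapply(4L:(n - 1L), day_behaviour))
  sensors <- list(
    list(name = "eyes", to = 5L,
         sense = function(state, tick) {
           if (sh$gate == 0) return(NULL)   # choked during sleep/dream
           list(gist = gist("outer scene", tags = "vision"), weight = 0.5)
         }),
    list(name = "ears", to = ear_addr,
         sense = function(state, tick) {    # loud-noise path is never gated
           if (!is.null(noise_tick) && tick == noise_tick)
             list(gist = gist("loud noise", tags = "tactile"), weight = 1e9)
           else NULL
         })
  )
  actuators <- list(list(name = "hand", from = speech_recipient,
                         act = function(state, g, tick) state))
  cfg <- machine_config(n = n, master_seed = seed, ticks = max(ticks, 8L))
  m <- ctm(cfg, behaviours, env_state = list(), sensors = sensors,
           actuators = actuators,
           prelinked = list(c(inner_addr, speech_recipient)))
  trace <- run_ctm(m, ticks)
  b <- trace_broadcasts(trace)
  phases <- sh$phase_log
  phase_of_sub <- phases[b$t + 1L]
  sleep_rows <- b[phase_of_sub == "sleep", , drop = FALSE]
  noise_rows <- sleep_rows[sleep_rows$gist_payload == "loud noise", , drop = FALSE]
  empty_rows <- sleep_rows[sleep_rows$gist_tags == "empty", , drop = FALSE]
  dream_rows <- b[phase_of_sub == "dream", , drop = FALSE]
  creator_rows <- dream_rows[dream_rows$address == creator_addr |
                               startsWith(dream_rows$gist_payload, "dream of"), ,
                             drop = FALSE]
  act_ev <- Filter(function(e) e$kind == "env_action", trace$events)
  act_phases <- phases[vapply(act_ev, `[[`, numeric(1), "tick") + 1L]
  list(trace = trace, phases = phases,
       sleep_broadcasts = nrow(sleep_rows),
       sleep_empty_broadcasts = nrow(empty_rows),
       noise_broadcasts = nrow(noise_rows),
       dream_broadcasts = nrow(dream_rows),
       dream_creator_broadcasts = nrow(creator_rows),
       actions_while_asleep = sum(act_phases != "awake"),
       summary = data.frame(
         phase = c("awake", "sleep", "dream"),
         ticks = c(sum(phases == "awake"), sum(phases == "sleep"),
                   sum(phases == "dream")),
         broadcasts = c(sum(phase_of_sub == "awake"), nrow(sleep_rows),
                        nrow(dream_rows))))
}

#' Two-expert Sleeping-Experts recovery demo
#'
#' A reliable processor (its gist always has ground-truth value 1) starts at
#' the minimum intensity scale; an unreliable one (value 0) starts at scale 1
#' and initially wins every tournament. Embolden/hush feedback doubles the
#' reliable expert's scale on each valuable loss and halves the unreliable
#' winner's, so the reliable expert overtakes within a few tens of ticks and
#' wins a strict majority of the run's broadcasts.
#'
#' @param seed master seed.
#' @param ticks run length (default 200).
#' @return list with \code{reliable_wins}, \code{total_broadcasts},
#'   \code{majority} (logical) and the trace.
#' @export
sea_two_expert <- function(seed = 1L, ticks = 200L) {
  cfg <- machine_config(n = 2L, master_seed = seed, ticks = max(ticks, 2L))
  mk <- function(payload) list(emit = function(proc, inbox, tick, ctx)
    list(gist = gist(payload, tags = "answer"), weight = 1))
  m <- ctm(cfg, list(mk("signal"), mk("noise")),
           evaluator = function(g) if (identical(g$payload, "signal")) 1 else 0,
           sea_scales = c(cfg$scale_min, 1))
  trace <- run_ctm(m, ticks)
  b <- trace_broadcasts(trace)
  wins <- sum(b$address == 0L, na.rm = TRUE)
  list(reliable_wins = wins, total_broadcasts = nrow(b),
       majority = wins > nrow(b) / 2, trace = trace,
       final_scales = c(m$procs[[1L]]$sea_scale, m$procs[[2L]]$sea_scale))
}
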