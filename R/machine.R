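# The assembled machine: <STM, LTM, Up Tree, Down Tree, Links, Input,
# Output>. One short-term-memory slot; N long-term-memory processors; the
# probabilistic tournament tree feeding the slot; a depth-1 broadcast tree
# returning its content to every processor; a link graph for unconscious
# traffic; and input/output maps touching only designated processors.
#
# Intra-tick phase order (fixed, logged in the trace ordering):
#   1. sensors convert the environment into input chunks;
#   2. deliveries scheduled for this tick (broadcast, link messages) join the
#      inboxes, and Sleeping-Experts feedback for the delivered broadcast's
#      competition is applied;
#   3. every processor steps and submits one chunk;
#   4. the tick's tournament runs; in pipelined mode its root chunk enters
#      the slot at t + h and is received by all processors at t + h + 1
#      (collapsed debug mode: slot at t, reception at t + 1);
#   5. queued actuator commands mutate the environment.

#' Wire sensors and actuators to a machine configuration
#'
#' Validates the input/output maps before a machine is built. Exactly five
#' connection kinds exist in the resulting wiring: environment to processors
#' (sensors), processors to the competition, slot to processors (broadcast),
#' processor to processor (links), and processors to the environment
#' (actuators). Inputs never enter the slot directly: wiring a sensor to
#' \code{"STM"} is rejected.
#'
#' @param config a \code{ctm_config}.
#' @param sensors list of sensor specs: \code{list(name =, to = <0-based
#'   addresses>, sense = function(state, tick) NULL | list(gist, weight))}.
#' @param actuators list of actuator specs: \code{list(name =, from = <0-based
#'   address>, act = function(state, gist, tick) -> new state)}.
#' @return a validated wiring list with a \code{kinds} audit field.
#' @export
attach_io <- function(config, sensors = list(), actuators = list()) {
  for (s in sensors) {
    stopifnot(is.function(s$sense), !is.null(s$name))
    if (any(s$to == "STM"))
      stop("sensors must feed LTM processors, never the short-term-memory slot directly")
    to <- as.integer(s$to)
    if (any(to < 0L | to >= config$n))
      stop("sensor ", s$name, " wired to invalid processor address")
  }
  for (a in actuators) {
    stopifnot(is.function(a$act), !is.null(a$name))
    if (identical(a$from, "STM"))
      stop("actuators must be driven by LTM processors, never by the slot directly")
    from <- as.integer(a$from)
    if (from < 0L || from >= config$n)
      stop("actuator ", a$name, " wired to invalid processor address")
  }
  kinds <- c("env_to_ltm"[length(sensors) > 0],
             "ltm_to_stm", "stm_to_ltm", "ltm_to_ltm",
             "ltm_to_env"[length(actuators) > 0])
  list(sensors = sensors, actuators = actuators, kinds = kinds)
}

#' Assemble a machine
#'
#' @param config a \code{ctm_config}.
#' @param behaviours list of \code{config$n} behaviour lists (see
#'   \code{\link{processor}}), in address order.
#' @param env_state initial environment state (any R object; \code{NULL} for
#'   a closed-box machine).
#' @param sensors,actuators input/output maps, validated by
#'   \code{\link{attach_io}}.
#' @param evaluator optional ground-truth function \code{gist -> value} used
#'   for Sleeping-Experts feedback; without it no scale updates happen.
#' @param prelinked optional list of address pairs \code{c(a, b)} whose links
#'   exist from tick 0 (strength 1).
#' @param sea_scales optional numeric vector of initial Sleeping-Experts
#'   scales per processor.
#' @return an object of class \code{ctm_machine}.
#' @export
ctm <- function(config, behaviours, env_state = NULL,
                sensors = list(), actuators = list(),
                evaluator = NULL, prelinked = list(), sea_scales = NULL) {
  if (length(behaviours) != config$n)
    stop("scenario/config mismatch: ", length(behaviours),
         " behaviours for n = ", config$n, " processors")
  io <- attach_io(config, sensors, actuators)
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$io <- io
  m$env_state <- env_state
  m$evaluator <- evaluator
  m$links <- link_graph(config$k_link, config$w_link)
  for (pr in prelinked) m$links$edges[[edge_key(pr[1L], pr[2L])]] <- 1L
  root <- rng_stream(config$master_seed)
  m$rng_env <- rng_spawn(root, 1L)[[1L]]
  m$rng_procs <- rng_spawn(root, config$n)
  n_nodes <- max(1L, as.integer(2^config$h) - 1L)
  m$rng_nodes <- rng_spawn(root, n_nodes)
  if (is.null(sea_scales)) sea_scales <- rep(1, config$n)
  m$procs <- lapply(seq_len(config$n), function(i)
    processor(i - 1L, behaviours[[i]], sea_scales[i], config))
  m$f <- competition_function(config$c)
  class(m) <- "ctm_machine"
  m
}

# flat serializable form of a chunk, fixed field order for byte-exact replay
flatten_chunk <- function(ch) {
  list(address = if (is.na(ch$address)) NULL else ch$address,
       t = ch$t,
       gist_tags = paste(ch$gist$tags, collapse = ","),
       gist_payload = ch$gist$payload,
       weight = ch$weight, intensity = ch$intensity, mood = ch$mood)
}

#' Run the machine for a number of ticks
#'
#' The clock loop of the architecture. Returns the replayable trace: the
#' totally ordered event stream (submissions, local tournament wins,
#' broadcasts, link messages, acknowledgments, environment inputs and
#' actions) that includes the machine's stream of consciousness — the
#' time-ordered broadcast chunks.
#'
#' @param machine a \code{ctm_machine}.
#' @param ticks number of ticks to run (default: the configured lifetime).
#' @param log_local_wins record a \code{local_win} event per tree node per
#'   tick (turn off for long runs).
#' @return an object of class \code{ctm_trace}.
#' @export
run_ctm <- function(machine, ticks = NULL, log_local_wins = FALSE) {
  cfg <- machine$config
  if (is.null(ticks)) ticks <- cfg$ticks
  n <- cfg$n
  h <- cfg$h
  lat_root <- if (cfg$pipelined) h else 0L   # submission tick -> slot tick
  events <- vector("list", 1024L)
  n_ev <- 0L
  push <- function(e) {
    n_ev <<- n_ev + 1L
    if (n_ev > length(events)) length(events) <<- 2L * n_ev
    events[[n_ev]] <<- e
  }
  submissions <- vector("list", ticks)   # per submission tick, list of chunks
  due_broadcast <- vector("list", ticks + 1L)  # reception tick -> chunk
  due_links <- vector("list", ticks + 1L)      # reception tick -> deliveries
  pending_acts <- list()
  inboxes <- lapply(seq_len(n), function(i)
    list(broadcast = NULL, links = list(), inputs = list()))

  for (t in seq_len(ticks) - 1L) {
    ti <- t + 1L
    # -- phase 1: sensors ---------------------------------------------------
    for (s in machine$io$sensors) {
      out <- s$sense(machine$env_state, t)
      if (!is.null(out)) {
        for (addr in as.integer(s$to)) {
          in_ch <- chunk(addr, t, out$gist, out$weight)
          inboxes[[addr + 1L]]$inputs <- c(inboxes[[addr + 1L]]$inputs, list(in_ch))
          push(list(tick = t, kind = "env_input", origin = s$name,
                    chunk = flatten_chunk(in_ch)))
        }
      }
    }
    # -- phase 2: deliveries due this tick + learning feedback --------------
    bc <- due_broadcast[[ti]]
    if (!is.null(bc)) {
      for (i in seq_len(n)) inboxes[[i]]$broadcast <- bc
      push(list(tick = t, kind = "broadcast", origin = "STM",
                stm_tick = t - 1L, chunk = flatten_chunk(bc)))
      if (!is.null(machine$evaluator)) {
        subs <- submissions[[bc$t + 1L]]
        vals <- vapply(subs, function(ch) machine$evaluator(ch$gist), numeric(1))
        bval <- machine$evaluator(bc$gist)
        for (i in seq_len(n)) {
          won <- !is.na(bc$address) &&
            subs[[i]]$address == bc$address && subs[[i]]$t == bc$t
          best_loser <- if (won && n > 1L) max(vals[-i]) else -Inf
          old <- machine$procs[[i]]$sea_scale
          sea_update(machine$procs[[i]], won, vals[i], bval, best_loser)
          if (machine$procs[[i]]$sea_scale != old)
            push(list(tick = t, kind = "state_change", origin = i - 1L,
                      what = "sea_scale", value = machine$procs[[i]]$sea_scale))
        }
      }
    }
    for (d in due_links[[ti]]) {
      inboxes[[d$to + 1L]]$links <- c(inboxes[[d$to + 1L]]$links, list(d$chunk))
      push(list(tick = t, kind = "link_msg", origin = d$from, to = d$to,
                unconscious = TRUE, chunk = flatten_chunk(d$chunk)))
    }
    # -- phase 3: processor steps and submissions ---------------------------
    cur_tick <- t
    ctx_for <- function(addr) {
      list(
        send_link = function(to, gist, weight) {
          d <- send_on_link(machine$links, addr, to,
                            chunk(addr, cur_tick, gist, weight), cur_tick)
          if (d$deliver_at < ticks)
            due_links[[d$deliver_at + 1L]] <<- c(due_links[[d$deliver_at + 1L]], list(d))
          invisible(NULL)
        },
        acknowledge = function(to) {
          record_acknowledgment(machine$links, addr, to, cur_tick)
          push(list(tick = cur_tick, kind = "ack", origin = addr, to = to))
          invisible(NULL)
        },
        act = function(actuator, gist) {
          pending_acts[[length(pending_acts) + 1L]] <<-
            list(actuator = actuator, gist = gist, from = addr)
          invisible(NULL)
        },
        links = machine$links,
        env_state = function() machine$env_state
      )
    }
    leaf <- vector("list", n)
    for (i in seq_len(n)) {
      ch <- proc_step(machine$procs[[i]], inboxes[[i]], t,
                      machine$rng_procs[[i]], ctx_for(i - 1L))
      leaf[[i]] <- ch
      push(list(tick = t, kind = "submission", origin = i - 1L,
                chunk = flatten_chunk(ch)))
      inboxes[[i]] <- list(broadcast = NULL, links = list(), inputs = list())
    }
    submissions[[ti]] <- leaf
    # -- phase 4: tournament ------------------------------------------------
    recorder <- if (log_local_wins) {
      function(level, node, w) push(list(tick = t, kind = "local_win",
                                         origin = sprintf("L%d.%d", level, node),
                                         chunk = flatten_chunk(w)))
    } else NULL
    root <- run_competition(leaf, machine$f, machine$rng_nodes, recorder)
    stm_tick <- t + lat_root
    reception <- stm_tick + 1L
    if (reception < ticks) {
      due_broadcast[[reception + 1L]] <- root
    }
    # -- phase 5: actuators -------------------------------------------------
    for (pa in pending_acts) {
      spec <- NULL
      for (a in machine$io$actuators) if (identical(a$name, pa$actuator)) spec <- a
      if (is.null(spec)) stop("unknown actuator: ", pa$actuator)
      if (spec$from != pa$from)
        stop("actuator ", pa$actuator, " may only be driven by processor ", spec$from)
      machine$env_state <- spec$act(machine$env_state, pa$gist, t)
      push(list(tick = t, kind = "env_action", origin = pa$from,
                actuator = pa$actuator,
                gist_payload = pa$gist$payload))
    }
    pending_acts <- list()
  }
  structure(list(events = events[seq_len(n_ev)],
                 config = cfg, ticks = ticks,
                 submissions = submissions),
            class = "ctm_trace")
}

#' @export
print.ctm_trace <- function(x, ...) {
  kinds <- vapply(x$events, `[[`, character(1), "kind")
  cat(sprintf("<ctm_trace: %d ticks, %d events>\n", x$ticks, length(x$events)))
  print(table(kinds))
  invisible(x)
}

#' Broadcast events of a trace
#'
#' @param trace a \code{ctm_trace}.
#' @return data frame with one row per broadcast reception: \code{tick}
#'   (reception), \code{stm_tick} (slot occupancy), the winning processor's
#'   \code{address} and submission tick \code{t}, gist fields, weight,
#'   intensity and mood — the stream of consciousness in tabular form.
#' @export
trace_broadcasts <- function(trace) {
  ev <- Filter(function(e) e$kind == "broadcast", trace$events)
  data.frame(
    tick = vapply(ev, `[[`, numeric(1), "tick"),
    stm_tick = vapply(ev, `[[`, numeric(1), "stm_tick"),
    address = vapply(ev, function(e)
      if (is.null(e$chunk$address)) NA_integer_ else as.integer(e$chunk$address),
      integer(1)),
    t = vapply(ev, function(e) as.integer(e$chunk$t), integer(1)),
    gist_tags = vapply(ev, function(e) e$chunk$gist_tags, character(1)),
    gist_payload = vapply(ev, function(e) e$chunk$gist_payload, character(1)),
    weight = vapply(ev, function(e) e$chunk$weight, numeric(1)),
    intensity = vapply(ev, function(e) e$chunk$intensity, numeric(1)),
    mood = vapply(ev, function(e) e$chunk$mood, numeric(1))
  )
}

#' Mood readout at a tick
#'
#' The machine's mood at slot tick \code{t} is the mood of the chunk occupying
#' the slot then: the sum over all processors of the moods submitted at
#' \code{t - h} (pipelined) — so mood divided by N is the average submitted
#' mood, a machine-wide optimism/pessimism readout. Both routes (broadcast
#' chunk and submission sum) are computed and cross-checked.
#'
#' @param trace a \code{ctm_trace}.
#' @param tick slot tick (must have produced a broadcast).
#' @return list of class \code{ctm_mood}: tick, mood, intensity,
#'   average_mood, submitted_mood_sum.
#' @export
mood_readout <- function(trace, tick) {
  b <- trace_broadcasts(trace)
  row <- b[b$stm_tick == tick, , drop = FALSE]
  if (!nrow(row))
    stop("no broadcast for slot tick ", tick,
         " (warm-up, or beyond the run horizon)")
  lat <- if (trace$config$pipelined) trace$config$h else 0L
  sub_t <- tick - lat
  subs <- trace$submissions[[sub_t + 1L]]
  msum <- sum(vapply(subs, `[[`, numeric(1), "mood"))
  if (abs(msum - row$mood[1L]) > 1e-9)
    stop("mood cross-check failed: broadcast mood ", row$mood[1L],
         " != submitted sum ", msum)
  structure(list(tick = tick, mood = row$mood[1L], intensity = row$intensity[1L],
                 average_mood = row$mood[1L] / trace$config$n,
                 submitted_mood_sum = msum),
            class = "ctm_mood")
}

#' @export
print.ctm_mood <- function(x, ...) {
  cat(sprintf("mood at tick %d: %.4g (avg %.4g per processor, intensity %.4g) — %s\n",
              x$tick, x$mood, x$average_mood, x$intensity,
              if (x$mood > 0) "optimism/happiness" else
                if (x$mood < 0) "pessimism/sadness" else "neutral"))
  invisible(x)
}
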