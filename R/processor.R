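# LTM processors: the autonomous modules of the architecture. Each one
# submits exactly one chunk per tick (the null chunk when it has nothing to
# say), receives every broadcast, archives a time-ordered high-level story of
# what it submitted and received, registers predictions, and calibrates the
# magnitude of the weights it emits with a Sleeping-Experts multiplicative
# rule: embolden after losing with more valuable content than the broadcast,
# hush after winning with less valuable content than some loser.

#' Create a processor
#'
#' @param address 0-based leaf index.
#' @param behaviour a list of hooks, all optional except \code{emit}:
#'   \describe{
#'     \item{emit(proc, inbox, tick, ctx)}{returns \code{NULL} (submit the
#'       null chunk) or \code{list(gist =, weight =)} for a single chunk.
#'       Returning several chunk specs is a contract violation.}
#'     \item{on_broadcast(proc, chunk, tick, ctx)}{called on reception of the
#'       global broadcast.}
#'   }
#'   The \code{ctx} argument (supplied by the machine) exposes
#'   \code{send_link}, \code{acknowledge} and \code{act}.
#' @param sea_scale initial Sleeping-Experts multiplier on emitted
#'   \code{|weight|}.
#' @param config a \code{ctm_config} (for the scale bounds and beta).
#' @return an object of class \code{ctm_processor} (mutable environment).
#' @export
processor <- function(address, behaviour, sea_scale = 1, config = machine_config()) {
  stopifnot(is.list(behaviour), is.function(behaviour$emit))
  p <- new.env(parent = emptyenv())
  p$address <- as.integer(address)
  p$behaviour <- behaviour
  p$sea_scale <- min(max(sea_scale, config$scale_min), config$scale_max)
  p$config <- config
  p$memory <- list()          # high-level story, append-only between prunes
  p$predictions <- list()     # as.character(tick) -> predicted gist
  p$state <- new.env(parent = emptyenv())  # behaviour scratch space
  class(p) <- "ctm_processor"
  p
}

# pick which received link/input chunks enter the archive: the single
# largest-|weight| one per tick (surprising ones are flagged on the entry
# afterwards by predict_and_score)
select_archived <- function(extras) {
  if (!length(extras)) return(list())
  w <- vapply(extras, function(ch) abs(ch$weight), numeric(1))
  extras[which.max(w)]
}

#' Advance a processor by one tick
#'
#' Calls the behaviour's \code{emit} hook, scales the emitted weight by the
#' processor's Sleeping-Experts factor (sign preserved), constructs the
#' submission chunk and appends the tick's archive entry (submission,
#' broadcast received, selected link/input chunks).
#'
#' @param proc a \code{ctm_processor}.
#' @param inbox list with elements \code{broadcast} (a chunk or NULL; at most
#'   one), \code{links} (list of chunks), \code{inputs} (list of chunks).
#' @param tick current tick.
#' @param rng the processor's \code{ctm_rng} stream.
#' @param ctx machine context (may be NULL outside a machine run).
#' @return the submitted \code{ctm_chunk}.
#' @export
proc_step <- function(proc, inbox, tick, rng, ctx = NULL) {
  if (length(inbox$broadcast) && inherits(inbox$broadcast, "list"))
    stop("inbox may contain at most one broadcast")
  if (!is.null(proc$behaviour$on_broadcast) && !is.null(inbox$broadcast))
    proc$behaviour$on_broadcast(proc, inbox$broadcast, tick, ctx)
  em <- proc$behaviour$emit(proc, inbox, tick, ctx)
  if (is.null(em)) {
    ch <- null_chunk(proc$address, tick)
  } else {
    if (!is.list(em) || is.null(em$gist) || is.null(em$weight) ||
        inherits(em[[1L]], "list") && length(em) > 2L)
      stop("behaviour contract violation: emit must return NULL or one list(gist, weight)")
    ch <- chunk(proc$address, tick, em$gist, em$weight * proc$sea_scale)
  }
  proc$memory[[length(proc$memory) + 1L]] <- list(
    t = tick,
    submitted = ch,
    received_broadcast = inbox$broadcast,
    selected = select_archived(c(inbox$links, inbox$inputs)),
    surprise = FALSE
  )
  ch
}

#' Sleeping-Experts scale update
#'
#' Multiplicative embolden/hush on the processor's weight-scaling factor,
#' clipped to the configured bounds:
#' \itemize{
#'   \item embolden (scale multiplied by beta) when the processor's chunk did
#'     NOT reach the short-term-memory slot but its content was more valuable
#'     than what did;
#'   \item hush (scale divided by beta) when its chunk DID reach the slot but
#'     some losing submission was more valuable;
#'   \item otherwise unchanged.
#' }
#' "Value" comes from a scenario-supplied ground-truth evaluator; the machine
#' computes the best losing value from the archived submissions of the same
#' competition.
#'
#' @param proc a \code{ctm_processor}.
#' @param won logical: did this processor's chunk get broadcast?
#' @param own_value evaluator's value of the processor's submitted gist.
#' @param broadcast_value value of the broadcast gist.
#' @param best_loser_value highest value among losing submissions (only used
#'   on the hush branch; default \code{-Inf} disables it).
#' @return the new scale, invisibly.
#' @export
sea_update <- function(proc, won, own_value, broadcast_value,
                       best_loser_value = -Inf) {
  cfg <- proc$config
  if (!won && own_value > broadcast_value) {
    proc$sea_scale <- min(cfg$scale_max, proc$sea_scale * cfg$beta_sea)
  } else if (won && own_value < best_loser_value) {
    proc$sea_scale <- max(cfg$scale_min, proc$sea_scale / cfg$beta_sea)
  }
  invisible(proc$sea_scale)
}

#' Register a prediction for a future tick
#' @param proc a \code{ctm_processor}.
#' @param tick tick the prediction is about.
#' @param predicted a \code{ctm_gist}.
#' @export
predict_register <- function(proc, tick, predicted) {
  proc$predictions[[as.character(tick)]] <- predicted
  invisible(proc)
}

#' Score a registered prediction against the observation
#'
#' Default metric is gist equality: error 0 on a match, 1 otherwise; a
#' nonzero error raises the surprise flag, and the tick's archive entry is
#' marked salient so pruning retains it. Scoring a tick with no registered
#' prediction is an error.
#'
#' @param proc a \code{ctm_processor}.
#' @param tick the tick predicted.
#' @param observed the observed \code{ctm_gist}.
#' @return list(error, surprise).
#' @export
predict_and_score <- function(proc, tick, observed) {
  key <- as.character(tick)
  predicted <- proc$predictions[[key]]
  if (is.null(predicted))
    stop("no prediction registered for tick ", tick)
  proc$predictions[[key]] <- NULL
  err <- if (gist_equal(predicted, observed)) 0 else 1
  surprise <- err > 0
  if (surprise && length(proc$memory)) {
    for (i in rev(seq_along(proc$memory))) {
      if (proc$memory[[i]]$t == tick) {
        proc$memory[[i]]$surprise <- TRUE
        break
      }
      if (proc$memory[[i]]$t < tick) break
    }
  }
  list(error = err, surprise = surprise)
}

#' Prune a processor's memory down to salient entries
#'
#' Keeps entries whose submitted \code{|weight|} reaches the threshold or
#' that are flagged surprising; order is preserved, nothing is resurrected.
#'
#' @param proc a \code{ctm_processor}.
#' @param salience_threshold non-negative threshold on \code{|weight|}.
#' @return number of retained entries, invisibly.
#' @export
prune_memory <- function(proc, salience_threshold) {
  stopifnot(salience_threshold >= 0)
  keep <- vapply(proc$memory, function(e) {
    isTRUE(e$surprise) || abs(e$submitted$weight) >= salience_threshold
  }, logical(1))
  proc$memory <- proc$memory[keep]
  invisible(length(proc$memory))
}

#' @export
print.ctm_processor <- function(x, ...) {
  cat(sprintf("<processor %d: sea_scale=%.4g, %d archived tick(s)>\n",
              x$address, x$sea_scale, length(x$memory)))
  invisible(x)
}
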