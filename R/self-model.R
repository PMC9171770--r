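# Model-of-the-World self/not-self attribution and inner-speech routing.
#
# Self-attribution implements one operational rule: when the broadcast of a
# command thought is immediately (one tick later) followed by a particular
# actuator carrying out the matching action, consistently and repeatedly,
# that actuator is tagged part of self. Entities that act but never in step
# with any command are tagged not-self; insufficient evidence leaves unknown.

#' Create a self/not-self model
#'
#' @param k_self consecutive consistent thought-to-action pairings required
#'   to tag an entity as self (default 5).
#' @return an object of class \code{ctm_self_model} (mutable environment).
#' @export
self_model <- function(k_self = 5L) {
  sm <- new.env(parent = emptyenv())
  sm$k_self <- as.integer(k_self)
  sm$consec <- list()     # entity -> consecutive consistent pairings
  sm$cooccur <- list()    # entity -> total pairings ever
  sm$seen_acting <- character(0)
  sm$tags <- list()       # entity -> "self" | "not_self" (unknown when absent)
  class(sm) <- "ctm_self_model"
  sm
}

#' Observe one command-broadcast episode
#'
#' Call once per broadcast of a command gist: \code{action_by} names the
#' entity (actuator) observed carrying out the matching action one tick
#' later, or \code{NULL} when no matching action followed (a miss, which
#' resets that command's consecutive count to its floor of zero — tags never
#' flip without new evidence, so an entity already tagged self stays self).
#' Independently, any entity observed acting is registered; entities that act
#' but never co-occur with a command are tagged not-self.
#'
#' @param sm a \code{ctm_self_model}.
#' @param command_gist the broadcast command \code{ctm_gist}.
#' @param action_by entity name that performed the matching action at the
#'   next tick, or \code{NULL} on a miss.
#' @param acted_entities character vector of all entities observed acting at
#'   that tick (for not-self bookkeeping).
#' @param tick tick of the broadcast.
#' @return the model, invisibly; query with \code{\link{self_tag}}.
#' @export
self_attribution <- function(sm, command_gist, action_by = NULL,
                             acted_entities = character(0), tick = NA) {
  for (ent in unique(c(action_by, acted_entities)))
    sm$seen_acting <- union(sm$seen_acting, ent)
  if (!is.null(action_by)) {
    sm$consec[[action_by]] <- (if (is.null(sm$consec[[action_by]])) 0L
                               else sm$consec[[action_by]]) + 1L
    sm$cooccur[[action_by]] <- (if (is.null(sm$cooccur[[action_by]])) 0L
                                else sm$cooccur[[action_by]]) + 1L
    if (sm$consec[[action_by]] >= sm$k_self)
      sm$tags[[action_by]] <- "self"
  } else {
    # command occurred with no matching action: every candidate's streak
    # breaks (floor 0)
    for (ent in names(sm$consec)) sm$consec[[ent]] <- 0L
  }
  for (ent in setdiff(sm$seen_acting, names(sm$cooccur))) {
    if (is.null(sm$tags[[ent]])) sm$tags[[ent]] <- "not_self"
  }
  invisible(sm)
}

#' Tag of an entity in the self-model
#' @param sm a \code{ctm_self_model}.
#' @param entity entity name.
#' @return \code{"self"}, \code{"not_self"} or \code{"unknown"}.
#' @export
self_tag <- function(sm, entity) {
  tag <- sm$tags[[entity]]
  if (is.null(tag)) "unknown" else tag
}

#' @export
print.ctm_self_model <- function(x, ...) {
  cat(sprintf("<self model: k_self=%d>\n", x$k_self))
  for (ent in union(names(x$tags), x$seen_acting))
    cat(sprintf("  %s: %s (%s consecutive pairings)\n", ent, self_tag(x, ent),
                if (is.null(x$consec[[ent]])) 0L else x$consec[[ent]]))
  invisible(x)
}

#' Inner-speech routing of a broadcast
#'
#' Extracts speech content from the broadcast chunk and redelivers it to the
#' processors that receive outer speech from the input map, marked as
#' inner-origin — the same pathway that makes dreamt speech sound like heard
#' speech. Chunks without a speech modality tag are not redelivered (inner
#' vision and inner sensation are the analogous pathways for other
#' modalities).
#'
#' @param bchunk the broadcast \code{ctm_chunk}.
#' @param outer_speech_recipients 0-based addresses of the outer-speech
#'   processor set.
#' @return list of deliveries \code{list(to, chunk)} where each redelivered
#'   chunk's gist carries the note \code{"inner"}; empty when no speech tag.
#' @export
inner_speech_route <- function(bchunk, outer_speech_recipients) {
  if (!("speech" %in% bchunk$gist$tags)) return(list())
  g <- bchunk$gist
  inner <- structure(list(tags = g$tags, payload = g$payload, note = "inner"),
                     class = "ctm_gist")
  lapply(as.integer(outer_speech_recipients), function(to)
    list(to = to,
         chunk = new_chunk(bchunk$address, bchunk$t, inner, bchunk$weight,
                           bchunk$intensity, bchunk$mood)))
}
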