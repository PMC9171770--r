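# Links: direct processor-to-processor channels — the architecture's
# unconscious communication. A link between A and B forms only after A has
# acknowledged B's answers as useful k_link times within a sliding window of
# w_link ticks; once formed it is bidirectional, carries any chunk with a
# one-tick latency, and its strength only ever increases (each further
# k_link acknowledgments add one unit).

#' Create an empty link graph
#'
#' @param k_link acknowledgments within the window required to form (or
#'   strengthen) a link.
#' @param w_link window length in ticks.
#' @return an object of class \code{ctm_links} (mutable environment).
#' @export
link_graph <- function(k_link = 3L, w_link = 50L) {
  lg <- new.env(parent = emptyenv())
  lg$k_link <- as.integer(k_link)
  lg$w_link <- as.integer(w_link)
  lg$edges <- list()    # "a|b" (a < b) -> integer strength
  lg$acks <- list()     # "from>to"     -> numeric vector of tick stamps
  class(lg) <- "ctm_links"
  lg
}

edge_key <- function(a, b) paste(min(a, b), max(a, b), sep = "|")

#' Record an acknowledgment of a useful exchange
#'
#' Processor \code{from} signals that a chunk received from \code{to} was
#' useful. Acknowledgment timestamps older than the window are pruned; when
#' the count within the window reaches \code{k_link}, the bidirectional edge
#' is created (strength 1) or strengthened by one, and the counted
#' acknowledgments are consumed.
#'
#' @param lg a \code{ctm_links} graph.
#' @param from,to 0-based processor addresses, \code{from != to}.
#' @param tick current tick.
#' @return the graph, invisibly; query with \code{\link{has_link}} /
#'   \code{\link{link_strength}}.
#' @export
record_acknowledgment <- function(lg, from, to, tick) {
  if (from == to) stop("a processor cannot acknowledge itself")
  key <- paste(from, to, sep = ">")
  stamps <- c(lg$acks[[key]], tick)
  stamps <- stamps[stamps > tick - lg$w_link]
  if (length(stamps) >= lg$k_link) {
    ek <- edge_key(from, to)
    lg$edges[[ek]] <- (if (is.null(lg$edges[[ek]])) 0L else lg$edges[[ek]]) + 1L
    stamps <- numeric(0)
  }
  lg$acks[[key]] <- stamps
  invisible(lg)
}

#' Does a link exist between two processors?
#' @param lg a \code{ctm_links} graph.
#' @param a,b 0-based addresses.
#' @return logical.
#' @export
has_link <- function(lg, a, b) {
  !is.null(lg$edges[[edge_key(a, b)]])
}

#' Strength of a link (0 when absent)
#' @param lg a \code{ctm_links} graph.
#' @param a,b 0-based addresses.
#' @return integer strength.
#' @export
link_strength <- function(lg, a, b) {
  s <- lg$edges[[edge_key(a, b)]]
  if (is.null(s)) 0L else s
}

#' Edge list of a link graph
#' @param lg a \code{ctm_links} graph.
#' @return data frame (from, to, strength), one row per undirected edge;
#'   writable as TSV.
#' @export
link_edges <- function(lg) {
  keys <- names(lg$edges)
  if (!length(keys)) {
    return(data.frame(from = integer(0), to = integer(0), strength = integer(0)))
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(
    from = vapply(parts, function(p) as.integer(p[1L]), integer(1)),
    to = vapply(parts, function(p) as.integer(p[2L]), integer(1)),
    strength = vapply(lg$edges, as.integer, integer(1), USE.NAMES = FALSE)
  )
}

#' Send a chunk over an existing link
#'
#' Direct unconscious transmission: the chunk goes to the recipient's link
#' inbox one tick later and never passes through the tournament or the
#' broadcast. Sending over a missing edge is an error — without a link the
#' sender must compete for the short-term-memory slot instead.
#'
#' @param lg a \code{ctm_links} graph.
#' @param from,to 0-based addresses; the edge must exist.
#' @param chunk a \code{ctm_chunk}.
#' @param tick current tick.
#' @return a delivery record: list(to, chunk, deliver_at = tick + 1,
#'   unconscious = TRUE).
#' @export
send_on_link <- function(lg, from, to, chunk, tick) {
  if (!has_link(lg, from, to))
    stop("no link between processors ", from, " and ", to,
         ": form one via repeated acknowledgments first")
  list(to = as.integer(to), from = as.integer(from), chunk = chunk,
       deliver_at = as.integer(tick) + 1L, unconscious = TRUE)
}

#' @export
print.ctm_links <- function(x, ...) {
  e <- link_edges(x)
  cat(sprintf("<link graph: %d edge(s), k=%d acks per %d-tick window>\n",
              nrow(e), x$k_link, x$w_link))
  if (nrow(e)) print.data.frame(e, row.names = FALSE)
  invisible(x)
}
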