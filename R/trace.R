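# Trace persistence and audits. One JSON object per line, fixed field order
# and full-precision numbers, so a machine re-run under the same
# configuration and master seed writes a byte-identical file.

#' Write a trace as JSON lines
#'
#' @param trace a \code{ctm_trace}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(
    format = "ctm-trace-v1", ticks = trace$ticks,
    n = trace$config$n, h = trace$config$h,
    pipelined = trace$config$pipelined,
    master_seed = trace$config$master_seed
  ), auto_unbox = TRUE, digits = NA), con)
  for (e in trace$events) {
    writeLines(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA, null = "null"), con)
  }
  invisible(path)
}

#' Read a JSON-lines trace
#'
#' @param path file written by \code{\link{write_trace}}.
#' @return list with \code{header} and \code{events} (lists of parsed
#'   events).
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1L], simplifyVector = TRUE)
  if (!identical(header$format, "ctm-trace-v1"))
    stop("not a ctm trace file: ", path)
  events <- lapply(lines[-1L], jsonlite::fromJSON, simplifyVector = TRUE)
  list(header = header, events = events)
}

#' Audit a trace against the structural invariants
#'
#' Checks, over the whole event stream: the single-slot property (at most one
#' broadcast per tick), warm-pipeline cadence (exactly one broadcast per tick
#' from the first reception onward), and the unconscious-channel property
#' (a chunk delivered over a link at some tick is never also the broadcast of
#' that tick).
#'
#' @param trace a \code{ctm_trace}.
#' @return invisibly \code{TRUE}; stops with a description on violation.
#' @export
audit_trace <- function(trace) {
  b <- trace_broadcasts(trace)
  if (anyDuplicated(b$tick))
    stop("single-slot violation: more than one broadcast in a tick")
  if (nrow(b) > 1L) {
    if (!all(diff(sort(b$tick)) == 1L))
      stop("cadence violation: a warm-pipeline tick without a broadcast")
  }
  link_ev <- Filter(function(e) e$kind == "link_msg", trace$events)
  for (e in link_ev) {
    same <- b[b$tick == e$tick, , drop = FALSE]
    if (nrow(same) &&
        same$gist_payload[1L] == e$chunk$gist_payload &&
        !is.na(same$address[1L]) &&
        identical(as.integer(same$address[1L]), as.integer(e$chunk$address)) &&
        identical(as.integer(same$t[1L]), as.integer(e$chunk$t)))
      stop("unconscious-channel violation: link delivery duplicated as broadcast")
  }
  invisible(TRUE)
}
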