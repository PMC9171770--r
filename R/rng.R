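#' Deterministic random-number streams
#'
#' Every random draw in the simulator comes from a stream object derived,
#' directly or by spawning, from one master seed. Streams are L'Ecuyer-CMRG
#' generators (via the base \pkg{parallel} stream mechanism), so a machine
#' configured with the same seed replays its trace byte-exactly: the
#' "deterministic CTM" operating mode, in which all apparent randomness is
#' pseudorandomness.
#'
#' A stream is a mutable environment holding its own generator state; drawing
#' from it never touches, and is never affected by, the session's global RNG
#' state (which is saved and restored around each draw).
#'
#' @param seed integer master seed.
#' @return an object of class \code{ctm_rng}.
#' @examples
#' r <- rng_stream(1)
#' rng_unif(r, 3)
#' @export
rng_stream <- function(seed) {
  if (length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  seed <- as.integer(seed)
  glob <- globalenv()
  old_seed <- get0(".Random.seed", envir = glob, inherits = FALSE)
  old_kind <- RNGkind()
  on.exit({
    suppressWarnings(RNGkind(old_kind[1L], old_kind[2L], old_kind[3L]))
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = glob, inherits = FALSE))
        rm(".Random.seed", envir = glob)
    } else assign(".Random.seed", old_seed, envir = glob)
  })
  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(seed)
  r <- new.env(parent = emptyenv())
  r$seed <- get(".Random.seed", envir = glob, inherits = FALSE)
  class(r) <- "ctm_rng"
  r
}

#' Spawn independent child streams
#'
#' Children are produced by the L'Ecuyer stream-advance map in a fixed order,
#' so the set of streams spawned from a given parent is reproducible. The
#' parent's own state is advanced past all children, so parent and children
#' never overlap.
#'
#' @param rng a \code{ctm_rng} stream.
#' @param n number of children.
#' @return a list of \code{n} new \code{ctm_rng} streams.
#' @export
rng_spawn <- function(rng, n = 1L) {
  stopifnot(inherits(rng, "ctm_rng"), n >= 1L)
  kids <- vector("list", n)
  s <- rng$seed
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    k <- new.env(parent = emptyenv())
    k$seed <- s
    class(k) <- "ctm_rng"
    kids[[i]] <- k
  }
  rng$seed <- parallel::nextRNGStream(s)
  kids
}

#' Draw standard uniforms from a stream
#'
#' @param rng a \code{ctm_rng} stream.
#' @param n number of draws.
#' @return numeric vector of \code{n} U(0,1) draws; the stream state advances.
#' @export
rng_unif <- function(rng, n = 1L) {
  glob <- globalenv()
  old <- get0(".Random.seed", envir = glob, inherits = FALSE)
  assign(".Random.seed", rng$seed, envir = glob)
  u <- stats::runif(n)
  rng$seed <- get(".Random.seed", envir = glob, inherits = FALSE)
  if (is.null(old)) {
    rm(".Random.seed", envir = glob)
  } else {
    assign(".Random.seed", old, envir = glob)
  }
  u
}

#' @export
print.ctm_rng <- function(x, ...) {
  cat("<ctm_rng stream (L'Ecuyer-CMRG)>\n")
  invisible(x)
}
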