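# Core message algebra: gists, chunks, competition functions, configuration.
#
# A chunk is the universal message unit of the architecture, the six-tuple
# <address, t, gist, weight, intensity, mood>. At submission intensity =
# |weight| and mood = weight; as chunks merge on their way up the tournament
# tree, intensity and mood become subtree sums while address, t, gist and
# weight stay frozen. Hence |mood| <= intensity always (triangle inequality,
# by induction over merges).

#' Modality tags a gist may carry
#' @export
GIST_TAGS <- c("speech", "vision", "tactile", "command", "query", "answer", "empty")

#' Construct a gist
#'
#' A gist is the payload of a chunk: an opaque, bounded token sequence in the
#' machine's inner language, annotated with modality tags. The simulator
#' never interprets payloads; scenarios attach meaning to them. Equality is
#' byte-wise on the canonical serialization (sorted tags plus payload), so it
#' is total and well defined.
#'
#' @param payload a single character string (the opaque token sequence).
#' @param tags character vector of modality tags, a subset of
#'   \code{\link{GIST_TAGS}}.
#' @param note optional free-text origin note (not part of equality).
#' @param size_limit maximum serialized size in bytes (default 256).
#' @return an object of class \code{ctm_gist}.
#' @examples
#' g <- gist("see ball", tags = "vision")
#' gist_equal(g, gist("see ball", tags = "vision"))
#' @export
gist <- function(payload = "", tags = "vision", note = NULL, size_limit = 256L) {
  if (!is.character(payload) || length(payload) != 1L || is.na(payload))
    stop("gist payload must be a single character string")
  tags <- sort(unique(as.character(tags)))
  bad <- setdiff(tags, GIST_TAGS)
  if (length(bad))
    stop("unknown modality tags: ", paste(bad, collapse = ", "))
  if (length(tags) == 0L) tags <- "empty"
  g <- structure(list(tags = tags, payload = payload, note = note),
                 class = "ctm_gist")
  sz <- nchar(serialize_gist(g), type = "bytes")
  if (sz > size_limit)
    stop("gist serialized size ", sz, " bytes exceeds the bound of ",
         size_limit, " bytes")
  g
}

#' The distinguished empty gist
#'
#' Broadcast while the machine holds no content (for example during the sleep
#' state): modality tag \code{"empty"}, zero-length payload.
#' @return a \code{ctm_gist}.
#' @export
gist_empty <- function() {
  structure(list(tags = "empty", payload = "", note = NULL),
            class = "ctm_gist")
}

#' Canonical serialization of a gist (tags, then payload)
#' @param g a \code{ctm_gist}.
#' @return a single string; equality of gists is equality of these strings.
#' @export
serialize_gist <- function(g) {
  paste0(paste(g$tags, collapse = ","), "|", g$payload)
}

#' Byte-wise gist equality on the canonical serialization
#' @param a,b gists.
#' @return logical.
#' @export
gist_equal <- function(a, b) {
  identical(serialize_gist(a), serialize_gist(b))
}

#' Is this the empty gist?
#' @param g a \code{ctm_gist}.
#' @return logical.
#' @export
is_empty_gist <- function(g) {
  identical(g$tags, "empty") && identical(g$payload, "")
}

#' @export
print.ctm_gist <- function(x, ...) {
  cat(sprintf("<gist [%s] %s>\n", paste(x$tags, collapse = ","),
              if (nzchar(x$payload)) dQuote(x$payload) else "(empty)"))
  invisible(x)
}

# internal fast constructor: no validation, used on hot paths
new_chunk <- function(address, t, gist, weight, intensity, mood) {
  structure(list(address = address, t = t, gist = gist, weight = weight,
                 intensity = intensity, mood = mood),
            class = "ctm_chunk")
}

#' Construct a submission chunk
#'
#' At submission (tree level 0) a chunk's intensity is \code{|weight|} and its
#' mood is \code{weight}. Address, submission tick, gist and weight are frozen
#' for the chunk's lifetime; only intensity and mood change as it merges with
#' competitors on the way up the tree.
#'
#' @param address 0-based index of the submitting processor (leaf index);
#'   \code{NA} is reserved for padding chunks.
#' @param t submission tick, a non-negative integer.
#' @param gist a \code{ctm_gist}.
#' @param weight a finite signed real: the valence the processor assigns to
#'   its gist.
#' @return an object of class \code{ctm_chunk}.
#' @examples
#' ch <- chunk(3, 0, gist("hello", tags = "speech"), weight = 2)
#' ch$intensity  # 2
#' ch$mood       # 2
#' @export
chunk <- function(address, t, gist, weight) {
  if (length(weight) != 1L || !is.numeric(weight) || !is.finite(weight))
    stop("chunk weight must be a single finite number")
  if (length(address) != 1L || (!is.na(address) && (address < 0 || address != floor(address))))
    stop("address must be a non-negative integer leaf index (or NA for padding)")
  if (length(t) != 1L || !is.finite(t) || t < 0 || t != floor(t))
    stop("t must be a non-negative integer tick")
  if (!inherits(gist, "ctm_gist")) stop("gist must be a ctm_gist")
  new_chunk(as.integer(address), as.integer(t), gist,
            as.numeric(weight), abs(as.numeric(weight)), as.numeric(weight))
}

#' The null chunk: empty gist, zero weight
#'
#' Submitted when a processor has nothing to say (every processor must submit
#' each tick) and used to pad the tree to a full power of two.
#' @param address owning processor, or \code{NA} for tree padding.
#' @param t submission tick.
#' @return a \code{ctm_chunk} with intensity 0 and mood 0.
#' @export
null_chunk <- function(address = NA_integer_, t = 0L) {
  new_chunk(as.integer(address), as.integer(t), gist_empty(), 0, 0, 0)
}

#' @export
print.ctm_chunk <- function(x, ...) {
  cat(sprintf("<chunk addr=%s t=%d w=%.4g int=%.4g mood=%.4g [%s]%s>\n",
              ifelse(is.na(x$address), "NA", x$address), x$t, x$weight,
              x$intensity, x$mood, paste(x$gist$tags, collapse = ","),
              if (nzchar(x$gist$payload)) paste0(" ", dQuote(x$gist$payload)) else ""))
  invisible(x)
}

#' Linear additive competition function
#'
#' The bundled family f(chunk) = intensity + c * mood for a coefficient
#' c in [-1, 1]. Non-negativity follows from |mood| <= intensity. Every member
#' of the family is additive: f of a merged chunk equals the sum of f over
#' its parts, because intensity and mood both merge by summation.
#'
#' @param c coefficient in \code{[-1, 1]}. \code{c = 0} scores pure intensity;
#'   positive \code{c} favours positively valenced content, negative \code{c}
#'   the reverse.
#' @return an object of class \code{ctm_cfun}.
#' @export
competition_function <- function(c = 0) {
  if (length(c) != 1L || !is.finite(c) || c < -1 || c > 1)
    stop("coefficient c must lie in [-1, 1]")
  force(c)
  structure(list(form = "linear_additive", c = c,
                 fn = function(ch) ch$intensity + c * ch$mood,
                 description = sprintf("intensity + %g * mood", c)),
            class = "ctm_cfun")
}

#' Custom competition function
#'
#' Wraps an arbitrary chunk scorer. The evaluator receives the whole chunk;
#' its result must be a finite non-negative real, checked at every call
#' (contract violation otherwise). Custom functions need not be additive —
#' non-additive ones lose the proportional-selection guarantee and the
#' leaf-permutation invariance.
#'
#' @param fn function taking a \code{ctm_chunk} and returning a scalar.
#' @param description short label used in tables and printouts.
#' @return an object of class \code{ctm_cfun}.
#' @export
custom_competition_function <- function(fn, description = "custom") {
  stopifnot(is.function(fn))
  structure(list(form = "custom", fn = fn, description = description),
            class = "ctm_cfun")
}

#' Evaluate a competition function on a chunk
#'
#' For the linear additive family tiny negative values (floating-point dust
#' at the boundary |mood| = intensity, |c| = 1) are clamped to zero; a custom
#' evaluator returning a negative or non-finite value raises a contract
#' violation.
#'
#' @param f a \code{ctm_cfun}.
#' @param chunk a \code{ctm_chunk}.
#' @return a finite non-negative scalar.
#' @export
evaluate_f <- function(f, chunk) {
  v <- f$fn(chunk)
  if (length(v) != 1L || !is.finite(v))
    stop("competition function contract violation: non-finite value")
  if (v < 0) {
    if (f$form == "linear_additive" && v > -1e-9) return(0)
    stop("competition function contract violation: negative value ", v)
  }
  as.numeric(v)
}

#' @export
print.ctm_cfun <- function(x, ...) {
  cat(sprintf("<competition function: %s (%s)>\n", x$description, x$form))
  invisible(x)
}

#' Randomized additivity check
#'
#' A competition function f is additive when f(merged(L, R)) = f(L) + f(R),
#' with the merged chunk carrying summed intensity and mood. This samples
#' random chunk pairs (including internal-node-like chunks whose mood differs
#' from their weight) and checks the identity to tolerance 1e-9: a
#' necessary-condition sampler, exact for linear forms, and it rejects
#' f = |mood| with probability approaching 1 as \code{trials} grows (any
#' opposite-sign mood pair is a witness).
#'
#' @param f a \code{ctm_cfun}.
#' @param trials number of random pairs (>= 1).
#' @param rng a \code{ctm_rng} stream.
#' @return logical: \code{TRUE} iff no sampled pair violates additivity.
#' @export
is_additive <- function(f, trials = 100L, rng = rng_stream(1L)) {
  stopifnot(trials >= 1L)
  for (i in seq_len(trials)) {
    u <- rng_unif(rng, 4L)
    int_l <- 10 * u[1L]
    int_r <- 10 * u[2L]
    mood_l <- int_l * (2 * u[3L] - 1)
    mood_r <- int_r * (2 * u[4L] - 1)
    g <- gist_empty()
    l <- new_chunk(0L, 0L, g, mood_l, int_l, mood_l)
    r <- new_chunk(1L, 0L, g, mood_r, int_r, mood_r)
    m <- new_chunk(0L, 0L, g, l$weight, int_l + int_r, mood_l + mood_r)
    if (abs(evaluate_f(f, m) - (evaluate_f(f, l) + evaluate_f(f, r))) > 1e-9)
      return(FALSE)
  }
  TRUE
}

#' Machine configuration
#'
#' Collects every scalar the architecture is parameterised by. Defaults are
#' desk-scale: the structural guarantees under test (conservation,
#' proportional selection, pipeline cadence, learning recovery) are
#' scale-free, so a machine of 16 processors exercises the same logic as one
#' of 10^7.
#'
#' @param n number of processors (leaves); padded to 2^h when not a power of
#'   two.
#' @param h tournament-tree height; default \code{ceiling(log2(n))}.
#' @param ticks default lifetime T of a run.
#' @param c coefficient of the bundled linear competition function.
#' @param b_gist gist serialized-size bound in bytes.
#' @param master_seed integer seed from which all streams derive.
#' @param k_link acknowledgments within a window needed to form/strengthen a
#'   link.
#' @param w_link acknowledgment window length in ticks.
#' @param beta_sea Sleeping-Experts multiplicative factor (> 1).
#' @param scale_min,scale_max clip bounds for the Sleeping-Experts scale,
#'   with \code{0 < scale_min <= 1 <= scale_max}.
#' @param pipelined run one tree level per tick (the faithful mode) or
#'   collapse each competition into its submission tick (debug mode).
#' @return an object of class \code{ctm_config}.
#' @export
machine_config <- function(n = 16L, h = NULL, ticks = 10000L, c = 0,
                           b_gist = 256L, master_seed = 1L,
                           k_link = 3L, w_link = 50L,
                           beta_sea = 2, scale_min = 0.01, scale_max = 100,
                           pipelined = TRUE) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (is.null(h)) h <- max(0L, as.integer(ceiling(log2(n))))
  h <- as.integer(h)
  if (2^h < n) stop("tree of height ", h, " cannot hold ", n, " leaves (2^h >= n required)")
  ticks <- as.integer(ticks)
  if (ticks < h) stop("lifetime ticks must be >= tree height h")
  if (beta_sea <= 1) stop("beta_sea must be > 1")
  if (!(scale_min > 0 && scale_min <= 1 && scale_max >= 1))
    stop("scale bounds must satisfy 0 < scale_min <= 1 <= scale_max")
  if (k_link < 1L || w_link < 1L) stop("k_link and w_link must be >= 1")
  structure(list(n = n, h = h, ticks = ticks, c = c,
                 b_gist = as.integer(b_gist),
                 master_seed = as.integer(master_seed),
                 k_link = as.integer(k_link), w_link = as.integer(w_link),
                 beta_sea = beta_sea,
                 scale_min = scale_min, scale_max = scale_max,
                 pipelined = isTRUE(pipelined)),
            class = "ctm_config")
}

#' @export
print.ctm_config <- function(x, ...) {
  cat(sprintf("CTM configuration: N=%d processors, tree height h=%d, T=%d ticks\n",
              x$n, x$h, x$ticks))
  cat(sprintf("  competition f = intensity + %g*mood; gist bound %d bytes\n",
              x$c, x$b_gist))
  cat(sprintf("  links: k=%d acks in %d ticks; SEA beta=%g, scale in [%g, %g]\n",
              x$k_link, x$w_link, x$beta_sea, x$scale_min, x$scale_max))
  cat(sprintf("  mode: %s; master seed %d\n",
              if (x$pipelined) "pipelined (one tree level per tick)" else "collapsed",
              x$master_seed))
  invisible(x)
}

#' Read a machine configuration from a YAML file
#'
#' Accepts a YAML mapping with any subset of the \code{\link{machine_config}}
#' arguments.
#' @param path file path.
#' @return a \code{ctm_config}.
#' @export
read_config_yaml <- function(path) {
  # YAML 1.1 would read the bare key "n" as a boolean; keep single-letter
  # keys as strings while still parsing true boolean values
  handlers <- list(
    "bool#yes" = function(x) if (toupper(x) %in% c("TRUE", "YES", "ON")) TRUE else x,
    "bool#no"  = function(x) if (toupper(x) %in% c("FALSE", "NO", "OFF")) FALSE else x)
  y <- yaml::read_yaml(path, handlers = handlers)
  keep <- intersect(names(y), names(formals(machine_config)))
  do.call(machine_config, y[keep])
}
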