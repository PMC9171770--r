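# The probabilistic Up-Tree competition.
#
# N submission chunks sit at the leaves of a full binary tree of height h.
# Each internal node runs a local competition between its two children: the
# coin-flip neuron picks the left child's chunk with probability
# f(L) / (f(L) + f(R)) (1/2 when both scores are zero), and the chunk that
# moves up keeps the winner's identity (address, t, gist, weight) but carries
# the SUM of the children's intensities and moods. The root chunk therefore
# aggregates the whole machine's intensity and mood while naming exactly one
# submitting processor — the conscious content of the tick.
#
# For additive f, the winner's distribution has the closed form f_i / sum f
# (proportional selection), independent of how processors are assigned to
# leaves. exact_win_probabilities() is an independent dynamic-programming
# oracle that computes the distribution for ANY competition function by
# conditioning on the winner identity on each side of every node.

pad_to_pow2 <- function(leaf_chunks) {
  n <- length(leaf_chunks)
  h <- if (n <= 1L) 0L else as.integer(ceiling(log2(n)))
  m <- as.integer(2^h)
  if (m > n) {
    t0 <- if (n) leaf_chunks[[1L]]$t else 0L
    pad <- lapply(seq_len(m - n), function(i) null_chunk(NA_integer_, t0))
    leaf_chunks <- c(leaf_chunks, pad)
  }
  leaf_chunks
}

#' The coin-flip neuron
#'
#' Takes an ordered pair of non-negative reals (a, b) and selects the first
#' with probability a / (a + b), or with probability 1/2 when a = b = 0.
#' Exactly one uniform draw is consumed per call, whatever the inputs, so
#' stream alignment is input-independent.
#'
#' @param a,b non-negative finite reals.
#' @param rng a \code{ctm_rng} stream.
#' @return \code{1L} (first selected) or \code{2L} (second).
#' @export
coin_flip_select <- function(a, b, rng) {
  if (!is.finite(a) || !is.finite(b) || a < 0 || b < 0)
    stop("coin-flip neuron contract violation: inputs must be finite and non-negative")
  s <- a + b
  p <- if (s > 0) a / s else 0.5
  if (rng_unif(rng, 1L) < p) 1L else 2L
}

# merge step shared by all competition paths: winner identity, summed
# intensity and mood
merge_winner <- function(winner, left, right) {
  new_chunk(winner$address, winner$t, winner$gist, winner$weight,
            left$intensity + right$intensity,
            left$mood + right$mood)
}

#' One local competition at a tree node
#'
#' Selects a winner between the two children's chunks by the coin-flip neuron
#' applied to their competition-function values, and returns the chunk that
#' moves into the node: the winner's address, t, gist and weight with
#' intensity and mood equal to the sums over both children.
#'
#' @param left,right child chunks (padding null chunks allowed).
#' @param f a \code{ctm_cfun}.
#' @param rng a \code{ctm_rng} stream.
#' @return the merged \code{ctm_chunk}.
#' @export
local_compete <- function(left, right, f, rng) {
  sel <- coin_flip_select(evaluate_f(f, left), evaluate_f(f, right), rng)
  merge_winner(if (sel == 1L) left else right, left, right)
}

#' Run one full tournament
#'
#' Every processor submits exactly one chunk; the list is padded with null
#' chunks to the next power of two and competitions run level by level to the
#' root. The root chunk's identity equals one submission's, and its intensity
#' (mood) is the exact sum of all submitted intensities (moods).
#'
#' @param leaf_chunks list of \code{ctm_chunk}, one per processor, in leaf
#'   order.
#' @param f a \code{ctm_cfun}.
#' @param rng a single \code{ctm_rng} used for every node, or a list of one
#'   stream per internal node (level-major order: all nodes of level 1 left to
#'   right, then level 2, ...), as used by the machine so that each tree node
#'   owns an independent stream.
#' @param on_local_win optional callback \code{function(level, node_index,
#'   winner_chunk)} invoked after each local competition (used for tracing).
#' @return the root \code{ctm_chunk}.
#' @export
run_competition <- function(leaf_chunks, f, rng, on_local_win = NULL) {
  if (!length(leaf_chunks)) stop("at least one submission is required")
  level <- pad_to_pow2(leaf_chunks)
  per_node <- is.list(rng)
  node_i <- 0L
  lev <- 0L
  while (length(level) > 1L) {
    lev <- lev + 1L
    nxt <- vector("list", length(level) %/% 2L)
    for (k in seq_along(nxt)) {
      node_i <- node_i + 1L
      r <- if (per_node) rng[[node_i]] else rng
      w <- local_compete(level[[2L * k - 1L]], level[[2L * k]], f, r)
      if (!is.null(on_local_win)) on_local_win(lev, k, w)
      nxt[[k]] <- w
    }
    level <- nxt
  }
  level[[1L]]
}

#' Exact per-leaf win probabilities (dynamic-programming oracle)
#'
#' Computes, for every leaf, the exact probability that its submission
#' reaches the root, for an arbitrary competition function. The recursion
#' exploits the structure of the merge rule: the intensity and mood of the
#' chunk at any node are fixed subtree sums regardless of which leaf's
#' identity occupies it, so the state at a node is just the distribution over
#' occupying identities together with the (possibly identity-dependent)
#' f-value of the merged chunk under each identity. Combining two children is
#' a bilinear sum over identity pairs — O(n^2) per level, exact, no
#' enumeration of win paths.
#'
#' For an additive f the result provably equals \code{f(leaf) / sum(f)}; this
#' oracle does not use that closed form and so serves as its independent
#' cross-check.
#'
#' @param leaf_chunks list of submissions in leaf order (padded internally).
#' @param f a \code{ctm_cfun}.
#' @return a data frame of class \code{ctm_win_table} with columns
#'   \code{leaf} (0-based position), \code{address}, \code{f_value} (at the
#'   leaf) and \code{probability}; probabilities sum to 1.
#' @export
exact_win_probabilities <- function(leaf_chunks, f) {
  leaves <- pad_to_pow2(leaf_chunks)
  m <- length(leaves)
  leaf_f <- vapply(leaves, function(ch) evaluate_f(f, ch), numeric(1))
  # node state: p (prob identity k occupies node), fv (f of node chunk under
  # identity k), int, mood
  states <- lapply(seq_len(m), function(k) {
    p <- numeric(m); p[k] <- 1
    fv <- numeric(m); fv[k] <- leaf_f[k]
    list(p = p, fv = fv, int = leaves[[k]]$intensity, mood = leaves[[k]]$mood)
  })
  while (length(states) > 1L) {
    nxt <- vector("list", length(states) %/% 2L)
    for (k in seq_along(nxt)) {
      L <- states[[2L * k - 1L]]
      R <- states[[2L * k]]
      int <- L$int + R$int
      mood <- L$mood + R$mood
      p <- numeric(m)
      il <- which(L$p > 0)
      ir <- which(R$p > 0)
      for (i in il) {
        for (j in ir) {
          pij <- L$p[i] * R$p[j]
          d <- L$fv[i] + R$fv[j]
          w <- if (d > 0) L$fv[i] / d else 0.5
          p[i] <- p[i] + pij * w
          p[j] <- p[j] + pij * (1 - w)
        }
      }
      fv <- numeric(m)
      for (k2 in which(p > 0)) {
        id <- leaves[[k2]]
        fv[k2] <- evaluate_f(f, new_chunk(id$address, id$t, id$gist, id$weight,
                                          int, mood))
      }
      nxt[[k]] <- list(p = p, fv = fv, int = int, mood = mood)
    }
    states <- nxt
  }
  prob <- states[[1L]]$p
  stopifnot(abs(sum(prob) - 1) < 1e-9)
  out <- data.frame(
    leaf = seq_len(m) - 1L,
    address = vapply(leaves, function(ch) as.integer(ch$address), integer(1)),
    f_value = leaf_f,
    probability = prob
  )
  class(out) <- c("ctm_win_table", "data.frame")
  attr(out, "f_description") <- f$description
  out
}

#' @export
print.ctm_win_table <- function(x, ...) {
  cat(sprintf("Up-Tree win probabilities under f = %s\n",
              attr(x, "f_description")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

# per-node f-values for identity-independent f (bundled family): returns
# list(fv = list per level of node f-value vectors) or NULL when f turns out
# to depend on the occupying identity at some node.
node_f_values <- function(leaves, f) {
  m <- length(leaves)
  h <- as.integer(log2(m))
  ints <- vapply(leaves, `[[`, numeric(1), "intensity")
  moods <- vapply(leaves, `[[`, numeric(1), "mood")
  fvals <- vector("list", h + 1L)
  fvals[[1L]] <- vapply(leaves, function(ch) evaluate_f(f, ch), numeric(1))
  # representative leaf index per node per level (first leaf of the subtree)
  first_leaf <- seq_len(m)
  for (s in seq_len(h)) {
    n_nodes <- m %/% 2L^s
    ci <- numeric(n_nodes); cm <- numeric(n_nodes)
    fv <- numeric(n_nodes)
    step <- 2L^s
    for (k in seq_len(n_nodes)) {
      lo <- (k - 1L) * step + 1L
      hi <- k * step
      ci[k] <- sum(ints[lo:hi])
      cm[k] <- sum(moods[lo:hi])
      # probe two candidate identities; if f differs, it is identity-dependent
      idx_a <- lo
      idx_b <- lo + step %/% 2L
      a <- leaves[[idx_a]]; b <- leaves[[idx_b]]
      va <- evaluate_f(f, new_chunk(a$address, a$t, a$gist, a$weight, ci[k], cm[k]))
      vb <- evaluate_f(f, new_chunk(b$address, b$t, b$gist, b$weight, ci[k], cm[k]))
      if (abs(va - vb) > 1e-12) return(NULL)
      fv[k] <- va
    }
    fvals[[s + 1L]] <- fv
  }
  fvals
}

#' Monte-Carlo tournament sampler
#'
#' Runs \code{runs} independent tournaments over the same submissions and
#' tabulates how often each leaf reaches the root. When the competition
#' function scores merged chunks independently of the occupying identity (as
#' the bundled intensity/mood family does), every node's local win
#' probability is a fixed number and the sampler vectorises over runs — one
#' uniform vector per internal node, drawn in level-major node order.
#' Otherwise it falls back to looping \code{\link{run_competition}}.
#'
#' @param leaf_chunks list of submissions in leaf order.
#' @param f a \code{ctm_cfun}.
#' @param runs number of tournaments.
#' @param rng a \code{ctm_rng} stream.
#' @return integer vector of root counts per (padded) leaf; sums to
#'   \code{runs}.
#' @export
simulate_win_counts <- function(leaf_chunks, f, runs, rng) {
  leaves <- pad_to_pow2(leaf_chunks)
  m <- length(leaves)
  fvals <- node_f_values(leaves, f)
  if (is.null(fvals)) {
    counts <- integer(m)
    for (r in seq_len(runs)) {
      root <- run_competition(leaves, f, rng)
      k <- which(vapply(leaves, function(ch)
        identical(ch$address, root$address) && identical(ch$t, root$t) &&
          identical(ch$weight, root$weight) && gist_equal(ch$gist, root$gist),
        logical(1)))[1L]
      counts[k] <- counts[k] + 1L
    }
    return(counts)
  }
  h <- as.integer(log2(m))
  win <- lapply(seq_len(m), function(k) rep.int(k, runs))
  for (s in seq_len(h)) {
    fv_child <- fvals[[s]]
    n_nodes <- m %/% 2L^s
    nxt <- vector("list", n_nodes)
    for (k in seq_len(n_nodes)) {
      a <- fv_child[2L * k - 1L]
      b <- fv_child[2L * k]
      p <- if (a + b > 0) a / (a + b) else 0.5
      u <- rng_unif(rng, runs)
      sel <- u < p
      nxt[[k]] <- ifelse(sel, win[[2L * k - 1L]], win[[2L * k]])
    }
    win <- nxt
  }
  tabulate(win[[1L]], nbins = m)
}

#' Assign processors' submissions to tree leaves under a permutation
#'
#' Position \code{p} of the returned leaf order holds the chunk of the
#' processor that \code{permutation} maps to \code{p}. For additive
#' competition functions the induced win-probability table (by address) is
#' invariant to the permutation; non-additive functions can and do break this
#' invariance.
#'
#' @param leaf_chunks list of N submissions.
#' @param permutation a bijection of \code{1..N} (1-based leaf positions).
#' @return the permuted list of chunks.
#' @export
assign_leaves <- function(leaf_chunks, permutation) {
  n <- length(leaf_chunks)
  if (length(permutation) != n || !identical(sort(as.integer(permutation)), seq_len(n)))
    stop("permutation must be a bijection of 1..", n)
  out <- vector("list", n)
  for (i in seq_len(n)) out[[permutation[i]]] <- leaf_chunks[[i]]
  out
}
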