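# Independent oracles used to cross-check the package's implementations.
# Each is deliberately written by a different route than the code it
# checks (brute force, enumeration, linear algebra) and kept small.

# All simple directed cycles of a tiny network by brute force: every node
# subset, every cyclic order (smallest element first), checked edge by
# edge against the adjacency. Returns counts by sign.
oracle_cycle_counts <- function(net) {
  n <- length(net$nodes)
  stopifnot(n <= 7)
  J <- sign(interaction_matrix(net))  # J[target, source]
  has_edge <- function(a, b) J[b, a] != 0
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  pos <- neg <- 0L
  for (k in seq_len(n)) {
    for (subset in utils::combn(n, k, simplify = FALSE)) {
      first <- subset[1]
      rest <- subset[-1]
      for (p in perms(rest)) {
        cyc <- c(first, p)
        nxt <- c(cyc[-1], cyc[1])
        if (all(J[cbind(nxt, cyc)] != 0)) {
          if (prod(J[cbind(nxt, cyc)]) > 0) pos <- pos + 1L
          else neg <- neg + 1L
        }
      }
    }
  }
  list(pfl = pos, nfl = neg)
}

# Balance check of the undirected signed (multi)graph by parity BFS:
# consistent iff nodes can be 2-coloured so activating edges join equal
# colours and inhibiting edges opposite ones.
oracle_is_balanced <- function(net) {
  e <- net$edges
  if (any(e$sign < 0 & e$source == e$target)) return(FALSE)
  e <- e[e$source != e$target, , drop = FALSE]
  colour <- setNames(rep(NA_integer_, length(net$nodes)), net$nodes)
  for (start in net$nodes) {
    if (!is.na(colour[start])) next
    colour[start] <- 1L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      inc <- which(e$source == v | e$target == v)
      for (k in inc) {
        w <- if (e$source[k] == v) e$target[k] else e$source[k]
        want <- colour[v] * sign(e$sign[k])
        if (is.na(colour[w])) {
          colour[w] <- want
          queue <- c(queue, w)
        } else if (colour[w] != want) return(FALSE)
      }
    }
  }
  TRUE
}

# Exact minimum number of sign flips to balance a tiny network: brute
# force over all flip subsets.
oracle_min_flips <- function(net) {
  m <- nrow(net$edges)
  stopifnot(m <= 10)
  for (k in 0:m) {
    for (subset in utils::combn(m, k, simplify = FALSE)) {
      flipped <- net
      flipped$edges$sign[subset] <- -flipped$edges$sign[subset]
      if (oracle_is_balanced(flipped)) return(k)
    }
  }
  m
}

# All Boolean fixed points of a tiny network by exhaustive enumeration.
oracle_fixed_points <- function(net, convention = "ising") {
  n <- length(net$nodes)
  stopifnot(n <= 12)
  states <- expand.grid(rep(list(0:1), n))
  keep <- apply(states, 1, function(s)
    is_boolean_fixed_point(as.integer(s), net, convention))
  apply(states[keep, , drop = FALSE], 1, paste, collapse = "")
}

# Absorption distribution of the asynchronous update chain from uniform
# initial states: exact transition matrix over 2^n states (one uniformly
# chosen node updated per step), advanced by repeated squaring until the
# mass on fixed points stabilizes; returns the distribution conditioned
# on absorption.
oracle_absorption <- function(net, convention = "ising", squarings = 12) {
  n <- length(net$nodes)
  stopifnot(n <= 8)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  ns <- nrow(grid)
  Tm <- matrix(0, ns, ns)
  enc <- function(bits) sum(bits * 2^(seq_len(n) - 1)) + 1
  for (s in seq_len(ns)) {
    bits <- grid[s, ]
    for (i in seq_len(n)) {
      nb <- unname(threshold_update(setNames(bits, net$nodes), net, i,
                                    convention))
      Tm[s, enc(nb)] <- Tm[s, enc(nb)] + 1 / n
    }
  }
  fixed <- which(vapply(seq_len(ns), function(s)
    is_boolean_fixed_point(as.integer(grid[s, ]), net, convention),
    logical(1)))
  for (k in seq_len(squarings)) Tm <- Tm %*% Tm  # T^(2^squarings)
  p <- rep(1 / ns, ns) %*% Tm
  mass <- p[fixed]
  names(mass) <- apply(grid[fixed, , drop = FALSE], 1, paste, collapse = "")
  mass / sum(mass)
}

random_distribution <- function(n_states, string_len = 4) {
  states <- replicate(n_states,
    paste(sample(0:1, string_len, replace = TRUE), collapse = ""))
  states <- unique(states)
  f <- runif(length(states))
  setNames(f / sum(f), states)
}
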