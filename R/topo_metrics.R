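# Simulation-free metrics of a signed topology: directed feedback-loop
# censuses, predicted frustration, influence matrix and influence-based
# loops, interconnected-PFL motifs, and sign-consistency deficit.

default_cycle_cap <- function(net, max_len) {
  if (!is.null(max_len)) return(as.integer(max_len))
  if (n_nodes(net) <= 30) NA_integer_ else 10L  # NA = uncapped
}

#' Enumerate simple directed cycles (feedback loops)
#'
#' A feedback loop is a directed path that starts and ends at the same node
#' with no repeated intermediate node. Each cycle is returned once, in
#' canonical rotation (starting at its smallest node index). Self-loops are
#' length-1 cycles. Enumeration is exhaustive DFS; for networks larger than
#' 30 nodes a default length cap of 10 is applied (override with
#' `max_len`).
#'
#' @param net a [grn].
#' @param max_len optional maximum cycle length (number of edges).
#' @return list of character vectors, each the node sequence of one cycle
#'   (length = number of edges in the loop).
#' @export
enumerate_cycles <- function(net, max_len = NULL) {
  cap <- default_cycle_cap(net, max_len)
  n <- n_nodes(net)
  idx <- seq_len(n)
  e <- net$edges
  adj <- vector("list", n)
  if (nrow(e) > 0) {
    si <- match(e$source, net$nodes); ti <- match(e$target, net$nodes)
    for (k in seq_along(si)) adj[[si[k]]] <- c(adj[[si[k]]], ti[k])
    adj <- lapply(adj, sort)
  }
  cycles <- list()
  path <- integer(n)
  on_path <- logical(n)
  dfs <- function(start, v, depth) {
    path[depth] <<- v
    on_path[v] <<- TRUE
    for (w in adj[[v]]) {
      if (w == start) {
        cycles[[length(cycles) + 1L]] <<- path[seq_len(depth)]
      } else if (w > start && !on_path[w] &&
                 (is.na(cap) || depth < cap)) {
        dfs(start, w, depth + 1L)
      }
    }
    on_path[v] <<- FALSE
  }
  for (s in idx) if (length(adj[[s]]) > 0) dfs(s, s, 1L)
  lapply(cycles, function(cy) net$nodes[cy])
}

cycle_sign <- function(cycle_nodes, sign_lookup) {
  nxt <- c(cycle_nodes[-1], cycle_nodes[1])
  prod(sign_lookup[cbind(nxt, cycle_nodes)])  # J[target, source]
}

#' Census of positive and negative feedback loops
#'
#' Counts simple directed cycles split by sign (product of edge signs:
#' positive loops have an even number of inhibitions). Weighted counts sum,
#' over the loops of each sign, a per-loop weight: the loop length (number
#' of participating edges, default) or its reciprocal.
#'
#' @param net a [grn].
#' @param max_len optional cycle-length cap (see [enumerate_cycles]).
#' @param weight_mode "length" (weight = number of edges in the loop) or
#'   "inv_length" (weight = 1/length).
#' @return list with `pfl`, `nfl`, `weighted_pfl`, `weighted_nfl`,
#'   `pfl_fraction` (NA when the network is acyclic), `by_length` (count
#'   table rows: length, sign, n) and the cap used.
#' @export
loop_census <- function(net, max_len = NULL, weight_mode = c("length",
                                                             "inv_length")) {
  weight_mode <- match.arg(weight_mode)
  cycles <- enumerate_cycles(net, max_len = max_len)
  J <- sign(interaction_matrix(net))
  signs <- vapply(cycles, cycle_sign, numeric(1), sign_lookup = J)
  lens <- lengths(cycles)
  w <- if (weight_mode == "length") lens else 1 / lens
  pfl <- sum(signs > 0); nfl <- sum(signs < 0)
  by_length <- if (length(lens) > 0)
    as.data.frame(table(length = lens, sign = signs), stringsAsFactors = FALSE)
  else data.frame(length = character(), sign = character(), Freq = integer())
  names(by_length)[3] <- "n"
  list(pfl = pfl, nfl = nfl,
       weighted_pfl = sum(w[signs > 0]), weighted_nfl = sum(w[signs < 0]),
       pfl_fraction = if (pfl + nfl > 0) pfl / (pfl + nfl) else NA_real_,
       by_length = by_length,
       max_len = default_cycle_cap(net, max_len))
}

#' Predicted frustration of a topology
#'
#' The number of short negative feedback loops: simple directed cycles of
#' length at most six edges whose sign product is negative. A purely
#' topological proxy for the dynamical frustration of the steady states a
#' network emits.
#'
#' @param net a [grn].
#' @param max_len loop-length cutoff (default 6 edges).
#' @return integer count.
#' @export
predicted_frustration <- function(net, max_len = 6) {
  loop_census(net, max_len = max_len)$nfl
}

#' Influence matrix of a signed topology
#'
#' Accumulates signed adjacency powers, each elementwise-normalized by the
#' corresponding power of the unsigned pattern matrix (the maximum
#' attainable interaction), averaged over path lengths 1..`lmax`:
#' entry (i, j) is the net path-weighted influence of node i on node j,
#' bounded in [-1, 1]. With `lmax = 1` and unit weights this is the signed
#' adjacency itself.
#'
#' @param net a [grn].
#' @param lmax path-length horizon (default 10).
#' @return object of class `influence_matrix`: list with `matrix` (N x N,
#'   source rows) and `lmax`.
#' @export
influence_matrix <- function(net, lmax = 10) {
  stopifnot(lmax >= 1)
  A <- t(interaction_matrix(net))       # (i, j) = signed weight of i -> j
  Amax <- (A != 0) * 1
  acc <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  Al <- diag(nrow(A)); Bl <- diag(nrow(A))
  for (l in seq_len(lmax)) {
    Al <- Al %*% A
    Bl <- Bl %*% Amax
    if (any(Al[Bl == 0] != 0))
      stop("internal error: nonzero signed path where pattern matrix is zero")
    ratio <- ifelse(Bl == 0, 0, Al / ifelse(Bl == 0, 1, Bl))
    acc <- acc + ratio
  }
  m <- acc / lmax
  stopifnot(all(abs(m) <= 1 + 1e-12))
  structure(list(matrix = m, lmax = as.integer(lmax)),
            class = "influence_matrix")
}

#' Loop strengths from an influence matrix
#'
#' For every unordered node pair (i, j), the product of mutual influences
#' I_ij * I_ji is the strength of the effective feedback between them:
#' positive products are effective positive loops, negative products
#' effective negative loops. Returns the summed strengths by sign.
#'
#' @param inf an [influence_matrix] (or a plain square matrix).
#' @return list with `positive_total` (>= 0) and `negative_total` (<= 0).
#' @export
influence_loop_strengths <- function(inf) {
  m <- if (inherits(inf, "influence_matrix")) inf$matrix else inf
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  p <- m * t(m)
  ut <- upper.tri(p)   # unordered pairs i < j, diagonal excluded
  vals <- p[ut]
  list(positive_total = sum(vals[vals > 0]),
       negative_total = sum(vals[vals < 0]))
}

# cycles as (node index vector, edge-key set, sign); shared by hiloops
cycle_details <- function(net, max_len = NULL) {
  cycles <- enumerate_cycles(net, max_len = max_len)
  J <- sign(interaction_matrix(net))
  lapply(cycles, function(cy) {
    nxt <- c(cy[-1], cy[1])
    list(nodes = cy, edges = edge_key(cy, nxt),
         sign = prod(J[cbind(nxt, cy)]))
  })
}

#' Census of interconnected positive-feedback-loop motifs
#'
#' Three motif families built from positive feedback loops (PFLs):
#' \describe{
#'   \item{type1}{unordered triples of distinct PFLs that all pass through
#'     at least one common node.}
#'   \item{type2}{instances of a central PFL through two nodes u and v,
#'     with u on a second PFL avoiding v and v on a third PFL avoiding u,
#'     the three loops pairwise edge-disjoint; each (central loop,
#'     unordered satellite pair) counted once.}
#'   \item{missa}{mutual-inhibition pairs (u -| v and v -| u) where u or v
#'     also carries a self-activation (`missa_mode = "strict"`, default) or
#'     lies on some other PFL (`missa_mode = "relaxed"`); each node pair
#'     counted once.}
#' }
#'
#' @param net a [grn].
#' @param max_len optional cycle-length cap for the underlying PFL list.
#' @param missa_mode "strict" or "relaxed" (see above).
#' @return list with integer counts `type1`, `type2`, `missa`.
#' @export
hiloop_census <- function(net, max_len = NULL,
                          missa_mode = c("strict", "relaxed")) {
  missa_mode <- match.arg(missa_mode)
  det <- cycle_details(net, max_len = max_len)
  pfls <- det[vapply(det, function(d) d$sign > 0, logical(1))]
  np <- length(pfls)

  type1 <- 0L
  if (np >= 3) {
    for (a in 1:(np - 2)) for (b in (a + 1):(np - 1)) {
      nab <- intersect(pfls[[a]]$nodes, pfls[[b]]$nodes)
      if (length(nab) == 0) next
      for (c_ in (b + 1):np)
        if (length(intersect(nab, pfls[[c_]]$nodes)) > 0)
          type1 <- type1 + 1L
    }
  }

  type2 <- 0L
  if (np >= 3) {
    for (c0 in seq_len(np)) {
      L0 <- pfls[[c0]]
      others <- setdiff(seq_len(np), c0)
      ok <- others[vapply(others, function(k)
        length(intersect(pfls[[k]]$edges, L0$edges)) == 0 &&
          length(intersect(pfls[[k]]$nodes, L0$nodes)) > 0, logical(1))]
      if (length(ok) < 2) next
      for (ia in seq_along(ok)[-length(ok)])
        for (ib in seq((ia + 1), length(ok))) {
          L1 <- pfls[[ok[ia]]]; L2 <- pfls[[ok[ib]]]
          if (length(intersect(L1$edges, L2$edges)) > 0) next
          us <- setdiff(intersect(L0$nodes, L1$nodes), L2$nodes)
          vs <- setdiff(intersect(L0$nodes, L2$nodes), L1$nodes)
          if (length(us) > 0 && length(vs) > 0 &&
              length(unique(c(us, vs))) >= 2)
            type2 <- type2 + 1L
        }
    }
  }

  e <- net$edges
  J <- sign(interaction_matrix(net))
  self_act <- net$nodes[diag(J) > 0]
  missa <- 0L
  if (nrow(e) > 0) {
    mi <- e[e$sign < 0 & e$source != e$target, , drop = FALSE]
    pairs <- unique(t(apply(mi[, c("source", "target")], 1, sort)))
    if (length(pairs) > 0) {
      for (r in seq_len(nrow(pairs))) {
        u <- pairs[r, 1]; v <- pairs[r, 2]
        mutual <- J[v, u] < 0 && J[u, v] < 0
        if (!mutual) next
        qual <- if (missa_mode == "strict") {
          u %in% self_act || v %in% self_act
        } else {
          pair_cycle <- sort(c(u, v))
          any(vapply(pfls, function(L)
            (u %in% L$nodes || v %in% L$nodes) &&
              !identical(sort(L$nodes), pair_cycle), logical(1)))
        }
        if (qual) missa <- missa + 1L
      }
    }
  }
  list(type1 = type1, type2 = type2, missa = missa)
}

# ---- sign-consistency deficit ("inconsistency") ----------------------------

# Undirected signed cycles of a grn, as lists of edge indices into
# net$edges plus the cycle sign. Two modes: fundamental cycle basis of a
# spanning forest (polynomial; balance decision exact), or all undirected
# simple cycles up to a length cap.
undirected_cycles <- function(net, cycle_space = c("basis",
                                                   "all_simple_capped"),
                              max_len = 10) {
  cycle_space <- match.arg(cycle_space)
  e <- net$edges
  m <- nrow(e)
  if (m == 0) return(list())
  si <- match(e$source, net$nodes); ti <- match(e$target, net$nodes)
  n <- n_nodes(net)

  if (cycle_space == "basis") {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    tree_adj <- vector("list", n)   # list of c(neighbor, edge_index)
    extra <- integer()
    for (k in seq_len(m)) {
      if (si[k] == ti[k]) { extra <- c(extra, k); next }  # self-loop
      ra <- find(si[k]); rb <- find(ti[k])
      if (ra != rb) {
        parent[ra] <- rb
        tree_adj[[si[k]]] <- c(tree_adj[[si[k]]], list(c(ti[k], k)))
        tree_adj[[ti[k]]] <- c(tree_adj[[ti[k]]], list(c(si[k], k)))
      } else extra <- c(extra, k)
    }
    tree_path <- function(a, b) {  # edge indices along unique tree path
      prev_node <- rep(NA_integer_, n); prev_edge <- rep(NA_integer_, n)
      prev_node[a] <- a
      q <- a
      while (length(q) > 0 && is.na(prev_edge[b])) {
        v <- q[1]; q <- q[-1]
        for (ne in tree_adj[[v]]) {
          w <- ne[1]
          if (is.na(prev_node[w])) {
            prev_node[w] <- v; prev_edge[w] <- ne[2]
            q <- c(q, w)
          }
        }
      }
      path <- integer()
      v <- b
      while (v != a) { path <- c(path, prev_edge[v]); v <- prev_node[v] }
      path
    }
    lapply(extra, function(k) {
      eidx <- if (si[k] == ti[k]) k else c(k, tree_path(si[k], ti[k]))
      list(edges = eidx, sign = prod(e$sign[eidx]))
    })
  } else {
    # undirected simple cycles up to max_len; multigraph-aware (a pair of
    # antiparallel directed edges yields a 2-cycle and edge choices on
    # longer cycles).
    adj <- vector("list", n)  # per node: list of c(neighbor, edge_index)
    for (k in seq_len(m)) {
      if (si[k] == ti[k]) next
      adj[[si[k]]] <- c(adj[[si[k]]], list(c(ti[k], k)))
      adj[[ti[k]]] <- c(adj[[ti[k]]], list(c(si[k], k)))
    }
    out <- list()
    for (k in seq_len(m)) if (si[k] == ti[k])
      out[[length(out) + 1L]] <- list(edges = k, sign = e$sign[k])
    seen <- character()
    path_nodes <- integer(max_len + 1)
    path_edges <- integer(max_len)
    on_path <- logical(n)
    dfs <- function(start, v, depth) {
      path_nodes[depth] <<- v
      on_path[v] <<- TRUE
      for (ne in adj[[v]]) {
        w <- ne[1]; k <- ne[2]
        if (depth > 1 && k == path_edges[depth - 1]) next
        if (w == start && depth >= 2) {
          eidx <- sort(c(path_edges[seq_len(depth - 1)], k))
          key <- paste(eidx, collapse = ",")
          if (!key %in% seen) {
            seen <<- c(seen, key)
            out[[length(out) + 1L]] <<- list(edges = eidx,
                                             sign = prod(e$sign[eidx]))
          }
        } else if (w > start && !on_path[w] && depth < max_len) {
          path_edges[depth] <<- k
          dfs(start, w, depth + 1L)
        }
      }
      on_path[v] <<- FALSE
    }
    for (s in seq_len(n)) if (length(adj[[s]]) > 0) dfs(s, s, 1L)
    out
  }
}

#' Sign-consistency deficit of a network (greedy)
#'
#' The inconsistency of a signed network is the minimum number of edge-sign
#' flips needed so that every undirected cycle carries an even number of
#' inhibitions (a balanced, conflict-free wiring). It is estimated greedily:
#' among the currently negative cycles, flip the edge shared by the most of
#' them (ties broken by disturbing the fewest positive cycles, then by edge
#' order), recomputing signs after each flip. The greedy count is an upper
#' bound on the true minimum; a network is reported consistent (value 0)
#' exactly when it is balanced.
#'
#' @param net a [grn].
#' @param cycle_space "basis" (fundamental cycles of a spanning forest;
#'   polynomial and decision-exact, default) or "all_simple_capped" (all
#'   undirected simple cycles up to `max_len` edges).
#' @param max_len cycle-length cap for the "all_simple_capped" mode.
#' @return list with `value` (flip count), `flipped_edges` (data frame of
#'   source, target), and `n_cycles` inspected.
#' @export
inconsistency <- function(net, cycle_space = c("basis", "all_simple_capped"),
                          max_len = 10) {
  cycle_space <- match.arg(cycle_space)
  cyc <- undirected_cycles(net, cycle_space, max_len)
  m <- n_edges(net)
  flips <- integer()
  if (length(cyc) > 0 && m > 0) {
    member <- matrix(FALSE, length(cyc), m)
    for (i in seq_along(cyc)) member[i, cyc[[i]]$edges] <- TRUE
    signs <- vapply(cyc, `[[`, numeric(1), "sign")
    seen <- character()
    while (any(signs < 0)) {
      key <- paste(signs, collapse = "")
      if (key %in% seen || length(flips) > 4L * m)
        stop("greedy sign-flip procedure made no progress ",
             "(pathological cycle space)")
      seen <- c(seen, key)
      neg <- signs < 0
      n_neg <- colSums(member[neg, , drop = FALSE])
      n_pos <- colSums(member[!neg, , drop = FALSE])
      # prefer flips that strictly shrink the negative-cycle count (in the
      # basis space one always exists: the defining chord of any negative
      # fundamental cycle covers it alone); fall back to the best
      # non-worsening flip and let the revisit guard stop pathologies
      cand <- which(n_neg > n_pos)
      if (length(cand) == 0) cand <- which(n_neg > 0)
      score <- n_neg[cand] - n_pos[cand]
      cand <- cand[score == max(score)]
      cand <- cand[n_pos[cand] == min(n_pos[cand])]
      pick <- cand[1]
      signs[member[, pick]] <- -signs[member[, pick]]
      flips <- c(flips, pick)
    }
  }
  list(value = length(flips),
       flipped_edges = net$edges[flips, c("source", "target"), drop = FALSE],
       n_cycles = length(cyc))
}
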