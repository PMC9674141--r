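#' Built-in analytic network fixtures
#'
#' Small signed circuits with hand-verifiable dynamics and loop structure,
#' used throughout the test-suite and examples:
#' \describe{
#'   \item{toggle}{mutual inhibition A -| B, B -| A (one positive loop).}
#'   \item{toggle_missa}{toggle plus self-activation A -> A: the canonical
#'     mutual-inhibition-single-self-activation motif.}
#'   \item{repressilator}{three-cycle of inhibitions A -| B -| C -| A (one
#'     negative loop; no stable Boolean fixed point).}
#'   \item{type1_hub}{hub node H on three mutual-activation positive loops
#'     (H <-> X1, H <-> X2, H <-> X3), the three-loops-through-one-node
#'     motif.}
#'   \item{emt_core}{a 4-node, 7-edge epithelial-mesenchymal core circuit
#'     over miR200, ZEB, GRHL2 and SNAIL: miR200 -| ZEB, ZEB -| miR200,
#'     ZEB -| GRHL2, GRHL2 -| ZEB, SNAIL -| miR200, SNAIL -> ZEB and
#'     ZEB -> ZEB, with SNAIL an input (signal) node. This is a synthetic
#'     reconstruction of the well-known miR200/ZEB/GRHL2 circuit from the
#'     EMT literature, not a transcription of any published figure.}
#' }
#'
#' @param name one of "toggle", "toggle_missa", "repressilator",
#'   "emt_core", "type1_hub".
#' @return a [grn].
#' @export
make_fixture <- function(name = c("toggle", "toggle_missa", "repressilator",
                                  "emt_core", "type1_hub")) {
  name <- match.arg(name)
  ed <- function(s, t, g) data.frame(source = s, target = t, sign = g)
  switch(name,
    toggle = grn(c("A", "B"),
                 ed(c("A", "B"), c("B", "A"), c(-1, -1)), "toggle"),
    toggle_missa = grn(c("A", "B"),
                       ed(c("A", "B", "A"), c("B", "A", "A"), c(-1, -1, 1)),
                       "toggle_missa"),
    repressilator = grn(c("A", "B", "C"),
                        ed(c("A", "B", "C"), c("B", "C", "A"), c(-1, -1, -1)),
                        "repressilator"),
    type1_hub = grn(c("H", "X1", "X2", "X3"),
                    ed(c("H", "X1", "H", "X2", "H", "X3"),
                       c("X1", "H", "X2", "H", "X3", "H"),
                       rep(1, 6)), "type1_hub"),
    emt_core = grn(c("SNAIL", "miR200", "ZEB", "GRHL2"),
                   ed(c("miR200", "ZEB", "ZEB", "GRHL2", "SNAIL", "SNAIL",
                        "ZEB"),
                      c("ZEB", "miR200", "GRHL2", "ZEB", "miR200", "ZEB",
                        "ZEB"),
                      c(-1, -1, -1, -1, -1, 1, 1)), "emt_core"))
}

#' Generate a random signed regulatory topology
#'
#' Edges are distinct ordered node pairs drawn uniformly at random; each
#' edge is inhibitory with probability `p_inhibition`. The first `n_signal`
#' nodes receive no incoming edges, emulating the upstream signal inputs of
#' curated EMT networks; placing them first keeps trimmed state strings
#' stable. Self-loops are excluded by default (curated networks carry only
#' deliberate self-activations; see [make_fixture]).
#'
#' @param n_nodes,n_edges network size.
#' @param p_inhibition probability that an edge is inhibitory.
#' @param n_signal number of input-only nodes (placed first in node order).
#' @param seed integer seed.
#' @param allow_self_loops include diagonal pairs among candidates.
#' @param name network label.
#' @return a [grn].
#' @export
generate_random_grn <- function(n_nodes, n_edges, p_inhibition = 0.5,
                                n_signal = 0, seed = NULL,
                                allow_self_loops = FALSE,
                                name = "synthetic") {
  stopifnot(n_nodes >= 1, p_inhibition >= 0, p_inhibition <= 1,
            n_signal >= 0, n_signal < n_nodes)
  nodes <- sprintf("G%02d", seq_len(n_nodes))
  src_pool <- nodes
  tgt_pool <- nodes[setdiff(seq_len(n_nodes), seq_len(n_signal))]
  pairs <- expand.grid(source = src_pool, target = tgt_pool,
                       stringsAsFactors = FALSE)
  if (!allow_self_loops) pairs <- pairs[pairs$source != pairs$target, ]
  if (n_edges > nrow(pairs))
    stop(sprintf("n_edges = %d exceeds the %d available ordered pairs",
                 n_edges, nrow(pairs)))
  with_seed(seed, {
    idx <- sample.int(nrow(pairs), n_edges)
    sgn <- ifelse(runif(n_edges) < p_inhibition, -1, 1)
    grn(nodes, data.frame(source = pairs$source[idx],
                          target = pairs$target[idx], sign = sgn),
        name = name)
  })
}

#' Generate a two-team signed topology
#'
#' Emulates the hallmark structure of epithelial-mesenchymal regulatory
#' networks: nodes split into two teams (epithelial-like and
#' mesenchymal-like), edges drawn as uniform random distinct ordered
#' pairs, activating within a team and inhibiting across teams. Such a
#' wiring is balanced — every feedback loop is positive — so it sits at
#' PFL fraction 1; [tune_loop_composition] can then flip signs toward any
#' lower target.
#'
#' @param n_nodes total node count (teams of `ceiling(n/2)` and the rest).
#' @param n_edges number of edges.
#' @param seed integer seed.
#' @param name network label.
#' @return list with `net` (a [grn]) and `anchors` (node -> "E"/"M"
#'   labels suitable for [partition_nodes] or direct use as a partition).
#' @export
generate_team_grn <- function(n_nodes, n_edges, seed = NULL,
                              name = "team") {
  stopifnot(n_nodes >= 2)
  nodes <- sprintf("G%02d", seq_len(n_nodes))
  team <- rep(c("E", "M"), c(ceiling(n_nodes / 2), floor(n_nodes / 2)))
  pairs <- expand.grid(s = seq_len(n_nodes), t = seq_len(n_nodes))
  pairs <- pairs[pairs$s != pairs$t, ]
  if (n_edges > nrow(pairs)) stop("n_edges exceeds available ordered pairs")
  with_seed(seed, {
    idx <- sample.int(nrow(pairs), n_edges)
    s <- pairs$s[idx]; t <- pairs$t[idx]
    sgn <- ifelse(team[s] == team[t], 1, -1)
    list(net = grn(nodes, data.frame(source = nodes[s], target = nodes[t],
                                     sign = sgn), name = name),
         anchors = setNames(team, nodes))
  })
}

#' Tune the positive-feedback-loop fraction of a topology
#'
#' Hill-climbs over single-edge sign flips to bring the fraction of
#' positive feedback loops (PFLs over all simple directed cycles) as close
#' as possible to `target`. A sign flip inverts the sign of every cycle
#' through that edge, so the reachable fractions form a rich set for most
#' connected topologies. The objective |fraction - target| never increases
#' across iterations; the best network found is returned.
#'
#' @param net a [grn] with at least one directed cycle.
#' @param target desired PFL fraction in [0, 1].
#' @param max_iters maximum number of accepted flips.
#' @param seed integer seed (breaks ties among equally good flips).
#' @param max_len cycle-length cap forwarded to [loop_census].
#' @return a [grn] whose PFL fraction is locally closest to `target`.
#' @export
tune_loop_composition <- function(net, target, max_iters = 50, seed = NULL,
                                  max_len = NULL) {
  stopifnot(target >= 0, target <= 1)
  cen <- loop_census(net, max_len = max_len)
  if (cen$pfl + cen$nfl == 0)
    stop("network has no directed cycles; PFL fraction undefined")
  with_seed(seed, {
    objective <- function(x) abs(loop_census(x, max_len = max_len)$pfl_fraction - target)
    best <- net
    best_obj <- objective(net)
    for (iter in seq_len(max_iters)) {
      if (best_obj == 0) break
      cand_obj <- rep(NA_real_, n_edges(best))
      for (i in seq_len(n_edges(best))) {
        cand <- best
        cand$edges$sign[i] <- -cand$edges$sign[i]
        cand_obj[i] <- objective(cand)
      }
      improving <- which(cand_obj < best_obj)
      if (length(improving) == 0) break
      pick <- improving[which.min(cand_obj[improving])]
      ties <- improving[cand_obj[improving] == cand_obj[pick]]
      pick <- if (length(ties) > 1) ties[sample.int(length(ties), 1)] else pick
      best$edges$sign[pick] <- -best$edges$sign[pick]
      best_obj <- cand_obj[pick]
    }
    best
  })
}
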