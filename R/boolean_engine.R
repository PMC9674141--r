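# Parameter-independent asynchronous threshold Boolean engine, including
# the weighted-edge variant (non-unit edge weights flow through the same
# update rule).

boolean_ising <- function(convention = c("ising", "literal01")) {
  match.arg(convention) == "ising"
}

#' Threshold update of a single node
#'
#' The node's next value is determined by the sign of the weighted sum of
#' its inputs, `sum_j J_ij s_j`: positive sets the node to 1, negative to
#' 0, and a zero sum (including the no-input case) holds the current
#' value. Under the default `ising` convention the 0/1 states enter the
#' sum as spins -1/+1 (so an inactive inhibitor pushes its target up);
#' `literal01` uses the raw 0/1 values, under which inactive regulators
#' contribute nothing.
#'
#' @param state named 0/1 vector over all nodes (or unnamed in node order).
#' @param net a [grn].
#' @param node node name or index to update.
#' @param convention "ising" (default) or "literal01".
#' @return the updated state vector.
#' @export
threshold_update <- function(state, net, node,
                             convention = c("ising", "literal01")) {
  ising <- boolean_ising(convention)
  state <- state_bits(state, net$nodes)
  if (is.character(node)) node <- match(node, net$nodes)
  J <- interaction_matrix(net)
  vals <- if (ising) 2 * state - 1 else state
  s <- sum(J[node, ] * vals)
  if (s > 0) state[node] <- 1L else if (s < 0) state[node] <- 0L
  state
}

#' Check whether a Boolean state is a fixed point
#'
#' @inheritParams threshold_update
#' @return TRUE when no single-node update changes the state.
#' @export
is_boolean_fixed_point <- function(state, net,
                                   convention = c("ising", "literal01")) {
  state <- state_bits(state, net$nodes)
  for (i in seq_len(n_nodes(net)))
    if (threshold_update(state, net, i, convention)[i] != state[i])
      return(FALSE)
  TRUE
}

#' Simulate one asynchronous Boolean trajectory
#'
#' At each time step one uniformly chosen node is updated; the run stops
#' when the state is invariant under the update of every node (a fixed
#' point) or after `max_steps` updates, in which case it is flagged
#' unconverged (cyclic attractors are not catalogued).
#'
#' @param net a [grn].
#' @param ic initial 0/1 state.
#' @param max_steps maximum number of asynchronous updates.
#' @param seed integer seed.
#' @param convention "ising" or "literal01".
#' @return list with `converged` (reached a fixed point), `state` (final
#'   named 0/1 vector) and `steps` used.
#' @export
simulate_async <- function(net, ic, max_steps = 1000, seed = NULL,
                           convention = c("ising", "literal01")) {
  ising <- boolean_ising(convention)
  ic <- state_bits(ic, net$nodes)
  ei <- edge_indices(net)
  w <- net$edges$sign * net$edges$weight
  res <- with_seed(seed,
    cpp_boolean_single(n_nodes(net), ei$src, ei$tgt, w, as.integer(ic),
                       as.integer(max_steps), ising))
  list(converged = res$converged,
       state = setNames(as.integer(res$state), net$nodes),
       steps = res$steps)
}

#' Run the asynchronous Boolean ensemble
#'
#' Simulates `n_ics` trajectories per repeat from initial states drawn
#' uniformly on \{0,1\}^N. The frequency of a fixed point is the fraction
#' of converged trajectories absorbed by it (unconverged runs are
#' excluded); repeat distributions are averaged pointwise and
#' renormalized, and signal nodes are trimmed from reported strings.
#' Every reported state is re-verified to be a true fixed point. Edge
#' weights participate in the update sum, so a weighted topology (see
#' [assign_edge_weights]) runs through the identical code path.
#'
#' @param net a [grn].
#' @param n_ics initial conditions per repeat.
#' @param max_steps update budget per trajectory.
#' @param repeats independent repeats (repeat r uses `seed + r - 1`).
#' @param seed integer seed.
#' @param convention "ising" (default) or "literal01".
#' @param signal_nodes nodes trimmed from reported state strings.
#' @return a [phenotype_distribution]; the pooled converged final states
#'   (0/1 matrix) are attached as attribute `"levels"` for correlation
#'   analyses.
#' @export
run_boolean_ensemble <- function(net, n_ics = 100000, max_steps = 1000,
                                 repeats = 3, seed = NULL,
                                 convention = c("ising", "literal01"),
                                 signal_nodes = find_signal_nodes(net)) {
  ising <- boolean_ising(convention)
  ei <- edge_indices(net)
  w <- net$edges$sign * net$edges$weight
  tables <- vector("list", repeats)
  pooled <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    rseed <- if (is.null(seed)) NULL else seed + r - 1
    res <- with_seed(rseed,
      cpp_boolean_ensemble(n_nodes(net), ei$src, ei$tgt, w,
                           as.integer(n_ics), as.integer(max_steps), ising))
    conv <- res$converged
    if (!any(conv))
      stop("no initial condition reached a fixed point")
    st <- res$states[conv, , drop = FALSE]
    colnames(st) <- net$nodes
    pooled[[r]] <- st
    full <- apply(st, 1, paste, collapse = "")
    tb <- table(full)
    tables[[r]] <- data.frame(full = names(tb),
                              freq = as.numeric(tb) / nrow(st))
  }
  full_freq <- average_state_tables(tables)
  for (s in names(full_freq))
    if (!is_boolean_fixed_point(s, net, convention))
      stop("internal error: reported state ", s, " is not a fixed point")
  dist <- build_distribution(full_freq, net$nodes, signal_nodes)
  attr(dist, "levels") <- do.call(rbind, pooled)
  dist
}
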