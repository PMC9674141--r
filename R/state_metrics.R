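# Metrics computed from steady states and their frequency distributions:
# E/M node partitioning, EMT score, hybridness, Jensen-Shannon divergence,
# the J cohesion metric, and state/network frustration.

#' Phenotype distribution over binarized steady states
#'
#' The common currency of both simulation engines: a normalized frequency
#' map over binary state strings. Reported strings are *trimmed* to the
#' non-signal nodes (inputs carry no phenotype information); the distinct
#' untrimmed states are retained alongside for frustration, which needs
#' every edge endpoint.
#'
#' @param freq named numeric vector: trimmed state string -> frequency
#'   (non-negative, summing to 1).
#' @param states data frame with columns `full` (state string over all
#'   nodes), `trimmed`, `freq` — one row per distinct full steady state.
#' @param nodes all node names in state-string order.
#' @param signal_nodes names trimmed from reported strings.
#' @return object of class `phenotype_distribution`.
#' @export
phenotype_distribution <- function(freq, states, nodes,
                                   signal_nodes = character()) {
  stopifnot(is.numeric(freq), !is.null(names(freq)))
  if (any(freq < 0) || abs(sum(freq) - 1) > 1e-9)
    stop("frequencies must be non-negative and sum to 1")
  scored <- setdiff(nodes, signal_nodes)
  if (any(nchar(names(freq)) != length(scored)))
    stop("state-string length must equal the number of non-signal nodes")
  structure(list(freq = freq, states = states, nodes = nodes,
                 signal_nodes = signal_nodes),
            class = "phenotype_distribution")
}

#' @export
print.phenotype_distribution <- function(x, ...) {
  cat(sprintf("phenotype distribution over %d states (%d nodes%s)\n",
              length(x$freq), length(x$nodes),
              if (length(x$signal_nodes))
                sprintf(", %d signal trimmed", length(x$signal_nodes))
              else ""))
  print(round(sort(x$freq, decreasing = TRUE), 4))
  invisible(x)
}

state_bits <- function(state, nodes = NULL) {
  if (is.character(state) && length(state) == 1) {
    bits <- as.integer(strsplit(state, "")[[1]])
    if (is.null(nodes)) stop("node names required for a bare state string")
    if (length(bits) != length(nodes))
      stop("state string length does not match node count")
    names(bits) <- nodes
    bits
  } else {
    if (is.null(names(state))) {
      if (is.null(nodes)) stop("unnamed state vector needs node names")
      names(state) <- nodes
    }
    state
  }
}

#' Partition nodes into epithelial and mesenchymal groups
#'
#' Hierarchically clusters the rows of a node-node correlation matrix
#' (Euclidean distance, complete linkage) and cuts the dendrogram into two
#' clusters. Cluster identity is assigned from `anchors` — any nodes of
#' known biochemical class (e.g. `c(miR200 = "E")`); without anchors the
#' cluster containing the lexicographically first node is labelled E and a
#' warning records the arbitrary choice. Hybridness itself is invariant
#' under swapping the two labels, so unanchored partitions are safe for
#' hybridness but not for reporting which states are epithelial.
#'
#' @param correlations symmetric node x node correlation matrix.
#' @param anchors optional named character vector mapping node -> "E"/"M".
#' @return object of class `node_partition`: list with `e_nodes`, `m_nodes`.
#' @export
partition_nodes <- function(correlations, anchors = NULL) {
  stopifnot(is.matrix(correlations),
            nrow(correlations) == ncol(correlations))
  if (nrow(correlations) < 2) stop("need at least 2 nodes to partition")
  if (anyNA(correlations)) {
    warning("NA correlations (constant node levels) replaced by 0")
    correlations[is.na(correlations)] <- 0
  }
  cl <- cutree(hclust(dist(correlations), method = "complete"), k = 2)
  if (min(table(cl)) == 0) stop("degenerate clustering: empty cluster")
  g1 <- names(cl)[cl == 1]; g2 <- names(cl)[cl == 2]
  e_first <- NA
  if (!is.null(anchors)) {
    votes1 <- anchors[names(anchors) %in% g1]
    votes2 <- anchors[names(anchors) %in% g2]
    e1 <- sum(votes1 == "E") + sum(votes2 == "M")
    m1 <- sum(votes1 == "M") + sum(votes2 == "E")
    if (e1 == m1)
      stop("anchors do not determine the cluster labels (tied votes)")
    e_first <- e1 > m1
  } else {
    warning("no anchors given: cluster containing the lexicographically ",
            "first node labelled E")
    e_first <- sort(c(g1, g2))[1] %in% g1
  }
  part <- if (e_first) list(e_nodes = g1, m_nodes = g2)
          else list(e_nodes = g2, m_nodes = g1)
  structure(part, class = "node_partition")
}

#' @export
print.node_partition <- function(x, ...) {
  cat("E:", paste(x$e_nodes, collapse = ", "), "\n")
  cat("M:", paste(x$m_nodes, collapse = ", "), "\n")
  invisible(x)
}

#' EMT score of a binary state
#'
#' Mean expression of the epithelial nodes minus mean expression of the
#' mesenchymal nodes, in [-1, 1]: +1 is fully epithelial, -1 fully
#' mesenchymal.
#'
#' @param state binary state — a named 0/1 vector, or a state string
#'   accompanied by `nodes`.
#' @param part a [node_partition].
#' @param nodes node names when `state` is a bare string.
#' @return numeric score in [-1, 1].
#' @export
emt_score <- function(state, part, nodes = NULL) {
  bits <- state_bits(state, nodes)
  missing <- setdiff(c(part$e_nodes, part$m_nodes), names(bits))
  if (length(missing) > 0)
    stop("state lacks partition node(s): ", paste(missing, collapse = ", "))
  mean(bits[part$e_nodes]) - mean(bits[part$m_nodes])
}

#' Classify a state as epithelial, mesenchymal or hybrid
#'
#' Hybrid when |EMT score| <= 0.5 (boundary inclusive); otherwise E for
#' positive scores and M for negative.
#'
#' @inheritParams emt_score
#' @return one of "E", "M", "hybrid".
#' @export
classify_state <- function(state, part, nodes = NULL) {
  s <- emt_score(state, part, nodes)
  if (abs(s) <= 0.5) "hybrid" else if (s > 0) "E" else "M"
}

#' Hybridness of a phenotype distribution
#'
#' The summed normalized frequency of all hybrid steady states — the
#' probability mass a network places on states co-expressing epithelial
#' and mesenchymal markers.
#'
#' @param dist a [phenotype_distribution].
#' @param part a [node_partition] over the non-signal nodes.
#' @return numeric in [0, 1].
#' @export
hybridness <- function(dist, part) {
  scored <- setdiff(dist$nodes, dist$signal_nodes)
  cls <- vapply(names(dist$freq), classify_state, character(1),
                part = part, nodes = scored)
  sum(dist$freq[cls == "hybrid"])
}

kl_div_log2 <- function(p, q) {
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / q[nz]))
}

#' Jensen-Shannon divergence between two phenotype distributions
#'
#' JSD(f1, f2) = D(f1 || M)/2 + D(f2 || M)/2 with M the pointwise mixture
#' (f1 + f2)/2 and D the Kullback-Leibler divergence in bits (log base 2),
#' so values lie in [0, 1]: 0 for identical distributions, 1 for disjoint
#' supports. Supports are aligned on the union of state strings with
#' missing states at frequency 0.
#'
#' @param f1,f2 [phenotype_distribution]s or named numeric frequency
#'   vectors.
#' @return numeric in [0, 1].
#' @export
jensen_shannon_divergence <- function(f1, f2) {
  v1 <- if (inherits(f1, "phenotype_distribution")) f1$freq else f1
  v2 <- if (inherits(f2, "phenotype_distribution")) f2$freq else f2
  if (abs(sum(v1) - 1) > 1e-6 || abs(sum(v2) - 1) > 1e-6)
    stop("inputs must be normalized frequency distributions")
  states <- union(names(v1), names(v2))
  p <- setNames(rep(0, length(states)), states)
  q <- p
  p[names(v1)] <- v1
  q[names(v2)] <- v2
  m <- (p + q) / 2
  0.5 * kl_div_log2(p, m) + 0.5 * kl_div_log2(q, m)
}

#' J metric: cohesion of node expression levels
#'
#' The sum of the strict upper triangle of the node-node correlation
#' matrix. High values mean the nodes move together across the ensemble;
#' hybrid-prone networks score low.
#'
#' @param correlations symmetric correlation matrix.
#' @return numeric.
#' @export
j_metric <- function(correlations) {
  if (!is.matrix(correlations) || nrow(correlations) != ncol(correlations))
    stop("correlation input must be a square matrix")
  sum(correlations[upper.tri(correlations)])
}

#' Frustration of a single steady state
#'
#' An edge is frustrated in a state when its sign conflicts with the spin
#' product of its endpoints: sign(J) * s_source * s_target = -1, with bits
#' mapped 0 -> -1, 1 -> +1. A self-loop's spin product is +1, so
#' self-inhibitions are always frustrated and self-activations never. The
#' state frustration is the frustrated fraction of all edges, and is
#' evaluated on the *full* state including signal nodes (their outgoing
#' edges count).
#'
#' @param state full binary state (named 0/1 vector, or string + the
#'   network's node order).
#' @param net a [grn].
#' @return numeric in [0, 1].
#' @export
state_frustration <- function(state, net) {
  bits <- state_bits(state, net$nodes)
  missing <- setdiff(unique(c(net$edges$source, net$edges$target)),
                     names(bits))
  if (length(missing) > 0)
    stop("state lacks value for node(s): ", paste(missing, collapse = ", "))
  if (n_edges(net) == 0) return(0)
  spin <- 2 * bits - 1
  frustrated <- sign(net$edges$sign) * spin[net$edges$source] *
    spin[net$edges$target] < 0
  mean(frustrated)
}

#' Network-level frustration over an ensemble of steady states
#'
#' Minimum, mean and maximum state frustration across the distinct steady
#' states a network emits. The mean is unweighted over distinct states by
#' default; `weighted = TRUE` weights each state by its frequency.
#'
#' @param dist a [phenotype_distribution] (its distinct full states are
#'   used), or a character vector of full state strings.
#' @param net a [grn].
#' @param weighted frequency-weight the mean.
#' @return list with `min`, `mean`, `max` and `per_state` (data frame of
#'   state and frustration).
#' @export
network_frustration <- function(dist, net, weighted = FALSE) {
  if (inherits(dist, "phenotype_distribution")) {
    states <- dist$states$full
    w <- dist$states$freq
  } else {
    states <- dist
    w <- rep(1, length(states))
  }
  if (length(states) == 0) stop("no steady states supplied")
  f <- vapply(states, state_frustration, numeric(1), net = net)
  list(min = min(f),
       mean = if (weighted) sum(f * w) / sum(w) else mean(f),
       max = max(f),
       per_state = data.frame(state = states, frustration = unname(f)))
}

#' Node-node correlation matrix from an ensemble of steady states
#'
#' Pearson correlations between node levels across the rows of a
#' run-by-node matrix (continuous ODE levels or 0/1 Boolean states).
#' Constant columns yield undefined correlations, which are reported as 0
#' with a warning (no co-variation evidence either way).
#'
#' @param levels numeric matrix, one row per converged run, one column per
#'   node (named).
#' @return symmetric correlation matrix.
#' @export
node_correlations <- function(levels) {
  stopifnot(is.matrix(levels), !is.null(colnames(levels)))
  cc <- suppressWarnings(cor(levels))
  if (anyNA(cc)) {
    warning("constant node level(s): undefined correlations set to 0")
    cc[is.na(cc)] <- 0
    diag(cc) <- 1
  }
  cc
}
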