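#' @useDynLib grnhybrid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif cor hclust cutree dist sd median cor.test setNames pnorm qnorm
#' @importFrom utils head combn
NULL

#' Construct a signed gene-regulatory-network topology
#'
#' A `grn` object is the container every engine and metric in this package
#' consumes: a directed graph with named nodes and signed, optionally
#' weighted, edges. Sign +1 encodes transcriptional activation, -1
#' inhibition. Weights in (0, 1] scale edge magnitude in the weighted
#' Boolean variant and the influence matrix; the default weight 1 recovers
#' the plain signed topology.
#'
#' @param nodes character vector of unique node names (order is preserved
#'   and defines state-string order).
#' @param edges data frame with columns `source`, `target`, `sign`
#'   (+1/-1) and optionally `weight` (real in (0, 1], default 1).
#' @param name label used in reports.
#' @return an object of class `grn`.
#' @examples
#' toggle <- grn(c("A", "B"),
#'               data.frame(source = c("A", "B"), target = c("B", "A"),
#'                          sign = c(-1, -1)))
#' @export
grn <- function(nodes, edges, name = "net") {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(source = character(), target = character(),
                        sign = numeric(), weight = numeric())
  } else {
    edges <- as.data.frame(edges)
    if (is.null(edges$weight)) edges$weight <- 1
    edges <- edges[, c("source", "target", "sign", "weight")]
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
  }
  rownames(edges) <- NULL
  net <- structure(list(name = name, nodes = nodes, edges = edges),
                   class = "grn")
  validate_grn(net)
  net
}

validate_grn <- function(net) {
  e <- net$edges
  if (!all(e$source %in% net$nodes) || !all(e$target %in% net$nodes))
    stop("edge endpoint not among declared nodes")
  if (!all(e$sign %in% c(-1, 1))) stop("edge sign must be +1 or -1")
  if (any(e$weight <= 0 | e$weight > 1)) stop("edge weight must lie in (0, 1]")
  if (anyDuplicated(paste(e$source, e$target, sep = "\r")))
    stop("duplicate (source, target) edge")
  invisible(net)
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("grn '%s': %d nodes, %d edges (%d activating, %d inhibiting)\n",
              x$name, length(x$nodes), nrow(x$edges),
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

n_nodes <- function(net) length(net$nodes)
n_edges <- function(net) nrow(net$edges)

edge_key <- function(src, tgt) paste(src, tgt, sep = "\r")

#' Parse a topology from RACIPE .topo text
#'
#' The .topo convention: a header line `Source Target Type` followed by
#' whitespace-delimited rows, Type 1 = activation, Type 2 = inhibition. An
#' optional fourth `Weight` column carries edge weights (absent means 1).
#' Node order is first-appearance order in the edge rows.
#'
#' @param text character: either a path to a .topo file or the file content
#'   itself (detected by the presence of newlines).
#' @param name network label; defaults to the file base name when a path is
#'   given.
#' @return a [grn] object.
#' @export
parse_topo <- function(text, name = NULL) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    if (is.null(name)) name <- sub("\\.topo$", "", basename(text))
    lines <- readLines(text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  }
  if (is.null(name)) name <- "net"
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty .topo input")
  body <- lines[-1]  # header line dropped
  nodes <- character()
  src <- tgt <- character(length(body))
  sgn <- wt <- numeric(length(body))
  seen <- character()
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "[ \t]+")[[1]]
    if (length(f) < 3 || length(f) > 4)
      stop(sprintf("malformed .topo row at line %d: '%s'", i + 1, body[i]))
    type <- suppressWarnings(as.numeric(f[3]))
    if (is.na(type) || !type %in% c(1, 2))
      stop(sprintf("unknown Type code '%s' at line %d (expected 1 or 2)",
                   f[3], i + 1))
    k <- edge_key(f[1], f[2])
    if (k %in% seen)
      stop(sprintf("duplicate edge %s->%s at line %d", f[1], f[2], i + 1))
    seen <- c(seen, k)
    src[i] <- f[1]; tgt[i] <- f[2]
    sgn[i] <- if (type == 1) 1 else -1
    wt[i] <- if (length(f) == 4) as.numeric(f[4]) else 1
    for (nd in c(f[1], f[2])) if (!nd %in% nodes) nodes <- c(nodes, nd)
  }
  grn(nodes, data.frame(source = src, target = tgt, sign = sgn, weight = wt),
      name = name)
}

#' Serialize a topology to RACIPE .topo text
#'
#' Weights are written as a fourth column only when some edge weight
#' differs from 1, keeping plain topologies byte-compatible with standard
#' .topo consumers.
#'
#' @param net a [grn].
#' @param path optional file path; when given the text is also written there.
#' @return the .topo text, invisibly when `path` is given.
#' @export
write_topo <- function(net, path = NULL) {
  validate_grn(net)
  e <- net$edges
  type <- ifelse(e$sign > 0, 1L, 2L)
  if (nrow(e) > 0 && any(e$weight != 1)) {
    rows <- sprintf("%s %s %d %.17g", e$source, e$target, type, e$weight)
    header <- "Source Target Type Weight"
  } else {
    rows <- sprintf("%s %s %d", e$source, e$target, type)
    header <- "Source Target Type"
  }
  txt <- paste(c(header, rows), collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Signed interaction matrix of a topology
#'
#' Entry (i, j) is sign x weight of the edge j -> i and 0 when the edge is
#' absent: rows index targets, columns index sources. This orientation is
#' the one the Boolean threshold update uses (row i accumulates inputs of
#' node i).
#'
#' @param net a [grn].
#' @return numeric N x N matrix with node names on both dimensions.
#' @export
interaction_matrix <- function(net) {
  n <- n_nodes(net)
  J <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  e <- net$edges
  if (nrow(e) > 0)
    J[cbind(match(e$target, net$nodes), match(e$source, net$nodes))] <-
      e$sign * e$weight
  J
}

#' Signal (input) nodes of a topology
#'
#' A signal node receives no edge from any *other* node; a node whose only
#' input is its own self-loop still counts as a signal node. Signal nodes
#' are excluded from reported phenotype state strings.
#'
#' @param net a [grn].
#' @return character vector of signal node names (possibly empty).
#' @export
find_signal_nodes <- function(net) {
  e <- net$edges
  regulated <- unique(e$target[e$source != e$target])
  setdiff(net$nodes, regulated)
}

perturbation_label <- function(src, tgt, sign, kind) {
  old_type <- if (sign > 0) 1L else 2L
  if (kind == "delete") sprintf("%s-%s_%d-0", src, tgt, old_type)
  else sprintf("%s-%s_%d-%d", src, tgt, old_type, 3L - old_type)
}

#' Enumerate all single-edge perturbations of a topology
#'
#' For each of the E edges, produce the edge-deletion variant and the
#' sign-flip variant (activation <-> inhibition): 2E perturbed networks in
#' total, in edge order with deletions first. Labels follow the
#' `SRC-TGT_origType-newType` convention (deletion encoded as new type 0).
#'
#' @param net a [grn] with at least one edge.
#' @return list of entries with fields `kind` ("delete" or "sign_flip"),
#'   `edge` (source, target), `label`, and `net` (the perturbed [grn]).
#' @export
enumerate_edge_perturbations <- function(net) {
  e <- net$edges
  if (nrow(e) < 1) stop("network has no edges to perturb")
  out <- vector("list", 2L * nrow(e))
  for (i in seq_len(nrow(e))) {
    del <- net
    del$edges <- e[-i, , drop = FALSE]
    rownames(del$edges) <- NULL
    lab <- perturbation_label(e$source[i], e$target[i], e$sign[i], "delete")
    del$name <- paste0(net$name, ":", lab)
    out[[i]] <- list(kind = "delete",
                     edge = c(source = e$source[i], target = e$target[i]),
                     label = lab, net = del)
    flip <- net
    flip$edges$sign[i] <- -e$sign[i]
    lab <- perturbation_label(e$source[i], e$target[i], e$sign[i], "sign_flip")
    flip$name <- paste0(net$name, ":", lab)
    out[[nrow(e) + i]] <- list(kind = "sign_flip",
                               edge = c(source = e$source[i],
                                        target = e$target[i]),
                               label = lab, net = flip)
  }
  out
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All seeded operations in the package route here.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Degree-preserving randomization by signed double-edge swaps
#'
#' Repeatedly picks two distinct edges (a -> b, c -> d) and rewires them to
#' (a -> d, c -> b), each edge keeping its own sign and weight. In- and
#' out-degree sequences and the global sign multiset are conserved. Swaps
#' that would create a duplicate edge or a self-loop are rejected and
#' redrawn, capped at `100 * n_swaps` attempts.
#'
#' @param net a [grn] with at least 2 edges.
#' @param n_swaps number of successful swaps to perform.
#' @param seed integer seed for reproducibility.
#' @param shuffle_signs if TRUE, additionally permute the signs across the
#'   edge list after swapping (an alternative null model; default FALSE
#'   keeps each edge's sign attached to it).
#' @return a randomized [grn].
#' @export
swap_edges_random <- function(net, n_swaps, seed = NULL,
                              shuffle_signs = FALSE) {
  if (n_edges(net) < 2) stop("need at least 2 edges to swap")
  with_seed(seed, {
    e <- net$edges
    keys <- new.env(hash = TRUE)
    for (k in edge_key(e$source, e$target)) assign(k, TRUE, envir = keys)
    done <- 0L
    attempts <- 0L
    max_attempts <- 100L * as.integer(n_swaps)
    while (done < n_swaps) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("edge-swap randomization failed to find legal swaps ",
             "(graph too rigid)")
      ij <- sample.int(nrow(e), 2L)
      i <- ij[1]; j <- ij[2]
      a <- e$source[i]; b <- e$target[i]
      c_ <- e$source[j]; d <- e$target[j]
      # proposed: a->d, c->b
      if (a == d || c_ == b) next
      k1 <- edge_key(a, d); k2 <- edge_key(c_, b)
      if (exists(k1, envir = keys, inherits = FALSE) ||
          exists(k2, envir = keys, inherits = FALSE) || k1 == k2) next
      rm(list = c(edge_key(a, b), edge_key(c_, d)), envir = keys)
      assign(k1, TRUE, envir = keys); assign(k2, TRUE, envir = keys)
      e$target[i] <- d; e$target[j] <- b
      done <- done + 1L
    }
    if (shuffle_signs) {
      perm <- sample.int(nrow(e))
      e$sign <- e$sign[perm]
      e$weight <- e$weight[perm]
    }
    net$edges <- e
    net$name <- paste0(net$name, ":rand")
    validate_grn(net)
    net
  })
}

#' Assign random magnitudes to edges
#'
#' Each edge keeps its sign and wiring but receives a weight drawn
#' uniformly on (0, 1). This is the "weighted-edge" Boolean perturbation:
#' a continuous analogue of random kinetic-parameter sampling that leaves
#' the topology untouched.
#'
#' @param net a [grn].
#' @param seed integer seed.
#' @return a [grn] with randomized weights.
#' @export
assign_edge_weights <- function(net, seed = NULL) {
  with_seed(seed, {
    m <- n_edges(net)
    if (m > 0) {
      w <- runif(m)
      w[w == 0] <- .Machine$double.eps  # open interval (0, 1)
      net$edges$weight <- w
    }
    net$name <- paste0(net$name, ":wtd")
    net
  })
}
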