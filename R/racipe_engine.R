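# Random-parameter ODE ensemble engine: shifted-Hill kinetics under
# thousands of randomly sampled kinetic parameter sets, forward-Euler
# integration from random initial conditions, steady-state collection,
# z-score binarization and multistability.

#' Shifted Hill regulation function
#'
#' `lambda + (1 - lambda) / (1 + (x / x0)^n)`: equals 1 when the regulator
#' is absent and saturates at the fold-change `lambda` — below 1 for
#' inhibition, above 1 for activation. The production rate of a target is
#' multiplied by one such term per incoming edge.
#'
#' @param x regulator level (>= 0).
#' @param x0 threshold level (> 0).
#' @param n Hill coefficient (integer >= 1).
#' @param lambda fold change.
#' @return the regulation multiplier (vectorized over `x`).
#' @examples
#' shifted_hill(0, 10, 4, 0.5)   # 1: no regulator, no effect
#' shifted_hill(10, 10, 4, 0.5)  # 0.75: half-effect at threshold
#' @export
shifted_hill <- function(x, x0, n, lambda) {
  if (any(x0 <= 0)) stop("threshold x0 must be positive")
  stopifnot(all(x >= 0), all(n >= 1))
  lambda + (1 - lambda) / (1 + (x / x0)^n)
}

#' Configuration for the ODE ensemble engine
#'
#' Sampling ranges follow the random-circuit-perturbation convention:
#' production 1-100 (concentration/time), degradation 0.1-1 (1/time),
#' inhibitory fold change 0.01-1, activating fold change 1-100, integer
#' Hill coefficients 1-6, and thresholds spanning 0.02-1.98 times the
#' median unregulated level (median production / median degradation).
#' Integration is forward Euler with step 0.1, run in `n_windows`
#' successive windows of `window_time` time units; a run converges when
#' the largest node-wise change over one window drops below `cutoff`
#' (also the tolerance for merging distinct states within a parameter
#' set).
#'
#' @param n_sets,n_ics,repeats ensemble sizes: random parameter sets,
#'   initial conditions per set, independent simulation repeats.
#' @param dt Euler step size (time units).
#' @param window_time length of one convergence-test window.
#' @param n_windows maximum number of windows per initial condition.
#' @param cutoff convergence and state-merge tolerance (concentration).
#' @param production_range,degradation_range per-node rate ranges.
#' @param lambda_inh_range,lambda_act_range fold-change ranges by edge sign.
#' @param hill_range integer Hill-coefficient range.
#' @param threshold_factor_range threshold range as multiples of the
#'   median unregulated level.
#' @param distribution "uniform" or "gaussian" (truncated, mid-range mean,
#'   range/4 standard deviation).
#' @param log2_levels log2-transform levels before z-score binarization.
#' @return a config list used by [sample_parameters] and [run_ensemble].
#' @export
ode_config <- function(n_sets = 10000, n_ics = 100, repeats = 3, dt = 0.1,
                       window_time = 50, n_windows = 20, cutoff = 1.0,
                       production_range = c(1, 100),
                       degradation_range = c(0.1, 1),
                       lambda_inh_range = c(0.01, 1),
                       lambda_act_range = c(1, 100),
                       hill_range = c(1, 6),
                       threshold_factor_range = c(0.02, 1.98),
                       distribution = c("uniform", "gaussian"),
                       log2_levels = FALSE) {
  ranges <- list(production_range, degradation_range, lambda_inh_range,
                 lambda_act_range, hill_range, threshold_factor_range)
  if (any(vapply(ranges, function(r) r[1] >= r[2], logical(1))))
    stop("invalid range: min must be below max")
  list(n_sets = n_sets, n_ics = n_ics, repeats = repeats, dt = dt,
       window_time = window_time, n_windows = n_windows, cutoff = cutoff,
       production_range = production_range,
       degradation_range = degradation_range,
       lambda_inh_range = lambda_inh_range,
       lambda_act_range = lambda_act_range, hill_range = hill_range,
       threshold_factor_range = threshold_factor_range,
       distribution = match.arg(distribution), log2_levels = log2_levels)
}

sample_range <- function(n, range, distribution) {
  if (distribution == "uniform") return(runif(n, range[1], range[2]))
  mu <- mean(range); sdv <- diff(range) / 4
  lo <- pnorm(range[1], mu, sdv); hi <- pnorm(range[2], mu, sdv)
  qnorm(runif(n, lo, hi), mu, sdv)  # truncated Gaussian
}

#' Sample a random kinetic-parameter ensemble for a topology
#'
#' Draws `n_sets` independent parameter sets: per node a production and a
#' degradation rate, per edge a fold change (below 1 for inhibitions,
#' above 1 for activations), an integer Hill coefficient and a threshold.
#'
#' @param net a [grn].
#' @param n_sets number of parameter sets.
#' @param config an [ode_config].
#' @param seed integer seed.
#' @return object of class `parameter_ensemble`: matrices `P`, `D`
#'   (sets x nodes), `lambda`, `hill`, `y0` (sets x edges).
#' @export
sample_parameters <- function(net, n_sets = NULL, config = ode_config(),
                              seed = NULL) {
  if (is.null(n_sets)) n_sets <- config$n_sets
  stopifnot(n_sets >= 1)
  n <- n_nodes(net); m <- n_edges(net)
  dist <- config$distribution
  with_seed(seed, {
    P <- matrix(sample_range(n_sets * n, config$production_range, dist),
                n_sets, n, dimnames = list(NULL, net$nodes))
    D <- matrix(sample_range(n_sets * n, config$degradation_range, dist),
                n_sets, n, dimnames = list(NULL, net$nodes))
    lambda <- y0 <- matrix(numeric(0), n_sets, m)
    hill <- matrix(integer(0), n_sets, m)
    if (m > 0) {
      lambda <- matrix(NA_real_, n_sets, m)
      inh <- net$edges$sign < 0
      if (any(inh)) {
        # inhibitory fold changes are reciprocals of activating-scale
        # draws (fold repression uniform on [1/max, 1/min]), so strong
        # repression is as likely as strong activation
        r <- sort(1 / config$lambda_inh_range)
        lambda[, inh] <- 1 / sample_range(n_sets * sum(inh), r, dist)
      }
      if (any(!inh))
        lambda[, !inh] <- sample_range(n_sets * sum(!inh),
                                       config$lambda_act_range, dist)
      hr <- config$hill_range
      hill <- if (dist == "uniform")
        matrix(sample(seq(hr[1], hr[2]), n_sets * m, replace = TRUE),
               n_sets, m)
      else
        matrix(pmin(hr[2], pmax(hr[1], round(
          sample_range(n_sets * m, hr, dist)))), n_sets, m)
      # thresholds scale with the median unregulated level of the source
      med <- median(config$production_range) /
        median(config$degradation_range)
      fr <- config$threshold_factor_range
      y0 <- matrix(sample_range(n_sets * m, fr * med, dist), n_sets, m)
    }
    structure(list(P = P, D = D, lambda = lambda, hill = hill, y0 = y0,
                   nodes = net$nodes, edges = net$edges, config = config,
                   seed = seed),
              class = "parameter_ensemble")
  })
}

#' Extract one parameter set from an ensemble
#'
#' @param params a `parameter_ensemble`.
#' @param i set index.
#' @return list of vectors `P`, `D`, `lambda`, `hill`, `y0`.
#' @export
parameter_set <- function(params, i) {
  list(P = params$P[i, ], D = params$D[i, ],
       lambda = params$lambda[i, ], hill = params$hill[i, ],
       y0 = params$y0[i, ])
}

edge_indices <- function(net) {
  list(src = match(net$edges$source, net$nodes) - 1L,
       tgt = match(net$edges$target, net$nodes) - 1L)
}

#' Integrate one circuit trajectory to steady state
#'
#' Forward-Euler integration of `dX_i/dt = P_i * prod(H_s(regulators)) -
#' D_i * X_i` (incoming shifted-Hill terms combine multiplicatively) from
#' a given initial condition. Convergence is declared when the largest
#' node-wise change over one window of `window_time` time units falls
#' below `cutoff`; levels are clipped at zero, and a non-finite trajectory
#' is reported as non-converged.
#'
#' @param net a [grn].
#' @param pset one parameter set (see [parameter_set]).
#' @param ic non-negative initial levels (named or in node order).
#' @param dt,window_time,n_windows,cutoff integration controls (defaults as
#'   in [ode_config]).
#' @return list with `converged` (flag) and `state` (named level vector).
#' @export
integrate_circuit <- function(net, pset, ic, dt = 0.1, window_time = 50,
                              n_windows = 20, cutoff = 1.0) {
  stopifnot(all(ic >= 0), length(ic) == n_nodes(net))
  ei <- edge_indices(net)
  res <- cpp_integrate_single(n_nodes(net), ei$src, ei$tgt,
                              as.numeric(pset$P), as.numeric(pset$D),
                              as.numeric(pset$lambda),
                              as.integer(pset$hill), as.numeric(pset$y0),
                              as.numeric(ic), dt,
                              as.integer(round(window_time / dt)),
                              n_windows, cutoff)
  list(converged = res$converged,
       state = setNames(res$state, net$nodes))
}

#' Run the random-parameter ODE ensemble
#'
#' For each repeat, samples a fresh parameter ensemble and integrates
#' every (parameter set, initial condition) pair; initial conditions are
#' uniform on [0, 1.5 * P/D] per node (the span of attainable unregulated
#' expression). Distinct stable states within a parameter set are merged
#' at tolerance `cutoff`. Repeats use consecutive derived seeds and are
#' combined downstream at the distribution level.
#'
#' @param net a [grn].
#' @param config an [ode_config] (ensemble sizes live here).
#' @param seed integer seed; repeat r uses `seed + r - 1`.
#' @return object of class `steady_state_ensemble`: per repeat the run
#'   table (`levels` matrix, `set`, `ic`, `converged`, per-set
#'   `distinct_counts`), plus the network and config.
#' @export
run_ensemble <- function(net, config = ode_config(), seed = NULL) {
  ei <- edge_indices(net)
  reps <- vector("list", config$repeats)
  for (r in seq_len(config$repeats)) {
    rseed <- if (is.null(seed)) NULL else seed + r - 1
    reps[[r]] <- with_seed(rseed, {
      params <- sample_parameters(net, config$n_sets, config, seed = NULL)
      res <- cpp_ode_ensemble(n_nodes(net), ei$src, ei$tgt, params$P,
                              params$D, params$lambda, params$hill,
                              params$y0, config$n_ics, config$dt,
                              as.integer(round(config$window_time /
                                               config$dt)),
                              config$n_windows, config$cutoff)
      colnames(res$levels) <- net$nodes
      list(levels = res$levels, set = res$set, ic = res$ic,
           converged = res$converged,
           distinct_counts = cpp_distinct_counts(res$levels, res$set,
                                                 res$converged,
                                                 config$n_sets,
                                                 config$cutoff))
    })
  }
  structure(list(repeats = reps, net = net, config = config, seed = seed),
            class = "steady_state_ensemble")
}

#' @export
print.steady_state_ensemble <- function(x, ...) {
  conv <- mean(unlist(lapply(x$repeats, `[[`, "converged")))
  cat(sprintf(paste0("steady-state ensemble of '%s': %d repeat(s) x %d ",
                     "sets x %d ICs, %.1f%% converged\n"),
              x$net$name, length(x$repeats), x$config$n_sets,
              x$config$n_ics, 100 * conv))
  invisible(x)
}

#' Pooled steady-state levels of converged runs
#'
#' @param ens a `steady_state_ensemble`.
#' @return numeric matrix (converged runs x nodes) pooled over repeats.
#' @export
ensemble_levels <- function(ens) {
  do.call(rbind, lapply(ens$repeats,
                        function(r) r$levels[r$converged, , drop = FALSE]))
}

# Average state-frequency tables (full-state string -> freq) over repeats:
# union support, pointwise mean, renormalized.
average_state_tables <- function(tables) {
  states <- unique(unlist(lapply(tables, function(t) t$full)))
  acc <- setNames(rep(0, length(states)), states)
  for (t in tables) acc[t$full] <- acc[t$full] + t$freq
  acc <- acc / length(tables)
  acc / sum(acc)
}

build_distribution <- function(full_freq, nodes, signal_nodes) {
  keep <- !(nodes %in% signal_nodes)
  trim <- function(s)
    paste(strsplit(s, "")[[1]][keep], collapse = "")
  trimmed <- vapply(names(full_freq), trim, character(1))
  states <- data.frame(full = names(full_freq), trimmed = trimmed,
                       freq = unname(full_freq))
  freq <- tapply(states$freq, states$trimmed, sum)
  freq <- setNames(as.numeric(freq), names(freq))
  phenotype_distribution(freq / sum(freq), states, nodes, signal_nodes)
}

#' Binarize an ODE steady-state ensemble into a phenotype distribution
#'
#' Within each repeat, every node's converged levels are z-scored over all
#' converged runs (all parameter sets pooled); positive z maps to 1,
#' otherwise 0. The frequency of a binary state is the fraction of
#' converged runs landing on it; repeat distributions are averaged
#' pointwise and renormalized. Signal nodes are trimmed from the reported
#' strings (the distinct full states are kept for frustration).
#'
#' @param ens a `steady_state_ensemble`.
#' @param signal_nodes nodes to trim (default: computed from the network).
#' @return a [phenotype_distribution].
#' @export
binarize <- function(ens, signal_nodes = find_signal_nodes(ens$net)) {
  tables <- lapply(ens$repeats, function(r) {
    lv <- r$levels[r$converged, , drop = FALSE]
    if (nrow(lv) == 0) stop("no converged runs in a repeat")
    if (ens$config$log2_levels) lv <- log2(pmax(lv, .Machine$double.xmin))
    sds <- apply(lv, 2, sd)
    if (any(sds == 0))
      stop("zero variance for node(s): ",
           paste(colnames(lv)[sds == 0], collapse = ", "))
    z <- scale(lv)
    bits <- (z > 0) + 0L
    full <- apply(bits, 1, paste, collapse = "")
    tb <- table(full)
    data.frame(full = names(tb), freq = as.numeric(tb) / nrow(lv))
  })
  build_distribution(average_state_tables(tables), ens$net$nodes,
                     signal_nodes)
}

#' Multistability of a parameter ensemble
#'
#' The fraction of parameter sets whose converged runs settle into more
#' than one distinct stable state (after merging at the convergence
#' tolerance), averaged over repeats. Parameter sets with no converged run
#' are excluded from the denominator.
#'
#' @param ens a `steady_state_ensemble`.
#' @return numeric in [0, 1].
#' @export
multistability_fraction <- function(ens) {
  fr <- vapply(ens$repeats, function(r) {
    counts <- r$distinct_counts
    if (all(counts == 0)) stop("no parameter set produced a converged run")
    mean(counts[counts > 0] > 1)
  }, numeric(1))
  mean(fr)
}
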