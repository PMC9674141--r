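# Orchestration of the perturbation, correlation and randomization
# experiments, plus a thin command-line wrapper over the package
# functions.

#' Configuration for the Boolean engine
#'
#' @param n_ics initial conditions per repeat.
#' @param max_steps asynchronous updates per trajectory.
#' @param repeats independent repeats.
#' @param convention "ising" or "literal01" (see [threshold_update]).
#' @return a config list for [simulate_grn].
#' @export
boolean_config <- function(n_ics = 100000, max_steps = 1000, repeats = 3,
                           convention = "ising") {
  list(engine = "boolean", n_ics = n_ics, max_steps = max_steps,
       repeats = repeats, convention = convention)
}

#' Simulate a topology with either engine
#'
#' Unified front end: runs the asynchronous Boolean ensemble or the
#' random-parameter ODE ensemble and returns the phenotype distribution
#' together with the node-node correlation matrix of the converged
#' steady-state levels (binary states for Boolean, continuous levels for
#' ODE) and, for the ODE engine, the multistability fraction.
#'
#' @param net a [grn].
#' @param engine "boolean" or "ode".
#' @param config a [boolean_config] or [ode_config]; engine defaults used
#'   when NULL.
#' @param seed integer seed.
#' @param signal_nodes nodes trimmed from reported state strings; defaults
#'   to the network's own signal nodes, but a perturbation sweep passes
#'   the wild-type set so that all variants share one state space.
#' @return list with `distribution` ([phenotype_distribution]),
#'   `correlations` (all nodes), `multistability` (NA for Boolean) and
#'   `engine`.
#' @export
simulate_grn <- function(net, engine = c("boolean", "ode"), config = NULL,
                         seed = NULL,
                         signal_nodes = find_signal_nodes(net)) {
  engine <- match.arg(engine)
  if (engine == "boolean") {
    if (is.null(config)) config <- boolean_config()
    dist <- run_boolean_ensemble(net, n_ics = config$n_ics,
                                 max_steps = config$max_steps,
                                 repeats = config$repeats, seed = seed,
                                 convention = config$convention,
                                 signal_nodes = signal_nodes)
    levels <- attr(dist, "levels")
    list(distribution = dist, correlations = node_correlations(levels),
         multistability = NA_real_, engine = engine)
  } else {
    if (is.null(config)) config <- ode_config()
    ens <- run_ensemble(net, config = config, seed = seed)
    list(distribution = binarize(ens, signal_nodes = signal_nodes),
         correlations = node_correlations(ensemble_levels(ens)),
         multistability = multistability_fraction(ens), engine = engine)
  }
}

#' All simulation-free topology metrics of a network
#'
#' @param net a [grn].
#' @param max_len cycle-length cap forwarded to the loop-based metrics.
#' @param lmax influence-matrix path horizon.
#' @return named list: pfl, nfl, weighted_pfl, weighted_nfl, pfl_fraction,
#'   predicted_frustration, influence_pos, influence_neg, type1, type2,
#'   missa, inconsistency.
#' @export
topology_metrics <- function(net, max_len = NULL, lmax = 10) {
  cen <- loop_census(net, max_len = max_len)
  inf <- influence_loop_strengths(influence_matrix(net, lmax = lmax))
  hi <- hiloop_census(net, max_len = max_len)
  list(pfl = cen$pfl, nfl = cen$nfl, weighted_pfl = cen$weighted_pfl,
       weighted_nfl = cen$weighted_nfl, pfl_fraction = cen$pfl_fraction,
       predicted_frustration = predicted_frustration(net),
       influence_pos = inf$positive_total,
       influence_neg = inf$negative_total,
       type1 = hi$type1, type2 = hi$type2, missa = hi$missa,
       inconsistency = inconsistency(net)$value)
}

sweep_row <- function(label, engine) {
  data.frame(label = label, engine = engine, ok = NA, hybridness = NA_real_,
             jsd_vs_wt = NA_real_, j_metric = NA_real_,
             multistability = NA_real_, frustration_min = NA_real_,
             frustration_mean = NA_real_, frustration_max = NA_real_,
             predicted_frustration = NA_real_, pfl = NA_real_,
             nfl = NA_real_, weighted_pfl = NA_real_,
             weighted_nfl = NA_real_, pfl_fraction = NA_real_,
             influence_pos = NA_real_, influence_neg = NA_real_,
             type1 = NA_real_, type2 = NA_real_, missa = NA_real_,
             inconsistency = NA_real_)
}

#' Single-edge perturbation sweep
#'
#' Simulates the wild-type network and all 2E single-edge perturbations
#' (one deletion and one sign flip per edge) with the chosen engine, and
#' assembles one metrics row per variant: hybridness, divergence from the
#' wild-type distribution, cohesion, multistability (ODE engine),
#' frustration statistics and all topology metrics. The E/M node
#' partition is clustered once on the wild-type correlations and reused
#' for every variant, and all variants report states over the wild-type
#' non-signal nodes, so scores and divergences are comparable. A variant
#' whose simulation fails is kept as a row with `ok = FALSE`.
#'
#' @param net the wild-type [grn].
#' @param engine "boolean" or "ode".
#' @param config engine config ([boolean_config] or [ode_config]).
#' @param seed integer seed (same seed used for every variant).
#' @param anchors optional node -> "E"/"M" labels for [partition_nodes].
#' @param max_len cycle-length cap for loop metrics.
#' @return data frame of class `metrics_table`, wild-type row first; the
#'   wild-type [node_partition] is attached as attribute `"partition"`.
#' @export
perturbation_sweep <- function(net, engine = c("boolean", "ode"),
                               config = NULL, seed = NULL, anchors = NULL,
                               max_len = NULL) {
  engine <- match.arg(engine)
  wt_signal <- find_signal_nodes(net)
  wt <- simulate_grn(net, engine, config, seed, signal_nodes = wt_signal)
  scored <- setdiff(net$nodes, wt_signal)
  part <- partition_nodes(wt$correlations[scored, scored, drop = FALSE],
                          anchors = anchors)
  variants <- c(list(list(label = "WT", net = net)),
                enumerate_edge_perturbations(net))
  rows <- vector("list", length(variants))
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    row <- sweep_row(v$label, engine)
    sim <- if (v$label == "WT") wt else
      tryCatch(simulate_grn(v$net, engine, config, seed,
                            signal_nodes = wt_signal),
               error = function(e) e)
    if (inherits(sim, "error")) {
      row$ok <- FALSE
    } else {
      row$ok <- TRUE
      row$hybridness <- hybridness(sim$distribution, part)
      row$jsd_vs_wt <- jensen_shannon_divergence(wt$distribution,
                                                 sim$distribution)
      row$j_metric <- j_metric(sim$correlations)
      row$multistability <- sim$multistability
      fr <- network_frustration(sim$distribution, v$net)
      row$frustration_min <- fr$min
      row$frustration_mean <- fr$mean
      row$frustration_max <- fr$max
    }
    tm <- topology_metrics(v$net, max_len = max_len)
    row[names(tm)] <- unlist(tm)
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metrics_table", class(out))
  attr(out, "partition") <- part
  out
}

#' Spearman correlations of metrics against hybridness
#'
#' For every metric column of a sweep table, the Spearman rank correlation
#' with hybridness over the successfully simulated rows, with a two-sided
#' p-value (average ranks under ties) and a significance flag at p < 0.05.
#' Constant columns have undefined rank correlation and are reported with
#' `rho = NA` rather than 0.
#'
#' @param table a `metrics_table` from [perturbation_sweep] (>= 3 rows).
#' @return data frame: metric, rho, p_value, n, significant.
#' @export
correlation_report <- function(table) {
  tab <- table[!is.na(table$ok) & table$ok, , drop = FALSE]
  if (nrow(tab) < 3) stop("need at least 3 simulated rows")
  metrics <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))],
                     "hybridness")
  rows <- lapply(metrics, function(m) {
    x <- tab[[m]]; y <- tab$hybridness
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < 3 || length(unique(x[keep])) < 2 ||
        length(unique(y[keep])) < 2)
      return(data.frame(metric = m, rho = NA_real_, p_value = NA_real_,
                        n = sum(keep), significant = NA))
    ct <- suppressWarnings(cor.test(x[keep], y[keep], method = "spearman",
                                    exact = FALSE))
    data.frame(metric = m, rho = unname(ct$estimate),
               p_value = ct$p.value, n = sum(keep),
               significant = ct$p.value < 0.05)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentile of the wild-type metric among randomized networks
#'
#' Generates degree-preserving randomizations of the network (signed
#' double-edge swaps) and places the wild-type value of a topology metric
#' in their distribution: `100 * (#randoms below WT + 0.5 * #ties) /
#' n_random`.
#'
#' @param net a [grn].
#' @param metric name of a [topology_metrics] entry (e.g. "pfl",
#'   "inconsistency", "type1").
#' @param n_random number of randomized networks.
#' @param n_swaps swaps per randomization (default: one per edge).
#' @param seed integer seed.
#' @param max_len cycle-length cap for loop metrics.
#' @return percentile in [0, 100].
#' @export
randomization_percentile <- function(net, metric, n_random = 100,
                                     n_swaps = NULL, seed = NULL,
                                     max_len = NULL) {
  if (is.null(n_swaps)) n_swaps <- n_edges(net)
  wt_val <- topology_metrics(net, max_len = max_len)[[metric]]
  if (is.null(wt_val)) stop("unknown metric: ", metric)
  with_seed(seed, {
    vals <- rep(NA_real_, n_random)
    for (i in seq_len(n_random)) {
      vals[i] <- tryCatch({
        rnd <- swap_edges_random(net, n_swaps, seed = NULL)
        topology_metrics(rnd, max_len = max_len)[[metric]]
      }, error = function(e) NA_real_)
    }
    if (mean(is.na(vals)) > 0.1)
      stop("metric failed on more than 10% of randomized networks")
    vals <- vals[!is.na(vals)]
    100 * (sum(vals < wt_val) + 0.5 * sum(vals == wt_val)) / length(vals)
  })
}

#' Synthetic directionality experiment
#'
#' Does loop composition drive hybridness on networks where the ground
#' truth is controlled? Generates two-team topologies (see
#' [generate_team_grn]), tunes each toward a target PFL fraction spread
#' over [0, 1], simulates each with the Boolean engine, and records the
#' realized PFL fraction, hybridness (scored against the built-in team
#' partition) and mean steady-state frustration. Networks tuned so far
#' toward negative loops that no Boolean fixed point survives are
#' dropped (their phenotype distribution is undefined).
#'
#' @param n_networks number of tuned networks to attempt.
#' @param n_nodes,n_edges size of each synthetic network.
#' @param n_ics Boolean initial conditions per network.
#' @param seed integer master seed.
#' @return list with `table` (one row per simulated network: pfl_fraction,
#'   hybridness, frustration_mean) and `correlations` (Spearman rho and p
#'   for pfl_fraction vs hybridness and frustration_mean vs hybridness).
#' @export
directionality_experiment <- function(n_networks = 40, n_nodes = 8,
                                      n_edges = 16, n_ics = 5000,
                                      seed = 1) {
  targets <- rep_len(seq(0, 1, length.out = 10), n_networks)
  rows <- vector("list", n_networks)
  for (i in seq_len(n_networks)) {
    sd <- seed * 1000 + i
    g <- generate_team_grn(n_nodes, n_edges, seed = sd)
    net <- tryCatch(tune_loop_composition(g$net, targets[i], seed = sd + 1),
                    error = function(e) g$net)
    sim <- tryCatch(suppressWarnings(
      simulate_grn(net, "boolean", boolean_config(n_ics = n_ics,
                                                  repeats = 1),
                   seed = sd + 2)),
      error = function(e) NULL)
    if (is.null(sim)) next
    d <- sim$distribution
    scored <- setdiff(d$nodes, d$signal_nodes)
    part <- structure(
      list(e_nodes = intersect(scored,
                               names(g$anchors)[g$anchors == "E"]),
           m_nodes = intersect(scored,
                               names(g$anchors)[g$anchors == "M"])),
      class = "node_partition")
    rows[[i]] <- data.frame(
      pfl_fraction = loop_census(net)$pfl_fraction,
      hybridness = hybridness(d, part),
      frustration_mean = network_frustration(d, net)$mean)
  }
  tab <- do.call(rbind, rows)
  sp <- function(x, y) {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    c(rho = unname(ct$estimate), p_value = ct$p.value)
  }
  list(table = tab,
       correlations = rbind(
         pfl_fraction = sp(tab$pfl_fraction, tab$hybridness),
         frustration_mean = sp(tab$frustration_mean, tab$hybridness)))
}

# ---- thin command-line wrapper ---------------------------------------------

cli_args_to_list <- function(argv) {
  out <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    out[[substring(a, 3)]] <- argv[i + 1]
    i <- i + 2
  }
  out
}

cli_num <- function(opts, name, default) {
  if (is.null(opts[[name]])) default else as.numeric(opts[[name]])
}

#' Command-line entry point
#'
#' A thin shell over the package functions for scripted use:
#' \preformatted{
#'   run_cli(c("sweep", "--topo", "net.topo", "--engine", "boolean",
#'             "--seed", "1", "--out", "metrics.tsv"))
#' }
#' Subcommands: `simulate` (distribution TSV of a topology), `sweep`
#' (metrics table of all single-edge perturbations, plus a correlation
#' TSV when `--report` is given), `metrics` (topology metrics of a
#' .topo), `randomize` (percentile of a metric among randomized
#' networks), `synth` (write a random synthetic topology). Common
#' options: `--topo`, `--out`, `--seed`, `--engine`, `--n-ics`,
#' `--n-sets`, `--repeats`. Progress and the seed in use are logged to
#' stderr.
#'
#' @param argv character vector of arguments (subcommand first).
#' @return exit code, invisibly: 0 on success, 1 on error.
#' @export
run_cli <- function(argv) {
  code <- tryCatch({
    if (length(argv) < 1) stop("usage: <simulate|sweep|metrics|randomize|",
                               "synth> [--options]")
    cmd <- argv[1]
    opts <- cli_args_to_list(argv[-1])
    seed <- if (is.null(opts$seed)) NULL else as.integer(opts$seed)
    message(sprintf("[grnhybrid] %s (seed: %s)", cmd,
                    if (is.null(seed)) "none" else seed))
    engine_config <- function(engine) {
      if (engine == "boolean")
        boolean_config(n_ics = cli_num(opts, "n-ics", 100000),
                       repeats = cli_num(opts, "repeats", 3))
      else
        ode_config(n_sets = cli_num(opts, "n-sets", 10000),
                   n_ics = cli_num(opts, "n-ics", 100),
                   repeats = cli_num(opts, "repeats", 3))
    }
    load_topo <- function() {
      if (is.null(opts$topo)) stop("--topo is required")
      if (!file.exists(opts$topo)) stop("topo file not found: ", opts$topo)
      parse_topo(opts$topo)
    }
    write_tsv <- function(df, path) {
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      message("[grnhybrid] wrote ", path)
    }
    out <- if (is.null(opts$out)) stop("--out is required") else opts$out
    engine <- if (is.null(opts$engine)) "boolean" else opts$engine
    switch(cmd,
      simulate = {
        sim <- simulate_grn(load_topo(), engine, engine_config(engine),
                            seed)
        write_tsv(data.frame(state = names(sim$distribution$freq),
                             frequency = unname(sim$distribution$freq)),
                  out)
      },
      sweep = {
        tab <- perturbation_sweep(load_topo(), engine,
                                  engine_config(engine), seed)
        write_tsv(as.data.frame(tab), out)
        if (!is.null(opts$report)) write_tsv(correlation_report(tab),
                                             opts$report)
      },
      metrics = {
        tm <- topology_metrics(load_topo())
        write_tsv(data.frame(metric = names(tm),
                             value = unlist(tm, use.names = FALSE)), out)
      },
      randomize = {
        if (is.null(opts$metric)) stop("--metric is required")
        p <- randomization_percentile(load_topo(), opts$metric,
                                      n_random = cli_num(opts, "n-random",
                                                         100),
                                      seed = seed)
        write_tsv(data.frame(metric = opts$metric, percentile = p), out)
      },
      synth = {
        net <- generate_random_grn(cli_num(opts, "n-nodes", 8),
                                   cli_num(opts, "n-edges", 16),
                                   p_inhibition = cli_num(opts,
                                                          "p-inhibition",
                                                          0.5),
                                   n_signal = cli_num(opts, "n-signal", 0),
                                   seed = seed)
        write_topo(net, out)
        message("[grnhybrid] wrote ", out)
      },
      stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("[grnhybrid] error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
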