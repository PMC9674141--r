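test_that("shifted Hill function hits its anchor values and limits", {
  expect_equal(shifted_hill(0, 10, 4, 0.5), 1)
  expect_equal(shifted_hill(0, 10, 4, 7), 1)
  expect_equal(shifted_hill(10, 10, 4, 0.5), 0.75)
  expect_equal(shifted_hill(1e6, 10, 2, 3), 3, tolerance = 1e-6)
  expect_equal(shifted_hill(1e6, 10, 2, 0.2), 0.2, tolerance = 1e-6)
  expect_error(shifted_hill(1, 0, 2, 0.5), "positive")
  # monotone decreasing for inhibition, increasing for activation
  x <- seq(0, 100, by = 1)
  expect_true(all(diff(shifted_hill(x, 20, 3, 0.1)) <= 0))
  expect_true(all(diff(shifted_hill(x, 20, 3, 10)) >= 0))
})

test_that("parameter sampling respects ranges, signs and the seed", {
  emt <- make_fixture("emt_core")
  ps <- sample_parameters(emt, 300, seed = 5)
  inh <- emt$edges$sign < 0
  expect_true(all(ps$lambda[, inh] < 1 & ps$lambda[, inh] > 0))
  expect_true(all(ps$lambda[, !inh] > 1))
  expect_true(all(ps$hill == round(ps$hill) & ps$hill >= 1 & ps$hill <= 6))
  expect_true(all(ps$P >= 1 & ps$P <= 100))
  expect_true(all(ps$D >= 0.1 & ps$D <= 1))
  expect_true(all(ps$y0 > 0))
  expect_identical(sample_parameters(emt, 50, seed = 9),
                   sample_parameters(emt, 50, seed = 9))
  gs <- sample_parameters(emt, 200, ode_config(distribution = "gaussian"),
                          seed = 2)
  expect_true(all(gs$P >= 1 & gs$P <= 100))
  expect_true(all(gs$lambda[, inh] < 1))
  expect_error(ode_config(production_range = c(5, 1)), "range")
})

test_that("integration reaches P/D for an unregulated node", {
  solo <- grn("A", NULL)
  pset <- list(P = 10, D = 0.5, lambda = numeric(), hill = integer(),
               y0 = numeric())
  res <- integrate_circuit(solo, pset, ic = 0)
  expect_true(res$converged)
  expect_equal(unname(res$state), 20, tolerance = 1e-3)
})

test_that("a strongly inhibiting toggle resolves to mutually exclusive
           states from asymmetric starts", {
  tog <- make_fixture("toggle")
  pset <- list(P = c(50, 50), D = c(0.5, 0.5), lambda = c(0.01, 0.01),
               hill = c(4L, 4L), y0 = c(10, 10))
  hi_a <- integrate_circuit(tog, pset, c(100, 0))
  expect_true(hi_a$converged)
  # nullcline fixed point: A = P/D * H(B); B repressed to ~ lambda*P/D
  expect_gt(hi_a$state["A"], 90)
  expect_lt(hi_a$state["B"], 5)
  hi_b <- integrate_circuit(tog, pset, c(0, 100))
  expect_equal(unname(hi_b$state), unname(rev(hi_a$state)),
               tolerance = 1e-6)
})

test_that("halving the Euler step barely moves converged levels", {
  tog <- make_fixture("toggle")
  ps <- sample_parameters(tog, 100, seed = 21)
  set.seed(22)
  n_close <- 0
  for (i in 1:100) {
    pset <- parameter_set(ps, i)
    ic <- runif(2, 0, 1.5 * pset$P / pset$D)
    r1 <- integrate_circuit(tog, pset, ic, dt = 0.1)
    r2 <- integrate_circuit(tog, pset, ic, dt = 0.05)
    if (r1$converged && r2$converged &&
        max(abs(r1$state - r2$state) / pmax(abs(r2$state), 1)) < 0.01)
      n_close <- n_close + 1
  }
  expect_gte(n_close, 99)
})

test_that("ensemble bookkeeping: run counts, repeats, determinism", {
  tog <- make_fixture("toggle")
  cfg <- ode_config(n_sets = 40, n_ics = 5, repeats = 2)
  ens <- run_ensemble(tog, cfg, seed = 3)
  expect_length(ens$repeats, 2)
  for (r in ens$repeats) {
    expect_equal(nrow(r$levels), 40 * 5)
    expect_length(r$distinct_counts, 40)
  }
  ens2 <- run_ensemble(tog, cfg, seed = 3)
  expect_identical(ens$repeats[[1]]$levels, ens2$repeats[[1]]$levels)
  # levels bounded by the maximal activated production over degradation
  solo <- grn("A", NULL)
  se <- run_ensemble(solo, ode_config(n_sets = 30, n_ics = 4, repeats = 1),
                     seed = 1)
  expect_true(all(se$repeats[[1]]$distinct_counts == 1))
  expect_equal(multistability_fraction(se), 0)
})

test_that("the toggle is bistable and loses bistability with an edge cut", {
  tog <- make_fixture("toggle")
  cfg <- ode_config(n_sets = 200, n_ics = 15, repeats = 1)
  ms_tog <- mean(vapply(1:3, function(s)
    multistability_fraction(run_ensemble(tog, cfg, seed = s)), numeric(1)))
  expect_gt(ms_tog, 0)
  cut <- enumerate_edge_perturbations(tog)[[1]]$net   # one inhibition left
  ms_cut <- mean(vapply(1:3, function(s)
    multistability_fraction(run_ensemble(cut, cfg, seed = s)), numeric(1)))
  expect_gt(ms_tog, ms_cut)
})

test_that("binarization z-scores per node and trims signal nodes", {
  # hand-built ensemble: two mirrored states at equal frequency
  lv <- matrix(c(10, 1, 1, 10, 10, 1, 1, 10), 4, 2, byrow = TRUE,
               dimnames = list(NULL, c("A", "B")))
  ens <- structure(list(
    repeats = list(list(levels = lv, set = rep(1:2, each = 2),
                        ic = rep(1:2, 2), converged = rep(TRUE, 4),
                        distinct_counts = c(2L, 2L))),
    net = make_fixture("toggle"),
    config = ode_config(n_sets = 2, n_ics = 2, repeats = 1)),
    class = "steady_state_ensemble")
  d <- binarize(ens)
  expect_equal(sort(names(d$freq)), c("01", "10"))
  expect_equal(unname(d$freq[c("10", "01")]), c(0.5, 0.5))
  expect_equal(sum(d$freq), 1)
  # signal trimming shortens the string
  d2 <- binarize(ens, signal_nodes = "A")
  expect_equal(nchar(names(d2$freq)), rep(1, 2))
  # constant node -> error naming it
  ens$repeats[[1]]$levels[, "B"] <- 5
  expect_error(binarize(ens), "zero variance.*B")
})

test_that("multistability errors when nothing converged", {
  ens <- structure(list(
    repeats = list(list(levels = matrix(0, 1, 2), set = 1L, ic = 1L,
                        converged = FALSE, distinct_counts = 0L)),
    net = make_fixture("toggle"),
    config = ode_config(n_sets = 1, n_ics = 1, repeats = 1)),
    class = "steady_state_ensemble")
  expect_error(multistability_fraction(ens), "no parameter set")
})
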