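test_that("threshold update follows the signed-sum rule in both
           conventions", {
  tog <- make_fixture("toggle")
  # ising: from (1,1), A's input is -1 * (+1) = -1 -> A drops to 0
  expect_equal(unname(threshold_update(c(A = 1, B = 1), tog, "A")),
               c(0, 1))
  # literal01: from (0,0) the sum is 0 * (-1) = 0 -> held
  expect_equal(unname(threshold_update(c(A = 0, B = 0), tog, "A",
                                       convention = "literal01")), c(0, 0))
  # ising: from (0,0), inactive inhibitor pushes the target up
  expect_equal(unname(threshold_update(c(A = 0, B = 0), tog, "A")), c(1, 0))
  # a node with no inputs never changes
  chain <- parse_topo("Source Target Type\nS A 1")
  expect_equal(unname(threshold_update(c(S = 1, A = 0), chain, "S")),
               c(1, 0))
  expect_equal(unname(threshold_update(c(S = 0, A = 0), chain, "S")),
               c(0, 0))
})

test_that("asynchronous trajectories stop at fixed points and are
           reproducible", {
  tog <- make_fixture("toggle")
  r <- simulate_async(tog, c(1, 0), seed = 1)
  expect_true(r$converged)
  expect_equal(unname(r$state), c(1, 0))
  expect_equal(r$steps, 0)
  rep3 <- make_fixture("repressilator")
  expect_length(oracle_fixed_points(rep3), 0)  # no state is fixed
  rr <- simulate_async(rep3, c(1, 0, 0), max_steps = 500, seed = 2)
  expect_false(rr$converged)
  s1 <- simulate_async(tog, c(1, 1), seed = 7)
  s2 <- simulate_async(tog, c(1, 1), seed = 7)
  expect_identical(s1, s2)
})

test_that("every reported ensemble state is a true fixed point and the
           toggle splits evenly", {
  tog <- make_fixture("toggle")
  d <- run_boolean_ensemble(tog, n_ics = 20000, repeats = 1, seed = 1)
  expect_setequal(names(d$freq), c("10", "01"))
  expect_equal(sum(d$freq), 1)
  # binomial 3-sigma band around 1/2 at n = 20000
  expect_lt(abs(d$freq[["10"]] - 0.5), 3 * sqrt(0.25 / 20000) + 1e-9)
  for (s in d$states$full)
    expect_true(is_boolean_fixed_point(s, tog))
})

test_that("fixed-point sets match exhaustive enumeration for small nets", {
  nets <- list(toggle = make_fixture("toggle"),
               missa = make_fixture("toggle_missa"),
               emt = make_fixture("emt_core"),
               rnd = generate_random_grn(5, 10, seed = 77))
  for (nm in names(nets)) {
    for (conv in c("ising", "literal01")) {
      fps <- oracle_fixed_points(nets[[nm]], conv)
      # closure: updating any node of a fixed point returns the same state
      for (s in fps)
        for (i in seq_along(nets[[nm]]$nodes))
          expect_equal(paste(threshold_update(s, nets[[nm]], i, conv),
                             collapse = ""), s)
    }
  }
  # literal01 makes the all-zero state spuriously fixed on the toggle
  expect_true("00" %in% oracle_fixed_points(nets$toggle, "literal01"))
  expect_false("00" %in% oracle_fixed_points(nets$toggle, "ising"))
})

test_that("simulated frequencies match the exact absorption distribution", {
  nets <- list(make_fixture("toggle"),
               make_fixture("emt_core"),
               generate_random_grn(5, 12, p_inhibition = 0.4, seed = 31))
  for (net in nets) {
    exact <- oracle_absorption(net)
    d <- run_boolean_ensemble(net, n_ics = 30000, repeats = 1, seed = 5,
                              signal_nodes = character())
    expect_setequal(names(d$freq), names(exact))
    expect_lt(max(abs(d$freq[names(exact)] - exact)), 0.02)
  }
})

test_that("weighted edges change absorption without changing support
           wiring", {
  emt <- make_fixture("emt_core")
  wtd <- assign_edge_weights(emt, seed = 12)
  d0 <- run_boolean_ensemble(emt, n_ics = 10000, repeats = 1, seed = 3)
  d1 <- run_boolean_ensemble(wtd, n_ics = 10000, repeats = 1, seed = 3)
  expect_equal(sum(d1$freq), 1)
  for (s in d1$states$full) expect_true(is_boolean_fixed_point(s, wtd))
  # same seed, same engine path -> deterministic
  d2 <- run_boolean_ensemble(wtd, n_ics = 10000, repeats = 1, seed = 3)
  expect_identical(d1$freq, d2$freq)
})

test_that("repeats average at the distribution level", {
  tog <- make_fixture("toggle")
  d3 <- run_boolean_ensemble(tog, n_ics = 5000, repeats = 3, seed = 11)
  expect_equal(sum(d3$freq), 1)
  expect_setequal(names(d3$freq), c("10", "01"))
  # an ensemble with no fixed points errors out
  expect_error(run_boolean_ensemble(make_fixture("repressilator"),
                                    n_ics = 200, repeats = 1, seed = 1),
               "no initial condition")
})
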