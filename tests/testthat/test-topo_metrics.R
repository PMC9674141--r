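test_that("cycle enumeration matches brute force on random graphs", {
  for (s in 1:25) {
    net <- generate_random_grn(sample(3:6, 1), sample(4:10, 1),
                               p_inhibition = 0.5, seed = 300 + s,
                               allow_self_loops = TRUE)
    cen <- loop_census(net)
    ora <- oracle_cycle_counts(net)
    expect_equal(cen$pfl, ora$pfl, info = paste("seed", 300 + s))
    expect_equal(cen$nfl, ora$nfl, info = paste("seed", 300 + s))
  }
})

test_that("loop census: signs, weights and fraction on fixtures", {
  tog <- loop_census(make_fixture("toggle"))
  expect_equal(tog[c("pfl", "nfl", "weighted_pfl", "pfl_fraction")],
               list(pfl = 1, nfl = 0, weighted_pfl = 2, pfl_fraction = 1))
  rep3 <- loop_census(make_fixture("repressilator"))
  expect_equal(rep3$nfl, 1)
  expect_equal(rep3$weighted_nfl, 3)
  expect_equal(loop_census(make_fixture("repressilator"),
                           weight_mode = "inv_length")$weighted_nfl, 1 / 3)
  tm <- loop_census(make_fixture("toggle_missa"))
  expect_equal(tm$pfl, 2)
  expect_equal(tm$pfl_fraction, 1)
  expect_true(is.na(loop_census(parse_topo(
    "Source Target Type\nA B 1"))$pfl_fraction))
})

test_that("length caps bound the census and predicted frustration", {
  # single 7-long negative cycle
  nodes <- LETTERS[1:7]
  e <- data.frame(source = nodes, target = c(nodes[-1], nodes[1]),
                  sign = c(-1, rep(1, 6)))
  net <- grn(nodes, e)
  expect_equal(loop_census(net)$nfl, 1)
  expect_equal(loop_census(net, max_len = 6)$nfl, 0)
  expect_equal(predicted_frustration(net), 0)
  expect_equal(predicted_frustration(make_fixture("repressilator")), 1)
  expect_equal(predicted_frustration(make_fixture("toggle")), 0)
})

test_that("influence matrix: lmax=1 identity with adjacency, toggle case", {
  for (s in 1:5) {
    net <- generate_random_grn(6, 12, seed = 400 + s)
    expect_equal(influence_matrix(net, lmax = 1)$matrix,
                 t(interaction_matrix(net)))
  }
  inf2 <- influence_matrix(make_fixture("toggle"), lmax = 2)
  expect_equal(unname(inf2$matrix), matrix(c(0.5, -0.5, -0.5, 0.5), 2))
  net <- generate_random_grn(8, 24, seed = 7)
  expect_true(all(abs(influence_matrix(net, lmax = 10)$matrix) <= 1))
})

test_that("influence loop strengths split by sign of mutual products", {
  ls <- influence_loop_strengths(influence_matrix(make_fixture("toggle"),
                                                  lmax = 2))
  expect_equal(ls$positive_total, 0.25)
  expect_equal(ls$negative_total, 0)
  chain <- parse_topo("Source Target Type\nA B 1")
  lc <- influence_loop_strengths(influence_matrix(chain, lmax = 3))
  expect_equal(c(lc$positive_total, lc$negative_total), c(0, 0))
  for (s in 1:5) {
    net <- generate_random_grn(7, 18, p_inhibition = 0.5, seed = 500 + s)
    ls <- influence_loop_strengths(influence_matrix(net))
    expect_gte(ls$positive_total, 0)
    expect_lte(ls$negative_total, 0)
  }
})

test_that("hiloop counts on constructed motifs and invariance to labels", {
  expect_equal(hiloop_census(make_fixture("toggle")),
               list(type1 = 0, type2 = 0, missa = 0))
  tm <- hiloop_census(make_fixture("toggle_missa"))
  expect_equal(tm$missa, 1)
  expect_equal(tm$type1, 0)
  hub <- hiloop_census(make_fixture("type1_hub"))
  expect_equal(hub$type1, 1)
  expect_equal(hub$type2, 0)

  # type2: central 2-node PFL u-v plus disjoint PFLs at u and at v
  t2 <- parse_topo(paste("Source Target Type", "U V 1", "V U 1",
                         "U A 1", "A U 1", "V B 1", "B V 1", sep = "\n"))
  expect_equal(hiloop_census(t2)$type2, 1)

  # relabeling nodes must not change any census
  net <- generate_random_grn(7, 16, p_inhibition = 0.4, seed = 42)
  relab <- net
  perm <- rev(seq_along(net$nodes))
  map <- setNames(sprintf("Z%02d", perm), net$nodes)
  relab$nodes <- unname(map[net$nodes])
  relab$edges$source <- unname(map[net$edges$source])
  relab$edges$target <- unname(map[net$edges$target])
  expect_equal(hiloop_census(relab), hiloop_census(net))
})

test_that("missa relaxed mode accepts a PFL in place of self-activation", {
  # mutual inhibition + u on a separate 2-node activation loop
  net <- parse_topo(paste("Source Target Type", "U V 2", "V U 2",
                          "U A 1", "A U 1", sep = "\n"))
  expect_equal(hiloop_census(net, missa_mode = "strict")$missa, 0)
  expect_equal(hiloop_census(net, missa_mode = "relaxed")$missa, 1)
})

test_that("inconsistency: exact on fixtures, greedy >= brute-force min", {
  one_neg <- parse_topo("Source Target Type\nA B 2\nB A 1")
  expect_equal(inconsistency(one_neg)$value, 1)
  expect_equal(inconsistency(make_fixture("toggle"))$value, 0)
  expect_equal(inconsistency(make_fixture("repressilator"))$value, 1)
  for (s in 1:20) {
    net <- generate_random_grn(sample(4:6, 1), sample(5:9, 1),
                               p_inhibition = 0.5, seed = 600 + s)
    true_min <- oracle_min_flips(net)
    for (space in c("basis", "all_simple_capped")) {
      g <- inconsistency(net, cycle_space = space)$value
      expect_gte(g, true_min)
      expect_equal(g == 0, true_min == 0,
                   info = paste("seed", 600 + s, space))
    }
  }
})
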