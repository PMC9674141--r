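test_that("partitioning recovers a two-block correlation structure", {
  nodes <- c("E1", "E2", "M1", "M2")
  cc <- matrix(-1, 4, 4, dimnames = list(nodes, nodes))
  cc[1:2, 1:2] <- 1
  cc[3:4, 3:4] <- 1
  part <- partition_nodes(cc, anchors = c(E1 = "E"))
  expect_setequal(part$e_nodes, c("E1", "E2"))
  expect_setequal(part$m_nodes, c("M1", "M2"))
  # anchor on the other side flips the labels
  part2 <- partition_nodes(cc, anchors = c(M1 = "E"))
  expect_setequal(part2$e_nodes, c("M1", "M2"))
  expect_warning(p3 <- partition_nodes(cc), "lexicographically")
  expect_setequal(p3$e_nodes, c("E1", "E2"))
  tog <- matrix(c(1, -1, -1, 1), 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  expect_warning(pt <- partition_nodes(tog))
  expect_length(pt$e_nodes, 1)
  expect_length(pt$m_nodes, 1)
})

test_that("EMT score and classification, boundary inclusive", {
  part <- structure(list(e_nodes = c("E1", "E2"), m_nodes = c("M1", "M2")),
                    class = "node_partition")
  nodes <- c("E1", "E2", "M1", "M2")
  expect_equal(emt_score("1100", part, nodes), 1)
  expect_equal(emt_score("0011", part, nodes), -1)
  expect_equal(emt_score("1010", part, nodes), 0)
  expect_equal(classify_state("1100", part, nodes), "E")
  expect_equal(classify_state("0011", part, nodes), "M")
  # score exactly +0.5 counts as hybrid
  part3 <- structure(list(e_nodes = c("E1", "E2"), m_nodes = "M1"),
                     class = "node_partition")
  expect_equal(emt_score("110", part3, c("E1", "E2", "M1")), 1)
  expect_equal(classify_state("100", part3, c("E1", "E2", "M1")), "hybrid")
  expect_error(emt_score("11", part, c("E1", "E2")), "lacks partition")
  # antisymmetry under swapping the labels
  swapped <- structure(list(e_nodes = part$m_nodes, m_nodes = part$e_nodes),
                       class = "node_partition")
  for (s in c("1100", "0110", "1111", "0001"))
    expect_equal(emt_score(s, part, nodes), -emt_score(s, swapped, nodes))
})

test_that("hybridness sums the frequencies of hybrid states", {
  part <- structure(list(e_nodes = c("A", "B"), m_nodes = c("C", "D")),
                    class = "node_partition")
  mk <- function(freq) {
    states <- data.frame(full = names(freq), trimmed = names(freq),
                         freq = unname(freq))
    phenotype_distribution(freq, states, c("A", "B", "C", "D"))
  }
  d <- mk(c("1100" = 0.5, "0011" = 0.3, "1010" = 0.2))
  expect_equal(hybridness(d, part), 0.2)
  expect_equal(hybridness(mk(c("1100" = 1)), part), 0)
  expect_equal(hybridness(mk(c("1010" = 0.6, "0101" = 0.4)), part), 1)
  # hybridness + terminal frequency = 1
  d2 <- mk(c("1100" = 0.25, "0011" = 0.25, "1010" = 0.25, "1111" = 0.25))
  scored <- c("A", "B", "C", "D")
  cls <- vapply(names(d2$freq), classify_state, character(1), part = part,
                nodes = scored)
  expect_equal(hybridness(d2, part) + sum(d2$freq[cls %in% c("E", "M")]), 1)
})

test_that("Jensen-Shannon divergence: axioms and the 0.3113 case", {
  expect_equal(jensen_shannon_divergence(c(A = 0.6, B = 0.4),
                                         c(A = 0.6, B = 0.4)), 0)
  expect_equal(jensen_shannon_divergence(c(A = 1), c(B = 1)), 1)
  expect_equal(jensen_shannon_divergence(c(A = 1), c(A = 0.5, B = 0.5)),
               0.5 * log2(1 / 0.75) +
                 0.5 * (0.5 * log2(0.5 / 0.75) + 0.5 * log2(0.5 / 0.25)),
               tolerance = 1e-12)
  expect_equal(round(jensen_shannon_divergence(c(A = 1),
                                               c(A = 0.5, B = 0.5)), 4),
               0.3113)
  expect_error(jensen_shannon_divergence(c(A = 0.7), c(A = 1)),
               "normalized")
  set.seed(99)
  for (i in 1:25) {
    f1 <- random_distribution(4)
    f2 <- random_distribution(4)
    j12 <- jensen_shannon_divergence(f1, f2)
    expect_equal(j12, jensen_shannon_divergence(f2, f1))
    expect_gte(j12, 0)
    expect_lte(j12, 1)
    expect_equal(jensen_shannon_divergence(f1, f1), 0)
  }
})

test_that("J metric is the strict upper-triangle sum", {
  expect_equal(j_metric(matrix(c(1, 0.5, 0.5, 1), 2)), 0.5)
  expect_equal(j_metric(diag(3)), 0)
  expect_equal(j_metric(matrix(1, 3, 3)), 3)
  expect_error(j_metric(matrix(1, 2, 3)), "square")
})

test_that("state frustration on fixtures matches hand enumeration", {
  tog <- make_fixture("toggle")
  expect_equal(state_frustration("10", tog), 0)
  expect_equal(state_frustration("01", tog), 0)
  expect_equal(state_frustration("11", tog), 1)
  expect_equal(state_frustration("00", tog), 1)
  rep3 <- make_fixture("repressilator")
  expect_equal(state_frustration("100", rep3), 1 / 3)
  all_states <- apply(expand.grid(0:1, 0:1, 0:1), 1, paste, collapse = "")
  fr <- vapply(all_states, state_frustration, numeric(1), net = rep3)
  expect_equal(min(fr), 1 / 3)   # no state beats 1/3
  expect_equal(max(fr), 1)
  # self-inhibition always frustrated, self-activation never
  selfi <- grn("A", data.frame(source = "A", target = "A", sign = -1))
  expect_equal(state_frustration("1", selfi), 1)
  expect_equal(state_frustration("0", selfi), 1)
  selfa <- grn("A", data.frame(source = "A", target = "A", sign = 1))
  expect_equal(state_frustration("1", selfa), 0)
})

test_that("network frustration aggregates distinct states", {
  tog <- make_fixture("toggle")
  fr <- network_frustration(c("10", "01"), tog)
  expect_equal(c(fr$min, fr$mean, fr$max), c(0, 0, 0))
  fr1 <- network_frustration("11", tog)
  expect_equal(c(fr1$min, fr1$mean, fr1$max), c(1, 1, 1))
  rep3 <- make_fixture("repressilator")
  all_states <- apply(expand.grid(0:1, 0:1, 0:1), 1, paste, collapse = "")
  fr8 <- network_frustration(all_states, rep3)
  expect_equal(fr8$min, 1 / 3)
  expect_equal(fr8$max, 1)
  # frequency weighting changes the mean, not the extremes
  states <- data.frame(full = c("11", "10"), trimmed = c("11", "10"),
                       freq = c(0.9, 0.1))
  d <- phenotype_distribution(c("11" = 0.9, "10" = 0.1), states,
                              c("A", "B"))
  expect_equal(network_frustration(d, tog)$mean, 0.5)
  expect_equal(network_frustration(d, tog, weighted = TRUE)$mean, 0.9)
  expect_error(network_frustration(character(), tog), "no steady states")
})
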