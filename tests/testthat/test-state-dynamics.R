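test_that("transition counts skip censored gaps", {
  N <- transition_counts(c(1, 1, 1), k = 2)
  expect_equal(N["1", "1"], 2)
  expect_equal(sum(N), 2)

  N2 <- transition_counts(c(1, 2, 1, 0, 2), k = 2)
  expect_equal(N2["1", "2"], 1)
  expect_equal(N2["2", "1"], 1)
  expect_equal(N2["1", "0"], 1)
  expect_equal(N2["0", "2"], 1)
  expect_equal(sum(N2), 4)

  N3 <- transition_counts(c(1, NA, 2), k = 2)
  expect_equal(sum(N3), 0)

  expect_error(transition_counts(integer(0), 2), "non-empty")
  expect_error(transition_counts(c(1, 3), 2), "0\\.\\.2")
})

test_that("temporal metrics match closed forms on tiny sequences", {
  m <- compute_metrics(c(1, 1, 1, 1), tr_seconds = 2, k = 2)
  r1 <- m[m$state == 1, ]
  expect_equal(r1$occurrence, 1)
  expect_equal(r1$duration, 8)
  expect_equal(r1$resilience, 1)
  expect_equal(r1$in_degree, 0)
  expect_equal(r1$out_degree, 0)
  expect_false(m$visited[m$state == 2])

  # strict alternation: zero resilience; balanced alternation (even switch
  # counts both ways) gives symmetric degrees
  m2 <- compute_metrics(c(1, 2, 1, 2), tr_seconds = 1, k = 2)
  expect_equal(m2$resilience[m2$state %in% 1:2], c(0, 0))
  expect_equal(m2$occurrence[m2$state %in% 1:2], c(0.5, 0.5))
  m2b <- compute_metrics(c(1, 2, 1, 2, 1), tr_seconds = 1, k = 2)
  expect_equal(m2b$in_degree[m2b$state == 1], m2b$in_degree[m2b$state == 2])
  expect_equal(m2b$out_degree[m2b$state == 1], m2b$out_degree[m2b$state == 2])

  expect_error(compute_metrics(c(NA, NA), 2, 2), "censored")
})

test_that("occupancy and degree conservation hold on generated sequences", {
  P <- default_transition_matrix(4)
  for (r in 1:5) {
    s <- sample_state_sequence(P, 300, rng_seed = r)
    m <- compute_metrics(s, 2, 4)
    expect_equal(sum(m$occurrence), 1)
    expect_equal(sum(m$in_degree), 1)
    expect_equal(sum(m$out_degree), 1)
    expect_true(all(m$resilience >= 0 & m$resilience <= 1))
    expect_true(all(m$betweenness >= 0 & m$betweenness <= 1))
  }
})

test_that("estimated resilience converges to the chain self-transition", {
  P <- default_transition_matrix(4)
  s <- sample_state_sequence(P, 1000, rng_seed = 10)
  m <- compute_metrics(s, 2, 4)
  for (st in 1:4) {
    n_from <- sum(s[-length(s)] == st)
    se <- sqrt(0.6 * 0.4 / n_from)
    expect_lt(abs(m$resilience[m$state == st] - 0.6), 3 * se)
  }
})

test_that("metrics are invariant to appending censored frames", {
  s <- sample_state_sequence(default_transition_matrix(3), 200, rng_seed = 2)
  m1 <- compute_metrics(s, 2, 3)
  m2 <- compute_metrics(c(s, NA, NA, NA), 2, 3)
  expect_equal(m1, m2)
})

test_that("metrics are equivariant under state relabeling", {
  s <- sample_state_sequence(default_transition_matrix(3), 400, rng_seed = 6)
  perm <- c(2L, 3L, 1L)  # relabel CAP states, baseline fixed
  s_rel <- s
  s_rel[s > 0] <- perm[s[s > 0]]
  m <- compute_metrics(s, 2, 3)
  m_rel <- compute_metrics(s_rel, 2, 3)
  for (st in 1:3) {
    a <- m[m$state == st, -1]
    b <- m_rel[m_rel$state == perm[st], -1]
    expect_equal(a, b, ignore_attr = TRUE)
  }
})

test_that("betweenness matches trivial graphs", {
  # two states only: no possible intermediary
  N <- matrix(0, 3, 3, dimnames = list(0:2, 0:2))
  N["1", "2"] <- 5
  N["2", "1"] <- 3
  expect_equal(unname(betweenness_centrality(N)), c(0, 0, 0))

  # pure relay chain 1 -> 2 -> 3: the middle node carries the only path
  N2 <- matrix(0, 4, 4, dimnames = list(0:3, 0:3))
  N2["1", "2"] <- 2
  N2["2", "3"] <- 2
  b <- betweenness_centrality(N2)
  expect_equal(unname(b), c(0, 0, 1, 0))
})

test_that("betweenness equals exhaustive path enumeration on random graphs", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(3:5, 1)
    counts <- matrix(rpois(n * n, 1.2), n, n)
    diag(counts) <- rpois(n, 3)
    # avoid single-exit rows: a lone outgoing edge has probability 1, i.e.
    # a zero-length edge, whose ties neither algorithm can order uniquely
    for (i in seq_len(n)) {
      off_i <- counts[i, -i]
      if (sum(off_i > 0) == 1) {
        j <- setdiff(seq_len(n), i)[which(off_i == 0)][1]
        counts[i, j] <- 1
      }
    }
    dimnames(counts) <- list(0:(n - 1), 0:(n - 1))
    got <- betweenness_centrality(counts)

    off <- counts
    diag(off) <- 0
    flow <- rowSums(off) + colSums(off)
    nodes <- which(flow > 0)
    if (length(nodes) < 3) {
      expect_true(all(got == 0))
      next
    }
    sub <- off[nodes, nodes, drop = FALSE]
    rs <- rowSums(sub)
    p <- sub
    p[rs > 0, ] <- sub[rs > 0, , drop = FALSE] / rs[rs > 0]
    W <- matrix(Inf, length(nodes), length(nodes))
    W[sub > 0] <- pmax(-log(p[sub > 0]), 1e-12)
    expected <- numeric(nrow(counts))
    expected[nodes] <- brute_betweenness(W)
    expect_equal(unname(got), expected, tolerance = 1e-9)
  }
})

test_that("longitudinal deltas subtract sessions per subject and state", {
  seqs <- tibble::tibble(
    subject = rep(c("a", "b"), each = 2),
    session = rep(c("pre", "post3m"), 2),
    sequence = list(
      c(1, 1, 2, 0), c(1, 1, 2, 0),          # identical sessions -> 0
      c(1, 1, 1, 1, 0, 2, 0, 2, 1, 1),
      c(2, 2, 1, 0, 1, 1, 2, 0, 0, 0)
    )
  )
  metrics <- cohort_metrics(seqs, tr_seconds = 2, k = 2)
  d <- longitudinal_delta(metrics)
  expect_true(all(d$delta[d$subject == "a"] == 0))
  occ_b_pre <- mean(seqs$sequence[[3]] == 1)
  occ_b_post <- mean(seqs$sequence[[4]] == 1)
  expect_equal(
    d$delta[d$subject == "b" & d$state == 1 & d$metric == "occurrence"],
    occ_b_post - occ_b_pre
  )

  expect_error(longitudinal_delta(metrics[metrics$session == "pre", ]),
    "not both present")
})

test_that("a planted self-transition increase appears in the mean delta", {
  # post chain raises state-4 stickiness by ~0.1; with 22 subjects the mean
  # delta resilience should sit within 3 SE of the planted shift
  P_pre <- default_transition_matrix(4, self_cap = 0.55)
  P_post <- default_transition_matrix(4, self_cap = 0.65)
  deltas <- vapply(1:22, function(i) {
    s_pre <- sample_state_sequence(P_pre, 600, rng_seed = 100 + i)
    s_post <- sample_state_sequence(P_post, 600, rng_seed = 200 + i)
    m_pre <- compute_metrics(s_pre, 2, 4)
    m_post <- compute_metrics(s_post, 2, 4)
    m_post$resilience[m_post$state == 4] - m_pre$resilience[m_pre$state == 4]
  }, numeric(1))
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas) - 0.1), 3 * se + 0.01)
})
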