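test_that("state sequences follow the transition matrix exactly in degenerate chains", {
  # absorbing chain: identity matrix keeps the initial state forever
  P <- diag(3)
  init <- c(0, 0, 1)
  expect_equal(sample_state_sequence(P, 5, init, rng_seed = 1), rep(2L, 5))

  # deterministic alternation
  P2 <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  expect_equal(sample_state_sequence(P2, 4, c(1, 0), rng_seed = 1),
    c(0L, 1L, 0L, 1L))
})

test_that("long-run occupancy matches the stationary distribution", {
  # sticky symmetric chain: occupancy is autocorrelated, so average five
  # independent sequences to bring the Monte-Carlo error below the 0.02 band
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  occ <- vapply(1:5, function(r) {
    mean(sample_state_sequence(P, 10000, rng_seed = r) == 0)
  }, numeric(1))
  expect_lt(abs(mean(occ) - 0.5), 0.02)

  # asymmetric chain against the eigenvector solution, 3 SE tolerance
  P3 <- matrix(c(
    0.7, 0.2, 0.1,
    0.3, 0.6, 0.1,
    0.2, 0.3, 0.5
  ), 3, 3, byrow = TRUE)
  pi3 <- capdyn:::stationary_distribution(P3)
  s3 <- sample_state_sequence(P3, 20000, rng_seed = 4)
  for (k in 1:3) {
    se <- sqrt(pi3[k] * (1 - pi3[k]) / 20000) * 3  # correlated draws inflate
    expect_lt(abs(mean(s3 == k - 1) - pi3[k]), max(3 * se, 0.02))
  }
})

test_that("non-stochastic matrices are rejected with the offending row named", {
  P <- matrix(c(0.5, 0.4, 0.5, 0.5), 2, 2, byrow = TRUE)
  expect_error(sample_state_sequence(P, 10), "row 1")
  P2 <- matrix(c(1, 0, -0.1, 1.1), 2, 2, byrow = TRUE)
  expect_error(sample_state_sequence(P2, 10), "negative")
})

test_that("noiseless generation reproduces the state maps exactly", {
  model <- state_model(n_states = 3, n_parcels = 20, seed_parcels = 1:4,
    transition_matrix = default_transition_matrix(3),
    amplitude_mean = 1, amplitude_sd = 0, noise_sd = 0, rng_seed = 9)
  sq <- c(1L, 2L, 3L, 1L)
  ts <- generate_subject_timeseries(model, sq, rng_seed = 2)
  for (t in seq_along(sq)) {
    expect_equal(unname(ts$values[t, ]), unname(model$maps[sq[t], ]))
  }
  # spatial correlation of two frames equals correlation of their maps
  ts2 <- generate_subject_timeseries(model, c(1L, 2L), rng_seed = 2)
  expect_equal(
    cor(ts2$values[1, ], ts2$values[2, ]),
    cor(model$maps[1, ], model$maps[2, ])
  )
})

test_that("baseline frames are pure unit noise (law of large numbers)", {
  model <- state_model(n_states = 2, n_parcels = 5, seed_parcels = 1:2,
    transition_matrix = default_transition_matrix(2), noise_sd = 1,
    rng_seed = 1)
  ts <- generate_subject_timeseries(model, rep(0L, 10000), rng_seed = 8)
  expect_true(all(abs(colMeans(ts$values)) < 0.05))
  expect_true(all(abs(apply(ts$values, 2, sd) - 1) < 0.05))
})

test_that("sequence labels outside 0..K are rejected", {
  model <- state_model(n_states = 2, n_parcels = 5, seed_parcels = 1,
    transition_matrix = default_transition_matrix(2), rng_seed = 1)
  expect_error(generate_subject_timeseries(model, c(0L, 3L)), "0\\.\\.K")
})

test_that("behavior generation plants the latent axis as specified", {
  spec <- cohort_spec(n_subjects = 6, n_deficit = 3, seed = 5,
    behavior_noise_sd = 0)
  metrics <- tidyr::expand_grid(
    subject = spec$subjects, session = spec$sessions,
    state = 1:4, metric = c("occurrence", "resilience")
  )
  set.seed(11)
  metrics$value <- runif(nrow(metrics))

  # null axis: zero loadings and zero noise collapse pre/3m scores to the
  # intercept for every subject
  bp <- default_behavior_params()
  bp$loading <- c(0, 0, 0)
  spec0 <- cohort_spec(n_subjects = 6, n_deficit = 3, seed = 5,
    behavior_noise_sd = 0, behavior_params = bp)
  beh0 <- generate_behavior(metrics, spec0)
  pre0 <- dplyr::filter(beh0, timepoint == "pre", score == "TMTA")
  expect_true(all(pre0$value == bp$intercept[bp$score == "TMTA"]))
  tm0 <- dplyr::filter(beh0, timepoint == "3m", score == "TMTB")
  expect_true(all(tm0$value == bp$intercept[bp$score == "TMTB"]))

  # noiseless nonzero loading: the 3m score rank-correlates perfectly with
  # the latent combination
  beh <- generate_behavior(metrics, spec)
  tm <- dplyr::filter(beh, timepoint == "3m", score == "TMTA")
  d <- metrics |>
    dplyr::filter(state == spec$fpn_state) |>
    tidyr::pivot_wider(names_from = session, values_from = value) |>
    dplyr::mutate(delta = post3m - pre) |>
    tidyr::pivot_wider(names_from = metric, values_from = delta,
      id_cols = subject)
  latent <- scale(scale(d$occurrence) + scale(d$resilience))[, 1]
  # negative loading: higher latent -> lower completion time
  expect_equal(cor(tm$value[match(d$subject, tm$subject)], latent,
    method = "spearman"), -1)
})

test_that("TMT B-A equals TMT-B minus TMT-A at every timepoint", {
  coh <- tiny_cohort(seed = 3)
  wide <- coh$behavior |>
    tidyr::pivot_wider(names_from = score, values_from = value,
      id_cols = c(subject, timepoint))
  expect_equal(wide$TMTBA, wide$TMTB - wide$TMTA)
})

test_that("behavior generation requires complete metric rows", {
  spec <- cohort_spec(n_subjects = 4, n_deficit = 2, seed = 1)
  metrics <- tibble::tibble(subject = "sub01", session = "pre",
    state = 4, metric = "occurrence", value = 0.2)
  expect_error(generate_behavior(metrics, spec), "sub02")
})

test_that("cohort generation is deterministic and complete", {
  c1 <- tiny_cohort(seed = 17)
  c2 <- tiny_cohort(seed = 17)
  expect_identical(c1$sequences, c2$sequences)
  expect_identical(c1$behavior, c2$behavior)
  expect_identical(c1$timeseries[["sub01_pre"]]$values,
    c2$timeseries[["sub01_pre"]]$values)

  expect_equal(nrow(c1$manifest), 8 * 2)
  expect_equal(length(c1$timeseries), 16)

  # adding subjects never perturbs existing per-subject streams
  c3 <- generate_cohort(cohort_spec(n_subjects = 10, n_frames = 120,
    n_deficit = 4, seed = 17))
  expect_identical(c1$sequences[["sub03_pre"]], c3$sequences[["sub03_pre"]])
})

test_that("group-effect modifiers keep transition rows stochastic", {
  P <- default_transition_matrix(4)
  Pd <- apply_group_effects(P, 4, 0.6, 1.6)
  expect_equal(rowSums(Pd), rep(1, 5))
  expect_true(all(Pd >= 0))
  expect_lt(Pd[5, 5], P[5, 5])          # destabilized
  expect_gt(Pd[2, 5], P[2, 5])          # more switching into the state
  # identity modifiers are a no-op
  expect_equal(apply_group_effects(P, 4, 1, 1), P)
})

test_that("written cohorts round-trip through the readers", {
  coh <- generate_cohort(cohort_spec(n_subjects = 3, n_frames = 40,
    n_deficit = 1, seed = 23))
  dir <- tempfile("cohort_")
  write_cohort(coh, dir)
  man <- load_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 6)
  expect_true(all(man$complete))
  beh <- load_behavior(file.path(dir, "behavior.csv"))
  expect_equal(nrow(beh), nrow(coh$behavior))
  ts <- read_timeseries(file.path(dir, "sub02_pre.tsv"),
    subject_id = "sub02", session_id = "pre")
  expect_equal(ts$values, coh$timeseries[["sub02_pre"]]$values,
    ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
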