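test_that("run z-scoring uses population SD over usable frames only", {
  x <- parcel_ts(cbind(c(1, 2, 3), c(2, 4, 6)))
  z <- zscore_run(x)
  expect_equal(unname(z$values[, 1]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  # idempotence
  z2 <- zscore_run(z)
  expect_equal(z2$values, z$values, tolerance = 1e-12)

  # censored middle frame: stats from the usable frames only, censored value
  # passed through untouched
  xc <- parcel_ts(cbind(c(1, 9, 3), c(0, 5, 1)),
    censor_mask = c(TRUE, FALSE, TRUE))
  zc <- zscore_run(xc)
  expect_equal(unname(zc$values[c(1, 3), 1]), c(-1, 1))  # mean 2, pop sd 1
  expect_equal(unname(zc$values[2, ]), c(9, 5))

  # zero-variance parcel: named error, or dropped on request
  const <- parcel_ts(cbind(c(1, 2, 3), c(4, 4, 4)),
    parcel_ids = c("a", "flat"))
  expect_error(zscore_run(const), "flat")
  dropped <- zscore_run(const, on_constant = "drop")
  expect_equal(dropped$parcel_ids, "a")
})

test_that("frame selection honors fraction, threshold, polarity and censoring", {
  set.seed(7)
  vals <- matrix(rnorm(100 * 6), 100, 6)
  x <- zscore_run(parcel_ts(vals))
  seedd <- seed_definition("FPN", 1:2)

  sel <- select_frames(x, seedd, frame_policy(fraction = 0.15))
  expect_length(sel$activation, 15)
  expect_true(all(diff(sel$activation) > 0))
  # the selected frames are exactly the top-15 seed z-scores
  expect_setequal(sel$activation, order(-sel$seed_z)[1:15])

  # polarity both adds the same count of lowest frames
  selb <- select_frames(x, seedd, frame_policy(fraction = 0.10, polarity = "both"))
  expect_length(selb$deactivation, 10)
  expect_setequal(selb$deactivation, order(sel$seed_z)[1:10])

  # threshold mode: strict cut on the re-standardized signal, both signs
  selz <- select_frames(x, seedd,
    frame_policy(mode = "z_threshold", z_cut = 1.5, polarity = "both"))
  expect_setequal(selz$activation, which(sel$seed_z > 1.5))
  expect_setequal(selz$deactivation, which(sel$seed_z < -1.5))

  # censored frames are never selected
  cm <- rep(TRUE, 100)
  cm[sel$activation[1]] <- FALSE
  xc <- zscore_run(parcel_ts(vals, censor_mask = cm))
  selc <- select_frames(xc, seedd, frame_policy(fraction = 0.15))
  expect_false(sel$activation[1] %in% selc$activation)
  expect_length(selc$activation, ceiling(0.15 * 99))
})

test_that("k-means separates planted orthogonal patterns perfectly", {
  set.seed(3)
  m1 <- c(rep(2, 5), rep(-1, 5))
  m2 <- c(rep(-1, 5), rep(2, 5))
  frames <- rbind(
    matrix(rep(m1, 10), 10, byrow = TRUE),
    matrix(rep(m2, 10), 10, byrow = TRUE)
  )
  fit <- kmeans_caps(frames, 2, rng_seed = 1)
  expect_equal(fit$member_counts, c(10L, 10L))
  expect_length(unique(fit$labels[1:10]), 1)
  expect_length(unique(fit$labels[11:20]), 1)
  expect_true(fit$labels[1] != fit$labels[11])
  lab1 <- fit$labels[1]
  expect_equal(unname(fit$maps[lab1, ]), m1)
  expect_equal(unname(fit$maps[3 - lab1, ]), m2)

  # k = 1: single map is the grand mean
  fit1 <- kmeans_caps(frames, 1, rng_seed = 1)
  expect_equal(unname(fit1$maps[1, ]), colMeans(frames))

  expect_error(kmeans_caps(frames[1:3, ], 4), "at least k")
})

test_that("k-means matches the brute-force optimal 2-partition on 6 frames", {
  set.seed(21)
  for (rep in 1:5) {
    frames <- matrix(rnorm(6 * 3), 6, 3)
    fit <- kmeans_caps(frames, 2, rng_seed = rep, n_restarts = 30)
    objs <- vapply(two_partitions(6), function(lab) {
      partition_objective(frames, lab)
    }, numeric(1))
    expect_equal(fit$objective, min(objs), tolerance = 1e-8)
  }
})

test_that("consensus clustering recovers the planted model order", {
  # four well-separated planted clusters
  set.seed(13)
  maps <- matrix(rnorm(4 * 30), 4, 30)
  frames <- maps[rep(1:4, each = 25), ] + matrix(rnorm(100 * 30, 0, 0.15), 100, 30)
  rep_out <- consensus_select_k(frames, k_range = 2:8, n_resamples = 40,
    rng_seed = 2)
  expect_equal(rep_out$selected_k, 4)
  expect_lt(rep_out$summary$pac[rep_out$summary$k == 4], 0.02)

  # consensus matrices: symmetric, unit diagonal, PAC in [0, 1]
  for (cons in rep_out$consensus) {
    d <- diag(cons)
    expect_true(all(abs(d[!is.na(d)] - 1) < 1e-12))
    expect_true(isTRUE(all.equal(cons, t(cons))))
  }
  expect_true(all(rep_out$summary$pac >= 0 & rep_out$summary$pac <= 1))

  # degenerate input: identical frames give consensus 1 for every order and
  # the tie-break returns the smallest candidate
  same <- matrix(rep(c(1, 5, 2, 8), 12), 12, 4, byrow = TRUE)
  rep_deg <- suppressWarnings(
    consensus_select_k(same, k_range = 2:4, n_resamples = 10, rng_seed = 1)
  )
  expect_equal(rep_deg$selected_k, 2)
  off <- rep_deg$consensus[["2"]][upper.tri(rep_deg$consensus[["2"]])]
  expect_true(all(off[!is.na(off)] == 1))
})

test_that("within-cluster consensus exceeds between-cluster consensus", {
  set.seed(31)
  maps <- matrix(rnorm(3 * 20), 3, 20)
  lab <- rep(1:3, each = 20)
  frames <- maps[lab, ] + matrix(rnorm(60 * 20, 0, 0.3), 60, 20)
  rep_out <- consensus_select_k(frames, k_range = 3, n_resamples = 50,
    rng_seed = 4)
  cons <- rep_out$consensus[["3"]]
  same <- outer(lab, lab, "==")
  within <- mean(cons[same & upper.tri(cons)], na.rm = TRUE)
  between <- mean(cons[!same & upper.tri(cons)], na.rm = TRUE)
  expect_gt(within, between)
})

test_that("state assignment labels selected frames by maximum correlation", {
  set.seed(17)
  maps <- matrix(rnorm(3 * 40), 3, 40)
  caps <- kmeans_caps(maps[rep(1:3, each = 4), ], 3, rng_seed = 1)

  # a frame equal to a CAP map gets that CAP's label: build a run whose
  # top-seed frames are exact map copies
  seedd <- seed_definition("s", 1:40)  # seed signal = row mean
  amp <- c(4, 5, 6)
  vals <- rbind(
    3 * maps[1, ], 3 * maps[2, ], 3 * maps[3, ],
    matrix(rnorm(37 * 40, 0, 0.05), 37, 40)
  )
  x <- parcel_ts(vals)
  z <- zscore_run(x)
  seq_out <- assign_states(z, caps, seedd,
    frame_policy(mode = "z_threshold", z_cut = -Inf))
  # with everything selected, each map-copy frame matches its own CAP
  cn <- capdyn:::normalize_rows(caps$maps)$X
  for (t in 1:3) {
    sims <- cn %*% capdyn:::normalize_rows(z$values[t, , drop = FALSE])$X[1, ]
    expect_equal(seq_out[t], unname(which.max(sims)))
  }
  expect_equal(length(seq_out), 40)

  # tie-break: a frame equidistant from two CAPs takes the lower index
  caps2 <- caps
  caps2$maps <- rbind(maps[1, ], maps[1, ], maps[2, ])  # duplicated map
  seq2 <- assign_states(z, caps2, seedd,
    frame_policy(mode = "z_threshold", z_cut = -Inf))
  expect_equal(seq2[1], 1L)

  # censored frames are NA, unselected usable frames are baseline
  cm <- rep(TRUE, 40)
  cm[40] <- FALSE
  zc <- zscore_run(parcel_ts(vals, censor_mask = cm))
  seq3 <- assign_states(zc, caps, seedd, frame_policy(fraction = 0.1))
  expect_true(is.na(seq3[40]))
  expect_equal(sum(seq3 > 0, na.rm = TRUE), ceiling(0.1 * 39))
  expect_true(all(seq3[!is.na(seq3) & seq3 == 0] == 0))
})

test_that("noiseless frames are assigned back to their planted states exactly", {
  set.seed(29)
  model <- state_model(n_states = 4, n_parcels = 50, seed_parcels = 1:8,
    amplitude_mean = 1, amplitude_sd = 0, noise_sd = 0, rng_seed = 6)
  # frames = exact map copies, cluster and assign
  frames <- model$maps[rep(1:4, each = 6), ]
  caps <- kmeans_caps(frames, 4, rng_seed = 3)
  m <- capdyn:::match_states(caps$maps, model$maps)
  expect_equal(sort(m$perm), 1:4)
  expect_true(all(m$correlations > 1 - 1e-12))
  planted <- rep(1:4, each = 6)
  recovered <- m$perm[caps$labels]
  expect_equal(recovered, planted)
})

test_that("pooled extraction recovers planted maps on a default-noise cohort", {
  coh <- tiny_cohort(seed = 19, n_subjects = 6, n_frames = 150)
  seedd <- seed_definition("FPN", coh$spec$seed_parcels)
  ex <- extract_caps(coh$timeseries, seedd, k = 4, rng_seed = 2)
  m <- capdyn:::match_states(ex$caps$maps, coh$model$maps)
  expect_gt(mean(m$correlations), 0.85)  # small cohort; full-size bound is 0.90
  expect_equal(nrow(ex$sequences), 12)
  expect_equal(sum(ex$caps$member_counts), nrow(ex$selected))
})

test_that("the k-means objective is reproducible at a fixed seed", {
  set.seed(41)
  frames <- matrix(rnorm(80 * 10), 80, 10)
  f1 <- kmeans_caps(frames, 3, rng_seed = 7)
  f2 <- kmeans_caps(frames, 3, rng_seed = 7)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$maps, f2$maps)
})
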