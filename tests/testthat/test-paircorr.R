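test_that("signal removal centers every identity's residuals exactly", {
  tens <- noise_tensor(4, 6, 30, n_omission = 5, seed = 2, identities = 3)
  res <- remove_stimulus_signal(tens)
  lab <- tens$trial_labels
  for (id in unique(na.omit(lab$image_identity))) {
    idx <- which(lab$condition == "image" & lab$image_identity == id)
    m <- apply(res$data[, , idx, drop = FALSE], c(1, 2), mean)
    expect_lt(max(abs(m)), 1e-12)
  }
  m_om <- apply(res$data[, , lab$condition == "omission", drop = FALSE],
                c(1, 2), mean)
  expect_lt(max(abs(m_om)), 1e-12)
  # identical trials of one identity -> exactly zero residual
  tens2 <- tens
  idx1 <- which(lab$condition == "image" & lab$image_identity == 1)
  for (k in idx1) tens2$data[, , k] <- tens2$data[, , idx1[1]]
  res2 <- remove_stimulus_signal(tens2)
  expect_true(all(res2$data[, , idx1] == 0))
})

test_that("frame-wise Spearman has the monotone-invariance fixed points", {
  tens <- noise_tensor(2, 5, 20, seed = 4)
  tens$data[2, , ] <- 2 * tens$data[1, , ] + 1
  cc <- framewise_pair_correlation(tens, matrix(c(1, 2), 1))
  expect_true(all(abs(cc - 1) < 1e-12))
  tens$data[2, , ] <- -tens$data[1, , ]
  cc2 <- framewise_pair_correlation(tens, matrix(c(1, 2), 1))
  expect_true(all(abs(cc2 + 1) < 1e-12))
  # invariant to a strictly monotone transform of either neuron
  tens3 <- noise_tensor(2, 5, 20, seed = 5)
  base <- framewise_pair_correlation(tens3, matrix(c(1, 2), 1))
  tens3$data[1, , ] <- exp(tens3$data[1, , ])
  tens3$data[2, , ] <- tens3$data[2, , ]^3
  expect_equal(framewise_pair_correlation(tens3, matrix(c(1, 2), 1)),
               base, tolerance = 1e-12)
})

test_that("frame-wise Spearman matches a rank-then-Pearson oracle on a toy pair", {
  # printed 6-trial toy with a tie in neuron B
  a <- c(3.1, 0.2, 5.5, 2.2, 4.4, 1.0)
  b <- c(10, 12, 31, 12, 25, 11)
  X <- array(0, c(2, 1, 6))
  X[1, 1, ] <- a; X[2, 1, ] <- b
  tens <- aligned_tensor(X, 0, data.frame(condition = rep("image", 6)))
  cc <- framewise_pair_correlation(tens, matrix(c(1, 2), 1))
  oracle <- cor(rank(a), rank(b))
  expect_equal(as.numeric(cc), oracle, tolerance = 1e-12)
  expect_equal(as.numeric(cc),
               suppressWarnings(cor(a, b, method = "spearman")),
               tolerance = 1e-12)
})

test_that("degenerate constant frames are excluded and counted", {
  tens <- noise_tensor(3, 4, 12, seed = 6)
  tens$data[2, 1, ] <- 99
  cc <- framewise_pair_correlation(tens)
  expect_true(is.na(cc[1, 1]))   # pair (1,2) at frame 1
  expect_gt(attr(cc, "n_degenerate"), 0)
  expect_error(framewise_pair_correlation(noise_tensor(2, 3, 4, seed = 1)),
               "trials")
})

test_that("shuffle null is reproducible, centered, and identity-free under independence", {
  tens <- noise_tensor(4, 3, 200, seed = 7)
  null1 <- correlation_shuffle_null(tens, n_shuffles = 10, seed = 3)
  null2 <- correlation_shuffle_null(tens, n_shuffles = 10, seed = 3)
  expect_identical(null1, null2)
  expect_lt(abs(mean(null1)), 0.02)
  # pooled null is centered at zero within 3 standard errors
  se <- sd(null1) / sqrt(length(null1))
  expect_lt(abs(mean(null1)), 3 * se + 1e-12)
})

test_that("cc quantification recovers flat and step structures", {
  offsets <- seq(-1, 2, by = 0.1)
  flat <- matrix(0.3, 2, length(offsets))
  q <- quantify_cc_change(flat, "excitatory", offsets = offsets)
  expect_equal(q$delta_image, c(0, 0), tolerance = 1e-12)
  expect_equal(q$delta_omission, c(0, 0), tolerance = 1e-12)
  # a step of height 0.25 on the omission window; the excitatory baseline
  # frames are those preceding the image flashes at -0.75, +0.75 and +1.5,
  # i.e. offsets -0.8, +0.7 (inside the step) and +1.4
  step <- matrix(0.1, 1, length(offsets))
  om <- offsets >= 0 & offsets < 0.75 - 1e-9
  step[, om] <- 0.35
  q2 <- quantify_cc_change(step, "excitatory", offsets = offsets)
  base_expect <- mean(c(0.1, 0.35, 0.1))
  expect_equal(q2$baseline_cc, base_expect, tolerance = 1e-9)
  expect_equal(q2$delta_omission, 0.35 - base_expect, tolerance = 1e-9)
  expect_error(quantify_cc_change(matrix(0, 1, 3), "VIP",
                                  offsets = c(0, 0.1, 0.2)),
               "windows")
})

test_that("plane-pair aggregation reports means and both p-value flavors", {
  tens <- noise_tensor(6, 31, 40, seed = 9)
  tens$offsets <- seq(-1, 2, by = 0.1)
  tens$neurons <- data.frame(id = 1:6, area = "V1",
                             depth = rep(c(100, 300), each = 3),
                             plane_id = rep(c(1, 2), each = 3))
  res <- remove_stimulus_signal(tens)
  cc <- framewise_pair_correlation(res)
  q <- quantify_cc_change(cc, "VIP")
  null_cc <- correlation_shuffle_null(res, n_shuffles = 8, seed = 2)
  agg <- aggregate_plane_pairs(q, attr(cc, "pairs"), tens$neurons,
                               null_cc = null_cc, cell_class = "VIP",
                               n_trials = 40)
  expect_equal(sum(agg$n_pairs), choose(6, 2))
  expect_equal(nrow(agg), 3)  # 1-1, 1-2, 2-2
  expect_true(all(is.finite(agg$omission_cc_mean)))
  expect_true(all(agg$p_shuffle_t >= 0 & agg$p_shuffle_t <= 1))
  expect_true(all(agg$p_spearman >= 0 & agg$p_spearman <= 1))
  # independent data: the rank-based per-pair p flavor is not degenerate
  expect_true(any(agg$p_spearman > 0.05))
  # single pair: mean equals the pair's value
  agg1 <- aggregate_plane_pairs(q[1, , drop = FALSE],
                                attr(cc, "pairs")[1, , drop = FALSE],
                                tens$neurons)
  expect_equal(agg1$omission_cc_mean, q$omission_cc[1])
})

test_that("signal removal keeps independent neurons' correlations null-calibrated", {
  # type-I: share of nominally significant pair-frames near alpha = 0.05
  rejections <- 0L
  total <- 0L
  for (seed in 1:10) {
    tens <- noise_tensor(4, 4, 60, seed = 100 + seed)
    res <- remove_stimulus_signal(tens)
    cc <- framewise_pair_correlation(res)
    n <- 60
    p <- 2 * pt(-abs(cc * sqrt((n - 2) / (1 - cc^2))), df = n - 2)
    rejections <- rejections + sum(p < 0.05, na.rm = TRUE)
    total <- total + sum(is.finite(p))
  }
  rate <- rejections / total
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.12)
})
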