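# Build a tca_model by hand with prescribed trial weights.
injected_model <- function(trial_weights, n_neurons = 8, n_time = 5,
                           lambda = NULL) {
  R <- ncol(trial_weights)
  unit <- function(n, r) {
    M <- matrix(abs(rnorm(n * r)) + 0.1, n, r)
    sweep(M, 2, sqrt(colSums(M^2)), "/")
  }
  set.seed(1)
  C <- sweep(trial_weights, 2,
             pmax(sqrt(colSums(trial_weights^2)), 1e-12), "/")
  structure(list(
    neuron_factor = unit(n_neurons, R),
    temporal_factor = unit(n_time, R),
    trial_factor = C,
    lambda = if (is.null(lambda)) rep(1, R) else lambda,
    rank = as.integer(R),
    dims = c(as.integer(n_neurons), as.integer(n_time),
             nrow(trial_weights)),
    error = 0, iterations = 1L, converged = TRUE, seed = 1L
  ), class = "tca_model")
}

cond_labels <- function(n_image, n_omission) {
  data.frame(condition = c(rep("image", n_image),
                           rep("omission", n_omission)))
}

test_that("condition-pure components are classified with certainty", {
  labels <- cond_labels(159, 30)
  set.seed(2)
  w_om <- c(rep(0, 159), rep(1, 30)) + rnorm(189, sd = 1e-3)
  w_im <- c(rep(1, 159), rep(0, 30)) + rnorm(189, sd = 1e-3)
  w_neg <- c(rnorm(159, sd = 0.01), -(1 + runif(30)))  # negative but large
  m <- injected_model(cbind(w_om, w_im, w_neg))
  lab <- classify_components(m, labels)
  expect_equal(lab$specificity, c("omission", "image", "omission"))
  expect_true(all(lab$p_value[1:3] < 0.05))
})

test_that("identical weight distributions are nonspecific", {
  labels <- cond_labels(40, 40)
  set.seed(3)
  w <- rnorm(80)
  m <- injected_model(cbind(w, sample(w)))
  lab <- classify_components(m, labels)
  expect_true(all(lab$specificity == "nonspecific"))
  expect_error(classify_components(m, cond_labels(80, 0)), "non-empty")
})

test_that("component counts are conserved and summarized across iterations", {
  labels <- cond_labels(50, 20)
  set.seed(4)
  mk <- function() injected_model(cbind(
    c(rep(0, 50), rep(1, 20)) + rnorm(70, sd = 1e-3),
    rnorm(70)
  ))
  labs <- replicate(6, classify_components(mk(), labels), simplify = FALSE)
  counts <- count_components_by_specificity(labs)
  expect_true(all(rowSums(counts$per_iteration[, c("image", "omission",
                                                   "nonspecific")]) == 2))
  expect_equal(nrow(counts$summary), 3)
  om_mean <- counts$summary$mean[counts$summary$specificity == "omission"]
  expect_gte(om_mean, 1)
})

test_that("trial-weight SD matches closed forms and a two-pass oracle", {
  labels <- cond_labels(2, 2)
  m <- injected_model(cbind(c(1, 1, 1, 1), c(0, 2, 0, 2)),
                      lambda = c(1, 1))
  res <- trial_weight_sd(m, labels)
  # weights are unit-normalized columns scaled by lambda^(1/3)=1
  W <- component_weights(m, "trial", scaled = TRUE)
  expect_equal(res$sd_all[1], sd(W[, 1]), tolerance = 1e-12)
  expect_equal(res$sd_all[1], 0, tolerance = 1e-12)     # constant weights
  expect_equal(res$sd_all[2], sd(W[, 2]), tolerance = 1e-12)
  set.seed(5)
  w10 <- rnorm(10)
  m10 <- injected_model(cbind(w10), lambda = 2)
  got <- trial_weight_sd(m10, cond_labels(5, 5))$sd_all
  W10 <- component_weights(m10, "trial")[, 1]
  two_pass <- sqrt(sum((W10 - mean(W10))^2) / 9)
  expect_equal(got, two_pass, tolerance = 1e-12)
  expect_error(trial_weight_sd(m10, cond_labels(5, 5), integer(0)),
               "non-empty")
})

test_that("within-condition shuffling preserves per-neuron condition multisets exactly", {
  tens <- noise_tensor(5, 4, 30, n_omission = 8, seed = 6)
  shuf <- shuffle_within_condition(tens, seed = 9)
  cond <- tens$trial_labels$condition
  for (cnd in c("image", "omission")) {
    idx <- which(cond == cnd)
    for (i in 1:5) {
      orig <- apply(tens$data[i, , idx], 2, paste, collapse = ",")
      perm <- apply(shuf$data[i, , idx], 2, paste, collapse = ",")
      expect_identical(sort(orig), sort(perm))
      # condition-mean trace is bit-exact
      expect_identical(rowMeans(tens$data[i, , idx]),
                       rowMeans(shuf$data[i, , idx]))
    }
  }
  # labels untouched, deterministic, and single-trial conditions unchanged
  expect_identical(shuf$trial_labels, tens$trial_labels)
  expect_identical(shuffle_within_condition(tens, seed = 9)$data, shuf$data)
  tens1 <- noise_tensor(3, 4, 10, n_omission = 1, seed = 7)
  shuf1 <- shuffle_within_condition(tens1, seed = 2)
  om <- which(tens1$trial_labels$condition == "omission")
  expect_identical(shuf1$data[, , om], tens1$data[, , om])
})

test_that("shuffling destroys shared across-trial amplitude structure", {
  s <- generate_session(fixture_config("latent", seed = 8))
  tens <- align_to_events(s, c("image", "omission"), c(-0.3, 0.6))
  img <- tens$trial_labels$condition == "image"
  amp <- function(x) apply(x[, tens$offsets >= -0.25 & tens$offsets < 0.1,
                             img, drop = FALSE], c(1, 3), mean)
  mean_offdiag <- function(a) {
    cc <- cor(t(a))
    mean(cc[upper.tri(cc)])
  }
  before <- mean_offdiag(amp(tens$data))
  shuf <- shuffle_within_condition(tens, seed = 3)
  after <- mean_offdiag(amp(shuf$data))
  expect_gt(before, after)
  expect_lt(abs(after), 0.05)
})

test_that("superficial/deep split follows the 250 um rule", {
  expect_equal(depth_layer(c(100, 200, 249, 250, 300, 375)),
               c("superficial", "superficial", "superficial",
                 "deep", "deep", "deep"))
})

test_that("real-vs-shuffled comparison is flat when both ensembles are identical", {
  tens <- noise_tensor(6, 5, 60, n_omission = 15, seed = 11)
  tens$neurons <- data.frame(id = 1:6, area = "V1",
                             depth = rep(c(100, 300), 3))
  ens <- run_tca_ensemble(tens$data, n_iterations = 4, rank = 2, seed = 3)
  cmp <- compare_real_vs_shuffled_weights(ens, ens, tens$trial_labels,
                                          tens$neurons)
  if (!is.null(cmp$groups)) {
    expect_true(all(cmp$groups$p_pooled[is.finite(cmp$groups$p_pooled)] >
                      0.9999))
  }
  expect_true(is.na(cmp$overall$p_value) || cmp$overall$p_value > 0.99)
})

test_that("behavior median split detects coupling and stays honest without it", {
  labels <- cond_labels(60, 30)
  set.seed(12)
  labels$wheel <- runif(90, 0, 10)
  labels$pupil <- runif(90, 100, 400)
  # weights strictly increasing in wheel speed on omissions -> minimal p
  w <- c(rnorm(60, sd = 1e-3), rank(labels$wheel[61:90]) / 10 + 1)
  m <- injected_model(cbind(w))
  res <- behavior_median_split_compare(m, labels)
  p_wheel <- res$p_value[res$variable == "wheel"]
  # perfect separation of 15 vs 15 under the normal approximation
  expect_lt(p_wheel, rank_sum_test(1:15, 16:30)$p.value + 1e-12)
  # behavior-independent weights: near-nominal rejection over seeds
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed + 100)
    lab2 <- labels
    w2 <- c(rnorm(60, sd = 1e-3), rnorm(30) + 2)
    m2 <- injected_model(cbind(w2))
    r2 <- behavior_median_split_compare(m2, lab2)
    hits <- hits + sum(r2$p_value < 0.05, na.rm = TRUE)
  }
  expect_lte(hits, 8)  # 40 tests at alpha 0.05: expect ~2
  set.seed(13)
  m_small <- injected_model(cbind(rnorm(62)))
  expect_error(
    behavior_median_split_compare(m_small,
                                  cbind(cond_labels(60, 2),
                                        wheel = 1:62, pupil = 1:62)),
    "fewer than 2")
})
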