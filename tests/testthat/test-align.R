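test_that("alignment uses the first frame at/after onset and half-open windows", {
  s <- generate_session(tiny_config(session_duration = 60, seed = 2))
  tens <- align_to_events(s, "image", c(-0.3, 0.6))
  expect_length(tens$offsets, 9)
  expect_equal(tens$offsets[1], -0.3)
  expect_equal(max(tens$offsets), 0.5)
  # an event at t = 10.0 s with 0.1 s frames: offset 0 is the frame at 10.0
  ev <- which(abs(tens$trial_labels$onset_time - 0.75) < 1e-9)[1]
  i0 <- which(tens$offsets == 0)
  frame_at_onset <- which(s$frame_times >= 0.75 - 1e-9)[1]
  expect_equal(tens$data[3, i0, ev], s$traces[3, frame_at_onset])
})

test_that("constant traces align to constant tensors and labels match events", {
  s <- generate_session(tiny_config(session_duration = 60, noise_sd = 0))
  s$traces[] <- 7
  tens <- align_to_events(s, c("image", "omission"), c(-0.3, 0.6))
  expect_true(all(tens$data == 7))
  sch_kind <- s$schedule$event_kind[match(tens$trial_labels$onset_time,
                                          s$schedule$onset_time)]
  expect_true(all((sch_kind == "omission") ==
                    (tens$trial_labels$condition == "omission")))
  expect_false(any(sch_kind == "change"))
})

test_that("events truncated by the recording edge are dropped and counted", {
  s <- generate_session(tiny_config(session_duration = 60, omission_prob = 0,
                                    change_prob = 0))
  n_events <- nrow(s$schedule)
  tens <- align_to_events(s, "image", c(-0.3, 30))
  expect_lt(dim(tens$data)[3], n_events)
  expect_equal(dim(tens$data)[3] + attr(tens, "n_truncated"), n_events)
  expect_error(align_to_events(s, "image", c(-0.3, 1000)), "no usable")
})

test_that("baseline-SD normalization rescales correctly and flags zero-SD units", {
  tens <- noise_tensor(5, 9, 40, seed = 3, sd = 2)
  norm <- normalize_to_baseline_sd(tens, c(-0.3, 0))
  base <- norm$offsets >= -0.3 & norm$offsets < 0
  sds <- apply(norm$data[, base, , drop = FALSE], 1,
               function(x) sd(as.vector(x)))
  expect_true(all(abs(sds - 1) < 1e-9))
  # already unit-SD baseline stays put
  again <- normalize_to_baseline_sd(norm, c(-0.3, 0))
  expect_equal(again$data, norm$data, tolerance = 1e-9)
  const <- tens
  const$data[2, , ] <- 5
  normc <- normalize_to_baseline_sd(const, c(-0.3, 0))
  expect_equal(attr(normc, "n_excluded"), 1)
  expect_equal(dim(normc$data)[1], 4)
})

test_that("normalization of synthetic noise recovers unit baseline SD", {
  cfg <- tiny_config(noise_sd = 0.3, session_duration = 200,
                     latent_strength = 0, seed = 6)
  s <- generate_session(cfg)
  tens <- align_to_events(s, "image", c(-0.3, 0.6), trace = "rate")
  norm <- normalize_to_baseline_sd(tens, c(-0.3, -0.25))
  base <- norm$offsets >= -0.3 - 1e-9 & norm$offsets < -0.25 - 1e-9
  sds <- apply(norm$data[, base, , drop = FALSE], 1,
               function(x) sd(as.vector(x)))
  expect_true(all(abs(sds - 1) < 1e-9))
})

test_that("population summary is median-then-mean and robust to outlier trials", {
  set.seed(8)
  X <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  tens <- aligned_tensor(X, seq(-0.1, 0.2, by = 0.1),
                         data.frame(condition = rep("image", 5)))
  ps <- population_trace_summary(tens)
  brute <- sapply(1:4, function(t_) {
    mean(sapply(1:3, function(n_) median(X[n_, t_, ])))
  })
  expect_equal(ps$mean, brute, tolerance = 1e-12)
  # one wild trial per neuron barely moves the median stage (a mean-based
  # first stage would shift by ~outlier/n_trials = 2e5)
  X2 <- X
  X2[, , 5] <- 1e6
  tens2 <- aligned_tensor(X2, tens$offsets, tens$trial_labels)
  expect_lt(max(abs(population_trace_summary(tens2)$mean - ps$mean)), 5)
  # constant population: mean c, sem 0
  Xc <- array(2.5, c(3, 4, 5))
  psc <- population_trace_summary(
    aligned_tensor(Xc, tens$offsets, tens$trial_labels))
  expect_true(all(psc$mean == 2.5) && all(psc$sem == 0))
  # single neuron: sem undefined
  ps1 <- population_trace_summary(
    aligned_tensor(X[1, , , drop = FALSE], tens$offsets, tens$trial_labels))
  expect_true(all(is.na(ps1$sem)))
})

test_that("evoked quantification windows follow the class/event rule table", {
  expect_equal(evoked_window_rule("excitatory", "image"), c(0, 0.35))
  expect_equal(evoked_window_rule("SST", "image"), c(0, 0.35))
  expect_equal(evoked_window_rule("VIP", "image"), c(-0.25, 0.1))
  expect_equal(evoked_window_rule("VIP", "omission"), c(0, 0.5))
  flat <- aligned_tensor(array(3, c(2, 9, 6)),
                         seq(-0.3, 0.5, by = 0.1),
                         data.frame(condition = rep(c("image", "omission"),
                                                    3)))
  for (cl in c("excitatory", "SST", "VIP")) {
    for (ev in c("image", "omission")) {
      expect_equal(quantify_evoked_response(flat, cl, ev)$session, 3)
    }
  }
  narrow <- aligned_tensor(array(1, c(2, 2, 4)), c(0, 0.1),
                           data.frame(condition = rep("image", 4)))
  expect_error(quantify_evoked_response(narrow, "excitatory", "image"),
               "required window")
})

test_that("alignment and averaging are shift-equivariant", {
  s <- generate_session(tiny_config(session_duration = 80, seed = 13))
  t1 <- align_to_events(s, "image", c(-0.3, 0.6))
  s2 <- s
  s2$traces <- s$traces + 4
  t2 <- align_to_events(s2, "image", c(-0.3, 0.6))
  expect_equal(population_trace_summary(t2)$mean,
               population_trace_summary(t1)$mean + 4, tolerance = 1e-12)
})

test_that("on a latent fixture VIP omission responses exceed image responses", {
  s <- generate_session(fixture_config("latent", seed = 5))
  tens <- align_to_events(s, c("image", "omission"), c(-0.3, 0.6))
  q_om <- quantify_evoked_response(tens, "VIP", "omission")$session
  q_im <- quantify_evoked_response(tens, "VIP", "image")$session
  expect_gt(q_om, q_im)
})
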