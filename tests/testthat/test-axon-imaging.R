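empty_schedule <- function() manual_schedule(character(0), numeric(0))

test_that("dF/F handles worked examples, neuropil and degenerate traces", {
  # constant trace -> zeros
  expect_equal(as.vector(compute_dff(matrix(5, 1, 10))), rep(0, 10))
  # forced arithmetic
  expect_equal(as.vector(compute_dff(matrix(c(1, 1, 2), 1))),
               c(-0.25, -0.25, 0.5))
  # neuropil correction: 10 - 0.7 * 10 = 3, constant -> zeros
  f <- matrix(10, 1, 5)
  expect_equal(as.vector(compute_dff(
    axon_recording(f, neuropil = f, frame_rate = 30,
                   schedule = empty_schedule()))), rep(0, 5))
  # degenerate (non-positive mean) ROI excluded with a log message
  m <- rbind(c(1, 1, 2), c(0, 0, 0))
  expect_message(d <- compute_dff(m), "excluded")
  expect_true(all(is.na(d[2, ])))
  expect_identical(attr(d, "excluded"), 2L)
})

test_that("dF/F is invariant to rescaling the raw fluorescence", {
  set.seed(21)
  f <- matrix(abs(rnorm(200, 5)), 4, 50)
  for (c_scale in c(0.2, 3, 1000)) {
    expect_equal(compute_dff(c_scale * f), compute_dff(f),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("trial windows span -2 s to +6 s and drop edge trials", {
  dff <- matrix(0, 1, 30 * 20)
  sched <- manual_schedule(c("sound", "light"), c(1, 10))
  expect_message(tw <- trial_windows(dff, sched, 30), "dropped")
  expect_identical(tw$dropped, 1L)
  expect_equal(dim(tw$segments), c(1, 1, 240))
  # onset at 10 s, 30 Hz: window covers frames for [8 s, 16 s)
  expect_equal(tw$pre_frames, 60)
  t_first <- (10 * 30 - 60) / 30  # time of first window frame
  expect_equal(t_first, 8)

  # two identical trials (far enough apart that tails have fully decayed):
  # per-type average equals either segment
  dff2 <- matrix(make_trace(c(10, 110), 30 * 120, amplitude = 1), nrow = 1)
  sch2 <- manual_schedule(c("sound", "sound"), c(10, 110))
  tw2 <- trial_windows(dff2, sch2, 30)
  avg <- type_averages(tw2)
  expect_equal(as.vector(avg$sound), tw2$segments[1, 1, ],
               tolerance = 1e-12)
})

test_that("responsiveness testing flags tuned types and skips sparse ones", {
  set.seed(31)
  n_types <- 4
  onsets <- cumsum(runif(60, 8, 11))
  types <- rep(c("whisker", "sound", "light", "blank"), 15)
  sched <- manual_schedule(types, onsets)
  tr <- make_trace(onsets[types == "whisker"], round((max(onsets) + 8) * 30),
                   amplitude = 0.4, noise_sd = 0.1, seed = 31)
  null_tr <- make_trace(numeric(0), round((max(onsets) + 8) * 30),
                        noise_sd = 0.1, seed = 32)
  dff <- compute_dff(rbind(tr, null_tr))
  tw <- trial_windows(dff, sched, 30)
  resp <- responsiveness_test(tw, alpha = 0.01)
  expect_true("whisker" %in% resp$responsive_types[[1]])
  expect_false("sound" %in% resp$responsive_types[[1]])
  expect_length(resp$responsive_types[[2]], 0)

  # a type with fewer than 3 trials is untestable (NA p)
  sparse_sched <- manual_schedule(c(rep("sound", 10), "light", "light"),
                                  cumsum(runif(12, 8, 11)))
  sparse_dff <- compute_dff(matrix(
    make_trace(numeric(0), 30 * 150, noise_sd = 0.1, seed = 33), nrow = 1))
  tw_sp <- trial_windows(sparse_dff, sparse_sched, 30)
  r_sp <- responsiveness_test(tw_sp)
  expect_true(is.na(r_sp$p[1, "light"]))
  expect_false(is.na(r_sp$p[1, "sound"]))
})

test_that("sensory taxonomy matches the spec's worked patterns", {
  expect_equal(classify_sensory(c("sound", "sound+light", "sound+whisker",
                                  "sound+light+whisker"))$sensory_class,
               "unisensory")
  one <- classify_sensory("sound")
  expect_equal(one$sensory_class, "multisensory")
  expect_equal(one$modal_category, "exclusively_unimodal")
  mm <- classify_sensory("sound+light")
  expect_equal(mm$sensory_class, "multisensory")
  expect_equal(mm$modal_category, "exclusively_multimodal")
  none <- classify_sensory(character(0))
  expect_equal(none$sensory_class, "non_responsive")
  expect_equal(none$modal_category, "none")
  # blank never changes the call
  expect_equal(classify_sensory(c("blank", "sound+light")),
               classify_sensory("sound+light"))
})

test_that("trial response probabilities equal a recount of thresholded AUCs", {
  set.seed(41)
  onsets <- cumsum(runif(40, 8, 11))
  types <- sample(c("sound", "light"), 40, replace = TRUE)
  sched <- manual_schedule(types, onsets)
  dff <- compute_dff(rbind(
    make_trace(onsets[types == "sound"], round((max(onsets) + 8) * 30),
               amplitude = 0.5, noise_sd = 0.1, seed = 41),
    make_trace(numeric(0), round((max(onsets) + 8) * 30),
               noise_sd = 0.1, seed = 42)))
  tw <- trial_windows(dff, sched, 30)
  rp <- trial_response_probability(tw)
  # recount oracle
  thr <- mean(rp$auc) + sd(as.vector(rp$auc))
  expect_equal(rp$threshold, thr)
  for (a in 1:2) {
    for (ty in colnames(rp$probability)) {
      idx <- which(tw$trial_type == ty)
      expect_equal(unname(rp$probability[a, ty]), mean(rp$auc[a, idx] > thr))
    }
  }

  # degenerate pool: all AUCs equal -> nothing exceeds mean + 0 SD
  flat <- matrix(0.5, 2, length(make_trace(numeric(0), 30 * 60)))
  twf <- trial_windows(flat, manual_schedule(rep("sound", 4),
                                             c(10, 20, 30, 40)), 30)
  rpf <- trial_response_probability(twf)
  expect_true(all(rpf$probability[, "sound"] == 0))

  # saturation: a huge response on every sound trial
  expect_equal(unname(rp$probability[1, "sound"]), 1)
})

test_that("population tests match rank arithmetic and handle degeneracy", {
  groups <- list(a = c(1.1, 2.2, 3.3), b = c(4.4, 5.5, 6.6),
                 c = c(0.5, 7.7, 8.8))
  pm <- matrix(NA_real_, 3, 3, dimnames = list(NULL, names(groups)))
  for (j in 1:3) pm[, j] <- groups[[j]]
  pt <- population_tests(pm)
  expect_equal(pt$kruskal$H, kruskal_oracle_h(groups), tolerance = 1e-12)

  # all groups identical -> H = 0, p = 1
  same <- matrix(rep(c(1, 2, 3), 3), 3, 3,
                 dimnames = list(NULL, c("x", "y", "z")))
  pt0 <- population_tests(same)
  expect_equal(pt0$kruskal$H, 0, tolerance = 1e-12)
  expect_equal(pt0$kruskal$p, 1, tolerance = 1e-6)

  # zero-variance session means -> r absent
  pt_r <- population_tests(pm, session_index = 1:5,
                           session_means = rep(0.3, 5))
  expect_true(is.na(pt_r$pearson$r))
  pt_r2 <- population_tests(pm, session_index = 1:5,
                            session_means = c(0.1, 0.3, 0.2, 0.4, 0.5))
  expect_equal(pt_r2$pearson$r,
               cor(1:5, c(0.1, 0.3, 0.2, 0.4, 0.5)), tolerance = 1e-12)
})

test_that("analyze_axons recovers tuned axons on a small synthetic cohort", {
  cfg <- sim_config(seed = 51, n_units = 30, n_trials = 120,
                    transient_amplitude = 0.3)
  truth <- make_axon_truth(cfg, respond_prob = 1)
  rec <- simulate_axon_population(cfg, make_stimulus_schedule(cfg), truth)
  prof <- analyze_axons(rec)
  called <- prof$sensory_class != "non_responsive"
  true_resp <- truth$label != "non_responsive"
  expect_gt(mean(called == true_resp), 0.9)
})
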