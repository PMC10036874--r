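test_that("simulated conductance traces recover the injected amplitude", {
  s <- build_acquisition_schedule("imagery_acquisition", "p01", seed = 1)
  run <- s[s$run_index == 2, ]
  cfg <- synth_config(scr_amp_csplus = 0.5, scr_amp_csminus = 0.5,
                      scr_zero_prob = 0, scr_noise_sd = 0)
  tr <- simulate_scr_trace(run, cfg, seed = 4, run_duration = 218)
  sc <- score_run(tr, run)
  expect_equal(sc$raw_amplitude, rep(0.5, 12), tolerance = 0.02)

  # zero amplitude, zero noise: every trial scores zero
  cfg0 <- synth_config(scr_amp_csplus = 0, scr_amp_csminus = 0,
                       scr_zero_prob = 0, scr_noise_sd = 0)
  tr0 <- simulate_scr_trace(run, cfg0, seed = 4, run_duration = 218)
  expect_true(all(score_run(tr0, run)$raw_amplitude == 0))

  # seeded determinism
  tr2 <- simulate_scr_trace(run, cfg, seed = 4, run_duration = 218)
  expect_identical(tr$values, tr2$values)
  expect_equal(length(tr$values), 218 * cfg$sampling_rate)
  expect_true(all(tr$values >= 0))
})

test_that("conditioned-modality CS+ evokes the largest mean response", {
  s <- build_acquisition_schedule("imagery_acquisition", "p01", seed = 6)
  run <- s[s$run_index == 3, ]
  cfg <- synth_config(scr_zero_prob = 0, scr_noise_sd = 0)
  tr <- simulate_scr_trace(run, cfg, seed = 9, run_duration = 218)
  sc <- score_run(tr, run)
  m <- tapply(sc$raw_amplitude, paste(sc$modality, sc$cs_type), mean)
  expect_gt(m[["imagine CSplus"]], m[["imagine CSminus"]])
  expect_gt(m[["imagine CSplus"]], m[["view CSplus"]])     # partial generalization
  expect_gte(m[["view CSplus"]], m[["view CSminus"]])
})

test_that("pattern datasets carry one row per analysis trial and share directions by design", {
  cfg <- synth_config(shared_fraction = 0.6)
  s <- build_acquisition_schedule("imagery_acquisition", "p01", seed = 2)
  pd <- simulate_pattern_dataset(s, cfg, seed = 3)
  expect_s3_class(pd, "pattern_dataset")
  expect_equal(nrow(pd$X), 48)           # 24 imagine + 24 view analysis trials
  expect_equal(ncol(pd$X), cfg$roi_n_voxels)
  expect_true(all(is.finite(pd$X)))
  expect_equal(unname(table(pd$labels$cs_type)), array(c(24L, 24L)))
  # determinism
  pd2 <- simulate_pattern_dataset(s, cfg, seed = 3)
  expect_identical(pd$X, pd2$X)
  # the two modality directions overlap by exactly shared_fraction
  for (sf in c(0, 0.4, 1)) {
    lat <- participant_latents(synth_config(shared_fraction = sf), "pZ", seed = 5)
    expect_equal(sum(lat$u_view * lat$u_imagine), sf, tolerance = 1e-10)
    expect_equal(sum(lat$u_view^2), 1, tolerance = 1e-10)
  }
})

test_that("pattern separation matches the Gaussian two-class closed form", {
  # a classifier using the TRUE direction attains accuracy Phi(d/2);
  # Monte-Carlo over participants at d = 2 (Phi(1) = 0.841)
  cfg <- synth_config(pattern_effect = 2, effect_rel_sd = 0, shared_fraction = 1)
  accs <- vapply(1:8, function(i) {
    pid <- sprintf("p%02d", i)
    lat <- participant_latents(cfg, pid, seed = 7)
    s <- build_acquisition_schedule("imagery_acquisition", pid, seed = i)
    pd <- simulate_pattern_dataset(s, cfg, seed = 100 + i, latents = lat)
    proj <- drop(pd$X %*% lat$u_imagine)
    mean((proj > 0) == (pd$labels$cs_type == "CSplus"))
  }, 0)
  expect_equal(mean(accs), pnorm(1), tolerance = 0.035)
})

test_that("zero pattern effect leaves decoding at chance", {
  cfg <- synth_config(pattern_effect = 0, n_participants = 4)
  accs <- vapply(1:6, function(i) {
    p <- simulate_participant(cfg, sprintf("p%02d", i), seed = 40 + i)
    tr <- subset_patterns(p$patterns$imagery_acquisition, modality = "imagine")
    te <- subset_patterns(p$patterns$visual_acquisition, modality = "view")
    cross_classify(tr, te)$accuracy
  }, 0)
  expect_equal(mean(accs), 0.5, tolerance = 0.12)
})

test_that("cross-modality transfer grows with the shared fraction", {
  grid <- c(0, 0.5, 1)
  mean_acc <- vapply(grid, function(sf) {
    cfg <- synth_config(pattern_effect = 4, shared_fraction = sf,
                        effect_rel_sd = 0)
    mean(vapply(1:6, function(i) {
      p <- simulate_participant(cfg, sprintf("p%02d", i), seed = 70 + i)
      tr <- subset_patterns(p$patterns$imagery_acquisition, modality = "imagine")
      te <- subset_patterns(p$patterns$visual_acquisition, modality = "view")
      cross_classify(tr, te)$accuracy
    }, 0))
  }, 0)
  expect_true(all(diff(mean_acc) > -0.02))   # non-decreasing up to noise
  expect_gt(mean_acc[3], mean_acc[1] + 0.2)  # and substantially so overall
})

test_that("BOLD runs are exact in the noiseless limit and AR(1)-correlated otherwise", {
  s <- build_acquisition_schedule("imagery_acquisition", "p01", seed = 3)
  run <- s[s$run_index == 1, ]
  cfg <- synth_config(bold_noise_sd = 0)
  sim <- simulate_bold_run(run, cfg, seed = 5, n_voxels = 6, run_duration = 218)
  est <- estimate_trial_betas(sim$Y, sim$design, normalize = FALSE)
  expect_equal(est$all_beta, sim$true_beta, tolerance = 1e-10,
               ignore_attr = TRUE)

  # all-zero true betas, zero noise: a flat zero series
  zero <- simulate_bold_run(run, cfg, seed = 5, n_voxels = 3,
                            true_beta = matrix(0, ncol(sim$design$X), 3),
                            run_duration = 218)
  expect_true(all(zero$Y == 0))

  # white noise has near-zero lag-1 autocorrelation, AR(1) noise does not
  ar0 <- synth_config(bold_noise_sd = 1, ar1_coef = 0)
  sim0 <- simulate_bold_run(run, ar0, seed = 8, n_voxels = 40,
                            true_beta = matrix(0, ncol(sim$design$X), 40),
                            run_duration = 218)
  r1 <- mean(apply(sim0$Y, 2, function(y) cor(y[-1], y[-length(y)])))
  expect_lt(abs(r1), 0.08)
  ar5 <- synth_config(bold_noise_sd = 1, ar1_coef = 0.5)
  sim5 <- simulate_bold_run(run, ar5, seed = 8, n_voxels = 40,
                            true_beta = matrix(0, ncol(sim$design$X), 40),
                            run_duration = 218)
  r5 <- mean(apply(sim5$Y, 2, function(y) cor(y[-1], y[-length(y)])))
  expect_equal(r5, 0.5, tolerance = 0.1)
})

test_that("Likert ratings stay on the 7-point scale and track the shift", {
  cfg <- synth_config(n_participants = 30)
  r <- simulate_ratings(cfg, seed = 21)
  expect_equal(nrow(r), 30 * 8)
  expect_true(all(r$rating %in% 1:7))
  expect_identical(r, simulate_ratings(cfg, seed = 21))

  # degenerate config: no noise, no shift, latent mean 4 -> all ratings 4
  flat <- synth_config(rating_shift = 0, rating_subject_sd = 0,
                       rating_noise_sd = 0)
  expect_true(all(simulate_ratings(flat, seed = 1)$rating == 4))

  # a large shift orders the condition medians
  big <- synth_config(n_participants = 40, rating_shift = 2.5)
  rb <- simulate_ratings(big, seed = 3)
  cond <- rb$modality == vapply(rb$phase, conditioned_modality, "")
  expect_gt(median(rb$rating[cond & rb$cs_type == "CSplus"]),
            median(rb$rating[cond & rb$cs_type == "CSminus"]))
})
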