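test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  bad <- matrix(0.25, 4, 4)
  expect_error(sim_config(transition = bad), "diagonal")
  bad2 <- matrix(1 / 3, 4, 4); diag(bad2) <- 0; bad2[1, 2] <- 1
  expect_error(sim_config(transition = bad2), "sum to 1")
  expect_error(sim_config(snr = 0), "snr")
  expect_error(sim_config(dur_mean_ms = -5), "> 0")
  expect_error(sim_config(n_hp = 0), "cohort sizes")
})

test_that("state sequences are reproducible and degenerate cases work", {
  cfg <- sim_config(length_s = 10)
  a <- sample_state_sequence(cfg, seed = 5)
  b <- sample_state_sequence(cfg, seed = 5)
  expect_identical(a, b)
  expect_true(all(a %in% 1:4))
  one <- sim_config(K = 1, transition = matrix(0, 1, 1))
  expect_identical(unique(sample_state_sequence(one, n_samples = 100)), 1L)
  M <- cfg$transition; M[1, 2] <- 0.9
  expect_error(sample_state_sequence(cfg, transition = M), "stochastic")
})

test_that("run lengths and transition shares follow the configured laws", {
  cfg <- sim_config(length_s = 600)
  lab <- sample_state_sequence(cfg, seed = 42)
  r <- rle(lab)
  mean_run_ms <- mean(r$lengths) * 1000 / cfg$sfreq
  expect_gt(mean_run_ms, 90); expect_lt(mean_run_ms, 110)
  # hand-count the 12 transition shares
  from <- r$values[-length(r$values)]; to <- r$values[-1L]
  share <- table(factor(from, 1:4), factor(to, 1:4)) / length(from)
  off <- share[row(share) != col(share)]
  expect_true(all(abs(off - 1 / 12) <= 0.02))
})

test_that("rendering hits the requested SNR and is identifiable", {
  cfg <- sim_config(length_s = 60, snr = 5)
  tm <- canonical_templates()
  lab <- sample_state_sequence(cfg, seed = 3)
  rec <- render_eeg(lab, tm, cfg, keep_components = TRUE, seed = 4)
  cmp <- attr(rec, "components")
  snr_hat <- sqrt(mean(cmp$clean^2)) / sqrt(mean(cmp$noise^2))
  expect_gte(snr_hat, 4.75); expect_lte(snr_hat, 5.25)

  # noiseless rendering: backfitting the generating templates is exact
  cfg0 <- sim_config(length_s = 5, snr = Inf)
  lab0 <- sample_state_sequence(cfg0, seed = 6)
  rec0 <- render_eeg(lab0, tm, cfg0, seed = 7)
  expect_identical(backfit(rec0, tm)$labels, lab0)

  # zero templates -> pure noise, GFP fluctuating around the noise level
  recz <- render_eeg(lab0, tm * 0, cfg, seed = 8)
  g <- compute_gfp(recz)
  expect_gt(sd(recz$data), 0.9)
  expect_equal(mean(g$gfp), 1, tolerance = 0.1)
})

test_that("every noiseless sample matches its generating template exactly", {
  cfg <- sim_config(length_s = 2, snr = Inf)
  tm <- canonical_templates()
  lab <- sample_state_sequence(cfg, seed = 13)
  rec <- render_eeg(lab, tm, cfg, seed = 14)
  cc <- abs(microstatr:::map_template_corr(rec$data, tm))
  expect_equal(unname(cc[cbind(lab, seq_along(lab))]),
               rep(1, length(lab)), tolerance = 1e-9)
})

test_that("cohorts are deterministic with the clinical group structure", {
  cfg <- sim_config(n_hp = 3, n_lp = 4, length_s = 4, seed = 17)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$recordings[[5]]$data, b$recordings[[5]]$data)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$ground_truth$metrics, b$ground_truth$metrics)

  expect_equal(sum(a$subjects$group == "HP"), 3L)
  expect_true(all(a$subjects$nrs[a$subjects$group == "HP"] %in% 4:10))
  expect_true(all(a$subjects$nrs[a$subjects$group == "LP"] %in% 0:3))

  d <- sim_config()
  expect_equal(d$n_hp, 21L)
  expect_equal(d$n_lp, 45L)
})

test_that("zero group effect means identical generative parameters", {
  cfg <- sim_config(effect_d = 0)
  expect_equal(microstatr:::calibrate_bias(cfg), 0)
  M <- microstatr:::bias_transition(cfg$transition, exp(0))
  expect_equal(M, cfg$transition)
})

test_that("true metrics are recomputable from the stored true labels", {
  cfg <- sim_config(n_hp = 1, n_lp = 1, length_s = 5, seed = 23)
  coh <- simulate_cohort(cfg)
  m <- compute_metrics(coh$ground_truth$labels[[2]], sfreq = cfg$sfreq,
                       classes = c("A", "B", "C", "D"), subject = "S02")
  expect_equal(m, coh$ground_truth$metrics[2, ], ignore_attr = TRUE)
})
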