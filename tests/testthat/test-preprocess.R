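sine_rec <- function(freq, sfreq = 500, secs = 4, n_ch = 4, amp = 1) {
  tt <- (seq_len(secs * sfreq) - 1) / sfreq
  recording(matrix(rep(amp * sin(2 * pi * freq * tt), each = n_ch), n_ch),
            sfreq = sfreq, labels = paste0("ch", seq_len(n_ch)))
}

trim <- function(rec, secs = 1) {
  i <- seq(rec$sfreq * secs, ncol(rec$data) - rec$sfreq * secs)
  rec$data[, i, drop = FALSE]
}

rms <- function(x) sqrt(mean(x^2))

test_that("band-pass removes DC and preserves the alpha band", {
  dc <- recording(matrix(5, 4, 2000), 500, labels = paste0("c", 1:4))
  out <- pp_bandpass(dc)
  expect_lt(max(abs(trim(out))), 1e-3 * 5)

  s10 <- sine_rec(10)
  out10 <- pp_bandpass(s10)
  expect_equal(rms(trim(out10)), rms(trim(s10)), tolerance = 0.05)
})

test_that("band-pass attenuates the stopband by at least 20 dB", {
  s150 <- sine_rec(150, sfreq = 1000)
  out <- pp_bandpass(s150)
  expect_lt(rms(trim(out)) / rms(trim(s150)), 10^(-20 / 20))
  expect_error(pp_bandpass(sine_rec(10), high = 300), "Nyquist")
})

test_that("notch kills 50 Hz, spares 10 Hz, and maps zero to zero", {
  s50 <- sine_rec(50)
  expect_lt(rms(trim(pp_notch(s50))) / rms(trim(s50)), 0.03)
  s10 <- sine_rec(10)
  expect_equal(rms(trim(pp_notch(s10))), rms(trim(s10)), tolerance = 0.05)
  z <- recording(matrix(0, 4, 2000), 500, labels = paste0("c", 1:4))
  expect_equal(max(abs(pp_notch(z)$data)), 0)
})

test_that("resampling halves counts, rescales annotations, keeps waveform", {
  r <- sine_rec(10, sfreq = 1000, secs = 10)
  r$bad_segments <- microstatr:::normalize_segments(cbind(1000, 2000), 10000)
  out <- pp_resample(r, 500)
  expect_equal(out$sfreq, 500)
  expect_equal(ncol(out$data), 5000)
  expect_equal(unname(out$bad_segments), matrix(c(500, 1000), 1))
  ideal <- sin(2 * pi * 10 * (seq_len(5000) - 1) / 500)
  i <- 500:4500
  xc <- max(ccf(out$data[1, i], ideal[i], lag.max = 5,
                plot = FALSE)$acf)
  expect_gte(xc, 0.999)
  expect_error(pp_resample(r, 2000), "upsampling")
})

test_that("mastoid re-referencing subtracts the average and is invertible", {
  m <- standard_montage(include_mastoids = TRUE)
  dat <- matrix(rnorm(32 * 50), 32, dimnames = list(m$labels, NULL))
  dat["M1", ] <- 0; dat["M2", ] <- 0
  r <- recording(dat, 500, labels = m$labels)
  out <- pp_rereference(r)
  expect_equal(out$data, dat[setdiff(m$labels, c("M1", "M2")), ])
  expect_false(any(c("M1", "M2") %in% out$labels))

  dat["M1", ] <- 2; dat["M2", ] <- 4
  r2 <- recording(dat, 500, labels = m$labels)
  out2 <- pp_rereference(r2)
  expect_equal(out2$data, dat[out2$labels, ] - 3)
  # invertibility from the stored reference
  rebuilt <- sweep(out2$data, 2L, attr(out2, "reference"), "+")
  expect_equal(rebuilt, dat[out2$labels, ])
  expect_error(pp_rereference(recording(dat[1:30, ], 500)), "missing")
})

test_that("bad-channel interpolation follows the >3 exclusion rule", {
  mont <- standard_montage()
  dat <- matrix(rnorm(30 * 40), 30, dimnames = list(mont$labels, NULL))
  r4 <- recording(dat, 500, bad_channels = c("F3", "F4", "P3", "P4"))
  expect_error(pp_interpolate_bad(r4, mont), class = "subject_excluded")

  # one bad channel whose nearest neighbours are all constant 7
  dat7 <- dat
  dat7[c("FCz", "CPz", "Fz", "C3", "C4", "Pz"), ] <- 7
  rb <- recording(dat7, 500, bad_channels = "Cz")
  out <- pp_interpolate_bad(rb, mont)
  expect_equal(unname(out$data["Cz", ]), rep(7, 40))
  expect_length(out$bad_channels, 0L)

  r0 <- recording(dat, 500)
  expect_identical(pp_interpolate_bad(r0, mont)$data, r0$data)
})

test_that("preprocessing barely perturbs microstate labels of clean data", {
  cfg <- sim_config(n_hp = 1, n_lp = 1, length_s = 20, seed = 31)
  tm <- canonical_templates()
  lab <- sample_state_sequence(cfg, seed = 31)
  rec <- render_eeg(lab, tm, cfg, seed = 32)
  raw_fit <- backfit(rec, tm)
  pp_fit <- backfit(preprocess(rec), tm)
  expect_lt(mean(raw_fit$labels != pp_fit$labels), 0.05)
})

test_that("preprocessing chain is deterministic and keeps channel order", {
  cfg <- sim_config(n_hp = 1, n_lp = 1, length_s = 5, seed = 9)
  rec <- render_eeg(sample_state_sequence(cfg, seed = 9),
                    canonical_templates(), cfg, seed = 10)
  a <- preprocess(rec); b <- preprocess(rec)
  expect_identical(a$data, b$data)
  expect_identical(a$labels, rec$labels)
})
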