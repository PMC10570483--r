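test_that("toy label sequence reproduces the hand-enumerated metrics", {
  lab <- c(1L, 1L, 2L, 2L, 2L, 1L, 3L, 3L, 4L, 4L)  # A A B B B A C C D D
  m <- compute_metrics(lab, sfreq = 10)
  expect_equal(m$cov_A, 30); expect_equal(m$cov_B, 30)
  expect_equal(m$cov_C, 20); expect_equal(m$cov_D, 20)
  expect_equal(m$dur_A, 150); expect_equal(m$dur_B, 300)
  expect_equal(m$dur_C, 200); expect_equal(m$dur_D, 200)
  expect_equal(m$occ_A, 2); expect_equal(m$occ_B, 1)
  expect_equal(m$occ_C, 1); expect_equal(m$occ_D, 1)
  expect_equal(m$tr_AB, 25); expect_equal(m$tr_BA, 25)
  expect_equal(m$tr_AC, 25); expect_equal(m$tr_CD, 25)
  other <- grep("^tr_", names(m), value = TRUE)
  other <- setdiff(other, c("tr_AB", "tr_BA", "tr_AC", "tr_CD"))
  expect_true(all(m[other] == 0))
})

test_that("coverage and transition percentages sum to 100", {
  set.seed(12)
  for (i in 1:5) {
    lab <- sample.int(4L, 500, TRUE)
    m <- compute_metrics(lab, sfreq = 100)
    expect_equal(sum(m[grep("^cov_", names(m))]), 100, tolerance = 1e-6)
    expect_equal(sum(m[grep("^tr_", names(m))]), 100, tolerance = 1e-6)
  }
})

test_that("a constant sequence has one run and no transitions", {
  expect_warning(compute_metrics(rep(2L, 50), sfreq = 10,
                                 classes = c("A", "B")),
                 "no transitions")
  m <- suppressWarnings(compute_metrics(rep(2L, 50), sfreq = 10,
                                        classes = c("A", "B")))
  expect_equal(m$cov_B, 100)
  expect_equal(m$occ_B, 1 / 5)
  expect_equal(m$dur_B, 5000)
  expect_true(all(m[grep("^tr_", names(m))] == 0))
  expect_true(attr(m, "no_transitions"))
})

test_that("runs and transitions never cross a mask boundary", {
  lab <- c(1L, 1L, NA, NA, 1L, 2L, NA, 3L, 3L, 3L)   # 7 unmasked samples
  m <- compute_metrics(lab, sfreq = 10)
  # spans: [A A] [A B] [C C C]: runs A(2), A(1), B(1), C(3)
  expect_equal(m$occ_A, 2 / 0.7)
  expect_equal(m$dur_A, 150)
  expect_equal(m$cov_C, 100 * 3 / 7)
  # only transition inside a span is A -> B
  expect_equal(m$tr_AB, 100)
  expect_equal(sum(m[grep("^tr_", names(m))]), 100)
})

test_that("backfit labels data generated from a single template as that class", {
  tm <- canonical_templates()
  env <- 0.3 + abs(sin(seq(0, 20, length.out = 400)))
  dat <- tm[, "C"] %o% (env * rep(c(1, -1), 200))   # any sign, any scale
  rec <- recording(dat, 500, labels = rownames(tm))
  bf <- backfit(rec, tm)
  expect_true(all(bf$labels == 3L))
  expect_equal(bf$gev, 1, tolerance = 1e-12)
})

test_that("backfit ties go to the lowest class and zero samples inherit", {
  # orthogonal synthetic templates so the C/D tie is exact in floating point
  base <- matrix(0, 8, 4, dimnames = list(paste0("e", 1:8),
                                          c("A", "B", "C", "D")))
  base[cbind(1:8, rep(1:4, each = 2))] <- c(1, -1)
  tm <- microstatr:::normalize_maps(base)
  half <- tm[, "C"] + tm[, "D"]        # equal |corr| with C and D
  dat <- cbind(tm[, "D"], half, 0 * half, tm[, "B"])
  rec <- recording(dat, 100, labels = rownames(tm))
  bf <- backfit(rec, tm)
  expect_equal(bf$labels, c(4L, 3L, 3L, 2L))  # tie -> C < D; zero inherits
  dat0 <- cbind(0 * half, tm[, "C"])
  bf0 <- backfit(recording(dat0, 100, labels = rownames(base)), tm)
  expect_equal(bf0$labels, c(3L, 3L))          # leading zero takes next label
})

test_that("backfit is polarity and scale invariant", {
  cfg <- sim_config(n_hp = 1, n_lp = 1, length_s = 5, seed = 21)
  tm <- canonical_templates()
  rec <- render_eeg(sample_state_sequence(cfg, seed = 21), tm, cfg, seed = 2)
  a <- backfit(rec, tm)
  rec_f <- rec; rec_f$data <- -3 * rec_f$data
  b <- backfit(rec_f, tm)
  expect_identical(a$labels, b$labels)
})

test_that("masked samples carry no labels or correlations", {
  tm <- canonical_templates()
  dat <- tm[, c(1, 2, 3, 4, 1, 2)]
  rec <- recording(dat, 100, labels = rownames(tm),
                   bad_segments = cbind(2, 4))
  bf <- backfit(rec, tm)
  expect_true(all(is.na(bf$labels[3:4])))
  expect_true(all(is.na(bf$corr[3:4])))
  expect_equal(bf$labels[c(1, 2, 5, 6)], c(1L, 2L, 1L, 2L))
  rec_all <- recording(dat, 100, labels = rownames(tm),
                       bad_segments = cbind(0, 6))
  expect_error(backfit(rec_all, tm), "no unmasked")
})
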