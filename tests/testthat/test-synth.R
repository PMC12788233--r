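# 12-lead simulator: beat model, lead projections, record/dataset
# generation, ground-truth metadata.

test_that("beat morphology validates its invariants", {
  expect_error(beat_morphology(qrs_duration_ms = 0), "qrs_duration")
  expect_error(beat_morphology(r_amp = -1), "R amplitude")
  expect_error(beat_morphology(p_width = -5), "width")
  m <- beat_morphology(90)
  expect_identical(m$wave, c("P", "Q", "R", "S", "T"))
  expect_true(all(diff(m$center) > 0))
})

test_that("generate_beat evaluates the Gaussian-bump sum on its grid", {
  fs <- 500
  zero <- generate_beat(beat_morphology(90, r_amp = 1e-300, q_amp = 0,
                                        s_amp = 0, p_amp = 0, t_amp = 0), fs)
  expect_lt(max(abs(zero$values)), 1e-12)

  # single R bump of 1 mV centered at 0 peaks at exactly 1 at the center
  m <- beat_morphology(90, r_amp = 1, q_amp = 0, s_amp = 0, p_amp = 0,
                       t_amp = 0)
  b <- generate_beat(m, fs)
  expect_equal(max(b$values), 1, tolerance = 1e-12)
  expect_equal(b$offsets[which.max(b$values)], 0)

  # R 1.0 / S -0.3: minimum matches the closed-form Gaussian sum near the
  # S center (independent oracle: direct evaluation of the formula)
  m2 <- beat_morphology(90, r_amp = 1, s_amp = -0.3, q_amp = 0, p_amp = 0,
                        t_amp = 0)
  b2 <- generate_beat(m2, fs)
  t_ms <- b2$offsets / fs * 1000
  oracle <- sapply(t_ms, function(t)
    sum(m2$amp * exp(-(t - m2$center)^2 / (2 * m2$width^2))))
  expect_equal(b2$values, oracle, tolerance = 1e-12)
  s_center_samp <- round(m2$center[m2$wave == "S"] / 1000 * fs)
  expect_lte(abs(b2$offsets[which.min(b2$values)] - s_center_samp), 1)
  expect_equal(min(b2$values), min(oracle), tolerance = 1e-12)

  expect_error(generate_beat(beat_morphology(90), fs = 0), "fs")
})

test_that("frontal projection satisfies the Einthoven/Goldberger identities", {
  set.seed(1)
  dip <- rbind(rnorm(50), rnorm(50))
  L <- project_frontal_leads(dip, theta = 33)
  expect_equal(L["III", ], L["II", ] - L["I", ], tolerance = 1e-12)
  expect_equal(L["aVR", ], -(L["I", ] + L["II", ]) / 2, tolerance = 1e-12)
  expect_equal(L["aVL", ], L["I", ] - L["II", ] / 2, tolerance = 1e-12)
  expect_equal(L["aVF", ], L["II", ] - L["I", ] / 2, tolerance = 1e-12)

  # zero dipole -> all leads zero
  expect_true(all(project_frontal_leads(matrix(0, 2, 10)) == 0))

  # unit dipole along 0 deg: Lead I carries the full magnitude, II = cos(60)
  u <- project_frontal_leads(rbind(1, 0), theta = 0)
  expect_equal(unname(u["I", 1]), 1)
  expect_equal(unname(u["II", 1]), cos(pi / 3))
  # rotating the dipole to the lead-II direction maximizes II
  u2 <- project_frontal_leads(rbind(1, 0), theta = 60)
  expect_equal(unname(u2["II", 1]), 1, tolerance = 1e-12)
  expect_error(project_frontal_leads(rbind(NA, 1)), "finite")
})

test_that("generate_record places beats at the stated rate with ground truth", {
  p <- subject_params(theta_r = 45, theta_t = 40, heart_rate = 72)
  r <- generate_record(p, seed = 7)
  expect_s3_class(r, "ecg_record")
  expect_identical(rownames(r$signal), LEAD_NAMES)
  expect_equal(ncol(r$signal), 5000)
  expect_equal(r$meta$QRSCount, 12)           # floor(10 s * 72 / 60)
  expect_equal(r$meta$VentricularRate, 72)
  expect_equal(r$meta$RAxis, 45)

  # determinism: identical seed, identical signal; different seeds differ
  # once the record has stochastic components
  r2 <- generate_record(p, seed = 7)
  expect_identical(r$signal, r2$signal)
  pn <- subject_params(theta_r = 45, theta_t = 40, heart_rate = 72,
                       noise_amp = 0.02, rr_jitter = 0.02)
  expect_identical(generate_record(pn, seed = 7)$signal,
                   generate_record(pn, seed = 7)$signal)
  expect_false(identical(generate_record(pn, seed = 7)$signal,
                         generate_record(pn, seed = 8)$signal))
  expect_error(generate_record(p), "seed")

  # theta_r = 45 discretizes to Normal on the emitted metadata
  expect_equal(unname(discretize_metadata(r$meta)[["RAxis"]]), "Normal")
})

test_that("generated records satisfy lead identities and recover axis/rate", {
  set.seed(3)
  for (k in 1:20) {
    th <- runif(1, -170, 170)
    p <- subject_params(theta_r = th, theta_t = runif(1, -170, 170),
                        heart_rate = runif(1, 50, 130),
                        rr_jitter = 0.02, noise_amp = 0.02)
    r <- generate_record(p, seed = 100 + k)
    s <- r$signal
    dev <- max(abs(s["III", ] - (s["II", ] - s["I", ])),
               abs(s["aVR", ] + (s["I", ] + s["II", ]) / 2),
               abs(s["aVL", ] - (s["I", ] - s["II", ] / 2)),
               abs(s["aVF", ] - (s["II", ] - s["I", ] / 2)))
    expect_lt(dev, 1e-9)
  }
  # axis recovery within +/-5 deg and exact beat count on noise-free records
  for (th in c(-120, -45, 10, 60, 150)) {
    p <- subject_params(theta_r = th, theta_t = th - 10, heart_rate = 75)
    r <- generate_record(p, seed = 11)
    expect_lt(abs(estimate_frontal_axis(r) - th), 5)
    pk <- detect_r_peaks(r$signal["II", ], r$fs)
    expect_equal(length(pk), r$meta$QRSCount)
  }
})

test_that("generate_dataset splits 70/15/15 and is seed-reproducible", {
  ds <- generate_dataset(100, seed = 2)
  expect_equal(as.vector(table(ds$split)), c(70, 15, 15))
  expect_length(ds$records, 100)
  ds2 <- generate_dataset(100, seed = 2)
  expect_identical(ds$split, ds2$split)
  expect_identical(ds$records[[17]]$signal, ds2$records[[17]]$signal)
  expect_error(generate_dataset(5, seed = 1), "n must be")
  expect_error(generate_dataset(100), "seed")
})

test_that("stratified sampling covers every metadata category", {
  ds <- memo("strat_dataset", generate_dataset(400, seed = 9, stratified = TRUE))
  cats <- t(vapply(ds$records,
                   function(r) unclass(discretize_metadata(r$meta)),
                   character(5)))
  for (f in METADATA_FEATURES)
    expect_setequal(unique(cats[, f]), ecgrecon:::METADATA_LEVELS[[f]])
})
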