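# Decimation, windowing, clinical discretization, one-hot encoding,
# metadata estimation from Lead I, dataset splitting.

test_that("direct decimation keeps every k-th sample from index 0", {
  x <- seq(0, 9)
  expect_equal(decimate(x, 5), c(0, 5))
  expect_equal(decimate(x, 1), x)
  expect_length(decimate(rnorm(5000), 5), 1000)
  m <- matrix(rnorm(120), 12)                  # 12 leads x 10 samples
  expect_equal(decimate(m, 5), m[, c(1, 6)])
  expect_equal(ncol(decimate(m, 2)), 5)
  expect_error(decimate(x, 2.5), "integer")
  expect_error(decimate(x, 0), "integer")
})

test_that("centered window extraction uses floor((T - L)/2)", {
  x <- seq_len(1000)
  w <- extract_window(x, 512)
  expect_equal(w[1], 245)                      # 0-based start 244
  expect_equal(w[512], 756)
  expect_identical(extract_window(seq_len(512), 512), seq_len(512))
  expect_equal(extract_window(seq_len(513), 512)[1], 1)   # floor(1/2) = 0
  expect_error(extract_window(seq_len(100), 512), "shorter")
  m <- matrix(seq_len(2000), 2, byrow = FALSE)
  expect_equal(dim(extract_window(m, 512)), c(2L, 512L))
})

test_that("metadata discretization matches the clinical thresholds", {
  mk <- function(ra = 45, ta = 45, vr = 72, qc = 12, qd = 90)
    list(RAxis = ra, TAxis = ta, VentricularRate = vr, QRSCount = qc,
         QRSDuration = qd)
  d <- function(raw) unclass(discretize_metadata(raw))
  expect_equal(d(mk())[["RAxis"]], "Normal")              # 45 deg
  expect_equal(d(mk(ra = -30))[["RAxis"]], "Normal")
  expect_equal(d(mk(ra = 90))[["RAxis"]], "Normal")
  expect_equal(d(mk(ra = 91))[["RAxis"]], "Right")
  expect_equal(d(mk(ra = 180))[["RAxis"]], "Right")
  expect_equal(d(mk(ra = -31))[["RAxis"]], "Left")
  expect_equal(d(mk(ra = -89.5))[["RAxis"]], "Left")
  expect_equal(d(mk(ra = -90))[["RAxis"]], "Extreme")
  expect_equal(d(mk(ra = -179))[["RAxis"]], "Extreme")
  expect_equal(d(mk(qd = 120))[["QRSDuration"]], "Prolonged")
  expect_equal(d(mk(qd = 119.9))[["QRSDuration"]], "Normal")
  expect_equal(d(mk(vr = 59))[["VentricularRate"]], "Bradycardia")
  expect_equal(d(mk(vr = 60))[["VentricularRate"]], "Normal")
  expect_equal(d(mk(vr = 100))[["VentricularRate"]], "Normal")
  expect_equal(d(mk(vr = 101))[["VentricularRate"]], "Tachycardia")
  expect_equal(d(mk(qc = 9))[["QRSCount"]], "Low")
  expect_equal(d(mk(qc = 10))[["QRSCount"]], "Normal")
  expect_equal(d(mk(qc = 16))[["QRSCount"]], "Normal")
  expect_equal(d(mk(qc = 17))[["QRSCount"]], "High")
  expect_error(discretize_metadata(mk(ra = 181)), "-180")
  expect_error(discretize_metadata(mk(ta = -180)), "-180")
  expect_error(discretize_metadata(mk(vr = -1)), "finite")
})

test_that("discretization is total: every in-range input maps to one category", {
  for (th in seq(-179, 180, by = 1)) {
    cat <- ecgrecon:::.axis_category(th)
    expect_true(cat %in% c("Normal", "Left", "Right", "Extreme"))
  }
  for (vr in seq(0, 220, by = 1)) {
    c1 <- unclass(discretize_metadata(list(RAxis = 0, TAxis = 0,
                                           VentricularRate = vr,
                                           QRSCount = 12, QRSDuration = 90)))
    expect_length(c1[["VentricularRate"]], 1)
  }
  for (qd in seq(0, 250, by = 1)) {
    c1 <- unclass(discretize_metadata(list(RAxis = 0, TAxis = 0,
                                           VentricularRate = 70,
                                           QRSCount = 12, QRSDuration = qd)))
    expect_true(c1[["QRSDuration"]] %in% c("Normal", "Prolonged"))
  }
})

test_that("one-hot encoding follows the fixed category order", {
  cats <- discretize_metadata(list(RAxis = 45, TAxis = -45,
                                   VentricularRate = 72, QRSCount = 12,
                                   QRSDuration = 130))
  v <- one_hot_metadata(cats)
  expect_length(v, 16)
  expect_equal(sum(v), 5)
  expect_equal(unname(v[1:4]), c(1, 0, 0, 0))             # RAxis Normal first
  expect_equal(unname(v[5:8]), c(0, 1, 0, 0))             # TAxis Left second
  expect_equal(unname(v[9:10]), c(0, 1))                  # QRSDuration Prolonged
  expect_length(one_hot_metadata(cats, "RAxis"), 4)
  expect_length(one_hot_metadata(cats, c("RAxis", "QRSDuration")), 6)
  expect_equal(one_hot_dim(), 16L)
  expect_equal(one_hot_dim(c("RAxis", "QRSDuration")), 6L)
  expect_error(one_hot_metadata(cats, character(0)), "non-empty")

  # injectivity over the whole category space
  grid <- expand.grid(ecgrecon:::METADATA_LEVELS, stringsAsFactors = FALSE)
  vecs <- apply(grid, 1, function(row) {
    cats <- structure(unlist(row), class = "metadata_categories")
    paste(one_hot_metadata(cats), collapse = "")
  })
  expect_equal(anyDuplicated(vecs), 0)
})

test_that("round trip: targeted generator params discretize back exactly", {
  targets <- list(
    list(f = "RAxis", val = list(theta_r = 30), cat = "Normal"),
    list(f = "RAxis", val = list(theta_r = -60), cat = "Left"),
    list(f = "RAxis", val = list(theta_r = 135), cat = "Right"),
    list(f = "RAxis", val = list(theta_r = -135), cat = "Extreme"),
    list(f = "TAxis", val = list(theta_t = 45), cat = "Normal"),
    list(f = "TAxis", val = list(theta_t = -60), cat = "Left"),
    list(f = "TAxis", val = list(theta_t = 135), cat = "Right"),
    list(f = "TAxis", val = list(theta_t = -135), cat = "Extreme"),
    list(f = "QRSDuration", val = list(qrs_duration = 90), cat = "Normal"),
    list(f = "QRSDuration", val = list(qrs_duration = 130), cat = "Prolonged"),
    list(f = "VentricularRate", val = list(heart_rate = 48), cat = "Bradycardia"),
    list(f = "VentricularRate", val = list(heart_rate = 72), cat = "Normal"),
    list(f = "VentricularRate", val = list(heart_rate = 120), cat = "Tachycardia"),
    list(f = "QRSCount", val = list(heart_rate = 48), cat = "Low"),
    list(f = "QRSCount", val = list(heart_rate = 72), cat = "Normal"),
    list(f = "QRSCount", val = list(heart_rate = 120), cat = "High"))
  for (tg in targets) {
    p <- do.call(subject_params, tg$val)
    r <- generate_record(p, seed = 31)
    cats <- discretize_metadata(r$meta)
    expect_equal(unname(cats[[tg$f]]), tg$cat,
                 label = paste(tg$f, tg$cat))
  }
})

test_that("metadata estimation from Lead I recovers count and rate", {
  p <- subject_params(theta_r = 20, heart_rate = 72)
  r <- generate_record(p, seed = 4)
  lead1 <- decimate(r$signal["I", ], 5)
  est <- estimate_metadata_from_lead1(lead1, fs = 100)
  expect_equal(est$QRSCount, 12)
  expect_equal(est$VentricularRate, 72)
  expect_true(is.na(est$RAxis) && is.na(est$TAxis))
  expect_gt(est$QRSDuration, 20)
  expect_lt(est$QRSDuration, 200)
  expect_error(estimate_metadata_from_lead1(rep(0, 1000), 100), "quality|QRS")
  expect_error(estimate_metadata_from_lead1(rnorm(50), 100), "2 s")
})

test_that("record-level split honours fractions, seed and size limits", {
  s <- split_dataset(20, seed = 1)
  expect_equal(as.vector(table(s)), c(14, 3, 3))
  expect_identical(split_dataset(20, seed = 1), s)
  expect_false(identical(split_dataset(20, seed = 2), s))
  expect_error(split_dataset(3, seed = 1), "too small")
  expect_error(split_dataset(20, fractions = c(0.5, 0.2, 0.2), seed = 1),
               "sum to 1")
  expect_error(split_dataset(20), "seed")
})

test_that("windowed pairs carry shapes, order and one-hot metadata", {
  pr <- tiny_pairs()
  n <- length(tiny_dataset()$records)
  expect_equal(dim(pr$X), c(n, 512L))
  expect_equal(dim(pr$Y), c(n, 11L, 512L))
  expect_equal(dim(pr$M), c(n, 16L))
  expect_true(all(rowSums(pr$M) == 5))
  expect_equal(pr$fs, 100)

  # target rows follow the fixed lead order: II is the first target row
  r1 <- tiny_dataset()$records[[1]]
  sig <- extract_window(decimate(r1$signal, 5), 512)
  expect_equal(pr$Y[1, 1, ], unname(sig["II", ]))
  expect_equal(pr$Y[1, 11, ], unname(sig["V6", ]))
  expect_equal(pr$X[1, ], unname(sig["I", ]))

  none <- make_windowed_pairs(tiny_dataset()$records[1:3],
                              features = character(0))
  expect_equal(ncol(none$M), 0L)
  sub <- pairs_subset(pr, "test")
  expect_equal(nrow(sub$X), sum(tiny_dataset()$split == "test"))
})
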