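# Monte Carlo dropout, predictive standard deviation, normalization,
# relative error, reliability analyses.

mk_stack <- function(samples, seed = 1L) {
  structure(list(samples = samples, mean = apply(samples, c(2, 3), mean),
                 N = dim(samples)[1], seed = seed),
            class = "mc_stack")
}

test_that("predictive_std implements the population (divisor-N) form", {
  # two passes with values 0 and 2 at one point: mean 1, sigma 1
  s <- array(0, c(2, 11, 4))
  s[2, , ] <- 2
  pr <- predictive_std(mk_stack(s))
  expect_true(all(abs(pr$sigma - 1) < 1e-14))

  # identical passes: sigma identically zero
  s2 <- array(rep(rnorm(11 * 4), each = 3), c(3, 11, 4))
  expect_true(all(predictive_std(mk_stack(s2))$sigma < 1e-14))

  # random stack vs an explicit loop over the definition
  set.seed(2)
  N <- 50
  s3 <- array(rnorm(N * 11 * 32), c(N, 11, 32))
  pr3 <- predictive_std(mk_stack(s3))
  oracle <- matrix(0, 11, 32)
  for (l in 1:11) for (t in 1:32) {
    y <- s3[, l, t]
    oracle[l, t] <- sqrt(sum((y - mean(y))^2) / N)
  }
  expect_lt(max(abs(pr3$sigma - oracle)), 1e-10)
})

test_that("normalization divides by the per-lead temporal maximum", {
  s <- array(0, c(2, 11, 3))
  pr <- predictive_std(mk_stack(s))
  pr$sigma <- matrix(rep(c(1, 2, 4), each = 11), 11, 3)
  pr <- normalize_std(pr)
  expect_equal(unname(pr$sigma_norm[1, ]), c(0.25, 0.5, 1))
  expect_equal(max(pr$sigma_norm), 1)

  pr$sigma <- matrix(3, 11, 3)                 # constant -> all ones
  expect_true(all(normalize_std(pr)$sigma_norm == 1))
  pr$sigma <- matrix(0, 11, 3)                 # zero -> all zeros, no NaN
  expect_true(all(normalize_std(pr)$sigma_norm == 0))
})

test_that("relative error follows |pred - ref| / (|ref| + eps)", {
  p <- matrix(1, 2, 3); r <- matrix(1, 2, 3)
  expect_true(all(relative_error(p, r) == 0))
  expect_equal(relative_error(matrix(2), matrix(1), eps = 0.001)[1],
               1 / 1.001, tolerance = 1e-12)
  expect_equal(relative_error(matrix(0.01), matrix(0), eps = 0.001)[1],
               10, tolerance = 1e-12)
  expect_equal(relative_error(matrix(0.5), matrix(1), eps = 0.001,
                              signed = TRUE)[1], -0.5 / 1.001,
               tolerance = 1e-12)
  expect_error(relative_error(p, r, eps = 0), "eps")
  expect_error(relative_error(p, matrix(1, 3, 2)), "shape")
})

test_that("mc_predict is seeded, validates N, and degenerates without dropout", {
  fit <- tiny_fit()
  pr <- tiny_pairs()
  st <- mc_predict(fit, pr$X[1, ], pr$M[1, ], N = 8, seed = 3)
  expect_s3_class(st, "mc_stack")
  expect_equal(dim(st$samples), c(8L, 11L, 512L))
  expect_equal(st$mean, apply(st$samples, c(2, 3), mean), tolerance = 1e-12)
  st2 <- mc_predict(fit, pr$X[1, ], pr$M[1, ], N = 8, seed = 3)
  expect_identical(st$samples, st2$samples)
  st3 <- mc_predict(fit, pr$X[1, ], pr$M[1, ], N = 8, seed = 4)
  expect_false(identical(st$samples, st3$samples))
  expect_error(mc_predict(fit, pr$X[1, ], pr$M[1, ], N = 1, seed = 1), "N")
  expect_error(mc_predict(fit, pr$X[1, ], pr$M[1, ], N = 8), "seed")

  # dropout rate 0: all passes identical, sigma identically 0
  fit0 <- ecg_reconstruct(pairs_subset(pr, 1:10), "dual",
                          tiny_config(dropout_rate = 0, epochs = 1L))
  st0 <- mc_predict(fit0, pr$X[1, ], pr$M[1, ], N = 5, seed = 1)
  expect_true(all(predictive_std(st0)$sigma < 1e-14))
})

test_that("disjoint MC seeds agree within Monte Carlo error", {
  fit <- tiny_fit()
  pr <- tiny_pairs()
  a <- predictive_std(mc_predict(fit, pr$X[2, ], pr$M[2, ], N = 300, seed = 1))
  b <- predictive_std(mc_predict(fit, pr$X[2, ], pr$M[2, ], N = 300, seed = 77))
  expect_lt(abs(mean(a$sigma) - mean(b$sigma)) / mean(a$sigma), 0.1)
})

test_that("uncertainty-error correlation is 1 for identical fields and ~0 when shuffled", {
  set.seed(4)
  mkprof <- function(sn) structure(list(sigma = sn, sigma_norm = sn),
                                   class = "uncertainty_profile")
  sn <- matrix(runif(11 * 100), 11, 100)
  rownames(sn) <- TARGET_LEADS
  r1 <- uncertainty_error_correlation(list(mkprof(sn)), list(sn))
  expect_true(all(abs(r1 - 1) < 1e-12))

  # independence: pooled n = 10^4 per lead
  profs <- lapply(1:100, function(i) mkprof(matrix(runif(11 * 100), 11, 100)))
  errs <- lapply(1:100, function(i) matrix(runif(11 * 100), 11, 100))
  r0 <- uncertainty_error_correlation(profs, errs)
  expect_true(all(abs(r0) < 0.1))

  # per-record averaging variant returns one value per lead too
  rpr <- uncertainty_error_correlation(profs[1:5], errs[1:5],
                                       per_record = TRUE)
  expect_length(rpr, 11)
})

test_that("quantile table is monotone for monotone error and flat for constant", {
  mkprof <- function(sn) structure(list(sigma = sn, sigma_norm = sn),
                                   class = "uncertainty_profile")
  sn <- matrix(seq(0, 1, length.out = 11 * 40), 11, 40)
  e <- 2 * sn + 1                               # strictly increasing in sigma
  qt <- quantile_error_table(list(mkprof(sn)), list(e))
  expect_equal(qt$quantile, paste0("Q", 1:4))
  expect_true(all(diff(qt$mean_error) > 0))
  expect_true(all(diff(qt$mean_sigma_norm) > 0))
  expect_equal(sum(qt$n), length(sn))

  e2 <- matrix(1, 11, 40)
  qt2 <- quantile_error_table(list(mkprof(sn)), list(e2))
  expect_true(all(qt2$mean_error == 1))
  expect_true(all(qt2$sd_error == 0))
})

test_that("heatmap rendering writes a non-empty image", {
  set.seed(5)
  pred <- matrix(rnorm(11 * 128), 11, 128)
  ref <- pred + rnorm(11 * 128, 0, 0.1)
  sn <- matrix(runif(11 * 128), 11, 128)
  f <- tempfile(fileext = ".png")
  render_heatmap(pred, ref, sn, f, leads = c("II", "V6"))
  expect_true(file.exists(f))
  expect_gt(file.info(f)$size, 1000)
})
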