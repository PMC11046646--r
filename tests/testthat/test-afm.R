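noiseless_spring <- function(k = 2, f_adh = 120, d0 = 50, d_max = 600, ds = 1) {
  d <- seq(0, d_max, by = ds)
  f <- ifelse(d >= d0 & d <= d0 + f_adh / k, k * (d - d0), 0)
  fd_curve(d, f)
}

noiseless_plateau <- function(fp = 220, len = 150, d0 = 50, d_max = 600) {
  d <- seq(0, d_max, by = 1)
  d1 <- d0 + fp / 30
  f <- numeric(length(d))
  f[d >= d0 & d < d1] <- 30 * (d[d >= d0 & d < d1] - d0)
  f[d >= d1 & d <= d1 + len] <- fp
  fd_curve(d, f)
}

test_that("baseline correction removes offset and drift", {
  set.seed(2)
  d <- seq(0, 600, by = 1)
  cv <- fd_curve(d, rnorm(length(d), 0, 5) + 15)
  bc <- baseline_correct(cv)
  tail_idx <- seq(541, 601)
  expect_lt(abs(median(bc$force[tail_idx])), 0.5)
  # a pure linear drift of 0.01 pN/nm is removed to < 0.001 pN/nm residual
  cv2 <- fd_curve(d, 0.01 * d)
  bc2 <- baseline_correct(cv2)
  slope <- coef(lm(bc2$force[tail_idx] ~ d[tail_idx]))[2]
  expect_lt(abs(slope), 0.001)
  # with noise on top the residual drift stays small
  cv2n <- fd_curve(d, rnorm(length(d), 0, 1) + 0.01 * d)
  slope_n <- coef(lm(baseline_correct(cv2n)$force ~ d))[2]
  expect_lt(abs(slope_n), 0.002)
  # the zero curve is a fixed point (flagged constant)
  cv3 <- fd_curve(d, rep(0, length(d)))
  bc3 <- baseline_correct(cv3)
  expect_equal(bc3$force, rep(0, length(d)))
  expect_equal(bc3$flag, "constant")
})

test_that("classification identifies the canonical signatures", {
  sp <- classify_signature(baseline_correct(noiseless_spring(5.5, 120)))
  expect_equal(sp$kind, "nanospring")
  pl <- classify_signature(baseline_correct(noiseless_plateau(220, 150)))
  expect_equal(pl$kind, "plateau")
  expect_equal(pl$plateau_force, 220, tolerance = 1e-6)
  set.seed(5)
  noise <- fd_curve(seq(0, 600, 1), rnorm(601, 0, 5))
  expect_equal(classify_signature(baseline_correct(noise))$kind, "none")
  # a long shallow rise feeding a plateau is scored as "both"
  d <- seq(0, 600, by = 1)
  f <- numeric(601)
  f[d >= 50 & d < 150] <- 2 * (d[d >= 50 & d < 150] - 50)
  f[d >= 150 & d <= 300] <- 200
  both <- classify_signature(baseline_correct(fd_curve(d, f)))
  expect_equal(both$kind, "both")
  expect_equal(both$k_pilus, 2, tolerance = 0.05)
})

test_that("noiseless nanospring parameters are recovered exactly", {
  fit <- fit_nanospring(baseline_correct(noiseless_spring(2, 120)))
  expect_equal(fit$k_pilus, 2, tolerance = 1e-9)
  expect_equal(fit$f_adh, 120, tolerance = 2)
  expect_gt(fit$r2, 0.999999)
  # recovered k invariant under factor-2 decimation
  cv <- noiseless_spring(2, 120, ds = 1)
  half <- fd_curve(cv$distance[seq(1, 601, 2)], cv$force[seq(1, 601, 2)])
  fit2 <- fit_nanospring(baseline_correct(half))
  expect_lt(abs(fit2$k_pilus - fit$k_pilus) / fit$k_pilus, 0.001)
})

test_that("rupture forces up to 500 pN are handled without clipping", {
  fit <- fit_nanospring(baseline_correct(noiseless_spring(5, 500)))
  expect_equal(fit$f_adh, 500, tolerance = 2)
  sig <- classify_signature(baseline_correct(noiseless_spring(5, 500)))
  expect_equal(sig$kind, "nanospring")
})

test_that("plateau measurement is robust to noise and rejects degenerates", {
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    cv <- noiseless_plateau(220, 150)
    cv$force <- cv$force + rnorm(length(cv$force), 0, 10)
    measure_plateau(baseline_correct(cv))$plateau_force - 220
  }, 0)
  expect_lt(abs(mean(errs)), 2)
  # 1-sample "plateau" exercises the error path
  expect_error(measure_plateau(baseline_correct(noiseless_plateau(220, 1))),
               "plateau")
})

test_that("classification is invariant to force offset and distance shift", {
  cv <- noiseless_spring(5.5, 120)
  set.seed(3)
  cv$force <- cv$force + rnorm(length(cv$force), 0, 3)
  ref <- classify_signature(baseline_correct(cv))
  shifted <- fd_curve(cv$distance + 250, cv$force + 40)
  got <- classify_signature(baseline_correct(shifted))
  expect_equal(got$kind, ref$kind)
  expect_equal(got$k_pilus, ref$k_pilus, tolerance = 1e-6)
})

test_that("curve TSV round trip preserves the record", {
  cv <- noiseless_spring(3, 90)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fd_tsv(cv, path)
  back <- read_fd_tsv(path)
  expect_equal(back$distance, cv$distance)
  expect_equal(back$force, cv$force, tolerance = 1e-9)
})
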