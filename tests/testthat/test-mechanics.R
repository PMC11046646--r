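straight_trace <- function(L = 100, n = 11) {
  trace2d(seq(0, L, length.out = n), rep(0, n))
}

test_that("discretization resamples at uniform arc length", {
  # straight 100 nm segment at ds 10 -> 11 equally spaced points
  tr <- discretize_trace(trace2d(c(0, 40, 100), c(0, 0, 0)), 10)
  expect_length(tr$x, 11)
  expect_equal(tr$x, seq(0, 100, 10))
  expect_equal(tr$y, rep(0, 11))
  # idempotent on an already-uniform trace
  tr2 <- discretize_trace(tr, 10)
  expect_equal(tr2$x, tr$x, tolerance = 1e-9)
  expect_equal(tr2$y, tr$y, tolerance = 1e-9)
  # quarter circle: all turning angles equal ds / R
  R <- 500
  th <- seq(0, pi / 2, length.out = 2000)
  qc <- discretize_trace(trace2d(R * cos(th), R * sin(th)), 20)
  ang <- atan2(diff(qc$y), diff(qc$x))
  turns <- diff(ang)[1:30]
  expect_equal(turns, rep(20 / R, 30), tolerance = 1e-3)
  expect_error(discretize_trace(straight_trace(), 60), "ds")
})

test_that("pooled tangent correlation equals a brute-force evaluation", {
  traces <- simulate_wlc_traces(3, lp_um = 5, contour_um = 1, ds_nm = 10,
                                n_traces = 5)
  pooled <- pilusmech:::pooled_tancorr(traces, 10, 40)
  # brute force from the stored angles
  for (m in c(1, 7, 25)) {
    num <- 0; cnt <- 0
    for (tr in traces) {
      th <- atan2(diff(tr$y), diff(tr$x))
      for (i in seq_len(length(th) - m)) {
        num <- num + cos(th[i + m] - th[i])
        cnt <- cnt + 1
      }
    }
    expect_equal(pooled$corr[pooled$lag == m], num / cnt, tolerance = 1e-12)
  }
})

test_that("straight traces return the infinite-stiffness sentinel", {
  traces <- replicate(5, straight_trace(2000, 201), simplify = FALSE)
  est <- estimate_pl_tancorr(traces, 10, s_max = 0.5, n_boot = 0)
  expect_true(is.infinite(est$lp))
  expect_match(est$flag, "straight")
  est2 <- estimate_pl_msd(traces, 10, s_max = 0.5, n_boot = 0)
  expect_true(is.infinite(est2$lp))
})

test_that("rigid limit of the 2D WLC form is <R^2> = s^2", {
  s <- seq(1, 100, by = 1)
  lp <- 1e7
  expect_equal(pilusmech:::wlc_msd_2d(s, lp), s^2, tolerance = 1e-4)
})

test_that("both estimators recover the generating persistence length", {
  traces <- simulate_wlc_traces(11, lp_um = 21, contour_um = 4, ds_nm = 10,
                                n_traces = 200)
  tc <- estimate_pl_tancorr(traces, 10, n_boot = 0)
  expect_lt(abs(tc$lp - 21) / 21, 0.15)
  traces13 <- simulate_wlc_traces(12, lp_um = 13, contour_um = 4, ds_nm = 10,
                                  n_traces = 200)
  ms <- estimate_pl_msd(traces13, 10, n_boot = 0)
  expect_lt(abs(ms$lp - 13) / 13, 0.15)
  # the two estimators agree on the same ensemble within bootstrap CIs
  set.seed(1)
  tc13 <- estimate_pl_tancorr(traces13, 10, n_boot = 60)
  expect_true(ms$lp >= tc13$ci_low && ms$lp <= tc13$ci_high)
  expect_true(tc13$ci_low <= tc13$lp && tc13$lp <= tc13$ci_high)
})

test_that("the 2D-vs-3D decay conventions differ by exactly a factor 2", {
  # 2D-equilibrium data decay as exp(-s/2Lp); reading them through the 3D
  # formula exp(-s/Lp) misestimates Lp by exactly a factor of two - the
  # regression guard on the planar-equilibrium factor
  traces <- simulate_wlc_traces(5, lp_um = 10, contour_um = 4, ds_nm = 10,
                                n_traces = 100)
  lp2d <- estimate_pl_tancorr(traces, 10, n_boot = 0)$lp
  lp3d <- estimate_pl_tancorr(traces, 10, dim = "3d", n_boot = 0)$lp
  expect_equal(lp3d, 2 * lp2d, tolerance = 1e-9)
  expect_lt(abs(lp2d - 10) / 10, 0.15)
})

test_that("estimates are exactly invariant under rigid motions of the data", {
  traces <- simulate_wlc_traces(8, lp_um = 8, contour_um = 2, ds_nm = 10,
                                n_traces = 20)
  ang <- 1.1
  moved <- lapply(traces, function(tr) {
    trace2d(cos(ang) * tr$x - sin(ang) * tr$y + 500,
            sin(ang) * tr$x + cos(ang) * tr$y - 200)
  })
  # fixed s_max: the default depends on the contour length, whose last digit
  # can flip a floor() under rotation round-off
  a <- estimate_pl_tancorr(traces, 10, s_max = 0.8, n_boot = 0)$lp
  b <- estimate_pl_tancorr(moved, 10, s_max = 0.8, n_boot = 0)$lp
  expect_equal(a, b, tolerance = 1e-12)
  am <- estimate_pl_msd(traces, 10, s_max = 0.8, n_boot = 0)$lp
  bm <- estimate_pl_msd(moved, 10, s_max = 0.8, n_boot = 0)$lp
  expect_equal(am, bm, tolerance = 1e-9)
})

test_that("trace TSV round trip preserves contours", {
  traces <- simulate_wlc_traces(4, lp_um = 5, contour_um = 1, ds_nm = 10,
                                n_traces = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_traces_tsv(traces, path)
  back <- read_traces_tsv(path)
  expect_length(back, 3)
  expect_equal(back[[2]]$x, traces[[2]]$x, tolerance = 1e-5)
  expect_equal(back[[2]]$label, traces[[2]]$label)
})
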