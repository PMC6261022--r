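test_that("SoAD is the component-sum of absolute beta differences", {
  # two components: beta_{t-1} = (1, 2), beta_t = (1.5, 1) -> SoAD = 1.5
  tr <- fake_trajectory(t_start = 50L, T = 51L, nc = 2L,
                        fill = function(t, ty, co) {
                          if (t == 50) c(1, 2)[co] else c(1.5, 1)[co]
                        })
  s <- soad(tr, "SS")
  expect_equal(s$soad, 1.5)
  expect_equal(s$volume, 51L)
  # constant trajectory -> identically zero
  trc <- fake_trajectory(fill = function(t, ty, co) ty + co)
  expect_true(all(soad(trc, "GfSS")$soad == 0))
  # brute-force loop oracle on a random 22-component trajectory
  set.seed(12)
  vals <- array(rnorm(30 * 6 * 22), c(30, 6, 22))
  trr <- fake_trajectory(t_start = 50L, T = 79L, nc = 22L,
                         fill = function(t, ty, co) vals[t - 49, ty, co])
  s2 <- soad(trr, "FS")
  oracle <- sapply(2:30, function(i) {
    acc <- 0
    for (co in 1:22) acc <- acc + abs(vals[i, 6, co] - vals[i - 1, 6, co])
    acc
  })
  expect_equal(s2$soad, oracle, tolerance = 1e-12)
  # single-volume trajectories are refused
  tr1 <- fake_trajectory(t_start = 50L, T = 50L)
  expect_error(soad(tr1, "SS"), "insufficient data")
})

test_that("robust line fit recovers exact lines and resists outliers", {
  x <- 1:30
  y <- 3 - 0.02 * x
  f <- robust_linfit(x, y)
  expect_equal(f$slope, -0.02, tolerance = 1e-10)
  expect_equal(f$intercept, 3, tolerance = 1e-10)
  expect_equal(f$weights, rep(1, 30))
  # one gross outlier barely moves the line
  y2 <- y; y2[10] <- y2[10] + 50
  f2 <- robust_linfit(x, y2)
  clean <- stats::lm.fit(cbind(1, x[-10]), y[-10])$coefficients
  expect_equal(f2$slope, unname(clean[2]), tolerance = 1e-3)
  expect_lt(f2$weights[10], 0.01)
  expect_error(robust_linfit(1:2, c(1, 2)), "at least 3 points")
  expect_error(robust_linfit(rep(2, 5), rnorm(5)), "singular design")
})

test_that("robust line fit agrees with an independent bisquare implementation", {
  skip_if_not_installed("MASS")
  set.seed(42)
  x <- 1:100
  y <- 3 - 0.02 * x + rnorm(100, 0, 0.3)
  y[c(10, 50)] <- y[c(10, 50)] + 5
  f <- robust_linfit(x, y)
  r <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, maxit = 50)
  expect_equal(f$intercept, unname(coef(r)[1]), tolerance = 0.01)
  expect_equal(f$slope, unname(coef(r)[2]), tolerance = 1e-3)
})

test_that("exponential decay parameters are recovered from clean series", {
  t <- 51:500
  fit <- fit_decay(tibble::tibble(volume = t, soad = 10 * exp(-0.02 * t)))
  expect_equal(fit$lambda, 0.02, tolerance = 1e-8)
  expect_equal(fit$n0, 10, tolerance = 1e-6)
  expect_equal(fit$t_half, log(2) / 0.02, tolerance = 1e-6)
  expect_true(fit$valid)
  # lambda = ln 2 gives a one-volume half-life
  f2 <- fit_decay(tibble::tibble(volume = 1:20, soad = exp(-log(2) * (1:20))))
  expect_equal(f2$t_half, 1, tolerance = 1e-8)
  # growing series: flagged invalid, no half-life
  f3 <- fit_decay(tibble::tibble(volume = 1:20, soad = exp(0.1 * (1:20))))
  expect_false(f3$valid)
  expect_true(is.na(f3$t_half))
  # non-positive values are excluded, not floored
  s <- tibble::tibble(volume = 1:10, soad = c(2, 0, 1.5, -1, rep(1, 6)))
  f4 <- fit_decay(s)
  expect_equal(f4$n_excluded, 2L)
  expect_equal(f4$n_points_used, 8L)
  expect_error(fit_decay(tibble::tibble(volume = 1:4, soad = c(1, 0, 0, 0))),
               "insufficient data")
})

test_that("half-life identity and recovery under multiplicative noise", {
  set.seed(7)
  lams <- replicate(100, {
    t <- 51:500
    s <- 10 * exp(-0.0139 * t) * exp(rnorm(450, 0, 0.2))
    fit_decay(tibble::tibble(volume = t, soad = s))
  }, simplify = FALSE)
  # Eq-3 identity holds exactly for every valid fit
  for (f in lams[1:20]) {
    expect_true(f$valid)
    expect_equal(f$lambda * f$t_half, log(2), tolerance = 1e-12)
  }
  lam_hat <- sapply(lams, `[[`, "lambda")
  expect_lt(abs(median(lam_hat) - 0.0139) / 0.0139, 0.05)
})

test_that("stopping times anchor at the series start, round half-up, clip at T", {
  mkfit <- function(t_half, t_start = 50L) {
    structure(list(n0 = 10, lambda = log(2) / t_half, t_half = t_half,
                   valid = TRUE, n_points_used = 100L, n_excluded = 0L,
                   robust_converged = TRUE, t_start = t_start,
                   subject_id = "s1", trial_type = "GfSS", method = "robust"),
              class = "decay_fit")
  }
  expect_equal(ost(mkfit(40), k = 2, T = 502)$stop_volume, 130L)
  expect_equal(ost(mkfit(20.5), k = 1, T = 502)$stop_volume, 71L) # 50 + 21
  o <- ost(mkfit(300), k = 4, T = 502)
  expect_equal(o$stop_volume, 502L)
  expect_true(o$clipped)
  # zero-anchored alternative
  expect_equal(ost(mkfit(40), k = 2, T = 502, anchor = "zero")$stop_volume, 80L)
  # invalid fits fall back to the full task, flagged
  bad <- mkfit(40); bad$valid <- FALSE; bad$t_half <- NA_real_
  ob <- ost(bad, k = 1, T = 502)
  expect_equal(ob$stop_volume, 502L)
  expect_true(ob$clipped)
  expect_false(ob$valid_fit)
  # monotone in k (strict before clipping)
  sv <- sapply(1:4, function(kk) ost(mkfit(60), kk, T = 502)$stop_volume)
  expect_true(all(diff(sv) > 0))
  sv2 <- sapply(1:4, function(kk) ost(mkfit(200), kk, T = 502)$stop_volume)
  expect_true(all(diff(sv2) >= 0))
  expect_warning(ost(mkfit(40), k = 5, T = 502), "outside the standard")
})

test_that("combined stopping time is the maximum over the four trial types", {
  d <- tibble::tibble(trial_type = c("GfSS", "GfFS", "SS", "FS"),
                      stop_volume = c(120L, 90L, 200L, 150L))
  expect_equal(combined_ost(d), 200L)
  expect_equal(combined_ost(rep(77L, 4)), 77L)
  d2 <- d; d2$stop_volume[3] <- 502L
  expect_equal(combined_ost(d2), 502L)
  expect_error(combined_ost(d[1:3, ]), "incomplete set")
})

test_that("decline percentages follow the half-life geometry", {
  expect_equal(decay_fraction(1:4), c(50, 75, 87.5, 93.75))
  expect_equal(decay_fraction(0), 0)
  expect_error(decay_fraction(-1), "non-negative")
})
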