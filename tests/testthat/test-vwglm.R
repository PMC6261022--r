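test_that("design matrix carries the full regressor set", {
  p <- small_paradigm(2)
  n_vol <- paradigm_n_volumes(p)
  mo <- synth_motion(n_vol, seed = 1)
  X <- build_design(p, mo$motion6)
  expect_false(anyDuplicated(colnames(X)) > 0)
  # 6 trial types + motor + 24 motion + intercept + drift
  expect_equal(sum(grepl("^(trans|rot)", colnames(X))), 24L)
  expect_true(all(c("instruction", "GG", "GfSS", "GfFS", "SS", "FS",
                    "motor", "intercept") %in% colnames(X)))
  # constant motion -> difference columns identically zero
  Xc <- build_design(p, matrix(1, n_vol, 6,
                               dimnames = list(NULL, colnames(mo$motion6))))
  expect_true(all(Xc[, grepl("_d$|_dsq$", colnames(Xc))] == 0))
  # a trial type with no events gives an identically-zero column
  p0 <- small_paradigm(2, small_cfg(n_stop = 0L))
  mo0 <- synth_motion(paradigm_n_volumes(p0), seed = 1)
  X0 <- build_design(p0, mo0$motion6)
  expect_true(all(X0[, "FS"] == 0))
  expect_true(all(X0[, "SS"] == 0))
  # events past the scan end are refused
  expect_error(build_design(p, mo$motion6[1:30, ], n_volumes = 30L),
               "outside the scan|rows")
})

test_that("censoring keeps volumes at or below the FD threshold", {
  expect_equal(censor_mask(c(0.1, 0.6, 0.4)), c(TRUE, FALSE, TRUE))
  expect_equal(censor_mask(0.5), TRUE) # boundary: rule is strictly greater
  expect_equal(censor_mask(rep(0, 5)), rep(TRUE, 5))
  expect_error(censor_mask(c(0.1, -0.2)), "non-negative")
  expect_error(censor_mask(c(0.1, NA)), "finite")
})

test_that("regression starts after burn-in once every regressor has support", {
  p <- small_paradigm(2)
  mo <- synth_motion(paradigm_n_volumes(p), seed = 1)
  X <- build_design(p, mo$motion6)
  t0 <- first_valid_volume(X)
  expect_equal(as.integer(t0), 50L)
  expect_true(attr(t0, "converged"))
  # late first event of a type pushes the start past the burn-in
  Xl <- X
  first_fs <- which(Xl[, "FS"] != 0)[1]
  Xl[seq_len(79), "FS"] <- 0
  attr(Xl, "trial_type_cols") <- attr(X, "trial_type_cols")
  attr(Xl, "motor_col") <- "motor"
  expect_gte(as.integer(first_valid_volume(Xl)), 80L)
  # a type that never occurs flags the subject
  p0 <- small_paradigm(2, small_cfg(n_stop = 0L))
  mo0 <- synth_motion(paradigm_n_volumes(p0), seed = 1)
  s <- first_valid_volume(build_design(p0, mo0$motion6))
  expect_equal(as.integer(s), paradigm_n_volumes(p0) + 1L)
  expect_false(attr(s, "converged"))
  expect_true("SS" %in% attr(s, "missing_regressors"))
})

test_that("OLS engine matches the normal-equations oracle", {
  set.seed(99)
  for (rep in 1:20) {
    X <- matrix(rnorm(200 * 10), 200, 10)
    Y <- matrix(rnorm(200 * 3), 200, 3)
    fit <- fit_glm(Y, X)
    oracle <- solve(crossprod(X), crossprod(X, Y))
    expect_equal(unname(fit$beta), unname(oracle), tolerance = 1e-8)
    expect_false(fit$rank_deficient)
  }
  # noiseless recovery is exact
  set.seed(1)
  X <- matrix(rnorm(50 * 4), 50, 4); b <- c(1, -2, 0.5, 3)
  fit <- fit_glm(X %*% b, X)
  expect_equal(as.numeric(fit$beta), b, tolerance = 1e-8)
  # duplicated column: flagged, fitted values unchanged
  X2 <- cbind(X, X[, 1])
  fit2 <- fit_glm(X %*% b, X2)
  expect_true(fit2$rank_deficient)
  expect_equal(as.numeric(X2 %*% fit2$beta), as.numeric(X %*% b),
               tolerance = 1e-8)
  expect_error(fit_glm(matrix(1, 1, 1), matrix(1, 1, 1)),
               "insufficient data")
})

test_that("incremental refits equal from-scratch solves at every probed t", {
  ds <- small_subject(seed = 6, amp_sd = 0.3, noise_sd = 0.5)
  tr <- run_vwglm(ds)
  expect_equal(dim(tr$betas)[1], nrow(ds$timecourses) - tr$t_start + 1L)
  X <- build_design(ds$paradigm, ds$motion6)
  keep <- censor_mask(ds$fd)
  types <- attr(X, "trial_type_cols")
  n_probed <- 0L
  for (t in c(tr$t_start, 63L, 81L, tr$T)) {
    rows <- which(keep[seq_len(t)])
    Xt <- unclass(X)[rows, , drop = FALSE]
    Yt <- ds$timecourses[rows, , drop = FALSE]
    nrm <- sqrt(colSums(Xt^2)); nrm[nrm == 0] <- 1
    Xs <- sweep(Xt, 2L, nrm, "/")
    xtx <- crossprod(Xs)
    if (rcond(xtx) < 1e-10) next # genuinely deficient probe
    oracle <- (solve(xtx, crossprod(Xs, Yt)) / nrm)[types, , drop = FALSE]
    got <- tr$betas[as.character(t), , ]
    expect_equal(unname(got), unname(oracle), tolerance = 1e-8)
    n_probed <- n_probed + 1L
  }
  expect_gte(n_probed, 2L)
  # the last snapshot is the full-task GLM
  full <- fit_glm(ds$timecourses, unclass(X), mask = keep)
  expect_equal(unname(tr$betas[dim(tr$betas)[1], , ]),
               unname(full$beta[types, ]), tolerance = 1e-10)
})

test_that("censoring by deletion is idempotent", {
  set.seed(3)
  X <- matrix(rnorm(80 * 5), 80, 5)
  Y <- matrix(rnorm(80 * 2), 80, 2)
  mask <- runif(80) > 0.2
  a <- fit_glm(Y, X, mask = mask)
  b <- fit_glm(Y[mask, ], X[mask, ], mask = NULL)
  c2 <- fit_glm(Y[mask, ], X[mask, ], mask = rep(TRUE, sum(mask)))
  expect_equal(a$beta, b$beta, tolerance = 1e-12)
  expect_equal(b$beta, c2$beta, tolerance = 1e-12)
})
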