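test_that("feature vectors concatenate the four trial types by component", {
  tr <- fake_trajectory(t_start = 50L, T = 60L, nc = 22L)
  v <- extract_features(tr, 55L)
  expect_length(v, 88L)
  # layout: GfSS (type index 3) first, components in order
  expect_equal(unname(v[1]), 55 + 1000 * 3 + 1)
  expect_equal(names(v)[1], "GfSS_IC01")
  expect_equal(unname(v[23]), 55 + 1000 * 4 + 1) # GfFS block starts at 23
  expect_equal(unname(v[88]), 55 + 1000 * 6 + 22) # FS, last component
  # stop at T reproduces the full-task feature
  expect_equal(extract_features(tr, 60L),
               extract_features(tr, tr$T))
  # a single component scales the contract down to 4 entries
  tr1 <- fake_trajectory(nc = 1L)
  expect_length(extract_features(tr1, 55L), 4L)
  expect_error(extract_features(tr, 49L), "invalid request")
  expect_error(extract_features(tr, 61L), "invalid request")
})

test_that("sex residualization removes additive sex effects exactly", {
  set.seed(5)
  n <- 30
  sex <- rep(c("M", "F"), c(18, 12))
  f <- matrix(rnorm(n * 6), n, 6)
  # inject a pure additive sex offset on dimension 3
  f[, 3] <- f[, 3] + ifelse(sex == "M", 2, 0)
  r <- residualize_sex(f, sex)
  gap <- colMeans(r[sex == "M", ]) - colMeans(r[sex == "F", ])
  expect_true(all(abs(gap) < 1e-10))
  # sex-independent features are simply mean-centred per sex-balanced fit
  f0 <- matrix(rnorm(n * 2), n, 2)
  r0 <- residualize_sex(f0, sex)
  expect_true(all(abs(colMeans(r0)) < 1e-10))
  # features that are purely sex collapse to ~0
  fp <- matrix(rep(ifelse(sex == "M", 1, -1), 2), n, 2)
  expect_lt(max(abs(residualize_sex(fp, sex))), 1e-10)
  expect_error(residualize_sex(f, rep("M", n)), "degenerate covariate")
})

test_that("balanced LOOCV balances training sets and is reproducible", {
  set.seed(2)
  f <- matrix(rnorm(67 * 8), 67, 8)
  lab <- rep(c("CD", "Con"), c(40, 27))
  cv <- balanced_loocv(f, lab, n_resamples = 3, seed = 4)
  # CD test subject -> 27+27; Con test subject -> 26+26
  expect_equal(unique(cv$scores$train_size[lab == "CD"]), 54L)
  expect_equal(unique(cv$scores$train_size[lab == "Con"]), 52L)
  cv2 <- balanced_loocv(f, lab, n_resamples = 3, seed = 4)
  expect_identical(cv$scores, cv2$scores)
  expect_error(balanced_loocv(f, rep("CD", 67), n_resamples = 2),
               "two groups")
})

test_that("LOOCV separates a separable cohort and not a permuted one", {
  set.seed(11)
  n <- 24
  lab <- rep(c("CD", "Con"), each = n / 2)
  f <- matrix(rnorm(n * 10), n, 10)
  f[lab == "CD", 1:4] <- f[lab == "CD", 1:4] + 4
  cv <- balanced_loocv(f, lab, n_resamples = 20, seed = 1)
  expect_gt(cv$accuracy, 0.9)
  # permuted labels -> near chance on average
  accs <- sapply(1:3, function(s) {
    perm <- with_seed(s, sample(lab))
    balanced_loocv(f, perm, n_resamples = 10, seed = s)$accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("accuracy-vs-chance test matches exact signed-rank enumeration", {
  mk <- function(scores) {
    structure(list(condition = "x",
                   scores = tibble::tibble(
                     subject_id = sprintf("s%02d", seq_along(scores)),
                     label = "CD", score = scores,
                     train_size = 10L)),
              class = "cv_result")
  }
  s10 <- 0.5 + c(0.12, -0.03, 0.07, 0.21, -0.09, 0.15, 0.02, -0.18, 0.05, 0.11)
  got <- test_vs_chance(mk(s10))$p_value
  expect_equal(got, enum_signedrank_p(s10 - 0.5), tolerance = 1e-12)
  # maximal evidence
  expect_lt(test_vs_chance(mk(rep(1, 67)))$p_value, 1e-10)
  # symmetric scores carry no evidence
  sym <- 0.5 + c(-0.2, -0.1, -0.05, 0.05, 0.1, 0.2)
  expect_gte(test_vs_chance(mk(sym))$p_value, 0.4)
  # degenerate: everyone exactly at chance
  d <- test_vs_chance(mk(rep(0.5, 12)))
  expect_equal(d$p_value, 1)
  expect_true(d$degenerate)
})

test_that("pairwise comparison is one-sided, paired, and Bonferroni-capped", {
  mk <- function(scores) {
    structure(list(condition = "x",
                   scores = tibble::tibble(
                     subject_id = sprintf("s%02d", seq_along(scores)),
                     label = "CD", score = scores, train_size = 10L)),
              class = "cv_result")
  }
  set.seed(8)
  base <- runif(10, 0.3, 0.7)
  a <- mk(pmin(base + seq(0.05, 0.23, length.out = 10), 1)); b <- mk(base)
  t1 <- test_pairwise(a, b, n_comparisons = 1)
  expect_equal(t1$p_value, 2^-10, tolerance = 1e-12) # all-positive differences
  # identical vectors: degenerate, p = 1
  expect_equal(test_pairwise(b, b, n_comparisons = 16)$p_value, 1)
  # the Bonferroni product caps at 1
  t2 <- test_pairwise(b, a, n_comparisons = 16)
  expect_equal(t2$p_value, 1)
  # mismatched subject sets are a pairing error
  c2 <- mk(base); c2$scores$subject_id <- rev(c2$scores$subject_id)
  expect_error(test_pairwise(a, c2), "pairing error")
})

test_that("rank-sum comparisons of stopping times use exact tails", {
  osts <- tibble::tibble(
    subject_id = rep(sprintf("s%02d", 1:20), each = 1),
    trial_type = "GfSS", k = 1,
    stop_volume = c(101:110, 201:210), clipped = FALSE,
    valid_fit = TRUE, anchor = "t_start")
  man <- tibble::tibble(subject_id = sprintf("s%02d", 1:20),
                        group = rep(c("CD", "Con"), each = 10))
  out <- ost_group_compare(osts, man, k = 1, by = "group")
  expect_equal(out$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  # identical distributions: no evidence
  osts2 <- osts; osts2$stop_volume <- rep(101:110, 2)
  out2 <- ost_group_compare(osts2, man, k = 1, by = "group")
  expect_gt(out2$p_value, 0.9)
  # trial-type contrast within a single pseudo-group
  osts3 <- dplyr::bind_rows(
    osts[1:10, ],
    dplyr::mutate(osts[1:10, ], trial_type = "FS",
                  stop_volume = stop_volume + 200L))
  out3 <- ost_group_compare(osts3, manifest = NULL, k = 1, by = "trial_type")
  expect_equal(out3$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_error(ost_group_compare(osts[0, ], man, by = "group"),
               "two groups|empty")
})

test_that("RT correlations compare truncated and full windows", {
  # lightweight cohort stand-ins: only paradigm, tr, subject_id are used;
  # subjects differ in mean go RT, as real participants do
  cohort <- lapply(1:8, function(i) {
    m <- race_model(go_rt_mu = 350 + 30 * i)
    p <- small_paradigm(i, model = m)
    list(subject_id = sprintf("sub-%03d", i), paradigm = p,
         tr = paradigm_tr(p))
  })
  # windows covering over half the trials: truncated means track full means
  out <- rt_correlation(cohort, stop_volumes = 45L, trial_type = "GG")
  expect_gt(out$r, 0.9)
  expect_equal(out$n_used, 8L)
  # everyone at the full task: all excluded, flagged as insufficient
  expect_error(rt_correlation(cohort, stop_volumes = 100L, trial_type = "GG"),
               "insufficient data")
  expect_error(rt_correlation(cohort, 40L, "SS"), "no reaction times")
})
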