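#' Extract a neural feature vector at a stopping volume
#'
#' The classification feature of a subject is the concatenation of its
#' volume-wise GLM beta weights for the four stop-related trial types at a
#' single volume (the stopping time), in fixed order GfSS, GfFS, SS, FS by
#' component: with 22 usable components this is an 88-dimensional vector.
#' `stop_volume = T` gives the full-task feature.
#'
#' @param trajectory A `beta_trajectory`.
#' @param stop_volume Volume at which to read the betas
#'   (`t_start <= stop_volume <= T`).
#' @return Named numeric vector of length `4 * n_components`, with
#'   attributes `subject_id` and `stop_volume`.
#' @export
extract_features <- function(trajectory, stop_volume) {
  stopifnot(inherits(trajectory, "beta_trajectory"), trajectory$converged)
  if (stop_volume < trajectory$t_start) {
    stop("invalid request: stop_volume ", stop_volume,
         " precedes the first fitted volume ", trajectory$t_start,
         call. = FALSE)
  }
  if (stop_volume > trajectory$T) {
    stop("invalid request: stop_volume ", stop_volume,
         " exceeds the last acquired volume ", trajectory$T, call. = FALSE)
  }
  i <- stop_volume - trajectory$t_start + 1L
  types <- feature_trial_types()
  b <- trajectory$betas[i, types, , drop = TRUE] # [type, component]
  if (is.null(dim(b))) b <- matrix(b, nrow = length(types))
  # concatenate type-by-type, components in order within each type
  v <- stats::setNames(
    as.numeric(t(b)),
    as.vector(t(outer(types, trajectory$components, paste, sep = "_")))
  )
  attr(v, "subject_id") <- trajectory$subject_id
  attr(v, "stop_volume") <- as.integer(stop_volume)
  v
}

#' Feature matrix across a cohort
#'
#' @param trajectories List of `beta_trajectory`s.
#' @param stop_volumes Either a single volume used for every subject, or a
#'   tibble with `subject_id` and `stop_volume`.
#' @return Numeric matrix (subjects x dimensions) with subject_id rownames
#'   and attribute `stop_volumes`.
#' @export
feature_matrix <- function(trajectories, stop_volumes) {
  ids <- vapply(trajectories, function(x) x$subject_id, character(1))
  sv <- if (is.data.frame(stop_volumes)) {
    stop_volumes$stop_volume[match(ids, stop_volumes$subject_id)]
  } else {
    rep_len(stop_volumes, length(ids))
  }
  if (anyNA(sv)) stop("missing stop_volume for some subjects", call. = FALSE)
  rows <- mapply(function(tr, v) extract_features(tr, v),
                 trajectories, sv, SIMPLIFY = FALSE)
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  attr(m, "stop_volumes") <- as.integer(sv)
  m
}

#' Regress sex out of a feature matrix
#'
#' Each feature dimension is regressed on a sex indicator (with intercept)
#' by ordinary least squares and replaced by its residuals, removing both
#' the overall mean and any additive sex effect.
#'
#' @param features Subjects-by-dimensions matrix.
#' @param sex Character/factor vector, one entry per subject; both levels
#'   must be present.
#' @return Residual matrix of the same shape.
#' @export
residualize_sex <- function(features, sex) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(sex))
  sex <- as.factor(sex)
  if (nlevels(droplevels(sex)) < 2L) {
    stop("degenerate covariate: only one sex present in the cohort",
         call. = FALSE)
  }
  X <- stats::model.matrix(~sex)
  features - X %*% qr.coef(qr(X), features)
}

#' Balanced leave-one-out SVM cross-validation
#'
#' Leave-one-out cross-validation in which every training set is balanced:
#' after excluding the left-out subject, both groups are subsampled to the
#' size of the smaller one (with 40 CD / 27 Con this gives 27+27 = 54
#' training subjects when the test subject is CD and 26+26 = 52 when it is
#' Con). `n_resamples` independently drawn training sets are fitted per
#' left-out subject with a linear-kernel soft-margin SVM at default cost,
#' and the subject's score is the fraction of the resampled classifiers
#' predicting its true label. Headline accuracy is the mean fractional
#' score; a majority-vote accuracy is also reported.
#'
#' @param features Subjects-by-dimensions numeric matrix.
#' @param labels Group labels, one per subject (two groups).
#' @param n_resamples Training-set draws per left-out subject.
#' @param seed Integer seed (split per subject).
#' @param cost SVM soft-margin cost.
#' @param scale Standardise features inside the SVM (off by default; the
#'   betas carry their own scale).
#' @param condition Free-text tag describing the feature condition.
#' @return A `cv_result`: list with `condition`, `scores` tibble
#'   (subject_id, label, score), `accuracy` (mean fractional score),
#'   `accuracy_vote`, `n_resamples`, `seed`.
#' @export
balanced_loocv <- function(features, labels, n_resamples = 1000L, seed = 1L,
                           cost = 1, scale = FALSE, condition = "features") {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(labels) == n)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("need exactly two groups", call. = FALSE)
  if (min(table(labels)) < 2L) {
    stop("insufficient data: smallest group has fewer than 2 subjects",
         call. = FALSE)
  }
  ids <- rownames(features) %||% sprintf("sub-%03d", seq_len(n))

  score <- numeric(n)
  train_size <- integer(n)
  for (i in seq_len(n)) {
    idx_a <- setdiff(which(labels == lev[1L]), i)
    idx_b <- setdiff(which(labels == lev[2L]), i)
    m <- min(length(idx_a), length(idx_b))
    train_size[i] <- 2L * m
    truth <- labels[i]
    correct <- with_seed(child_seed(seed, "loocv", i), {
      vapply(seq_len(n_resamples), function(r) {
        tr_idx <- c(sample(idx_a)[seq_len(m)], sample(idx_b)[seq_len(m)])
        fit <- e1071::svm(features[tr_idx, , drop = FALSE],
                          factor(labels[tr_idx], levels = lev),
                          kernel = "linear", cost = cost, scale = scale)
        pred <- stats::predict(fit, features[i, , drop = FALSE])
        as.character(pred) == truth
      }, logical(1))
    })
    score[i] <- mean(correct)
  }
  structure(list(
    condition = condition,
    scores = tibble::tibble(subject_id = ids, label = labels, score = score,
                            train_size = train_size),
    accuracy = mean(score),
    accuracy_vote = mean((score > 0.5) + 0.5 * (score == 0.5)),
    n_resamples = as.integer(n_resamples),
    seed = as.integer(seed)
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$condition, ": accuracy = ",
      round(x$accuracy, 3), " (vote ", round(x$accuracy_vote, 3), ", ",
      nrow(x$scores), " subjects x ", x$n_resamples, " resamples)\n",
      sep = "")
  invisible(x)
}

#' @rdname balanced_loocv
#' @param x A `cv_result`.
#' @param ... Unused.
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(condition = x$condition, accuracy = x$accuracy,
                 accuracy_vote = x$accuracy_vote,
                 n_subjects = nrow(x$scores), n_resamples = x$n_resamples)
}

#' @rdname balanced_loocv
#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::mutate(x$scores, condition = x$condition, .before = 1L)
}

wilcox_p <- function(x, y = NULL, mu = 0, paired = FALSE,
                     alternative = "greater") {
  n <- length(x)
  d <- if (paired) x - y else if (is.null(y)) x - mu else NULL
  if (!is.null(d) && all(d == 0)) {
    return(list(p = 1, statistic = NA_real_, degenerate = TRUE))
  }
  exact <- if (is.null(y) || paired) n <= 25L else (n <= 25L && length(y) <= 25L)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, mu = mu, paired = paired,
                       alternative = alternative,
                       exact = exact, correct = TRUE)
  )
  list(p = wt$p.value, statistic = unname(wt$statistic), degenerate = FALSE)
}

#' Test classification accuracy against chance
#'
#' One-sided, one-sample Wilcoxon signed-rank test of the per-subject
#' prediction scores against the chance level 0.5 (alternative: greater).
#' Exact null distribution for n <= 25, normal approximation with
#' continuity correction above. If every score equals 0.5 the test is
#' undefined and p = 1 is reported with a flag.
#'
#' @param result A `cv_result`.
#' @param mu Chance level.
#' @return List: `p_value`, `statistic`, `degenerate`.
#' @export
test_vs_chance <- function(result, mu = 0.5) {
  stopifnot(inherits(result, "cv_result"))
  w <- wilcox_p(result$scores$score, mu = mu, alternative = "greater")
  list(p_value = w$p, statistic = w$statistic, degenerate = w$degenerate)
}

#' Pairwise accuracy comparison between two conditions
#'
#' Paired one-sided Wilcoxon signed-rank test on the per-subject score
#' differences (a > b), Bonferroni-adjusted by the family size.
#'
#' @param result_a,result_b `cv_result`s over the same subjects in the
#'   same order.
#' @param n_comparisons Bonferroni family size (default 16: 4 trial types
#'   x 4 half-lives).
#' @return List: `p_value` (adjusted, capped at 1), `p_raw`, `statistic`,
#'   `degenerate`.
#' @export
test_pairwise <- function(result_a, result_b, n_comparisons = 16L) {
  stopifnot(inherits(result_a, "cv_result"), inherits(result_b, "cv_result"))
  if (!identical(result_a$scores$subject_id, result_b$scores$subject_id)) {
    stop("pairing error: the two results cover different subjects or orders",
         call. = FALSE)
  }
  w <- wilcox_p(result_a$scores$score, result_b$scores$score, paired = TRUE,
                alternative = "greater")
  list(p_value = min(1, w$p * n_comparisons), p_raw = w$p,
       statistic = w$statistic, degenerate = w$degenerate)
}

#' Rank-sum comparisons of stopping times
#'
#' Two-sided Wilcoxon rank-sum tests on stopping volumes: between clinical
#' groups within each trial type (`by = "group"`), or between trial-type
#' pairs within each group (`by = "trial_type"`).
#'
#' @param osts Tibble from [ost_table()], filtered to one k (or pass `k`).
#' @param manifest Cohort manifest with `subject_id`, `group`; optional
#'   for `by = "trial_type"` (a single pseudo-group is used).
#' @param k Half-life multiplier to test (default 1).
#' @param by `"group"` or `"trial_type"`.
#' @return Tibble of comparisons with `p_value` and group medians/sizes.
#' @export
ost_group_compare <- function(osts, manifest = NULL, k = 1,
                              by = c("group", "trial_type")) {
  by <- match.arg(by)
  d <- osts[osts$k == k, ]
  if (!is.null(manifest)) {
    d <- dplyr::left_join(d, manifest[, c("subject_id", "group")],
                          by = "subject_id")
  } else {
    d$group <- "all"
  }
  ranksum <- function(x, y) {
    if (!length(x) || !length(y)) stop("empty group", call. = FALSE)
    if (length(x) < 2L || length(y) < 2L) {
      stop("need at least 2 subjects per group", call. = FALSE)
    }
    exact <- length(x) <= 25L && length(y) <= 25L &&
      !any(duplicated(c(x, y)))
    suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                        exact = exact,
                                        correct = TRUE))$p.value
  }
  if (by == "group") {
    gs <- sort(unique(d$group))
    if (length(gs) != 2L) stop("need two groups to compare", call. = FALSE)
    purrr::map_dfr(unique(d$trial_type), function(tt) {
      a <- d$stop_volume[d$trial_type == tt & d$group == gs[1L]]
      b <- d$stop_volume[d$trial_type == tt & d$group == gs[2L]]
      tibble::tibble(trial_type = tt, group_a = gs[1L], group_b = gs[2L],
                     n_a = length(a), n_b = length(b),
                     median_a = stats::median(a), median_b = stats::median(b),
                     p_value = ranksum(a, b))
    })
  } else {
    types <- unique(d$trial_type)
    pairs <- utils::combn(types, 2L, simplify = FALSE)
    purrr::map_dfr(unique(d$group), function(g) {
      purrr::map_dfr(pairs, function(pr) {
        a <- d$stop_volume[d$trial_type == pr[1L] & d$group == g]
        b <- d$stop_volume[d$trial_type == pr[2L] & d$group == g]
        tibble::tibble(group = g, type_a = pr[1L], type_b = pr[2L],
                       n_a = length(a), n_b = length(b),
                       median_a = stats::median(a),
                       median_b = stats::median(b),
                       p_value = ranksum(a, b))
      })
    })
  }
}

#' Correlation of truncated vs full-task reaction times
#'
#' For each subject, the mean reaction time of a trial type is computed
#' over the trials presented before the stopping volume and over the whole
#' task; the two are correlated (Pearson) across subjects. Subjects whose
#' truncated window already contains every trial of that type contribute a
#' forced perfect match and are excluded. The SS trial type has no
#' reaction times and is refused.
#'
#' @param cohort An `sst_cohort` or list of `subject_dataset`s.
#' @param stop_volumes Tibble with `subject_id` and `stop_volume`, or a
#'   single volume.
#' @param trial_type One of GfSS, GfFS, FS (GG also allowed).
#' @return One-row tibble: trial_type, r, p_value, n_used, n_excluded.
#' @export
rt_correlation <- function(cohort, stop_volumes, trial_type) {
  if (trial_type == "SS") {
    stop("no reaction times: the SS trial type has no responses by definition",
         call. = FALSE)
  }
  ids <- vapply(cohort, function(s) s$subject_id, character(1))
  sv <- if (is.data.frame(stop_volumes)) {
    stop_volumes$stop_volume[match(ids, stop_volumes$subject_id)]
  } else {
    rep_len(stop_volumes, length(ids))
  }
  rt_full <- rt_trunc <- rep(NA_real_, length(cohort))
  spans_all <- logical(length(cohort))
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    ev <- tibble::as_tibble(s$paradigm)
    sel <- !is.na(ev$label) & ev$label == trial_type &
      !is.na(ev$responded) & ev$responded
    if (!any(sel)) next
    rts <- ev$rt_ms[sel]
    before <- ev$onset[sel] < sv[i] * s$tr
    spans_all[i] <- all(before)
    rt_full[i] <- mean(rts)
    rt_trunc[i] <- if (any(before)) mean(rts[before]) else NA_real_
  }
  use <- !spans_all & !is.na(rt_full) & !is.na(rt_trunc)
  n_excluded <- sum(spans_all)
  if (sum(use) < 3L) {
    stop("insufficient data: fewer than 3 subjects after exclusions",
         call. = FALSE)
  }
  ct <- stats::cor.test(rt_trunc[use], rt_full[use], method = "pearson")
  tibble::tibble(trial_type = trial_type, r = unname(ct$estimate),
                 p_value = ct$p.value, n_used = sum(use),
                 n_excluded = n_excluded)
}
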