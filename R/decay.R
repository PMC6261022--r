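#' Sum of absolute differences (SoAD) of a beta trajectory
#'
#' The convergence statistic: at each volume t past the start of the
#' trajectory, the sum over all usable components of
#' `|beta_t - beta_{t-1}|` for one trial type. As the GLM stabilises, the
#' series decays towards zero.
#'
#' @param trajectory A `beta_trajectory`.
#' @param trial_type One of `GfSS`, `GfFS`, `SS`, `FS` (any of the six
#'   modelled types is accepted).
#' @return Tibble: `subject_id`, `trial_type`, `volume`
#'   (`t_start + 1 .. T`), `soad`.
#' @export
soad <- function(trajectory, trial_type) {
  stopifnot(inherits(trajectory, "beta_trajectory"))
  trial_type <- match.arg(trial_type, trajectory$trial_types)
  if (!trajectory$converged || is.null(trajectory$betas) ||
      dim(trajectory$betas)[1L] < 2L) {
    stop("insufficient data: trajectory spans fewer than 2 volumes",
         call. = FALSE)
  }
  b <- trajectory$betas[, trial_type, , drop = TRUE] # [t, component]
  if (is.null(dim(b))) b <- matrix(b, ncol = 1L)
  s <- rowSums(abs(diff(b)))
  tibble::tibble(
    subject_id = trajectory$subject_id,
    trial_type = trial_type,
    volume = (trajectory$t_start + 1L):trajectory$T,
    soad = unname(s)
  )
}

#' @rdname soad
#' @param trial_types Types to compute; defaults to the four stop-related
#'   types the convergence analysis focuses on.
#' @export
soad_table <- function(trajectory, trial_types = feature_trial_types()) {
  dplyr::bind_rows(lapply(trial_types, function(tt) soad(trajectory, tt)))
}

bisquare_weight <- function(u) {
  w <- (1 - u^2)^2
  w[abs(u) >= 1] <- 0
  w
}

#' Robust straight-line fit (iteratively reweighted bisquare)
#'
#' Fits `y ~ x` by iteratively reweighted least squares with Tukey
#' bisquare weights at tuning constant 4.685. Residuals are
#' leverage-adjusted (`r / sqrt(1 - h)`), the scale is the median of the
#' `n - p + 1` largest absolute adjusted residuals divided by 0.6745, and
#' iteration stops when no coefficient moves by more than 1e-8 (relative)
#' or after 50 iterations. With zero residuals the OLS fit is returned
#' with unit weights.
#'
#' @param x,y Numeric vectors of equal length, at least 3 points.
#' @return List: `slope`, `intercept`, `weights`, `iterations`,
#'   `converged`.
#' @export
#' @examples
#' f <- robust_linfit(1:10, 3 - 0.02 * (1:10))
#' c(f$slope, f$intercept)
robust_linfit <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("robust fit needs at least 3 points", call. = FALSE)
  if (diff(range(x)) == 0) {
    stop("singular design: all x values identical", call. = FALSE)
  }
  X <- cbind(1, x)
  p <- 2L
  tune <- 4.685

  qx <- qr(X)
  h <- rowSums(qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]^2)
  adj <- 1 / sqrt(pmax(1 - h, 1e-8))

  b <- qr.coef(qx, y)
  w <- rep(1, n)
  converged <- FALSE
  iter <- 0L
  tiny_s <- 1e-6 * stats::sd(y) # fallback scale when over half the points fit exactly
  for (iter in seq_len(50L)) {
    r <- as.numeric(y - X %*% b)
    radj <- abs(r) * adj
    s <- max(stats::median(sort(radj)[p:n]) / 0.6745, tiny_s)
    if (s == 0) { # exact fit of constant data
      w <- rep(1, n)
      converged <- TRUE
      break
    }
    w <- as.numeric(bisquare_weight(r * adj / (tune * s)))
    if (sum(w > 0) < p) { # pathological: keep previous estimate
      converged <- FALSE
      break
    }
    sw <- sqrt(w)
    b_new <- qr.coef(qr(X * sw), y * sw)
    if (max(abs(b_new - b)) < 1e-8 * max(1, max(abs(b_new)))) {
      b <- b_new
      converged <- TRUE
      break
    }
    b <- b_new
  }
  list(slope = unname(b[2L]), intercept = unname(b[1L]),
       weights = as.numeric(w), iterations = iter, converged = converged)
}

#' Fit exponential decay to a SoAD series
#'
#' The SoAD series is modelled as `N(t) = N0 * exp(-lambda * t)`; taking
#' logs makes this a straight line in t, so `lambda` (the decay constant)
#' and `N0` are recovered as minus the slope and the exponentiated
#' intercept of a robust linear fit of `ln(SoAD)` on the volume index.
#' Non-positive SoAD values cannot be logged and are excluded (their count
#' is recorded). The half-life is `t_half = ln(2) / lambda`. A
#' non-positive `lambda` (a non-decaying subject) is a flagged, first-class
#' outcome, not an error.
#'
#' @param series Tibble from [soad()] (columns `volume`, `soad`), or a
#'   data frame with those columns.
#' @param robust Use the robust bisquare fit (default) or ordinary least
#'   squares.
#' @return A `decay_fit`: list with `n0`, `lambda`, `t_half`, `valid`,
#'   `n_points_used`, `n_excluded`, `robust_converged`, `t_start`,
#'   `subject_id`, `trial_type`, `method`.
#' @export
#' @examples
#' t <- 51:500
#' fit <- fit_decay(tibble::tibble(volume = t, soad = 10 * exp(-0.02 * t)))
#' c(fit$lambda, fit$t_half)
fit_decay <- function(series, robust = TRUE) {
  stopifnot(all(c("volume", "soad") %in% names(series)))
  pos <- is.finite(series$soad) & series$soad > 0
  n_excluded <- sum(!pos)
  if (sum(pos) < 3L) {
    stop("insufficient data: fewer than 3 positive SoAD values",
         call. = FALSE)
  }
  x <- series$volume[pos]
  y <- log(series$soad[pos])
  if (robust) {
    f <- robust_linfit(x, y)
    slope <- f$slope; intercept <- f$intercept
    rconv <- f$converged
  } else {
    b <- stats::lm.fit(cbind(1, x), y)$coefficients
    slope <- unname(b[2L]); intercept <- unname(b[1L])
    rconv <- TRUE
  }
  lam <- -slope
  valid <- is.finite(lam) && lam > 0
  structure(list(
    n0 = exp(intercept),
    lambda = lam,
    t_half = if (valid) log(2) / lam else NA_real_,
    valid = valid,
    n_points_used = sum(pos),
    n_excluded = n_excluded,
    robust_converged = rconv,
    t_start = min(series$volume) - 1L,
    subject_id = if ("subject_id" %in% names(series)) series$subject_id[1L] else NA_character_,
    trial_type = if ("trial_type" %in% names(series)) series$trial_type[1L] else NA_character_,
    method = if (robust) "robust" else "ols"
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> lambda = ", signif(x$lambda, 4),
      ", t_half = ", signif(x$t_half, 4), " volumes",
      if (!x$valid) " (invalid: non-decaying)", "\n", sep = "")
  invisible(x)
}

#' @rdname fit_decay
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id, trial_type = x$trial_type,
    n0 = x$n0, lambda = x$lambda, t_half = x$t_half, valid = x$valid,
    n_points_used = x$n_points_used, n_excluded = x$n_excluded,
    robust_converged = x$robust_converged, t_start = x$t_start,
    method = x$method
  )
}

#' @rdname fit_decay
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("log_n0", "lambda"),
    estimate = c(log(x$n0), x$lambda)
  )
}

#' Percent SoAD decline after k half-lives
#'
#' After k half-lives an exponential decay has fallen by
#' `100 * (1 - 2^-k)` percent: 50, 75, 87.5 and 93.75% for k = 1..4.
#'
#' @param k Half-life count (non-negative, vectorised).
#' @return Percent decline.
#' @export
#' @examples
#' decay_fraction(1:4)
decay_fraction <- function(k) {
  if (any(k < 0)) stop("k must be non-negative", call. = FALSE)
  100 * (1 - 2^(-k))
}

#' Optimal stopping time from a decay fit
#'
#' The stopping volume after k half-lives. The decay clock is anchored at
#' the first fitted volume (`t_start`), where the SoAD series begins; the
#' alternative of counting from volume 0 is available via
#' `anchor = "zero"`. Fractional volumes round half-up. Estimates beyond
#' the last acquired volume T are clipped to T and flagged, as are
#' estimates from invalid (non-decaying) fits.
#'
#' @param fit A `decay_fit`.
#' @param k Half-life multiplier; 1..4 in the standard analysis (other
#'   positive values are allowed with a warning).
#' @param t_start First fitted volume; defaults to the fit's.
#' @param T Last acquired volume.
#' @param anchor `"t_start"` (default) or `"zero"`.
#' @return One-row tibble: `subject_id`, `trial_type`, `k`, `stop_volume`,
#'   `clipped`, `valid_fit`, `anchor`.
#' @export
ost <- function(fit, k, t_start = fit$t_start, T,
                anchor = c("t_start", "zero")) {
  stopifnot(inherits(fit, "decay_fit"), length(k) == 1L, k > 0)
  anchor <- match.arg(anchor)
  if (!k %in% c(1, 2, 3, 4)) {
    warning("k = ", k, " is outside the standard 1..4 half-life set")
  }
  base <- if (anchor == "t_start") t_start else 0L
  if (!fit$valid) {
    sv <- as.integer(T); clip <- TRUE
  } else {
    raw <- base + round_half_up(k * fit$t_half)
    clip <- raw > T
    sv <- as.integer(min(raw, T))
  }
  tibble::tibble(subject_id = fit$subject_id, trial_type = fit$trial_type,
                 k = k, stop_volume = sv, clipped = clip,
                 valid_fit = fit$valid, anchor = anchor)
}

#' Largest stopping time across the four trial types
#'
#' At a fixed k, the subject-level stopping volume is the maximum of the
#' four trial-type OSTs, so every trial type's betas have stabilised by
#' the stop.
#'
#' @param per_type A tibble of OST rows (from [ost()] or [ost_table()])
#'   for one subject at one k, or a named numeric vector of stop volumes.
#' @return The combined stopping volume (integer).
#' @export
combined_ost <- function(per_type) {
  if (is.data.frame(per_type)) {
    missing <- setdiff(feature_trial_types(), per_type$trial_type)
    if (length(missing)) {
      stop("incomplete set: missing trial type(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    vols <- per_type$stop_volume
  } else {
    if (length(per_type) < 4L) {
      stop("incomplete set: need stopping times for all 4 trial types",
           call. = FALSE)
    }
    vols <- per_type
  }
  as.integer(max(vols))
}

#' Decay fits for a whole cohort of trajectories
#'
#' @param trajectories List of `beta_trajectory` objects (or an
#'   `sst_cohort`'s trajectories).
#' @param trial_types Trial types to fit.
#' @param robust Robust (default) or ordinary least-squares log-linear fit.
#' @return Tibble with one row per subject x trial type (the [glance()]
#'   columns).
#' @export
decay_table <- function(trajectories, trial_types = feature_trial_types(),
                        robust = TRUE) {
  purrr::map_dfr(trajectories, function(tr) {
    if (!tr$converged) return(NULL)
    purrr::map_dfr(trial_types, function(tt) {
      glance(fit_decay(soad(tr, tt), robust = robust))
    })
  })
}

#' Stopping-time table for a cohort
#'
#' @param decays Tibble from [decay_table()].
#' @param k Half-life multipliers.
#' @param T Last acquired volume.
#' @param anchor Decay-clock anchor, see [ost()].
#' @return Tibble: subject_id, trial_type, k, stop_volume, clipped,
#'   valid_fit, anchor.
#' @export
ost_table <- function(decays, k = 1:4, T, anchor = c("t_start", "zero")) {
  anchor <- match.arg(anchor)
  purrr::pmap_dfr(decays, function(...) {
    row <- list(...)
    fit <- structure(row, class = "decay_fit")
    dplyr::bind_rows(lapply(k, function(kk) {
      ost(fit, kk, t_start = row$t_start, T = T, anchor = anchor)
    }))
  })
}

#' Box-plot style group summary of stopping times
#'
#' Median, quartiles and outlier counts (points beyond 1.5 IQR of the
#' quartiles) of stopping volumes, by group and/or trial type.
#'
#' @param osts Tibble from [ost_table()].
#' @param manifest Optional cohort manifest with `subject_id` and `group`.
#' @return Tibble of per-stratum summaries.
#' @export
ost_summary <- function(osts, manifest = NULL) {
  d <- osts
  if (!is.null(manifest)) {
    d <- dplyr::left_join(d, manifest[, c("subject_id", "group")],
                          by = "subject_id")
  } else {
    d$group <- "all"
  }
  dplyr::summarise(
    dplyr::group_by(d, .data$group, .data$trial_type, .data$k),
    n = dplyr::n(),
    median = stats::median(.data$stop_volume),
    q25 = unname(stats::quantile(.data$stop_volume, 0.25)),
    q75 = unname(stats::quantile(.data$stop_volume, 0.75)),
    n_outliers = sum(.data$stop_volume > q75 + 1.5 * (q75 - q25) |
                     .data$stop_volume < q25 - 1.5 * (q75 - q25)),
    n_clipped = sum(.data$clipped),
    .groups = "drop"
  )
}
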