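#' Build the stop-signal task design matrix
#'
#' Assembles the regressors of the volume-wise GLM: six HRF-convolved
#' trial-type impulse trains (instruction, GG, GfSS, GfFS, SS, FS), one
#' HRF-convolved motor regressor with an impulse at every button press,
#' 24 motion regressors (the six raw parameters, their squares, backward
#' differences, and squared differences; first-row differences set to 0),
#' an intercept, and cosine drift columns up to the 1/128 Hz high-pass
#' cutoff.
#'
#' @param paradigm A labeled `sst_paradigm`.
#' @param motion6 `n_volumes x 6` motion-parameter matrix.
#' @param tr Repetition time (s); defaults to the paradigm's.
#' @param n_volumes Number of volumes; defaults to the paradigm's.
#' @param drift_cutoff Drift-basis frequency cutoff in Hz.
#' @return A numeric matrix of class `vw_design` with named columns and
#'   attributes `trial_type_cols` and `motor_col`.
#' @export
build_design <- function(paradigm, motion6, tr = paradigm_tr(paradigm),
                         n_volumes = paradigm_n_volumes(paradigm),
                         drift_cutoff = 1 / 128) {
  stopifnot(inherits(paradigm, "sst_paradigm"), is.matrix(motion6),
            ncol(motion6) == 6L)
  if (nrow(motion6) != n_volumes) {
    stop("motion6 has ", nrow(motion6), " rows but n_volumes is ",
         n_volumes, call. = FALSE)
  }
  ev <- tibble::as_tibble(paradigm)
  if (anyNA(ev$label[ev$base_type %in% c("go", "stop")])) {
    stop("paradigm must be labeled (run label_trials())", call. = FALSE)
  }
  kern <- hrf_kernel(tr)
  types <- trial_type_levels()

  task_cols <- sapply(types, function(tt) {
    event_regressor(ev$onset[!is.na(ev$label) & ev$label == tt],
                    n_volumes, tr, kernel = kern)
  })
  resp <- ev[!is.na(ev$responded) & ev$responded, ]
  motor <- event_regressor(resp$onset + resp$rt_ms / 1000, n_volumes, tr,
                           kernel = kern)

  d <- rbind(0, diff(motion6))
  mot <- cbind(motion6, motion6^2, d, d^2)
  colnames(mot) <- c(colnames(motion6),
                     paste0(colnames(motion6), "_sq"),
                     paste0(colnames(motion6), "_d"),
                     paste0(colnames(motion6), "_dsq"))

  B <- dct_basis(n_volumes, tr, cutoff = drift_cutoff)
  if (ncol(B)) colnames(B) <- sprintf("drift%02d", seq_len(ncol(B)))

  X <- cbind(task_cols, motor = motor, mot, intercept = 1, B)
  stopifnot(!anyDuplicated(colnames(X)))
  structure(X, trial_type_cols = types, motor_col = "motor",
            class = c("vw_design", "matrix", "array"))
}

#' Motion-censoring mask from framewise displacement
#'
#' Volumes whose framewise displacement strictly exceeds the threshold are
#' dropped from every regression.
#'
#' @param fd Per-volume framewise displacement (finite, non-negative).
#' @param threshold Censoring threshold in mm.
#' @return Logical vector, `TRUE` = keep.
#' @export
#' @examples
#' censor_mask(c(0.1, 0.6, 0.4)) # TRUE FALSE TRUE
censor_mask <- function(fd, threshold = 0.5) {
  if (any(!is.finite(fd)) || any(fd < 0)) {
    stop("fd must be finite and non-negative", call. = FALSE)
  }
  fd <= threshold
}

#' First volume at which the incremental GLM may start
#'
#' The volume-wise regression starts after a burn-in, and no earlier than
#' the first volume by which every trial-type regressor and the motor
#' regressor has non-zero support (so every coefficient is estimable from
#' data that contain its event type). If some regressor never acquires
#' support, the sentinel `n_volumes + 1` is returned with attribute
#' `converged = FALSE`, flagging the subject for exclusion.
#'
#' @param design A `vw_design`.
#' @param burn_in Burn-in: the regression starts at this volume (default
#'   the 50th, i.e. a 49-volume burn-in).
#' @return Integer volume index (1-based); attribute `converged`.
#' @export
first_valid_volume <- function(design, burn_in = 50L) {
  need <- c(attr(design, "trial_type_cols"), attr(design, "motor_col"))
  firsts <- vapply(need, function(cn) {
    nz <- which(design[, cn] != 0)
    if (length(nz)) nz[1L] else NA_integer_
  }, integer(1))
  if (anyNA(firsts)) {
    out <- nrow(design) + 1L
    attr(out, "converged") <- FALSE
    attr(out, "missing_regressors") <- names(firsts)[is.na(firsts)]
    return(out)
  }
  out <- max(as.integer(burn_in), max(firsts))
  attr(out, "converged") <- TRUE
  out
}

# Moore-Penrose pseudoinverse via SVD (for rank-deficient designs).
pinv <- function(X, tol = NULL) {
  s <- svd(X)
  tol <- tol %||% (max(dim(X)) * max(s$d) * .Machine$double.eps)
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Ordinary least-squares fit of the design to the timecourses
#'
#' Censored rows are deleted, then the system is solved per component by
#' ordinary least squares. Full-rank designs go through the QR
#' decomposition; rank-deficient designs are solved minimum-norm through
#' the SVD pseudoinverse and flagged (fitted values are unchanged by the
#' choice of solution).
#'
#' Columns are equilibrated to unit Euclidean norm before the solve (and
#' the coefficients rescaled back), so regressors of very different
#' magnitudes — motion differences squared versus the intercept — do not
#' corrupt the rank decision or the solution.
#'
#' @param Y `t x n_components` response matrix (rows = volumes).
#' @param X `t x p` design matrix.
#' @param mask Optional logical keep-mask of length `t`.
#' @return List: `beta` (`p x n_components`), `rank_deficient` flag,
#'   `n_rows` used.
#' @export
fit_glm <- function(Y, X, mask = NULL) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  stopifnot(nrow(Y) == nrow(X))
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(X))
    Y <- Y[mask, , drop = FALSE]
    X <- X[mask, , drop = FALSE]
  }
  if (nrow(X) < 2L) {
    stop("insufficient data: fewer than 2 uncensored volumes", call. = FALSE)
  }
  nrm <- sqrt(colSums(X^2))
  nrm[nrm == 0] <- 1
  Xs <- sweep(X, 2L, nrm, "/")
  qx <- qr(Xs)
  deficient <- qx$rank < ncol(Xs)
  beta <- if (deficient) {
    pinv(Xs) %*% Y
  } else {
    qr.coef(qx, Y)
  }
  beta <- beta / nrm
  rownames(beta) <- colnames(X)
  list(beta = beta, rank_deficient = deficient, n_rows = nrow(X))
}

#' Run the volume-wise GLM over a subject
#'
#' For every t from the first valid volume to the last acquired volume T,
#' refits the GLM on volumes 1..t (censored volumes deleted identically at
#' every t) and stores the six trial-type beta vectors, yielding the
#' subject's beta-weight trajectory. The t = T snapshot is exactly the
#' full-task GLM.
#'
#' @param dataset A `subject_dataset`.
#' @param burn_in Burn-in volume (see [first_valid_volume()]).
#' @param fd_threshold Censoring threshold in mm.
#' @param drift_cutoff Drift-basis cutoff in Hz.
#' @return A `beta_trajectory`: list with `subject_id`, `t_start`, `T`,
#'   `trial_types`, `components`, `betas` (array `[t, trial_type,
#'   component]` with volume dimnames), `censored`, `rank_deficient`
#'   (per-t flags), `converged`, `group`, `sex`.
#' @export
run_vwglm <- function(dataset, burn_in = 50L, fd_threshold = 0.5,
                      drift_cutoff = 1 / 128) {
  stopifnot(inherits(dataset, "subject_dataset"))
  Y <- dataset$timecourses
  Tn <- nrow(Y)
  X <- build_design(dataset$paradigm, dataset$motion6,
                    drift_cutoff = drift_cutoff)
  keep <- censor_mask(dataset$fd, threshold = fd_threshold)
  t0 <- first_valid_volume(X, burn_in = burn_in)
  types <- attr(X, "trial_type_cols")
  comps <- colnames(Y) %||% sprintf("IC%02d", seq_len(ncol(Y)))

  if (!isTRUE(attr(t0, "converged"))) {
    return(structure(list(
      subject_id = dataset$subject_id, t_start = NA_integer_, T = Tn,
      trial_types = types, components = comps, betas = NULL,
      censored = !keep, rank_deficient = logical(0), converged = FALSE,
      group = dataset$group, sex = dataset$sex
    ), class = "beta_trajectory"))
  }

  t0 <- as.integer(t0)
  ts <- t0:Tn
  betas <- array(NA_real_, dim = c(length(ts), length(types), length(comps)),
                 dimnames = list(volume = ts, trial_type = types,
                                 component = comps))
  rank_flags <- logical(length(ts))
  Xm <- unclass(X)
  for (i in seq_along(ts)) {
    t <- ts[i]
    fit <- fit_glm(Y[seq_len(t), , drop = FALSE],
                   Xm[seq_len(t), , drop = FALSE],
                   mask = keep[seq_len(t)])
    betas[i, , ] <- fit$beta[types, , drop = FALSE]
    rank_flags[i] <- fit$rank_deficient
  }
  structure(list(
    subject_id = dataset$subject_id, t_start = t0, T = Tn,
    trial_types = types, components = comps, betas = betas,
    censored = !keep, rank_deficient = rank_flags, converged = TRUE,
    group = dataset$group, sex = dataset$sex
  ), class = "beta_trajectory")
}

#' @export
print.beta_trajectory <- function(x, ...) {
  cat("<beta_trajectory> ", x$subject_id,
      if (!x$converged) " (did not converge)" else
        paste0(": volumes ", x$t_start, "..", x$T, ", ",
               length(x$components), " components"),
      "\n", sep = "")
  invisible(x)
}

#' Tidy a beta trajectory into a long tibble
#'
#' @param x A `beta_trajectory`.
#' @param ... Unused.
#' @return Tibble: subject_id, volume, trial_type, component, beta.
#' @export
tidy.beta_trajectory <- function(x, ...) {
  if (!x$converged || is.null(x$betas)) {
    return(tibble::tibble(subject_id = character(), volume = integer(),
                          trial_type = character(), component = character(),
                          beta = numeric()))
  }
  d <- as.data.frame.table(x$betas, responseName = "beta",
                           stringsAsFactors = FALSE)
  tibble::tibble(subject_id = x$subject_id,
                 volume = as.integer(d$volume),
                 trial_type = d$trial_type,
                 component = d$component,
                 beta = d$beta)
}
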