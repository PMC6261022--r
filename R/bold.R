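#' Canonical double-gamma hemodynamic response kernel
#'
#' The haemodynamic response is modelled as the difference of two gamma
#' densities: a response peaking near 5 s and an undershoot centred near
#' 15 s with 1/6 the amplitude. The kernel is sampled on the volume grid
#' and scaled so its sampled peak equals 1; it is causal, with value 0 at
#' t = 0.
#'
#' @param tr Sampling interval in seconds (the repetition time).
#' @param duration Kernel support in seconds.
#' @param peak,undershoot Shape parameters (seconds, rate 1) of the two
#'   gamma components; their modes sit at `peak - 1` and `undershoot - 1`.
#' @param ratio Undershoot amplitude relative to the response.
#' @return Numeric vector: the kernel sampled at `0, tr, 2*tr, ...`.
#' @export
#' @examples
#' k <- hrf_kernel(tr = 0.5)
#' which.max(k) # peak a few seconds in
hrf_kernel <- function(tr, duration = 32, peak = 6, undershoot = 16,
                       ratio = 1 / 6) {
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0) {
    stop("invalid configuration: tr must be a positive number", call. = FALSE)
  }
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h / max(h)
}

# Place amplitudes at event onsets on the volume grid and convolve with the
# HRF kernel. Volume v (1-based) covers [(v-1)*tr, v*tr); an event at onset
# s lands in bin floor(s/tr)+1. Shared by the generator and the design
# builder so that a noiseless synthetic subject is exactly identifiable.
event_regressor <- function(onsets, n_volumes, tr, amplitudes = 1,
                            kernel = hrf_kernel(tr)) {
  stick <- numeric(n_volumes)
  if (length(onsets)) {
    amplitudes <- rep_len(amplitudes, length(onsets))
    bins <- floor(onsets / tr) + 1L
    if (any(bins < 1L | bins > n_volumes)) {
      stop("event onset outside the scan (volume ",
           paste(bins[bins < 1L | bins > n_volumes], collapse = ", "),
           " of ", n_volumes, ")", call. = FALSE)
    }
    for (j in seq_along(bins)) stick[bins[j]] <- stick[bins[j]] + amplitudes[j]
  }
  out <- stats::convolve(stick, rev(kernel), type = "open")
  out[seq_len(n_volumes)]
}

# Discrete cosine drift basis: columns cos(pi * k * (2v - 1) / (2N)) for
# k = 1..K where K is the largest k with frequency k / (2 N tr) below
# `cutoff` (default the conventional 1/128 Hz high-pass edge).
dct_basis <- function(n_volumes, tr, cutoff = 1 / 128) {
  K <- floor(2 * n_volumes * tr * cutoff)
  v <- seq_len(n_volumes)
  if (K < 1L) return(matrix(numeric(0), nrow = n_volumes, ncol = 0))
  sapply(seq_len(K), function(k) cos(pi * k * (2 * v - 1) / (2 * n_volumes)))
}

#' Neural response specification for the synthetic generator
#'
#' Describes how a synthetic subject's independent-component (IC)
#' timecourses respond to the task: a mean response amplitude per trial
#' type and component, trial-by-trial amplitude jitter (`amp_sd`) whose
#' size controls how slowly the volume-wise GLM betas converge, motor
#' response amplitudes, AR(1) observation noise, and slow drift. Amplitudes
#' are in percent-signal-change units.
#'
#' @param n_components Number of usable ICs.
#' @param amp_mean Matrix `[6 trial types x n_components]` of mean response
#'   amplitudes, rows named `instruction, GG, GfSS, GfFS, SS, FS`. Defaults
#'   to a fixed structured pattern around 1.
#' @param amp_sd Trial-by-trial amplitude standard deviation: a scalar
#'   applied to every trial type, or a named vector over the six types so
#'   individual types can converge faster or slower than others.
#' @param amp_ar Autocorrelation of the amplitude jitter across successive
#'   trials of the same type, in `[0, 1)`. Trial-level response variability
#'   in task fMRI is not white: attention and arousal drift slowly, so a
#'   subject's effective response amplitude wanders over minutes. This
#'   drift is what makes a high-variance subject's beta estimate chase a
#'   moving target and converge slowly; with `amp_ar = 0` the jitter is
#'   independent across trials and mostly rescales the SoAD series without
#'   changing its decay rate.
#' @param motor_amp Per-component amplitude of the button-press response.
#' @param noise_sd Marginal SD of the AR(1) observation noise.
#' @param ar1 Lag-1 autocorrelation of the observation noise, in `[0, 1)`.
#' @param drift_amp SD of the random coefficients on the cosine drift basis.
#' @return A named list of class `neural_spec`.
#' @export
neural_spec <- function(n_components = 22L,
                        amp_mean = default_amp_mean(n_components),
                        amp_sd = 0.4,
                        amp_ar = 0.95,
                        motor_amp = default_motor_amp(n_components),
                        noise_sd = 1,
                        ar1 = 0.3,
                        drift_amp = 1) {
  n_components <- as.integer(n_components)
  stopifnot(is.matrix(amp_mean), ncol(amp_mean) == n_components,
            nrow(amp_mean) == 6L)
  if (is.null(rownames(amp_mean))) rownames(amp_mean) <- trial_type_levels()
  stopifnot(identical(rownames(amp_mean), trial_type_levels()))
  if (any(amp_sd < 0)) stop("amp_sd must be >= 0", call. = FALSE)
  if (amp_ar < 0 || amp_ar >= 1) stop("amp_ar must lie in [0, 1)", call. = FALSE)
  if (length(amp_sd) == 1L) {
    amp_sd <- stats::setNames(rep(amp_sd, 6L), trial_type_levels())
  } else {
    stopifnot(all(trial_type_levels() %in% names(amp_sd)))
    amp_sd <- amp_sd[trial_type_levels()]
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must lie in [0, 1)", call. = FALSE)
  structure(list(n_components = n_components, amp_mean = amp_mean,
                 amp_sd = amp_sd, amp_ar = amp_ar,
                 motor_amp = rep_len(motor_amp, n_components),
                 noise_sd = noise_sd, ar1 = ar1, drift_amp = drift_amp),
            class = "neural_spec")
}

#' Default mean-amplitude pattern
#'
#' A fixed, deterministic trial-type-by-component loading pattern centred
#' on 1 percent signal change, giving every trial type a distinct profile
#' across components.
#'
#' @param n_components Number of components.
#' @return A `6 x n_components` matrix with trial-type rownames.
#' @export
default_amp_mean <- function(n_components = 22L) {
  m <- outer(seq_len(6L), seq_len(n_components),
             function(i, j) 1 + 0.8 * sin(1.3 * i + 0.61 * j))
  rownames(m) <- trial_type_levels()
  m
}

#' @rdname default_amp_mean
#' @return `default_motor_amp()`: per-component motor-response amplitudes.
#' @export
default_motor_amp <- function(n_components = 22L) {
  0.5 + 0.3 * cos(0.9 * seq_len(n_components))
}

#' Simulate head-motion traces and framewise displacement
#'
#' Motion is a slow Gaussian random walk on 3 translations (mm) and 3
#' rotations (radians), with occasional persistent jumps ("spikes") on a
#' random translation axis that push the framewise displacement (FD) above
#' the 0.5 mm censoring threshold. FD is the Power backward-difference sum
#' over the six parameters with rotations converted to arc length on a
#' 50 mm sphere; FD at the first volume is 0 by convention.
#'
#' @param n_volumes Number of volumes.
#' @param spike_prob Per-volume probability of a motion spike.
#' @param seed Integer seed.
#' @param walk_sd_trans,walk_sd_rot Random-walk increment SDs (mm, rad).
#' @param spike_size Spike magnitude in mm.
#' @return A list with `motion6` (an `n_volumes x 6` matrix, columns
#'   `trans_x..rot_z`) and `fd` (length-`n_volumes` vector).
#' @export
synth_motion <- function(n_volumes, spike_prob = 0.02, seed = 1L,
                         walk_sd_trans = 0.01, walk_sd_rot = 2e-4,
                         spike_size = 0.8) {
  stopifnot(n_volumes > 0)
  with_seed(seed, {
    steps <- cbind(
      matrix(stats::rnorm(n_volumes * 3L, 0, walk_sd_trans), ncol = 3L),
      matrix(stats::rnorm(n_volumes * 3L, 0, walk_sd_rot), ncol = 3L)
    )
    steps[1L, ] <- 0
    spikes <- which(stats::runif(n_volumes) < spike_prob)
    spikes <- spikes[spikes > 1L]
    for (s in spikes) {
      axis <- sample.int(3L, 1L)
      steps[s, axis] <- steps[s, axis] + spike_size * sample(c(-1, 1), 1L)
    }
    motion6 <- apply(steps, 2L, cumsum)
    colnames(motion6) <- c("trans_x", "trans_y", "trans_z",
                           "rot_x", "rot_y", "rot_z")
    list(motion6 = motion6, fd = framewise_displacement(motion6))
  })
}

#' Framewise displacement from six motion parameters
#'
#' @param motion6 `n_volumes x 6` matrix: translations (mm) then rotations
#'   (radians).
#' @param rot_radius_mm Sphere radius converting rotations to mm.
#' @return Per-volume FD (mm); 0 at the first volume.
#' @export
framewise_displacement <- function(motion6, rot_radius_mm = 50) {
  stopifnot(is.matrix(motion6), ncol(motion6) == 6L)
  scaled <- motion6
  scaled[, 4:6] <- scaled[, 4:6] * rot_radius_mm
  d <- rbind(0, abs(diff(scaled)))
  rowSums(d)
}

#' Synthesize a subject's IC timecourses
#'
#' Builds the task component of each IC timecourse by placing one impulse
#' per task event at its onset, with amplitude
#' `amp_mean[label, component] + Normal(0, amp_sd^2)` drawn independently
#' per trial and component, convolving with [hrf_kernel()]; adds a motor
#' response (impulses at every button press, fixed per-component
#' amplitude), AR(1) observation noise, and random slow cosine drift.
#' Larger `amp_sd` produces noisier trial-level responses, hence slower
#' volume-wise beta convergence.
#'
#' @param paradigm A labeled `sst_paradigm`.
#' @param spec A [neural_spec()].
#' @param seed Integer seed.
#' @param subject_id Subject identifier string.
#' @param motion Optional result of [synth_motion()]; generated from a
#'   child seed when missing.
#' @param group,sex Optional covariates (`"CD"`/`"Con"`, `"M"`/`"F"`).
#' @return A `subject_dataset`: list with `subject_id`, `timecourses`
#'   (`n_volumes x n_components`), `tr`, `motion6`, `fd`, `paradigm`,
#'   `group`, `sex`, `spec`.
#' @export
synth_timecourses <- function(paradigm, spec = neural_spec(), seed = 1L,
                              subject_id = "sub-01", motion = NULL,
                              group = NA_character_, sex = NA_character_) {
  stopifnot(inherits(paradigm, "sst_paradigm"))
  if (anyNA(paradigm$label[paradigm$base_type %in% c("go", "stop")])) {
    stop("paradigm must be labeled (run label_trials())", call. = FALSE)
  }
  tr <- paradigm_tr(paradigm)
  n_vol <- paradigm_n_volumes(paradigm)
  nc <- spec$n_components
  kern <- hrf_kernel(tr)

  ev <- tibble::as_tibble(paradigm)
  task <- ev[ev$base_type %in% c("go", "stop", "instruction"), ]
  resp <- ev[!is.na(ev$responded) & ev$responded, ]

  if (is.null(motion)) {
    motion <- synth_motion(n_vol, seed = child_seed(seed, "motion"))
  }

  Y <- with_seed(child_seed(seed, "neural"), {
    # amplitude jitter: stationary AR(1) across successive trials of each
    # type (marginal sd amp_sd[type], lag-1 correlation amp_ar)
    eps <- matrix(0, nrow(task), nc)
    rho <- spec$amp_ar
    for (tt in unique(task$label)) {
      idx <- which(task$label == tt)
      sd_tt <- spec$amp_sd[tt]
      if (sd_tt <= 0) next
      e <- matrix(0, length(idx), nc)
      e[1L, ] <- stats::rnorm(nc, 0, sd_tt)
      if (length(idx) > 1L) {
        innov <- matrix(stats::rnorm((length(idx) - 1L) * nc, 0,
                                     sd_tt * sqrt(1 - rho^2)),
                        ncol = nc)
        for (r in 2L:length(idx)) e[r, ] <- rho * e[r - 1L, ] + innov[r - 1L, ]
      }
      eps[idx, ] <- e
    }
    amps <- spec$amp_mean[task$label, , drop = FALSE] + eps
    out <- matrix(0, n_vol, nc)
    for (j in seq_len(nc)) {
      out[, j] <- event_regressor(task$onset, n_vol, tr,
                                  amplitudes = amps[, j], kernel = kern)
    }
    if (nrow(resp)) {
      motor <- event_regressor(resp$onset + resp$rt_ms / 1000, n_vol, tr,
                               kernel = kern)
      out <- out + tcrossprod(motor, spec$motor_amp)
    }
    innov_sd <- spec$noise_sd * sqrt(1 - spec$ar1^2)
    noise <- sapply(seq_len(nc), function(j) {
      as.numeric(stats::filter(stats::rnorm(n_vol, 0, innov_sd),
                               spec$ar1, method = "recursive"))
    })
    B <- dct_basis(n_vol, tr)
    if (ncol(B)) {
      coefs <- matrix(stats::rnorm(ncol(B) * nc, 0, spec$drift_amp), ncol = nc)
      out <- out + B %*% coefs
    }
    out + noise
  })
  colnames(Y) <- sprintf("IC%02d", seq_len(nc))

  structure(list(subject_id = subject_id, timecourses = Y, tr = tr,
                 motion6 = motion$motion6, fd = motion$fd,
                 paradigm = paradigm, group = group, sex = sex, spec = spec),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat("<subject_dataset> ", x$subject_id, ": ",
      nrow(x$timecourses), " volumes x ", ncol(x$timecourses),
      " components, group = ", x$group, ", sex = ", x$sex, "\n", sep = "")
  invisible(x)
}

#' Cohort generation parameters
#'
#' @param n_cd,n_con Group sizes (cocaine-dependent, control).
#' @param group_effect Amplitude offset added to the CD group's mean
#'   response on the cells selected by `effect_rows`/`effect_components`.
#' @param effect_rows Trial types carrying the group effect.
#' @param effect_components Component indices carrying the group effect.
#' @param subject_sd SD of the subject-level jitter on `amp_mean`.
#' @param amp_sd_meanlog,amp_sd_sdlog Log-normal parameters of the
#'   per-subject trial-by-trial amplitude SD, giving the across-subject
#'   spread of convergence rates.
#' @param p_male_cd,p_male_con Male proportion per group (defaults 30/40
#'   and 14/27).
#' @param rt_mu_sd Across-subject SD (ms) of the mean go reaction time:
#'   subjects differ in overall speed, which is what makes truncated- and
#'   full-task mean RTs correlate strongly across a cohort.
#' @param n_components,noise_sd,ar1,drift_amp,motor_amp Passed to
#'   [neural_spec()].
#' @param spike_prob Motion-spike probability per volume.
#' @return A named list of class `cohort_config`.
#' @export
cohort_config <- function(n_cd = 40L, n_con = 27L, group_effect = 0.5,
                          effect_rows = c("GfSS", "SS"),
                          effect_components = NULL,
                          subject_sd = 0.2,
                          amp_sd_meanlog = log(0.4), amp_sd_sdlog = 0.5,
                          p_male_cd = 30 / 40, p_male_con = 14 / 27,
                          rt_mu_sd = 40,
                          n_components = 22L, noise_sd = 1, ar1 = 0.3,
                          drift_amp = 1, motor_amp = NULL,
                          spike_prob = 0.02) {
  structure(list(n_cd = as.integer(n_cd), n_con = as.integer(n_con),
                 group_effect = group_effect, effect_rows = effect_rows,
                 effect_components = effect_components,
                 subject_sd = subject_sd,
                 amp_sd_meanlog = amp_sd_meanlog, amp_sd_sdlog = amp_sd_sdlog,
                 p_male_cd = p_male_cd, p_male_con = p_male_con,
                 rt_mu_sd = rt_mu_sd,
                 n_components = as.integer(n_components),
                 noise_sd = noise_sd, ar1 = ar1, drift_amp = drift_amp,
                 motor_amp = motor_amp, spike_prob = spike_prob),
            class = "cohort_config")
}

#' Generate a synthetic CD/control cohort
#'
#' Each subject gets its own paradigm realisation and behavior, a mean
#' amplitude matrix equal to the population pattern plus a CD-only group
#' offset on selected trial-type-by-component cells plus subject-level
#' Gaussian jitter, and a subject-specific trial-by-trial amplitude SD
#' drawn log-normally so convergence rates vary across the cohort. Sexes
#' are assigned Bernoulli with the stated per-group male proportions.
#'
#' @param config A [cohort_config()].
#' @param paradigm_cfg A [paradigm_config()] shared by all subjects.
#' @param model A [race_model()] shared by all subjects.
#' @param seed Integer global seed, split per subject via [child_seed()].
#' @return A list of class `sst_cohort`: elements are `subject_dataset`s;
#'   attribute `manifest` is a tibble (subject_id, group, sex, amp_sd,
#'   seed).
#' @export
synth_cohort <- function(config = cohort_config(),
                         paradigm_cfg = paradigm_config(),
                         model = race_model(), seed = 1L) {
  cfg <- config
  stopifnot(cfg$n_cd >= 0L, cfg$n_con >= 0L)
  n <- cfg$n_cd + cfg$n_con
  groups <- rep(c("CD", "Con"), c(cfg$n_cd, cfg$n_con))
  nc <- cfg$n_components
  pop <- default_amp_mean(nc)
  eff_cols <- cfg$effect_components %||% seq_len(min(8L, nc))
  offset <- matrix(0, 6L, nc, dimnames = dimnames(pop))
  offset[cfg$effect_rows, eff_cols] <- cfg$group_effect

  subjects <- vector("list", n)
  man <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("sub-%03d", i)
    g <- groups[i]
    s_seed <- child_seed(seed, "subject", i)
    draw <- with_seed(child_seed(s_seed, "traits"), {
      list(
        jitter = matrix(stats::rnorm(6L * nc, 0, cfg$subject_sd), 6L, nc),
        amp_sd = stats::rlnorm(1, cfg$amp_sd_meanlog, cfg$amp_sd_sdlog),
        rt_shift = stats::rnorm(1, 0, cfg$rt_mu_sd),
        male = stats::runif(1) <
          if (g == "CD") cfg$p_male_cd else cfg$p_male_con
      )
    })
    subj_model <- model
    subj_model$go_rt_mu <- model$go_rt_mu + draw$rt_shift
    amp <- pop + draw$jitter + if (g == "CD") offset else 0
    rownames(amp) <- trial_type_levels()
    spec <- neural_spec(
      n_components = nc, amp_mean = amp, amp_sd = draw$amp_sd,
      motor_amp = cfg$motor_amp %||% default_motor_amp(nc),
      noise_sd = cfg$noise_sd, ar1 = cfg$ar1, drift_amp = cfg$drift_amp
    )
    p <- generate_paradigm(paradigm_cfg, seed = child_seed(s_seed, "paradigm"))
    p <- simulate_behavior(p, subj_model, seed = child_seed(s_seed, "behavior"))
    p <- label_trials(p)
    motion <- synth_motion(paradigm_n_volumes(p), spike_prob = cfg$spike_prob,
                           seed = child_seed(s_seed, "motion"))
    subjects[[i]] <- synth_timecourses(
      p, spec, seed = child_seed(s_seed, "bold"), subject_id = sid,
      motion = motion, group = g, sex = if (draw$male) "M" else "F"
    )
    man[[i]] <- tibble::tibble(subject_id = sid, group = g,
                               sex = if (draw$male) "M" else "F",
                               amp_sd = draw$amp_sd, seed = s_seed)
  }
  structure(subjects, manifest = dplyr::bind_rows(man),
            class = "sst_cohort")
}

#' @export
print.sst_cohort <- function(x, ...) {
  man <- attr(x, "manifest")
  cat("<sst_cohort> ", length(x), " subjects (",
      sum(man$group == "CD"), " CD / ", sum(man$group == "Con"), " Con)\n",
      sep = "")
  invisible(x)
}

#' Cohort manifest
#'
#' @param cohort An `sst_cohort`.
#' @return Tibble with one row per subject: subject_id, group, sex, amp_sd,
#'   seed.
#' @export
cohort_manifest <- function(cohort) attr(cohort, "manifest")
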