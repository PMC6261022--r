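#' Stop-signal task paradigm configuration
#'
#' Assembles the parameters of the performance-adjusted stop-signal task
#' (SST): a run of go trials in which a minority of trials additionally
#' present a stop signal after an adaptive stop-signal delay (SSD). Defaults
#' reproduce the canonical design: 300 task trials of which 75 are stop
#' trials, a fixed 2,000 ms inter-trial interval, SSD starting at 250 ms and
#' stepping by +/- 50 ms, three 20 s rest blocks, and a 502-volume
#' acquisition at TR = 2 s.
#'
#' The per-trial stimulus window (`trial_dur_ms`) controls how the 300 trials
#' are spread across the scan: consecutive trial onsets are separated by
#' `trial_dur_ms + iti_ms`. The default of 1,100 ms fills 497 of the 502
#' volumes, leaving a short rest tail at the end of the run.
#'
#' @param n_trials Total number of go/stop task trials.
#' @param n_stop Number of stop trials among `n_trials`.
#' @param iti_ms Inter-trial interval in milliseconds.
#' @param trial_dur_ms Stimulus window per trial in milliseconds; trial
#'   onsets are spaced `trial_dur_ms + iti_ms` apart.
#' @param ssd_init_ms Initial stop-signal delay in milliseconds.
#' @param ssd_step_ms Staircase step size in milliseconds.
#' @param ssd_floor_ms Lowest SSD the staircase may reach.
#' @param rest_after Trial indices after which a rest block is inserted.
#' @param rest_dur_s Duration of each rest block in seconds.
#' @param instr_dur_s Duration of the instruction block at run start, seconds.
#' @param tr_s Repetition time (volume duration) in seconds.
#' @param n_volumes Number of acquired volumes.
#' @return A named list of class `sst_config`.
#' @export
#' @examples
#' cfg <- paradigm_config()
#' cfg$n_trials
paradigm_config <- function(n_trials = 300L,
                            n_stop = 75L,
                            iti_ms = 2000,
                            trial_dur_ms = 1100,
                            ssd_init_ms = 250,
                            ssd_step_ms = 50,
                            ssd_floor_ms = 0,
                            rest_after = c(75L, 150L, 225L),
                            rest_dur_s = 20,
                            instr_dur_s = 4,
                            tr_s = 2,
                            n_volumes = 502L) {
  cfg <- list(
    n_trials = as.integer(n_trials), n_stop = as.integer(n_stop),
    iti_ms = iti_ms, trial_dur_ms = trial_dur_ms,
    ssd_init_ms = ssd_init_ms, ssd_step_ms = ssd_step_ms,
    ssd_floor_ms = ssd_floor_ms,
    rest_after = as.integer(rest_after), rest_dur_s = rest_dur_s,
    instr_dur_s = instr_dur_s, tr_s = tr_s, n_volumes = as.integer(n_volumes)
  )
  if (cfg$n_stop > cfg$n_trials) {
    stop("invalid configuration: n_stop (", cfg$n_stop,
         ") exceeds n_trials (", cfg$n_trials, ")", call. = FALSE)
  }
  if (cfg$n_stop > (cfg$n_trials + 1L) %/% 2L) {
    stop("invalid configuration: cannot place ", cfg$n_stop,
         " non-consecutive stop trials among ", cfg$n_trials, " trials",
         call. = FALSE)
  }
  if (cfg$tr_s <= 0) stop("invalid configuration: tr_s must be positive", call. = FALSE)
  structure(cfg, class = "sst_config")
}

#' Horse-race behavioral model parameters
#'
#' Parameters of the independent horse-race model used to simulate subject
#' behavior on the SST: an ex-Gaussian go process races an inhibitory stop
#' process of fixed latency (the stop-signal reaction time, SSRT). A stop
#' trial is successfully inhibited when `ssd + ssrt` precedes the sampled go
#' finishing time.
#'
#' @param go_rt_mu,go_rt_sigma Mean and SD of the Gaussian component of the
#'   go reaction time, ms.
#' @param go_rt_tau Mean of the exponential component, ms.
#' @param ssrt Stop-signal reaction time, ms.
#' @param omission_rate Probability that the go process never produces a
#'   response on a trial.
#' @return A named list of class `race_model`.
#' @export
race_model <- function(go_rt_mu = 450, go_rt_sigma = 80, go_rt_tau = 60,
                       ssrt = 250, omission_rate = 0.02) {
  m <- list(go_rt_mu = go_rt_mu, go_rt_sigma = go_rt_sigma,
            go_rt_tau = go_rt_tau, ssrt = ssrt,
            omission_rate = omission_rate)
  ok <- all(vapply(m, function(v) is.numeric(v) && is.finite(v), logical(1)))
  if (!ok) stop("race model parameters must be finite numbers", call. = FALSE)
  if (m$go_rt_sigma <= 0) stop("go_rt_sigma must be > 0", call. = FALSE)
  if (m$ssrt <= 0) stop("ssrt must be > 0", call. = FALSE)
  if (m$omission_rate < 0 || m$omission_rate >= 1) {
    stop("omission_rate must lie in [0, 1)", call. = FALSE)
  }
  structure(m, class = "race_model")
}

new_paradigm <- function(events, cfg, rest_blocks) {
  structure(events,
            tr = cfg$tr_s, n_volumes = cfg$n_volumes,
            rest_blocks = rest_blocks, config = cfg,
            class = c("sst_paradigm", class(tibble::tibble())))
}

#' @export
print.sst_paradigm <- function(x, ...) {
  cat("<sst_paradigm> ", sum(x$base_type %in% c("go", "stop")),
      " task trials, TR = ", attr(x, "tr"), " s, ",
      attr(x, "n_volumes"), " volumes\n", sep = "")
  NextMethod()
}

#' Paradigm attribute accessors
#'
#' @param paradigm An `sst_paradigm` object.
#' @return `paradigm_tr()` the repetition time in seconds;
#'   `paradigm_n_volumes()` the number of acquired volumes.
#' @export
paradigm_tr <- function(paradigm) attr(paradigm, "tr")

#' @rdname paradigm_tr
#' @export
paradigm_n_volumes <- function(paradigm) attr(paradigm, "n_volumes")

#' Generate a stop-signal task trial sequence
#'
#' Lays out an instruction block, task trials, and rest blocks on the scan
#' timeline and assigns stop trials to uniformly random, non-consecutive
#' trial slots. Behavioral fields (`ssd_ms`, `responded`, `rt_ms`) and trial
#' labels are left unset; fill them with [simulate_behavior()] and
#' [label_trials()].
#'
#' Stop positions are drawn uniformly among all subsets of trial slots with
#' no two adjacent stops, via the standard combination-with-gaps bijection.
#'
#' @param config An [paradigm_config()] list.
#' @param seed Integer seed; the event table is a pure function of
#'   `(config, seed)`.
#' @return An `sst_paradigm`: a tibble of events (columns `index`, `onset`,
#'   `duration`, `base_type`, `ssd_ms`, `responded`, `rt_ms`, `label`) with
#'   attributes `tr`, `n_volumes`, `rest_blocks`, `config`.
#' @export
#' @examples
#' p <- generate_paradigm(paradigm_config(), seed = 1)
#' table(p$base_type)
generate_paradigm <- function(config = paradigm_config(), seed = 1L) {
  cfg <- if (inherits(config, "sst_config")) config else do.call(paradigm_config, config)

  n <- cfg$n_trials
  stop_pos <- integer(0)
  if (cfg$n_stop > 0L) {
    s <- with_seed(seed, sort(sample.int(n - cfg$n_stop + 1L, cfg$n_stop)))
    stop_pos <- s + seq_len(cfg$n_stop) - 1L
  }

  spacing <- (cfg$trial_dur_ms + cfg$iti_ms) / 1000
  rows <- vector("list", n + length(cfg$rest_after) + 1L)
  rests <- list()
  cursor <- 0
  ri <- 1L
  rows[[ri]] <- list(onset = cursor, duration = cfg$instr_dur_s,
                     base_type = "instruction")
  cursor <- cursor + cfg$instr_dur_s
  for (i in seq_len(n)) {
    ri <- ri + 1L
    rows[[ri]] <- list(onset = cursor, duration = cfg$trial_dur_ms / 1000,
                       base_type = if (i %in% stop_pos) "stop" else "go")
    cursor <- cursor + spacing
    if (i %in% cfg$rest_after) {
      ri <- ri + 1L
      rows[[ri]] <- list(onset = cursor, duration = cfg$rest_dur_s,
                         base_type = "rest")
      rests[[length(rests) + 1L]] <- c(onset = cursor, duration = cfg$rest_dur_s)
      cursor <- cursor + cfg$rest_dur_s
    }
  }

  events <- dplyr::bind_rows(lapply(rows[seq_len(ri)], tibble::as_tibble))
  events <- tibble::tibble(
    index = seq_len(nrow(events)) - 1L,
    onset = events$onset, duration = events$duration,
    base_type = events$base_type,
    ssd_ms = NA_real_, responded = NA, rt_ms = NA_real_,
    label = NA_character_
  )

  rests <- if (length(rests)) {
    tibble::tibble(onset = vapply(rests, `[[`, numeric(1), "onset"),
                   duration = vapply(rests, `[[`, numeric(1), "duration"))
  } else {
    tibble::tibble(onset = numeric(0), duration = numeric(0))
  }

  total <- cfg$n_volumes * cfg$tr_s
  if (any(events$onset >= total)) {
    stop("invalid configuration: events extend past the scan end (",
         round(max(events$onset), 1), " s >= ", total, " s); increase ",
         "n_volumes or shorten the trial layout", call. = FALSE)
  }
  new_paradigm(events, cfg, rests)
}

#' Adaptive stop-signal-delay staircase update
#'
#' One step of the SSD staircase: successful inhibition makes the next stop
#' harder (SSD + step); a failed stop (error of commission) makes it easier
#' (SSD - step), floored at `floor_ms`.
#'
#' @param ssd Current stop-signal delay, ms; must be non-negative.
#' @param stop_outcome `"success"` or `"failure"`.
#' @param step_ms Staircase step, ms.
#' @param floor_ms Lowest admissible SSD, ms.
#' @return Updated SSD in ms.
#' @export
#' @examples
#' update_ssd(250, "success") # 300
#' update_ssd(250, "failure") # 200
update_ssd <- function(ssd, stop_outcome = c("success", "failure"),
                       step_ms = 50, floor_ms = 0) {
  stop_outcome <- match.arg(stop_outcome)
  if (!is.numeric(ssd) || length(ssd) != 1L || is.na(ssd) || ssd < 0) {
    stop("invalid staircase state: ssd must be a single non-negative number",
         call. = FALSE)
  }
  if (stop_outcome == "success") ssd + step_ms else max(ssd - step_ms, floor_ms)
}

rexgauss <- function(n, mu, sigma, tau) {
  pmax(stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau), 1)
}

#' Simulate subject behavior on a stop-signal paradigm
#'
#' Runs the horse-race model through the trial sequence: go trials respond
#' with probability `1 - omission_rate` at an ex-Gaussian latency; on stop
#' trials the go process races the stop process, succeeding to stop iff
#' `ssd + ssrt` precedes the sampled go finishing time (an omitted go counts
#' as a successful stop). The SSD staircase is updated after every stop
#' trial via [update_ssd()], starting at `config$ssd_init_ms`.
#'
#' @param paradigm An `sst_paradigm` with unset behavior.
#' @param model A [race_model()].
#' @param seed Integer seed.
#' @return The paradigm with `ssd_ms`, `responded` and `rt_ms` filled in.
#' @export
simulate_behavior <- function(paradigm, model = race_model(), seed = 1L) {
  stopifnot(inherits(paradigm, "sst_paradigm"))
  if (!inherits(model, "race_model")) model <- do.call(race_model, model)
  cfg <- attr(paradigm, "config")

  ev <- tibble::as_tibble(paradigm)
  task <- which(ev$base_type %in% c("go", "stop"))
  ssd <- cfg$ssd_init_ms
  with_seed(seed, {
    for (i in task) {
      omitted <- stats::runif(1) < model$omission_rate
      finish <- rexgauss(1, model$go_rt_mu, model$go_rt_sigma, model$go_rt_tau)
      if (ev$base_type[i] == "go") {
        if (omitted) {
          ev$responded[i] <- FALSE
        } else {
          ev$responded[i] <- TRUE
          ev$rt_ms[i] <- finish
        }
      } else {
        ev$ssd_ms[i] <- ssd
        success <- omitted || (ssd + model$ssrt < finish)
        if (success) {
          ev$responded[i] <- FALSE
        } else {
          ev$responded[i] <- TRUE
          ev$rt_ms[i] <- finish
        }
        ssd <- update_ssd(ssd, if (success) "success" else "failure",
                          step_ms = cfg$ssd_step_ms, floor_ms = cfg$ssd_floor_ms)
      }
    }
  })
  new_paradigm(ev, cfg, attr(paradigm, "rest_blocks"))
}

#' Assign the six SST trial-type labels
#'
#' Stop trials are labeled from their own outcome (`SS` successful stop,
#' `FS` failed stop). Go trials are labeled by their immediately preceding
#' task trial: go -> `GG`, SS -> `GfSS`, FS -> `GfFS`. The first task trial
#' and go trials immediately following an instruction or rest block default
#' to `GG`. Instruction events are labeled `instruction`; rest events get
#' `none`.
#'
#' @param paradigm An `sst_paradigm` with behavior simulated.
#' @return The paradigm with the `label` column filled.
#' @export
label_trials <- function(paradigm) {
  stopifnot(inherits(paradigm, "sst_paradigm"))
  ev <- tibble::as_tibble(paradigm)
  task <- which(ev$base_type %in% c("go", "stop"))
  if (length(task) && anyNA(ev$responded[task])) {
    stop("unlabeled behavior: run simulate_behavior() before label_trials()",
         call. = FALSE)
  }
  lab <- rep("none", nrow(ev))
  lab[ev$base_type == "instruction"] <- "instruction"
  prev_lab <- NA_character_   # label of the preceding task trial, if adjacent
  for (i in seq_len(nrow(ev))) {
    bt <- ev$base_type[i]
    if (bt %in% c("instruction", "rest")) {
      prev_lab <- NA_character_  # block boundary resets the predecessor
      next
    }
    if (bt == "stop") {
      lab[i] <- if (isTRUE(ev$responded[i])) "FS" else "SS"
    } else {
      lab[i] <- switch(ifelse(is.na(prev_lab), "none", prev_lab),
                       SS = "GfSS", FS = "GfFS", "GG")
    }
    prev_lab <- lab[i]
  }
  ev$label <- lab
  new_paradigm(ev, attr(paradigm, "config"), attr(paradigm, "rest_blocks"))
}

#' Reconstruct the SSD staircase from stop-trial labels
#'
#' The staircase is a deterministic function of the stop outcomes, so the
#' full SSD sequence can be rebuilt from the ordered SS/FS labels and the
#' initial delay. Useful for audit: it must reproduce the simulated
#' `ssd_ms` column exactly.
#'
#' @param labels Character vector of stop-trial labels, in trial order;
#'   each `"SS"` or `"FS"`.
#' @param ssd_init_ms,step_ms,floor_ms Staircase parameters.
#' @return Numeric vector: the SSD presented at each stop trial.
#' @export
staircase_from_labels <- function(labels, ssd_init_ms = 250, step_ms = 50,
                                  floor_ms = 0) {
  stopifnot(all(labels %in% c("SS", "FS")))
  ssd <- numeric(length(labels))
  cur <- ssd_init_ms
  for (i in seq_along(labels)) {
    ssd[i] <- cur
    cur <- update_ssd(cur, if (labels[i] == "SS") "success" else "failure",
                      step_ms = step_ms, floor_ms = floor_ms)
  }
  ssd
}

#' Fraction of stop trials successfully inhibited
#'
#' @param paradigm A labeled `sst_paradigm`.
#' @return Proportion of stop trials labeled `SS`.
#' @export
stop_success_rate <- function(paradigm) {
  stops <- paradigm$label[paradigm$base_type == "stop"]
  if (!length(stops)) return(NA_real_)
  mean(stops == "SS")
}
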