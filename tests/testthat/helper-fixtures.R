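# Small study configurations used across the suite: 40 trials / 10 stops on
# a 100-volume scan keeps every property testable in well under a second.

small_cfg <- function(n_volumes = 100L, n_trials = 40L, n_stop = 10L,
                      rest_after = c(20L), ...) {
  paradigm_config(n_trials = n_trials, n_stop = n_stop,
                  rest_after = rest_after, n_volumes = n_volumes, ...)
}

small_paradigm <- function(seed = 1, cfg = small_cfg(),
                           model = race_model()) {
  label_trials(simulate_behavior(generate_paradigm(cfg, seed), model,
                                 seed + 1000))
}

small_subject <- function(seed = 1, amp_sd = 0.4, noise_sd = 1, nc = 3L,
                          cfg = small_cfg(), ...) {
  p <- small_paradigm(seed, cfg)
  sp <- neural_spec(n_components = nc, amp_mean = default_amp_mean(nc),
                    amp_sd = amp_sd, noise_sd = noise_sd, ...)
  synth_timecourses(p, sp, seed = seed + 2000)
}

# Hand-built trajectory whose beta values are a known function of
# (volume, trial type, component): beta = volume + 1000*type_index + comp.
fake_trajectory <- function(t_start = 50L, T = 60L, nc = 2L,
                            subject_id = "sub-999",
                            fill = function(t, ty, co) t + 1000 * ty + co) {
  types <- c("instruction", "GG", "GfSS", "GfFS", "SS", "FS")
  comps <- sprintf("IC%02d", seq_len(nc))
  ts <- t_start:T
  betas <- array(0, dim = c(length(ts), 6L, nc),
                 dimnames = list(volume = ts, trial_type = types,
                                 component = comps))
  for (i in seq_along(ts)) {
    for (ty in seq_len(6L)) {
      for (co in seq_len(nc)) betas[i, ty, co] <- fill(ts[i], ty, co)
    }
  }
  structure(list(subject_id = subject_id, t_start = t_start, T = T,
                 trial_types = types, components = comps, betas = betas,
                 censored = rep(FALSE, T), rank_deficient = logical(length(ts)),
                 converged = TRUE, group = NA_character_,
                 sex = NA_character_),
            class = "beta_trajectory")
}

# Exact one-sided signed-rank p by full enumeration of the 2^n sign
# patterns (no ties or zeros allowed).
enum_signedrank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  mean(signs %*% r >= W)
}
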