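check_columns <- function(d, need, path) {
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Write and read paradigm event tables
#'
#' Events are stored as tab-separated text in the BIDS events dialect:
#' columns `onset` (s), `duration` (s), `trial_type` (the SST label),
#' `base_type`, `ssd_ms`, `response` (0/1), `rt_ms`, with `n/a` for
#' missing values. The scan geometry (TR, volume count) travels in a
#' matching `.json` sidecar so that `read_events()` can rebuild the
#' paradigm object losslessly.
#'
#' @param paradigm An `sst_paradigm`.
#' @param path Output `.tsv` path; the sidecar is written alongside with
#'   extension `.json`.
#' @return `write_events()` the path, invisibly; `read_events()` an
#'   `sst_paradigm`.
#' @export
write_events <- function(paradigm, path) {
  stopifnot(inherits(paradigm, "sst_paradigm"))
  ev <- tibble::as_tibble(paradigm)
  out <- tibble::tibble(
    onset = ev$onset, duration = ev$duration,
    trial_type = ev$label, base_type = ev$base_type,
    ssd_ms = ev$ssd_ms,
    response = ifelse(is.na(ev$responded), NA_integer_,
                      as.integer(ev$responded)),
    rt_ms = ev$rt_ms
  )
  readr::write_tsv(out, path, na = "n/a")
  side <- list(tr = paradigm_tr(paradigm),
               n_volumes = paradigm_n_volumes(paradigm),
               rest_blocks = attr(paradigm, "rest_blocks"),
               config = unclass(attr(paradigm, "config")))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' @rdname write_events
#' @export
read_events <- function(path) {
  d <- readr::read_tsv(path, na = "n/a", show_col_types = FALSE,
                       progress = FALSE)
  check_columns(d, c("onset", "duration", "trial_type", "base_type",
                     "ssd_ms", "response", "rt_ms"), path)
  if (is.unsorted(d$onset, strictly = TRUE)) {
    bad <- which(diff(d$onset) <= 0)[1L] + 1L
    stop("schema error in ", path, ": onsets not strictly increasing at line ",
         bad + 1L, call. = FALSE)
  }
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  ev <- tibble::tibble(
    index = seq_len(nrow(d)) - 1L,
    onset = d$onset, duration = d$duration, base_type = d$base_type,
    ssd_ms = d$ssd_ms,
    responded = ifelse(is.na(d$response), NA, d$response == 1L),
    rt_ms = d$rt_ms, label = d$trial_type
  )
  cfg <- do.call(paradigm_config, side$config[names(side$config) %in%
                                                names(formals(paradigm_config))])
  rests <- side$rest_blocks
  rests <- if (is.null(rests) || !length(rests)) {
    tibble::tibble(onset = numeric(0), duration = numeric(0))
  } else {
    tibble::as_tibble(rests)
  }
  new_paradigm(ev, cfg, rests)
}

#' Write and read numeric matrices as TSV
#'
#' Matrices (IC timecourses, motion parameters) are stored as plain TSV
#' with a header row of column names; round trips are exact to float
#' formatting (17 significant digits).
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @return `write_matrix()` the path, invisibly; `read_matrix()` a
#'   numeric matrix.
#' @export
write_matrix <- function(m, path) {
  d <- tibble::as_tibble(as.data.frame(m))
  readr::write_tsv(d, path, na = "n/a")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  d <- readr::read_tsv(path, na = "n/a", show_col_types = FALSE,
                       progress = FALSE)
  m <- as.matrix(d)
  if (!is.numeric(m)) {
    stop("schema error in ", path, ": non-numeric entries", call. = FALSE)
  }
  m
}

#' Write and read beta trajectories
#'
#' The trajectory is serialised as a long-format TSV (`subject_id`,
#' `volume`, `trial_type`, `component`, `beta`) with a JSON sidecar
#' carrying `t_start`, the last volume, the censor count, per-volume
#' rank-deficiency flags and covariates.
#'
#' @param trajectory A `beta_trajectory`.
#' @param path Output `.tsv` path.
#' @return `write_betas()` the path, invisibly; `read_betas()` a
#'   `beta_trajectory`.
#' @export
write_betas <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "beta_trajectory"))
  readr::write_tsv(tidy(trajectory), path, na = "n/a")
  side <- list(subject_id = trajectory$subject_id,
               t_start = trajectory$t_start, T = trajectory$T,
               trial_types = trajectory$trial_types,
               components = trajectory$components,
               n_censored = sum(trajectory$censored),
               censored = which(trajectory$censored),
               rank_deficient = which(trajectory$rank_deficient),
               converged = trajectory$converged,
               group = trajectory$group, sex = trajectory$sex)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_betas
#' @export
read_betas <- function(path) {
  d <- readr::read_tsv(path, na = "n/a", show_col_types = FALSE,
                       progress = FALSE)
  check_columns(d, c("subject_id", "volume", "trial_type", "component",
                     "beta"), path)
  if (anyNA(d$beta) || any(!is.finite(d$beta))) {
    bad <- which(!is.finite(d$beta))[1L]
    stop("schema error in ", path, ": non-finite beta at line ", bad + 1L,
         call. = FALSE)
  }
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  ts <- sort(unique(d$volume))
  types <- side$trial_types
  comps <- side$components
  betas <- array(NA_real_, dim = c(length(ts), length(types), length(comps)),
                 dimnames = list(volume = ts, trial_type = types,
                                 component = comps))
  betas[cbind(match(d$volume, ts), match(d$trial_type, types),
              match(d$component, comps))] <- d$beta
  censored <- rep(FALSE, side$T)
  censored[unlist(side$censored)] <- TRUE
  rank_def <- rep(FALSE, length(ts))
  rank_def[unlist(side$rank_deficient)] <- TRUE
  structure(list(
    subject_id = side$subject_id, t_start = as.integer(side$t_start),
    T = as.integer(side$T), trial_types = types, components = comps,
    betas = betas, censored = censored, rank_deficient = rank_def,
    converged = isTRUE(side$converged),
    group = side$group %||% NA_character_,
    sex = side$sex %||% NA_character_
  ), class = "beta_trajectory")
}

#' Write a subject dataset to a directory
#'
#' Writes the events table (+ sidecar), IC timecourses, motion parameters
#' and framewise displacement of one subject as TSV files named by
#' subject id.
#'
#' @param dataset A `subject_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_subject <- function(dataset, dir) {
  stopifnot(inherits(dataset, "subject_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stub <- file.path(dir, dataset$subject_id)
  write_events(dataset$paradigm, paste0(stub, "_events.tsv"))
  write_matrix(dataset$timecourses, paste0(stub, "_timecourses.tsv"))
  write_matrix(dataset$motion6, paste0(stub, "_motion.tsv"))
  write_matrix(matrix(dataset$fd, ncol = 1L, dimnames = list(NULL, "fd")),
               paste0(stub, "_fd.tsv"))
  invisible(dir)
}

#' Read and write run configuration as YAML
#'
#' @param config A [run_config()] list.
#' @param path YAML file path.
#' @return `write_run_config()` the path, invisibly; `read_run_config()`
#'   a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(strip_attrs(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[names(raw) %in% names(formals(run_config))])
}
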