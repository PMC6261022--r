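strip_attrs <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_attrs) else x
}

#' Full run configuration
#'
#' Bundles the per-stage parameter blocks of the end-to-end pipeline.
#' Every default equals the canonical study value where one exists
#' (burn-in at the 50th volume, FD censoring at 0.5 mm, 1000 LOOCV
#' resamples, k = 1..4 half-lives, Bonferroni family of 16).
#'
#' @param paradigm [paradigm_config()] block (or plain list of its
#'   arguments).
#' @param race [race_model()] block.
#' @param cohort [cohort_config()] block.
#' @param vwglm List: `burn_in`, `fd_threshold`, `drift_cutoff`.
#' @param decay List: `robust`, `anchor`.
#' @param validation List: `n_resamples`, `k`, `bonferroni`,
#'   `residualize_sex`.
#' @param seed Integer global seed.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(paradigm = paradigm_config(),
                       race = race_model(),
                       cohort = cohort_config(),
                       vwglm = list(),
                       decay = list(),
                       validation = list(),
                       seed = 1L) {
  as_block <- function(x, ctor, cls) {
    if (inherits(x, cls)) x else do.call(ctor, x)
  }
  vw <- utils::modifyList(
    list(burn_in = 50L, fd_threshold = 0.5, drift_cutoff = 1 / 128), vwglm)
  dc <- utils::modifyList(list(robust = TRUE, anchor = "t_start"), decay)
  vl <- utils::modifyList(
    list(n_resamples = 1000L, k = 1:4, bonferroni = 16L,
         residualize_sex = FALSE), validation)
  structure(list(
    paradigm = as_block(paradigm, paradigm_config, "sst_config"),
    race = as_block(race, race_model, "race_model"),
    cohort = as_block(cohort, cohort_config, "cohort_config"),
    vwglm = vw, decay = dc, validation = vl, seed = as.integer(seed)
  ), class = "run_config")
}

condition_tag <- function(trial_type, k) paste0(trial_type, "_k", k)

#' Accuracy table in the standard report layout
#'
#' Arranges LOOCV accuracies as rows = half-life 1..4 plus the full task,
#' columns = the four trial types, with significance flags from the
#' chance and pairwise tests.
#'
#' @param cv_results Named list of `cv_result`s; names are
#'   `<trial_type>_k<k>` plus `full_task`.
#' @param alpha Significance level for the flags.
#' @param bonferroni Family size for the pairwise adjustment.
#' @return Tibble with columns `task_length`, one column per trial type,
#'   and flag columns `<type>_sig`.
#' @export
accuracy_table <- function(cv_results, alpha = 0.05, bonferroni = 16L) {
  types <- feature_trial_types()
  full <- cv_results[["full_task"]]
  rows <- lapply(c(1:4, NA), function(kk) {
    vals <- sapply(types, function(tt) {
      r <- if (is.na(kk)) full else cv_results[[condition_tag(tt, kk)]]
      if (is.null(r)) NA_real_ else r$accuracy
    })
    sig <- sapply(types, function(tt) {
      r <- if (is.na(kk)) full else cv_results[[condition_tag(tt, kk)]]
      if (is.null(r)) NA else test_vs_chance(r)$p_value < alpha
    })
    tibble::tibble(
      task_length = if (is.na(kk)) "full task" else paste0(kk, " half-life"),
      !!!stats::setNames(as.list(vals), types),
      !!!stats::setNames(as.list(sig), paste0(types, "_sig"))
    )
  })
  dplyr::bind_rows(rows)
}

#' Run the full synthetic study pipeline
#'
#' Simulation, volume-wise GLM, decay/OST estimation, balanced-LOOCV
#' classification of OST-truncated versus full-task features, and the
#' behavioral reaction-time correlations, in one call. With `out_dir` set,
#' every intermediate is written as diffable TSV/CSV/JSON and a manifest
#' is produced.
#'
#' For each classification condition `(trial type X, k)`, each subject's
#' stopping volume is its own OST at k half-lives for X, and the betas of
#' all four trial types at that volume form the feature.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param stages Character subset of
#'   `c("simulate", "vwglm", "decay", "classify", "behave")`; later stages
#'   require earlier ones.
#' @return A list of class `ost_run`: `cohort`, `trajectories`, `decays`,
#'   `osts`, `cv_results`, `chance_tests`, `pairwise_tests`,
#'   `accuracy`, `rt_cors`, `ost_summaries`, `warnings`, `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         stages = c("simulate", "vwglm", "decay",
                                    "classify", "behave")) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  warnings <- character(0)
  res <- list(config = config)

  cohort <- synth_cohort(config$cohort, config$paradigm, config$race,
                         seed = child_seed(seed, "cohort"))
  res$cohort <- cohort
  man <- cohort_manifest(cohort)
  if (!"simulate" %in% stages || !"vwglm" %in% stages) {
    return(structure(res, class = "ost_run"))
  }

  trajectories <- lapply(cohort, run_vwglm,
                         burn_in = config$vwglm$burn_in,
                         fd_threshold = config$vwglm$fd_threshold,
                         drift_cutoff = config$vwglm$drift_cutoff)
  bad <- !vapply(trajectories, function(x) x$converged, logical(1))
  if (any(bad)) {
    warnings <- c(warnings, paste0("excluded subject (no regressor support): ",
                                   man$subject_id[bad]))
  }
  rank_n <- vapply(trajectories, function(x) sum(x$rank_deficient), integer(1))
  if (any(rank_n > 0)) {
    warnings <- c(warnings,
                  paste0("rank-deficient fits: ",
                         man$subject_id[rank_n > 0], " (", rank_n[rank_n > 0],
                         " volumes)"))
  }
  trajectories <- trajectories[!bad]
  man_used <- man[!bad, ]
  res$trajectories <- trajectories
  if (!"decay" %in% stages) {
    res$warnings <- warnings
    return(structure(res, class = "ost_run"))
  }

  decays <- decay_table(trajectories, robust = config$decay$robust)
  Tn <- config$paradigm$n_volumes
  osts <- ost_table(decays, k = config$validation$k, T = Tn,
                    anchor = config$decay$anchor)
  if (any(!decays$valid)) {
    warnings <- c(warnings,
                  paste0("invalid (non-decaying) fit: ",
                         decays$subject_id[!decays$valid], " ",
                         decays$trial_type[!decays$valid]))
  }
  n_clip <- sum(osts$clipped)
  if (n_clip) warnings <- c(warnings, paste0("clipped OSTs: ", n_clip))
  res$decays <- decays
  res$osts <- osts
  res$ost_summaries <- list(
    overall = ost_summary(osts),
    by_group = ost_summary(osts, man_used)
  )
  res$group_tests <- list(
    cd_vs_con = ost_group_compare(osts, man_used, k = 1, by = "group"),
    trial_types = ost_group_compare(osts, man_used, k = 1, by = "trial_type")
  )

  if ("classify" %in% stages) {
    labels <- man_used$group
    sexes <- man_used$sex
    conds <- list(full_task = rep(Tn, length(trajectories)))
    for (tt in feature_trial_types()) {
      for (kk in config$validation$k) {
        sv <- osts[osts$trial_type == tt & osts$k == kk, ]
        conds[[condition_tag(tt, kk)]] <-
          sv[match(man_used$subject_id, sv$subject_id), ]$stop_volume
      }
    }
    cv_results <- list()
    for (tag in names(conds)) {
      fm <- feature_matrix(trajectories, tibble::tibble(
        subject_id = man_used$subject_id, stop_volume = conds[[tag]]))
      if (isTRUE(config$validation$residualize_sex)) {
        fm <- residualize_sex(fm, sexes)
      }
      cv_results[[tag]] <- balanced_loocv(
        fm, labels, n_resamples = config$validation$n_resamples,
        seed = child_seed(seed, paste0("loocv_", tag)),
        condition = tag)
    }
    res$cv_results <- cv_results
    res$chance_tests <- purrr::map_dfr(cv_results, function(r) {
      t <- test_vs_chance(r)
      tibble::tibble(condition = r$condition, accuracy = r$accuracy,
                     p_vs_chance = t$p_value)
    })
    res$pairwise_tests <- purrr::map_dfr(
      setdiff(names(cv_results), "full_task"), function(tag) {
        t <- test_pairwise(cv_results[[tag]], cv_results[["full_task"]],
                           n_comparisons = config$validation$bonferroni)
        tibble::tibble(condition = tag, p_raw = t$p_raw,
                       p_adjusted = t$p_value)
      })
    res$accuracy <- accuracy_table(cv_results,
                                   bonferroni = config$validation$bonferroni)
  }

  if ("behave" %in% stages) {
    cohort_used <- cohort[!bad]
    res$rt_cors <- purrr::map_dfr(
      setdiff(feature_trial_types(), "SS"), function(tt) {
        purrr::map_dfr(config$validation$k, function(kk) {
          sv <- osts[osts$trial_type == tt & osts$k == kk,
                     c("subject_id", "stop_volume")]
          out <- tryCatch(rt_correlation(cohort_used, sv, tt),
                          error = function(e) {
                            tibble::tibble(trial_type = tt, r = NA_real_,
                                           p_value = NA_real_,
                                           n_used = 0L, n_excluded = NA_integer_)
                          })
          dplyr::mutate(out, k = kk, .after = "trial_type")
        })
      })
  }

  res$warnings <- warnings
  run <- structure(res, class = "ost_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.ost_run <- function(x, ...) {
  cat("<ost_run> ", length(x$cohort), " subjects",
      if (!is.null(x$trajectories)) paste0(", ", length(x$trajectories),
                                           " trajectories"),
      if (!is.null(x$accuracy)) ", classification done", "\n", sep = "")
  if (length(x$warnings)) {
    cat("warnings:\n")
    for (w in x$warnings) cat("  - ", w, "\n", sep = "")
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' @param run An `ost_run`.
#' @param out_dir Output directory.
#' @return The directory, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort_manifest(run$cohort)
  readr::write_csv(man, file.path(out_dir, "cohort_manifest.csv"))
  if (!is.null(run$decays)) {
    readr::write_tsv(run$decays, file.path(out_dir, "decay_report.tsv"))
    readr::write_tsv(run$osts, file.path(out_dir, "ost_table.tsv"))
    jsonlite::write_json(
      lapply(run$ost_summaries, function(d) as.data.frame(d)),
      file.path(out_dir, "ost_summaries.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(run$accuracy)) {
    readr::write_tsv(run$accuracy, file.path(out_dir, "accuracy_table.tsv"))
    jsonlite::write_json(
      lapply(run$cv_results, function(r) {
        list(condition = r$condition, accuracy = r$accuracy,
             accuracy_vote = r$accuracy_vote,
             scores = as.data.frame(r$scores))
      }),
      file.path(out_dir, "cv_results.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(run$rt_cors)) {
    readr::write_tsv(run$rt_cors, file.path(out_dir, "rt_correlations.tsv"))
  }
  manifest <- list(seed = run$config$seed,
                   n_subjects = length(run$cohort),
                   warnings = run$warnings,
                   files = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
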