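test_that("default paradigm reproduces the canonical trial structure", {
  p <- generate_paradigm(paradigm_config(), seed = 7)
  ev <- tibble::as_tibble(p)
  task <- ev[ev$base_type %in% c("go", "stop"), ]
  expect_equal(nrow(task), 300L)
  expect_equal(sum(task$base_type == "stop"), 75L)
  expect_equal(sum(ev$base_type == "rest"), 3L)
  expect_equal(sum(ev$base_type == "instruction"), 1L)
  expect_true(all(diff(ev$onset) > 0))
  expect_true(max(ev$onset) < paradigm_n_volumes(p) * paradigm_tr(p))
  # no two consecutive stop trials, in task-trial order
  is_stop <- task$base_type == "stop"
  expect_false(any(is_stop[-1] & is_stop[-length(is_stop)]))
})

test_that("paradigm generation is seeded and rejects impossible configs", {
  a <- generate_paradigm(paradigm_config(), seed = 11)
  b <- generate_paradigm(paradigm_config(), seed = 11)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  g <- generate_paradigm(small_cfg(n_stop = 0L), seed = 1)
  expect_true(all(g$base_type[g$base_type %in% c("go", "stop")] == "go"))
  expect_error(paradigm_config(n_trials = 10, n_stop = 11),
               "invalid configuration")
  expect_error(paradigm_config(n_trials = 10, n_stop = 8),
               "non-consecutive")
})

test_that("SSD staircase steps by 50 ms and floors at zero", {
  expect_equal(update_ssd(250, "success"), 300)
  expect_equal(update_ssd(250, "failure"), 200)
  expect_equal(update_ssd(0, "failure"), 0)
  expect_equal(update_ssd(30, "failure"), 0)
  expect_error(update_ssd(-10, "success"), "invalid staircase state")
})

test_that("simulated behavior obeys the race rule and staircase bookkeeping", {
  p <- small_paradigm(3)
  ev <- tibble::as_tibble(p)
  task <- ev[ev$base_type %in% c("go", "stop"), ]
  # rt present iff responded
  expect_true(all(is.na(task$rt_ms) == !task$responded))
  stops <- task[task$base_type == "stop", ]
  expect_true(all(stops$label %in% c("SS", "FS")))
  expect_true(all(stops$responded[stops$label == "FS"]))
  expect_false(any(stops$responded[stops$label == "SS"]))
  # the SSD sequence is exactly reconstructible from the outcome labels
  expect_equal(staircase_from_labels(stops$label, ssd_init_ms = 250),
               stops$ssd_ms)
  # label partition: every task trial gets exactly one of the five labels
  expect_true(all(task$label %in% c("GG", "GfSS", "GfFS", "SS", "FS")))
  expect_equal(nrow(task), 40L)
})

test_that("an unbeatable stop process fails every stop and drains the SSD", {
  m <- race_model(ssrt = 1e6, omission_rate = 0)
  p <- label_trials(simulate_behavior(generate_paradigm(small_cfg(), 5), m, 6))
  stops <- p[p$base_type == "stop", ]
  expect_true(all(stops$label == "FS"))
  expect_true(all(diff(stops$ssd_ms) <= 0))
  expect_equal(min(stops$ssd_ms), 0)
})

test_that("trial labels follow the predecessor rule", {
  p <- small_paradigm(9)
  ev <- tibble::as_tibble(p)
  # independent re-derivation: block-wise lag of outcome labels
  task_idx <- which(ev$base_type %in% c("go", "stop"))
  block <- cumsum(ev$base_type %in% c("rest", "instruction"))[task_idx]
  own <- ifelse(ev$base_type[task_idx] == "stop",
                ifelse(ev$responded[task_idx], "FS", "SS"), "go")
  expected <- character(length(task_idx))
  for (i in seq_along(task_idx)) {
    if (own[i] != "go") {
      expected[i] <- own[i]
    } else {
      prev <- i - 1L
      if (prev >= 1L && block[prev] == block[i]) {
        expected[i] <- switch(own[prev], SS = "GfSS", FS = "GfFS", "GG")
      } else {
        expected[i] <- "GG"
      }
    }
  }
  expect_equal(ev$label[task_idx], expected)
  expect_error(label_trials(generate_paradigm(small_cfg(), 1)),
               "unlabeled behavior")
})

test_that("the default race model keeps stop success broadly balanced", {
  p <- label_trials(simulate_behavior(generate_paradigm(paradigm_config(), 2),
                                      race_model(), 3))
  expect_gt(stop_success_rate(p), 0.35)
  expect_lt(stop_success_rate(p), 0.65)
})
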