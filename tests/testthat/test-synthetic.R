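test_that("scan generation is deterministic and respects the noiseless limit", {
  d <- planted_design(n_nodes = 8, n_volumes = 100,
                      base_partition = rep(1:2, each = 4),
                      within_module_corr = 0.9, noise_sd = 1e-6)
  s1 <- generate_scan(d, seed = 11)
  s2 <- generate_scan(d, seed = 11)
  expect_identical(s1$values, s2$values)
  expect_identical(s1$motion, s2$motion)
  s3 <- generate_scan(d, seed = 12)
  expect_false(identical(s1$values, s3$values))
  # noise_sd -> 0: within-module window correlations -> 1
  stack <- window_connectivity(s1, window_config(30, 20, 0))
  within <- tanh(stack$layers[1, 2, ])
  expect_true(all(within > 0.999))
})

test_that("realized correlations follow the loading model in closed form", {
  # expected within-module correlation is c / (c + noise_sd^2)
  d <- planted_design(n_nodes = 6, n_volumes = 200,
                      base_partition = rep(1:2, each = 3),
                      within_module_corr = 0.6)
  cfg <- window_config(50, 50, 0)
  mean_corr <- function(design, pair, windows = NULL) {
    vals <- sapply(1:25, function(s) {
      st <- window_connectivity(generate_scan(design, seed = s), cfg)
      z <- st$layers[pair[1], pair[2], ]
      if (!is.null(windows)) z <- z[windows]
      mean(tanh(z))
    })
    mean(vals)
  }
  expect_lt(abs(mean_corr(d, c(1, 2)) - 0.6), 0.04)
  expect_lt(abs(mean_corr(d, c(1, 4))), 0.04)
  # correlation is monotone decreasing in noise_sd
  d_noisy <- planted_design(n_nodes = 6, n_volumes = 200,
                            base_partition = rep(1:2, each = 3),
                            within_module_corr = 0.6, noise_sd = 1.5)
  expect_lt(mean_corr(d_noisy, c(1, 2)), mean_corr(d, c(1, 2)))
  # a node reassigned at volume 101: its correlation to the old module
  # drops from c to ~0 across the event (windows 1-2 pre, 3-4 post)
  d_ev <- planted_design(n_nodes = 6, n_volumes = 200,
                         base_partition = rep(1:2, each = 3),
                         within_module_corr = 0.6,
                         switch_events = data.frame(node = 1, volume = 101,
                                                    module = 2))
  pre <- mean_corr(d_ev, c(1, 2), windows = 1:2)
  post <- mean_corr(d_ev, c(1, 2), windows = 3:4)
  expect_lt(abs((pre - post) - 0.6), 0.05)
})

test_that("planted switching rates count majority flips of the schedule", {
  base <- rep(1:2, each = 5)
  w <- window_config(20, 5, 0)
  d0 <- planted_design(n_nodes = 10, n_volumes = 120, base_partition = base,
                       within_module_corr = 0.5)
  expect_equal(unname(planted_switch_rate(d0, w)), rep(0, 10))
  # one event: that node switches once over n_windows - 1 transitions
  d1 <- planted_design(n_nodes = 10, n_volumes = 120, base_partition = base,
                       within_module_corr = 0.5,
                       switch_events = data.frame(node = 3, volume = 60,
                                                  module = 2))
  W <- nrow(sliding_windows(120, w))
  r1 <- planted_switch_rate(d1, w)
  expect_equal(unname(r1[3]), 1 / (W - 1))
  expect_equal(unname(r1[-3]), rep(0, 9))
  # relabeled every volume: rate saturates near 1
  sched <- lapply(seq_len(40), function(v) {
    list(start = v, end = v + 1L,
         labels = c((v %% 2) + 1L, rep(1L, 9)))
  })
  d2 <- planted_design(n_nodes = 10, n_volumes = 40, base_partition = base,
                       within_module_corr = 0.5, partition_schedule = sched)
  r2 <- planted_switch_rate(d2, window_config(3, 1, 0))
  expect_gt(unname(r2[1]), 0.9)
})

test_that("design validation rejects malformed schedules", {
  expect_error(planted_design(n_nodes = 4, n_volumes = 10,
                              within_module_corr = 1), "within_module_corr")
  expect_error(planted_design(n_nodes = 4, n_volumes = 10, noise_sd = 0),
               "noise_sd")
  bad <- list(list(start = 1L, end = 5L, labels = rep(1L, 4)),
              list(start = 6L, end = 11L, labels = rep(1L, 4)))
  expect_error(planted_design(n_nodes = 4, n_volumes = 10,
                              partition_schedule = bad), "tile")
  expect_error(planted_design(n_nodes = 4, n_volumes = 10,
                              switch_events = data.frame(node = 9, volume = 5,
                                                         module = 1)),
               "out of range")
})

test_that("cohorts reproduce the study arm sizes and are deterministic", {
  small <- planted_design(n_nodes = 10, n_volumes = 150,
                          base_partition = rep(1:2, each = 5),
                          within_module_corr = 0.8)
  w <- window_config(40, 5, 10)
  coh <- generate_cohort(design_by_condition = list(pre = small),
                         effect = 0, seed = 2, window = w, events_lambda = 3)
  expect_equal(as.integer(table(coh$subjects$group)[c("dependent", "control")]),
               c(24L, 26L))
  coh2 <- generate_cohort(design_by_condition = list(pre = small),
                          effect = 0, seed = 2, window = w, events_lambda = 3)
  expect_identical(coh$outcomes, coh2$outcomes)
  expect_identical(coh$subjects, coh2$subjects)
  s1 <- subject_scan(coh, "dep01", "pre")
  s2 <- subject_scan(coh2, "dep01", "pre")
  expect_identical(s1$values, s2$values)
  expect_equal(mean_fd(s1$motion),
               coh$subjects$mean_fd[coh$subjects$subject_id == "dep01"])
  # both scans share node count and ordering
  expect_identical(s1$node_ids, subject_scan(coh, "dep01", "post")$node_ids)
})

test_that("a null cohort has centred paired differences", {
  small <- planted_design(n_nodes = 10, n_volumes = 150,
                          base_partition = rep(1:2, each = 5),
                          within_module_corr = 0.8)
  w <- window_config(40, 5, 10)
  coh <- generate_cohort(c(dependent = 40, control = 40),
                         list(pre = small), effect = 0, seed = 9, window = w,
                         events_lambda = 3)
  d <- outcome_vector(coh, "global", "global", "post") -
    outcome_vector(coh, "global", "global", "pre")
  expect_lt(abs(mean(d)) / (sd(d) / sqrt(length(d))), 3)
  # planted node rates all within [0, 1]
  pr <- planted_switch_rate(coh$designs[["dep01"]]$pre, w)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("the configured score-rate correlation is recovered", {
  small <- planted_design(n_nodes = 10, n_volumes = 150,
                          base_partition = rep(1:2, each = 5),
                          within_module_corr = 0.8)
  w <- window_config(40, 5, 10)
  rhos <- sapply(1:6, function(r) {
    coh <- generate_cohort(c(dependent = 120, control = 2),
                           list(pre = small), effect = 0, seed = 40 + r,
                           window = w, events_lambda = 3,
                           score_rate_corr = c(BQDS = 0.9))
    dep <- coh$subjects$group == "dependent"
    pre <- outcome_vector(coh, "global", "global", "pre")
    cor(pre[dep], coh$subjects$BQDS[dep], method = "spearman")
  })
  expect_lt(abs(mean(rhos) - 0.9), 0.05)
})
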