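test_that("clean bouts emit exactly four reads each and zero foragers give an empty stream", {
  cfg <- simulation_config(n_foragers = 1, n_days = 1, seed = 5,
                           short_visit_rate = 0)
  fp <- forager_params("bee1", recruit_day = 0L, lifespan_days = 1L,
                       activity_rate = 5)
  sim <- simulate_colony(cfg, foragers = fp)
  expect_gt(nrow(sim$truth$planted_bouts), 0)
  expect_equal(nrow(sim$events), 4 * nrow(sim$truth$planted_bouts))

  empty <- simulate_colony(simulation_config(n_foragers = 0, seed = 1))
  expect_equal(nrow(empty$events), 0L)
  expect_equal(nrow(empty$truth$planted_bouts), 0L)
})

test_that("simulation is a deterministic function of its configuration", {
  cfg <- simulation_config(n_foragers = 8, n_days = 3, seed = 1,
                           read_failure_prob = 0.1, duplicate_read_prob = 0.05)
  a <- simulate_colony(cfg)
  b <- simulate_colony(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$truth$planted_bouts, b$truth$planted_bouts)

  # byte-level determinism of the written log
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_events(a$events, p1); write_events(b$events, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("planted truth respects the forager windows and the bout rule", {
  sim <- simulate_colony(simulation_config(n_foragers = 15, n_days = 6,
                                           seed = 3))
  tr <- sim$truth$planted_bouts
  fp <- sim$truth$forager_params
  expect_true(all(tr$duration_s > 60 & tr$duration_s < 1800))
  expect_true(all(tr$day == floor(tr$start / 86400)))
  win <- merge(tr, fp[c("tag_id", "recruit_day", "lifespan_days")])
  expect_true(all(win$day >= win$recruit_day))
  expect_true(all(win$day <= pmin(win$recruit_day + win$lifespan_days - 1, 5)))
  # short visits are genuinely sub-60 s
  expect_true(all(sim$truth$short_visits$duration_s < 60))
})

test_that("corrupt_events matches its marginal read-loss law", {
  ev <- make_events(seq_len(10000), rep("b1", 10000), rep("A_outer", 10000))

  expect_identical(corrupt_events(ev, m = 0, duplicate_read_prob = 0,
                                  seed = 1), ev)
  expect_equal(nrow(corrupt_events(ev, m = 1, seed = 1)), 0L)

  dropped <- 10000 - nrow(corrupt_events(ev, m = 0.1, seed = 42))
  expect_lt(abs(dropped - 1000), 4 * sqrt(10000 * 0.1 * 0.9))

  dup <- corrupt_events(ev[1:100, ], m = 0, duplicate_read_prob = 1, seed = 7)
  expect_equal(nrow(dup), 200L)
  expect_true(!is.unsorted(dup$timestamp))
})

test_that("expected_constancy matches hand algebra and rejects degenerate preference", {
  res <- expected_constancy(0.5, 0.3)
  expect_equal(res$e, 0.5)
  expect_equal(res$c_inf, 0.65)
  expect_equal(res$ci_inf, 0.3)

  expect_equal(expected_constancy(0.5, 0)$ci_inf, 0)   # memoryless = random
  expect_equal(expected_constancy(0.5, 1)$ci_inf, 1)   # perfect runs
  expect_error(expected_constancy(0, 0.3),
               class = "rfidforage_degenerate_error")
  expect_error(expected_constancy(1, 0.3),
               class = "rfidforage_degenerate_error")
})

test_that("simulated constancy and preference match the chain's closed forms", {
  # mixed-day-only colony: p_day is constant so lifetime CI estimates s
  cfg <- simulation_config(n_foragers = 40, n_days = 20, seed = 19,
                           short_visit_rate = 0,
                           regime_mix = c(pollen = 0, nectar = 0, mixed = 1))
  fp <- forager_params(sprintf("b%02d", 1:40), recruit_day = 0L,
                       lifespan_days = 20L, activity_rate = 12,
                       base_pref_nectar = 0.5, persistence = 0.3,
                       regime_mix = c(pollen = 0, nectar = 0, mixed = 1))
  sim <- simulate_colony(cfg, foragers = fp)
  tr <- sim$truth$planted_bouts

  cres <- constancy_cohort(forager_constancy(tr))$included
  expect_equal(nrow(cres), 40L)
  mc_se <- sd(cres$ci) / sqrt(nrow(cres))
  expect_lt(abs(mean(cres$ci) - 0.3), 3 * mc_se)

  # empirical preference within 4 chain-corrected SDs of p for every forager
  pref <- dplyr::summarise(dplyr::group_by(tr, tag_id),
                           p_hat = mean(reward == "nectar"),
                           n = dplyr::n(), .groups = "drop")
  expect_true(all(pref$n >= 100))
  z <- abs(pref$p_hat - 0.5) / preference_sampling_sd(0.5, 0.3, pref$n)
  expect_true(all(z < 4))
})

test_that("configuration validation rejects bad parameters", {
  expect_error(simulation_config(read_failure_prob = 1.2),
               class = "rfidforage_config_error")
  expect_error(simulation_config(n_days = 0),
               class = "rfidforage_config_error")
  expect_error(simulation_config(regime_mix = c(0.5, 0.5, 0.5)),
               class = "rfidforage_config_error")
  expect_error(simulation_config(pairing_gap_s = -1),
               class = "rfidforage_config_error")
  expect_error(forager_params("a", -1L, 5L, 3),
               class = "rfidforage_config_error")
  expect_error(forager_params(c("a", "a"), 0L, 5L, 3),
               class = "rfidforage_config_error")
})

test_that("simulations round-trip to disk and YAML configs load", {
  sim <- simulate_colony(simulation_config(n_foragers = 3, n_days = 2,
                                           seed = 2))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  back <- read_events(file.path(dir, "events.csv"), sim$setup)
  expect_equal(back[c("timestamp", "tag_id", "reader_id")],
               sim$events[c("timestamp", "tag_id", "reader_id")],
               ignore_attr = TRUE)

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_foragers: 7", "n_days: 5", "seed: 99",
               "persistence: 0.4",
               "regime_mix:", "  pollen: 0.2", "  nectar: 0.2", "  mixed: 0.6"),
             yml)
  cfg <- simulation_config_from_yaml(yml)
  expect_equal(cfg$n_foragers, 7L)
  expect_equal(cfg$persistence, 0.4)
  expect_equal(unname(cfg$regime_mix["mixed"]), 0.6)
})
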