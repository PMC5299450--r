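test_that("daily summaries compute preference, degree and class per forager-day", {
  bouts <- dplyr::bind_rows(
    make_bouts("b1", 0L, c(rep("nectar", 3), "pollen")),
    make_bouts("b2", 0L, rep("nectar", 10)),
    make_bouts("b3", 1L, c(rep("nectar", 9), "pollen")))
  daily <- summarize_forager_days(bouts)

  b1 <- daily[daily$tag_id == "b1", ]
  expect_equal(b1$nectar_pref, 0.75)
  expect_equal(b1$degree, 0.75)
  expect_equal(b1$specialist_class, "generalist")

  b2 <- daily[daily$tag_id == "b2", ]
  expect_equal(b2$nectar_pref, 1)
  expect_equal(b2$specialist_class, "nectar")

  # exactly 90% is a generalist under the strict > threshold rule
  b3 <- daily[daily$tag_id == "b3", ]
  expect_equal(b3$nectar_pref, 0.9)
  expect_equal(b3$specialist_class, "generalist")
})

test_that("lifetime aggregation is consistent with daily rows", {
  bouts <- dplyr::bind_rows(
    make_bouts("b1", 0L, rep("pollen", 4), start = 1:4 * 1000),
    make_bouts("b1", 1L, rep("nectar", 4), start = 86400 + 1:4 * 1000))
  life <- summarize_forager_lifetime(summarize_forager_days(bouts))
  expect_equal(life$lifetime_nectar_pref, 0.5)
  expect_equal(life$total_days_foraged, 2L)
  expect_equal(life$mean_daily_bouts, 4)
  expect_equal(life$daily_degree_variance, 0)    # both days 100% specialized

  single <- summarize_forager_lifetime(
    summarize_forager_days(make_bouts("b9", 3L, c("nectar", "pollen"))))
  expect_equal(single$daily_degree_variance, 0)  # one day: variance 0

  # one row per forager, and daily bout counts sum to lifetime counts
  many <- dplyr::bind_rows(lapply(1:97, function(i) {
    make_bouts(sprintf("t%03d", i), i %% 5,
               sample(c("nectar", "pollen"), 3 + i %% 4, replace = TRUE))
  }))
  daily <- summarize_forager_days(many)
  life97 <- summarize_forager_lifetime(daily)
  expect_equal(nrow(life97), 97L)
  agg <- dplyr::summarise(dplyr::group_by(daily, tag_id),
                          n = sum(n_bouts), .groups = "drop")
  expect_equal(life97$lifetime_bouts[order(life97$tag_id)],
               agg$n[order(agg$tag_id)])
})

test_that("classify_specialist uses strict inequalities and validates threshold", {
  expect_equal(classify_specialist(c(0.95, 0.05, 0.90, 0.10, 0.5)),
               c("nectar", "pollen", "generalist", "generalist", "generalist"))
  expect_error(classify_specialist(0.5, threshold = 0.5),
               class = "rfidforage_config_error")
  expect_error(classify_specialist(0.5, threshold = 1),
               class = "rfidforage_config_error")
  expect_error(classify_specialist(1.2), class = "rfidforage_data_error")
})

test_that("jacobs_ci reproduces the analytic anchors", {
  alt <- rep(c("nectar", "pollen"), 5)
  expect_equal(jacobs_ci(alt)$ci, -1)

  runs <- rep(c("nectar", "pollen"), each = 4)
  res <- jacobs_ci(runs)
  expect_equal(res$c, 6 / 7)
  expect_equal(res$e, 0.5)
  expect_equal(res$ci, 5 / 7)

  # single-reward sequence: undefined, flagged not numeric
  mono <- jacobs_ci(rep("nectar", 6))
  expect_false(mono$defined)
  expect_true(is.na(mono$ci))

  expect_error(jacobs_ci("nectar"),
               class = "rfidforage_insufficient_data_error")
  expect_error(jacobs_ci(c("nectar", "water")),
               class = "rfidforage_data_error")
})

test_that("jacobs_ci agrees with the transition-counting oracle exhaustively (L <= 8)", {
  for (L in c(2, 3, 5, 8)) {
    for (s in all_reward_sequences(L)) {
      got <- jacobs_ci(s)
      want <- jacobs_ci_oracle(s)
      if (is.na(want)) {
        expect_false(got$defined)
      } else {
        expect_equal(got$ci, want)
        # the index is zero exactly when observed c equals expected e
        expect_equal(got$ci == 0, got$c == got$e)
      }
    }
  }
})

test_that("the index is invariant under reward relabelling and maximal for two runs", {
  set.seed(42)
  for (i in 1:25) {
    s <- sample(c("nectar", "pollen"), 30, replace = TRUE)
    if (length(unique(s)) < 2) next
    flipped <- ifelse(s == "nectar", "pollen", "nectar")
    expect_equal(jacobs_ci(s)$ci, jacobs_ci(flipped)$ci)
  }

  # for fixed composition, the two-run arrangement maximises the index
  for (L in c(6, 8)) {
    seqs <- all_reward_sequences(L)
    ci <- vapply(seqs, function(s) {
      r <- jacobs_ci(s); if (r$defined) r$ci else NA_real_
    }, numeric(1))
    k <- vapply(seqs, function(s) sum(s == "nectar"), integer(1))
    for (comp in 1:(L - 1)) {
      sel <- k == comp
      two_run <- jacobs_ci(rep(c("nectar", "pollen"),
                               c(comp, L - comp)))$ci
      expect_equal(max(ci[sel], na.rm = TRUE), two_run)
      expect_gt(two_run, 0)
    }
  }
})

test_that("constancy cohort applies the minimum-bout inclusion rule", {
  seq_of <- function(n) rep(c("nectar", "pollen"), length.out = n)
  bouts <- dplyr::bind_rows(
    make_bouts("a", 0L, seq_of(18)),
    make_bouts("b", 0L, seq_of(19)),
    make_bouts("c", 0L, seq_of(200)))
  res <- forager_constancy(bouts)
  coh <- constancy_cohort(res)
  expect_equal(sort(coh$included$tag_id), c("b", "c"))
  expect_equal(coh$n_excluded, 1L)

  # all below threshold: empty set, no error
  low <- forager_constancy(make_bouts("a", 0L, seq_of(5)))
  expect_equal(nrow(constancy_cohort(low)$included), 0L)

  # 90 foragers, 22 under the rule -> 68 included
  sizes <- c(rep(10, 22), rep(40, 68))
  big <- dplyr::bind_rows(lapply(seq_along(sizes), function(i) {
    make_bouts(sprintf("f%02d", i), 0L, seq_of(sizes[i]))
  }))
  coh90 <- constancy_cohort(forager_constancy(big))
  expect_equal(nrow(coh90$included), 68L)
  expect_equal(coh90$n_excluded, 22L)

  # undefined index is excluded even with enough bouts
  mono <- forager_constancy(make_bouts("m", 0L, rep("nectar", 50)))
  expect_equal(nrow(constancy_cohort(mono)$included), 0L)
})
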