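test_that("ventilatory clearance follows 1/(1 + lambda*Q/V_A)", {
  expect_equal(round(clearance(1.3, 5, 5), 2), 0.43)
  expect_equal(round(clearance(0.42, 5, 2.5), 2), 0.54)
  expect_equal(clearance(0, 5, 5), 1)
  expect_equal(clearance(1, 7, 7), 0.5)
  expect_error(clearance(1.3, 5, 0), class = "macawake_schema_error")
  expect_error(clearance(-0.1, 5, 5), class = "macawake_schema_error")
})

test_that("clearance is monotone: increasing in V_A, decreasing in solubility and Q", {
  va <- seq(0.5, 10, by = 0.5)
  expect_true(all(diff(clearance(1.3, 5, va)) > 0))
  lam <- seq(0.1, 2, by = 0.1)
  expect_true(all(diff(clearance(lam, 5, 5)) < 0))
  q <- seq(1, 10, by = 0.5)
  expect_true(all(diff(clearance(0.65, q, 5)) < 0))
})

test_that("the clearance grid reproduces the published table cells", {
  tab <- clearance_table()
  cell <- function(agent, q, va) tab[tab$agent == agent & tab$q_total == q & tab$v_a == va, ]
  # 15 clearance cells at 2 decimals
  expect_equal(cell("desflurane", 5, 5)$clearance_2dp, 0.70)
  expect_equal(cell("desflurane", 5, 2.5)$clearance_2dp, 0.54)
  expect_equal(cell("desflurane", 5, 10)$clearance_2dp, 0.83)
  expect_equal(cell("sevoflurane", 5, 5)$clearance_2dp, 0.61)
  expect_equal(cell("sevoflurane", 10, 5)$clearance_2dp, 0.43)
  expect_equal(cell("isoflurane", 5, 5)$clearance_2dp, 0.43)
  expect_equal(cell("isoflurane", 5, 10)$clearance_2dp, 0.61)
  # percent-of-baseline cells round to integers
  expect_equal(cell("isoflurane", 5, 10)$pct_baseline_int, 139)
  expect_equal(cell("isoflurane", 5, 2.5)$pct_baseline_int, 64)
  expect_equal(cell("sevoflurane", 10, 5)$pct_baseline_int, 72)
  expect_equal(cell("desflurane", 2.5, 5)$pct_baseline_int, 117)
  expect_equal(cell("desflurane", 5, 5)$pct_baseline_int, 100)
  # Q and V_A scale as a ratio: halving Q equals doubling V_A
  expect_equal(cell("sevoflurane", 2.5, 5)$clearance,
               cell("sevoflurane", 5, 10)$clearance)
  expect_error(clearance_table(grid = tibble::tibble(q_total = 2.5, v_a = 5)),
               class = "macawake_schema_error")
})

test_that("threshold crossings are located by interpolation on an analytic trace", {
  t <- seq(0, 3, by = 1 / 60)
  tr <- tibble::tibble(t_min = t, f_vrg = exp(-t))
  expect_equal(time_to_threshold(tr, "f_vrg", 0.5), log(2), tolerance = 1e-4)
  # upward crossing is inferred from the starting side
  tr2 <- tibble::tibble(t_min = t, f_vrg = 1 - exp(-t))
  expect_equal(time_to_threshold(tr2, "f_vrg", 0.5), log(2), tolerance = 1e-4)
  expect_error(time_to_threshold(tr, "f_vrg", 2), class = "macawake_no_crossing")
  expect_error(time_to_threshold(tr, "nope", 0.5), class = "macawake_schema_error")
  # from_t skips the early part of the trace
  tr3 <- tibble::tibble(t_min = t, f_vrg = cos(2 * pi * t) + 1.001)
  first <- time_to_threshold(tr3, "f_vrg", 1.001)
  second <- time_to_threshold(tr3, "f_vrg", 1.001, from_t = first + 0.3)
  expect_gt(second, first + 0.2)
})

test_that("percent reduction compares ventilation modes on the recovery time scale", {
  expect_equal(round(percent_reduction(14.7, 10.3)), 30)
  expect_equal(round(percent_reduction(6.2, 5.4)), 13)
  expect_equal(percent_reduction(7.5, 7.5), 0)
  expect_error(percent_reduction(0, 5), class = "macawake_schema_error")
})

test_that("rehypnotization means a strict rebound above 0.3 MAC after the crossing", {
  # synthetic monotone decline: never rehypnotizes
  t <- seq(0, 40, by = 1 / 60)
  tr <- tibble::tibble(t_min = t, f_vrg = 1.2 * exp(-t / 8))
  det <- detect_rehypnotization(tr, ISO, t_macawake = 8 * log(1.2 / 0.36),
                                baseline_fvrg = 1.2)
  expect_false(det$result$rehypnotized)
  # rebound that exactly touches the threshold does not count (strict >)
  t2 <- seq(0, 20, by = 0.1)
  reb <- 0.36 - 0.1 * abs(sin(t2))  # dips below, returns to at most 0.36
  tr2 <- tibble::tibble(t_min = t2, f_vrg = pmin(reb + 0.1 * (t2 > 10), 0.36))
  det2 <- detect_rehypnotization(tr2, ISO, t_macawake = 0.05, baseline_fvrg = 1.2)
  expect_false(det2$result$rehypnotized)
  # any strict exceedance counts, and the peak is reported
  tr3 <- tr2
  tr3$f_vrg[tr3$t_min > 15] <- 0.40
  det3 <- detect_rehypnotization(tr3, ISO, t_macawake = 0.05, baseline_fvrg = 1.2)
  expect_true(det3$result$rehypnotized)
  expect_equal(det3$result$peak_post_fvrg, 0.40)
  # a short observation window is refused
  expect_error(detect_rehypnotization(tr[tr$t_min < 12, ], ISO, t_macawake = 8),
               class = "macawake_short_window")
  # decrement fractions at the probe times
  expect_equal(det$probes$fraction, exp(-30 / 8), tolerance = 1e-4)
})
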