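# ROR / PRR / chi-squared on 2x2 tables, threshold flags and ranking.
# Frozen expected values were computed by direct evaluation of the closed
# forms (independently of the package) before the implementation was written.

test_that("contingency tables are built from the event list", {
  ev <- rbind(
    events_from_counts(c(PT1 = 3, PT2 = 7)),
    events_from_counts(c(PT1 = 5, PT2 = 85), is_target = FALSE,
                       id_offset = 1000L))
  tab <- build_contingency(ev, "PT1")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(3L, 7L, 5L, 85L))
  # absent PT: a = c = 0, margins preserved
  none <- build_contingency(ev, "PT99")
  expect_equal(c(none$a, none$b, none$c, none$d), c(0L, 10L, 0L, 90L))
  expect_error(contingency_table(-1, 1, 1, 1), "nonnegative")
})

test_that("ROR, CI, PRR and chi-squared match frozen closed-form values", {
  tab <- contingency_table(10, 90, 100, 9900)
  r <- ror(tab)
  expect_equal(unname(r["estimate"]), 11)
  expect_equal(unname(r["ci_low"]), 5.5595149289, tolerance = 1e-9)
  expect_equal(unname(r["ci_high"]), 21.7644887274, tolerance = 1e-9)
  expect_equal(prr(tab), 10)
  expect_equal(chi_square(tab), 74.4471744472, tolerance = 1e-9)

  flat <- contingency_table(5, 5, 5, 5)
  expect_equal(unname(ror(flat)["estimate"]), 1)
  expect_lt(unname(ror(flat)["ci_low"]), 1)
  expect_gt(unname(ror(flat)["ci_high"]), 1)
  expect_equal(prr(flat), 1)
  expect_equal(chi_square(flat), 0)

  expect_equal(prr(contingency_table(3, 0, 1, 1)), 2)  # (3/3)/(1/2)
})

test_that("zero cells: undefined without correction, defined with it", {
  tab <- contingency_table(0, 10, 5, 100)
  expect_true(all(is.na(ror(tab))))
  withcorr <- ror(tab, correction = TRUE)
  expect_false(any(is.na(withcorr)))
  expect_equal(unname(withcorr["estimate"]),
               (0.5 * 100.5) / (10.5 * 5.5), tolerance = 1e-12)
  expect_true(is.na(prr(contingency_table(5, 5, 0, 10))))  # c = 0
  expect_true(is.na(chi_square(contingency_table(0, 0, 5, 5))))  # zero margin
})

test_that("exhaustive small-table equivalence with independent oracles", {
  grid <- expand.grid(a = 1:6, b = 1:6, c = 1:6, d = 1:6)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tab <- contingency_table(g$a, g$b, g$c, g$d)
    # brute-force oracles: odds ratio from odds, PRR from proportions
    expect_equal(unname(ror(tab)["estimate"]),
                 (g$a / g$b) / (g$c / g$d), tolerance = 1e-12)
    expect_equal(prr(tab), (g$a / (g$a + g$b)) / (g$c / (g$c + g$d)),
                 tolerance = 1e-12)
    # generic uncorrected Pearson chi-squared
    ref <- unname(suppressWarnings(chisq.test(
      matrix(c(g$a, g$c, g$b, g$d), 2), correct = FALSE))$statistic)
    expect_equal(chi_square(tab), ref, tolerance = 1e-9)
  }
})

test_that("CI is symmetric about the estimate on the log scale", {
  set.seed(42)
  for (i in 1:50) {
    cells <- sample(1:500, 4, replace = TRUE)
    r <- ror(contingency_table(cells[1], cells[2], cells[3], cells[4]))
    expect_equal(log(r[["ci_low"]]) + log(r[["ci_high"]]),
                 2 * log(r[["estimate"]]), tolerance = 1e-9)
    expect_lte(r[["ci_low"]], r[["estimate"]])
    expect_lte(r[["estimate"]], r[["ci_high"]])
  }
})

test_that("ROR is invariant under background scaling (c,d) -> (kc,kd)", {
  base <- ror(contingency_table(8, 92, 40, 960))[["estimate"]]
  for (k in c(2L, 5L, 10L)) {
    expect_equal(ror(contingency_table(8, 92, 40 * k, 960 * k))[["estimate"]],
                 base)
  }
})

test_that("ROR converges to PRR in the rare-event limit", {
  # a and c fixed while both event shares shrink: b and d grow together
  rel <- vapply(10^(2:6), function(k) {
    tab <- contingency_table(5, k, 20, 100 * k)
    abs(ror(tab)[["estimate"]] - prr(tab)) / prr(tab)
  }, numeric(1))
  expect_true(all(diff(rel) < 0))
  expect_lt(rel[length(rel)], 1e-3)
})

test_that("ROR and PRR increase strictly with a (b, c, d fixed)", {
  rors <- vapply(1:20, function(a)
    ror(contingency_table(a, 50, 30, 1000))[["estimate"]], numeric(1))
  prrs <- vapply(1:20, function(a)
    prr(contingency_table(a, 50, 30, 1000)), numeric(1))
  expect_true(all(diff(rors) > 0))
  expect_true(all(diff(prrs) > 0))
})

test_that("signal thresholds: a >= 3 gate, strict > elsewhere", {
  f <- flag_signals(a = 525, ror_ci_low = 17.04, prr = 18.09, chi2 = 8000)
  expect_true(f$ror_signal)
  expect_true(f$prr_signal)
  # a-gate
  f2 <- flag_signals(a = 2, ror_ci_low = 50, prr = 50, chi2 = 50)
  expect_false(f2$ror_signal)
  expect_false(f2$prr_signal)
  # boundary values do not flag (strict inequalities)
  f3 <- flag_signals(a = 10, ror_ci_low = 1, prr = 2, chi2 = 10)
  expect_false(f3$ror_signal)
  expect_false(f3$prr_signal)
  f4 <- flag_signals(a = 10, ror_ci_low = 1.01, prr = 2.01, chi2 = 4)
  expect_true(f4$ror_signal)
  expect_false(f4$prr_signal)   # chi2 must exceed 4
  # undefined estimates never flag
  f5 <- flag_signals(a = 10, ror_ci_low = NA, prr = NA, chi2 = NA)
  expect_false(f5$ror_signal)
  expect_false(f5$prr_signal)
})

test_that("rank_signals orders by key with (a, pt) tie-breaks", {
  sig <- tibble::tibble(
    pt = c("B", "A", "C", "D", "E"),
    a = c(10L, 10L, 20L, 5L, 4L),
    b = 1L, c = 1L, d = 1L,
    ror = c(113.92, 144.27, 107.67, 50, 9),
    ror_ci_low = 2, ror_ci_high = 999, prr = c(5, 6, 7, 50, 9), chi2 = 100,
    ror_signal = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    prr_signal = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  ranked <- rank_signals(sig, key = "ror")
  expect_equal(ranked$pt, c("A", "B", "C", "D"))  # descending ROR
  # equal key: larger a first, then alphabetical
  tie <- sig
  tie$ror <- 10
  expect_equal(rank_signals(tie, key = "ror")$pt, c("C", "A", "B", "D"))
  # top_n larger than the list returns the full list
  expect_equal(nrow(rank_signals(sig, top_n = 99)), 4L)
  expect_equal(nrow(rank_signals(sig, top_n = 2)), 2L)
})

test_that("signal_table agrees with per-PT scalar computation", {
  cfg <- planted_rare_config(n_cases = 2000, seed = 5)
  tabs <- generate_faers(cfg)
  co <- build_cohort(deduplicate_demo(tabs$DEMO), tabs$DRUG, tabs$REAC,
                     c("selinexor", "xpovio"))
  st <- signal_table(co$events)
  expect_false(anyDuplicated(st$pt) > 0)
  for (i in sample(nrow(st), 5)) {
    tab <- build_contingency(co$events, st$pt[i])
    expect_equal(st$a[i], tab$a)
    expect_equal(st$c[i], tab$c)
    r <- ror(tab)
    expect_equal(st$ror[i], unname(r["estimate"]))
    expect_equal(st$prr[i], prr(tab))
    expect_equal(st$chi2[i], chi_square(tab))
  }
  # a + b constant across rows: total target events
  expect_true(all(st$a + st$b == sum(co$events$is_target_drug)))
})
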