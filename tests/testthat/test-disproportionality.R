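# Independently coded odds-ratio / Woolf-interval routine used as the
# oracle; kept deliberately separate from the package's code path.
oracle_or <- function(a, b, c, d, level = 0.95) {
  or <- (a / b) / (c / d)
  v <- 1 / a + 1 / b + 1 / c + 1 / d
  z <- qnorm(1 - (1 - level) / 2)
  list(or = or, lo = exp(log(or) - z * sqrt(v)),
       hi = exp(log(or) + z * sqrt(v)))
}

test_that("contingency construction reproduces the documented cell algebra", {
  # 8,737 exposed reports of 622,289, 491 exposed cases, 1,883 cases total
  rec <- data.frame(case_id = c(paste0("e", 1:10), paste0("c", 1:3)),
                    drug = "oxa", atc_code = "L01XA03",
                    is_case = c(rep(TRUE, 4), rep(FALSE, 6), rep(TRUE, 3)),
                    stringsAsFactors = FALSE)
  tab <- build_contingency(rec[rec$drug == "oxa" & substr(rec$case_id, 1, 1) == "e", ],
                           "oxa", total_reports = 100L, total_cases = 7L)
  expect_equal(tab$a, 4L); expect_equal(tab$b, 6L)
  expect_equal(tab$c, 3L); expect_equal(tab$d, 87L)
  # the published oxaliplatin construction, from its marginal counts
  tab2 <- contingency_table(491, 8737 - 491, 1883 - 491,
                            622289 - 8737 - (1883 - 491))
  expect_equal(tab2$d, 612160)
  res <- compute_ror(tab2)
  expect_equal(round(res$ror, 1), 26.2)
  # zero exposures degenerate cleanly
  tab0 <- build_contingency(rec[0, ], "absent", 100L, 7L)
  expect_equal(c(tab0$a, tab0$b, tab0$c, tab0$d), c(0L, 0L, 7L, 93L))
  # inconsistent denominators are refused
  expect_error(contingency_table(-1, 2, 3, 4), "non-negative")
})

test_that("ROR and Woolf interval match published one-decimal values", {
  # (total exposed, exposed cases, ror, ci_low, ci_high) over a
  # 622,289-report database with 1,883 event reports
  anchors <- list(
    vinblastine = c(294, 17, 20.4, 12.5, 33.4),
    oxaliplatin = c(8737, 491, 26.2, 23.6, 29.1),
    bortezomib = c(2727, 210, 30.8, 26.6, 35.8))
  for (nm in names(anchors)) {
    v <- anchors[[nm]]
    tab <- contingency_table(v[2], v[1] - v[2], 1883 - v[2],
                             622289 - v[1] - (1883 - v[2]))
    res <- compute_ror(tab)
    expect_equal(round(res$ror, 1), v[3], info = nm)
    expect_equal(round(res$ci_low, 1), v[4], info = nm)
    expect_equal(round(res$ci_high, 1), v[5], info = nm)
  }
})

test_that("a balanced table gives ROR 1 with a log-symmetric interval", {
  res <- compute_ror(contingency_table(10, 10, 10, 10))
  expect_equal(res$ror, 1)
  expect_equal(log(res$ci_high), -log(res$ci_low), tolerance = 1e-12)
})

test_that("ROR/CI agree with an independent routine on 1,000 random tables", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    cells <- sample(2:5000, 4, replace = TRUE)
    res <- compute_ror(contingency_table(cells[1], cells[2], cells[3],
                                         cells[4]))
    o <- oracle_or(cells[1], cells[2], cells[3], cells[4])
    worst <- max(worst, abs(log(res$ror) - log(o$or)),
                 abs(log(res$ci_low) - log(o$lo)),
                 abs(log(res$ci_high) - log(o$hi)))
  }
  expect_lt(worst, 1e-10)
})

test_that("exchange symmetry and scale behaviour of the ROR", {
  set.seed(7)
  for (i in 1:50) {
    cells <- sample(2:500, 4, replace = TRUE)
    r1 <- compute_ror(contingency_table(cells[1], cells[2], cells[3], cells[4]))
    r2 <- compute_ror(contingency_table(cells[3], cells[4], cells[1], cells[2]))
    expect_equal(r1$ror, 1 / r2$ror, tolerance = 1e-12)
    rk <- compute_ror(contingency_table(3 * cells[1], 3 * cells[2],
                                        3 * cells[3], 3 * cells[4]))
    expect_equal(rk$ror, r1$ror, tolerance = 1e-12)
    expect_lt(log(rk$ci_high) - log(rk$ci_low),
              log(r1$ci_high) - log(r1$ci_low))
  }
})

test_that("the signal rule requires ROR > 1, CI floor > 1 and two cases", {
  mk <- function(ror, lo, n) {
    structure(data.frame(drug_or_class = "x", n_total = n + 10, n_case = n,
                         ror = ror, ci_low = lo, ci_high = ror * 2,
                         evaluable = TRUE, is_signal = NA),
              class = c("signal_result", "data.frame"))
  }
  expect_true(detect_signal(mk(26.2, 23.6, 491))$is_signal)
  expect_false(detect_signal(mk(3, 0.99, 50))$is_signal)
  expect_false(detect_signal(mk(3, 1.2, 1))$is_signal)
  # a < 2 is non-evaluable straight from compute_ror
  res <- compute_ror(contingency_table(1, 50, 20, 1000))
  expect_false(res$evaluable)
  expect_true(is.na(res$ror))
  expect_false(detect_signal(res)$is_signal)
  # zero cell without correction: non-evaluable; with Haldane: estimable
  res0 <- compute_ror(contingency_table(5, 0, 20, 1000))
  expect_false(res0$evaluable)
  resH <- compute_ror(contingency_table(5, 0, 20, 1000), haldane = TRUE)
  expect_true(resH$evaluable)
  expect_gt(resH$ror, 1)
})

test_that("screen over targets is ordered, denominator-safe and warns on unknowns", {
  cfg <- sim_config(10000L, 0.01,
                    drugs = list(drug_spec("zeta", "L01XX02", 0.03, 8),
                                 drug_spec("alpha", "L01AA01", 0.03, 1)),
                    seed = 2L)
  rec <- sim_analysis_set(cfg)
  expect_warning(scr <- run_signal_screen(rec, c("zeta", "alpha", "ghost")),
                 "ghost")
  expect_equal(nrow(scr), 3L)
  expect_equal(scr$drug_or_class[1], "alpha")  # ATC ordering
  expect_false(scr$evaluable[scr$drug_or_class == "ghost"])
  expect_equal(attr(scr, "n_reports"), 10000L)
  # formatted table renders dashes for non-evaluable rows
  fmt <- format_signal_table(scr)
  expect_equal(fmt$ror[fmt$drug == "ghost"], "-")
  # empty record set: all targets non-evaluable
  empty <- rec[0, ]
  attr(empty, "n_reports") <- 0L; attr(empty, "n_cases") <- 0L
  class(empty) <- c("analysis_set", "data.frame")
  scr0 <- suppressWarnings(run_signal_screen(empty, c("a", "b")))
  expect_false(any(scr0$evaluable))
})

test_that("null generator configs rarely trigger the signal rule", {
  # one-sided rule on a 95% interval: ~2.5% expected; allow Monte-Carlo
  # margin up to 5% over 200 replicates
  hits <- logical(200)
  for (s in 1:200) {
    cfg <- one_drug_config(n = 30000L, multiplier = 1, seed = 7000L + s,
                           exposure = 0.02, background = 0.01)
    rec <- sim_analysis_set(cfg)
    scr <- run_signal_screen(rec, "drugA")
    hits[s] <- isTRUE(scr$is_signal)
  }
  expect_lte(mean(hits), 0.05)
})
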