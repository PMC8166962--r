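test_that("latency derivation applies the exclusion rules with accounting", {
  rec <- data.frame(
    case_id = sprintf("C%d", 1:6),
    drug = "d", atc_code = "L01XX01", is_case = TRUE,
    start_date = c("20200101", "20200101", "202001", "20200101",
                   "20200601", "20200101"),
    onset_date = c("20200115", "202003", "20200301", "20191220",
                   NA, "20210601"),
    outcome = "recovered", n_dup_rows = c(0L, 0L, 0L, 1L, 0L, 0L),
    stringsAsFactors = FALSE)
  ls <- compute_latencies(rec, "d")
  expect_equal(ls$latencies_days, 14)          # complete pair only
  expect_equal(ls$n_excluded_incomplete, 3L)   # partial onset/start, NA
  expect_equal(ls$n_excluded_negative, 1L)     # onset before start
  expect_equal(ls$n_excluded_window, 1L)       # beyond 365 days
  expect_equal(ls$n_excluded_duplicate, 1L)
  # accounting conserves the candidate count
  expect_equal(length(ls$latencies_days) + ls$n_excluded_incomplete +
                 ls$n_excluded_negative + ls$n_excluded_window,
               ls$n_candidates)
  # widening the window rescues the long latency
  expect_equal(length(compute_latencies(rec, "d", 600L)$latencies_days), 2L)
})

test_that("latency summaries follow the (n+1)p quantile convention", {
  expect_equal(summarize_latency(as_latency_set(5)),
               list(median_days = 5, q1_days = 5, q3_days = 5, n = 1L))
  s <- summarize_latency(as_latency_set(c(1, 2, 3, 4)))
  expect_equal(s$median_days, 2.5)
  expect_equal(s$q1_days, 1.25)
  expect_equal(s$q3_days, 3.75)
  expect_error(summarize_latency(as_latency_set(numeric(0))), "no retained")
})

test_that("sample median of exponential draws tracks the closed form", {
  set.seed(1)
  x <- rweibull(10000, shape = 1, scale = 50)
  s <- summarize_latency(as_latency_set(x))
  expect_equal(s$median_days, 50 * log(2), tolerance = 0.05)
})

test_that("Weibull fit recovers parameters with small bias over 100 seeds", {
  alphas <- betas <- numeric(100)
  for (s in 1:100) {
    set.seed(2000 + s)
    x <- rweibull(1000, shape = 0.8, scale = 50)
    fit <- fit_weibull(as_latency_set(x))
    alphas[s] <- fit$alpha_days; betas[s] <- fit$beta
  }
  expect_lt(abs(mean(alphas) - 50) / 50, 0.05)
  expect_lt(abs(mean(betas) - 0.8) / 0.8, 0.05)
  # CIs cover the truth roughly at nominal rate (sanity band)
  expect_gt(mean(alphas > 45 & alphas < 55), 0.9)
})

test_that("exponential special case: scale estimate near the sample mean", {
  set.seed(5)
  x <- rweibull(2000, shape = 1, scale = 30)
  fit <- fit_weibull(as_latency_set(x))
  expect_equal(fit$beta, 1, tolerance = 0.05)
  expect_equal(fit$alpha_days, mean(x), tolerance = 0.05 * mean(x))
})

test_that("the optimum dominates a surrounding parameter grid", {
  set.seed(9)
  x <- rweibull(300, shape = 0.7, scale = 40)
  ls <- as_latency_set(x)
  fit <- fit_weibull(ls)
  ll <- function(alpha, beta) sum(dweibull(x, beta, alpha, log = TRUE))
  grid <- expand.grid(fa = seq(0.8, 1.2, length.out = 10),
                      fb = seq(0.8, 1.2, length.out = 10))
  for (i in seq_len(nrow(grid))) {
    if (grid$fa[i] == 1 && grid$fb[i] == 1) next
    expect_gte(fit$log_likelihood + 1e-8,
               ll(fit$alpha_days * grid$fa[i], fit$beta * grid$fb[i]))
  }
})

test_that("fit agrees with an independent MLE implementation", {
  skip_if_not_installed("fitdistrplus")
  set.seed(13)
  x <- rweibull(500, shape = 0.9, scale = 60)
  fit <- fit_weibull(as_latency_set(x))
  ref <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(fit$beta, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit$alpha_days, unname(ref$estimate["scale"]), tolerance = 1e-3)
})

test_that("scale equivariance: latencies times k scale alpha, not beta", {
  set.seed(21)
  x <- rweibull(400, shape = 0.8, scale = 20)
  f1 <- fit_weibull(as_latency_set(x))
  f2 <- fit_weibull(as_latency_set(7 * x))
  expect_equal(f2$alpha_days / f1$alpha_days, 7, tolerance = 1e-6)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
})

test_that("fitted scale times ln(2)^(1/shape) tracks the sample median", {
  set.seed(33)
  x <- rweibull(20000, shape = 0.8, scale = 50)
  fit <- fit_weibull(as_latency_set(x))
  expect_equal(fit$alpha_days * log(2)^(1 / fit$beta), median(x),
               tolerance = 0.03 * median(x))
})

test_that("zero-day latencies are adjusted for fitting but kept for quantiles", {
  set.seed(17)
  x <- c(rep(0, 30), round(rweibull(270, 0.8, 40)))
  ls <- as_latency_set(x)
  fit <- fit_weibull(ls)
  expect_equal(fit$n_zero_adjusted, sum(x == 0))
  expect_true(is.finite(fit$log_likelihood))
  expect_equal(summarize_latency(as_latency_set(c(0, 0, 0)))$median_days, 0)
})

test_that("small sets are refused, not fitted unstably", {
  expect_error(fit_weibull(as_latency_set(c(1, 5, 9))), "too few")
})

test_that("hazard classification follows the strict CI rule", {
  mk <- function(lo, hi) list(beta_ci = c(lo, hi))
  expect_equal(classify_hazard(mk(0.64, 0.89)), "initial_failure")
  expect_equal(classify_hazard(mk(0.85, 1.05)), "random_failure")
  expect_equal(classify_hazard(mk(1.10, 1.50)), "wear_out_failure")
  # a bound exactly at 1 is never initial/wear-out
  expect_equal(classify_hazard(mk(0.8, 1.0)), "random_failure")
  expect_equal(classify_hazard(mk(1.0, 1.4)), "random_failure")
})

test_that("the tto table assembles per-target summaries with accounting", {
  cfg <- one_drug_config(n = 30000L, multiplier = 20, seed = 44L,
                         exposure = 0.03, background = 0.005,
                         alpha = 50, beta = 0.8,
                         missing_date_prob = 0.1)
  rec <- sim_analysis_set(cfg)
  tt <- run_tto_table(rec, c("drugA", "ghost"))
  expect_equal(nrow(tt), 2L)
  a <- tt[tt$drug_or_class == "drugA", ]
  expect_gt(a$n, 10)
  expect_true(a$hazard_class %in% c("initial_failure", "random_failure",
                                    "wear_out_failure"))
  expect_true(a$q1_days <= a$median_days && a$median_days <= a$q3_days)
  g <- tt[tt$drug_or_class == "ghost", ]
  expect_equal(g$n, 0L)
  expect_true(is.na(g$alpha))
})
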