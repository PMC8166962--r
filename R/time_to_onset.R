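#' Per-report onset latencies for one drug or class
#'
#' Latency is the difference in days between the earliest complete
#' administration start date and the first complete onset date of the
#' focal event within the same report. Candidate records (case records
#' of the drug/class) are excluded, with counts, when either date is
#' incomplete (\code{n_excluded_incomplete}), the latency is negative
#' (\code{n_excluded_negative}), or it exceeds the analysis window
#' (\code{n_excluded_window}, default 365 days). Duplicate prescription
#' rows collapsed during assembly are reported in
#' \code{n_excluded_duplicate}.
#'
#' @param records an \code{analysis_set} (drug-level or ATC-aggregated).
#' @param drug_or_class value of the \code{drug} column.
#' @param window_days analysis window after the start of
#'   administration, days.
#' @return a \code{latency_set}: list with \code{drug_or_class},
#'   numeric \code{latencies_days}, the four exclusion counts and
#'   \code{n_candidates}.
#' @export
compute_latencies <- function(records, drug_or_class, window_days = 365L) {
  stopifnot(is.data.frame(records), window_days >= 1)
  r <- records[records$drug == drug_or_class & records$is_case, , drop = FALSE]
  start_ord <- date_ordinal(r$start_date)
  onset_ord <- date_ordinal(r$onset_date)
  incomplete <- is.na(start_ord) | is.na(onset_ord)
  lat <- onset_ord - start_ord
  negative <- !incomplete & lat < 0
  beyond <- !incomplete & !negative & lat > window_days
  keep <- !incomplete & !negative & !beyond
  structure(list(drug_or_class = drug_or_class,
                 latencies_days = as.numeric(lat[keep]),
                 n_candidates = nrow(r),
                 n_excluded_incomplete = sum(incomplete),
                 n_excluded_negative = sum(negative),
                 n_excluded_window = sum(beyond),
                 n_excluded_duplicate = sum(r$n_dup_rows)),
            class = "latency_set")
}

#' @export
print.latency_set <- function(x, ...) {
  cat("<latency_set> ", x$drug_or_class, ": n=", length(x$latencies_days),
      " (excluded: incomplete=", x$n_excluded_incomplete,
      ", negative=", x$n_excluded_negative,
      ", window=", x$n_excluded_window,
      "; duplicate rows collapsed=", x$n_excluded_duplicate, ")\n", sep = "")
  invisible(x)
}

#' Bare latency set from a numeric vector
#'
#' Wraps externally supplied latencies (e.g. raw simulation draws) so
#' they can flow through the fitting and comparison functions.
#'
#' @param latencies_days non-negative numeric vector of days.
#' @param drug_or_class label.
#' @return a \code{latency_set} with zero exclusion counts.
#' @export
as_latency_set <- function(latencies_days, drug_or_class = "") {
  stopifnot(is.numeric(latencies_days), all(latencies_days >= 0))
  structure(list(drug_or_class = drug_or_class,
                 latencies_days = as.numeric(latencies_days),
                 n_candidates = length(latencies_days),
                 n_excluded_incomplete = 0L, n_excluded_negative = 0L,
                 n_excluded_window = 0L, n_excluded_duplicate = 0L),
            class = "latency_set")
}

#' Median and interquartile range of onset latencies
#'
#' Quantiles use the (n+1)p convention with linear interpolation
#' (quantile type 6), the convention of the statistical software
#' customarily used for these tables; set \code{type} for an
#' alternative.
#'
#' @param latencies a \code{latency_set}.
#' @param type quantile algorithm passed to \code{\link[stats]{quantile}}.
#' @return list with \code{median_days}, \code{q1_days}, \code{q3_days},
#'   \code{n}.
#' @export
summarize_latency <- function(latencies, type = 6L) {
  stopifnot(inherits(latencies, "latency_set"))
  x <- latencies$latencies_days
  if (!length(x)) stop("no retained latencies to summarise", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  list(median_days = q[2], q1_days = q[1], q3_days = q[3], n = length(x))
}

# Weibull log-likelihood on log-parameters (log alpha = scale,
# log beta = shape); optimisation on the log scale keeps the support
# constraint implicit and makes Wald intervals respect positivity.
weibull_negloglik <- function(logpar, x) {
  alpha <- exp(logpar[1]); beta <- exp(logpar[2])
  ll <- length(x) * (log(beta) - beta * log(alpha)) +
    (beta - 1) * sum(log(x)) - sum((x / alpha)^beta)
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Fit a Weibull time-to-onset distribution
#'
#' Maximum-likelihood fit of the Weibull density
#' \eqn{f(t) = (\beta/\alpha)(t/\alpha)^{\beta-1} e^{-(t/\alpha)^\beta}}
#' to retained latencies. Zero-day latencies (the log-density is
#' undefined at 0) are replaced by 0.5 days for fitting only; the count
#' is reported in \code{n_zero_adjusted}. Confidence intervals are Wald
#' intervals on \eqn{(\log\alpha, \log\beta)} using the observed
#' information at the optimum, exponentiated back. Initialisation is
#' moment-style (shape from the coefficient of variation, scale from
#' the mean), with a small multi-start fallback if the optimiser fails.
#'
#' @param latencies a \code{latency_set}.
#' @param ci_level two-sided confidence level.
#' @param min_n minimum number of latencies required (classes with few
#'   retained reports are refused rather than fitted unstably).
#' @return a \code{weibull_fit}: list with \code{alpha_days},
#'   \code{alpha_ci}, \code{beta}, \code{beta_ci}, \code{log_likelihood},
#'   \code{n}, \code{n_zero_adjusted} and \code{hazard_class}.
#' @export
fit_weibull <- function(latencies, ci_level = 0.95, min_n = 10L) {
  stopifnot(inherits(latencies, "latency_set"))
  x <- latencies$latencies_days
  if (length(x) < min_n)
    stop("too few latencies to fit (", length(x), " < ", min_n, ") for ",
         sQuote(latencies$drug_or_class), call. = FALSE)
  n_zero <- sum(x == 0)
  x[x == 0] <- 0.5

  cv <- stats::sd(x) / mean(x)
  beta0 <- if (is.finite(cv) && cv > 0) max(0.1, min(10, cv^-1.086)) else 1
  alpha0 <- mean(x) / gamma(1 + 1 / beta0)
  starts <- list(c(log(alpha0), log(beta0)),
                 c(log(stats::median(x) + 0.5), 0),
                 c(log(mean(x)), log(0.5)))
  fit <- NULL
  for (s in starts) {
    f <- tryCatch(stats::optim(s, weibull_negloglik, x = x,
                               method = "BFGS", hessian = TRUE,
                               control = list(reltol = 1e-12, maxit = 500L)),
                  error = function(e) NULL)
    if (!is.null(f) && f$convergence == 0 &&
        all(is.finite(f$hessian)) && all(diag(f$hessian) > 0)) { fit <- f; break }
  }
  if (is.null(fit))
    stop("Weibull fit failed to converge for ",
         sQuote(latencies$drug_or_class), call. = FALSE)

  se <- sqrt(diag(solve(fit$hessian)))
  z <- stats::qnorm((1 + ci_level) / 2)
  est <- exp(fit$par)
  lo <- exp(fit$par - z * se)
  hi <- exp(fit$par + z * se)
  out <- structure(list(drug_or_class = latencies$drug_or_class,
                        alpha_days = est[1], alpha_ci = c(lo[1], hi[1]),
                        beta = est[2], beta_ci = c(lo[2], hi[2]),
                        log_likelihood = -fit$value,
                        n = length(x), n_zero_adjusted = n_zero,
                        hazard_class = NA_character_),
                   class = "weibull_fit")
  out$hazard_class <- classify_hazard(out)
  out
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("<weibull_fit> %s: alpha=%.2f (%.2f-%.2f) beta=%.2f (%.2f-%.2f) n=%d [%s]\n",
              x$drug_or_class, x$alpha_days, x$alpha_ci[1], x$alpha_ci[2],
              x$beta, x$beta_ci[1], x$beta_ci[2], x$n, x$hazard_class))
  invisible(x)
}

#' Classify the hazard from the shape-parameter confidence interval
#'
#' The Weibull shape parameter \eqn{\beta} indexes how the reporting
#' hazard of the event changes with time since the start of
#' administration: \code{initial_failure} (decreasing hazard) when the
#' upper CI limit of \eqn{\beta} is strictly below 1,
#' \code{wear_out_failure} (increasing hazard) when the lower limit is
#' strictly above 1, and \code{random_failure} (constant hazard)
#' otherwise. A limit exactly equal to 1 classifies as random failure.
#'
#' @param fit a \code{weibull_fit}, or anything with a \code{beta_ci}
#'   field of length 2.
#' @return \code{"initial_failure"}, \code{"random_failure"} or
#'   \code{"wear_out_failure"}.
#' @export
classify_hazard <- function(fit) {
  ci <- fit$beta_ci
  stopifnot(length(ci) == 2, all(is.finite(ci)), ci[1] <= ci[2])
  if (ci[2] < 1) "initial_failure"
  else if (ci[1] > 1) "wear_out_failure"
  else "random_failure"
}

#' Time-to-onset summary table over several drugs or classes
#'
#' Runs \code{\link{compute_latencies}}, \code{\link{summarize_latency}}
#' and \code{\link{fit_weibull}} per target, mirroring the customary
#' presentation (n, median with IQR, Weibull scale and shape with CIs,
#' hazard class) plus the exclusion accounting. Targets with too few
#' retained latencies appear with \code{NA} fit columns.
#'
#' @param records an \code{analysis_set}.
#' @param targets character vector of drug or class labels.
#' @param window_days analysis window in days.
#' @param ci_level confidence level.
#' @param min_n minimum retained latencies for fitting.
#' @return data frame, one row per target.
#' @export
run_tto_table <- function(records, targets, window_days = 365L,
                          ci_level = 0.95, min_n = 10L) {
  rows <- lapply(targets, function(tg) {
    ls <- compute_latencies(records, tg, window_days)
    n <- length(ls$latencies_days)
    base <- data.frame(drug_or_class = tg, n = n,
                       median_days = NA_real_, q1_days = NA_real_,
                       q3_days = NA_real_, alpha = NA_real_,
                       alpha_low = NA_real_, alpha_high = NA_real_,
                       beta = NA_real_, beta_low = NA_real_,
                       beta_high = NA_real_, hazard_class = NA_character_,
                       n_excluded_incomplete = ls$n_excluded_incomplete,
                       n_excluded_negative = ls$n_excluded_negative,
                       n_excluded_window = ls$n_excluded_window,
                       n_excluded_duplicate = ls$n_excluded_duplicate,
                       stringsAsFactors = FALSE)
    if (n >= 1) {
      s <- summarize_latency(ls)
      base$median_days <- s$median_days
      base$q1_days <- s$q1_days
      base$q3_days <- s$q3_days
    }
    if (n >= min_n) {
      fit <- tryCatch(fit_weibull(ls, ci_level, min_n),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        base$alpha <- fit$alpha_days
        base$alpha_low <- fit$alpha_ci[1]; base$alpha_high <- fit$alpha_ci[2]
        base$beta <- fit$beta
        base$beta_low <- fit$beta_ci[1]; base$beta_high <- fit$beta_ci[2]
        base$hazard_class <- fit$hazard_class
      }
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
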