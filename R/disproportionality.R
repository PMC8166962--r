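#' 2x2 drug-by-event contingency table
#'
#' Cells follow the standard spontaneous-report construction:
#' \code{a} = reports with the drug and the event, \code{b} = drug
#' without event, \code{c} = event without drug, \code{d} = neither.
#' The four cells always sum to the total number of reports.
#'
#' @param a,b,c,d non-negative cell counts.
#' @param integer_cells require whole-number cells (expected cells from
#'   the generator oracle are real-valued).
#' @return a \code{contingency_table} object.
#' @export
contingency_table <- function(a, b, c, d, integer_cells = TRUE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("contingency cells must be non-negative", call. = FALSE)
  if (integer_cells && any(cells != round(cells)))
    stop("contingency cells must be whole counts", call. = FALSE)
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(unlist(x), 2, 2, byrow = TRUE,
              dimnames = list(c("drug", "no drug"),
                              c("event", "no event")))
  print(m[, c(1, 2)])
  invisible(x)
}

#' Build the 2x2 table for one drug or class
#'
#' Exposure is counted at report level (a report exposed to several
#' member drugs of a class counts once), so
#' \code{a} = exposed case reports, \code{b} = exposed non-case reports,
#' \code{c = total_cases - a}, \code{d = total_reports - a - b - c}.
#'
#' @param records an \code{analysis_set} (drug-level or ATC-aggregated).
#' @param drug_or_class value of the \code{drug} column to tabulate.
#' @param total_reports,total_cases analysis denominators; default to
#'   the attributes carried by \code{records}.
#' @return a \code{\link{contingency_table}}.
#' @export
build_contingency <- function(records, drug_or_class,
                              total_reports = attr(records, "n_reports"),
                              total_cases = attr(records, "n_cases")) {
  stopifnot(is.data.frame(records), total_reports >= total_cases)
  r <- records[records$drug == drug_or_class, , drop = FALSE]
  exposed <- length(unique(r$case_id))
  a <- length(unique(r$case_id[r$is_case]))
  b <- exposed - a
  c_ <- total_cases - a
  d <- total_reports - exposed - c_
  if (c_ < 0 || d < 0)
    stop("inconsistent denominators for ", sQuote(drug_or_class),
         ": derived cell is negative", call. = FALSE)
  contingency_table(a, b, c_, d)
}

round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' ROR = (a d)/(b c); the confidence interval is the Woolf (logit)
#' interval, \eqn{\exp(\log ROR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})}.
#' The result is non-evaluable (ROR undefined) when \code{a < 2} or any
#' of \code{b}, \code{c}, \code{d} is zero; no continuity correction is
#' applied by default. Set \code{haldane = TRUE} to add 0.5 to every
#' cell before estimation (a non-default convention, flagged in the
#' result).
#'
#' @param table a \code{\link{contingency_table}}.
#' @param ci_level two-sided confidence level, default 0.95.
#' @param drug_or_class label carried into the result.
#' @param haldane apply the Haldane-Anscombe 0.5 correction.
#' @return a \code{signal_result}: one-row data frame with columns
#'   \code{drug_or_class}, \code{n_total}, \code{n_case}, \code{ror},
#'   \code{ci_low}, \code{ci_high}, \code{evaluable}, \code{is_signal}
#'   (\code{NA} until \code{\link{detect_signal}}).
#' @export
compute_ror <- function(table, ci_level = 0.95, drug_or_class = "",
                        haldane = FALSE) {
  stopifnot(inherits(table, "contingency_table"),
            ci_level > 0, ci_level < 1)
  a <- table$a; b <- table$b; c_ <- table$c; d <- table$d
  evaluable <- a >= 2 && b > 0 && c_ > 0 && d > 0
  if (haldane) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  if (evaluable || (haldane && table$a >= 2)) {
    ror <- (a * d) / (b * c_)
    z <- stats::qnorm((1 + ci_level) / 2)
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    ci_low <- exp(log(ror) - z * se)
    ci_high <- exp(log(ror) + z * se)
    evaluable <- TRUE
  } else {
    ror <- ci_low <- ci_high <- NA_real_
    evaluable <- FALSE
  }
  structure(data.frame(drug_or_class = drug_or_class,
                       n_total = table$a + table$b,
                       n_case = table$a,
                       ror = ror, ci_low = ci_low, ci_high = ci_high,
                       evaluable = evaluable, is_signal = NA,
                       stringsAsFactors = FALSE),
            class = c("signal_result", "data.frame"))
}

#' Apply the signal-detection rule
#'
#' A drug-event pair is a signal when the estimated ROR and the lower
#' limit of its confidence interval both exceed 1 and at least two case
#' reports exist.
#'
#' @param result a \code{signal_result} from \code{\link{compute_ror}}.
#' @return the result with \code{is_signal} set.
#' @export
detect_signal <- function(result) {
  stopifnot(inherits(result, "signal_result"))
  result$is_signal <- !is.na(result$evaluable) & result$evaluable &
    !is.na(result$ror) & result$ror > 1 & result$ci_low > 1 &
    result$n_case >= 2
  result
}

#' Screen a list of drugs or classes for disproportionality signals
#'
#' Builds the 2x2 table, estimates the ROR with its confidence interval
#' and applies the signal rule for every target, recomputing the report
#' and case denominators from the analysis set itself. Unknown targets
#' appear as non-evaluable rows with a warning. Rows are ordered by ATC
#' code then name.
#'
#' @param records an \code{analysis_set}.
#' @param targets character vector of drug or class labels (values of
#'   the \code{drug} column).
#' @param ci_level confidence level for the Woolf interval.
#' @return data frame of signal results, one row per target, with the
#'   denominators as attributes \code{n_reports} / \code{n_cases}.
#' @export
run_signal_screen <- function(records, targets, ci_level = 0.95) {
  stopifnot(length(targets) >= 1)
  total_reports <- attr(records, "n_reports")
  total_cases <- attr(records, "n_cases")
  atc <- records$atc_code[match(targets, records$drug)]
  known <- targets %in% records$drug
  if (any(!known))
    warning("target(s) not present in analysis set: ",
            paste(targets[!known], collapse = ", "), call. = FALSE)
  rows <- lapply(seq_along(targets), function(i) {
    if (!known[i]) {
      out <- compute_ror(contingency_table(0, 0, total_cases,
                                           total_reports - total_cases),
                         ci_level, targets[i])
      return(detect_signal(out))
    }
    tab <- build_contingency(records, targets[i], total_reports, total_cases)
    detect_signal(compute_ror(tab, ci_level, targets[i]))
  })
  out <- do.call(rbind, rows)
  out$atc_code <- ifelse(is.na(atc), "unassigned", atc)
  out <- out[order(out$atc_code, out$drug_or_class), , drop = FALSE]
  out <- out[, c("atc_code", "drug_or_class", "n_total", "n_case",
                 "ror", "ci_low", "ci_high", "evaluable", "is_signal")]
  rownames(out) <- NULL
  structure(out, n_reports = total_reports, n_cases = total_cases)
}

#' Format a screen table for reporting
#'
#' Rounds ROR and interval to one decimal (half-up, matching the usual
#' presentation in pharmacovigilance tables) and renders the interval
#' as \code{"low-high"}; internal full-precision values are untouched.
#'
#' @param screen output of \code{\link{run_signal_screen}}.
#' @return data frame with display columns.
#' @export
format_signal_table <- function(screen) {
  data.frame(atc_code = screen$atc_code,
             drug = screen$drug_or_class,
             total_n = screen$n_total,
             case_n = screen$n_case,
             ror = ifelse(screen$evaluable,
                          sprintf("%.1f", round_half_up(screen$ror, 1L)), "-"),
             ci95 = ifelse(screen$evaluable,
                           sprintf("%.1f-%.1f",
                                   round_half_up(screen$ci_low, 1L),
                                   round_half_up(screen$ci_high, 1L)), "-"),
             signal = ifelse(!is.na(screen$is_signal) & screen$is_signal,
                             "*", ""),
             stringsAsFactors = FALSE)
}
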