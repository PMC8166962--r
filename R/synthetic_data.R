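#' Specify a simulated drug
#'
#' Each drug in the generator is defined by its marginal probability of
#' appearing (as a suspected drug) on a report, the multiplicative effect
#' of exposure on the odds of the focal adverse event, a Weibull latency
#' law for onset after the start of administration, and an outcome mixture
#' over the six SRS outcome categories.
#'
#' The association is parameterised on the odds scale so that the
#' configured \code{event_odds_multiplier} is exactly the estimand of the
#' reporting odds ratio: in a single-drug configuration the odds ratio of
#' the expected 2x2 cells equals the multiplier.
#'
#' @param name product name (also used as canonical drug name).
#' @param atc_code WHO ATC code, e.g. \code{"L01XA03"}, or
#'   \code{"unassigned"}.
#' @param marginal_exposure_prob probability a report lists the drug.
#' @param event_odds_multiplier multiplicative effect of exposure on the
#'   odds of the focal event; 1 means no association.
#' @param latency_alpha_days Weibull scale of onset latency, days.
#' @param latency_beta Weibull shape of onset latency.
#' @param outcome_probs probabilities over
#'   \code{c("death","with_sequelae","not_recovered","improved",
#'   "recovered","unknown")}, summing to 1.
#' @return a \code{drug_spec} list.
#' @export
drug_spec <- function(name, atc_code = "unassigned",
                      marginal_exposure_prob = 0.01,
                      event_odds_multiplier = 1,
                      latency_alpha_days = 50,
                      latency_beta = 0.8,
                      outcome_probs = c(death = 0.02, with_sequelae = 0.03,
                                        not_recovered = 0.30, improved = 0.25,
                                        recovered = 0.30, unknown = 0.10)) {
  stopifnot(nzchar(name),
            marginal_exposure_prob >= 0, marginal_exposure_prob <= 1,
            event_odds_multiplier > 0,
            latency_alpha_days > 0, latency_beta > 0,
            length(outcome_probs) == 6L, all(outcome_probs >= 0))
  if (abs(sum(outcome_probs) - 1) > 1e-9)
    stop("outcome_probs must sum to 1", call. = FALSE)
  names(outcome_probs) <- OUTCOME_CODES[1:6]
  structure(list(name = name, atc_code = atc_code,
                 marginal_exposure_prob = marginal_exposure_prob,
                 event_odds_multiplier = event_odds_multiplier,
                 latency_alpha_days = latency_alpha_days,
                 latency_beta = latency_beta,
                 outcome_probs = outcome_probs),
            class = "drug_spec")
}

#' Configure the synthetic-report generator
#'
#' @param n_reports number of reports (rows of demo).
#' @param background_event_prob probability of the focal event for a
#'   report exposed to none of the configured drugs.
#' @param drugs list of \code{\link{drug_spec}} objects.
#' @param missing_date_prob probability that any given start or onset
#'   date is degraded to year-month precision (emulating incomplete
#'   reporting).
#' @param duplicate_prescription_prob probability that a drug record is
#'   cloned under a new \code{drug_seq} (duplicate prescription rows).
#' @param seed integer RNG seed; identical seed and config give an
#'   identical dataset.
#' @param calendar_year year over which administration start dates are
#'   drawn uniformly.
#' @param pt_code MedDRA preferred-term code of the focal event.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_reports, background_event_prob = 0.003,
                       drugs = list(), missing_date_prob = 0,
                       duplicate_prescription_prob = 0, seed = 1L,
                       calendar_year = 2019L, pt_code = 10029331L) {
  stopifnot(n_reports >= 1,
            background_event_prob >= 0, background_event_prob <= 1,
            missing_date_prob >= 0, missing_date_prob <= 1,
            duplicate_prescription_prob >= 0, duplicate_prescription_prob <= 1)
  drugs <- lapply(drugs, function(d) {
    if (!inherits(d, "drug_spec")) do.call(drug_spec, d) else d
  })
  nm <- vapply(drugs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate drug names in config", call. = FALSE)
  structure(list(n_reports = as.integer(n_reports),
                 background_event_prob = background_event_prob,
                 drugs = drugs,
                 missing_date_prob = missing_date_prob,
                 duplicate_prescription_prob = duplicate_prescription_prob,
                 seed = as.integer(seed),
                 calendar_year = as.integer(calendar_year),
                 pt_code = as.integer(pt_code)),
            class = "sim_config")
}

#' Read a generator configuration file
#'
#' YAML file whose keys are the \code{\link{sim_config}} arguments;
#' \code{drugs} is a list of \code{\link{drug_spec}} argument maps.
#'
#' @param path path to the YAML config.
#' @return a \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$drugs))
    raw$drugs <- lapply(raw$drugs, function(d) {
      if (!is.null(d$outcome_probs)) d$outcome_probs <- unlist(d$outcome_probs)
      do.call(drug_spec, d)
    })
  do.call(sim_config, raw)
}

# filler PT for non-focal reactions so every report carries an event row
OTHER_PT_CODE <- 10019211L
OTHER_PT_NAME <- "headache"

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic SRS dataset
#'
#' Each report independently draws drug exposures from their marginal
#' probabilities. The focal event occurs with probability given by the
#' background odds multiplied by the \code{event_odds_multiplier} of every
#' exposed drug. Reports that are both exposed and cases receive an onset
#' date equal to the (first-listed exposed) drug's start date plus a
#' Weibull latency rounded to whole days; latencies rounding to 0 are
#' emitted as day 0. Every report carries at least one reaction row (a
#' filler preferred term when the focal event did not occur), so outcome
#' mixtures are observable for cases and non-cases alike. Dates are
#' degraded to year-month precision with \code{missing_date_prob} and drug
#' rows cloned with \code{duplicate_prescription_prob}.
#'
#' The returned dataset carries a \code{truth} attribute with the
#' realised bookkeeping (per-drug exposed and exposed-case counts, total
#' case count, and per-drug realised latencies before any date
#' degradation), for use as an oracle when validating analyses.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a validated \code{\link{srs_dataset}} with attribute
#'   \code{truth}.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(config) {
  n <- config$n_reports
  k <- length(config$drugs)
  case_id <- sprintf("R%07d", seq_len(n))

  expo <- matrix(FALSE, n, k)
  for (j in seq_len(k))
    expo[, j] <- stats::runif(n) < config$drugs[[j]]$marginal_exposure_prob

  p0 <- config$background_event_prob
  odds <- rep(p0 / (1 - p0), n)
  for (j in seq_len(k))
    odds[expo[, j]] <- odds[expo[, j]] * config$drugs[[j]]$event_odds_multiplier
  is_case <- stats::runif(n) < odds / (1 + odds)

  year0 <- as.Date(sprintf("%04d-01-01", config$calendar_year))
  ndays <- as.integer(as.Date(sprintf("%04d-12-31", config$calendar_year)) - year0) + 1L

  # demo -------------------------------------------------------------
  demo <- data.frame(
    case_id = case_id,
    sex = sample(c("male", "female", "unknown"), n, TRUE, c(0.48, 0.48, 0.04)),
    age_band = paste0(sample(1:8, n, TRUE) * 10, "s"),
    report_period = sprintf("%04d", config$calendar_year),
    stringsAsFactors = FALSE)

  # drug rows ---------------------------------------------------------
  drug_list <- vector("list", k)
  start_day <- matrix(NA_integer_, n, k)
  for (j in seq_len(k)) {
    idx <- which(expo[, j])
    if (!length(idx)) next
    sd <- sample.int(ndays, length(idx), replace = TRUE) - 1L
    start_day[idx, j] <- sd
    drug_list[[j]] <- data.frame(
      case_id = case_id[idx],
      drug_seq = 0L,  # assigned after assembly
      product_name = config$drugs[[j]]$name,
      role_code = "suspected",
      start_date = format(year0 + sd, "%Y%m%d"),
      end_date = "",
      stringsAsFactors = FALSE)
  }
  drug <- do.call(rbind, c(drug_list,
                           list(empty_table("drug"))))

  # attribute each case's latency to its first-listed exposed drug ----
  onset_day <- rep(NA_integer_, n)
  truth_lat <- setNames(vector("list", k),
                        vapply(config$drugs, `[[`, "", "name"))
  attributed <- rep(NA_integer_, n)
  for (j in seq_len(k)) {
    idx <- which(is_case & expo[, j] & is.na(attributed))
    if (!length(idx)) next
    attributed[idx] <- j
    lat <- round(stats::rweibull(length(idx),
                                 shape = config$drugs[[j]]$latency_beta,
                                 scale = config$drugs[[j]]$latency_alpha_days))
    truth_lat[[j]] <- lat
    onset_day[idx] <- start_day[idx, j] + lat
  }
  bg_case <- which(is_case & is.na(attributed))
  onset_day[bg_case] <- sample.int(ndays, length(bg_case), replace = TRUE) - 1L
  non_case <- which(!is_case)
  other_onset <- rep(NA_integer_, n)
  other_onset[non_case] <- sample.int(ndays, length(non_case), replace = TRUE) - 1L

  # outcomes ----------------------------------------------------------
  draw_outcome <- function(m, probs)
    sample(OUTCOME_CODES[1:6], m, TRUE, probs)
  outcome <- character(n)
  bg_probs <- drug_spec("bg")$outcome_probs
  for (j in seq_len(k)) {
    idx <- which(attributed == j)
    outcome[idx] <- draw_outcome(length(idx), config$drugs[[j]]$outcome_probs)
  }
  rest <- which(is.na(attributed))
  outcome[rest] <- draw_outcome(length(rest), bg_probs)

  # reac rows: focal event for cases, filler PT otherwise -------------
  reac <- data.frame(
    case_id = case_id,
    pt_code = ifelse(is_case, config$pt_code, OTHER_PT_CODE),
    pt_name = ifelse(is_case, "peripheral neuropathy", OTHER_PT_NAME),
    onset_date = format(year0 + ifelse(is_case, onset_day, other_onset),
                        "%Y%m%d"),
    outcome = outcome,
    stringsAsFactors = FALSE)

  # hist ---------------------------------------------------------------
  hist <- data.frame(
    case_id = case_id,
    disease_name = sample(c("colorectal cancer", "breast cancer",
                            "multiple myeloma", "lung cancer"), n, TRUE),
    stringsAsFactors = FALSE)

  # date degradation ---------------------------------------------------
  if (config$missing_date_prob > 0) {
    if (nrow(drug)) {
      deg <- stats::runif(nrow(drug)) < config$missing_date_prob
      drug$start_date[deg] <- degrade_to_year_month(drug$start_date[deg])
    }
    deg <- stats::runif(nrow(reac)) < config$missing_date_prob
    reac$onset_date[deg] <- degrade_to_year_month(reac$onset_date[deg])
  }

  # duplicate prescriptions -------------------------------------------
  if (config$duplicate_prescription_prob > 0 && nrow(drug)) {
    dup <- which(stats::runif(nrow(drug)) < config$duplicate_prescription_prob)
    if (length(dup)) drug <- rbind(drug, drug[dup, , drop = FALSE])
  }
  if (nrow(drug)) {
    ord <- order(drug$case_id, drug$product_name)
    drug <- drug[ord, , drop = FALSE]
    drug$drug_seq <- stats::ave(seq_len(nrow(drug)), drug$case_id,
                                FUN = seq_along)
    rownames(drug) <- NULL
  }

  out <- new_srs_dataset(demo, drug, reac, hist)
  attr(out, "truth") <- list(
    n_cases = sum(is_case),
    exposure = data.frame(
      drug = vapply(config$drugs, `[[`, "", "name"),
      n_exposed = colSums(expo),
      n_exposed_case = vapply(seq_len(k), function(j) sum(expo[, j] & is_case),
                              integer(1)),
      stringsAsFactors = FALSE),
    latencies = truth_lat)
  out
}

#' Expected 2x2 contingency cells under the generative model
#'
#' Closed-form expectation of the drug-by-event contingency table,
#' marginalising exactly over the exposure status of every other
#' configured drug. Serves as the analytic oracle for realised cell
#' counts and for the odds-ratio estimand: with a single configured drug
#' the odds ratio of the expected cells equals its
#' \code{event_odds_multiplier} exactly.
#'
#' @param config a \code{\link{sim_config}}.
#' @param drug_name name of a configured drug.
#' @return a \code{\link{contingency_table}} with real-valued cells
#'   summing to \code{n_reports}.
#' @export
expected_contingency <- function(config, drug_name) {
  stopifnot(inherits(config, "sim_config"))
  nm <- vapply(config$drugs, `[[`, "", "name")
  j <- match(drug_name, nm)
  if (is.na(j)) stop("unknown drug: ", sQuote(drug_name), call. = FALSE)
  p0 <- config$background_event_prob
  o0 <- p0 / (1 - p0)
  others <- setdiff(seq_along(nm), j)
  # P(event | exposure of drug j), marginal over other drugs' exposures
  p_event_given <- function(exposed_j) {
    base <- o0 * if (exposed_j) config$drugs[[j]]$event_odds_multiplier else 1
    if (!length(others)) return(base / (1 + base))
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(others)))
    tot <- 0
    for (r in seq_len(nrow(grid))) {
      w <- 1; odds <- base
      for (ii in seq_along(others)) {
        dk <- config$drugs[[others[ii]]]
        if (grid[r, ii]) {
          w <- w * dk$marginal_exposure_prob
          odds <- odds * dk$event_odds_multiplier
        } else w <- w * (1 - dk$marginal_exposure_prob)
      }
      tot <- tot + w * odds / (1 + odds)
    }
    tot
  }
  pe <- config$drugs[[j]]$marginal_exposure_prob
  n <- config$n_reports
  a <- n * pe * p_event_given(TRUE)
  b <- n * pe - a
  c_ <- n * (1 - pe) * p_event_given(FALSE)
  d <- n * (1 - pe) - c_
  contingency_table(a, b, c_, d, integer_cells = FALSE)
}

#' Drug vocabulary implied by a generator config
#'
#' @param config a \code{\link{sim_config}}.
#' @return data frame with columns \code{product_name},
#'   \code{canonical_name}, \code{atc_code} (identity mapping).
#' @export
sim_vocabulary <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  data.frame(
    product_name = vapply(config$drugs, `[[`, "", "name"),
    canonical_name = vapply(config$drugs, `[[`, "", "name"),
    atc_code = vapply(config$drugs, `[[`, "", "atc_code"),
    stringsAsFactors = FALSE)
}
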