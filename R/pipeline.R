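#' Configure an end-to-end analysis run
#'
#' Exactly one of \code{paths} (four-table input files) or \code{sim}
#' (a \code{\link{sim_config}} for the synthetic generator) must be
#' supplied.
#'
#' @param pt_codes integer vector of focal MedDRA PT codes.
#' @param targets character vector of drug names to screen.
#' @param paths named list of input files (demo/drug/reac/hist), or
#'   \code{NULL}.
#' @param sim a \code{\link{sim_config}}, or \code{NULL}.
#' @param vocab vocabulary data frame or path to a vocabulary CSV; when
#'   \code{NULL} and simulating, the generator's own vocabulary is used.
#' @param class_level optional ATC prefix length (1/3/4/5/7); when set,
#'   class-level screening and time-to-onset tables are produced for the
#'   classes covering the targets.
#' @param compare optional character pair: two drug names whose onset
#'   profiles are compared by Kaplan-Meier and log-rank.
#' @param window_days time-to-onset analysis window, days.
#' @param ci_level confidence level used throughout.
#' @param seed master seed for the run (forwarded to the generator).
#' @param out_dir output directory.
#' @return a \code{run_config} list.
#' @export
run_config <- function(pt_codes, targets, paths = NULL, sim = NULL,
                       vocab = NULL, class_level = NULL, compare = NULL,
                       window_days = 365L, ci_level = 0.95, seed = 1L,
                       out_dir = tempfile("pvonset_run_")) {
  if (is.null(paths) == is.null(sim))
    stop("supply exactly one of `paths` or `sim`", call. = FALSE)
  stopifnot(length(pt_codes) >= 1, length(targets) >= 1)
  if (!is.null(compare)) stopifnot(length(compare) == 2L)
  structure(list(pt_codes = as.integer(pt_codes), targets = targets,
                 paths = paths, sim = sim, vocab = vocab,
                 class_level = class_level, compare = compare,
                 window_days = as.integer(window_days),
                 ci_level = ci_level, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

write_stage <- function(df, dir, name, log) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  log(sprintf("wrote %s (%d rows)", name, nrow(df)))
  path
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) the four-table dataset, assemble the analysis
#' set, screen the targets for disproportionality signals, build the
#' time-to-onset table, optionally compare two arms and aggregate to
#' ATC classes, profile outcomes, and write every stage as a delimited
#' file plus a structured run log. Identical configs (same seed)
#' reproduce identical outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @return invisibly, a \code{report_bundle} list with elements
#'   \code{screen}, \code{tto}, \code{comparison} (or NULL),
#'   \code{outcomes}, \code{mosaic}, \code{log}, \code{config},
#'   \code{files}.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)
  files <- character(0)

  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    dataset <- generate_dataset(sim)
    log(sprintf("simulated %d reports (seed %d)", n_reports(dataset),
                config$seed))
    tab_paths <- as.list(file.path(config$out_dir,
                                   paste0(c("demo", "drug", "reac", "hist"),
                                          ".csv")))
    names(tab_paths) <- c("demo", "drug", "reac", "hist")
    write_srs_dataset(dataset, tab_paths)
    files <- c(files, unlist(tab_paths))
    prov <- list(seed = config$seed, n_reports = sim$n_reports,
                 background_event_prob = sim$background_event_prob,
                 drugs = lapply(sim$drugs, function(d)
                   d[c("name", "atc_code", "marginal_exposure_prob",
                       "event_odds_multiplier", "latency_alpha_days",
                       "latency_beta")]))
    yaml::write_yaml(prov, file.path(config$out_dir, "provenance.yaml"))
    vocab <- if (is.null(config$vocab)) sim_vocabulary(sim) else config$vocab
  } else {
    dataset <- read_srs_dataset(config$paths)
    log(sprintf("read %d reports", n_reports(dataset)))
    vocab <- config$vocab
  }
  if (is.character(vocab)) vocab <- read_vocabulary(vocab)
  if (is.null(vocab)) stop("no vocabulary available", call. = FALSE)

  records <- assemble_analysis_set(dataset, vocab, config$pt_codes)
  log(sprintf("analysis set: %d (report, drug) records; %d reports; %d cases",
              nrow(records), attr(records, "n_reports"),
              attr(records, "n_cases")))

  screen <- run_signal_screen(records, config$targets, config$ci_level)
  files <- c(files, write_stage(format_signal_table(screen), config$out_dir,
                                "signals.csv", log))

  tto <- run_tto_table(records, config$targets, config$window_days,
                       config$ci_level)
  files <- c(files, write_stage(tto, config$out_dir, "time_to_onset.csv", log))

  class_screen <- class_tto <- NULL
  if (!is.null(config$class_level)) {
    cls_records <- aggregate_by_atc(records, config$class_level)
    cls <- sort(unique(substr(
      records$atc_code[records$drug %in% config$targets &
                         records$atc_code != "unassigned"],
      1L, config$class_level)))
    if (length(cls)) {
      class_screen <- run_signal_screen(cls_records, cls, config$ci_level)
      files <- c(files, write_stage(format_signal_table(class_screen),
                                    config$out_dir, "signals_atc.csv", log))
      class_tto <- run_tto_table(cls_records, cls, config$window_days,
                                 config$ci_level)
      files <- c(files, write_stage(class_tto, config$out_dir,
                                    "time_to_onset_atc.csv", log))
    }
  }

  comparison <- NULL
  if (!is.null(config$compare)) {
    comparison <- compare_onset_profiles(records, config$compare[1],
                                         config$compare[2],
                                         config$window_days)
    km_df <- rbind(cbind(arm = comparison$arm1$label, comparison$arm1$km),
                   cbind(arm = comparison$arm2$label, comparison$arm2$km))
    files <- c(files, write_stage(km_df, config$out_dir, "km_curves.csv", log))
    lr_df <- data.frame(arm1 = comparison$arm1$label,
                        arm2 = comparison$arm2$label,
                        chi_square = comparison$logrank$chi_square,
                        p_value = comparison$logrank$p_value,
                        significant = comparison$significant)
    files <- c(files, write_stage(lr_df, config$out_dir, "logrank.csv", log))
  }

  out_tabs <- lapply(config$targets, function(tg)
    tabulate_outcomes(records, tg))
  nonempty <- vapply(out_tabs, function(t) t$denominator > 0, logical(1))
  outcome_df <- do.call(rbind, lapply(out_tabs, function(t)
    data.frame(drug_or_class = t$drug_or_class, t(t$counts),
               denominator = t$denominator,
               n_excluded_unknown = t$n_excluded_unknown)))
  files <- c(files, write_stage(outcome_df, config$out_dir, "outcomes.csv",
                                log))
  mosaic <- if (any(nonempty)) mosaic_data(out_tabs[nonempty]) else NULL
  if (!is.null(mosaic))
    files <- c(files, write_stage(mosaic, config$out_dir, "mosaic.csv", log))

  log_obj <- list(seed = config$seed,
                  package_version = as.character(utils::packageVersion("pvonset")),
                  n_reports = attr(records, "n_reports"),
                  n_cases = attr(records, "n_cases"),
                  stages = log_lines)
  jsonlite::write_json(log_obj, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, file.path(config$out_dir, "run_log.json"))

  invisible(structure(list(screen = screen, tto = tto,
                           class_screen = class_screen, class_tto = class_tto,
                           comparison = comparison, outcomes = out_tabs,
                           mosaic = mosaic, log = log_obj, config = config,
                           files = files),
                      class = "report_bundle"))
}

#' Render a human-readable run summary
#'
#' One plain-text document listing detected signals, hazard
#' classifications, the onset comparison and outcome fractions, each
#' traceable to a machine-readable stage file written by
#' \code{\link{run_full_analysis}}.
#'
#' @param bundle a \code{report_bundle}.
#' @param path optional file to write the text to.
#' @return the report text, invisibly when written to \code{path}.
#' @export
render_report <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "report_bundle"))
  need <- c("screen", "tto", "outcomes", "log")
  missing <- need[vapply(need, function(f) is.null(bundle[[f]]), logical(1))]
  if (length(missing))
    stop("incomplete bundle, missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  l <- character(0)
  add <- function(...) l <<- c(l, sprintf(...))
  add("Spontaneous-report analysis run (seed %d)", bundle$log$seed)
  add("Reports: %d | focal-event cases: %d", bundle$log$n_reports,
      bundle$log$n_cases)
  add("")
  sig <- bundle$screen[!is.na(bundle$screen$is_signal) &
                         bundle$screen$is_signal, , drop = FALSE]
  if (nrow(sig) == 0) {
    if (!any(bundle$screen$evaluable)) add("Signals: no evaluable targets")
    else add("Signals: none detected among %d evaluable target(s)",
             sum(bundle$screen$evaluable))
  } else {
    add("Signals (ROR > 1, CI lower bound > 1, >= 2 cases):")
    for (i in seq_len(nrow(sig)))
      add("  %s [%s]: ROR %.1f (%.1f-%.1f), %d cases",
          sig$drug_or_class[i], sig$atc_code[i],
          round_half_up(sig$ror[i], 1), round_half_up(sig$ci_low[i], 1),
          round_half_up(sig$ci_high[i], 1), sig$n_case[i])
  }
  add("")
  fitted <- bundle$tto[!is.na(bundle$tto$hazard_class), , drop = FALSE]
  if (nrow(fitted)) {
    add("Time-to-onset (Weibull):")
    for (i in seq_len(nrow(fitted)))
      add("  %s: median %.1f d (IQR %.1f-%.1f), alpha %.1f, beta %.2f (%.2f-%.2f) -> %s",
          fitted$drug_or_class[i], fitted$median_days[i], fitted$q1_days[i],
          fitted$q3_days[i], fitted$alpha[i], fitted$beta[i],
          fitted$beta_low[i], fitted$beta_high[i], fitted$hazard_class[i])
  }
  if (!is.null(bundle$comparison)) {
    cmp <- bundle$comparison
    add("")
    add("Onset comparison: %s vs %s: log-rank p = %.4g (%ssignificant at 0.05)",
        cmp$arm1$label, cmp$arm2$label, cmp$logrank$p_value,
        if (cmp$significant) "" else "not ")
  }
  add("")
  add("Outcomes (unfavourable = death + with sequelae + not recovered):")
  for (t in bundle$outcomes) {
    if (t$denominator == 0) {
      add("  %s: no informative outcomes", t$drug_or_class)
    } else {
      f <- combined_frequencies(t)
      add("  %s: unfavourable %.1f%% (%d/%d), %d unknown/blank excluded",
          t$drug_or_class, round_half_up(100 * f$unfavourable_frac, 1),
          f$unfavourable_n, f$denominator, t$n_excluded_unknown)
    }
  }
  txt <- paste(l, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
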