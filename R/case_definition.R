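#' Read a drug vocabulary file
#'
#' Maps reported product names to canonical drug names and ATC codes.
#' Distinct formulations of the same substance may map to distinct
#' canonical names while sharing an ATC code (e.g. solvent-based and
#' albumin-bound paclitaxel both under L01CD01), so formulation-level
#' contrasts remain possible alongside class-level aggregation.
#'
#' @param path CSV file with columns \code{product_name},
#'   \code{canonical_name}, \code{atc_code}.
#' @return data frame vocabulary.
#' @export
read_vocabulary <- function(path) {
  v <- utils::read.csv(path, colClasses = "character")
  need <- c("product_name", "canonical_name", "atc_code")
  miss <- setdiff(need, names(v))
  if (length(miss))
    stop("vocabulary is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(v$product_name))
    stop("vocabulary maps a product_name more than once", call. = FALSE)
  if (any(!nzchar(v$canonical_name)))
    stop("vocabulary contains empty canonical names", call. = FALSE)
  v[need]
}

#' Keep only suspected-drug records
#'
#' Restricts the drug table to records with role code
#' \code{"suspected"}; demo, reac and hist are untouched, so the report
#' denominator and the case definition are unchanged.
#'
#' @param dataset an \code{\link{srs_dataset}}.
#' @return the filtered \code{srs_dataset}.
#' @export
filter_suspected <- function(dataset) {
  stopifnot(inherits(dataset, "srs_dataset"))
  dataset$drug <- dataset$drug[dataset$drug$role_code == "suspected", ,
                               drop = FALSE]
  rownames(dataset$drug) <- NULL
  dataset
}

#' Flag case reports by preferred-term codes
#'
#' A report is a case iff any of its reaction rows carries one of the
#' focal MedDRA preferred-term codes; repeated occurrences of a PT
#' within one report flag it once (set semantics). Depends only on the
#' reac table, so it is invariant under drug-role filtering.
#'
#' @param dataset an \code{\link{srs_dataset}}.
#' @param pt_codes integer vector of MedDRA PT codes defining the event.
#' @return named logical vector over all demo case_ids, with attribute
#'   \code{n_flagged}.
#' @export
flag_cases <- function(dataset, pt_codes) {
  stopifnot(inherits(dataset, "srs_dataset"), length(pt_codes) >= 1)
  hit <- unique(dataset$reac$case_id[dataset$reac$pt_code %in% pt_codes])
  flags <- setNames(dataset$demo$case_id %in% hit, dataset$demo$case_id)
  attr(flags, "n_flagged") <- sum(flags)
  flags
}

#' Assemble the per-(report, drug) analysis set
#'
#' Applies the suspected-role filter, maps product names through the
#' vocabulary, and collapses duplicate prescription rows so that each
#' (report, canonical drug) pair contributes exactly one analysis
#' record. The record keeps the earliest complete start date among that
#' drug's rows (falling back to the earliest partial date, which the
#' latency stage will exclude with accounting), the earliest complete
#' onset date among the report's focal-event reactions, and the outcome
#' of the first-listed focal-event reaction. Product names absent from
#' the vocabulary keep their own name with ATC \code{"unassigned"} and a
#' warning.
#'
#' @param dataset an \code{\link{srs_dataset}}.
#' @param vocab vocabulary data frame (\code{\link{read_vocabulary}}).
#' @param pt_codes integer vector of focal MedDRA PT codes.
#' @return an \code{analysis_set}: data frame with columns
#'   \code{case_id}, \code{drug}, \code{atc_code}, \code{is_case},
#'   \code{start_date}, \code{onset_date}, \code{outcome},
#'   \code{n_dup_rows}; attributes \code{n_reports} and \code{n_cases}
#'   carry the analysis denominators.
#' @export
assemble_analysis_set <- function(dataset, vocab, pt_codes) {
  stopifnot(inherits(dataset, "srs_dataset"))
  total_reports <- n_reports(dataset)
  flags <- flag_cases(dataset, pt_codes)
  ds <- filter_suspected(dataset)
  drug <- ds$drug

  idx <- match(drug$product_name, vocab$product_name)
  unknown <- unique(drug$product_name[is.na(idx)])
  if (length(unknown))
    warning("product name(s) absent from vocabulary, kept unassigned: ",
            paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  drug$drug <- ifelse(is.na(idx), drug$product_name,
                      vocab$canonical_name[idx])
  drug$atc_code <- ifelse(is.na(idx), "unassigned", vocab$atc_code[idx])

  # earliest complete onset + first-listed outcome per focal-PT case
  focal <- dataset$reac[dataset$reac$pt_code %in% pt_codes, , drop = FALSE]
  onset_by_case <- character(0)
  outcome_by_case <- character(0)
  if (nrow(focal)) {
    comp <- focal[!is.na(date_ordinal(focal$onset_date)), , drop = FALSE]
    if (nrow(comp)) {
      ord <- comp[order(comp$case_id, date_ordinal(comp$onset_date)), ]
      first <- ord[!duplicated(ord$case_id), ]
      onset_by_case <- setNames(first$onset_date, first$case_id)
    }
    first_out <- focal[!duplicated(focal$case_id), ]
    outcome_by_case <- setNames(first_out$outcome, first_out$case_id)
  }

  if (nrow(drug) == 0L) {
    rec <- data.frame(case_id = character(0), drug = character(0),
                      atc_code = character(0), is_case = logical(0),
                      start_date = character(0), onset_date = character(0),
                      outcome = character(0), n_dup_rows = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    # earliest complete start date per (case, drug); fall back to the
    # earliest partial date so incompleteness stays visible downstream
    key <- paste(drug$case_id, drug$drug, sep = "\r")
    ordval <- date_ordinal(drug$start_date)
    rank <- ifelse(!is.na(ordval), ordval,
                   ifelse(nzchar(drug$start_date), .Machine$integer.max - 1L,
                          .Machine$integer.max))
    o <- order(key, rank)
    drug <- drug[o, , drop = FALSE]
    key <- key[o]
    keep <- !duplicated(key)
    n_dup <- as.integer(table(key)[key[keep]]) - 1L
    rec <- data.frame(case_id = drug$case_id[keep],
                      drug = drug$drug[keep],
                      atc_code = drug$atc_code[keep],
                      stringsAsFactors = FALSE)
    rec$is_case <- unname(flags[rec$case_id])
    rec$start_date <- drug$start_date[keep]
    rec$onset_date <- ifelse(rec$is_case,
                             unname(onset_by_case[rec$case_id]), NA_character_)
    rec$outcome <- ifelse(rec$is_case,
                          unname(outcome_by_case[rec$case_id]), NA_character_)
    rec$n_dup_rows <- n_dup
    rec <- rec[order(rec$atc_code, rec$drug, rec$case_id), , drop = FALSE]
    rownames(rec) <- NULL
  }
  structure(rec, class = c("analysis_set", "data.frame"),
            n_reports = total_reports,
            n_cases = attr(flags, "n_flagged"))
}

#' Aggregate analysis records under ATC prefixes
#'
#' Groups records by a prefix of the ATC code (1, 3, 4, 5 or 7
#' characters, the WHO hierarchy levels). A report exposed to several
#' drugs of one class counts once for that class: records collapse to
#' one per (report, class), keeping the earliest complete start date
#' among the member drugs so the class denominator stays a report count.
#' Records with ATC \code{"unassigned"} are dropped from class grouping
#' (they remain analysable at drug level).
#'
#' @param records an \code{analysis_set}.
#' @param level ATC prefix length: 1, 3, 4, 5 or 7.
#' @return an \code{analysis_set} whose \code{drug} and \code{atc_code}
#'   columns hold the class prefix.
#' @export
aggregate_by_atc <- function(records, level = 5L) {
  stopifnot(inherits(records, "analysis_set"), level %in% c(1L, 3L, 4L, 5L, 7L))
  keep <- records$atc_code != "unassigned" & !is.na(records$atc_code)
  r <- records[keep, , drop = FALSE]
  r$drug <- substr(r$atc_code, 1L, level)
  r$atc_code <- r$drug
  if (nrow(r)) {
    key <- paste(r$case_id, r$drug, sep = "\r")
    ordval <- date_ordinal(r$start_date)
    rank <- ifelse(!is.na(ordval), ordval, .Machine$integer.max)
    o <- order(key, rank)
    r <- r[o, , drop = FALSE]
    key <- key[o]
    dups <- stats::ave(r$n_dup_rows, key, FUN = sum)
    keep1 <- !duplicated(key)
    r$n_dup_rows[keep1] <- dups[keep1]
    r <- r[keep1, , drop = FALSE]
    r <- r[order(r$drug, r$case_id), , drop = FALSE]
    rownames(r) <- NULL
  }
  structure(r, class = c("analysis_set", "data.frame"),
            n_reports = attr(records, "n_reports"),
            n_cases = attr(records, "n_cases"))
}
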