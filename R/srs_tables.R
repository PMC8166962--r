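#' @name srs_dataset
#' @title Four-table spontaneous-report dataset
#'
#' @description
#' Container mirroring the JADER relational layout: \code{demo} (one row
#' per report: case identifier, sex, age band, reporting period),
#' \code{drug} (one row per prescription record: role code, product name,
#' administration dates), \code{reac} (one row per reported adverse event:
#' MedDRA preferred-term code and name, onset date, outcome) and
#' \code{hist} (primary disease). All tables link on \code{case_id}; the
#' number of \code{demo} rows is the report denominator used by every
#' downstream analysis.
#'
#' Dates are stored as digit strings (\code{YYYYMMDD}, \code{YYYYMM} or
#' \code{YYYY}; see \code{\link{parse_partial_date}}); role and outcome
#' codes as canonical tokens (see \code{\link{default_code_map}}).
NULL

ROLE_CODES <- c("suspected", "concomitant", "interacting")
OUTCOME_CODES <- c("death", "with_sequelae", "not_recovered",
                   "improved", "recovered", "unknown", "")

demo_cols <- c("case_id", "sex", "age_band", "report_period")
drug_cols <- c("case_id", "drug_seq", "product_name", "role_code",
               "start_date", "end_date")
reac_cols <- c("case_id", "pt_code", "pt_name", "onset_date", "outcome")
hist_cols <- c("case_id", "disease_name")

#' Construct and validate an SRS dataset
#'
#' @param demo,drug,reac,hist data frames with the schema columns (see
#'   \code{\link{srs_dataset}}). Missing optional tables default to empty.
#' @return an object of class \code{srs_dataset}.
#' @export
new_srs_dataset <- function(demo = empty_table("demo"),
                            drug = empty_table("drug"),
                            reac = empty_table("reac"),
                            hist = empty_table("hist")) {
  x <- structure(list(demo = as.data.frame(demo),
                      drug = as.data.frame(drug),
                      reac = as.data.frame(reac),
                      hist = as.data.frame(hist)),
                 class = "srs_dataset")
  validate_srs_dataset(x)
  x
}

#' Empty schema table
#'
#' @param table one of \code{"demo"}, \code{"drug"}, \code{"reac"},
#'   \code{"hist"}.
#' @return a zero-row data frame with the table's columns.
#' @export
empty_table <- function(table = c("demo", "drug", "reac", "hist")) {
  table <- match.arg(table)
  cols <- switch(table, demo = demo_cols, drug = drug_cols,
                 reac = reac_cols, hist = hist_cols)
  out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  if (table == "drug") out$drug_seq <- integer(0)
  if (table == "reac") out$pt_code <- integer(0)
  out
}

#' Validate dataset invariants
#'
#' Checks schema columns, uniqueness of \code{case_id} in demo and of
#' \code{(case_id, drug_seq)} in drug, closed role/outcome vocabularies,
#' positive PT codes, and referential integrity (every drug/reac/hist
#' case appears in demo).
#'
#' @param x an \code{srs_dataset}.
#' @return \code{x}, invisibly; errors describe the first violation found.
#' @export
validate_srs_dataset <- function(x) {
  stopifnot(inherits(x, "srs_dataset"))
  for (tab in c("demo", "drug", "reac", "hist")) {
    want <- switch(tab, demo = demo_cols, drug = drug_cols,
                   reac = reac_cols, hist = hist_cols)
    miss <- setdiff(want, names(x[[tab]]))
    if (length(miss))
      stop(tab, " table is missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  dup <- x$demo$case_id[duplicated(x$demo$case_id)]
  if (length(dup))
    stop("duplicate case_id in demo table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (any(!nzchar(x$demo$case_id)))
    stop("empty case_id in demo table", call. = FALSE)
  key <- paste(x$drug$case_id, x$drug$drug_seq)
  if (anyDuplicated(key))
    stop("duplicate (case_id, drug_seq) in drug table", call. = FALSE)
  bad_role <- setdiff(unique(x$drug$role_code), ROLE_CODES)
  if (length(bad_role))
    stop("unknown role_code: ", paste(bad_role, collapse = ", "), call. = FALSE)
  bad_out <- setdiff(unique(x$reac$outcome), OUTCOME_CODES)
  if (length(bad_out))
    stop("unknown outcome code: ", paste(bad_out, collapse = ", "), call. = FALSE)
  if (nrow(x$reac) && any(is.na(x$reac$pt_code) | x$reac$pt_code <= 0))
    stop("pt_code must be a positive integer", call. = FALSE)
  for (tab in c("drug", "reac", "hist")) {
    orphan <- setdiff(unique(x[[tab]]$case_id), x$demo$case_id)
    if (length(orphan))
      stop(tab, " table references case_id absent from demo: ",
           paste(utils::head(orphan, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.srs_dataset <- function(x, ...) {
  cat("<srs_dataset> ", nrow(x$demo), " reports | ",
      nrow(x$drug), " drug records | ",
      nrow(x$reac), " reactions | ",
      nrow(x$hist), " history rows\n", sep = "")
  invisible(x)
}

#' Number of reports (the analysis denominator)
#'
#' @param x an \code{srs_dataset}.
#' @return integer count of demo rows.
#' @export
n_reports <- function(x) {
  stopifnot(inherits(x, "srs_dataset"))
  nrow(x$demo)
}

#' Default source-code mapping
#'
#' Identity mapping from canonical role/outcome tokens to themselves.
#' Real extracts carry source-language labels; supply a YAML file with
#' \code{role_codes:} and \code{outcome_codes:} sections mapping source
#' strings to the canonical tokens and pass it to
#' \code{\link{read_srs_dataset}}.
#'
#' @return list with \code{role_codes} and \code{outcome_codes} named
#'   character vectors (source label -> canonical token).
#' @export
default_code_map <- function() {
  list(role_codes = setNames(ROLE_CODES, ROLE_CODES),
       outcome_codes = setNames(OUTCOME_CODES, OUTCOME_CODES))
}

#' Read a code-mapping file
#'
#' @param path YAML file with \code{role_codes} / \code{outcome_codes}
#'   maps from source labels to canonical tokens.
#' @return list in the format of \code{\link{default_code_map}}.
#' @export
read_code_map <- function(path) {
  raw <- yaml::read_yaml(path)
  map <- default_code_map()
  for (sec in c("role_codes", "outcome_codes")) {
    if (!is.null(raw[[sec]])) {
      extra <- unlist(raw[[sec]])
      bad <- setdiff(extra, if (sec == "role_codes") ROLE_CODES else OUTCOME_CODES)
      if (length(bad))
        stop("mapping file targets unknown canonical token(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      map[[sec]] <- c(map[[sec]], extra)
    }
  }
  map
}

apply_code_map <- function(x, map) {
  hit <- x %in% names(map)
  x[hit] <- unname(map[x[hit]])
  x
}

#' Read the four-table dataset from delimited files
#'
#' Files are comma-separated UTF-8 with a header row (set \code{encoding}
#' for other source encodings). Rows whose mandatory fields fail to parse
#' (bad dates, unknown role/outcome codes after mapping, non-positive PT
#' codes) are dropped and counted; the count is attached as attribute
#' \code{n_rejected} and reported via a warning.
#'
#' @param paths named list/vector with elements \code{demo}, \code{drug},
#'   \code{reac}, \code{hist} giving file paths.
#' @param code_map mapping of source role/outcome labels to canonical
#'   tokens, as from \code{\link{read_code_map}}.
#' @param encoding file encoding passed to the reader.
#' @return a validated \code{srs_dataset} with attribute
#'   \code{n_rejected} (named integer per table).
#' @export
read_srs_dataset <- function(paths, code_map = default_code_map(),
                             encoding = "UTF-8") {
  for (tab in c("demo", "drug", "reac", "hist"))
    if (is.null(paths[[tab]]) || !file.exists(paths[[tab]]))
      stop("missing input file for table ", sQuote(tab), call. = FALSE)
  rd <- function(p) utils::read.csv(p, colClasses = "character",
                                    fileEncoding = encoding,
                                    check.names = FALSE)
  demo <- rd(paths$demo); drug <- rd(paths$drug)
  reac <- rd(paths$reac); hist <- rd(paths$hist)
  rejected <- c(demo = 0L, drug = 0L, reac = 0L, hist = 0L)

  drug$role_code <- apply_code_map(drug$role_code, code_map$role_codes)
  reac$outcome <- apply_code_map(reac$outcome, code_map$outcome_codes)

  ok_date <- function(x) !nzchar(x) | !is.na(date_completeness(x))
  if (nrow(drug)) {
    drug$drug_seq <- suppressWarnings(as.integer(drug$drug_seq))
    keep <- !is.na(drug$drug_seq) & drug$drug_seq >= 1L &
      drug$role_code %in% ROLE_CODES &
      ok_date(drug$start_date) & ok_date(drug$end_date)
    rejected["drug"] <- sum(!keep)
    drug <- drug[keep, , drop = FALSE]
  } else drug$drug_seq <- integer(0)
  if (nrow(reac)) {
    reac$pt_code <- suppressWarnings(as.integer(reac$pt_code))
    keep <- !is.na(reac$pt_code) & reac$pt_code > 0L &
      reac$outcome %in% OUTCOME_CODES & ok_date(reac$onset_date)
    rejected["reac"] <- sum(!keep)
    reac <- reac[keep, , drop = FALSE]
  } else reac$pt_code <- integer(0)
  if (sum(rejected) > 0)
    warning(sum(rejected), " record(s) rejected during parsing (",
            paste(names(rejected), rejected, sep = "=", collapse = ", "),
            ")", call. = FALSE)
  out <- new_srs_dataset(demo, drug, reac, hist)
  attr(out, "n_rejected") <- rejected
  out
}

#' Write the four-table dataset to delimited files
#'
#' Inverse of \code{\link{read_srs_dataset}}: writing then reading back
#' yields an equal dataset (round-trip identity), including partial
#' dates, which are serialised at their stored precision.
#'
#' @param x a validated \code{srs_dataset}.
#' @param paths named list/vector with elements \code{demo}, \code{drug},
#'   \code{reac}, \code{hist} giving output file paths.
#' @return \code{paths}, invisibly.
#' @export
write_srs_dataset <- function(x, paths) {
  validate_srs_dataset(x)
  for (tab in c("demo", "drug", "reac", "hist"))
    if (is.null(paths[[tab]]))
      stop("no output path for table ", sQuote(tab), call. = FALSE)
  for (tab in c("demo", "drug", "reac", "hist"))
    utils::write.csv(x[[tab]], paths[[tab]], row.names = FALSE,
                     fileEncoding = "UTF-8", quote = TRUE, na = "")
  invisible(paths)
}
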